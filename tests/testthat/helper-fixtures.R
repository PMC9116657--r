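# Small handcrafted deposit: 3 squares, two strata, all four categories.
make_small_deposit <- function() {
  deposit(tibble::tibble(
    us = c(11L, 11L, 11L, 11L, 11L, 12L),
    cut = c("I", "I", "II", NA, "roof", NA),
    row = c("G", "G", "G", "F", "A", "B"),
    column = c(5L, 5L, 4L, 3L, 26L, 27L),
    size_class = c("lt20", "ge20", "ge20", "lt20", "lt20", "tooth"),
    region = c("undetermined", "cranial", "postcranial", "undetermined",
               "undetermined", "tooth"),
    weight_g = c(100, 25, 60, 10, 5, 2)
  ))
}

# Independent brute-force oracle for the inverse weight budget: exhaustive
# search over unit counts, minimising |modelled - observed|; ties go to the
# larger count (the half-up convention).
brute_force_mni <- function(scenario, observed_total_g, max_units = NULL) {
  contrib <- cremains::per_capita_contribution(scenario)$contribution_g
  ratios <- scenario$classes$ratio
  unit <- sum(ratios * contrib)
  if (is.null(max_units)) max_units <- ceiling(observed_total_g / unit) + 2
  n <- 0:max_units
  err <- abs(n * unit - observed_total_g)
  best <- n[err == min(err)]
  n_star <- max(best)
  list(unit_count = n_star, mni = n_star * sum(ratios))
}

# Random scenario for property tests (classes, contributions, ratios).
random_scenario <- function() {
  k <- sample(1:4, 1)
  classes <- purrr::map_dfr(seq_len(k), function(i) {
    cremains::age_sex_class(
      name = paste0("class", i),
      expected_mass_g = stats::runif(1, 50, 3000),
      ratio = sample(1:5, 1)
    )
  })
  cremains::demographic_scenario(classes, mode = "primary",
                                 label = "random")
}

expect_deposit_equal <- function(a, b) {
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_identical(attr(a, "row_alphabet"), attr(b, "row_alphabet"))
  expect_identical(attr(a, "n_cols"), attr(b, "n_cols"))
  expect_equal(attr(a, "cell_size"), attr(b, "cell_size"))
}
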