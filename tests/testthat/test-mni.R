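test_that("per-capita contributions follow the depositional mode", {
  s <- salorno_scenarios()
  a <- per_capita_contribution(s$salorno_a)
  expect_equal(a$contribution_g, c(2500, 1800, 500))
  b <- per_capita_contribution(s$salorno_b)
  expect_equal(b$contribution_g, c(2500 - 1695, 1800 - 1443, 157))
  bp <- per_capita_contribution(s$salorno_b_printed)
  expect_equal(bp$contribution_g, c(805, 357, 343))
  # complete collection leaves nothing
  full <- demographic_scenario(
    age_sex_class("x", 1000, collected_mass_g = 1000), "residual")
  expect_equal(per_capita_contribution(full)$contribution_g, 0)
  # over-collection is a model error
  over <- demographic_scenario(
    age_sex_class("x", 1000, collected_mass_g = 1200), "residual")
  expect_error(per_capita_contribution(over),
               class = "cremains_model_error")
})

test_that("forward weight reproduces both published budget equations", {
  s <- salorno_scenarios()
  expect_identical(forward_weight(s$salorno_a, c(12, 12, 24)), 63600)
  expect_identical(forward_weight(s$salorno_b, c(43, 43, 86)), 63468)
  expect_equal(forward_weight(s$salorno_a, c(0, 0, 0)), 0)
  # named counts are matched by class
  expect_equal(forward_weight(s$salorno_a,
                              c(subadult = 24, adult_male = 12,
                                adult_female = 12)), 63600)
  expect_error(forward_weight(s$salorno_a, c(1, 2)),
               class = "cremains_validation_error")
  expect_error(forward_weight(s$salorno_a, c(-1, 0, 0)),
               class = "cremains_validation_error")
})

test_that("inverse solver returns the published MNIs at 63,555 g", {
  s <- salorno_scenarios()
  sol_a <- solve_mni(s$salorno_a, 63555)
  expect_equal(sol_a$unit_count, 12)
  expect_equal(sol_a$counts$count, c(12, 12, 24))
  expect_equal(sol_a$mni, 48)
  expect_equal(sol_a$modelled_mass_g, 63600)
  expect_equal(sol_a$misfit_g, 45)

  sol_b <- solve_mni(s$salorno_b, 63555)
  expect_equal(sol_b$unit_count, 43)
  expect_equal(sol_b$counts$count, c(43, 43, 86))
  expect_equal(sol_b$mni, 172)
  expect_equal(sol_b$modelled_mass_g, 63468)

  expect_equal(solve_mni(s$salorno_a, 0)$mni, 0)
  # floor semantics give the strict lower reading
  expect_equal(solve_mni(s$salorno_a, 63555, rounding = "floor")$mni, 44)
  expect_equal(solve_mni(s$salorno_a, 63555, rounding = "ceil")$mni, 48)
})

test_that("solver equals the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    sc <- random_scenario()
    observed <- runif(1, 0, 50000)
    sol <- solve_mni(sc, observed)
    oracle <- brute_force_mni(sc, observed)
    expect_equal(sol$unit_count, oracle$unit_count)
    expect_equal(sol$mni, oracle$mni)
  }
})

test_that("solver is exact on forward-generated totals, monotone and homogeneous", {
  set.seed(77)
  for (i in 1:50) {
    sc <- random_scenario()
    n <- sample(0:500, 1)
    total <- forward_weight(sc, n * sc$classes$ratio)
    expect_equal(solve_mni(sc, total)$unit_count, n)
    # homogeneity: scaling masses and observation leaves the count fixed
    c0 <- runif(1, 0.1, 10)
    sc2 <- demographic_scenario(
      dplyr::mutate(sc$classes, expected_mass_g = expected_mass_g * c0),
      mode = sc$mode)
    expect_equal(solve_mni(sc2, total * c0)$unit_count, n)
  }
  s <- salorno_scenarios()$salorno_a
  mnis <- vapply(seq(0, 2e5, length.out = 80),
                 function(w) solve_mni(s, w)$mni, double(1))
  expect_true(all(diff(mnis) >= 0))
})

test_that("generational capacity model is plain arithmetic with guards", {
  g <- generational_deaths(200, 25, 6)
  expect_equal(g$generations, 8)
  expect_equal(g$deaths, 48)
  g2 <- generational_deaths(100, 25, 4)
  expect_equal(g2$generations, 4)
  expect_equal(g2$deaths, 16)
  expect_error(generational_deaths(0, 25, 6),
               class = "cremains_domain_error")
  expect_error(generational_deaths(200, -1, 6),
               class = "cremains_domain_error")
})

test_that("hypothesis comparison is order-equivariant and verdict-free", {
  s <- salorno_scenarios()
  cmp <- compare_hypotheses(63555, s)
  expect_equal(nrow(cmp), 3)
  expect_equal(cmp$mni[1:2], c(48, 172))
  rev_cmp <- compare_hypotheses(63555, rev(s))
  expect_equal(rev_cmp$label, rev(cmp$label))
  expect_equal(rev_cmp$mni, rev(cmp$mni))
  expect_equal(sort(rev_cmp$misfit_rank), sort(cmp$misfit_rank))
  single <- compare_hypotheses(63555, s$salorno_a)
  expect_equal(nrow(single), 1)
  expect_false(any(grepl("verdict", names(cmp))))
})

test_that("scenario ratios reduce to smallest integer terms", {
  doubled <- demographic_scenario(
    dplyr::bind_rows(
      age_sex_class("m", 2500, ratio = 2),
      age_sex_class("f", 1800, ratio = 2),
      age_sex_class("s", 500, ratio = 4)
    ), "primary")
  expect_equal(doubled$classes$ratio, c(1, 1, 2))
  expect_error(
    demographic_scenario(age_sex_class("m", 100, ratio = 0), "primary"),
    class = "cremains_validation_error")
  expect_error(
    demographic_scenario(dplyr::bind_rows(age_sex_class("m", 1),
                                          age_sex_class("m", 2)),
                         "primary"),
    class = "cremains_validation_error")
})

test_that("shipped YAML configs load to the same scenarios", {
  s <- salorno_scenarios()
  for (pair in list(
    c("salorno_scenario_a.yaml", "salorno_a"),
    c("salorno_scenario_b_reproduced.yaml", "salorno_b"),
    c("salorno_scenario_b_printed.yaml", "salorno_b_printed")
  )) {
    path <- system.file("extdata", pair[1], package = "cremains")
    expect_true(nzchar(path))
    cfg <- read_scenario_config(path)
    expect_equal(cfg$mode, s[[pair[2]]]$mode)
    expect_equal(per_capita_contribution(cfg),
                 per_capita_contribution(s[[pair[2]]]))
    expect_equal(cfg$classes$ratio, s[[pair[2]]]$classes$ratio)
  }
})

test_that("tidy and glance expose the solution as tibbles", {
  sol <- solve_mni(salorno_scenarios()$salorno_a, 63555)
  td <- tidy(sol)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$mass_g), sol$modelled_mass_g)
  gl <- glance(sol)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$mni, 48)
  expect_equal(gl$misfit_g, gl$modelled_mass_g - gl$observed_total_g)
})
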