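make_cluster_deposit <- function() {
  # core pair G4/G5 plus two satellite groups:
  # A1-A2 (edge-adjacent) and C10/D11 (corner-adjacent only)
  deposit(tibble::tibble(
    us = 11L, cut = NA_character_,
    row = c("G", "G", "A", "A", "C", "D"),
    column = c(4L, 5L, 1L, 2L, 10L, 11L),
    size_class = c("lt20", "ge20", "lt20", "ge20", "lt20", "ge20"),
    region = c("undetermined", "postcranial", "undetermined", "cranial",
               "undetermined", "postcranial"),
    weight_g = c(300, 100, 68, 50, 30, 10)
  ))
}

test_that("weight map conserves filtered totals over a complete grid", {
  d <- simulate_deposit(simulation_params(seed = 2))
  m <- weight_map(d)
  expect_s3_class(m, "grid_map")
  expect_equal(nrow(m), 18 * 28)
  expect_equal(sum(m$weight_g), total_weight(d), tolerance = 1e-9)
  m11 <- weight_map(d, us = 11)
  expect_equal(sum(m11$weight_g), total_weight(d, us = 11),
               tolerance = 1e-9)
  expect_warning(weight_map(d, us = 19), class = "cremains_empty_map")

  one <- deposit(tibble::tibble(us = 11L, cut = NA_character_, row = "F",
                                column = 3L, size_class = "lt20",
                                region = "undetermined", weight_g = 10))
  mo <- weight_map(one)
  expect_equal(sum(mo$weight_g > 0), 1)
  expect_equal(mo$weight_g[mo$square == "F3"], 10)
})

test_that("transects run in grid order and partition the map", {
  d <- make_cluster_deposit()
  m <- weight_map(d)
  tg <- transect(m, "row", "G")
  expect_equal(nrow(tg), 28)
  expect_equal(tg$position, 1:28)
  expect_equal(tg$weight_g[tg$position == 4], 300)
  t5 <- transect(m, "column", 5)
  expect_equal(nrow(t5), 18)
  expect_equal(t5$position, LETTERS[1:18])
  # all row transects together partition the map total
  rows_sum <- sum(vapply(LETTERS[1:18],
                         function(r) sum(transect(m, "row", r)$weight_g),
                         double(1)))
  expect_equal(rows_sum, sum(m$weight_g), tolerance = 1e-9)
  expect_error(transect(m, "row", "Z"),
               class = "cremains_validation_error")
  expect_error(transect(m, "column", 99),
               class = "cremains_validation_error")
  # an all-zero map yields an all-zero transect
  mz <- weight_map(deposit())
  expect_true(all(transect(mz, "row", "A")$weight_g == 0))
})

test_that("hotspot ranking is a permutation of cells with lexical ties", {
  d <- make_cluster_deposit()
  m <- weight_map(d)
  top <- top_squares(m, k = 3)
  expect_equal(top$square, c("G4", "G5", "A1"))
  expect_equal(top$weight_g, c(300, 100, 68))
  # maximum of all transects equals the top square
  expect_equal(max(m$weight_g), top$weight_g[1])
  # k beyond the non-zero count returns all non-zero squares, no invention
  all_nz <- top_squares(m, k = 100)
  expect_equal(nrow(all_nz), 6)
  expect_setequal(all_nz$square, c("G4", "G5", "A1", "A2", "C10", "D11"))
  # ties break by row letter then column
  tie <- deposit(tibble::tibble(
    us = 11L, cut = NA_character_, row = c("B", "A", "A"),
    column = c(1L, 9L, 2L), size_class = "lt20",
    region = "undetermined", weight_g = 5
  ))
  expect_equal(top_squares(weight_map(tie), k = 3)$square,
               c("A2", "A9", "B1"))
})

test_that("region statistics report totals, means and metric extent", {
  d <- make_cluster_deposit()
  m <- weight_map(d)
  core <- region_stats(m, c("F3", "F4", "F5", "G3", "G4", "G5",
                            "H3", "H4", "H5"))
  expect_equal(core$n_squares, 9)
  expect_equal(core$total_g, 400)
  expect_equal(core$mean_g * core$n_squares, core$total_g)
  expect_equal(core$extent_row_m, 0.75)
  expect_equal(core$extent_col_m, 0.75)
  one <- region_stats(m, "G4")
  expect_equal(one$total_g, 300)
  expect_equal(one$mean_g, 300)
  expect_equal(c(one$extent_row_m, one$extent_col_m), c(0.25, 0.25))
  expect_error(region_stats(m, character()),
               class = "cremains_validation_error")
  expect_error(region_stats(m, "Q99"),
               class = "cremains_validation_error")
})

test_that("peripheral clusters honour connectivity and partition cells", {
  d <- make_cluster_deposit()
  core <- c("G4", "G5")
  cl8 <- peripheral_clusters(d, core = core, connectivity = 8)
  expect_equal(nrow(cl8), 2)
  expect_setequal(unlist(cl8$squares), c("A1", "A2", "C10", "D11"))
  a <- cl8[vapply(cl8$squares, function(s) "A1" %in% s, logical(1)), ]
  expect_equal(a$weight_g, 118)
  expect_equal(a$fragmentation_index, 68 / 50 * 100)
  # 4-connectivity splits the diagonal pair
  cl4 <- peripheral_clusters(d, core = core, connectivity = 4)
  expect_equal(nrow(cl4), 3)
  # every non-zero non-core cell appears in exactly one cluster
  all_sq <- unlist(cl4$squares)
  expect_equal(sort(all_sq), sort(c("A1", "A2", "C10", "D11")))
  expect_false(anyDuplicated(all_sq) > 0)
  # subadditivity against the map total
  expect_lte(sum(cl8$weight_g) + region_stats(weight_map(d), core)$total_g,
             total_weight(d) + 1e-9)
  # core-only map yields no clusters
  core_only <- filter_deposit(d)
  core_only <- deposit(tibble::as_tibble(core_only)[
    core_only$row == "G", ])
  expect_equal(nrow(peripheral_clusters(core_only, core = core)), 0)
})

test_that("explicit groupings are scored without an adjacency rule", {
  d <- make_cluster_deposit()
  # a field-recorded 'accumulation' need not be grid-connected
  cs <- cluster_stats(d, members = c("A1", "D11"))
  expect_equal(cs$weight_g, 78)
  expect_equal(cs$fragmentation_index, 68 / 10 * 100)
  expect_equal(cs$n_squares, 2)
})

test_that("regional CPC pools weights over member squares", {
  d <- make_cluster_deposit()
  r <- regional_cpc(d, members = c("A1", "A2", "G4", "G5"))
  expect_equal(r$value, 50 / 100 * 100)
  expect_true(r$defined)
  # region with no post-cranial weight is flagged, not an error
  u <- regional_cpc(d, members = "A2")
  expect_false(u$defined)
  # equal cranial and post-cranial weight gives 100
  eq <- deposit(tibble::tibble(
    us = 11L, cut = NA_character_, row = "C", column = 3L,
    size_class = "ge20", region = c("cranial", "postcranial"),
    weight_g = 33
  ))
  expect_equal(regional_cpc(eq)$value, 100)
})

test_that("core detection returns the bounding rectangle of hot cells", {
  d <- make_cluster_deposit()
  m <- weight_map(d)
  core <- detect_core(m, fraction = 0.3)  # G4 (300) and G5 (100)
  expect_setequal(core, c("G4", "G5"))
  wide <- detect_core(m, fraction = 0.1)  # includes A1/A2 -> rectangle
  expect_true(all(c("A1", "G5") %in% wide))
  expect_equal(detect_core(weight_map(deposit())), character())
})

test_that("map centroid recovers the simulated pyre centre within 1 cell", {
  params <- simulation_params(generations = 5, family_size = 4,
                              pyre_centre = "J12", seed = 21)
  d <- simulate_deposit(params)  # 20 individuals
  cen <- map_centroid(weight_map(d))
  expect_lt(abs(cen$row_centre - (match("J", LETTERS) - 0.5)), 1)
  expect_lt(abs(cen$col_centre - 11.5), 1)
  expect_error(map_centroid(weight_map(deposit())),
               class = "cremains_domain_error")
})
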