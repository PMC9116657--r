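#' Run the full deposit analysis
#'
#' Orchestrates the pipeline over one deposit: totals and per-stratum /
#' size-class / region breakdowns, pooled fragmentation and CPC indices
#' with the cranial share, the density map's hotspot ranking, core-region
#' statistics, peripheral clusters, and the weight-budget MNI comparison
#' across the supplied demographic scenarios. Every number in the report is
#' recomputable from the deposit and the arguments alone; the report
#' carries no timestamps, so repeated runs on the same input serialise
#' identically.
#'
#' @param deposit A [deposit()].
#' @param scenarios Named list of [demographic_scenario()] objects
#'   (default [salorno_scenarios()]).
#' @param us Optional stratigraphic-unit filter applied to the spatial
#'   stage (totals and indices always cover the whole deposit).
#' @param core Character vector of square labels for the core region;
#'   `NULL` uses [detect_core()].
#' @param core_fraction Threshold for [detect_core()].
#' @param top_k Hotspots to rank.
#' @param connectivity Passed to [peripheral_clusters()].
#' @param rounding Passed to [solve_mni()].
#' @return A list of class `"cremains_report"` with tibble elements
#'   `totals`, `strata`, `composition`, `regions`, `indices`, `hotspots`,
#'   `core`, `clusters`, `mni`, and a `provenance` list.
#' @examples
#' d <- simulate_deposit(simulation_params(seed = 1))
#' rep <- run_analysis(d)
#' rep$mni
#' @export
run_analysis <- function(deposit,
                         scenarios = salorno_scenarios(),
                         us = NULL,
                         core = NULL,
                         core_fraction = 0.1,
                         top_k = 5,
                         connectivity = 8,
                         rounding = "nearest") {
  stopifnot(is_deposit(deposit))
  total <- total_weight(deposit)
  strata <- aggregate_weights(deposit, by = "stratum")
  composition <- if (total > 0) composition_shares(deposit) else NULL
  regions <- aggregate_weights(deposit, by = "region")
  indices <- if (total > 0) {
    dplyr::bind_cols(
      pooled_indices(deposit),
      pooled_indices(deposit, method = "mean") |>
        dplyr::select(fragmentation_index_mean = "fragmentation_index",
                      cpc_index_mean = "cpc_index")
    )
  } else NULL

  map <- weight_map(deposit, us = us)
  hotspots <- top_squares(map, k = top_k)
  core_members <- core %||% detect_core(map, fraction = core_fraction)
  core_stats <- if (length(core_members) > 0) {
    region_stats(map, core_members)
  } else NULL
  clusters <- peripheral_clusters(deposit, core = core_members,
                                  connectivity = connectivity, us = us)

  mni <- compare_hypotheses(total, scenarios, rounding = rounding)

  structure(
    list(
      totals = tibble::tibble(total_g = total,
                              n_records = nrow(deposit),
                              n_nonzero_squares = sum(map$weight_g > 0)),
      strata = strata,
      composition = composition,
      regions = regions,
      indices = indices,
      hotspots = hotspots,
      core = core_stats,
      clusters = clusters,
      mni = tibble::as_tibble(mni),
      provenance = list(
        tool = "cremains",
        version = as.character(utils::packageVersion("cremains")),
        deposit_hash = rlang::hash(tibble::as_tibble(deposit)),
        grid = deposit_grid(deposit),
        us_filter = us,
        core = sort(core_members),
        rounding = rounding
      )
    ),
    class = "cremains_report"
  )
}

#' @export
print.cremains_report <- function(x, ...) {
  cat("<cremains_report>\n")
  cat("  total: ", round_half_up(x$totals$total_g, 1), " g over ",
      x$totals$n_nonzero_squares, " squares (", x$totals$n_records,
      " records)\n", sep = "")
  if (!is.null(x$composition)) {
    sh <- round_half_up(x$composition$share_pct, 1)
    cat("  composition: ", paste0(x$composition$size_class, " ", sh, "%",
                                  collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$indices)) {
    cat("  fragmentation index ",
        round_half_up(x$indices$fragmentation_index, 0),
        "; CPC ", round_half_up(x$indices$cpc_index, 1),
        "; cranial share ", round_half_up(x$indices$cranial_share_pct, 1),
        "%\n", sep = "")
  }
  if (nrow(x$hotspots) > 0) {
    cat("  hotspots: ",
        paste0(x$hotspots$square, " (",
               round_half_up(x$hotspots$weight_g, 1), " g)",
               collapse = ", "), "\n", sep = "")
  }
  cat("  MNI by scenario:\n")
  print(x$mni[c("label", "mode", "mni", "modelled_mass_g", "misfit_g")])
  invisible(x)
}

#' Serialise a report to JSON
#'
#' Deterministic JSON export (no timestamps): the same report always
#' produces byte-identical output.
#'
#' @param report A [run_analysis()] report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "cremains_report"))
  out <- report
  class(out) <- NULL
  # list columns of square labels serialise as arrays
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
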