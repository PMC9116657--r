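#' Fragmentation and cranial/post-cranial indices
#'
#' Two weight-ratio indices summarise a cremated-bone assemblage:
#'
#' * the **fragmentation index**, the weight of fragments below 20 mm over
#'   the weight of fragments above 20 mm, times 100 — the higher the value,
#'   the more comminuted the sample;
#' * the **CPC (cranial/post-cranial) index**, the weight of cranial
#'   fragments over the weight of post-cranial fragments, times 100 — a
#'   probe for post-cremation selection or displacement of skull remains.
#'
#' Both are percent-scaled ratios of two non-negative weights. A zero
#' denominator yields a *flagged* undefined result (`defined = FALSE`,
#' `value = NA`) rather than an error, so maps over sparse excavation grids
#' — where many peripheral squares hold a single size class — do not abort.
#'
#' @param w_lt20,w_ge20 Weights (grams) of the sub-20 mm and over-20 mm
#'   fragment subgroups.
#' @param w_cranial,w_postcranial Weights (grams) of identified cranial and
#'   post-cranial fragments.
#' @return A tibble with one row per input: `value` (percent-scaled ratio,
#'   full precision), `numerator_g`, `denominator_g`, `defined`.
#' @examples
#' fragmentation_index(76.6, 22.5)  # ~340
#' cpc_index(2317, 12007)           # ~19.3
#' @export
fragmentation_index <- function(w_lt20, w_ge20) {
  weight_ratio_index(w_lt20, w_ge20)
}

#' @rdname fragmentation_index
#' @export
cpc_index <- function(w_cranial, w_postcranial) {
  weight_ratio_index(w_cranial, w_postcranial)
}

weight_ratio_index <- function(numerator, denominator) {
  check_nonneg(numerator, "numerator weight")
  check_nonneg(denominator, "denominator weight")
  n <- max(length(numerator), length(denominator))
  numerator <- rep_len(as.double(numerator), n)
  denominator <- rep_len(as.double(denominator), n)
  defined <- denominator > 0
  tibble::tibble(
    value = ifelse(defined, numerator / denominator * 100, NA_real_),
    numerator_g = numerator,
    denominator_g = denominator,
    defined = defined
  )
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    rlang::abort(paste(what, "must be non-negative"),
                 class = "cremains_domain_error")
  }
}

#' Cranial share of identified weight
#'
#' Percentage of the identified (cranial + post-cranial) weight that is
#' cranial. Related to the CPC index by
#' `cpc / 100 = share / (100 - share)`.
#'
#' @inheritParams fragmentation_index
#' @return A tibble with `value` (percent), `numerator_g`, `denominator_g`,
#'   `defined` (`FALSE` when both weights are zero).
#' @examples
#' cranial_share(2317, 12007)  # ~16.2
#' @export
cranial_share <- function(w_cranial, w_postcranial) {
  check_nonneg(w_cranial, "cranial weight")
  check_nonneg(w_postcranial, "post-cranial weight")
  weight_ratio_index(w_cranial, w_cranial + w_postcranial)
}

#' Size-class composition of a deposit
#'
#' Shares of total weight held by the three disjoint size categories:
#' fragments below 20 mm, fragments above 20 mm, and teeth (tracked
#' separately from the size split). Shares sum to 100.
#'
#' @param deposit A [deposit()] with positive total weight.
#' @return A tibble with one row per size class: `size_class`, `weight_g`,
#'   `share_pct`.
#' @export
composition_shares <- function(deposit) {
  stopifnot(is_deposit(deposit))
  total <- total_weight(deposit)
  if (total <= 0) {
    rlang::abort("composition shares are undefined for an empty deposit",
                 class = "cremains_domain_error")
  }
  tibble::as_tibble(deposit) |>
    dplyr::group_by(size_class = factor(.data$size_class,
                                        levels = SIZE_CLASSES)) |>
    dplyr::summarise(weight_g = sum(.data$weight_g), .groups = "drop") |>
    tidyr::complete(.data$size_class,
                    fill = list(weight_g = 0)) |>
    dplyr::mutate(size_class = as.character(.data$size_class),
                  share_pct = .data$weight_g / total * 100)
}

#' Pooled indices over a deposit subset
#'
#' Computes the pooled (summed-weight) fragmentation index, CPC index and
#' cranial share over an optional square subset and stratum filter of a
#' deposit. Pooling sums weights before taking the ratio; this is the
#' package's default "average" index for a region. A per-square mean of
#' defined square-level ratios is available via `method = "mean"`.
#'
#' @param deposit A [deposit()].
#' @param members Optional character vector of square labels (e.g.
#'   `c("G4", "G5")`) restricting the computation.
#' @param us Optional stratigraphic-unit filter.
#' @param method `"pooled"` (ratio of summed weights, default) or `"mean"`
#'   (mean of per-square ratios, squares with a zero denominator excluded).
#' @return A one-row tibble: `weight_g`, `fragmentation_index`, `cpc_index`,
#'   `cranial_share_pct`, with `NA` where the relevant denominator is zero.
#' @export
pooled_indices <- function(deposit, members = NULL, us = NULL,
                           method = c("pooled", "mean")) {
  stopifnot(is_deposit(deposit))
  method <- match.arg(method)
  d <- filter_deposit(deposit, us = us)
  tbl <- tibble::as_tibble(d)
  if (!is.null(members)) {
    sq <- parse_squares(members, attr(deposit, "row_alphabet"),
                        attr(deposit, "n_cols"))
    tbl <- dplyr::semi_join(tbl, sq, by = c("row", "column"))
  }
  if (method == "pooled") {
    w <- function(...) sum(tbl$weight_g[ok_rows(tbl, ...)])
    frag <- fragmentation_index(w(size_class = "lt20"),
                                w(size_class = "ge20"))
    cpc <- cpc_index(w(region = "cranial"), w(region = "postcranial"))
    share <- cranial_share(w(region = "cranial"), w(region = "postcranial"))
    tibble::tibble(
      weight_g = sum(tbl$weight_g),
      fragmentation_index = frag$value,
      cpc_index = cpc$value,
      cranial_share_pct = share$value
    )
  } else {
    per <- tbl |>
      dplyr::group_by(.data$row, .data$column) |>
      dplyr::summarise(
        lt20 = sum(.data$weight_g[.data$size_class == "lt20"]),
        ge20 = sum(.data$weight_g[.data$size_class == "ge20"]),
        cran = sum(.data$weight_g[.data$region == "cranial"]),
        post = sum(.data$weight_g[.data$region == "postcranial"]),
        .groups = "drop"
      )
    mean_defined <- function(num, den) {
      ok <- den > 0
      if (!any(ok)) NA_real_ else mean(num[ok] / den[ok] * 100)
    }
    tibble::tibble(
      weight_g = sum(tbl$weight_g),
      fragmentation_index = mean_defined(per$lt20, per$ge20),
      cpc_index = mean_defined(per$cran, per$post),
      cranial_share_pct = mean_defined(per$cran, per$cran + per$post)
    )
  }
}

ok_rows <- function(tbl, size_class = NULL, region = NULL) {
  keep <- rep(TRUE, nrow(tbl))
  if (!is.null(size_class)) keep <- keep & tbl$size_class %in% size_class
  if (!is.null(region)) keep <- keep & tbl$region %in% region
  keep
}

#' Round half away from zero
#'
#' Presentation rounding for reported indices and shares: exact halves round
#' away from zero (so 0.5 -> 1), unlike base [round()]'s round-half-to-even.
#' Internal index values are kept at full precision; rounding is applied only
#' when formatting reports.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
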