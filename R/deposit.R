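#' Build a cremation-deposit table
#'
#' A deposit is the unit of analysis: every weighed lot of cremated bone from
#' an excavation, recorded in long format (one row per lot) against the grid
#' and stratigraphic coding used in the field. Squares are addressed by a
#' letter row and a numeric column over a rectangular grid of square cells
#' (default 18 letter rows A-R by 28 columns of 0.25 m cells); strata by a
#' stratigraphic-unit number (US) and an optional cut label.
#'
#' Duplicate `(us, cut, row, column, size_class, region)` keys are collapsed
#' by summing their weights, so a valid deposit has unique keys. Rows are
#' stored in a canonical sort order (us, cut, row, column, size_class,
#' region), which makes writes byte-stable.
#'
#' @param records A data frame with columns `us` (integer stratigraphic unit,
#'   10-20), `cut` (character: `"I"`-`"IV"`, `"roof"`, or `NA`), `row`
#'   (letter), `column` (integer), `size_class` (`"lt20"`, `"ge20"` or
#'   `"tooth"`), `region` (`"cranial"`, `"postcranial"`, `"tooth"` or
#'   `"undetermined"`), `weight_g` (non-negative grams). `NULL` gives an
#'   empty deposit.
#' @param row_alphabet Character vector of admissible row letters, in grid
#'   order. Default `LETTERS[1:18]` (A-R).
#' @param n_cols Number of grid columns. Default 28.
#' @param cell_size Cell side length in metres. Default 0.25.
#' @return A tibble of class `"deposit"` carrying the grid geometry as
#'   attributes (see [deposit_grid()]).
#' @examples
#' d <- deposit(tibble::tibble(
#'   us = 11L, cut = "I", row = "G", column = 5L,
#'   size_class = "lt20", region = "undetermined", weight_g = 120
#' ))
#' total_weight(d)
#' @export
deposit <- function(records = NULL,
                    row_alphabet = LETTERS[1:18],
                    n_cols = 28,
                    cell_size = 0.25) {
  if (is.null(records)) {
    records <- tibble::tibble(
      us = integer(), cut = character(), row = character(),
      column = integer(), size_class = character(), region = character(),
      weight_g = double()
    )
  }
  records <- tibble::as_tibble(records)
  validate_records(records, row_alphabet, n_cols)

  records <- records |>
    dplyr::mutate(
      us = as.integer(.data$us),
      cut = as.character(.data$cut),
      row = as.character(.data$row),
      column = as.integer(.data$column),
      weight_g = as.double(.data$weight_g)
    ) |>
    dplyr::group_by(
      .data$us, .data$cut, .data$row, .data$column,
      .data$size_class, .data$region
    ) |>
    dplyr::summarise(weight_g = sum(.data$weight_g), .groups = "drop") |>
    arrange_canonical(row_alphabet)

  structure(
    records,
    row_alphabet = row_alphabet,
    n_cols = as.integer(n_cols),
    cell_size = cell_size,
    class = c("deposit", class(tibble::tibble()))
  )
}

#' @rdname deposit
#' @param x Object to coerce or test.
#' @param ... Passed to [deposit()].
#' @export
as_deposit <- function(x, ...) {
  if (is_deposit(x)) return(x)
  deposit(x, ...)
}

#' @rdname deposit
#' @export
is_deposit <- function(x) inherits(x, "deposit")

#' Grid geometry of a deposit or grid map
#'
#' @param x A deposit or grid map.
#' @return A list with `row_alphabet`, `n_rows`, `n_cols`, `cell_size`,
#'   `n_squares` and `area_m2`.
#' @export
deposit_grid <- function(x) {
  ra <- attr(x, "row_alphabet")
  nc <- attr(x, "n_cols")
  cs <- attr(x, "cell_size")
  list(
    row_alphabet = ra,
    n_rows = length(ra),
    n_cols = nc,
    cell_size = cs,
    n_squares = length(ra) * nc,
    area_m2 = length(ra) * nc * cs^2
  )
}

SIZE_CLASSES <- c("lt20", "ge20", "tooth")
REGIONS <- c("cranial", "postcranial", "tooth", "undetermined")
CUTS <- c("I", "II", "III", "IV", "roof")

validate_records <- function(records, row_alphabet, n_cols, where = "record") {
  needed <- c("us", "cut", "row", "column", "size_class", "region", "weight_g")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("missing column(s): ", paste(missing, collapse = ", ")),
      class = "cremains_format_error"
    )
  }
  if (nrow(records) == 0) return(invisible(records))

  problems <- character()
  flag <- function(bad, msg, detail) {
    if (any(bad, na.rm = TRUE)) {
      idx <- which(bad | is.na(bad))
      idx <- idx[seq_len(min(5, length(idx)))]
      problems <<- c(problems, paste0(
        msg, " in ", where, "(s) ", paste(idx, collapse = ", "),
        " [", paste(detail[idx], collapse = ", "), "]"
      ))
    }
  }
  flag(!(records$row %in% row_alphabet), "unknown row letter", records$row)
  col_ok <- !is.na(records$column) & records$column >= 1 &
    records$column <= n_cols & records$column == floor(records$column)
  flag(!col_ok, "column outside grid", records$column)
  flag(
    !is.na(records$cut) & !(records$cut %in% CUTS),
    "unknown cut label", records$cut
  )
  us_ok <- !is.na(records$us) & records$us >= 10 & records$us <= 20
  flag(!us_ok, "stratigraphic unit outside 10..20", records$us)
  flag(!(records$size_class %in% SIZE_CLASSES), "unknown size class",
       records$size_class)
  flag(!(records$region %in% REGIONS), "unknown region", records$region)
  w_ok <- !is.na(records$weight_g) & is.finite(records$weight_g) &
    records$weight_g >= 0
  flag(!w_ok, "negative or non-numeric weight", records$weight_g)
  tooth_ok <- (records$size_class == "tooth") == (records$region == "tooth")
  flag(!tooth_ok, "tooth region must pair with tooth size class",
       paste(records$size_class, records$region, sep = "/"))

  if (length(problems) > 0) {
    rlang::abort(
      c("invalid deposit records", problems),
      class = "cremains_validation_error"
    )
  }
  invisible(records)
}

arrange_canonical <- function(records, row_alphabet) {
  dplyr::arrange(
    records,
    .data$us,
    match(.data$cut, CUTS),
    match(.data$row, row_alphabet),
    .data$column,
    match(.data$size_class, SIZE_CLASSES),
    match(.data$region, REGIONS)
  )
}

#' Filter a deposit by stratum, size class or region
#'
#' Each argument keeps only matching records; `NULL` means no restriction.
#' Filtering on `us` alone keeps every cut of that unit (including a "roof"
#' surface layer).
#'
#' @param deposit A [deposit()].
#' @param us Integer vector of stratigraphic units to keep.
#' @param cut Character vector of cut labels to keep (`NA` matches records
#'   without a cut).
#' @param size_class,region Character vectors of categories to keep.
#' @return A deposit containing the matching records.
#' @export
filter_deposit <- function(deposit, us = NULL, cut = NULL,
                           size_class = NULL, region = NULL) {
  stopifnot(is_deposit(deposit))
  keep <- rep(TRUE, nrow(deposit))
  if (!is.null(us)) keep <- keep & deposit$us %in% us
  if (!is.null(cut)) keep <- keep & (deposit$cut %in% cut |
                                       (anyNA(cut) & is.na(deposit$cut)))
  if (!is.null(size_class)) keep <- keep & deposit$size_class %in% size_class
  if (!is.null(region)) keep <- keep & deposit$region %in% region
  out <- tibble::as_tibble(deposit)[keep, ]
  deposit(out,
          row_alphabet = attr(deposit, "row_alphabet"),
          n_cols = attr(deposit, "n_cols"),
          cell_size = attr(deposit, "cell_size"))
}

#' Total weight of a deposit
#'
#' @inheritParams filter_deposit
#' @return Total weight in grams of the records matching the filters
#'   (0 for an empty selection).
#' @examples
#' d <- simulate_deposit(simulation_params(seed = 1))
#' total_weight(d)
#' total_weight(d, size_class = "tooth")
#' @export
total_weight <- function(deposit, us = NULL, cut = NULL,
                         size_class = NULL, region = NULL) {
  f <- filter_deposit(deposit, us = us, cut = cut,
                      size_class = size_class, region = region)
  sum(f$weight_g)
}

#' Aggregate deposit weights by a grouping key
#'
#' Groups partition the records, so group sums always add up to
#' [total_weight()]. `share_pct` is each group's percentage of the total
#' (full precision; round for presentation with [round_half_up()]).
#'
#' @param deposit A [deposit()].
#' @param by One of `"square"`, `"stratum"`, `"size_class"`, `"region"`.
#' @return A tibble with the grouping column(s), `weight_g` and `share_pct`.
#' @export
aggregate_weights <- function(deposit,
                              by = c("square", "stratum", "size_class",
                                     "region")) {
  stopifnot(is_deposit(deposit))
  by <- match.arg(by)
  tbl <- tibble::as_tibble(deposit)
  keys <- switch(by,
    square = c("row", "column"),
    stratum = c("us", "cut"),
    size_class = "size_class",
    region = "region"
  )
  out <- tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(weight_g = sum(.data$weight_g), .groups = "drop")
  if (by == "square") {
    out <- dplyr::mutate(out,
                         square = square_label(.data$row, .data$column),
                         .before = 1)
  }
  total <- sum(out$weight_g)
  dplyr::mutate(out,
                share_pct = if (total > 0) .data$weight_g / total * 100
                            else NA_real_)
}
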