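#' Read a deposit table from CSV
#'
#' The canonical on-disk format is a long-format CSV with header
#' `us, cut, row, column, size_class, region, weight_g`: one weighed lot per
#' row, weights in grams, `cut` empty where a unit is not subdivided. The
#' same column contract is accepted from XLSX workbooks (the format used for
#' published per-square weight tables) via [read_deposit_xlsx()].
#'
#' Malformed rows are reported with their data-row numbers and offending
#' values; blank or unrecognised `cut` cells load as `NA` rather than
#' erroring.
#'
#' @param path Path to a CSV file.
#' @inheritParams deposit
#' @return A validated [deposit()].
#' @export
read_deposit_csv <- function(path,
                             row_alphabet = LETTERS[1:18],
                             n_cols = 28,
                             cell_size = 0.25) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(c("us", "cut", "row", "column", "size_class",
                       "region", "weight_g"), tolower(trimws(header)))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("input table lacks column(s): ",
             paste(missing, collapse = ", ")),
      class = "cremains_format_error"
    )
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      us = readr::col_integer(),
      cut = readr::col_character(),
      row = readr::col_character(),
      column = readr::col_integer(),
      size_class = readr::col_character(),
      region = readr::col_character(),
      weight_g = readr::col_double()
    )
  )
  build_deposit_from_raw(raw, row_alphabet, n_cols, cell_size)
}

#' @rdname read_deposit_csv
#' @param sheet Worksheet to read (first by default).
#' @export
read_deposit_xlsx <- function(path, sheet = 1,
                              row_alphabet = LETTERS[1:18],
                              n_cols = 28,
                              cell_size = 0.25) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    rlang::abort("reading XLSX requires the readxl package",
                 class = "cremains_format_error")
  }
  raw <- readxl::read_excel(path, sheet = sheet)
  build_deposit_from_raw(raw, row_alphabet, n_cols, cell_size)
}

build_deposit_from_raw <- function(raw, row_alphabet, n_cols, cell_size) {
  raw <- tibble::as_tibble(raw)
  names(raw) <- tolower(trimws(names(raw)))
  needed <- c("us", "cut", "row", "column", "size_class", "region",
              "weight_g")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("input table lacks column(s): ",
             paste(missing, collapse = ", ")),
      class = "cremains_format_error"
    )
  }
  raw <- raw[needed]
  raw$cut <- as.character(raw$cut)
  raw$cut[!is.na(raw$cut) & !(raw$cut %in% CUTS)] <- NA_character_
  raw$row <- toupper(trimws(as.character(raw$row)))
  validate_records(raw, row_alphabet, n_cols, where = "data row")
  deposit(raw, row_alphabet = row_alphabet, n_cols = n_cols,
          cell_size = cell_size)
}

#' Write a deposit table to CSV
#'
#' Records are written in the canonical sort order (us, cut, row, column,
#' size_class, region), so repeated writes of the same deposit are
#' byte-identical and `read_deposit_csv(write_deposit_csv(d))` returns a
#' deposit equal to `d`.
#'
#' @param deposit A [deposit()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deposit_csv <- function(deposit, path) {
  stopifnot(is_deposit(deposit))
  readr::write_csv(tibble::as_tibble(deposit), path, na = "")
  invisible(path)
}
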