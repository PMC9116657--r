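#' Square labels and their parts
#'
#' Grid squares are addressed in field notation as a row letter followed by
#' a column number, e.g. `"G5"`.
#'
#' @param row Character vector of row letters.
#' @param column Integer vector of column numbers.
#' @export
square_label <- function(row, column) paste0(row, column)

#' @rdname square_label
#' @param x Character vector of square labels.
#' @param row_alphabet Admissible row letters.
#' @param n_cols Number of grid columns.
#' @return `parse_squares()` returns a tibble with `square`, `row`,
#'   `column`.
#' @export
parse_squares <- function(x, row_alphabet = LETTERS[1:18], n_cols = 28) {
  m <- regmatches(x, regexec("^([[:alpha:]])([0-9]+)$", toupper(trimws(x))))
  bad <- vapply(m, length, integer(1)) != 3
  out <- tibble::tibble(
    square = toupper(trimws(x)),
    row = vapply(m, function(p) if (length(p) == 3) p[2] else NA_character_,
                 character(1)),
    column = vapply(m, function(p) if (length(p) == 3) as.integer(p[3])
                    else NA_integer_, integer(1))
  )
  bad <- bad | !(out$row %in% row_alphabet) |
    is.na(out$column) | out$column < 1 | out$column > n_cols
  if (any(bad)) {
    rlang::abort(
      paste0("square label(s) outside the grid: ",
             paste(unique(x[bad]), collapse = ", ")),
      class = "cremains_validation_error"
    )
  }
  out
}

#' Per-square weight map
#'
#' Sums record weights into a complete grid of cells (squares with no
#' records are 0), optionally restricted to a stratigraphic unit and/or
#' categories. Filtering on `us` alone keeps all its cuts, including a
#' "roof" surface layer.
#'
#' @inheritParams filter_deposit
#' @return A tibble of class `"grid_map"` with one row per grid cell:
#'   `row`, `column`, `square`, `weight_g`; grid geometry is carried in
#'   attributes (see [deposit_grid()]). The cell sum equals the filtered
#'   [total_weight()].
#' @examples
#' d <- simulate_deposit(simulation_params(seed = 1))
#' m <- weight_map(d, us = 11)
#' top_squares(m, k = 3)
#' @export
weight_map <- function(deposit, us = NULL, cut = NULL,
                       size_class = NULL, region = NULL) {
  stopifnot(is_deposit(deposit))
  d <- filter_deposit(deposit, us = us, cut = cut,
                      size_class = size_class, region = region)
  if (!is.null(us) && nrow(d) == 0 && nrow(deposit) > 0) {
    rlang::warn("stratum filter matched no records; map is empty",
                class = "cremains_empty_map")
  }
  ra <- attr(deposit, "row_alphabet")
  nc <- attr(deposit, "n_cols")
  cells <- tidyr::expand_grid(row = ra, column = seq_len(nc))
  sums <- tibble::as_tibble(d) |>
    dplyr::group_by(.data$row, .data$column) |>
    dplyr::summarise(weight_g = sum(.data$weight_g), .groups = "drop")
  out <- cells |>
    dplyr::left_join(sums, by = c("row", "column")) |>
    dplyr::mutate(
      weight_g = dplyr::coalesce(.data$weight_g, 0),
      square = square_label(.data$row, .data$column)
    ) |>
    dplyr::select("row", "column", "square", "weight_g")
  structure(out,
            row_alphabet = ra, n_cols = nc,
            cell_size = attr(deposit, "cell_size"),
            class = c("grid_map", class(tibble::tibble())))
}

#' Transect through a weight map
#'
#' Extracts the ordered series of cell weights along one grid row (ordered
#' by increasing column) or one grid column (ordered by row letter), the
#' standard way of profiling how bone density falls off away from the pyre
#' centre.
#'
#' @param map A [weight_map()].
#' @param axis `"row"` (transect along a lettered row) or `"column"`
#'   (transect along a numbered column).
#' @param label The row letter or column number to profile.
#' @return A tibble with `position` (column number or row letter), `square`
#'   and `weight_g`, in grid order.
#' @export
transect <- function(map, axis = c("row", "column"), label) {
  stopifnot(inherits(map, "grid_map"))
  axis <- match.arg(axis)
  ra <- attr(map, "row_alphabet")
  if (axis == "row") {
    label <- toupper(as.character(label))
    if (!label %in% ra) {
      rlang::abort(paste0("row '", label, "' is outside the grid"),
                   class = "cremains_validation_error")
    }
    out <- map[map$row == label, ] |>
      dplyr::arrange(.data$column) |>
      dplyr::transmute(position = .data$column, square = .data$square,
                       weight_g = .data$weight_g)
  } else {
    label <- as.integer(label)
    if (is.na(label) || label < 1 || label > attr(map, "n_cols")) {
      rlang::abort(paste0("column ", label, " is outside the grid"),
                   class = "cremains_validation_error")
    }
    out <- map[map$column == label, ] |>
      dplyr::arrange(match(.data$row, ra)) |>
      dplyr::transmute(position = .data$row, square = .data$square,
                       weight_g = .data$weight_g)
  }
  tibble::as_tibble(out)
}

#' Rank the heaviest squares
#'
#' @param map A [weight_map()].
#' @param k Number of squares to return (capped at the number of squares
#'   with non-zero weight).
#' @return A tibble of the top `k` non-zero cells, descending by weight,
#'   ties broken by row letter then column number.
#' @export
top_squares <- function(map, k = 5) {
  stopifnot(inherits(map, "grid_map"), k >= 1)
  ra <- attr(map, "row_alphabet")
  nz <- tibble::as_tibble(map)[map$weight_g > 0, ]
  nz |>
    dplyr::arrange(dplyr::desc(.data$weight_g), match(.data$row, ra),
                   .data$column) |>
    utils::head(n = k)
}

#' Summary statistics of a square region
#'
#' @param map A [weight_map()].
#' @param members Character vector of square labels forming the region.
#' @return A one-row tibble: `n_squares`, `total_g`, `mean_g`,
#'   `extent_row_m` x `extent_col_m` (bounding spans in metres), and the
#'   member labels as a list column.
#' @examples
#' d <- simulate_deposit(simulation_params(seed = 1))
#' m <- weight_map(d)
#' region_stats(m, c("F3", "F4", "F5", "G3", "G4", "G5", "H3", "H4", "H5"))
#' @export
region_stats <- function(map, members) {
  stopifnot(inherits(map, "grid_map"))
  if (length(members) == 0) {
    rlang::abort("region must contain at least one square",
                 class = "cremains_validation_error")
  }
  ra <- attr(map, "row_alphabet")
  cs <- attr(map, "cell_size")
  sq <- parse_squares(members, ra, attr(map, "n_cols"))
  cells <- dplyr::semi_join(tibble::as_tibble(map), sq,
                            by = c("row", "column"))
  ri <- match(sq$row, ra)
  tibble::tibble(
    n_squares = nrow(sq),
    total_g = sum(cells$weight_g),
    mean_g = sum(cells$weight_g) / nrow(sq),
    extent_row_m = (diff(range(ri)) + 1) * cs,
    extent_col_m = (diff(range(sq$column)) + 1) * cs,
    squares = list(sort(unique(sq$square)))
  )
}

#' Delineate the high-density core of a map
#'
#' Default rule: the smallest axis-aligned rectangle containing every cell
#' whose weight is at least `fraction` of the map maximum. A region known
#' from the field record can instead be supplied to downstream functions as
#' an explicit member list.
#'
#' @param map A [weight_map()].
#' @param fraction Threshold as a fraction of the maximum cell weight
#'   (default 0.1).
#' @return Character vector of square labels covering the core rectangle.
#' @export
detect_core <- function(map, fraction = 0.1) {
  stopifnot(inherits(map, "grid_map"), fraction > 0, fraction <= 1)
  ra <- attr(map, "row_alphabet")
  mx <- max(map$weight_g)
  if (mx <= 0) return(character())
  hot <- map[map$weight_g >= fraction * mx, ]
  ri <- range(match(hot$row, ra))
  ci <- range(hot$column)
  grid <- tidyr::expand_grid(row = ra[ri[1]:ri[2]], column = ci[1]:ci[2])
  square_label(grid$row, grid$column)
}

#' Detect peripheral bone clusters outside a core region
#'
#' Finds connected components (4- or 8-connectivity) of non-zero squares
#' disjoint from the core, and reports each with its pooled weight and
#' pooled fragmentation index. Field-recorded accumulations are often
#' grouped visually rather than by strict grid adjacency, so an explicit
#' grouping can be scored instead with [cluster_stats()].
#'
#' @param deposit A [deposit()].
#' @param core Character vector of square labels forming the core (e.g.
#'   from [detect_core()]).
#' @param connectivity 4 (edge-sharing) or 8 (edge- or corner-sharing).
#' @inheritParams pooled_indices
#' @return A tibble with one row per cluster: `cluster`, `n_squares`,
#'   `weight_g`, `fragmentation_index`, `cpc_index`, `cranial_share_pct`,
#'   and member `squares` as a list column. Empty tibble when there are no
#'   clusters.
#' @export
peripheral_clusters <- function(deposit, core, connectivity = 8, us = NULL) {
  stopifnot(is_deposit(deposit), connectivity %in% c(4, 8))
  ra <- attr(deposit, "row_alphabet")
  nc <- attr(deposit, "n_cols")
  map <- weight_map(filter_deposit(deposit, us = us))
  core_sq <- if (length(core) > 0) parse_squares(core, ra, nc)$square
             else character()
  nz <- map[map$weight_g > 0 & !(map$square %in% core_sq), ]
  if (nrow(nz) == 0) {
    return(tibble::tibble(cluster = integer(), n_squares = integer(),
                          weight_g = double(),
                          fragmentation_index = double(),
                          cpc_index = double(),
                          cranial_share_pct = double(), squares = list()))
  }
  comp <- grid_components(match(nz$row, ra), nz$column, connectivity)
  groups <- split(nz$square, comp)
  purrr::imap_dfr(groups, function(sqs, id) {
    stats <- pooled_indices(deposit, members = sqs, us = us)
    tibble::tibble(
      cluster = as.integer(id),
      n_squares = length(sqs),
      weight_g = stats$weight_g,
      fragmentation_index = stats$fragmentation_index,
      cpc_index = stats$cpc_index,
      cranial_share_pct = stats$cranial_share_pct,
      squares = list(sort(sqs))
    )
  }) |>
    dplyr::arrange(dplyr::desc(.data$weight_g)) |>
    dplyr::mutate(cluster = dplyr::row_number())
}

# flood fill over (row index, column) cells; returns component id per cell
grid_components <- function(ri, ci, connectivity = 8) {
  n <- length(ri)
  key <- paste(ri, ci)
  idx <- stats::setNames(seq_len(n), key)
  if (connectivity == 4) {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  } else {
    dr <- rep(-1:1, times = 3); dc <- rep(-1:1, each = 3)
    keep <- !(dr == 0 & dc == 0); dr <- dr[keep]; dc <- dc[keep]
  }
  comp <- integer(n)
  current <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    current <- current + 1L
    queue <- start
    comp[start] <- current
    while (length(queue) > 0) {
      cell <- queue[1]; queue <- queue[-1]
      nb_key <- paste(ri[cell] + dr, ci[cell] + dc)
      nb <- idx[nb_key]
      nb <- nb[!is.na(nb)]
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- current
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Score an explicit square grouping
#'
#' Pooled weight, fragmentation index, CPC index and cranial share for a
#' square set given a priori (for instance an accumulation delineated during
#' excavation), regardless of grid adjacency.
#'
#' @inheritParams pooled_indices
#' @return A one-row tibble like a [peripheral_clusters()] row.
#' @export
cluster_stats <- function(deposit, members, us = NULL) {
  stopifnot(is_deposit(deposit))
  sq <- parse_squares(members, attr(deposit, "row_alphabet"),
                      attr(deposit, "n_cols"))
  stats <- pooled_indices(deposit, members = members, us = us)
  tibble::tibble(
    n_squares = nrow(sq),
    weight_g = stats$weight_g,
    fragmentation_index = stats$fragmentation_index,
    cpc_index = stats$cpc_index,
    cranial_share_pct = stats$cranial_share_pct,
    squares = list(sort(unique(sq$square)))
  )
}

#' Regional cranial/post-cranial index
#'
#' Pooled (or per-square mean) CPC index over a square subset of a deposit.
#'
#' @inheritParams pooled_indices
#' @return A one-row tibble as returned by [cpc_index()] for the pooled
#'   weights (`method = "pooled"`), or with `value` the mean of defined
#'   per-square CPC ratios (`method = "mean"`, `numerator_g`/`denominator_g`
#'   still the pooled weights).
#' @export
regional_cpc <- function(deposit, members = NULL, us = NULL,
                         method = c("pooled", "mean")) {
  method <- match.arg(method)
  d <- filter_deposit(deposit, us = us)
  tbl <- tibble::as_tibble(d)
  if (!is.null(members)) {
    sq <- parse_squares(members, attr(deposit, "row_alphabet"),
                        attr(deposit, "n_cols"))
    tbl <- dplyr::semi_join(tbl, sq, by = c("row", "column"))
  }
  cran <- sum(tbl$weight_g[tbl$region == "cranial"])
  post <- sum(tbl$weight_g[tbl$region == "postcranial"])
  out <- cpc_index(cran, post)
  if (method == "mean") {
    out$value <- pooled_indices(deposit, members = members, us = us,
                                method = "mean")$cpc_index
    out$defined <- !is.na(out$value)
  }
  out
}

#' Weighted centroid of a weight map
#'
#' @param map A [weight_map()] with positive total weight.
#' @return A one-row tibble with the mass-weighted centroid in continuous
#'   cell coordinates (`row_centre`, `col_centre`; cell i spans i-1..i) and
#'   in metres (`x_m` along columns, `y_m` along rows).
#' @export
map_centroid <- function(map) {
  stopifnot(inherits(map, "grid_map"))
  total <- sum(map$weight_g)
  if (total <= 0) {
    rlang::abort("centroid is undefined for an all-zero map",
                 class = "cremains_domain_error")
  }
  ra <- attr(map, "row_alphabet")
  cs <- attr(map, "cell_size")
  ri <- match(map$row, ra) - 0.5
  ci <- map$column - 0.5
  tibble::tibble(
    row_centre = sum(ri * map$weight_g) / total,
    col_centre = sum(ci * map$weight_g) / total,
    x_m = sum(ci * map$weight_g) / total * cs,
    y_m = sum(ri * map$weight_g) / total * cs
  )
}
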