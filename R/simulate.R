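#' Parameters for the synthetic deposit generator
#'
#' Defines the community, fragmentation and scatter structure of a
#' simulated cremation deposit. Defaults encode the study conditions the
#' analysis pipeline assumes: a small stable community of 8 generations of
#' nuclear families of 6 (48 deaths), a 1:1 adult sex ratio with 50%
#' subadult mortality, complete burnt-skeleton masses of 2,500 / 1,800 /
#' 500 g for adult males / adult females / subadults (spreads set to a
#' quarter of the cited modern adult ranges: sd 250 g for adults, 125 g for
#' subadults), a pooled fragmentation-index target of 340, a 15% cranial
#' share of identifiable mass, a 0.8% tooth share, and an isotropic
#' Gaussian scatter (sd 0.5 m) around a pyre centre at square G5 of an
#' 18 x 28 grid of 0.25 m cells.
#'
#' @param generations Number of generations using the site.
#' @param family_size Deaths per generation.
#' @param sex_ratio Probability an adult death is male.
#' @param subadult_fraction Probability a death is subadult.
#' @param class_masses Tibble with `class`, `mean_g`, `sd_g` giving the
#'   per-class cremated-skeleton mass distribution (normal truncated at 0).
#' @param class_assignment `"expected"` (deterministic counts at the
#'   expected proportions, default) or `"stochastic"` (each death sampled
#'   independently).
#' @param fragmentation_target Expected pooled fragmentation index.
#' @param frag_concentration Beta concentration of the per-individual
#'   sub-20-mm mass fraction; `Inf` = no noise.
#' @param cranial_fraction Expected cranial share of identifiable
#'   (over-20 mm) mass.
#' @param cranial_concentration Beta concentration of the per-individual
#'   cranial fraction; `Inf` = no noise.
#' @param tooth_fraction Tooth share of each individual's mass
#'   (deterministic).
#' @param pyre_centre Square label of the pyre centre.
#' @param scatter_sd Isotropic Gaussian scatter of lots around the centre,
#'   in metres (0 puts everything in the centre cell).
#' @param n_lots Number of lots each individual's per-category mass is
#'   split into before scatter (so the per-square table resembles field
#'   recording of many small weighed bags).
#' @param collection Optional named numeric vector: grams collected per
#'   individual of each class before deposition (residual-mode deposits).
#'   Collection takes over-20-mm mass first, then sub-20-mm, then teeth.
#' @param us Stratigraphic unit written on generated records.
#' @param row_alphabet,n_cols,cell_size Grid geometry, as in [deposit()].
#' @param seed Master seed; per-stage streams are derived from it, so each
#'   stage is independently reproducible.
#' @return A validated list of class `"simulation_params"`.
#' @export
simulation_params <- function(generations = 8,
                              family_size = 6,
                              sex_ratio = 0.5,
                              subadult_fraction = 0.5,
                              class_masses = default_class_masses(),
                              class_assignment = c("expected", "stochastic"),
                              fragmentation_target = 340,
                              frag_concentration = 50,
                              cranial_fraction = 0.15,
                              cranial_concentration = 50,
                              tooth_fraction = 0.008,
                              pyre_centre = "G5",
                              scatter_sd = 0.5,
                              n_lots = 20,
                              collection = NULL,
                              us = 11,
                              row_alphabet = LETTERS[1:18],
                              n_cols = 28,
                              cell_size = 0.25,
                              seed = 1L) {
  class_assignment <- match.arg(class_assignment)
  class_masses <- tibble::as_tibble(class_masses)
  stopifnot(
    generations > 0, family_size > 0,
    sex_ratio >= 0, sex_ratio <= 1,
    subadult_fraction >= 0, subadult_fraction <= 1,
    all(c("class", "mean_g", "sd_g") %in% names(class_masses)),
    all(class_masses$mean_g > 0), all(class_masses$sd_g >= 0),
    fragmentation_target > 0, frag_concentration > 0,
    cranial_fraction > 0, cranial_fraction < 1, cranial_concentration > 0,
    tooth_fraction >= 0, tooth_fraction < 1,
    scatter_sd >= 0, n_lots >= 1
  )
  parse_squares(pyre_centre, row_alphabet, n_cols)  # errors if outside grid
  if (!is.null(collection)) {
    stopifnot(!is.null(names(collection)),
              all(names(collection) %in% class_masses$class),
              all(collection >= 0))
  }
  structure(
    list(
      generations = generations, family_size = family_size,
      sex_ratio = sex_ratio, subadult_fraction = subadult_fraction,
      class_masses = class_masses, class_assignment = class_assignment,
      fragmentation_target = fragmentation_target,
      frag_concentration = frag_concentration,
      cranial_fraction = cranial_fraction,
      cranial_concentration = cranial_concentration,
      tooth_fraction = tooth_fraction,
      pyre_centre = pyre_centre, scatter_sd = scatter_sd,
      n_lots = as.integer(n_lots), collection = collection,
      us = as.integer(us),
      row_alphabet = row_alphabet, n_cols = as.integer(n_cols),
      cell_size = cell_size, seed = as.integer(seed)
    ),
    class = "simulation_params"
  )
}

#' @rdname simulation_params
#' @export
default_class_masses <- function() {
  tibble::tibble(
    class = c("adult_male", "adult_female", "subadult"),
    mean_g = c(2500, 1800, 500),
    sd_g = c(250, 250, 125)
  )
}

#' Simulate the deaths of a small community
#'
#' Draws `generations * family_size` individuals with an age/sex class and
#' a cremated-skeleton mass. Under `"expected"` assignment the class counts
#' are fixed at the expected proportions (rounded), so the demographic
#' structure holds exactly; under `"stochastic"` each death is sampled
#' independently. Masses are normal draws truncated at zero (exact means
#' when `sd_g` is 0).
#'
#' @param params A [simulation_params()].
#' @param seed Optional seed for this stage (defaults to a stream derived
#'   from `params$seed` when called via [simulate_deposit()]).
#' @return A roster tibble: `id`, `class`, `mass_g`.
#' @examples
#' simulate_community(simulation_params(seed = 7))
#' @export
simulate_community <- function(params, seed = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- round(params$generations * params$family_size)
  cm <- params$class_masses
  if (params$class_assignment == "expected") {
    n_sub <- round(n * params$subadult_fraction)
    n_ad <- n - n_sub
    n_male <- round(n_ad * params$sex_ratio)
    classes <- rep(c("adult_male", "adult_female", "subadult"),
                   c(n_male, n_ad - n_male, n_sub))
  } else {
    classes <- sample(
      c("adult_male", "adult_female", "subadult"), n, replace = TRUE,
      prob = c((1 - params$subadult_fraction) * params$sex_ratio,
               (1 - params$subadult_fraction) * (1 - params$sex_ratio),
               params$subadult_fraction)
    )
  }
  i <- match(classes, cm$class)
  if (anyNA(i)) {
    rlang::abort("class_masses must cover adult_male, adult_female, subadult",
                 class = "cremains_validation_error")
  }
  tibble::tibble(
    id = seq_len(n),
    class = classes,
    mass_g = rnorm_trunc0(n, cm$mean_g[i], cm$sd_g[i])
  )
}

# normal truncated at 0 by rejection; exact mean when sd = 0
rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Split individual skeletal mass into recording categories
#'
#' Partitions each cremated-skeleton mass into the four categories of the
#' field recording scheme — sub-20-mm (undetermined), over-20-mm cranial,
#' over-20-mm post-cranial, and tooth — conserving mass exactly. The
#' tooth share is deterministic; the sub-20-mm fraction of the remainder is
#' Beta-distributed with mean `target / (target + 100)` (so the pooled
#' fragmentation index converges to the target), and the cranial fraction
#' of the over-20-mm mass is Beta-distributed around `cranial_fraction`.
#' Infinite concentrations give exact fractions.
#'
#' @param mass_g Vector of individual cremated-skeleton masses (grams).
#' @inheritParams simulate_community
#' @return A tibble, one row per input mass: `lt20_g`, `ge20_cranial_g`,
#'   `ge20_postcranial_g`, `tooth_g`.
#' @export
fragment_individual <- function(mass_g, params, seed = NULL) {
  stopifnot(inherits(params, "simulation_params"), all(mass_g > 0))
  if (!is.null(seed)) set.seed(seed)
  n <- length(mass_g)
  p_lt <- params$fragmentation_target / (params$fragmentation_target + 100)
  lt_frac <- rbeta_or_exact(n, p_lt, params$frag_concentration)
  cr_frac <- rbeta_or_exact(n, params$cranial_fraction,
                            params$cranial_concentration)
  tooth <- params$tooth_fraction * mass_g
  rest <- mass_g - tooth
  lt20 <- lt_frac * rest
  ge20 <- rest - lt20
  tibble::tibble(
    lt20_g = lt20,
    ge20_cranial_g = cr_frac * ge20,
    ge20_postcranial_g = (1 - cr_frac) * ge20,
    tooth_g = tooth
  )
}

rbeta_or_exact <- function(n, mean, concentration) {
  if (is.infinite(concentration)) return(rep(mean, n))
  stats::rbeta(n, mean * concentration, (1 - mean) * concentration)
}

#' Scatter fragmented remains over the excavation grid
#'
#' Splits each individual's per-category mass into `n_lots` equal lots,
#' scatters each lot around the pyre centre by an isotropic 2-D Gaussian
#' (`scatter_sd` metres), quantises positions to grid cells and clips to
#' the grid (clipped mass lands in the nearest edge cell). When
#' `params$collection` is set, the collected mass is removed per individual
#' before deposition, taking over-20-mm mass first (cranial and
#' post-cranial in proportion), then sub-20-mm, then teeth — emulating an
#' ossilegium that favours large identifiable pieces.
#'
#' @param fragments A tibble as returned by [fragment_individual()], plus
#'   `id` and `class` columns from the roster.
#' @inheritParams simulate_community
#' @return A [deposit()] whose total equals the roster total minus any
#'   collected mass.
#' @export
deposit_spatially <- function(fragments, params, seed = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(seed)) set.seed(seed)
  frag <- tibble::as_tibble(fragments)
  needed <- c("class", "lt20_g", "ge20_cranial_g", "ge20_postcranial_g",
              "tooth_g")
  stopifnot(all(needed %in% names(frag)))
  if (!is.null(params$collection)) {
    frag <- apply_collection(frag, params$collection)
  }
  long <- frag |>
    dplyr::mutate(.id = dplyr::row_number()) |>
    tidyr::pivot_longer(dplyr::all_of(c("lt20_g", "ge20_cranial_g",
                                        "ge20_postcranial_g", "tooth_g")),
                        names_to = "category", values_to = "mass_g") |>
    dplyr::filter(.data$mass_g > 0)

  centre <- parse_squares(params$pyre_centre, params$row_alphabet,
                          params$n_cols)
  cs <- params$cell_size
  x0 <- (centre$column - 0.5) * cs
  y0 <- (match(centre$row, params$row_alphabet) - 0.5) * cs

  k <- params$n_lots
  lots <- long[rep(seq_len(nrow(long)), each = k), ]
  lots$mass_g <- lots$mass_g / k
  m <- nrow(lots)
  x <- x0 + stats::rnorm(m, 0, params$scatter_sd)
  y <- y0 + stats::rnorm(m, 0, params$scatter_sd)
  col <- pmin(pmax(ceiling(x / cs), 1L), params$n_cols)
  rowi <- pmin(pmax(ceiling(y / cs), 1L), length(params$row_alphabet))

  cat_map <- tibble::tibble(
    category = c("lt20_g", "ge20_cranial_g", "ge20_postcranial_g",
                 "tooth_g"),
    size_class = c("lt20", "ge20", "ge20", "tooth"),
    region = c("undetermined", "cranial", "postcranial", "tooth")
  )
  records <- tibble::tibble(
    us = params$us, cut = NA_character_,
    row = params$row_alphabet[rowi], column = as.integer(col),
    category = lots$category, weight_g = lots$mass_g
  ) |>
    dplyr::left_join(cat_map, by = "category") |>
    dplyr::select("us", "cut", "row", "column", "size_class", "region",
                  "weight_g")
  deposit(records, row_alphabet = params$row_alphabet,
          n_cols = params$n_cols, cell_size = params$cell_size)
}

# remove up to collection[class] grams per individual: ge20 first
# (cranial/post-cranial in proportion), then lt20, then tooth
apply_collection <- function(frag, collection) {
  target <- unname(collection[frag$class])
  target[is.na(target)] <- 0
  ge20 <- frag$ge20_cranial_g + frag$ge20_postcranial_g
  take_ge20 <- pmin(target, ge20)
  prop_cr <- ifelse(ge20 > 0, frag$ge20_cranial_g / ge20, 0)
  remaining <- target - take_ge20
  take_lt20 <- pmin(remaining, frag$lt20_g)
  remaining <- remaining - take_lt20
  take_tooth <- pmin(remaining, frag$tooth_g)
  frag$ge20_cranial_g <- frag$ge20_cranial_g - take_ge20 * prop_cr
  frag$ge20_postcranial_g <- frag$ge20_postcranial_g -
    take_ge20 * (1 - prop_cr)
  frag$lt20_g <- frag$lt20_g - take_lt20
  frag$tooth_g <- frag$tooth_g - take_tooth
  frag
}

#' Simulate a complete synthetic cremation deposit
#'
#' End-to-end composition of [simulate_community()],
#' [fragment_individual()] and [deposit_spatially()]. The master seed
#' derives three independent per-stage streams, so the whole pipeline and
#' each stage are reproducible.
#'
#' @inheritParams simulate_community
#' @param csv Optional path: when given, the deposit is also written with
#'   [write_deposit_csv()].
#' @return A [deposit()].
#' @examples
#' d <- simulate_deposit(simulation_params(seed = 42))
#' total_weight(d)
#' @export
simulate_deposit <- function(params, csv = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  stage_seeds <- sample.int(2147483646L, 3)
  roster <- simulate_community(params, seed = stage_seeds[1])
  frag <- fragment_individual(roster$mass_g, params, seed = stage_seeds[2])
  frag$id <- roster$id
  frag$class <- roster$class
  d <- deposit_spatially(frag, params, seed = stage_seeds[3])
  if (!is.null(csv)) write_deposit_csv(d, csv)
  d
}
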