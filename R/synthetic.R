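#' Configuration for the synthetic rating generator
#'
#' The generator emulates a list-based multidimensional norming study: items
#' split across lists, each rater rating every variable for one list's words,
#' eight semantic dimensions of which 1-8 are "relevant" per item, Gaussian
#' rater noise, optional careless (constant-response) raters and rare outlier
#' responses, and a semantic-diversity variable negatively coupled to latent
#' exclusivity.
#'
#' Defaults mirror a 964-word study design: 157 concrete filler items among
#' 964 total, 24 lists, at least 20 raters per list, and an E-to-SEM_DIV
#' population correlation of -0.47.
#'
#' @param n_items Total number of words (abstract + concrete fillers).
#' @param n_concrete Number of concrete filler items (rated but excluded from
#'   the exclusivity analysis).
#' @param n_lists Number of disjoint word lists.
#' @param raters_per_list Raters assigned to each list (>= 1; the study design
#'   this emulates guarantees >= 20 per word).
#' @param noise_sd SD of the per-response Gaussian noise, in rating-scale
#'   units. Rater offsets are drawn with SD `noise_sd / 2`.
#' @param careless_rate Proportion of raters replaced by constant responders.
#' @param outlier_rate Proportion of Likert responses pushed to the scale
#'   extreme opposite their item mean.
#' @param relevant_dim_count_weights Probability weights over 1..8 for the
#'   number of relevant dimensions per abstract item.
#' @param relevant_level_range Interval within (3.5, 7] for the true means of
#'   relevant dimensions.
#' @param irrelevant_level_range Interval within [1, 3.5] for the true means
#'   of irrelevant dimensions.
#' @param semdiv_coupling Target population correlation in [-1, 0] between
#'   latent exclusivity and latent semantic diversity.
#' @param dimension_families Optional list of disjoint character vectors of
#'   dimension names; when given, each item's relevant dimensions are drawn
#'   from a single family, planting a co-occurrence cluster structure.
#' @param seed Integer seed; all generator output is deterministic given it.
#' @return A named list of class `semdim_gencfg`.
#' @export
generator_config <- function(n_items = 964,
                             n_concrete = 157,
                             n_lists = 24,
                             raters_per_list = 20,
                             noise_sd = 1,
                             careless_rate = 0,
                             outlier_rate = 0,
                             relevant_dim_count_weights =
                               c(0.091, 0.19, 0.25, 0.28, 0.12, 0.05, 0.014, 0.005),
                             relevant_level_range = c(4.5, 6.8),
                             irrelevant_level_range = c(1.2, 3.2),
                             semdiv_coupling = -0.47,
                             dimension_families = NULL,
                             seed = 1L) {
  cfg <- list(
    n_items = n_items, n_concrete = n_concrete, n_lists = n_lists,
    raters_per_list = raters_per_list, noise_sd = noise_sd,
    careless_rate = careless_rate, outlier_rate = outlier_rate,
    relevant_dim_count_weights = relevant_dim_count_weights,
    relevant_level_range = relevant_level_range,
    irrelevant_level_range = irrelevant_level_range,
    semdiv_coupling = semdiv_coupling,
    dimension_families = dimension_families,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  stopifnot(
    cfg$n_items >= 1, cfg$n_concrete >= 0, cfg$n_concrete < cfg$n_items,
    cfg$n_lists >= 1, cfg$raters_per_list >= 1, cfg$noise_sd >= 0
  )
  if (cfg$careless_rate < 0 || cfg$careless_rate > 1 ||
      cfg$outlier_rate < 0 || cfg$outlier_rate > 1) {
    abort("`careless_rate` and `outlier_rate` must lie in [0, 1].")
  }
  w <- cfg$relevant_dim_count_weights
  if (length(w) != 8 || any(w < 0) || sum(w) <= 0) {
    abort("`relevant_dim_count_weights` must be 8 nonnegative weights.")
  }
  rr <- cfg$relevant_level_range
  ir <- cfg$irrelevant_level_range
  if (rr[1] <= 3.5 || rr[2] > 7 || rr[1] > rr[2]) {
    abort("`relevant_level_range` must lie within (3.5, 7].")
  }
  if (ir[1] < 1 || ir[2] > 3.5 || ir[1] > ir[2]) {
    abort("`irrelevant_level_range` must lie within [1, 3.5].")
  }
  if (cfg$semdiv_coupling < -1 || cfg$semdiv_coupling > 0) {
    abort("`semdiv_coupling` must lie in [-1, 0].")
  }
  if (!is.null(cfg$dimension_families)) {
    dims <- unlist(cfg$dimension_families)
    if (anyDuplicated(dims) || !all(dims %in% semantic_dimensions())) {
      abort("`dimension_families` must be disjoint subsets of semantic_dimensions().")
    }
  }
  structure(cfg, class = "semdim_gencfg")
}

#' Generate latent word profiles
#'
#' Draws, for each word, a set of relevant semantic dimensions (count from
#' `relevant_dim_count_weights`), true dimension means inside the relevant or
#' irrelevant level range, true means for the psycholinguistic and affective
#' variables, and a latent semantic-diversity value linearly coupled to the
#' word's latent exclusivity so that the population correlation between the
#' two equals `semdiv_coupling`. Concrete filler items get high concreteness
#' and imageability and uniformly low dimension means; their latent
#' exclusivity is `NA` (the statistic is defined for abstract words only).
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per word: `word`, `is_abstract`,
#'   `relevant_dims` (list-column), one column per variable holding the true
#'   mean, and `latent_E`.
#' @export
make_profiles <- function(config = generator_config()) {
  config <- validate_generator_config(unclass(config))
  set.seed(config$seed)
  dims <- semantic_dimensions()
  n <- config$n_items
  n_abs <- n - config$n_concrete
  is_abstract <- rep(c(TRUE, FALSE), c(n_abs, config$n_concrete))
  word <- sprintf("w%04d", seq_len(n))

  families <- config$dimension_families
  k <- integer(n)
  relevant <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is_abstract[i]) {
      relevant[[i]] <- character(0)
      next
    }
    pool <- if (is.null(families)) dims else
      families[[sample.int(length(families), 1)]]
    ki <- sample.int(8, 1, prob = config$relevant_dim_count_weights)
    ki <- min(ki, length(pool))
    k[i] <- ki
    relevant[[i]] <- sort(sample_safe(pool, ki))
  }

  dim_means <- matrix(
    runif(n * 8, config$irrelevant_level_range[1], config$irrelevant_level_range[2]),
    nrow = n, dimnames = list(NULL, dims)
  )
  for (i in seq_len(n)) {
    r <- relevant[[i]]
    if (length(r) > 0) {
      dim_means[i, r] <- runif(length(r), config$relevant_level_range[1],
                               config$relevant_level_range[2])
    }
  }

  latent_E <- apply(dim_means, 1, exclusivity_score)
  latent_E[!is_abstract] <- NA_real_

  # SEM_DIV: linear-Gaussian coupling to standardized latent E, so that the
  # population correlation equals semdiv_coupling; mapped to the 1-7 scale
  # around midpoint 4 with SD 0.8 (clamping is then rare enough not to
  # attenuate the correlation measurably).
  rho <- config$semdiv_coupling
  semdiv <- runif(n, 2.5, 5.5)
  if (n_abs >= 2 && sd(latent_E[is_abstract]) > 0) {
    zE <- as.numeric(scale(latent_E[is_abstract]))
    z <- rho * zE + sqrt(1 - rho^2) * rnorm(n_abs)
    semdiv[is_abstract] <- clamp(4 + 0.8 * z, 1, 7)
  }

  profiles <- tibble(
    word = word,
    is_abstract = is_abstract,
    relevant_dims = relevant,
    CNC = clamp(rnorm(n, ifelse(is_abstract, 3.0, 6.88),
                      ifelse(is_abstract, 1.0, 0.35)), 1, 7),
    IMG = clamp(rnorm(n, ifelse(is_abstract, 3.2, 6.87),
                      ifelse(is_abstract, 1.1, 0.35)), 1, 7),
    FAM = runif(n, 3, 6.8),
    SEM_DIV = semdiv,
    AoA = clamp(rnorm(n, 9, 3), 1, 18),
    VAL = runif(n, 2, 8),
    ARO = runif(n, 2, 8)
  )
  profiles <- bind_cols(profiles, as_tibble(dim_means))
  profiles$latent_E <- latent_E
  profiles
}

#' Simulate rater-level rating records from latent profiles
#'
#' Words are dealt round-robin into `n_lists` lists; each list receives
#' `raters_per_list` raters; each rater rates every registry variable for
#' every word of their list. A response is
#' `clamp(round(true_mean + rater_offset + noise), scale_min, scale_max)`
#' with half-away-from-zero rounding; rater offsets are `N(0, noise_sd/2)`.
#' Age of acquisition uses uniform noise on `[-2, 2] * noise_sd` years and is
#' bounded below by 0 only.
#'
#' @param profiles Output of [make_profiles()].
#' @param config The same [generator_config()].
#' @param registry Variable registry (defaults to [default_registry()]).
#' @return A tibble of rating records: `rater_id`, `list_id`, `word`,
#'   `variable`, `value`.
#' @export
simulate_ratings <- function(profiles, config = generator_config(),
                             registry = default_registry()) {
  assert_df(profiles, "profiles")
  config <- validate_generator_config(unclass(config))
  set.seed(config$seed + 1L)

  n <- nrow(profiles)
  list_id <- sprintf("L%02d", rep_len(seq_len(config$n_lists), n))
  word_list <- tibble(word = profiles$word, list_id = list_id)

  raters <- tidyr::crossing(
    list_id = sprintf("L%02d", seq_len(config$n_lists)),
    idx = seq_len(config$raters_per_list)
  ) |>
    mutate(
      rater_id = sprintf("%s_R%03d", .data$list_id, .data$idx),
      offset = rnorm(dplyr::n(), 0, config$noise_sd / 2)
    ) |>
    select(-"idx")

  long <- profiles |>
    select("word", dplyr::all_of(registry$name)) |>
    tidyr::pivot_longer(-"word", names_to = "variable", values_to = "true_mean") |>
    inner_join(word_list, by = "word")

  records <- inner_join(raters, long, by = "list_id",
                        relationship = "many-to-many")
  m <- nrow(records)
  scl <- registry[match(records$variable, registry$name), ]
  is_aoa <- scl$kind == "age_numeric"
  noise <- numeric(m)
  noise[!is_aoa] <- rnorm(sum(!is_aoa), 0, config$noise_sd)
  noise[is_aoa] <- runif(sum(is_aoa), -2 * config$noise_sd, 2 * config$noise_sd)
  raw <- round_half_away(records$true_mean + records$offset + noise)
  records$value <- clamp(raw, scl$scale_min, scl$scale_max)

  records |>
    select("rater_id", "list_id", "word", "variable", "value") |>
    arrange(.data$rater_id, .data$word, .data$variable)
}

#' Plant careless (constant-response) raters
#'
#' Replaces every Likert response of a `careless_rate` fraction of raters
#' (count rounded to nearest integer) by one constant value per rater, drawn
#' from 1..7. Age-of-acquisition responses are left untouched; the careless
#' rule does not count them either.
#'
#' @param records Rating records tibble.
#' @param config A [generator_config()] with `careless_rate > 0` (a rate of 0
#'   returns the input unchanged).
#' @param registry Variable registry.
#' @return A list with `records` (modified tibble) and `careless_raters`
#'   (character vector of altered rater ids).
#' @export
inject_careless <- function(records, config = generator_config(),
                            registry = default_registry()) {
  assert_df(records, "records")
  config <- validate_generator_config(unclass(config))
  raters <- sort(unique(records$rater_id))
  n_careless <- round(config$careless_rate * length(raters))
  if (n_careless == 0) {
    return(list(records = records, careless_raters = character(0)))
  }
  set.seed(config$seed + 2L)
  chosen <- sort(sample_safe(raters, n_careless))
  constants <- setNames(sample(1:7, n_careless, replace = TRUE), chosen)
  likert <- likert_variables(registry)
  hit <- records$rater_id %in% chosen & records$variable %in% likert
  records$value[hit] <- constants[records$rater_id[hit]]
  list(records = records, careless_raters = chosen)
}

#' Plant extreme outlier responses
#'
#' Pushes an `outlier_rate` fraction of Likert responses to the scale extreme
#' opposite their item mean (scale minimum when the item mean is above the
#' scale midpoint, maximum otherwise), so that planted outliers are maximally
#' distant from the item mean while staying within scale bounds.
#'
#' @inheritParams inject_careless
#' @return A list with `records` and `outliers`, a tibble of altered
#'   `(rater_id, word, variable)` triples.
#' @export
inject_outliers <- function(records, config = generator_config(),
                            registry = default_registry()) {
  assert_df(records, "records")
  config <- validate_generator_config(unclass(config))
  likert <- likert_variables(registry)
  eligible <- which(records$variable %in% likert)
  n_out <- round(config$outlier_rate * length(eligible))
  if (n_out == 0) {
    return(list(records = records,
                outliers = tibble(rater_id = character(0), word = character(0),
                                  variable = character(0))))
  }
  set.seed(config$seed + 3L)
  rows <- sort(sample_safe(eligible, n_out))

  cell_means <- records |>
    group_by(.data$word, .data$variable) |>
    summarise(cell_mean = mean(.data$value), .groups = "drop")
  tgt <- records[rows, ] |>
    left_join(cell_means, by = c("word", "variable"))
  scl <- registry[match(tgt$variable, registry$name), ]
  midpoint <- (scl$scale_min + scl$scale_max) / 2
  records$value[rows] <- ifelse(tgt$cell_mean > midpoint, scl$scale_min,
                                scl$scale_max)
  list(
    records = records,
    outliers = records[rows, c("rater_id", "word", "variable")]
  )
}

#' Write the generator's ground truth for a profile set
#'
#' Emits a TSV with one row per word: the word, its latent exclusivity and
#' its pipe-joined relevant dimension set, for use as ground truth in
#' recovery tests.
#'
#' @param profiles Output of [make_profiles()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(profiles, path) {
  out <- tibble(
    word = profiles$word,
    latent_E = profiles$latent_E,
    relevant_dims = purrr::map_chr(profiles$relevant_dims, paste, collapse = "|")
  )
  readr::write_tsv(out, path)
  invisible(path)
}
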