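#' Default analysis configuration
#'
#' The thresholds used throughout the pipeline, with the conventional defaults
#' of dimension-rating norming studies:
#'
#' * `careless_threshold` (0.85): a rater is excluded when one response value
#'   accounts for strictly more than this share of their Likert responses.
#' * `trim_sd` (3): responses further than this many standard deviations from
#'   their item mean are removed.
#' * `leave_one_out` (`FALSE`): whether the trimming mean/SD exclude the
#'   candidate response itself.
#' * `representative_threshold` (3.5): a word is representative of a dimension
#'   when its mean on that dimension is strictly greater than this.
#' * `round_norms_before_threshold` (`FALSE`): threshold published 2-decimal
#'   norms instead of exact means.
#' * `percentiles` (`c(25, 75)`): exclusivity level cutoffs.
#' * `percentile_method` (`"linear"`): `"linear"` is interpolation between
#'   order statistics (R quantile type 7); `"spss"` is the SPSS
#'   weighted-average convention (type 6).
#' * `alpha_floor` (0.6): pooled Cronbach's alpha above this is acceptable.
#' * `completeness_fraction` (1): minimum share of expected responses a rater
#'   must have provided.
#' * `min_n_warn` (20): warn when a word x variable cell aggregates fewer
#'   responses than this.
#' * `seed` (1): seed for any stochastic step.
#' * `aliases` (empty): named list mapping external column names to canonical
#'   variable names, used when reading foreign norms tables.
#'
#' @return A named list of class `semdim_config`.
#' @export
default_config <- function() {
  structure(
    list(
      careless_threshold = 0.85,
      trim_sd = 3,
      leave_one_out = FALSE,
      representative_threshold = 3.5,
      round_norms_before_threshold = FALSE,
      percentiles = c(25, 75),
      percentile_method = "linear",
      alpha_floor = 0.6,
      completeness_fraction = 1,
      min_n_warn = 20,
      seed = 1L,
      aliases = list()
    ),
    class = "semdim_config"
  )
}

#' Load an analysis configuration from YAML or JSON
#'
#' Unknown keys produce a warning and are ignored; known keys override the
#' defaults of [default_config()]. An empty or absent file yields the
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for pure
#'   defaults.
#' @return A `semdim_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) return(cfg)
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown) > 0) {
    warn(sprintf("Ignoring unknown config key(s): %s.",
                 paste(unknown, collapse = ", ")))
    raw <- raw[setdiff(names(raw), unknown)]
  }
  cfg[names(raw)] <- raw
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num_keys <- c(
    "careless_threshold", "trim_sd", "representative_threshold",
    "alpha_floor", "completeness_fraction", "min_n_warn", "seed"
  )
  for (k in num_keys) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || is.na(cfg[[k]])) {
      abort(sprintf("Config key `%s` must be a single number.", k))
    }
  }
  if (cfg$careless_threshold < 0 || cfg$careless_threshold > 1) {
    abort("`careless_threshold` must lie in [0, 1].")
  }
  if (!is.numeric(cfg$percentiles) || length(cfg$percentiles) != 2 ||
      cfg$percentiles[1] > cfg$percentiles[2]) {
    abort("`percentiles` must be two ordered numbers in [0, 100].")
  }
  if (!cfg$percentile_method %in% c("linear", "spss")) {
    abort('`percentile_method` must be "linear" or "spss".')
  }
  if (!is.logical(cfg$leave_one_out) ||
      !is.logical(cfg$round_norms_before_threshold)) {
    abort("`leave_one_out` and `round_norms_before_threshold` must be logical.")
  }
  structure(cfg, class = "semdim_config")
}

#' @export
print.semdim_config <- function(x, ...) {
  cat("<semdim_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (is.list(v)) v <- if (length(v)) paste(names(v), collapse = ", ") else "(none)"
    cat(sprintf("  %-28s %s\n", k, paste(v, collapse = ", ")))
  }
  invisible(x)
}
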