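#' Exclusivity score of one dimension profile
#'
#' The per-word exclusivity statistic over the eight semantic dimensions:
#' \deqn{E = \frac{\max - \min}{\sum} \times 100}
#' computed on the word's eight dimension means. A word rated equally on all
#' dimensions scores 0 (fully multidimensional); on the 1-7 scale with eight
#' dimensions the maximum is \eqn{(7-1)/(7+7\cdot 1)\times 100 = 42.857}
#' (one dimension at 7, the rest at 1).
#'
#' @param means Numeric vector of exactly 8 dimension means, each in [1, 7].
#' @return The exclusivity score, a number in [0, 42.857].
#' @export
#' @examples
#' exclusivity_score(rep(4, 8))          # 0
#' exclusivity_score(c(7, rep(1, 7)))    # 42.857...
exclusivity_score <- function(means) {
  if (length(means) != 8 || anyNA(means)) {
    abort("Exclusivity needs exactly 8 non-missing dimension means.")
  }
  if (any(means < 1 | means > 7)) {
    abort("Dimension means must lie within the 1-7 scale.")
  }
  (max(means) - min(means)) / sum(means) * 100
}

#' Exclusivity scores for a norms table
#'
#' Applies [exclusivity_score()] to each abstract word's eight semantic
#' dimension means.
#'
#' @param norms Wide norms tibble with `<DIM>_mean` columns for all eight
#'   dimensions.
#' @param dims Dimension names (default [semantic_dimensions()]).
#' @param abstract_only Keep abstract words only (default `TRUE`; the
#'   statistic is not defined for concrete fillers).
#' @return A tibble `word`, the eight dimension mean columns, `E`.
#' @export
compute_exclusivity <- function(norms, dims = semantic_dimensions(),
                                abstract_only = TRUE) {
  assert_df(norms, "norms")
  cols <- paste0(dims, "_mean")
  assert_cols(norms, cols, "norms")
  sub <- if (abstract_only && "is_abstract" %in% names(norms)) {
    norms[norms$is_abstract, ]
  } else {
    norms
  }
  m <- as.matrix(sub[, cols])
  colnames(m) <- dims
  E <- apply(m, 1, exclusivity_score)
  bind_cols(tibble(word = sub$word), as_tibble(m), tibble(E = E))
}

#' Stratify exclusivity scores into low / medium / high levels
#'
#' Cutoffs are the 25th and 75th percentiles of the E distribution (or the
#' configured `percentiles`); a word is `low` when `E < p25`, `medium` when
#' `p25 <= E <= p75` (closed on both sides) and `high` when `E > p75`.
#' The `"linear"` percentile method interpolates between order statistics
#' (R quantile type 7); `"spss"` uses the SPSS weighted-average convention
#' (type 6) — the two can differ in the second decimal.
#'
#' @param e_table Tibble with columns `word` and `E` (from
#'   [compute_exclusivity()]), or a bare numeric vector of E values.
#' @param percentiles Two percentages, default `c(25, 75)`.
#' @param method `"linear"` or `"spss"`.
#' @return The input tibble with a `level` factor column added
#'   (`low < medium < high`), of class `semdim_exclusivity`; cutoffs are
#'   available via [level_cutoffs()] or [glance()].
#' @export
assign_levels <- function(e_table, percentiles = c(25, 75),
                          method = c("linear", "spss")) {
  method <- match.arg(method)
  if (is.numeric(e_table)) {
    e_table <- tibble(word = sprintf("v%04d", seq_along(e_table)), E = e_table)
  }
  assert_df(e_table, "e_table")
  assert_cols(e_table, c("word", "E"), "e_table")
  if (nrow(e_table) < 4) abort("Need at least 4 E values to stratify.")
  qtype <- if (method == "linear") 7 else 6
  cuts <- quantile(e_table$E, probs = percentiles / 100, type = qtype,
                   names = FALSE)
  if (cuts[1] == cuts[2] && sd(e_table$E) == 0) {
    warn("All E values identical; every word assigned to the medium level.")
  }
  lv <- dplyr::case_when(
    e_table$E < cuts[1] ~ "low",
    e_table$E > cuts[2] ~ "high",
    TRUE ~ "medium"
  )
  e_table$level <- factor(lv, levels = c("low", "medium", "high"))
  structure(
    e_table,
    class = c("semdim_exclusivity", class(tibble())),
    cutoffs = list(p25 = cuts[1], p75 = cuts[2], method = method,
                   percentiles = percentiles)
  )
}

#' Level cutoffs of a stratified exclusivity table
#'
#' @param x A `semdim_exclusivity` object from [assign_levels()].
#' @return A list `p25`, `p75`, `method`, `percentiles`.
#' @export
level_cutoffs <- function(x) {
  attr(x, "cutoffs")
}

#' @rdname assign_levels
#' @param x A `semdim_exclusivity` object.
#' @param ... Unused.
#' @export
glance.semdim_exclusivity <- function(x, ...) {
  cuts <- level_cutoffs(x)
  counts <- table(x$level)
  tibble(
    n = nrow(x),
    mean_E = mean(x$E), sd_E = sd(x$E),
    min_E = min(x$E), max_E = max(x$E),
    p25 = cuts$p25, p75 = cuts$p75, method = cuts$method,
    n_low = unname(counts["low"]), n_medium = unname(counts["medium"]),
    n_high = unname(counts["high"])
  )
}

#' Validity correlation between exclusivity and semantic diversity
#'
#' Pearson correlation (with two-sided p) between per-word E scores and
#' per-word semantic-diversity means. In a valid exclusivity measure the
#' association is negative: words used in many contexts engage more
#' dimensions.
#'
#' @param E Numeric vector of exclusivity scores, or a tibble with columns
#'   `E` and `SEM_DIV`.
#' @param semdiv Numeric vector of SEM_DIV means (omit when `E` is a tibble).
#' @return A tibble `r`, `p_value`, `n`.
#' @export
validity_correlation <- function(E, semdiv = NULL) {
  if (is.data.frame(E)) {
    assert_cols(E, c("E", "SEM_DIV"), "E")
    semdiv <- E$SEM_DIV
    E <- E$E
  }
  if (length(E) != length(semdiv)) abort("E and SEM_DIV must be paired.")
  if (length(E) < 3) abort("Need at least 3 pairs.")
  if (sd(E) == 0 || sd(semdiv) == 0) {
    warn("Zero variance; correlation is undefined.")
    return(tibble(r = NaN, p_value = NaN, n = length(E)))
  }
  ct <- stats::cor.test(E, semdiv, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(E))
}
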