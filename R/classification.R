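#' Representative-dimension label sets
#'
#' A word is representative of a dimension when its mean rating on that
#' dimension is strictly greater than `threshold` (default 3.5, the midpoint
#' between "neutral" and the first clearly-related scale point). A word may
#' be representative of several dimensions; words exceeding the threshold on
#' no dimension are retained with cardinality 0 and reported separately by
#' downstream summaries.
#'
#' @param norms Wide norms tibble with `<DIM>_mean` for all eight dimensions.
#' @param threshold Strict lower bound on the dimension mean (default 3.5).
#' @param dims Dimension names.
#' @param abstract_only Restrict to abstract words (default `TRUE`).
#' @param round_first Round means to 2 decimals before thresholding (for
#'   published-norms reproduction; default `FALSE`, exact means).
#' @return A tibble `word`, `dims` (list-column of dimension names),
#'   `cardinality`, `label` (pipe-joined dims in canonical order, `""` when
#'   empty).
#' @export
representative_labels <- function(norms, threshold = 3.5,
                                  dims = semantic_dimensions(),
                                  abstract_only = TRUE,
                                  round_first = FALSE) {
  assert_df(norms, "norms")
  cols <- paste0(dims, "_mean")
  assert_cols(norms, cols, "norms")
  sub <- if (abstract_only && "is_abstract" %in% names(norms)) {
    norms[norms$is_abstract, ]
  } else {
    norms
  }
  m <- as.matrix(sub[, cols])
  if (anyNA(m)) abort("Missing dimension mean(s) in norms.")
  if (round_first) m <- round(m, 2)
  colnames(m) <- dims
  sets <- apply(m > threshold, 1, function(row) dims[row], simplify = FALSE)
  tibble(
    word = sub$word,
    dims = sets,
    cardinality = lengths(sets),
    label = purrr::map_chr(sets, paste, collapse = "|")
  )
}

#' Words per dimension (marginal counts)
#'
#' Counts, for each dimension, the words whose label set contains it; a word
#' contributes to every dimension it is representative of.
#'
#' @param labels Output of [representative_labels()].
#' @param dims Dimension names (fixes output order and includes zero counts).
#' @return A tibble `dimension`, `n`.
#' @export
dimension_counts <- function(labels, dims = semantic_dimensions()) {
  assert_df(labels, "labels")
  assert_cols(labels, "dims", "labels")
  tallies <- table(factor(unlist(labels$dims), levels = dims))
  tibble(dimension = dims, n = as.integer(tallies))
}

#' Exact-combination intersection table
#'
#' The tabulation behind an UpSet plot: for every dimension combination that
#' occurs, the number of words whose label set is exactly that combination.
#' Cardinality-0 words are excluded from the table (their count is kept as an
#' attribute); rows are sorted by descending count, then ascending
#' cardinality, then label. The exact-combination counts partition the
#' representative words, and each dimension's marginal equals the sum of
#' counts of combinations containing it.
#'
#' @param labels Output of [representative_labels()].
#' @param dims Dimension names.
#' @return A tibble of class `semdim_intersections` with columns `label`,
#'   `dims` (list-column), `cardinality`, `n`; attributes `n_representative`,
#'   `n_unlabelled` and `marginals` (a [dimension_counts()] tibble).
#' @export
intersection_table <- function(labels, dims = semantic_dimensions()) {
  assert_df(labels, "labels")
  rep_words <- labels[labels$cardinality > 0, ]
  tab <- rep_words |>
    count(.data$label, name = "n") |>
    mutate(
      dims = purrr::map(.data$label, ~ strsplit(.x, "|", fixed = TRUE)[[1]]),
      cardinality = lengths(.data$dims)
    ) |>
    arrange(dplyr::desc(.data$n), .data$cardinality, .data$label) |>
    select("label", "dims", "cardinality", "n")
  structure(
    tab,
    class = c("semdim_intersections", class(tibble())),
    n_representative = nrow(rep_words),
    n_unlabelled = sum(labels$cardinality == 0),
    marginals = dimension_counts(rep_words, dims)
  )
}

#' @rdname intersection_table
#' @param x A `semdim_intersections` object.
#' @param ... Unused.
#' @export
glance.semdim_intersections <- function(x, ...) {
  tibble(
    n_combinations = nrow(x),
    n_representative = attr(x, "n_representative"),
    n_unlabelled = attr(x, "n_unlabelled"),
    top_label = if (nrow(x) > 0) x$label[1] else NA_character_,
    top_n = if (nrow(x) > 0) x$n[1] else NA_integer_
  )
}

#' Intersection tables and cardinality histogram per exclusivity level
#'
#' Splits the label sets by exclusivity level and builds one
#' [intersection_table()] per level, plus the level x cardinality histogram
#' (how many words of each level are representative of 0, 1, ..., 8
#' dimensions).
#'
#' @param labels Output of [representative_labels()].
#' @param levels_table A `semdim_exclusivity` tibble (word, E, level) over
#'   the same word universe.
#' @param dims Dimension names.
#' @return A list of class `semdim_crosstab`: `by_level` (named list of
#'   intersection tables) and `histogram` (tibble `level`, `cardinality`,
#'   `n`).
#' @export
crosstab_by_level <- function(labels, levels_table,
                              dims = semantic_dimensions()) {
  assert_df(labels, "labels")
  assert_df(levels_table, "levels_table")
  assert_cols(levels_table, c("word", "level"), "levels_table")
  if (!setequal(labels$word, levels_table$word)) {
    abort("`labels` and `levels_table` must cover the same words.")
  }
  joined <- inner_join(labels, levels_table[, c("word", "level")], by = "word")
  lvls <- levels(joined$level) %||% sort(unique(as.character(joined$level)))
  by_level <- purrr::map(setNames(lvls, lvls), function(l) {
    intersection_table(joined[joined$level == l, ], dims)
  })
  histogram <- joined |>
    count(.data$level, .data$cardinality, name = "n") |>
    arrange(.data$level, .data$cardinality)
  structure(list(by_level = by_level, histogram = histogram),
            class = "semdim_crosstab")
}

#' @rdname crosstab_by_level
#' @param x A `semdim_crosstab` object.
#' @param ... Unused.
#' @export
tidy.semdim_crosstab <- function(x, ...) {
  x$histogram
}
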