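#' Aggregate trimmed responses into word-level norms
#'
#' Per word x variable: mean, sample standard deviation (n-1 denominator) and
#' response count, laid out wide (`<VAR>_mean`, `<VAR>_sd`, `<VAR>_n`). A
#' warning reports how many cells aggregate fewer than `min_n_warn`
#' responses. Every word must have at least one response on every registry
#' variable.
#'
#' @param records Trimmed rating records.
#' @param meta Tibble `(word, is_abstract)`; words missing from `meta` error.
#' @param registry Variable registry.
#' @param min_n_warn Warn when any cell has fewer responses than this
#'   (default 20, the floor of the emulated study design).
#' @return A wide norms tibble: `word`, `is_abstract`, then three columns per
#'   variable.
#' @export
aggregate_norms <- function(records, meta, registry = default_registry(),
                            min_n_warn = 20) {
  assert_df(records, "records")
  assert_df(meta, "meta")
  assert_cols(meta, c("word", "is_abstract"), "meta")

  cells <- records |>
    group_by(.data$word, .data$variable) |>
    summarise(
      mean = mean(.data$value),
      sd = sd(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    )
  low <- sum(cells$n < min_n_warn)
  if (low > 0) {
    warn(sprintf("%d word x variable cell(s) aggregate fewer than %d responses.",
                 low, min_n_warn))
  }

  wide <- cells |>
    tidyr::pivot_wider(
      id_cols = "word", names_from = "variable",
      values_from = c("mean", "sd", "n"), names_glue = "{variable}_{.value}"
    )
  need <- paste0(registry$name, "_mean")
  missing_cols <- setdiff(need, names(wide))
  incomplete <- if (length(missing_cols) == 0) {
    wide$word[!complete.cases(wide[, need])]
  } else {
    wide$word
  }
  if (length(incomplete) > 0 || length(missing_cols) > 0) {
    abort(sprintf(
      "Word(s) with no responses on a required variable (first: %s).",
      if (length(incomplete) > 0) incomplete[1] else missing_cols[1]
    ))
  }

  unknown <- setdiff(wide$word, meta$word)
  if (length(unknown) > 0) {
    abort(sprintf("Word(s) absent from `meta`: %s ...", unknown[1]))
  }
  ord <- unlist(lapply(registry$name, function(v) paste0(v, c("_mean", "_sd", "_n"))))
  wide |>
    inner_join(meta[, c("word", "is_abstract")], by = "word") |>
    select("word", "is_abstract", dplyr::all_of(ord)) |>
    arrange(.data$word)
}

#' Compare concreteness and imageability across concrete and abstract words
#'
#' For CNC and IMG: group means and observed ranges for the concrete and
#' abstract groups, and a Welch two-sample t-test on the word-level means.
#' Additionally: the number of abstract words whose CNC mean falls inside the
#' closed range of the concrete group's CNC means, the percentage of each
#' group with CNC mean above 6, and the range-split table counting, per
#' group, words with CNC in `[concrete min, 6)` and in `[6, concrete max]`.
#'
#' @param norms A wide norms tibble with `CNC_mean`, `IMG_mean`,
#'   `is_abstract`.
#' @return A list of class `semdim_comparison`; see [tidy.semdim_comparison()].
#' @export
concreteness_comparison <- function(norms) {
  assert_df(norms, "norms")
  assert_cols(norms, c("word", "is_abstract", "CNC_mean", "IMG_mean"), "norms")
  if (!any(norms$is_abstract) || !any(!norms$is_abstract)) {
    abort("Both an abstract and a concrete group are required.")
  }
  conc <- norms[!norms$is_abstract, ]
  abst <- norms[norms$is_abstract, ]

  per_var <- purrr::map_dfr(c("CNC", "IMG"), function(v) {
    cv <- conc[[paste0(v, "_mean")]]
    av <- abst[[paste0(v, "_mean")]]
    tt <- t.test(cv, av)  # Welch by default
    tibble(
      variable = v,
      concrete_mean = mean(cv), abstract_mean = mean(av),
      concrete_min = min(cv), concrete_max = max(cv),
      abstract_min = min(av), abstract_max = max(av),
      t_statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  })

  rng <- c(min(conc$CNC_mean), max(conc$CNC_mean))
  in_range <- abst$CNC_mean >= rng[1] & abst$CNC_mean <= rng[2]
  split_at <- 6
  range_split <- tibble(
    cnc_range = c(sprintf("%.2f-%.2f", rng[1], split_at - 0.01),
                  sprintf("%.2f-%.2f", split_at, rng[2]),
                  "total"),
    n_concrete = c(sum(conc$CNC_mean < split_at),
                   sum(conc$CNC_mean >= split_at),
                   nrow(conc)),
    n_abstract = c(sum(in_range & abst$CNC_mean < split_at),
                   sum(in_range & abst$CNC_mean >= split_at),
                   sum(in_range))
  )

  structure(
    list(
      per_variable = per_var,
      n_abstract_in_concrete_range = sum(in_range),
      pct_above_6 = c(
        concrete = 100 * mean(conc$CNC_mean > 6),
        abstract = 100 * mean(abst$CNC_mean > 6)
      ),
      range_split = range_split,
      n_concrete = nrow(conc), n_abstract = nrow(abst)
    ),
    class = "semdim_comparison"
  )
}

#' @rdname concreteness_comparison
#' @param x A `semdim_comparison` object.
#' @param ... Unused.
#' @export
tidy.semdim_comparison <- function(x, ...) {
  x$per_variable
}

#' @rdname concreteness_comparison
#' @export
glance.semdim_comparison <- function(x, ...) {
  tibble(
    n_concrete = x$n_concrete, n_abstract = x$n_abstract,
    n_abstract_in_concrete_range = x$n_abstract_in_concrete_range,
    pct_concrete_above_6 = unname(x$pct_above_6["concrete"]),
    pct_abstract_above_6 = unname(x$pct_above_6["abstract"])
  )
}

#' @export
print.semdim_comparison <- function(x, ...) {
  cat("<semdim_comparison>\n")
  print(x$per_variable)
  cat(sprintf("  abstract words inside concrete CNC range: %d\n",
              x$n_abstract_in_concrete_range))
  cat(sprintf("  CNC mean > 6: concrete %.1f%%, abstract %.2f%%\n",
              x$pct_above_6["concrete"], x$pct_above_6["abstract"]))
  invisible(x)
}

#' Pairwise Pearson correlation matrix over word-level means
#'
#' Correlates every pair of variables across words (means from the norms
#' table), returning the coefficient matrix and two-sided p-values from the
#' t distribution with n - 2 degrees of freedom. Zero-variance variables get
#' `NaN` entries with a warning.
#'
#' @param norms Wide norms tibble.
#' @param variables Variables to include (default: all registry variables).
#' @param words Optional subset of words (default: abstract words only, the
#'   convention for dimension-rating analyses).
#' @param registry Variable registry.
#' @return A list of class `semdim_cormat`: `r` and `p` (symmetric matrices),
#'   `n` (number of words).
#' @export
correlation_matrix <- function(norms, variables = NULL, words = NULL,
                               registry = default_registry()) {
  assert_df(norms, "norms")
  variables <- variables %||% registry$name
  sub <- if (is.null(words)) norms[norms$is_abstract, ] else
    norms[norms$word %in% words, ]
  if (nrow(sub) < 3) abort("Need at least 3 words for correlations.")
  m <- as.matrix(sub[, paste0(variables, "_mean")])
  colnames(m) <- variables
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("Zero-variance variable(s): %s; correlations are NaN.",
                 paste(variables[sds == 0], collapse = ", ")))
  }
  n <- nrow(m)
  r <- suppressWarnings(cor(m))
  diag(r) <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n), class = "semdim_cormat")
}

#' @rdname correlation_matrix
#' @param x A `semdim_cormat` object.
#' @param ... Unused.
#' @export
tidy.semdim_cormat <- function(x, ...) {
  vars <- colnames(x$r)
  pairs <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    var_a = vars[pairs[, 1]],
    var_b = vars[pairs[, 2]],
    r = x$r[pairs],
    p_value = x$p[pairs],
    n = x$n
  )
}

#' @export
print.semdim_cormat <- function(x, ...) {
  cat(sprintf("<semdim_cormat> %d variables over %d words\n", ncol(x$r), x$n))
  print(round(x$r, 2))
  invisible(x)
}
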