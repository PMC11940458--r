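#' Cronbach's alpha for a complete words x raters block
#'
#' Inter-rater consistency with raters playing the role of scale items and
#' words the role of cases:
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)}
#' where \eqn{k} is the number of raters, \eqn{s_i^2} the variance of rater
#' \eqn{i}'s responses across words, and \eqn{s_T^2} the variance of the
#' per-word response sums. Requires a complete block (no missing cells);
#' in a list design, compute per list.
#'
#' @param mat Numeric matrix, words in rows, raters in columns, no `NA`.
#' @return Alpha (a single number, at most 1; `NaN` with a warning when the
#'   per-word sums have zero variance).
#' @export
#' @examples
#' m <- cbind(a = c(1, 4, 7), b = c(2, 4, 6))
#' cronbach_alpha(m)
cronbach_alpha <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) {
    abort("Matrix has missing cells; compute alpha per list (complete blocks).")
  }
  if (ncol(mat) < 2 || nrow(mat) < 2) {
    abort("Alpha needs at least 2 raters and 2 words.")
  }
  k <- ncol(mat)
  s2_raters <- apply(mat, 2, var)
  s2_total <- var(rowSums(mat))
  if (s2_total == 0) {
    warn("Per-word sums have zero variance; alpha is undefined.")
    return(NaN)
  }
  (k / (k - 1)) * (1 - sum(s2_raters) / s2_total)
}

#' Per-variable inter-rater reliability report
#'
#' Computes Cronbach's alpha within each list (the only complete
#' word x rater blocks in a list design), for every registry variable, and
#' pools across lists as the unweighted mean. A variable is acceptable when
#' its pooled alpha exceeds `alpha_floor`. Raters with missing responses on a
#' list's words (e.g. after trimming) are dropped from that list's block;
#' lists left with fewer than 2 raters or 2 words are skipped with a warning.
#'
#' @param records Trimmed rating records with `list_id`.
#' @param registry Variable registry.
#' @param alpha_floor Acceptability floor (default 0.6, exclusive).
#' @return A tibble of class `semdim_reliability`: one row per variable with
#'   `variable`, `n_lists`, `pooled_alpha`, `acceptable`, and a list-column
#'   `alpha_by_list`.
#' @export
reliability_report <- function(records, registry = default_registry(),
                               alpha_floor = 0.6) {
  assert_df(records, "records")
  assert_cols(records, c("rater_id", "list_id", "word", "variable", "value"),
              "records")
  skipped <- 0L
  rows <- purrr::map_dfr(registry$name, function(v) {
    sub <- records[records$variable == v, ]
    alphas <- purrr::map_dbl(sort(unique(sub$list_id)), function(l) {
      block <- sub[sub$list_id == l, ] |>
        tidyr::pivot_wider(id_cols = "word", names_from = "rater_id",
                           values_from = "value") |>
        select(-"word") |>
        as.matrix()
      block <- block[, colSums(is.na(block)) == 0, drop = FALSE]
      if (ncol(block) < 2 || nrow(block) < 2) {
        skipped <<- skipped + 1L
        return(NA_real_)
      }
      suppressWarnings(cronbach_alpha(block))
    })
    names(alphas) <- sort(unique(sub$list_id))
    tibble(
      variable = v,
      n_lists = sum(!is.na(alphas)),
      pooled_alpha = mean(alphas, na.rm = TRUE),
      alpha_by_list = list(alphas)
    )
  })
  if (skipped > 0) {
    warn(sprintf("%d list block(s) skipped (fewer than 2 raters or 2 words).",
                 skipped))
  }
  rows$acceptable <- rows$pooled_alpha > alpha_floor
  structure(rows, class = c("semdim_reliability", class(rows)),
            alpha_floor = alpha_floor)
}

#' @rdname reliability_report
#' @param x A `semdim_reliability` object.
#' @param ... Unused.
#' @export
tidy.semdim_reliability <- function(x, ...) {
  tibble(
    variable = rep(x$variable, lengths(x$alpha_by_list)),
    list_id = unlist(purrr::map(x$alpha_by_list, names)),
    alpha = unlist(x$alpha_by_list)
  )
}

#' @rdname reliability_report
#' @export
glance.semdim_reliability <- function(x, ...) {
  tibble(
    n_variables = nrow(x),
    min_alpha = min(x$pooled_alpha),
    max_alpha = max(x$pooled_alpha),
    all_acceptable = all(x$acceptable),
    alpha_floor = attr(x, "alpha_floor")
  )
}
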