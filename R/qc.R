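#' Flag careless (constant-response) raters
#'
#' A rater is flagged as careless when their modal response value accounts
#' for strictly more than `threshold` of their Likert responses, pooled
#' across all Likert-scaled variables (age-of-acquisition responses are not
#' counted: ages are not scale points). Raters with no Likert responses are
#' not judged here; [flag_incomplete()] catches them.
#'
#' @param records Tibble of rating records.
#' @param threshold Modal-share threshold (default 0.85; strict inequality).
#' @param registry Variable registry.
#' @return A tibble with one row per rater: `rater_id`, `n_responses`,
#'   `modal_value`, `modal_share`, `careless`.
#' @export
flag_careless <- function(records, threshold = 0.85,
                          registry = default_registry()) {
  assert_df(records, "records")
  assert_cols(records, c("rater_id", "variable", "value"), "records")
  likert <- likert_variables(registry)
  records |>
    filter(.data$variable %in% likert) |>
    group_by(.data$rater_id) |>
    summarise(
      n_responses = dplyr::n(),
      modal_value = as.numeric(names(which.max(table(.data$value)))),
      modal_share = max(table(.data$value)) / dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(careless = .data$modal_share > .env$threshold)
}

#' Flag raters with incomplete response sets
#'
#' Compares each rater's response count against the count expected from the
#' list design (every variable for every word of the rater's list, unless an
#' explicit expectation is supplied).
#'
#' @param records Tibble of rating records.
#' @param expected Either `NULL` (expected count derived per list as
#'   `#words in list x #registry variables`), a single number, or a tibble
#'   `(rater_id, expected)`.
#' @param completeness_fraction Minimum fraction of expected responses
#'   (default 1, i.e. fully complete).
#' @param registry Variable registry.
#' @return Tibble `rater_id`, `n_responses`, `expected`, `incomplete`.
#' @export
flag_incomplete <- function(records, expected = NULL,
                            completeness_fraction = 1,
                            registry = default_registry()) {
  assert_df(records, "records")
  counts <- records |>
    group_by(.data$rater_id) |>
    summarise(n_responses = dplyr::n(), .groups = "drop")
  if (is.null(expected)) {
    assert_cols(records, c("list_id", "word"), "records")
    per_list <- records |>
      distinct(.data$list_id, .data$word) |>
      count(.data$list_id, name = "n_words") |>
      mutate(expected = .data$n_words * nrow(registry))
    rater_list <- distinct(records, .data$rater_id, .data$list_id)
    counts <- counts |>
      left_join(rater_list, by = "rater_id") |>
      left_join(per_list[, c("list_id", "expected")], by = "list_id") |>
      group_by(.data$rater_id, .data$n_responses) |>
      summarise(expected = sum(.data$expected), .groups = "drop")
  } else if (is.data.frame(expected)) {
    counts <- left_join(counts, expected, by = "rater_id")
  } else {
    counts$expected <- expected
  }
  counts |>
    mutate(incomplete = .data$n_responses <
             .env$completeness_fraction * .data$expected) |>
    select("rater_id", "n_responses", "expected", "incomplete")
}

#' Trim responses far from their item mean
#'
#' Single-pass response-level trimming: within each word x variable cell,
#' responses whose distance from the cell mean exceeds `trim_sd` sample
#' standard deviations are removed. Mean and SD are computed once over all
#' responses of the cell, including the candidate (set `leave_one_out = TRUE`
#' to exclude it). Cells with zero SD lose nothing. The rule is applied once;
#' no re-trimming on the reduced cells.
#'
#' @param records Tibble of rating records (careless/incomplete raters
#'   already removed).
#' @param trim_sd Number of standard deviations (default 3).
#' @param leave_one_out Logical; use leave-one-out cell statistics.
#' @return A list of class `semdim_qc` with elements `records` (kept
#'   responses), `removed` (tibble of removed responses), and
#'   `pct_removed_by_variable` (tibble `variable`, `n_removed`, `n_total`,
#'   `pct_removed`).
#' @export
trim_responses <- function(records, trim_sd = 3, leave_one_out = FALSE) {
  assert_df(records, "records")
  assert_cols(records, c("word", "variable", "value"), "records")

  scored <- records |>
    group_by(.data$word, .data$variable) |>
    mutate(
      .n = dplyr::n(),
      .m = mean(.data$value),
      .s = sd(.data$value)
    ) |>
    ungroup()

  if (leave_one_out) {
    # Identities: loo mean = (n*m - x)/(n-1); loo SS = SS - (x-m)^2 * n/(n-1).
    n <- scored$.n; m <- scored$.m; x <- scored$value
    ss <- (n - 1) * scored$.s^2
    loo_m <- ifelse(n > 1, (n * m - x) / (n - 1), m)
    loo_ss <- pmax(ss - (x - m)^2 * n / (n - 1), 0)
    loo_s <- ifelse(n > 2, sqrt(loo_ss / (n - 2)), 0)
    drop <- n > 2 & loo_s > 0 & abs(x - loo_m) > trim_sd * loo_s
  } else {
    drop <- !is.na(scored$.s) & scored$.s > 0 &
      abs(scored$value - scored$.m) > trim_sd * scored$.s
  }

  emptied <- scored |>
    mutate(.drop = drop) |>
    group_by(.data$word, .data$variable) |>
    summarise(all_gone = all(.data$.drop), .groups = "drop") |>
    filter(.data$all_gone)
  if (nrow(emptied) > 0) {
    abort(sprintf(
      "Trimming would empty %d word x variable cell(s) (first: %s / %s).",
      nrow(emptied), emptied$word[1], emptied$variable[1]
    ))
  }

  kept <- records[!drop, , drop = FALSE]
  removed <- records[drop, , drop = FALSE]
  pct <- records |>
    mutate(.drop = drop) |>
    group_by(.data$variable) |>
    summarise(
      n_removed = sum(.data$.drop),
      n_total = dplyr::n(),
      pct_removed = 100 * .data$n_removed / .data$n_total,
      .groups = "drop"
    )
  structure(
    list(records = kept, removed = as_tibble(removed),
         pct_removed_by_variable = pct),
    class = "semdim_qc"
  )
}

#' Run both QC stages
#'
#' Applies rater-level exclusion (careless + incomplete) and then
#' response-level trimming, mirroring the two-stage cleaning of list-based
#' norming studies.
#'
#' @param records Tibble of rating records.
#' @param config A `semdim_config` (see [default_config()]).
#' @param registry Variable registry.
#' @return A `semdim_qc` list: `records`, `removed`,
#'   `pct_removed_by_variable`, plus `excluded_raters` (tibble `rater_id`,
#'   `reason`).
#' @export
qc_pipeline <- function(records, config = default_config(),
                        registry = default_registry()) {
  careless <- flag_careless(records, config$careless_threshold, registry)
  incomplete <- flag_incomplete(
    records, completeness_fraction = config$completeness_fraction,
    registry = registry
  )
  excluded <- bind_rows(
    tibble(rater_id = careless$rater_id[careless$careless], reason = "careless"),
    tibble(rater_id = incomplete$rater_id[incomplete$incomplete],
           reason = "incomplete")
  ) |> distinct(.data$rater_id, .keep_all = TRUE)

  clean <- records |> filter(!.data$rater_id %in% excluded$rater_id)
  res <- trim_responses(clean, trim_sd = config$trim_sd,
                        leave_one_out = config$leave_one_out)
  res$excluded_raters <- excluded
  res
}

#' @export
print.semdim_qc <- function(x, ...) {
  cat("<semdim_qc>\n")
  if (!is.null(x$excluded_raters)) {
    cat(sprintf("  raters excluded: %d\n", nrow(x$excluded_raters)))
  }
  cat(sprintf("  responses removed: %d of %d (%.2f%%)\n",
              nrow(x$removed), nrow(x$removed) + nrow(x$records),
              100 * nrow(x$removed) / (nrow(x$removed) + nrow(x$records))))
  rng <- range(x$pct_removed_by_variable$pct_removed)
  cat(sprintf("  per-variable removal: %.2f%% to %.2f%%\n", rng[1], rng[2]))
  invisible(x)
}

#' @rdname trim_responses
#' @param x A `semdim_qc` object.
#' @param ... Unused.
#' @export
tidy.semdim_qc <- function(x, ...) {
  x$pct_removed_by_variable
}
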