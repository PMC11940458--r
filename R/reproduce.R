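#' Published reference values of the source norming study
#'
#' The printed word-level results of the Italian abstract-concept norming
#' database this package's reproduction mode targets (964 words, 807
#' abstract; exclusivity over eight semantic dimensions). Used by
#' [reproduce()] to print a side-by-side comparison; these numbers are not
#' used by any computation.
#'
#' @return A tibble `quantity`, `reference`.
#' @export
reference_values <- function() {
  tibble::tribble(
    ~quantity,                        ~reference,
    "p25",                            15.24,
    "p75",                            20.29,
    "E_min",                          5.52,
    "E_max",                          35.76,
    "E_mean",                         17.9,
    "E_sd",                           4.22,
    "n_low",                          202,
    "n_medium",                       404,
    "n_high",                         201,
    "r_E_semdiv",                     -0.47,
    "abstract_CNC_mean",              3.02,
    "n_abstract_in_concrete_range",   117,
    "n_representative",               802,
    "n_unlabelled",                   5,
    "count_INTRO",                    417,
    "count_MENT_ST",                  420,
    "count_QUANT",                    245,
    "count_SPACE",                    135,
    "count_SOC",                      462,
    "count_MOR",                      321,
    "count_THEOR",                    272,
    "count_ECO",                      233
  )
}

#' Reproduce the word-level analysis from a norms table
#'
#' Runs every analysis stage that operates on word-level norms (skipping the
#' rater-level QC and reliability stages): exclusivity scores, percentile
#' cutoffs and level counts, the E-SEM_DIV validity correlation,
#' representative labels, dimension counts, intersections, the co-occurrence
#' network and its 2-cluster partition, and the concreteness comparison. When
#' printed, the result shows a side-by-side comparison with
#' [reference_values()]. Percentile cutoffs are computed under both the
#' linear-interpolation and the SPSS percentile conventions so the convention
#' matching a published cutoff pair can be identified.
#'
#' @param norms A wide norms tibble, or a path to a norms TSV
#'   ([read_norms()]).
#' @param column_map Optional named character vector renaming foreign columns
#'   to canonical ones, e.g. `c(CNC_mean = "concretezza")`; names are
#'   canonical, values are the columns present in the file.
#' @param config A `semdim_config`.
#' @param registry Variable registry.
#' @return A list of class `semdim_reproduction`: the stage outputs plus
#'   `comparison_table` (tibble `quantity`, `value`, `reference`).
#' @export
reproduce <- function(norms, column_map = NULL, config = default_config(),
                      registry = default_registry()) {
  if (is.character(norms) && length(norms) == 1) {
    norms <- readr::read_tsv(norms, show_col_types = FALSE, progress = FALSE)
  }
  assert_df(norms, "norms")
  if (!is.null(column_map)) {
    missing <- setdiff(unname(column_map), names(norms))
    if (length(missing) > 0) {
      abort(sprintf("column_map refers to absent column(s): %s.",
                    paste(missing, collapse = ", ")))
    }
    norms <- dplyr::rename(norms, dplyr::all_of(column_map))
  }
  need <- c("word", "is_abstract", paste0(semantic_dimensions(), "_mean"),
            "SEM_DIV_mean", "CNC_mean")
  missing <- setdiff(need, names(norms))
  if (length(missing) > 0) {
    abort(sprintf("Norms are missing unmapped column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  norms$is_abstract <- as.logical(norms$is_abstract)

  e_tbl <- compute_exclusivity(norms)
  e_tbl <- left_join(e_tbl,
                     tibble(word = norms$word, SEM_DIV = norms$SEM_DIV_mean),
                     by = "word")
  e_lv <- assign_levels(e_tbl, config$percentiles, config$percentile_method)
  alt_method <- setdiff(c("linear", "spss"), config$percentile_method)
  alt_cuts <- level_cutoffs(assign_levels(e_tbl, config$percentiles, alt_method))
  validity <- validity_correlation(e_lv)

  labels <- representative_labels(
    norms, config$representative_threshold,
    round_first = config$round_norms_before_threshold
  )
  counts <- dimension_counts(labels)
  intersections <- intersection_table(labels)
  crosstab <- crosstab_by_level(labels, e_lv)
  network <- suppressWarnings(cooccurrence(labels))
  clusters <- cluster_dimensions(network, k = 2)
  comparison <- if (any(!norms$is_abstract) && "IMG_mean" %in% names(norms)) {
    concreteness_comparison(norms)
  } else {
    NULL
  }

  cuts <- level_cutoffs(e_lv)
  lv_counts <- table(e_lv$level)
  values <- c(
    p25 = cuts$p25, p75 = cuts$p75,
    E_min = min(e_lv$E), E_max = max(e_lv$E),
    E_mean = mean(e_lv$E), E_sd = sd(e_lv$E),
    n_low = unname(lv_counts["low"]), n_medium = unname(lv_counts["medium"]),
    n_high = unname(lv_counts["high"]),
    r_E_semdiv = validity$r,
    abstract_CNC_mean = mean(norms$CNC_mean[norms$is_abstract]),
    n_abstract_in_concrete_range =
      if (!is.null(comparison)) comparison$n_abstract_in_concrete_range else NA,
    n_representative = attr(intersections, "n_representative"),
    n_unlabelled = attr(intersections, "n_unlabelled"),
    setNames(counts$n, paste0("count_", counts$dimension))
  )
  comparison_table <- reference_values() |>
    mutate(value = unname(values[.data$quantity])) |>
    select("quantity", "value", "reference")

  structure(
    list(
      norms = norms, exclusivity = e_lv, cutoffs = cuts,
      alt_cutoffs = alt_cuts, validity = validity, labels = labels,
      dimension_counts = counts, intersections = intersections,
      crosstab = crosstab, network = network, clusters = clusters,
      comparison = comparison, comparison_table = comparison_table,
      max_E_word = e_lv$word[which.max(e_lv$E)],
      min_E_word = e_lv$word[which.min(e_lv$E)]
    ),
    class = "semdim_reproduction"
  )
}

#' @rdname reproduce
#' @param x A `semdim_reproduction` object.
#' @param ... Unused.
#' @export
tidy.semdim_reproduction <- function(x, ...) {
  x$comparison_table
}

#' @export
print.semdim_reproduction <- function(x, ...) {
  cat("<semdim_reproduction>\n")
  cat(sprintf("  cutoffs (%s): p25 = %.2f, p75 = %.2f; (%s): %.2f, %.2f\n",
              x$cutoffs$method, x$cutoffs$p25, x$cutoffs$p75,
              x$alt_cutoffs$method, x$alt_cutoffs$p25, x$alt_cutoffs$p75))
  cat(sprintf("  highest-E word: %s; lowest-E word: %s\n",
              x$max_E_word, x$min_E_word))
  cl <- split(x$clusters$dimension, x$clusters$cluster)
  for (i in seq_along(cl)) {
    cat(sprintf("  cluster %d: %s\n", i, paste(cl[[i]], collapse = ", ")))
  }
  cat("  computed vs published reference values:\n")
  print(as.data.frame(x$comparison_table), row.names = FALSE)
  invisible(x)
}
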