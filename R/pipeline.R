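#' Run the full analysis on rater-level records
#'
#' Sequences the pipeline: careless/incomplete rater exclusion and 3-SD
#' response trimming, per-variable reliability, word-level aggregation,
#' exclusivity scoring and level stratification, the E-SEM_DIV validity
#' correlation, representative-dimension labels, intersection tables (global
#' and per level), the dimension co-occurrence network with its 2-cluster
#' partition, and the concreteness/imageability group comparison.
#'
#' @param records Tibble of rating records (see [read_ratings()]).
#' @param meta Tibble `(word, is_abstract)`.
#' @param config A `semdim_config` (see [default_config()]).
#' @param registry Variable registry.
#' @return A list of class `semdim_run`; see [glance.semdim_run()] and
#'   [report_as_list()].
#' @export
analyze_ratings <- function(records, meta, config = default_config(),
                            registry = default_registry()) {
  records <- validate_ratings(records, registry)
  config <- validate_config(config)

  qc <- qc_pipeline(records, config, registry)
  rel <- reliability_report(qc$records, registry, config$alpha_floor)
  norms <- aggregate_norms(qc$records, meta, registry, config$min_n_warn)

  e_tbl <- compute_exclusivity(norms)
  e_tbl <- left_join(e_tbl,
                     tibble(word = norms$word, SEM_DIV = norms$SEM_DIV_mean),
                     by = "word")
  e_lv <- assign_levels(e_tbl, config$percentiles, config$percentile_method)
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
  comparison <- if (any(!norms$is_abstract)) concreteness_comparison(norms) else NULL

  structure(
    list(
      config = config,
      qc = qc,
      reliability = rel,
      norms = norms,
      exclusivity = e_lv,
      validity = validity,
      labels = labels,
      dimension_counts = counts,
      intersections = intersections,
      crosstab = crosstab,
      network = network,
      clusters = clusters,
      comparison = comparison
    ),
    class = "semdim_run"
  )
}

#' Simulate a norming study and run the full analysis
#'
#' Generates latent profiles and rater-level records with
#' [make_profiles()]/[simulate_ratings()], plants careless raters and
#' outliers as configured, runs [analyze_ratings()], and optionally writes
#' all on-disk artifacts (ratings CSV, ground-truth TSV, norms TSV, labels
#' TSV, intersections TSV, network edge list + GraphML, JSON run report) to
#' `out_dir`. Deterministic given the generator seed.
#'
#' @param gen_config A [generator_config()].
#' @param config A `semdim_config`.
#' @param out_dir Optional output directory (created if missing).
#' @param registry Variable registry.
#' @return A `semdim_run` with an extra `generator` element holding the
#'   latent profiles and the planted careless raters / outlier triples.
#' @export
run_pipeline <- function(gen_config = generator_config(),
                         config = default_config(),
                         out_dir = NULL,
                         registry = default_registry()) {
  profiles <- make_profiles(gen_config)
  records <- simulate_ratings(profiles, gen_config, registry)
  cr <- inject_careless(records, gen_config, registry)
  ot <- inject_outliers(cr$records, gen_config, registry)
  meta <- profiles[, c("word", "is_abstract")]

  run <- analyze_ratings(ot$records, meta, config, registry)
  run$generator <- list(
    config = gen_config,
    profiles = profiles,
    careless_raters = cr$careless_raters,
    outliers = ot$outliers
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ratings(ot$records, file.path(out_dir, "ratings.csv"))
    write_ground_truth(profiles, file.path(out_dir, "ground_truth.tsv"))
    write_outputs(run, out_dir)
  }
  run
}

#' Write the on-disk artifacts of a run
#'
#' @param run A `semdim_run`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_norms(run$norms, file.path(out_dir, "norms.tsv"))
  lab <- left_join(
    run$labels,
    as_tibble(run$exclusivity)[, c("word", "E", "level")],
    by = "word"
  )
  write_labels(lab, file.path(out_dir, "labels.tsv"))
  readr::write_tsv(
    as_tibble(run$intersections)[, c("label", "cardinality", "n")],
    file.path(out_dir, "intersections.tsv"), progress = FALSE
  )
  write_network(run$network, file.path(out_dir, "network_edges.tsv"),
                file.path(out_dir, "network.graphml"))
  write_run_report(run, file.path(out_dir, "run_report.json"))
  invisible(out_dir)
}

#' Flatten a run into plain lists for JSON serialization
#'
#' @param run A `semdim_run`.
#' @return A nested list of plain vectors and data frames.
#' @export
report_as_list <- function(run) {
  cuts <- level_cutoffs(run$exclusivity)
  list(
    software = list(
      package = "semdim",
      version = as.character(utils::packageVersion("semdim"))
    ),
    config = unclass(run$config),
    qc = list(
      excluded_raters = as.data.frame(run$qc$excluded_raters),
      n_responses_removed = nrow(run$qc$removed),
      pct_removed_by_variable = as.data.frame(run$qc$pct_removed_by_variable)
    ),
    reliability = as.data.frame(
      run$reliability[, c("variable", "n_lists", "pooled_alpha", "acceptable")]
    ),
    exclusivity = list(
      cutoffs = cuts[c("p25", "p75", "method")],
      level_counts = as.list(table(run$exclusivity$level)),
      summary = as.data.frame(glance(run$exclusivity))
    ),
    validity = as.data.frame(run$validity),
    dimension_counts = as.data.frame(run$dimension_counts),
    top_intersections = as.data.frame(
      head(as_tibble(run$intersections)[, c("label", "cardinality", "n")], 10)
    ),
    n_representative = attr(run$intersections, "n_representative"),
    n_unlabelled = attr(run$intersections, "n_unlabelled"),
    clusters = as.data.frame(run$clusters),
    comparison = if (!is.null(run$comparison)) {
      list(
        per_variable = as.data.frame(run$comparison$per_variable),
        n_abstract_in_concrete_range =
          run$comparison$n_abstract_in_concrete_range,
        pct_above_6 = as.list(run$comparison$pct_above_6)
      )
    }
  )
}

#' @rdname analyze_ratings
#' @param x A `semdim_run`.
#' @param ... Unused.
#' @export
glance.semdim_run <- function(x, ...) {
  cuts <- level_cutoffs(x$exclusivity)
  tibble(
    n_words = nrow(x$norms),
    n_abstract = sum(x$norms$is_abstract),
    n_raters_excluded = nrow(x$qc$excluded_raters %||% tibble()),
    max_pct_removed = max(x$qc$pct_removed_by_variable$pct_removed),
    min_alpha = min(x$reliability$pooled_alpha),
    p25 = cuts$p25, p75 = cuts$p75,
    r_E_semdiv = x$validity$r,
    n_representative = attr(x$intersections, "n_representative"),
    n_unlabelled = attr(x$intersections, "n_unlabelled")
  )
}

#' @export
print.semdim_run <- function(x, ...) {
  g <- glance(x)
  cat("<semdim_run>\n")
  cat(sprintf("  words: %d (%d abstract)\n", g$n_words, g$n_abstract))
  cat(sprintf("  raters excluded: %d; max per-variable trim: %.2f%%\n",
              g$n_raters_excluded, g$max_pct_removed))
  cat(sprintf("  min pooled alpha: %.3f\n", g$min_alpha))
  cat(sprintf("  E cutoffs: p25 = %.2f, p75 = %.2f\n", g$p25, g$p75))
  cat(sprintf("  r(E, SEM_DIV) = %.3f\n", g$r_E_semdiv))
  cat(sprintf("  representative words: %d (+%d with no dimension)\n",
              g$n_representative, g$n_unlabelled))
  cl <- split(x$clusters$dimension, x$clusters$cluster)
  for (i in seq_along(cl)) {
    cat(sprintf("  cluster %d: %s\n", i, paste(cl[[i]], collapse = ", ")))
  }
  invisible(x)
}
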