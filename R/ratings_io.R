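#' Read and write long-format rating records
#'
#' The on-disk format for raw ratings is a UTF-8 CSV with header
#' `rater_id,list_id,word,variable,value`, one row per response. On read,
#' variable names are checked against the registry and every value against
#' its variable's scale bounds (age-of-acquisition values only need to be
#' nonnegative); duplicated `(rater_id, word, variable)` triples are
#' rejected.
#'
#' @param path File path.
#' @param registry Variable registry used for validation.
#' @param decimal_mark Decimal separator accepted on read (`"."` default;
#'   `","` supports locales that export with comma decimals).
#' @return `read_ratings()` returns a tibble of validated records;
#'   `write_ratings()` returns `path` invisibly.
#' @export
read_ratings <- function(path, registry = default_registry(),
                         decimal_mark = ".") {
  cols <- c("rater_id", "list_id", "word", "variable", "value")
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      rater_id = readr::col_character(), list_id = readr::col_character(),
      word = readr::col_character(), variable = readr::col_character(),
      value = readr::col_character()
    ),
    locale = readr::locale(decimal_mark = decimal_mark),
    progress = FALSE
  )
  assert_cols(df, cols, "ratings file")
  if (decimal_mark != ".") df$value <- gsub(decimal_mark, ".", df$value, fixed = TRUE)
  value <- suppressWarnings(as.numeric(df$value))
  if (anyNA(value)) {
    bad <- which(is.na(value))[1]
    abort(sprintf("Malformed value at data row %d of %s: %s",
                  bad, path, df$value[bad]))
  }
  df$value <- value
  validate_ratings(df, registry)
}

#' Validate a tibble of rating records
#'
#' @param records Data frame of rating records.
#' @inheritParams read_ratings
#' @return The validated records as a tibble.
#' @export
validate_ratings <- function(records, registry = default_registry()) {
  assert_df(records, "records")
  assert_cols(records, c("rater_id", "list_id", "word", "variable", "value"),
              "records")
  unknown <- setdiff(unique(records$variable), registry$name)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown variable name(s): %s.", paste(unknown, collapse = ", ")))
  }
  scl <- registry[match(records$variable, registry$name), ]
  bad <- which(records$value < scl$scale_min | records$value > scl$scale_max)
  if (length(bad) > 0) {
    b <- bad[1]
    abort(sprintf(
      "Out-of-range value %g for variable %s (rater %s, word %s); scale is [%g, %g].",
      records$value[b], records$variable[b], records$rater_id[b],
      records$word[b], scl$scale_min[b], scl$scale_max[b]
    ))
  }
  dup <- duplicated(records[, c("rater_id", "word", "variable")])
  if (any(dup)) {
    d <- which(dup)[1]
    abort(sprintf("Duplicate response: rater %s, word %s, variable %s.",
                  records$rater_id[d], records$word[d], records$variable[d]))
  }
  as_tibble(records)
}

#' @rdname read_ratings
#' @param records Tibble of rating records.
#' @export
write_ratings <- function(records, path) {
  assert_cols(records, c("rater_id", "list_id", "word", "variable", "value"),
              "records")
  readr::write_csv(records[, c("rater_id", "list_id", "word", "variable", "value")],
                   path, progress = FALSE)
  invisible(path)
}

#' Read and write word-level norms tables
#'
#' Norms are stored wide, one row per word: `word`, `is_abstract`, then
#' `<VAR>_mean`, `<VAR>_sd`, `<VAR>_n` per variable, tab-separated, numbers
#' printed with six decimals (round-trip stable to 1e-6).
#'
#' @param norms A norms tibble as produced by [aggregate_norms()].
#' @param path File path.
#' @param registry Variable registry; on read, `<VAR>_mean` columns must be
#'   present for every registry variable.
#' @return `read_norms()` returns the norms tibble; `write_norms()` returns
#'   `path` invisibly.
#' @export
write_norms <- function(norms, path) {
  assert_df(norms, "norms")
  assert_cols(norms, c("word", "is_abstract"), "norms")
  out <- norms |>
    mutate(across(where(is.double), ~ round(.x, 6)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_norms
#' @export
read_norms <- function(path, registry = default_registry()) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(df, c("word", "is_abstract"), "norms file")
  need <- paste0(registry$name, "_mean")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Norms file %s is missing column(s): %s.",
                  path, paste(missing, collapse = ", ")))
  }
  df$is_abstract <- as.logical(df$is_abstract)
  as_tibble(df)
}

#' Write representative-label and exclusivity-level table
#'
#' TSV with columns `word`, `E`, `level`, `dims` (pipe-joined dimension set)
#' and `cardinality`.
#'
#' @param labels Output of [representative_labels()] joined with levels, or
#'   any tibble with those columns.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  assert_df(labels, "labels")
  out <- labels
  if (is.list(out$dims)) {
    out$dims <- purrr::map_chr(out$dims, paste, collapse = "|")
  }
  keep <- intersect(c("word", "E", "level", "dims", "cardinality"), names(out))
  readr::write_tsv(out[, keep], path, progress = FALSE)
  invisible(path)
}

#' Export a co-occurrence network
#'
#' Writes the dimension pair table as an edge-list TSV (`dim_a`, `dim_b`,
#' `shared`, `jaccard`) and, optionally, the weighted graph as GraphML.
#'
#' @param network A `semdim_conetwork` from [cooccurrence()].
#' @param path Edge-list TSV path.
#' @param graphml_path Optional GraphML output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, graphml_path = NULL) {
  readr::write_tsv(network$pairs, path, progress = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      network$pairs[network$pairs$shared > 0, ],
      directed = FALSE,
      vertices = data.frame(name = network$dimensions)
    )
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(path)
}

#' Serialize a run report to JSON
#'
#' @param report A `semdim_run` object from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
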