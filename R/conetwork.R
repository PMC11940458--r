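#' Word-dimension bipartite edges
#'
#' One edge per (word, dimension) membership: the bipartite graph with the
#' eight dimensions as parent nodes and each word linked to every dimension
#' it is representative of. The number of edges equals the sum of label-set
#' cardinalities.
#'
#' @param labels Output of [representative_labels()].
#' @return A tibble `word`, `dimension`.
#' @export
bipartite_edges <- function(labels) {
  assert_df(labels, "labels")
  assert_cols(labels, c("word", "dims"), "labels")
  tibble(
    word = rep(labels$word, labels$cardinality),
    dimension = unlist(labels$dims) %||% character(0)
  )
}

#' Dimension co-occurrence network
#'
#' Projects the word-dimension bipartite graph onto the dimensions: for every
#' unordered dimension pair, the number of words representative of both
#' (shared-word count) and the Jaccard index (shared / words representative
#' of either). Dimensions with zero representative words get Jaccard 0 with a
#' warning.
#'
#' @param labels Output of [representative_labels()].
#' @param dims Dimension names.
#' @return A list of class `semdim_conetwork`: `dimensions`, `counts`
#'   (per-dimension word counts), `pairs` (tibble `dim_a`, `dim_b`, `shared`,
#'   `jaccard`), and symmetric matrices `shared` and `jaccard`.
#' @export
cooccurrence <- function(labels, dims = semantic_dimensions()) {
  assert_df(labels, "labels")
  rep_words <- labels[labels$cardinality > 0, ]
  # Word x dimension membership matrix; crossprod gives shared-word counts.
  memb <- vapply(dims, function(d) {
    purrr::map_lgl(rep_words$dims, ~ d %in% .x)
  }, logical(nrow(rep_words)))
  if (nrow(rep_words) == 0) memb <- matrix(FALSE, 0, length(dims),
                                           dimnames = list(NULL, dims))
  shared <- crossprod(memb)
  counts <- diag(shared)
  if (any(counts == 0)) {
    warn(sprintf("Dimension(s) with zero representative words: %s.",
                 paste(dims[counts == 0], collapse = ", ")))
  }
  union <- outer(counts, counts, "+") - shared
  jaccard <- ifelse(union > 0, shared / union, 0)
  diag(jaccard) <- 1
  pr <- which(upper.tri(shared), arr.ind = TRUE)
  pairs <- tibble(
    dim_a = dims[pr[, 1]],
    dim_b = dims[pr[, 2]],
    shared = as.integer(shared[pr]),
    jaccard = jaccard[pr]
  )
  structure(
    list(dimensions = dims, counts = setNames(as.integer(counts), dims),
         pairs = pairs, shared = shared, jaccard = jaccard),
    class = "semdim_conetwork"
  )
}

#' @rdname cooccurrence
#' @param x A `semdim_conetwork` object.
#' @param ... Unused.
#' @export
tidy.semdim_conetwork <- function(x, ...) {
  x$pairs
}

#' @export
print.semdim_conetwork <- function(x, ...) {
  cat(sprintf("<semdim_conetwork> %d dimensions, %d words projected\n",
              length(x$dimensions), max(x$counts)))
  print(round(x$jaccard, 2))
  invisible(x)
}

#' Cluster dimensions by co-occurrence
#'
#' Average-linkage hierarchical clustering of the dimensions on the distance
#' 1 - Jaccard, cut at `k` clusters. Dimensions are ordered lexicographically
#' before clustering so that ties resolve deterministically; cluster ids are
#' renumbered so that cluster 1 contains the lexicographically first
#' dimension.
#'
#' @param network A `semdim_conetwork` from [cooccurrence()].
#' @param k Number of clusters (default 2).
#' @param method Linkage method passed to [stats::hclust()].
#' @return A tibble `dimension`, `cluster` (integer), in canonical dimension
#'   order.
#' @export
cluster_dimensions <- function(network, k = 2, method = "average") {
  dims <- network$dimensions
  if (k > length(dims)) {
    abort(sprintf("k = %d exceeds the number of dimensions (%d).",
                  k, length(dims)))
  }
  ord <- order(dims)
  jac <- network$jaccard[ord, ord]
  d <- as.dist(1 - jac)
  hc <- hclust(d, method = method)
  cl <- cutree(hc, k = k)
  # renumber clusters by first (lexicographic) appearance
  first_seen <- unique(cl)
  cl <- match(cl, first_seen)
  out <- tibble(dimension = dims[ord], cluster = as.integer(cl))
  out[match(dims, out$dimension), ]
}
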