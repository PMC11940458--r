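# Independent brute-force oracles and small fixture builders.

# Exclusivity via explicit loops, independent of exclusivity_score().
oracle_exclusivity <- function(x) {
  mx <- x[1]; mn <- x[1]; s <- 0
  for (v in x) {
    if (v > mx) mx <- v
    if (v < mn) mn <- v
    s <- s + v
  }
  (mx - mn) / s * 100
}

# Cronbach's alpha from first principles: explicit variance sums.
oracle_alpha <- function(mat) {
  k <- ncol(mat)
  n <- nrow(mat)
  col_var <- numeric(k)
  for (j in seq_len(k)) {
    m <- sum(mat[, j]) / n
    col_var[j] <- sum((mat[, j] - m)^2) / (n - 1)
  }
  tot <- rowSums(mat)
  mt <- sum(tot) / n
  var_tot <- sum((tot - mt)^2) / (n - 1)
  (k / (k - 1)) * (1 - sum(col_var) / var_tot)
}

# Random representative-label sets in the shape representative_labels() emits.
random_label_sets <- function(n_words, seed, p_dim = 0.35) {
  set.seed(seed)
  dims <- semantic_dimensions()
  sets <- lapply(seq_len(n_words), function(i) {
    dims[runif(8) < p_dim]
  })
  tibble::tibble(
    word = sprintf("w%04d", seq_len(n_words)),
    dims = sets,
    cardinality = lengths(sets),
    label = vapply(sets, paste, "", collapse = "|")
  )
}

# Long rating records for one word x variable cell.
cell_records <- function(values, word = "w1", variable = "SOC") {
  tibble::tibble(
    rater_id = sprintf("r%03d", seq_along(values)),
    list_id = "L01",
    word = word,
    variable = variable,
    value = values
  )
}

# A small but complete generator configuration for fast end-to-end tests.
small_gencfg <- function(...) {
  generator_config(
    n_items = 120, n_concrete = 20, n_lists = 3, raters_per_list = 12,
    ...
  )
}

small_config <- function(...) {
  cfg <- default_config()
  cfg$min_n_warn <- 1
  extra <- list(...)
  cfg[names(extra)] <- extra
  validate_config(cfg)
}
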