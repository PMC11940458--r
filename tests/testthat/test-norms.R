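test_that("aggregation computes mean, sample SD and n per cell", {
  rec <- dplyr::bind_rows(lapply(default_registry()$name, function(v) {
    cell_records(c(1, 7), variable = v)
  }))
  meta <- tibble::tibble(word = "w1", is_abstract = TRUE)
  norms <- suppressWarnings(aggregate_norms(rec, meta, min_n_warn = 1))
  expect_equal(norms$SOC_mean, 4)
  expect_equal(norms$SOC_sd, sqrt(18), tolerance = 1e-12)  # 4.2426
  expect_equal(norms$SOC_n, 2)
  expect_equal(ncol(norms), 2 + 3 * 15)
})

test_that("trimming one response decrements the cell count by one", {
  g <- small_gencfg(noise_sd = 0.5, outlier_rate = 0.005, seed = 51)
  rec <- simulate_ratings(make_profiles(g), g)
  out <- inject_outliers(rec, g)
  meta <- tibble::tibble(word = unique(rec$word), is_abstract = TRUE)
  before <- suppressWarnings(aggregate_norms(out$records, meta, min_n_warn = 1))
  res <- trim_responses(out$records)
  after <- suppressWarnings(aggregate_norms(res$records, meta, min_n_warn = 1))
  removed_per_word <- dplyr::count(res$removed, .data$word, .data$variable)
  for (i in seq_len(min(nrow(removed_per_word), 10))) {
    w <- removed_per_word$word[i]
    v <- removed_per_word$variable[i]
    expect_equal(after[[paste0(v, "_n")]][after$word == w],
                 before[[paste0(v, "_n")]][before$word == w] -
                   removed_per_word$n[i])
  }
})

test_that("words with no responses on a required variable are rejected", {
  rec <- dplyr::bind_rows(lapply(default_registry()$name, function(v) {
    cell_records(c(2, 3), variable = v)
  }))
  meta <- tibble::tibble(word = "w1", is_abstract = TRUE)
  missing_var <- rec[rec$variable != "SOC", ]
  expect_error(
    suppressWarnings(aggregate_norms(missing_var, meta, min_n_warn = 1)),
    "no responses"
  )
  expect_warning(aggregate_norms(rec, meta, min_n_warn = 20), "fewer than 20")
})

test_that("identical groups give t = 0 and full range inclusion", {
  n <- 20
  base <- tibble::tibble(word = sprintf("w%02d", 1:(2 * n)),
                         is_abstract = rep(c(TRUE, FALSE), each = n),
                         CNC_mean = rep(seq(2, 6, length.out = n), 2),
                         IMG_mean = rep(seq(2, 6, length.out = n), 2))
  cmp <- concreteness_comparison(base)
  expect_equal(cmp$per_variable$t_statistic, c(0, 0))
  expect_equal(cmp$n_abstract_in_concrete_range, n)
  expect_equal(unname(cmp$pct_above_6["concrete"]),
               unname(cmp$pct_above_6["abstract"]))
  expect_error(concreteness_comparison(base[base$is_abstract, ]), "group")
})

test_that("group comparison matches Welch's t-test and splits the range at 6", {
  set.seed(52)
  norms <- tibble::tibble(
    word = sprintf("w%03d", 1:120),
    is_abstract = rep(c(TRUE, FALSE), c(90, 30)),
    CNC_mean = c(runif(90, 1.2, 6.5), runif(30, 4.8, 7)),
    IMG_mean = c(runif(90, 1.5, 6.8), runif(30, 4.5, 7))
  )
  cmp <- concreteness_comparison(norms)
  ref <- t.test(norms$CNC_mean[!norms$is_abstract],
                norms$CNC_mean[norms$is_abstract])
  expect_equal(cmp$per_variable$t_statistic[1], unname(ref$statistic))
  expect_equal(cmp$per_variable$p_value[1], ref$p.value)

  conc <- norms$CNC_mean[!norms$is_abstract]
  abst <- norms$CNC_mean[norms$is_abstract]
  in_rng <- abst >= min(conc) & abst <= max(conc)
  expect_equal(cmp$n_abstract_in_concrete_range, sum(in_rng))
  # split-at-6 counts partition each group's in-range words
  expect_equal(sum(cmp$range_split$n_concrete[1:2]), cmp$range_split$n_concrete[3])
  expect_equal(sum(cmp$range_split$n_abstract[1:2]), cmp$range_split$n_abstract[3])
  expect_equal(cmp$range_split$n_abstract[3], cmp$n_abstract_in_concrete_range)
  g <- glance(cmp)
  expect_equal(g$n_abstract_in_concrete_range, sum(in_rng))
})

test_that("the correlation matrix matches a brute-force oracle", {
  set.seed(53)
  norms <- tibble::tibble(word = sprintf("w%02d", 1:10), is_abstract = TRUE)
  for (v in default_registry()$name) {
    norms[[paste0(v, "_mean")]] <- runif(10, 1, 7)
  }
  cm <- correlation_matrix(norms)
  expect_equal(dim(cm$r), c(15, 15))
  expect_equal(diag(cm$r), rep(1, 15), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))

  # brute-force covariance / sd oracle on a pair
  for (pair in list(c("CNC", "IMG"), c("SOC", "ECO"), c("AoA", "SEM_DIV"))) {
    x <- norms[[paste0(pair[1], "_mean")]]
    y <- norms[[paste0(pair[2], "_mean")]]
    cov_xy <- sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
    r_oracle <- cov_xy / (sd(x) * sd(y))
    expect_equal(cm$r[pair[1], pair[2]], r_oracle, tolerance = 1e-12)
    ct <- cor.test(x, y)
    expect_equal(cm$p[pair[1], pair[2]], ct$p.value, tolerance = 1e-12)
  }

  # anti-correlated constructed pair
  norms$VAL_mean <- 10 - norms$ARO_mean
  cm2 <- correlation_matrix(norms)
  expect_equal(cm2$r["VAL", "ARO"], -1)

  # permutation invariance
  perm <- sample(nrow(norms))
  cm3 <- correlation_matrix(norms[perm, ])
  expect_equal(cm3$r, cm2$r)

  # zero-variance variable: NaN with a warning
  norms$FAM_mean <- 4
  expect_warning(cm4 <- correlation_matrix(norms), "Zero-variance")
  expect_true(is.na(cm4$r["FAM", "CNC"]))
})
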