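test_that("careless flagging uses a strict modal-share inequality", {
  # 80 identical responses of 80 -> flagged (100% > 85%)
  rec <- tibble::tibble(
    rater_id = "r1", list_id = "L01",
    word = sprintf("w%02d", 1:80), variable = "SOC", value = 5
  )
  fl <- flag_careless(rec)
  expect_true(fl$careless)

  # modal share exactly 0.85 -> NOT flagged
  rec2 <- tibble::tibble(
    rater_id = "r2", list_id = "L01",
    word = sprintf("w%02d", 1:20), variable = "SOC",
    value = c(rep(5, 17), 1, 2, 3)
  )
  fl2 <- flag_careless(rec2, threshold = 0.85)
  expect_equal(fl2$modal_share, 0.85)
  expect_false(fl2$careless)

  # one response above the threshold -> flagged
  rec3 <- rec2
  rec3$value[18] <- 5
  expect_true(flag_careless(rec3)$careless)
})

test_that("age-of-acquisition responses do not count toward carelessness", {
  # constant ages but varied Likert responses: not careless
  rec <- dplyr::bind_rows(
    cell_records(rep(6, 30), variable = "AoA"),
    cell_records(c(rep(1:7, 4), 1, 2), variable = "SOC")
  )
  rec$rater_id <- "r1"
  rec$word <- sprintf("w%02d", seq_len(nrow(rec)))
  expect_false(flag_careless(rec)$careless)
})

test_that("incomplete raters are flagged against the list design", {
  g <- small_gencfg(seed = 31)
  rec <- simulate_ratings(make_profiles(g), g)
  full <- flag_incomplete(rec)
  expect_false(any(full$incomplete))

  # drop half of one rater's responses
  victim <- rec$rater_id[1]
  drop <- which(rec$rater_id == victim)
  drop <- drop[seq_len(floor(length(drop) / 2))]
  fl <- flag_incomplete(rec[-drop, ])
  expect_true(fl$incomplete[fl$rater_id == victim])
  expect_equal(sum(fl$incomplete), 1)

  # a 90% completeness fraction retains a rater with 95% of responses
  fl2 <- flag_incomplete(
    tibble::tibble(rater_id = "r9", n = 1:19)["rater_id"] |>
      dplyr::mutate(list_id = "L01", word = sprintf("w%02d", 1:19),
                    variable = "SOC", value = 4),
    expected = 20, completeness_fraction = 0.9
  )
  expect_false(fl2$incomplete)
})

test_that("3-SD trimming matches a hand-computed oracle", {
  # 24 responses at 6 and one at 1: mean 5.8, sample SD 1; |1 - 5.8| > 3
  vals <- c(rep(6, 24), 1)
  expect_equal(mean(vals), 5.8)
  expect_equal(sd(vals), 1)
  res <- trim_responses(cell_records(vals))
  expect_equal(nrow(res$removed), 1)
  expect_equal(res$removed$value, 1)
  expect_equal(nrow(res$records), 24)
  expect_equal(res$pct_removed_by_variable$pct_removed, 4)

  # constant cell: SD 0, nothing removed
  res0 <- trim_responses(cell_records(rep(4, 5)))
  expect_equal(nrow(res0$removed), 0)

  # a response exactly at 3 SD is kept (strict inequality)
  # cell: 1, 2, 3 -> mean 2, sd 1; nothing is 3 SD away
  res1 <- trim_responses(cell_records(c(1, 2, 3)))
  expect_equal(nrow(res1$removed), 0)
})

test_that("leave-one-out trimming is stricter on isolated outliers", {
  vals <- c(rep(6, 10), 2)
  inc <- trim_responses(cell_records(vals))
  loo <- trim_responses(cell_records(vals), leave_one_out = TRUE)
  # with the candidate excluded the remaining cell is constant at 6 with
  # positive distance, so leave-one-out cannot fire (SD = 0); add jitter
  vals2 <- c(5, 6, 6, 6, 7, 6, 5, 6, 7, 6, 1)
  loo2 <- trim_responses(cell_records(vals2), leave_one_out = TRUE)
  expect_true(1 %in% loo2$removed$value)
  expect_false(1 %in% loo2$records$value)
  expect_equal(nrow(loo$removed) + nrow(loo$records), length(vals))
  expect_equal(nrow(inc$removed) + nrow(inc$records), length(vals))
})

test_that("planted careless raters are recovered exactly at the 85% rule", {
  g <- generator_config(n_items = 200, n_concrete = 30, n_lists = 5,
                        raters_per_list = 12, noise_sd = 1,
                        careless_rate = 0.15, seed = 32)
  rec <- simulate_ratings(make_profiles(g), g)
  out <- inject_careless(rec, g)
  fl <- flag_careless(out$records, threshold = 0.85)
  expect_setequal(fl$rater_id[fl$careless], out$careless_raters)
})

test_that("removal percentages stay below 2% at 1% contamination, with masking quantified", {
  g <- generator_config(n_items = 1000, n_concrete = 0, n_lists = 25,
                        raters_per_list = 25, noise_sd = 0.5,
                        outlier_rate = 0.01, seed = 1)
  rec <- simulate_ratings(make_profiles(g), g)
  out <- inject_outliers(rec, g)
  res <- trim_responses(out$records)
  expect_true(all(res$pct_removed_by_variable$pct_removed < 2))
  expect_true(all(res$pct_removed_by_variable$pct_removed >= 0))

  removed <- paste(res$removed$rater_id, res$removed$word, res$removed$variable)
  planted <- paste(out$outliers$rater_id, out$outliers$word, out$outliers$variable)
  # outliers alone in their cell are essentially always caught; aggregate
  # recall at this density is lower because co-occurring planted outliers
  # inflate the cell SD and mask each other (single-pass, include-self rule)
  cellcnt <- dplyr::count(out$outliers, .data$word, .data$variable)
  multi_cells <- paste(cellcnt$word[cellcnt$n > 1], cellcnt$variable[cellcnt$n > 1])
  solo <- !(paste(out$outliers$word, out$outliers$variable) %in% multi_cells)
  expect_gte(mean((planted %in% removed)[solo]), 0.99)
  expect_gte(mean(planted %in% removed), 0.85)
})

test_that("the QC pipeline excludes flagged raters before trimming", {
  g <- generator_config(n_items = 100, n_concrete = 0, n_lists = 2,
                        raters_per_list = 15, noise_sd = 1,
                        careless_rate = 0.2, seed = 33)
  rec <- simulate_ratings(make_profiles(g), g)
  out <- inject_careless(rec, g)
  res <- qc_pipeline(out$records, small_config())
  expect_setequal(
    res$excluded_raters$rater_id[res$excluded_raters$reason == "careless"],
    out$careless_raters
  )
  expect_false(any(res$records$rater_id %in% out$careless_raters))
  expect_true(all(res$pct_removed_by_variable$pct_removed >= 0 &
                    res$pct_removed_by_variable$pct_removed <= 100))
})
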