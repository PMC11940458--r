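test_that("generator output is deterministic given the seed", {
  g <- small_gencfg(noise_sd = 1, careless_rate = 0.1, outlier_rate = 0.01,
                    seed = 11)
  a <- make_profiles(g)
  b <- make_profiles(g)
  expect_identical(a, b)
  ra <- simulate_ratings(a, g)
  rb <- simulate_ratings(b, g)
  expect_identical(ra, rb)
  expect_identical(inject_careless(ra, g), inject_careless(rb, g))
  expect_identical(inject_outliers(ra, g), inject_outliers(rb, g))
})

test_that("latent exclusivity equals the formula applied to the true means", {
  p <- make_profiles(small_gencfg(seed = 4))
  dims <- semantic_dimensions()
  m <- as.matrix(p[p$is_abstract, dims])
  expect_equal(p$latent_E[p$is_abstract], apply(m, 1, oracle_exclusivity))
  expect_true(all(is.na(p$latent_E[!p$is_abstract])))
  # relevant dimensions sit above 3.5, irrelevant at or below
  for (i in which(p$is_abstract)[1:25]) {
    rel <- p$relevant_dims[[i]]
    expect_true(all(m[match(p$word[i], p$word[p$is_abstract]), rel] > 3.5))
    expect_true(all(m[match(p$word[i], p$word[p$is_abstract]),
                      setdiff(dims, rel)] <= 3.5))
  }
})

test_that("all simulated values lie within their variable's scale bounds", {
  g <- small_gencfg(noise_sd = 2, seed = 5)
  rec <- simulate_ratings(make_profiles(g), g)
  reg <- default_registry()
  scl <- reg[match(rec$variable, reg$name), ]
  expect_true(all(rec$value >= scl$scale_min & rec$value <= scl$scale_max))
  # integers on Likert scales
  lik <- rec$variable %in% setdiff(reg$name, "AoA")
  expect_true(all(rec$value[lik] == round(rec$value[lik])))
})

test_that("noiseless ratings reproduce the rounded latent profile exactly", {
  g <- small_gencfg(noise_sd = 0, seed = 6)
  p <- make_profiles(g)
  rec <- simulate_ratings(p, g)
  obs <- rec |>
    dplyr::filter(.data$variable %in% semantic_dimensions()) |>
    dplyr::group_by(.data$word, .data$variable) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop")
  truth <- tidyr::pivot_longer(
    p[, c("word", semantic_dimensions())], -"word",
    names_to = "variable", values_to = "true"
  )
  j <- dplyr::inner_join(obs, truth, by = c("word", "variable"))
  expect_equal(j$m, sign(j$true) * floor(abs(j$true) + 0.5))
})

test_that("observed cell means track the latent means (CLT bound, interior cells)", {
  # 25 raters, unit noise: |cell mean - true mean| <= 3/sqrt(25) should hold
  # for >= 99% of cells whose true mean is away from the scale ends (clamping
  # at the bounds biases extreme cells; see the methods vignette).
  g <- generator_config(n_items = 2000, n_concrete = 0, n_lists = 50,
                        raters_per_list = 25, noise_sd = 1, seed = 5)
  p <- make_profiles(g)
  rec <- simulate_ratings(p, g)
  obs <- rec |>
    dplyr::filter(.data$variable %in% semantic_dimensions()) |>
    dplyr::group_by(.data$word, .data$variable) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop")
  truth <- tidyr::pivot_longer(
    p[, c("word", semantic_dimensions())], -"word",
    names_to = "variable", values_to = "true"
  )
  j <- dplyr::inner_join(obs, truth, by = c("word", "variable"))
  interior <- j$true >= 2 & j$true <= 6
  expect_gt(sum(interior), 5000)
  expect_gte(mean(abs(j$m - j$true)[interior] <= 3 / sqrt(25)), 0.99)
})

test_that("semantic-diversity coupling is calibrated", {
  g <- generator_config(n_items = 2000, n_concrete = 0, semdiv_coupling = -0.47,
                        seed = 11)
  p <- make_profiles(g)
  r <- cor(p$latent_E, p$SEM_DIV)
  expect_lt(abs(r - (-0.47)), 0.05)
})

test_that("careless injection replaces the configured fraction of raters", {
  g <- generator_config(n_items = 50, n_concrete = 0, n_lists = 5,
                        raters_per_list = 10, careless_rate = 0.1, seed = 7)
  rec <- simulate_ratings(make_profiles(g), g)
  out <- inject_careless(rec, g)
  expect_length(out$careless_raters, 5)  # round(0.1 * 50)
  lik <- setdiff(default_registry()$name, "AoA")
  for (rt in out$careless_raters) {
    vals <- out$records$value[out$records$rater_id == rt &
                                out$records$variable %in% lik]
    expect_equal(length(unique(vals)), 1)
  }
  # AoA untouched
  expect_identical(
    out$records$value[out$records$variable == "AoA"],
    rec$value[rec$variable == "AoA"]
  )
  # rate 0: identity
  g0 <- generator_config(n_items = 50, n_concrete = 0, n_lists = 5,
                         raters_per_list = 10, careless_rate = 0, seed = 7)
  expect_identical(inject_careless(rec, g0)$records, rec)
})

test_that("outlier injection stays within scale bounds and reports triples", {
  g <- small_gencfg(noise_sd = 0.5, outlier_rate = 0.02, seed = 8)
  rec <- simulate_ratings(make_profiles(g), g)
  out <- inject_outliers(rec, g)
  expect_equal(nrow(out$outliers),
               round(0.02 * sum(rec$variable != "AoA")))
  reg <- default_registry()
  scl <- reg[match(out$records$variable, reg$name), ]
  expect_true(all(out$records$value >= scl$scale_min &
                    out$records$value <= scl$scale_max))
  # planted values sit at a scale extreme
  key <- paste(out$outliers$rater_id, out$outliers$word, out$outliers$variable)
  hit <- paste(out$records$rater_id, out$records$word, out$records$variable) %in% key
  sc <- reg[match(out$records$variable[hit], reg$name), ]
  expect_true(all(out$records$value[hit] == sc$scale_min |
                    out$records$value[hit] == sc$scale_max))
  # rate 0: identity
  g0 <- small_gencfg(noise_sd = 0.5, outlier_rate = 0, seed = 8)
  expect_identical(inject_outliers(rec, g0)$records, rec)
})

test_that("generator config validation rejects out-of-range parameters", {
  expect_error(generator_config(careless_rate = 1.2), "careless_rate")
  expect_error(generator_config(relevant_level_range = c(3, 6)), "relevant_level_range")
  expect_error(generator_config(irrelevant_level_range = c(1, 4)), "irrelevant_level_range")
  expect_error(generator_config(semdiv_coupling = 0.3), "semdiv_coupling")
  expect_error(generator_config(dimension_families = list("INTRO", "NOPE")),
               "dimension_families")
})

test_that("ground-truth export has one row per word", {
  p <- make_profiles(small_gencfg(seed = 9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(p, path)
  gt <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(gt), nrow(p))
  expect_named(gt, c("word", "latent_E", "relevant_dims"))
})
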