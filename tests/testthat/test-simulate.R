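test_that("configurations are validated and defaults match the study design", {
  cfg <- simulation_config(seed = 1)
  expect_equal(cfg$n_populations, 16L)
  expect_equal(cfg$n_ethanol_levels, 7L)
  expect_error(simulation_config(n_populations = 0), ">= 1")
  expect_error(simulation_config(proteomics_missing_rate = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(gompertz_truth = c(1, 2)), "four values")
})

test_that("identical configurations give bit-identical outputs", {
  a <- simulate_mutation_dataset(simulation_config(seed = 9))
  b <- simulate_mutation_dataset(simulation_config(seed = 9))
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$catalog, b$catalog)
  expect_false(identical(
    a$mutations, simulate_mutation_dataset(simulation_config(seed = 10))$mutations))

  ra <- simulate_reporter_series(simulation_config(seed = 9), 300)
  rb <- simulate_reporter_series(simulation_config(seed = 9), 300)
  expect_identical(ra$series, rb$series)

  pa <- simulate_protein_matrix(simulation_config(seed = 9), n_proteins = 50)
  pb <- simulate_protein_matrix(simulation_config(seed = 9), n_proteins = 50)
  expect_identical(pa$quant$intensity, pb$quant$intensity)
})

test_that("an empty genome yields an empty dataset and empty downstream results", {
  sim <- simulate_mutation_dataset(simulation_config(seed = 1, n_genes = 0))
  expect_equal(nrow(sim$mutations), 0)
  expect_length(build_mutation_matrices(sim$mutations), 0)
  res <- priority_rank(sim$mutations, sim$catalog)
  expect_equal(nrow(res), 0)
})

test_that("the planted TCS is strictly top-ranked", {
  sim <- simulate_mutation_dataset(simulation_config(seed = 1))
  res <- priority_rank(sim$mutations, sim$catalog, n_populations = 16, n_levels = 7)
  expect_equal(res$tcs[res$rank == 1], sim$truth$planted_top_tcs)
  top2 <- sort(res$pscore, decreasing = TRUE)[1:2]
  expect_gt(top2[1], top2[2])   # strict, not tie-broken
})

test_that("noise-free reporter series invert to the planted rF", {
  cfg <- simulation_config(seed = 2, reporter_noise_sd = 0)
  sim <- simulate_reporter_series(cfg, 375)
  expect_equal(unname(relative_fluorescence(sim$series)), rep(375, 11))

  # rF = 0 means the sample fluoresces exactly like the blank
  zero <- simulate_reporter_series(cfg, 0)
  expect_equal(zero$series$f_sample, zero$series$f_blank)

  # time-varying planted curve
  ramp <- simulate_reporter_series(cfg, function(t) 100 + 20 * t)
  expect_equal(unname(relative_fluorescence(ramp$series)), 100 + 20 * (0:10))
})

test_that("noisy rF estimates stay within 3 sd / sqrt(n) of truth", {
  true_rf <- 400
  ests <- vapply(1:50, function(s) {
    cfg <- simulation_config(seed = s, reporter_noise_sd = 5)
    sim <- simulate_reporter_series(cfg, true_rf)
    # late time points where the OD difference is large and stable
    mean(relative_fluorescence(sim$series, t = 7:10))
  }, numeric(1))
  # delta method: sd(rF) ~ noise_sd / (OD_s - OD_b) ~ 5 / 1.0 per point
  expect_lt(abs(mean(ests) - true_rf), 3 * 5 / sqrt(50 * 4))
})

test_that("planted differential proteins are recovered exactly in the clean design", {
  cfg <- simulation_config(seed = 4, proteomics_missing_rate = 0)
  sim <- simulate_protein_matrix(cfg, n_proteins = 300, planted_de = 1:12,
                                 log2fc = 3, within_sd = 0.1)
  x <- valid_value_filter(filter_records(sim$quant))
  x <- impute_missing(x, seed = 4)
  de <- differential_test(x, "A", "B")
  expect_setequal(de$protein[de$significant], sim$truth$planted_de)
})

test_that("a null matrix with tiny noise passes nothing through the fold gate", {
  cfg <- simulation_config(seed = 5, proteomics_missing_rate = 0)
  sim <- simulate_protein_matrix(cfg, n_proteins = 200, planted_de = character(),
                                 within_sd = 1e-3)
  de <- differential_test(impute_missing(sim$quant, seed = 5), "A", "B")
  expect_equal(sum(de$significant), 0)
})

test_that("a fully censored group removes the protein via the valid-value filter", {
  m <- matrix(rnorm(5 * 8, 25, 0.5), 5, 8,
              dimnames = list(sprintf("p%d", 1:5), NULL))
  m[1, ] <- NA   # censored everywhere
  m[2, 1:4] <- NA; m[2, 7:8] <- NA  # < 3 valid in both groups
  x <- protein_quant(m, rep(c("A", "B"), each = 4))
  kept <- valid_value_filter(x)
  expect_setequal(rownames(kept$intensity), c("p3", "p4", "p5"))
})

test_that("censoring is left-tailed at the configured rate", {
  full <- simulate_protein_matrix(
    simulation_config(seed = 6, proteomics_missing_rate = 0),
    n_proteins = 400)$quant$intensity
  cens <- simulate_protein_matrix(
    simulation_config(seed = 6, proteomics_missing_rate = 0.2),
    n_proteins = 400)$quant$intensity
  # same seed, censoring is deterministic: the underlying values coincide,
  # and exactly the sub-quantile values are masked
  expect_identical(full[!is.na(cens)], cens[!is.na(cens)])
  for (j in seq_len(ncol(full))) {
    expect_equal(mean(is.na(cens[, j])), 0.2, tolerance = 0.015)
    expected_na <- full[, j] < quantile(full[, j], 0.2)
    expect_identical(is.na(cens[, j]), expected_na)
  }
})

test_that("rendered plates carry valid grids and reject ill-fitting disks", {
  cfg <- simulation_config(seed = 7, spot_grid = c(2, 2))
  ok <- render_spot_plate(cfg, data.frame(row = 1, col = 2, radius = 30,
                                          intensity = 200))
  expect_s3_class(ok$plate, "spot_plate")
  m <- measure_spot(split_grid(ok$plate)[["r1c2"]], intensity_on = "mask")
  expect_equal(m$mean_intensity, 200)

  expect_error(render_spot_plate(
    cfg, data.frame(row = 1, col = 1, radius = 60, intensity = 200)),
    "fit fully inside")
  expect_error(render_spot_plate(
    cfg, data.frame(row = 5, col = 1, radius = 10, intensity = 200)),
    "outside the plate")
})

test_that("fermentation series follow the planted Gompertz truth", {
  cfg <- simulation_config(seed = 8)
  sim <- simulate_fermentation(cfg)
  fit <- fit_gompertz(sim$series$time, sim$series$ethanol_g)
  for (p in c("A", "mu", "lambda")) {
    expect_lt(abs(fit$parameters[p] - sim$truth[p]) / sim$truth[p], 1e-6)
  }
  expect_true(all(diff(sim$series$glucose_g_l) <= 1e-9))  # glucose never rises

  flat <- simulate_fermentation(
    simulation_config(seed = 8, gompertz_truth = c(10, 0, 10, 2)))
  expect_equal(production_rate(flat$series$time, flat$series$ethanol_g), 0)
})

test_that("planted production-rate contrasts are recovered", {
  base <- c(A = 20, mu = 0.3, lambda = 10, y0 = 0)
  fast <- base; fast["mu"] <- 0.3 * 1.35
  rates <- vapply(1:6, function(s) {
    wt <- simulate_fermentation(simulation_config(seed = s, gompertz_truth = base),
                                noise_sd = 0.2)
    mu <- simulate_fermentation(simulation_config(seed = 100 + s,
                                                  gompertz_truth = fast),
                                noise_sd = 0.2)
    c(fit_gompertz(wt$series$time, wt$series$ethanol_g)$production_rate,
      fit_gompertz(mu$series$time, mu$series$ethanol_g)$production_rate)
  }, numeric(2))
  rc <- rate_contrast(rates[1, ], rates[2, ])
  expect_equal(rc$ratio, 1.35, tolerance = 0.05)
  expect_lt(rc$p_value, 0.05)
})
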