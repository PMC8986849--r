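test_that("noiseless mono-exponential fits recover generating parameters exactly", {
  cases <- list(c(T1 = 1.0, Iinf = 1, B = 2),
                c(T1 = 0.05, Iinf = 3.2, B = 1.8),
                c(T1 = 12, Iinf = -2, B = 2.1))
  for (p in cases) {
    s <- make_ir_series(p[["T1"]], p[["Iinf"]], p[["B"]])
    f <- fit_inversion_recovery(s)
    expect_true(f$converged)
    expect_lt(abs(f$time_constant / p[["T1"]] - 1), 1e-8)
    expect_lt(abs(f$amplitude / p[["Iinf"]] - 1), 1e-8)
    expect_lt(abs(f$inversion_factor / p[["B"]] - 1), 1e-8)
    expect_equal(f$rate * f$time_constant, 1)
  }
  f <- fit_cpmg_decay(make_cpmg_series(T2 = 0.25))
  expect_equal(f$rate, 4.0, tolerance = 1e-10)
  expect_equal(f$loglinear_rate, 4.0, tolerance = 1e-10)
})

test_that("rate estimates are scale-equivariant and order-insensitive", {
  s <- make_ir_series(0.7, 1.5, 1.9)
  f1 <- fit_inversion_recovery(s)
  s2 <- decay_series(s$delays, 137.5 * s$intensities,
                     experiment = "inversion_recovery")
  f2 <- fit_inversion_recovery(s2)
  expect_equal(f1$rate, f2$rate, tolerance = 1e-9)

  # jointly permute then re-sort the points: fit must be identical
  set.seed(7)
  p <- sample(length(s$delays))
  o <- order(s$delays[p])
  s3 <- decay_series(s$delays[p][o], s$intensities[p][o],
                     experiment = "inversion_recovery")
  f3 <- fit_inversion_recovery(s3)
  expect_identical(f1$rate, f3$rate)

  c1 <- fit_cpmg_decay(make_cpmg_series(0.1, 2))
  c2 <- fit_cpmg_decay(make_cpmg_series(0.1, 2 * 0.003))
  expect_equal(c1$rate, c2$rate, tolerance = 1e-9)
})

test_that("noisy inversion recovery matches truth and an independent grid-search oracle", {
  set.seed(42)
  s <- make_ir_series(1.0, 1, 2, n = 12, sigma = 0.01)
  f <- fit_inversion_recovery(s)
  expect_true(f$converged)
  se_T1 <- f$stderr_rate / f$rate^2
  expect_lt(abs(f$time_constant - 1.0), 3 * se_T1)

  g <- ir_grid_oracle(s$delays, s$intensities,
                      T1_grid = seq(0.85, 1.15, by = 0.005),
                      Iinf_grid = seq(0.95, 1.05, by = 0.005),
                      B_grid = seq(1.9, 2.1, by = 0.005))
  expect_lt(abs(f$time_constant - g[["T1"]]), 0.005)
  expect_lt(abs(f$amplitude - g[["Iinf"]]), 0.005)
})

test_that("noisy CPMG fit agrees with the log-linear cross-check and truth", {
  set.seed(11)
  s <- make_cpmg_series(T2 = 0.25, n = 12, sigma = 0.02)
  f <- fit_cpmg_decay(s)
  expect_lt(abs(f$rate - 4.0), 3 * f$stderr_rate)
  expect_lt(abs(f$rate / f$loglinear_rate - 1), 0.02)
})

test_that("a 16.6-fold T2 contrast is recovered as a 16.6-fold rate ratio", {
  set.seed(3)
  slow <- fit_cpmg_decay(make_cpmg_series(T2 = 0.415, n = 12, sigma = 0.005))
  fast <- fit_cpmg_decay(make_cpmg_series(T2 = 0.415 / 16.6, n = 12,
                                          sigma = 0.005))
  expect_equal(fast$rate / slow$rate, 16.6, tolerance = 0.01)
})

test_that("degenerate and invalid decay inputs are refused", {
  # constant intensities: no recovery -> flagged, not an error
  flat <- decay_series(c(0.1, 0.2, 0.4, 0.8, 1.6),
                       rep(1, 5), experiment = "inversion_recovery")
  f <- fit_inversion_recovery(flat)
  expect_false(f$converged)
  expect_true(length(f$flags) > 0)

  # growing "decay" has no positive log-linear slope
  grow <- decay_series(c(0.1, 0.2, 0.3, 0.4), c(1, 2, 3, 4),
                       experiment = "cpmg")
  expect_error(fit_cpmg_decay(grow), "decay")

  # too few positive points
  neg <- decay_series(1:5 / 10, c(1, 0.5, -0.1, -0.2, -0.3),
                      experiment = "cpmg")
  expect_error(fit_cpmg_decay(neg), "positive")

  expect_error(decay_series(c(0.1, 0.2, 0.2, 0.3), 1:4,
                            experiment = "cpmg"), "increasing")
  expect_error(decay_series(c(0.1, 0.2, 0.3), 1:3, experiment = "cpmg"),
               "at least 4")
  expect_error(fit_cpmg_decay(make_ir_series()), "not a CPMG")
  expect_error(fit_inversion_recovery(make_cpmg_series()),
               "not an inversion-recovery")
})

test_that("time-constant/rate conversion is exact and guards its domain", {
  expect_equal(rate_from_time_constant(0.5), 2.0)
  expect_equal(rate_from_time_constant(1.0), 1.0)
  expect_equal(rate_from_time_constant(0.0125), 80)
  expect_error(rate_from_time_constant(0), "positive")
  expect_error(rate_from_time_constant(-1), "positive")
})

test_that("decay tables round-trip through CSV and batch fitting", {
  gt <- ground_truth(noise_sigma = 0, T_M1 = 0, T_M2 = 0)
  df <- simulate_decays(gt, temperatures = 298.15, fields = 500, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  back <- read_decay_csv(path)
  rt <- fit_decay_table(back)
  expect_setequal(rt$condition,
                  c("paramagnetic", "diamagnetic", "blocked_rotaxane"))
  dia <- rt[rt$condition == "diamagnetic", ]
  expect_equal(dia$R1_obs, gt$R1_0, tolerance = 1e-7)
  expect_equal(dia$R2_obs, gt$R2_0, tolerance = 1e-7)
})
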