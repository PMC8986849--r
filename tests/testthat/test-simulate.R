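test_that("the general inner-sphere model reduces to f/tau_M in the exact limit", {
  gt <- ground_truth(T_M1 = 0, T_M2 = 0, R1_os = 0, R2_os = 0,
                     noise_sigma = 0)
  temps <- seq(263.15, 343.15, by = 10)
  rp <- simulate_rp_general(gt, temps)
  expect_equal(rp$R1_p, rp$f / rp$tau_M, tolerance = 1e-14)
  expect_equal(rp$R2_p, rp$f / rp$tau_M, tolerance = 1e-14)
})

test_that("the simplified analysis is accurate at tau_M >= 100 T_M and biased at tau_M <= 3 T_M", {
  temps <- seq(263.15, 343.15, by = 10)

  # slow preset: tau_M dominates everywhere
  slow <- ground_truth(noise_sigma = 0)
  rp <- simulate_rp_general(slow, temps)
  expect_true(all(rp$tau_M >= 100 * rp$T_M1))
  tau_hat <- rp$f / (rp$R1_p - rp$R1_os)   # simplified Eq.-2 analysis
  expect_true(all(abs(tau_hat / rp$tau_M - 1) <= 0.01))

  # intermediate exchange: same analysis acquires > 10% bias
  inter <- gt_preset("intermediate", noise_sigma = 0)
  rpi <- simulate_rp_general(inter, temps)
  sel <- rpi$tau_M <= 3 * rpi$T_M1
  expect_true(any(sel))
  tau_hat_i <- rpi$f / (rpi$R1_p - rpi$R1_os)
  expect_true(all(abs(tau_hat_i[sel] / rpi$tau_M[sel] - 1) > 0.10))
})

test_that("simulated decay tables are deterministic given the seed", {
  gt <- ground_truth()
  a <- simulate_decays(gt, temperatures = c(278.15, 298.15), fields = 500,
                       seed = 42)
  b <- simulate_decays(gt, temperatures = c(278.15, 298.15), fields = 500,
                       seed = 42)
  expect_identical(a, b)
  c <- simulate_decays(gt, temperatures = c(278.15, 298.15), fields = 500,
                       seed = 43)
  expect_false(identical(a$intensity, c$intensity))

  # byte-identical files from identical seed + config
  d1 <- tempfile(); d2 <- tempfile()
  st1 <- simulate_study(gt, temperatures = c(278.15, 298.15, 318.15),
                        fields = 500, seed = 7, dir = d1)
  st2 <- simulate_study(gt, temperatures = c(278.15, 298.15, 318.15),
                        fields = 500, seed = 7, dir = d2)
  for (f in c("decays.csv", "conc_decays.csv", "titration.csv",
              "ground_truth.json", "config.yaml")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("ground truth round-trips through its JSON sidecar", {
  gt <- gt_preset("vp_like", noise_sigma = 0.02, seed = 9)
  dir <- tempfile()
  simulate_study(gt, temperatures = seq(293.15, 343.15, by = 25),
                 fields = 500, dir = dir)
  back <- read_ground_truth(file.path(dir, "ground_truth.json"))
  expect_s3_class(back, "ground_truth")
  expect_equal(back$Ka, gt$Ka)
  expect_equal(back$dS_act, gt$dS_act)
  expect_equal(back$seed, gt$seed)
  unlink(dir, recursive = TRUE)
})

test_that("simulated decays embed the generative rates", {
  gt <- ground_truth(noise_sigma = 0, T_M1 = 0, T_M2 = 0)
  df <- simulate_decays(gt, temperatures = 298.15, fields = 500, seed = 1)
  rt <- fit_decay_table(df)
  rp <- simulate_rp_general(gt, 298.15)
  pa <- rt[rt$condition == "paramagnetic", ]
  ro <- rt[rt$condition == "blocked_rotaxane", ]
  expect_equal(pa$R1_obs, gt$R1_0 + rp$R1_p, tolerance = 1e-7)
  expect_equal(pa$R2_obs, gt$R2_0 + rp$R2_p, tolerance = 1e-7)
  expect_equal(ro$R1_obs, gt$R1_0 + rp$R1_os, tolerance = 1e-7)
})

test_that("generator guards its preconditions", {
  expect_error(ground_truth(Ka = -1))
  expect_error(ground_truth(R_empty = 1, R_sat = 5))
  gt <- ground_truth()
  expect_error(simulate_decays(gt, n_delays = 4), "n_delays")
  expect_error(simulate_titration(gt, guest_grid = c(1e-4, 2e-4)),
               "span")
})
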