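para <- function(R1, R2, s1 = 0, s2 = 0, ...)
  rate_record("paramagnetic", R1, R2, s1, s2, ...)
dia <- function(R1, R2, s1 = 0, s2 = 0, ...)
  rate_record("diamagnetic", R1, R2, s1, s2, ...)
rot <- function(R1, R2, s1 = 0, s2 = 0, ...)
  rate_record("blocked_rotaxane", R1, R2, s1, s2, ...)

test_that("paramagnetic contribution is the observed-minus-control difference", {
  # trivial control R_0 = 0
  pr <- compute_Rp(para(11.94, 10.02), dia(0, 0))
  expect_equal(pr$R1_p, 11.94)
  expect_equal(pr$R2_p, 10.02)

  # identical observed and control rates
  pr0 <- compute_Rp(para(3, 4), dia(3, 4))
  expect_equal(pr0$R1_p, 0)
  expect_equal(pr0$R2_p, 0)

  # quadrature error combination
  pr2 <- compute_Rp(para(5, 5, 0.1, 0.1), dia(1, 1, 0.1, 0.1))
  expect_equal(pr2$R1_p, 4.0)
  expect_equal(pr2$R1_p_err, sqrt(0.02), tolerance = 1e-12)
})

test_that("negative differences are clamped within noise and rejected beyond it", {
  expect_warning(pr <- compute_Rp(para(1.0, 2, 0.1, 0), dia(1.1, 2, 0.1, 0)),
                 "clamped")
  expect_equal(pr$R1_p, 0)
  expect_true(pr$clamped)
  expect_error(compute_Rp(para(1.0, 2, 0.01, 0), dia(2.0, 2, 0.01, 0)),
               "inconsistent")
})

test_that("outer-sphere correction subtracts the rotaxane-derived R_os", {
  pr <- compute_Rp(para(10.91, 10.91), dia(0, 0))
  cor <- correct_outer_sphere(pr, rot(1.03, 1.38), dia(0, 0))
  expect_equal(cor$R1_os, 1.03)
  expect_equal(cor$R1_inner, 9.88)
  expect_true(cor$corrected)

  # R_os = 0 leaves R_p untouched
  cor0 <- correct_outer_sphere(compute_Rp(para(5, 5), dia(1, 1)),
                               rot(1, 1), dia(1, 1))
  expect_equal(cor0$R1_inner, cor0$R1_p)

  # additivity: chained subtraction equals single-shot R_obs - R_0 - R_os
  R_obs <- 7.31; R_0 <- 0.52; R_os_true <- 0.97
  cor2 <- correct_outer_sphere(compute_Rp(para(R_obs, R_obs), dia(R_0, R_0)),
                               rot(R_0 + R_os_true, R_0 + R_os_true),
                               dia(R_0, R_0))
  expect_equal(cor2$R1_inner, R_obs - R_0 - R_os_true, tolerance = 1e-14)
})

test_that("mismatched measurement conditions are rejected", {
  expect_error(compute_Rp(para(5, 5, temperature = 298),
                          dia(1, 1, temperature = 300)), "temperatures")
  expect_error(compute_Rp(para(5, 5, field = 500), dia(1, 1, field = 300)),
               "fields")
  pr <- compute_Rp(para(5, 5), dia(1, 1))
  expect_error(correct_outer_sphere(pr, rot(1, 1, temperature = 310),
                                    dia(1, 1, temperature = 310)),
               "temperatures")
  expect_error(compute_Rp(dia(1, 1), dia(1, 1)), "paramagnetic")
})

test_that("known inner/outer split is recovered exactly from the simulator", {
  gt <- ground_truth(noise_sigma = 0, T_M1 = 0, T_M2 = 0)
  Tk <- 298.15
  rp <- simulate_rp_general(gt, Tk)
  pr <- compute_Rp(para(gt$R1_0 + rp$R1_p, gt$R2_0 + rp$R2_p,
                        temperature = Tk),
                   dia(gt$R1_0, gt$R2_0, temperature = Tk))
  cor <- correct_outer_sphere(pr,
                              rot(gt$R1_0 + rp$R1_os, gt$R2_0 + rp$R2_os,
                                  temperature = Tk),
                              dia(gt$R1_0, gt$R2_0, temperature = Tk))
  expect_equal(cor$R1_inner, rp$f / rp$tau_M, tolerance = 1e-12)
  expect_equal(cor$R2_inner, rp$f / rp$tau_M, tolerance = 1e-12)
})

# helper: pre_rates table straight from the generative model (no noise)
rp_table <- function(gt, temps, fields = c(300, 500), correct = TRUE) {
  rows <- lapply(temps, function(Tk) {
    rp <- simulate_rp_general(gt, Tk)
    lapply(fields, function(B) {
      pr <- compute_Rp(para(gt$R1_0 + rp$R1_p, gt$R2_0 + rp$R2_p,
                            temperature = Tk, field = B),
                       dia(gt$R1_0, gt$R2_0, temperature = Tk, field = B))
      if (correct)
        pr <- correct_outer_sphere(
          pr, rot(gt$R1_0 + rp$R1_os, gt$R2_0 + rp$R2_os,
                  temperature = Tk, field = B),
          dia(gt$R1_0, gt$R2_0, temperature = Tk, field = B))
      pr
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  class(out) <- c("pre_rates", "data.frame")
  out
}

test_that("regime diagnostics reach all three verdicts", {
  temps <- seq(263.15, 343.15, by = 10)

  slow <- rp_table(ground_truth(noise_sigma = 0), temps)
  d1 <- diagnose_regime(slow)
  expect_identical(d1$verdict, "tau_M_dominated")
  expect_true(d1$dRp_dT_positive && d1$field_independent && d1$ratio_pass)

  # channel-asymmetric outer-sphere rates push R2_p/R1_p to ~1.5 at 263 K
  cont <- rp_table(gt_preset("contaminated", noise_sigma = 0), temps,
                   correct = FALSE)
  d2 <- diagnose_regime(cont)
  expect_identical(d2$verdict, "outer_sphere_contaminated")
  expect_gte(max(d2$ratio_pre), 1.5)

  # bound-state relaxation dominating and lengthening with T
  fast <- rp_table(gt_preset("fast", noise_sigma = 0), temps)
  d3 <- diagnose_regime(fast)
  expect_identical(d3$verdict, "fast_exchange_suspected")
  expect_lt(d3$slope, 0)
})

test_that("diagnostics verdict is invariant under uniform rescaling of rates", {
  temps <- seq(263.15, 343.15, by = 20)
  tab <- rp_table(ground_truth(noise_sigma = 0), temps)
  d1 <- diagnose_regime(tab)
  sc <- tab
  num <- c("R1_p", "R2_p", "R1_os", "R2_os", "R1_inner", "R2_inner")
  sc[num] <- lapply(sc[num], function(v) v * 17.3)
  d2 <- diagnose_regime(sc)
  expect_identical(d1$verdict, d2$verdict)
  expect_equal(d1$ratio_pre, d2$ratio_pre, tolerance = 1e-12)

  expect_error(diagnose_regime(tab[1:2, ]), "3 distinct temperatures")
  bad <- tab; bad$R1_p[1] <- 0
  expect_error(diagnose_regime(bad), "positive")
})

test_that("threading evidence compares observed against outer-sphere rates", {
  ev <- exchange_evidence(para(11.94, 10.02), rot(1.03, 1.38))
  expect_equal(ev$ratio_R1, 11.94 / 1.03, tolerance = 1e-12)
  expect_equal(ev$ratio_R2, 10.02 / 1.38, tolerance = 1e-12)
  expect_true(ev$threading)

  # observed equal to outer-sphere: no threading
  ev0 <- exchange_evidence(para(1.03, 1.38), rot(1.03, 1.38))
  expect_equal(ev0$ratio_R1, 1)
  expect_false(ev0$threading)

  # binding disabled in the simulator (rotaxane sample as "observed")
  gt <- gt_preset("vp_like", noise_sigma = 0)
  rp <- simulate_rp_general(gt, 293.15)
  obs <- para(gt$R1_0 + rp$R1_os, gt$R2_0 + rp$R2_os, temperature = 293.15)
  ev1 <- exchange_evidence(obs, rot(gt$R1_0 + rp$R1_os, gt$R2_0 + rp$R2_os,
                                    temperature = 293.15),
                           dia = dia(gt$R1_0, gt$R2_0, temperature = 293.15),
                           rotaxane_dia = dia(gt$R1_0, gt$R2_0,
                                              temperature = 293.15))
  expect_equal(ev1$ratio_R1, 1, tolerance = 1e-12)
  expect_false(ev1$threading)

  expect_error(exchange_evidence(para(5, 5), rot(0, 1)), "positive")
})
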