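test_that("the noiseless pipeline reproduces the generator's ground truth", {
  gt <- ground_truth(noise_sigma = 0, T_M1 = 0, T_M2 = 0)
  st <- simulate_study(gt, seed = 1)
  rep <- run_pipeline(st)
  expect_identical(rep$diagnostics$verdict, "tau_M_dominated")
  expect_equal(rep$binding$logKa, log10(gt$Ka), tolerance = 1e-6)
  expect_equal(rep$order$n, gt$order_n, tolerance = 1e-6)
  expect_equal(rep$eyring$dH, gt$dH_act, tolerance = 1e-6)
  expect_equal(rep$eyring$dS, gt$dS_act, tolerance = 1e-6)
  # per-temperature residence times match the generative kinetics
  expect_equal(rep$kinetics$kd, kd_true(gt, rep$kinetics$temperature),
               tolerance = 1e-6)
})

test_that("a titration-only study yields a binding-only report", {
  gt <- ground_truth(noise_sigma = 0, T_M1 = 0, T_M2 = 0)
  st <- structure(list(
    decays = simulate_decays(gt, temperatures = seq(278.15, 318.15, 10),
                             fields = 500, seed = 2),
    conc_decays = NULL,
    titration = simulate_titration(gt, seed = 3),
    meta = list(host_id = "host", guest_id = "guest",
                guest_ref = gt$guest_ref)), class = "pre_study")
  rep <- run_pipeline(st)
  expect_s3_class(rep$binding, "binding_fit")
  expect_null(rep$order)            # no concentration series
  expect_equal(rep$kinetics$n[1], 0)

  st$titration <- NULL
  expect_message(rep2 <- run_pipeline(st), "no association constant")
  expect_null(rep2$binding)
  expect_null(rep2$kinetics)
})

test_that("the pipeline halts kinetics outside the tau_M-dominated regime", {
  gt <- gt_preset("fast", noise_sigma = 0)
  st <- simulate_study(gt, fields = 500, seed = 4)
  expect_message(rep <- run_pipeline(st), "fast_exchange_suspected")
  expect_identical(rep$diagnostics$verdict, "fast_exchange_suspected")
  expect_null(rep$kinetics)
  expect_null(rep$eyring)
  # force pushes through the gate
  repf <- run_pipeline(st, force = TRUE)
  expect_false(is.null(repf$kinetics))
})

test_that("missing paired controls are reported with their condition tuple", {
  gt <- ground_truth(noise_sigma = 0)
  df <- simulate_decays(gt, temperatures = c(288.15, 298.15, 308.15),
                        fields = 500, seed = 5)
  df <- df[df$condition != "diamagnetic", ]
  st <- structure(list(decays = df, meta = list()), class = "pre_study")
  expect_error(run_pipeline(st), "missing paired control")
})

test_that("rendered tables have the documented schemas and JSON round-trips", {
  gt <- ground_truth(noise_sigma = 0, T_M1 = 0, T_M2 = 0)
  st <- simulate_study(gt, temperatures = seq(278.15, 338.15, 10),
                       fields = 500, seed = 6)
  rep <- run_pipeline(st)
  dir <- tempfile()
  paths <- render_tables(rep, dir)
  act <- read.csv(paths[["activation"]])
  expect_true(all(c("dH_kcal", "dS_cal", "dG_kcal", "temperature_K") %in%
                    names(act)))
  expect_equal(act$dH_kcal, gt$dH_act, tolerance = 1e-6)
  js <- read_report_json(paths[["report"]])
  expect_identical(js$schema, "prekin-report/1")
  expect_equal(js$activation$dH_kcal, rep$eyring$dH, tolerance = 1e-12)
  expect_equal(js$binding$logKa, rep$binding$logKa, tolerance = 1e-12)

  # empty sections still give valid header-only tables
  st2 <- st; st2$titration <- NULL; st2$conc_decays <- NULL
  rep2 <- suppressMessages(run_pipeline(st2))
  dir2 <- tempfile()
  p2 <- render_tables(rep2, dir2)
  bind <- read.csv(p2[["binding"]])
  expect_equal(nrow(bind), 0)
  expect_true("logKa" %in% names(bind))
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("a written study re-runs to identical results", {
  gt <- ground_truth(noise_sigma = 0.01, T_M1 = 0, T_M2 = 0)
  dir <- tempfile()
  simulate_study(gt, temperatures = seq(278.15, 318.15, 20), fields = 500,
                 seed = 8, dir = dir)
  r1 <- run_pipeline(read_study(dir))
  r2 <- run_pipeline(read_study(dir))
  expect_identical(r1$binding$logKa, r2$binding$logKa)
  expect_identical(r1$eyring$dH, r2$eyring$dH)
  expect_identical(r1$kinetics$kd, r2$kinetics$kd)
  unlink(dir, recursive = TRUE)
})
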