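#' Ground truth for the two-site-exchange synthetic data generator
#'
#' Collects every generative parameter of the simulator: the association
#' constant, the activation parameters that govern the dissociation rate
#' (and hence the residence time `tau_M(T) = 1/kd(T)`) via transition-state
#' kinetics, the bound-state relaxation time `T_M` per channel with an
#' optional exponential temperature scaling, the outer-sphere rates with a
#' mild exponential temperature decay, the apparent guest reaction order,
#' diamagnetic baselines, titration endpoints, concentrations, and the noise
#' level and seed.
#'
#' Defaults emulate a manganese(III) porphyrin cage with a small viologen
#' guest: `Ka = 4796 M^-1`, `dH_act = 8.35` kcal/mol,
#' `dS_act = -17.57` cal/(K mol), order ~0.3, host 0.5 mM with 10
#' equivalents of guest, 1% intensity noise.
#'
#' @param Ka Association constant, M^-1.
#' @param dH_act,dS_act Activation enthalpy (kcal/mol) and entropy
#'   (cal/(K mol)) of dissociation at the reference guest concentration.
#' @param T_M1,T_M2 Bound-state relaxation times (s) for the R1 and R2
#'   channels at the reference temperature.
#' @param T_M_theta Exponential temperature coefficient of `T_M` (K^-1);
#'   `T_M(T) = T_M * exp(T_M_theta * (T - T_ref))`.
#' @param R1_os,R2_os Outer-sphere rates (s^-1) at the reference
#'   temperature.
#' @param os_alpha Exponential temperature coefficient of the outer-sphere
#'   rates (K^-1); `R_os(T) = R_os * exp(-os_alpha * (T - T_ref))`, so the
#'   outer-sphere contribution grows in relative importance at low
#'   temperature.
#' @param order_n Apparent reaction order in guest concentration.
#' @param guest_ref Reference guest concentration (M) at which
#'   `(dH_act, dS_act)` define the dissociation rate.
#' @param R1_0,R2_0 Diamagnetic baseline rates (s^-1).
#' @param R_empty,R_sat Reporter-solvent titration endpoints (s^-1).
#' @param host_total,guest_total Default concentrations (M).
#' @param binding_sites Equivalent binding sites per host.
#' @param noise_sigma Fractional Gaussian noise on decay intensities.
#' @param seed Integer RNG seed associated with the dataset.
#' @param T_ref Reference temperature (K) for the temperature scalings.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(Ka = 4796, dH_act = 8.35, dS_act = -17.57,
                         T_M1 = 1e-6, T_M2 = 1e-6, T_M_theta = 0,
                         R1_os = 0.30, R2_os = 0.40, os_alpha = 0.01,
                         order_n = 0.3, guest_ref = 5e-3,
                         R1_0 = 0.50, R2_0 = 0.90,
                         R_empty = 10, R_sat = 2,
                         host_total = 5e-4, guest_total = 5e-3,
                         binding_sites = 1L,
                         noise_sigma = 0.01, seed = 1L, T_ref = 298.15) {
  gt <- list(Ka = Ka, dH_act = dH_act, dS_act = dS_act,
             T_M1 = T_M1, T_M2 = T_M2, T_M_theta = T_M_theta,
             R1_os = R1_os, R2_os = R2_os, os_alpha = os_alpha,
             order_n = order_n, guest_ref = guest_ref,
             R1_0 = R1_0, R2_0 = R2_0,
             R_empty = R_empty, R_sat = R_sat,
             host_total = host_total, guest_total = guest_total,
             binding_sites = binding_sites,
             noise_sigma = noise_sigma, seed = as.integer(seed),
             T_ref = T_ref)
  stopifnot(gt$Ka > 0, gt$guest_ref > 0, gt$host_total > 0,
            gt$guest_total > 0, gt$T_M1 >= 0, gt$T_M2 >= 0,
            gt$R1_os >= 0, gt$R2_os >= 0, gt$R1_0 >= 0, gt$R2_0 >= 0,
            gt$R_empty >= gt$R_sat, gt$noise_sigma >= 0)
  structure(gt, class = "ground_truth")
}

#' Named simulator presets covering the exchange regimes
#'
#' * `"slow"` -- residence-time-dominated exchange (`tau_M >> T_M`, small
#'   outer-sphere rates); the clean default emulating the cage/viologen
#'   system.
#' * `"intermediate"` -- `T_M` comparable to `tau_M`, where the simplified
#'   `R_p = f/tau_M + R_os` analysis acquires a visible bias.
#' * `"fast"` -- bound-state relaxation dominates and lengthens with
#'   temperature, so `R_p` decreases with temperature and the diagnostics
#'   flag a suspected fast-exchange regime.
#' * `"contaminated"` -- channel-asymmetric outer-sphere rates that push the
#'   uncorrected `R2_p/R1_p` ratio to ~1.5 at 263 K.
#' * `"vp_like"` -- polymer-threading scenario: weaker binding
#'   (`Ka = 1692 M^-1`), entropy-dominated dissociation barrier and
#'   outer-sphere rates of about 1.0/1.4 s^-1, reproducing an
#'   observed-to-outer-sphere ratio of roughly an order of magnitude.
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [ground_truth()].
#' @return A `ground_truth` object.
#' @export
gt_preset <- function(name = c("slow", "intermediate", "fast",
                               "contaminated", "vp_like"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    slow = list(),
    intermediate = list(T_M1 = 1.5e-3, T_M2 = 1.5e-3),
    fast = list(T_M1 = 0.1, T_M2 = 0.1, T_M_theta = 0.02),
    contaminated = list(R1_os = 1.41, R2_os = 5.3),
    vp_like = list(Ka = 1692, dH_act = 3.17, dS_act = -36.89,
                   guest_total = 1.03e-2, guest_ref = 1.03e-2,
                   R1_os = 1.03, R2_os = 1.38, os_alpha = 0,
                   R1_0 = 0.50, R2_0 = 0.90))
  over <- list(...)
  args[names(over)] <- over
  do.call(ground_truth, args)
}

# temperature scalings of the generative model
.tm_at <- function(gt, temperature, channel = 1) {
  base <- if (channel == 1) gt$T_M1 else gt$T_M2
  base * exp(gt$T_M_theta * (temperature - gt$T_ref))
}
.ros_at <- function(gt, temperature, channel = 1) {
  base <- if (channel == 1) gt$R1_os else gt$R2_os
  base * exp(-gt$os_alpha * (temperature - gt$T_ref))
}

#' Ground-truth dissociation rate constant
#'
#' `kd(T, G) = k_Eyring(dH_act, dS_act, T) * (G / guest_ref)^order_n`.
#'
#' @param gt A [ground_truth()] object.
#' @param temperature Temperature(s), K.
#' @param guest_total Guest concentration (M); defaults to the reference.
#' @return Dissociation rate constant(s), s^-1.
#' @export
kd_true <- function(gt, temperature, guest_total = gt$guest_ref) {
  stopifnot(inherits(gt, "ground_truth"))
  eyring_rate(gt$dH_act, gt$dS_act, temperature) *
    (guest_total / gt$guest_ref)^gt$order_n
}

#' Simulate paramagnetic rates from the general inner-sphere model
#'
#' The un-simplified two-site-exchange model
#' `R_p = f / (tau_M(T) + T_M(T)) + R_os(T)` per channel, with
#' `tau_M(T) = 1/kd(T)` from the ground truth's transition-state kinetics
#' and guest-order scaling. Setting `T_M = 0` and `R_os = 0` recovers the
#' simplified `R_p = f/tau_M` limit exactly.
#'
#' @param gt A [ground_truth()] object.
#' @param temperature Temperature(s), K.
#' @param host_total,guest_total Concentrations (M); default from `gt`.
#' @return A data frame with one row per temperature: `f`, `tau_M`, the
#'   per-channel `T_M` and `R_os`, and the resulting `R1_p`, `R2_p`.
#' @export
simulate_rp_general <- function(gt, temperature,
                                host_total = gt$host_total,
                                guest_total = gt$guest_total) {
  stopifnot(inherits(gt, "ground_truth"))
  f <- guest_bound_fraction(gt$Ka, host_total, guest_total,
                            gt$binding_sites)
  tau_M <- 1 / kd_true(gt, temperature, guest_total)
  T_M1 <- .tm_at(gt, temperature, 1); T_M2 <- .tm_at(gt, temperature, 2)
  R1_os <- .ros_at(gt, temperature, 1); R2_os <- .ros_at(gt, temperature, 2)
  data.frame(temperature = temperature, f = f, tau_M = tau_M,
             T_M1 = T_M1, T_M2 = T_M2, R1_os = R1_os, R2_os = R2_os,
             R1_p = f / (tau_M + T_M1) + R1_os,
             R2_p = f / (tau_M + T_M2) + R2_os)
}

# underlying observed rates for one condition at one temperature
.true_rates <- function(gt, temperature, condition, host_total, guest_total) {
  rp <- simulate_rp_general(gt, temperature, host_total, guest_total)
  switch(condition,
    paramagnetic = c(R1 = gt$R1_0 + rp$R1_p, R2 = gt$R2_0 + rp$R2_p),
    diamagnetic = c(R1 = gt$R1_0, R2 = gt$R2_0),
    blocked_rotaxane = c(R1 = gt$R1_0 + rp$R1_os,
                         R2 = gt$R2_0 + rp$R2_os),
    stop("unknown condition: ", condition))
}

#' Simulate inversion-recovery and CPMG decay series
#'
#' Emits a long-format decay table for the paramagnetic sample, the
#' diamagnetic control and the blocked-rotaxane control (binding disabled,
#' outer-sphere retained) over a grid of temperatures and fields. Underlying
#' rates equal the diamagnetic baseline plus the simulated paramagnetic
#' contribution; intensities carry seeded homoscedastic Gaussian noise of
#' fractional amplitude `noise_sigma`. Delay lists are log-spaced over the
#' relevant recovery/decay window of each series (as an experimenter would
#' set them).
#'
#' @param gt A [ground_truth()] object.
#' @param temperatures,fields Measurement grids (K; MHz).
#' @param host_total,guest_total Concentrations (M).
#' @param conditions Which sample types to emit.
#' @param n_delays Delays per series (>= 6).
#' @param noise_sigma Fractional intensity noise; default from `gt`.
#' @param seed RNG seed; default from `gt`.
#' @return A decay-table data frame (see [read_decay_csv()] for the schema)
#'   with extra columns `condition`, `host_total_M`, `guest_total_M`.
#' @export
simulate_decays <- function(gt, temperatures = seq(263.15, 343.15, by = 10),
                            fields = c(300, 500),
                            host_total = gt$host_total,
                            guest_total = gt$guest_total,
                            conditions = c("paramagnetic", "diamagnetic",
                                           "blocked_rotaxane"),
                            n_delays = 10, noise_sigma = gt$noise_sigma,
                            seed = gt$seed) {
  stopifnot(inherits(gt, "ground_truth"), n_delays >= 6)
  set.seed(seed)
  rows <- list()
  for (Tk in temperatures) for (B0 in fields) for (cond in conditions) {
    rr <- .true_rates(gt, Tk, cond, host_total, guest_total)
    sid <- sprintf("%s_G%.4gmM", cond, guest_total * 1e3)
    # inversion recovery: I(t) = Iinf (1 - 2 exp(-R1 t))
    T1 <- 1 / rr[["R1"]]
    t1 <- exp(seq(log(0.02 * T1), log(4 * T1), length.out = n_delays))
    i1 <- (1 - 2 * exp(-t1 / T1)) + rnorm(n_delays, sd = noise_sigma)
    # CPMG: I(t) = I0 exp(-R2 t)
    T2 <- 1 / rr[["R2"]]
    t2 <- exp(seq(log(0.05 * T2), log(3 * T2), length.out = n_delays))
    i2 <- exp(-t2 / T2) + rnorm(n_delays, sd = noise_sigma)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sid, condition = cond,
      experiment = rep(c("inversion_recovery", "cpmg"), each = n_delays),
      signal_label = "meta-H", temperature_K = Tk, field_MHz = B0,
      host_total_M = if (cond == "diamagnetic") 0 else host_total,
      guest_total_M = guest_total,
      delay_s = c(t1, t2), intensity = c(i1, i2),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a solvent-reporter binding titration
#'
#' Reporter rates from [predict_reporter_rate()] with the ground-truth
#' association constant and endpoints, plus seeded Gaussian noise.
#'
#' @param gt A [ground_truth()] object.
#' @param host_total Host concentration (M).
#' @param guest_grid Guest concentrations (M); must span 0 to at least
#'   10x the host concentration.
#' @param temperature Series temperature (K).
#' @param noise_sigma Fractional noise (of `R_empty`); default from `gt`.
#' @param seed RNG seed; default from `gt`.
#' @return A titration data frame (`host_total_M, guest_total_M,
#'   temperature_K, R1_obs, R1_err`).
#' @export
simulate_titration <- function(gt, host_total = gt$host_total,
                               guest_grid = host_total *
                                 c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 10, 12),
                               temperature = 298.15,
                               noise_sigma = gt$noise_sigma,
                               seed = gt$seed) {
  stopifnot(inherits(gt, "ground_truth"))
  if (min(guest_grid) > 0 || max(guest_grid) < 10 * host_total)
    stop("guest_grid must span 0 to at least 10x the host concentration")
  set.seed(seed)
  mu <- predict_reporter_rate(gt$Ka, gt$R_empty, gt$R_sat, host_total,
                              guest_grid)
  sdv <- noise_sigma * gt$R_empty
  data.frame(host_total_M = host_total, guest_total_M = guest_grid,
             temperature_K = temperature,
             R1_obs = mu + rnorm(length(guest_grid), sd = sdv),
             R1_err = sdv)
}

#' Materialise a full mock PRE study with known ground truth
#'
#' Generates every input the pipeline consumes: the variable-temperature
#' decay series (all three sample conditions, both fields), a
#' guest-concentration series at fixed temperature for the reaction-order
#' estimate, and a binding titration. If `dir` is given the study is also
#' written to disk as CSV files plus a `ground_truth.json` sidecar and a
#' `config.yaml`.
#'
#' @param gt A [ground_truth()] object.
#' @param temperatures Temperature grid (K) for the kinetics series.
#' @param fields Spectrometer fields (MHz).
#' @param conc_factors Multipliers of `gt$guest_total` for the
#'   concentration series.
#' @param conc_temperature Temperature (K) of the concentration series.
#' @param n_delays Delays per decay series.
#' @param seed Master seed; sub-stage seeds are derived from it.
#' @param dir Optional output directory.
#' @return A list of class `pre_study` with elements `decays`,
#'   `conc_decays`, `titration`, `ground_truth` and `meta`.
#' @export
simulate_study <- function(gt = ground_truth(),
                           temperatures = seq(263.15, 343.15, by = 10),
                           fields = c(300, 500),
                           conc_factors = c(0.5, 1, 2, 4),
                           conc_temperature = 298.15,
                           n_delays = 10, seed = gt$seed, dir = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  seed <- as.integer(seed)
  decays <- simulate_decays(gt, temperatures, fields, n_delays = n_delays,
                            seed = seed)
  conc <- lapply(seq_along(conc_factors), function(i)
    simulate_decays(gt, conc_temperature, fields[1],
                    guest_total = conc_factors[i] * gt$guest_total,
                    n_delays = n_delays, seed = seed + i))
  conc_decays <- do.call(rbind, conc)
  titration <- simulate_titration(gt, seed = seed + length(conc_factors) + 1L)
  study <- structure(list(
    decays = decays, conc_decays = conc_decays, titration = titration,
    ground_truth = gt,
    meta = list(host_id = "host", guest_id = "guest",
                guest_ref = gt$guest_ref, seed = seed)),
    class = "pre_study")
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' Write a study to a directory of CSV/JSON/YAML files
#'
#' @param study A `pre_study` list (from [simulate_study()] or
#'   [read_study()]).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(decays = file.path(dir, "decays.csv"),
             conc_decays = file.path(dir, "conc_decays.csv"),
             titration = file.path(dir, "titration.csv"),
             ground_truth = file.path(dir, "ground_truth.json"),
             config = file.path(dir, "config.yaml"))
  utils::write.csv(study$decays, paths[["decays"]], row.names = FALSE)
  if (!is.null(study$conc_decays))
    utils::write.csv(study$conc_decays, paths[["conc_decays"]],
                     row.names = FALSE)
  if (!is.null(study$titration))
    utils::write.csv(study$titration, paths[["titration"]],
                     row.names = FALSE)
  if (!is.null(study$ground_truth))
    jsonlite::write_json(unclass(study$ground_truth),
                         paths[["ground_truth"]], auto_unbox = TRUE,
                         digits = NA)
  cfg <- list(files = list(decays = "decays.csv",
                           conc_decays = if (!is.null(study$conc_decays))
                             "conc_decays.csv",
                           titration = if (!is.null(study$titration))
                             "titration.csv"),
              host_id = study$meta$host_id, guest_id = study$meta$guest_id,
              guest_ref_M = study$meta$guest_ref,
              seed = study$meta$seed)
  cfg$files <- Filter(Negate(is.null), cfg$files)
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}

#' Read a ground-truth sidecar
#' @param path Path to a `ground_truth.json` file.
#' @return A validated [ground_truth()] object.
#' @export
read_ground_truth <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(ground_truth, vals[names(vals) %in% names(formals(ground_truth))])
}

#' Read a study directory written by [write_study()]
#'
#' Validates the `config.yaml` (all referenced files must exist) and loads
#' the referenced CSVs, the ground-truth sidecar if present, and the
#' analysis settings.
#'
#' @param dir Study directory.
#' @return A `pre_study` list.
#' @export
read_study <- function(dir) {
  cfgp <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfgp)) yaml::read_yaml(cfgp) else
    list(files = list(decays = "decays.csv"))
  getf <- function(key) {
    f <- cfg$files[[key]]
    if (is.null(f)) return(NULL)
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("config references missing file: ", f)
    p
  }
  decp <- getf("decays")
  if (is.null(decp)) stop("study config must reference a decays file")
  gtp <- file.path(dir, "ground_truth.json")
  structure(list(
    decays = read_decay_csv(decp),
    conc_decays = if (!is.null(getf("conc_decays")))
      read_decay_csv(getf("conc_decays")),
    titration = if (!is.null(getf("titration")))
      read_titration_csv(getf("titration")),
    ground_truth = if (file.exists(gtp)) read_ground_truth(gtp),
    meta = list(host_id = cfg$host_id %||% "host",
                guest_id = cfg$guest_id %||% "guest",
                guest_ref = cfg$guest_ref_M,
                seed = cfg$seed %||% NA_integer_),
    settings = cfg$settings), class = "pre_study")
}
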