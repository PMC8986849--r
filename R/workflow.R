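#' Run the full PRE analysis pipeline on a study
#'
#' Executes the end-to-end analysis: decay fitting (relaxometry), rate
#' decomposition and outer-sphere correction, exchange-regime diagnostics,
#' binding-titration fitting, residence-time/dissociation-rate extraction
#' with reaction-order correction, and Eyring analysis of both dissociation
#' and threading. Kinetics stages are refused unless the diagnostics verdict
#' is `tau_M_dominated` (override with `force = TRUE`).
#'
#' @param study A `pre_study` list ([simulate_study()] / [read_study()]) or
#'   a study directory path.
#' @param ratio_band,field_tol,contaminated_ratio Diagnostics tolerances,
#'   see [diagnose_regime()].
#' @param guest_ref Reference guest concentration (M) for the order
#'   correction; defaults to the study's declared reference, falling back to
#'   the kinetics-series guest concentration.
#' @param reporting_temperature Temperature (K) at which free energies and
#'   the threading rate are reported; default 298.15.
#' @param threading_min_T Lowest temperature (K) used for the threading
#'   (k_on) Eyring fit; default 293.15.
#' @param mc_draws Monte-Carlo draws for the titration fit (0 = delta
#'   method only).
#' @param min_factor Threshold ratio for the threading-evidence check.
#' @param force Run kinetics even if the diagnostics verdict is not
#'   `tau_M_dominated`.
#' @return An object of class `pre_study_report` with elements `rates`,
#'   `pre_rates`, `diagnostics`, `binding`, `evidence`, `kinetics`, `order`,
#'   `eyring`, `threading` and `settings`.
#' @export
run_pipeline <- function(study, ratio_band = c(0.67, 1.3), field_tol = 0.15,
                         contaminated_ratio = 1.5, guest_ref = NULL,
                         reporting_temperature = 298.15,
                         threading_min_T = 293.15, mc_draws = 0,
                         min_factor = 3, force = FALSE) {
  if (is.character(study)) study <- read_study(study)
  stopifnot(inherits(study, "pre_study") || is.list(study))
  meta <- study$meta %||% list(host_id = "host", guest_id = "guest")

  rates <- fit_decay_table(study$decays)
  prr <- .pair_and_decompose(rates)
  diag <- diagnose_regime(prr, ratio_band = ratio_band,
                          field_tol = field_tol,
                          contaminated_ratio = contaminated_ratio)

  binding <- NULL
  if (!is.null(study$titration))
    binding <- fit_titration(study$titration, mc_draws = mc_draws)
  Ka <- if (!is.null(binding)) binding$Ka else study$Ka

  evidence <- .evidence_from_rates(rates, reporting_temperature, min_factor)

  kinetics <- order <- eyring <- threading <- NULL
  if (diag$verdict != "tau_M_dominated" && !force) {
    message("diagnostics verdict is '", diag$verdict,
            "'; kinetics stages skipped (use force = TRUE to override)")
  } else if (is.null(Ka)) {
    message("no association constant available (no titration data); ",
            "kinetics stages skipped")
  } else {
    kinetics <- .kinetics_table(prr, Ka, diag, force,
                                binding_sites = study$ground_truth$binding_sites %||% 1L)
    if (!is.null(study$conc_decays)) {
      cr <- fit_decay_table(study$conc_decays)
      cprr <- .pair_and_decompose(cr)
      cf <- guest_bound_fraction(Ka, cprr$host_total, cprr$guest_total)
      ck <- residence_time(cprr$R1_inner, cf, diag, force = force)
      order <- estimate_reaction_order(cprr$guest_total, ck$kd_obs)
    }
    n <- if (!is.null(order)) order$n else 0
    gref <- guest_ref %||% meta$guest_ref %||% kinetics$guest_total[1]
    kinetics$kd <- correct_kd(kinetics$kd_obs, kinetics$guest_total, n, gref)
    kinetics$n <- n
    eyring <- eyring_fit(kinetics$temperature, kinetics$kd)
    kd_ref <- predict(eyring, reporting_temperature)
    sub <- kinetics[kinetics$temperature >= threading_min_T - 0.5, ]
    eyr_on <- if (length(unique(sub$temperature)) >= 3)
      eyring_fit(sub$temperature, Ka * sub$kd)
    kon <- kon_from_Ka_kd(Ka, kd_ref,
                          Ka_err = if (!is.null(binding)) binding$se$Ka else 0)
    threading <- list(kon = kon$kon, kon_err = kon$kon_err,
                      dG_on = dG_from_rate(kon$kon, reporting_temperature),
                      eyring = eyr_on,
                      temperature = reporting_temperature)
  }

  structure(list(rates = rates, pre_rates = prr, diagnostics = diag,
                 binding = binding, evidence = evidence,
                 kinetics = kinetics, order = order, eyring = eyring,
                 threading = threading,
                 settings = list(ratio_band = ratio_band,
                                 field_tol = field_tol,
                                 guest_ref = guest_ref %||% meta$guest_ref,
                                 reporting_temperature = reporting_temperature,
                                 mc_draws = mc_draws, force = force),
                 meta = meta), class = "pre_study_report")
}

# pair paramagnetic/diamagnetic/rotaxane rows per (temperature, field) and
# build the pre_rates table
.pair_and_decompose <- function(rates) {
  if (is.null(rates$condition))
    stop("rate table needs a 'condition' column to pair samples")
  grp <- split(rates, interaction(round(rates$temperature_K, 1),
                                  rates$field_MHz,
                                  rates$guest_total_M, drop = TRUE))
  rows <- lapply(grp, function(g) {
    pick <- function(cond) {
      i <- which(g$condition == cond)
      if (!length(i)) return(NULL)
      g[i[1], , drop = FALSE]
    }
    para <- pick("paramagnetic"); dia <- pick("diamagnetic")
    if (is.null(para) || is.null(dia))
      stop("missing paired control: need paramagnetic and diamagnetic ",
           "records at (T = ", g$temperature_K[1], " K, field = ",
           g$field_MHz[1], " MHz, guest = ", g$guest_total_M[1], " M)")
    pr <- compute_Rp(para, dia)
    rot <- pick("blocked_rotaxane")
    if (!is.null(rot)) pr <- correct_outer_sphere(pr, rot, dia)
    pr
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pre_rates", "data.frame")
  out
}

# per-temperature kinetics from outer-sphere-corrected inner rates
.kinetics_table <- function(prr, Ka, diag, force, binding_sites = 1L) {
  if (!all(prr$corrected))
    warning("outer-sphere correction unavailable for some conditions; ",
            "using uncorrected R1_p for kinetics")
  prr$R1_use <- ifelse(prr$corrected, prr$R1_inner, prr$R1_p)
  grp <- split(prr, round(prr$temperature, 1))
  rows <- lapply(grp, function(g) data.frame(
    temperature = mean(g$temperature),
    host_total = g$host_total[1], guest_total = g$guest_total[1],
    R1_inner = mean(g$R1_use),
    R1_inner_err = sqrt(sum(g$R1_inner_err^2, na.rm = TRUE)) / nrow(g)))
  kin <- do.call(rbind, rows)
  kin$f <- guest_bound_fraction(Ka, kin$host_total, kin$guest_total,
                                binding_sites)
  rt <- residence_time(kin$R1_inner, kin$f, diag, force = force)
  kin$tau_M <- rt$tau_M
  kin$kd_obs <- rt$kd_obs
  kin <- kin[order(kin$temperature), ]
  rownames(kin) <- NULL
  kin
}

# threading-evidence check at the measured temperature nearest the
# reporting temperature where all three conditions exist
.evidence_from_rates <- function(rates, reporting_temperature, min_factor) {
  if (is.null(rates$condition)) return(NULL)
  grp <- split(rates, interaction(round(rates$temperature_K, 1),
                                  rates$field_MHz,
                                  rates$guest_total_M, drop = TRUE))
  full <- Filter(function(g)
    all(c("paramagnetic", "diamagnetic", "blocked_rotaxane") %in%
          g$condition), grp)
  if (!length(full)) return(NULL)
  dist <- vapply(full, function(g)
    abs(g$temperature_K[1] - reporting_temperature), numeric(1))
  g <- full[[which.min(dist)]]
  exchange_evidence(
    obs = g[g$condition == "paramagnetic", ][1, ],
    rotaxane = g[g$condition == "blocked_rotaxane", ][1, ],
    dia = g[g$condition == "diamagnetic", ][1, ],
    rotaxane_dia = g[g$condition == "diamagnetic", ][1, ],
    min_factor = min_factor)
}

#' @export
print.pre_study_report <- function(x, ...) {
  cat("<pre_study_report>\n")
  cat("  diagnostics verdict:", x$diagnostics$verdict, "\n")
  if (!is.null(x$binding))
    cat(sprintf("  binding: log10(Ka) = %.3f +/- %.3f, dG = %.2f kcal/mol\n",
                x$binding$logKa, x$binding$se$logKa, x$binding$dG))
  if (!is.null(x$evidence))
    cat(sprintf("  threading evidence: ratios %.2f / %.2f -> %s\n",
                x$evidence$ratio_R1, x$evidence$ratio_R2,
                x$evidence$threading))
  if (!is.null(x$order))
    cat(sprintf("  guest reaction order n = %.3f +/- %.3f\n",
                x$order$n, x$order$stderr))
  if (!is.null(x$eyring)) {
    g <- eyring_dG(x$eyring, x$settings$reporting_temperature)
    cat(sprintf("  dissociation: dH+ = %.2f, dS+ = %.2f, dG+(%.1f K) = %.2f kcal/mol\n",
                x$eyring$dH, x$eyring$dS,
                x$settings$reporting_temperature, g$dG))
  }
  if (!is.null(x$threading))
    cat(sprintf("  threading: k_on = %.3g M^-1 s^-1, dG+ = %.2f kcal/mol\n",
                x$threading$kon, x$threading$dG_on))
  if (is.null(x$kinetics))
    cat("  kinetics: not computed\n")
  invisible(x)
}

#' Render a study report into CSV and JSON summary tables
#'
#' Writes deterministic-column-order summaries: a binding table
#' (association constants and free energies), an activation table
#' (dissociation Eyring parameters), a threading table (k_on and its
#' activation parameters), the per-temperature kinetics table, and a
#' schema-versioned JSON report. Sections without results produce
#' empty-but-valid files with headers.
#'
#' @param report A `pre_study_report` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the written paths.
#' @export
render_tables <- function(report, dir) {
  stopifnot(inherits(report, "pre_study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Trep <- report$settings$reporting_temperature
  host <- report$meta$host_id %||% "host"
  guest <- report$meta$guest_id %||% "guest"

  bind_df <- if (!is.null(report$binding)) {
    b <- report$binding
    data.frame(host_id = host, guest_id = guest, logKa = b$logKa,
               logKa_err = b$se$logKa, Ka_M = b$Ka,
               dG_kcal = b$dG, dG_err = b$se$dG,
               temperature_K = b$temperature)
  } else data.frame(host_id = character(), guest_id = character(),
                    logKa = numeric(), logKa_err = numeric(),
                    Ka_M = numeric(), dG_kcal = numeric(),
                    dG_err = numeric(), temperature_K = numeric())

  act_df <- if (!is.null(report$eyring)) {
    e <- report$eyring; g <- eyring_dG(e, Trep)
    data.frame(host_id = host, guest_id = guest,
               dH_kcal = e$dH, dH_err = e$se_dH,
               dS_cal = e$dS, dS_err = e$se_dS,
               dG_kcal = g$dG, dG_err = g$se, temperature_K = Trep)
  } else data.frame(host_id = character(), guest_id = character(),
                    dH_kcal = numeric(), dH_err = numeric(),
                    dS_cal = numeric(), dS_err = numeric(),
                    dG_kcal = numeric(), dG_err = numeric(),
                    temperature_K = numeric())

  thr_df <- if (!is.null(report$threading)) {
    t <- report$threading; e <- t$eyring
    data.frame(host_id = host, guest_id = guest,
               kon_Msinv = t$kon, kon_err = t$kon_err,
               dH_kcal = if (!is.null(e)) e$dH else NA_real_,
               dS_cal = if (!is.null(e)) e$dS else NA_real_,
               dG_kcal = t$dG_on, temperature_K = t$temperature)
  } else data.frame(host_id = character(), guest_id = character(),
                    kon_Msinv = numeric(), kon_err = numeric(),
                    dH_kcal = numeric(), dS_cal = numeric(),
                    dG_kcal = numeric(), temperature_K = numeric())

  kin_df <- if (!is.null(report$kinetics)) {
    k <- report$kinetics
    data.frame(temperature_K = k$temperature, f = k$f,
               tau_M_s = k$tau_M, kd_obs = k$kd_obs, kd = k$kd, n = k$n)
  } else data.frame(temperature_K = numeric(), f = numeric(),
                    tau_M_s = numeric(), kd_obs = numeric(),
                    kd = numeric(), n = numeric())

  paths <- c(binding = file.path(dir, "binding_table.csv"),
             activation = file.path(dir, "activation_table.csv"),
             threading = file.path(dir, "threading_table.csv"),
             kinetics = file.path(dir, "kinetics.csv"),
             report = file.path(dir, "report.json"))
  utils::write.csv(bind_df, paths[["binding"]], row.names = FALSE)
  utils::write.csv(act_df, paths[["activation"]], row.names = FALSE)
  utils::write.csv(thr_df, paths[["threading"]], row.names = FALSE)
  utils::write.csv(kin_df, paths[["kinetics"]], row.names = FALSE)

  js <- list(schema = "prekin-report/1",
             diagnostics = list(verdict = report$diagnostics$verdict,
                                slope = report$diagnostics$slope,
                                max_field_reldiff =
                                  report$diagnostics$max_field_reldiff,
                                ratio_pre = report$diagnostics$ratio_pre,
                                ratio_post = report$diagnostics$ratio_post),
             binding = if (nrow(bind_df)) as.list(bind_df[1, ]),
             activation = if (nrow(act_df)) as.list(act_df[1, ]),
             threading = if (nrow(thr_df)) as.list(thr_df[1, ]),
             kinetics = kin_df,
             evidence = if (!is.null(report$evidence))
               list(ratio_R1 = report$evidence$ratio_R1,
                    ratio_R2 = report$evidence$ratio_R2,
                    threading = report$evidence$threading),
             settings = report$settings)
  jsonlite::write_json(js, paths[["report"]], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' Read back a JSON report written by [render_tables()]
#' @param path Path to `report.json`.
#' @return The report as a list.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
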