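#' Construct a rate record for one measured condition
#'
#' One row of observed longitudinal/transverse relaxation rates for a sample
#' under a given condition: the paramagnetic host + guest sample, the
#' guest-only diamagnetic control, or the cavity-blocked rotaxane control
#' used to measure outer-sphere effects.
#'
#' @param condition `"paramagnetic"`, `"diamagnetic"` or
#'   `"blocked_rotaxane"`.
#' @param R1_obs,R2_obs Observed rates in s^-1 (>= 0).
#' @param stderr_R1,stderr_R2 Standard errors of the observed rates (s^-1).
#' @param temperature Temperature in K.
#' @param field Spectrometer frequency in MHz.
#' @param host_total,guest_total Total concentrations in M (optional).
#' @param host_id,guest_id Text labels.
#' @return An object of class `rate_record`.
#' @export
rate_record <- function(condition = c("paramagnetic", "diamagnetic",
                                      "blocked_rotaxane"),
                        R1_obs, R2_obs, stderr_R1 = 0, stderr_R2 = 0,
                        temperature = 298.15, field = 500,
                        host_total = NA_real_, guest_total = NA_real_,
                        host_id = "", guest_id = "") {
  condition <- match.arg(condition)
  if (any(c(R1_obs, R2_obs) < 0, na.rm = TRUE))
    stop("observed rates must be non-negative")
  if (any(c(stderr_R1, stderr_R2) < 0))
    stop("rate standard errors must be non-negative")
  structure(list(condition = condition, R1_obs = R1_obs, R2_obs = R2_obs,
                 stderr_R1 = stderr_R1, stderr_R2 = stderr_R2,
                 temperature = temperature, field = field,
                 host_total = host_total, guest_total = guest_total,
                 host_id = host_id, guest_id = guest_id),
            class = "rate_record")
}

# coerce a one-row rate-table data.frame (fit_decay_table / read_rate_csv
# schema) into a rate_record
.as_rate_record <- function(x) {
  if (inherits(x, "rate_record")) return(x)
  if (is.data.frame(x) && nrow(x) == 1L) {
    return(rate_record(
      condition = x$condition %||% "paramagnetic",
      R1_obs = x$R1_obs, R2_obs = x$R2_obs,
      stderr_R1 = if (!is.null(x$R1_err) && is.finite(x$R1_err)) x$R1_err else 0,
      stderr_R2 = if (!is.null(x$R2_err) && is.finite(x$R2_err)) x$R2_err else 0,
      temperature = x$temperature_K %||% x$temperature %||% 298.15,
      field = x$field_MHz %||% x$field %||% 500,
      host_total = x$host_total_M %||% NA_real_,
      guest_total = x$guest_total_M %||% NA_real_,
      host_id = x$host_id %||% "", guest_id = x$guest_id %||% ""))
  }
  stop("cannot interpret object as a rate record")
}

.check_matched <- function(a, b, what, temp_tol = 0.5) {
  if (abs(a$temperature - b$temperature) > temp_tol)
    stop(what, ": temperatures differ by more than ", temp_tol, " K (",
         a$temperature, " vs ", b$temperature, ")")
  if (!isTRUE(all.equal(a$field, b$field)))
    stop(what, ": fields differ (", a$field, " vs ", b$field, " MHz)")
  if (is.finite(a$guest_total) && is.finite(b$guest_total) &&
      !isTRUE(all.equal(a$guest_total, b$guest_total)))
    stop(what, ": guest concentrations differ")
  invisible(TRUE)
}

# shared subtract-with-noise-guard: value, err are the difference and its
# combined standard error
.guarded_diff <- function(value, err, label, clamp_sigmas = 2) {
  flag <- FALSE
  if (value < 0) {
    if (err > 0 && value < -clamp_sigmas * err)
      stop(label, " is negative beyond ", clamp_sigmas,
           " combined standard errors (", signif(value, 4),
           " +/- ", signif(err, 4), "); inconsistent controls")
    if (err == 0)
      stop(label, " is negative with zero stated uncertainty (",
           signif(value, 4), "); inconsistent controls")
    warning(label, " slightly negative (", signif(value, 4),
            "); clamped to zero")
    value <- 0
    flag <- TRUE
  }
  list(value = value, err = err, clamped = flag)
}

#' Paramagnetic rate contribution from paired observed/control records
#'
#' The observed rate of a nucleus near a paramagnetic centre is the sum of a
#' diamagnetic baseline and a paramagnetic contribution,
#' `R_obs = R_0 + R_p`. This subtracts the diamagnetic control from the
#' paramagnetic sample per channel (R1 and R2), combining uncertainties in
#' quadrature. A slightly negative difference (within `2 sigma`) is clamped
#' to zero with a warning; one beyond that is an error.
#'
#' @param para Paramagnetic-sample [rate_record] (or one-row rate table).
#' @param dia Matching diamagnetic-control record (same temperature within
#'   0.5 K, same field and guest concentration).
#' @return A one-row data frame of class `pre_rates` with columns
#'   `R1_p, R1_p_err, R2_p, R2_p_err` (and `NA` placeholders for the
#'   outer-sphere columns filled by [correct_outer_sphere()]).
#' @export
compute_Rp <- function(para, dia) {
  para <- .as_rate_record(para); dia <- .as_rate_record(dia)
  if (para$condition != "paramagnetic")
    stop("'para' record must have condition 'paramagnetic'")
  if (dia$condition != "diamagnetic")
    stop("'dia' record must have condition 'diamagnetic'")
  .check_matched(para, dia, "compute_Rp")

  g1 <- .guarded_diff(para$R1_obs - dia$R1_obs,
                      sqrt(para$stderr_R1^2 + dia$stderr_R1^2), "R1_p")
  g2 <- .guarded_diff(para$R2_obs - dia$R2_obs,
                      sqrt(para$stderr_R2^2 + dia$stderr_R2^2), "R2_p")
  out <- data.frame(
    temperature = para$temperature, field = para$field,
    host_total = para$host_total, guest_total = para$guest_total,
    host_id = para$host_id, guest_id = para$guest_id,
    R1_p = g1$value, R1_p_err = g1$err,
    R2_p = g2$value, R2_p_err = g2$err,
    R1_os = NA_real_, R1_os_err = NA_real_,
    R2_os = NA_real_, R2_os_err = NA_real_,
    R1_inner = NA_real_, R1_inner_err = NA_real_,
    R2_inner = NA_real_, R2_inner_err = NA_real_,
    corrected = FALSE, clamped = g1$clamped || g2$clamped,
    stringsAsFactors = FALSE)
  class(out) <- c("pre_rates", "data.frame")
  out
}

#' Correct paramagnetic rates for outer-sphere contributions
#'
#' The paramagnetic contribution splits into inner-sphere (close, binding)
#' and outer-sphere (distant, non-binding) parts. The outer-sphere part is
#' measured empirically with a cavity-blocked rotaxane control:
#' `R_os = R_obs(rotaxane) - R_0(control)`, then
#' `R_inner = R_p - R_os` per channel with errors in quadrature.
#'
#' @param rates A `pre_rates` row from [compute_Rp()].
#' @param rotaxane_para Blocked-rotaxane [rate_record] measured under the
#'   same conditions (temperature within 0.5 K, field, guest concentration).
#' @param rotaxane_dia Diamagnetic control paired with the rotaxane sample.
#' @return The `pre_rates` row with `R*_os` and `R*_inner` columns filled and
#'   `corrected = TRUE`.
#' @export
correct_outer_sphere <- function(rates, rotaxane_para, rotaxane_dia) {
  stopifnot(inherits(rates, "pre_rates"), nrow(rates) == 1L)
  rp <- .as_rate_record(rotaxane_para); rd <- .as_rate_record(rotaxane_dia)
  if (rp$condition != "blocked_rotaxane")
    stop("'rotaxane_para' record must have condition 'blocked_rotaxane'")
  if (rd$condition != "diamagnetic")
    stop("'rotaxane_dia' record must have condition 'diamagnetic'")
  .check_matched(rp, rd, "correct_outer_sphere (rotaxane pair)")
  fake <- list(temperature = rates$temperature, field = rates$field,
               guest_total = rates$guest_total)
  .check_matched(fake, rp, "correct_outer_sphere (rates vs rotaxane)")

  os1 <- .guarded_diff(rp$R1_obs - rd$R1_obs,
                       sqrt(rp$stderr_R1^2 + rd$stderr_R1^2), "R1_os")
  os2 <- .guarded_diff(rp$R2_obs - rd$R2_obs,
                       sqrt(rp$stderr_R2^2 + rd$stderr_R2^2), "R2_os")
  in1 <- .guarded_diff(rates$R1_p - os1$value,
                       sqrt(rates$R1_p_err^2 + os1$err^2), "R1_inner",
                       clamp_sigmas = 2)
  in2 <- .guarded_diff(rates$R2_p - os2$value,
                       sqrt(rates$R2_p_err^2 + os2$err^2), "R2_inner",
                       clamp_sigmas = 2)
  rates$R1_os <- os1$value; rates$R1_os_err <- os1$err
  rates$R2_os <- os2$value; rates$R2_os_err <- os2$err
  rates$R1_inner <- in1$value; rates$R1_inner_err <- in1$err
  rates$R2_inner <- in2$value; rates$R2_inner_err <- in2$err
  rates$corrected <- TRUE
  rates
}

#' Diagnose whether exchange (residence time) dominates the paramagnetic rate
#'
#' For the inner-sphere rate to report on the guest residence time tau_M
#' (slow-to-intermediate exchange), three requirements must hold: (1) R_p
#' increases with temperature (exchange speeds up), (2) R_p is independent of
#' the field strength (tau_M is field-independent), and (3) R2_p is
#' approximately equal to R1_p. A R2_p/R1_p ratio approaching 1.5 signals
#' outer-sphere contamination at low temperature.
#'
#' @param rates A `pre_rates` data frame (rows from [compute_Rp()], possibly
#'   outer-sphere corrected) covering >= 3 distinct temperatures.
#' @param ratio_band Acceptable band for R2_p/R1_p; default `c(0.67, 1.3)`.
#' @param field_tol Maximum relative spread of R1_p across fields at a given
#'   temperature; default 0.15. With a single field the check is skipped
#'   with a warning.
#' @param contaminated_ratio Hard threshold at which the uncorrected
#'   R2_p/R1_p ratio is taken as evidence of outer-sphere contamination
#'   (default 1.5).
#' @return An object of class `regime_diagnostics` with the fitted slope of
#'   `ln(R1_p)` vs temperature, the maximum cross-field discrepancy, the
#'   per-temperature ratios before and after outer-sphere correction, and a
#'   `verdict`: `"tau_M_dominated"`, `"outer_sphere_contaminated"` or
#'   `"fast_exchange_suspected"`.
#' @export
diagnose_regime <- function(rates, ratio_band = c(0.67, 1.3),
                            field_tol = 0.15, contaminated_ratio = 1.5) {
  stopifnot(is.data.frame(rates))
  if (length(unique(round(rates$temperature, 1))) < 3L)
    stop("regime diagnostics need at least 3 distinct temperatures")
  if (any(rates$R1_p <= 0))
    stop("all R1_p must be positive for regime diagnostics")

  # (1) temperature trend of ln(R1_p)
  trend <- stats::lm(log(R1_p) ~ temperature, data = rates)
  slope <- unname(coef(trend)[2])
  slope_pass <- slope > 0

  # (2) field independence of R1_p per temperature
  tgrp <- split(rates, round(rates$temperature, 1))
  reldiff <- vapply(tgrp, function(g) {
    if (length(unique(g$field)) < 2L) return(NA_real_)
    (max(g$R1_p) - min(g$R1_p)) / mean(g$R1_p)
  }, numeric(1))
  field_checked <- any(is.finite(reldiff))
  max_reldiff <- if (field_checked) max(reldiff, na.rm = TRUE) else NA_real_
  field_pass <- !field_checked || max_reldiff <= field_tol
  if (!field_checked)
    warning("only one field present; field-independence check skipped")

  # (3) R2_p / R1_p, before and (if available) after outer-sphere correction
  ratio_pre <- rates$R2_p / rates$R1_p
  ratio_post <- if (all(rates$corrected) && all(rates$R1_inner > 0))
    rates$R2_inner / rates$R1_inner else rep(NA_real_, nrow(rates))
  ratio_used <- if (all(is.finite(ratio_post))) ratio_post else ratio_pre
  ratio_pass <- all(ratio_used >= ratio_band[1] & ratio_used <= ratio_band[2]) &&
    max(ratio_used) < contaminated_ratio

  verdict <- if (!slope_pass) "fast_exchange_suspected"
  else if (ratio_pass && field_pass) "tau_M_dominated"
  else "outer_sphere_contaminated"

  structure(list(
    slope = slope, dRp_dT_positive = slope_pass,
    field_checked = field_checked, max_field_reldiff = max_reldiff,
    field_independent = field_pass,
    ratio_pre = ratio_pre, ratio_post = ratio_post,
    ratio_band = ratio_band, ratio_pass = ratio_pass,
    temperatures = rates$temperature,
    verdict = verdict), class = "regime_diagnostics")
}

#' @export
print.regime_diagnostics <- function(x, ...) {
  cat("<regime_diagnostics>\n")
  cat(sprintf("  d ln(R1_p)/dT = %.4g K^-1 (%s)\n", x$slope,
              if (x$dRp_dT_positive) "increasing, pass" else "decreasing, FAIL"))
  if (x$field_checked)
    cat(sprintf("  max cross-field spread of R1_p: %.1f%% (%s)\n",
                100 * x$max_field_reldiff,
                if (x$field_independent) "pass" else "FAIL"))
  else cat("  field check skipped (single field)\n")
  cat(sprintf("  R2_p/R1_p range (pre-correction): %.2f-%.2f\n",
              min(x$ratio_pre), max(x$ratio_pre)))
  if (all(is.finite(x$ratio_post)))
    cat(sprintf("  R2_p/R1_p range (corrected): %.2f-%.2f\n",
                min(x$ratio_post), max(x$ratio_post)))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Threading evidence from observed vs outer-sphere rates
#'
#' If the observed relaxation rate of the free guest greatly exceeds the
#' outer-sphere contribution measured with a cavity-blocked rotaxane control
#' (`R_obs >> R_os`), exchange -- and hence threading of the guest through
#' the host cavity -- must be occurring. If `R_obs` is comparable to `R_os`
#' there is no inner-sphere contribution and no evidence of threading.
#'
#' @param obs [rate_record] of the paramagnetic host + guest sample.
#' @param rotaxane Blocked-rotaxane [rate_record] under matched conditions.
#' @param dia Optional diamagnetic control for the observed sample; when
#'   given, its baseline is subtracted from `R_obs` before forming the
#'   ratio. Without it the raw observed rate is used (appropriate when the
#'   diamagnetic baseline is negligible).
#' @param rotaxane_dia Optional diamagnetic control for the rotaxane sample
#'   (subtracted to give `R_os`); without it the rotaxane observed rate is
#'   used as `R_os` directly.
#' @param min_factor Minimum `R_obs/R_os` ratio (both channels) required to
#'   call threading; default 3.
#' @return An object of class `exchange_evidence` with `ratio_R1`,
#'   `ratio_R2` and the boolean `threading`.
#' @export
exchange_evidence <- function(obs, rotaxane, dia = NULL, rotaxane_dia = NULL,
                              min_factor = 3) {
  obs <- .as_rate_record(obs); rotaxane <- .as_rate_record(rotaxane)
  .check_matched(obs, rotaxane, "exchange_evidence")
  base1 <- 0; base2 <- 0
  if (!is.null(dia)) {
    dia <- .as_rate_record(dia)
    base1 <- dia$R1_obs; base2 <- dia$R2_obs
  }
  os1 <- rotaxane$R1_obs; os2 <- rotaxane$R2_obs
  if (!is.null(rotaxane_dia)) {
    rd <- .as_rate_record(rotaxane_dia)
    os1 <- os1 - rd$R1_obs; os2 <- os2 - rd$R2_obs
  }
  if (os1 <= 0 || os2 <= 0)
    stop("outer-sphere rates must be positive")
  r1 <- (obs$R1_obs - base1) / os1
  r2 <- (obs$R2_obs - base2) / os2
  structure(list(ratio_R1 = r1, ratio_R2 = r2,
                 threading = r1 >= min_factor && r2 >= min_factor,
                 min_factor = min_factor),
            class = "exchange_evidence")
}

#' @export
print.exchange_evidence <- function(x, ...) {
  cat(sprintf("<exchange_evidence> R1_obs/R1_os = %.2f, R2_obs/R2_os = %.2f -> threading: %s (min factor %g)\n",
              x$ratio_R1, x$ratio_R2, x$threading, x$min_factor))
  invisible(x)
}

#' Read a rate table from CSV
#'
#' Expects columns `condition, host_id, guest_id, host_total_M,
#' guest_total_M, temperature_K, field_MHz, R1_obs, R1_err, R2_obs, R2_err`.
#'
#' @param path Path to the CSV file.
#' @return A data frame, one row per measured condition.
#' @export
read_rate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("condition", "temperature_K", "field_MHz", "R1_obs", "R2_obs")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("rate CSV is missing columns: ", paste(miss, collapse = ", "))
  df
}
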