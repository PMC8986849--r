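#' Transition-state rate constant from activation parameters
#'
#' The Eyring relation with transmission coefficient 1:
#' `k(T) = (kB T / h) * exp(-(dH - T dS/1000) / (R T))`
#' with `dH` in kcal/mol and `dS` in cal/(K mol).
#'
#' @param dH Activation enthalpy, kcal/mol.
#' @param dS Activation entropy, cal/(K mol).
#' @param temperature Temperature(s) in K.
#' @return Rate constant(s) in the units implied by the process (s^-1 for
#'   unimolecular dissociation; numeric value at 1 M standard state for
#'   bimolecular rates).
#' @export
eyring_rate <- function(dH, dS, temperature) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  cc <- .pre_constants
  dG <- dH - temperature * dS / 1000
  cc$kB * temperature / cc$h * exp(-dG / (cc$R_kcal * temperature))
}

#' Eyring regression of rate constants versus temperature
#'
#' Linear regression of `ln(k/T)` on `1/T`: the slope is `-dH/R` and the
#' intercept `ln(kB/h) + dS/R`, giving the activation enthalpy (kcal/mol)
#' and entropy (cal/(K mol)) with standard errors and covariance from the
#' regression.
#'
#' @param temperature Temperatures in K (>= 3 distinct values).
#' @param k Positive rate constants, one per temperature.
#' @param weights Optional regression weights (e.g. `1/se(ln k)^2`).
#' @return An object of class `eyring_fit` with `dH`, `dS`, their standard
#'   errors, the (dH, dS) covariance, the underlying `lm` fit and the
#'   temperature range. Use [eyring_dG()] for the activation free energy at
#'   a reporting temperature and `predict()` for rates.
#' @export
eyring_fit <- function(temperature, k, weights = NULL) {
  if (length(temperature) != length(k))
    stop("temperature and k must have the same length")
  if (length(unique(temperature)) < 3L)
    stop("Eyring regression needs at least 3 distinct temperatures")
  if (any(k <= 0)) stop("rate constants must be positive")
  if (any(temperature <= 0)) stop("temperatures must be positive")
  cc <- .pre_constants
  x <- 1 / temperature
  y <- log(k / temperature)
  dat <- data.frame(x = x, y = y)
  fit <- if (is.null(weights)) stats::lm(y ~ x, data = dat)
  else stats::lm(y ~ x, data = dat, weights = weights)
  cf <- coef(fit); vc <- vcov(fit)
  dH <- -unname(cf[2]) * cc$R_kcal
  dS <- (unname(cf[1]) - log(cc$kB / cc$h)) * cc$R_cal
  structure(list(
    dH = dH, dS = dS,
    se_dH = cc$R_kcal * sqrt(vc[2, 2]),
    se_dS = cc$R_cal * sqrt(vc[1, 1]),
    cov_dH_dS = -cc$R_kcal * cc$R_cal * vc[1, 2],
    n_points = length(k),
    temperature_range = range(temperature),
    fit = fit), class = "eyring_fit")
}

#' @export
print.eyring_fit <- function(x, ...) {
  g <- eyring_dG(x)
  cat(sprintf("<eyring_fit> n = %d, T = %.1f-%.1f K\n", x$n_points,
              x$temperature_range[1], x$temperature_range[2]))
  cat(sprintf("  dH+ = %.3f +/- %.3f kcal/mol\n", x$dH, x$se_dH))
  cat(sprintf("  dS+ = %.3f +/- %.3f cal/(K mol)\n", x$dS, x$se_dS))
  cat(sprintf("  dG+(298.15 K) = %.3f +/- %.3f kcal/mol\n", g$dG, g$se))
  invisible(x)
}

#' @export
predict.eyring_fit <- function(object, temperature, ...) {
  eyring_rate(object$dH, object$dS, temperature)
}

#' Activation free energy (with error) from an Eyring fit
#'
#' `dG = dH - T dS/1000`, with the standard error propagated from the
#' (dH, dS) covariance of the regression.
#'
#' @param fit An [eyring_fit()] result.
#' @param temperature Reporting temperature in K (default 298.15).
#' @return A list with `dG` (kcal/mol) and `se`.
#' @export
eyring_dG <- function(fit, temperature = 298.15) {
  stopifnot(inherits(fit, "eyring_fit"))
  dG <- fit$dH - temperature * fit$dS / 1000
  v <- fit$se_dH^2 + (temperature / 1000)^2 * fit$se_dS^2 -
    2 * (temperature / 1000) * fit$cov_dH_dS
  list(dG = dG, se = sqrt(max(v, 0)))
}

#' Activation free energy from enthalpy and entropy
#'
#' `dG = dH - T * dS / 1000` (entropy converted cal -> kcal).
#'
#' @param dH Activation enthalpy, kcal/mol.
#' @param dS Activation entropy, cal/(K mol).
#' @param temperature Temperature in K (default 298.15).
#' @return Free energy in kcal/mol.
#' @examples
#' dG_from_dH_dS(8.35, -17.57) # 13.59 kcal/mol
#' @export
dG_from_dH_dS <- function(dH, dS, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  dH - temperature * dS / 1000
}

#' Activation free energy from a rate constant
#'
#' `dG = -R T ln(k h / (kB T))`. For bimolecular rate constants the numeric
#' value of `k` at the 1 M standard state is used directly, matching the
#' conventional treatment; this standard-state dependence is a caveat of the
#' formula, not corrected for here.
#'
#' @param k Rate constant (> 0); s^-1 (unimolecular) or the numeric value of
#'   a M^-1 s^-1 rate (bimolecular).
#' @param temperature Temperature in K.
#' @return Activation free energy in kcal/mol.
#' @examples
#' dG_from_rate(4.66e5, 298.15) # ~9.72 kcal/mol
#' @export
dG_from_rate <- function(k, temperature = 298.15) {
  if (any(k <= 0)) stop("rate constants must be positive")
  if (any(temperature <= 0)) stop("temperature must be positive")
  cc <- .pre_constants
  -cc$R_kcal * temperature * log(k * cc$h / (cc$kB * temperature))
}

#' Inverse of [dG_from_rate()]: rate constant from an activation free energy
#' @param dG Activation free energy in kcal/mol.
#' @inheritParams dG_from_rate
#' @return Rate constant (same unit convention as [dG_from_rate()]).
#' @export
rate_from_dG <- function(dG, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  cc <- .pre_constants
  cc$kB * temperature / cc$h * exp(-dG / (cc$R_kcal * temperature))
}

#' Threading (association) rate constant from Ka and the dissociation rate
#'
#' At equilibrium `Ka = k_on / k_d`, so `k_on = Ka * k_d`. Uncertainty is
#' propagated by quadrature of the relative errors.
#'
#' @param Ka Association constant (M^-1, > 0).
#' @param kd Dissociation rate constant (s^-1, > 0).
#' @param Ka_err,kd_err Optional standard errors.
#' @return A list with `kon` (M^-1 s^-1) and `kon_err`.
#' @examples
#' kon_from_Ka_kd(1692, 275.4)$kon # 4.66e5 M^-1 s^-1
#' @export
kon_from_Ka_kd <- function(Ka, kd, Ka_err = 0, kd_err = 0) {
  if (any(Ka <= 0) || any(kd <= 0)) stop("Ka and kd must be positive")
  kon <- Ka * kd
  list(kon = kon,
       kon_err = kon * sqrt((Ka_err / Ka)^2 + (kd_err / kd)^2))
}
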