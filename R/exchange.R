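#' Mole fraction of guest bound to the host
#'
#' `f = binding_sites * [HG] / guest_total`, with the complex concentration
#' from the exact 1:1 quadratic shared with the titration module. Under
#' excess guest and strong binding this approaches `H/G`, but the exact form
#' is used because moderate association constants (~10^3-10^4 M^-1) leave
#' the host incompletely saturated.
#'
#' @param Ka Association constant (M^-1, > 0).
#' @param host_total,guest_total Total concentrations (M); `guest_total > 0`.
#' @param binding_sites Number of equivalent binding sites per host
#'   (default 1; the cage host has a single cavity).
#' @return Bound-guest mole fraction in `[0, 1]`.
#' @examples
#' guest_bound_fraction(4796, 5e-4, 5e-3) # ~0.0956
#' @export
guest_bound_fraction <- function(Ka, host_total, guest_total,
                                 binding_sites = 1L) {
  if (any(guest_total <= 0)) stop("guest_total must be positive")
  binding_sites * complex_concentration(Ka, host_total, guest_total) /
    guest_total
}

#' Residence time and observed dissociation rate from an inner-sphere rate
#'
#' In the residence-time-dominated (slow-to-intermediate exchange) regime
#' the inner-sphere paramagnetic rate is `R_inner = f / tau_M`, so the mean
#' residence time of the guest on the host is `tau_M = f / R_inner` and its
#' inverse is the observed dissociation rate constant `kd_obs`. Because this
#' simplification is only valid when tau_M dominates the bound-state
#' relaxation time, the regime-diagnostics verdict must be supplied (or
#' `force = TRUE` given explicitly).
#'
#' @param R_inner Outer-sphere-corrected inner-sphere rate(s), s^-1 (> 0).
#' @param f Bound-guest mole fraction(s) (> 0), from
#'   [guest_bound_fraction()].
#' @param verdict A [diagnose_regime()] result (or its verdict string);
#'   must be `"tau_M_dominated"`.
#' @param force Skip the verdict gate (use with care).
#' @return A data frame of class `exchange_result` with columns `f`,
#'   `tau_M` (s) and `kd_obs` (s^-1).
#' @export
residence_time <- function(R_inner, f, verdict = NULL, force = FALSE) {
  if (!force) {
    v <- if (inherits(verdict, "regime_diagnostics")) verdict$verdict
    else verdict
    if (is.null(v))
      stop("a regime-diagnostics verdict is required (or force = TRUE)")
    if (!identical(v, "tau_M_dominated"))
      stop("residence-time analysis requires the tau_M-dominated regime; ",
           "diagnostics verdict was '", v, "'")
  }
  if (any(R_inner <= 0)) stop("R_inner must be positive")
  if (any(f <= 0) || any(f > 1)) stop("f must lie in (0, 1]")
  tau_M <- f / R_inner
  out <- data.frame(f = f, tau_M = tau_M, kd_obs = 1 / tau_M)
  class(out) <- c("exchange_result", "data.frame")
  out
}

#' Apparent reaction order of the dissociation in guest concentration
#'
#' Least-squares slope of `ln(kd_obs)` on `ln(guest_total)` at fixed
#' temperature and host concentration. A zero order means the residence time
#' is independent of guest concentration (simple dissociative exchange); a
#' non-integer order (~0.3 for the systems studied here) signals
#' exchange-promoting behaviour of excess guest.
#'
#' @param guest_total Guest concentrations (M), >= 3 distinct values.
#' @param kd_obs Observed dissociation rate constants (s^-1), same length.
#' @return A list of class `reaction_order` with `n` (the slope), `stderr`,
#'   and the underlying `lm` fit.
#' @export
estimate_reaction_order <- function(guest_total, kd_obs) {
  if (length(unique(guest_total)) < 3L)
    stop("reaction-order estimation needs at least 3 distinct guest concentrations")
  if (any(guest_total <= 0) || any(kd_obs <= 0))
    stop("concentrations and rate constants must be positive")
  fit <- stats::lm(log(kd_obs) ~ log(guest_total))
  structure(list(n = unname(coef(fit)[2]),
                 stderr = sqrt(diag(vcov(fit)))[2][[1]],
                 fit = fit),
            class = "reaction_order")
}

#' @export
print.reaction_order <- function(x, ...) {
  cat(sprintf("<reaction_order> n = %.3f +/- %.3f\n", x$n, x$stderr))
  invisible(x)
}

#' Normalise an observed dissociation rate constant to a reference guest
#' concentration
#'
#' When the exchange shows an apparent order `n` in guest concentration,
#' observed rate constants measured at different concentrations are put on a
#' common footing by `kd = kd_obs * (guest_ref / guest_total)^n`. This keeps
#' `kd` in s^-1; `guest_ref` declares the concentration the corrected values
#' refer to (conventionally the standard 10-equivalent condition).
#'
#' @param kd_obs Observed dissociation rate constant(s), s^-1.
#' @param guest_total Guest concentration(s) at which `kd_obs` was measured
#'   (M, > 0).
#' @param n Apparent reaction order in guest (dimensionless).
#' @param guest_ref Reference guest concentration (M, > 0).
#' @return Corrected `kd` in s^-1.
#' @examples
#' correct_kd(100, 10e-3, 0.3, 5e-3) # 81.2 s^-1
#' @export
correct_kd <- function(kd_obs, guest_total, n, guest_ref) {
  if (any(guest_total <= 0) || any(guest_ref <= 0))
    stop("guest concentrations must be positive")
  kd_obs * (guest_ref / guest_total)^n
}
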