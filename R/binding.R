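#' Equilibrium 1:1 complex concentration (exact quadratic)
#'
#' Solves the 1:1 mass-action equilibrium `H + G <-> HG`,
#' `Ka = [HG] / ([H][G])`, for the complex concentration given total host
#' and guest. Uses the numerically stable branch of the quadratic,
#' `[HG] = 2 H G / (b + sqrt(b^2 - 4 H G))` with `b = H + G + 1/Ka`, which
#' avoids catastrophic cancellation for strong binding.
#'
#' @param Ka Association constant in M^-1 (>= 0; `Inf` allowed for the
#'   stoichiometric limit).
#' @param host_total,guest_total Total concentrations in M (>= 0).
#' @return Complex concentration in M. Vectorised over all arguments.
#' @export
complex_concentration <- function(Ka, host_total, guest_total) {
  if (any(Ka < 0, na.rm = TRUE)) stop("Ka must be non-negative")
  if (any(c(host_total, guest_total) < 0, na.rm = TRUE))
    stop("concentrations must be non-negative")
  n <- max(length(Ka), length(host_total), length(guest_total))
  Ka <- rep_len(Ka, n); H <- rep_len(host_total, n)
  G <- rep_len(guest_total, n)
  out <- numeric(n)
  inf <- is.infinite(Ka)
  out[inf] <- pmin(H[inf], G[inf])
  fin <- !inf & Ka > 0 & H > 0 & G > 0
  b <- H[fin] + G[fin] + 1 / Ka[fin]
  disc <- pmax(b^2 - 4 * H[fin] * G[fin], 0)
  out[fin] <- 2 * H[fin] * G[fin] / (b + sqrt(disc))
  out
}

#' Fraction of host occupied by guest
#'
#' `theta = [HG] / host_total` from the exact 1:1 quadratic.
#'
#' @inheritParams complex_concentration
#' @return Occupancy in `[0, 1]`; 0 where `host_total == 0`.
#' @examples
#' bound_host_fraction(4796, 5e-4, 5e-3) # ~0.956
#' @export
bound_host_fraction <- function(Ka, host_total, guest_total) {
  cx <- complex_concentration(Ka, host_total, guest_total)
  H <- rep_len(host_total, length(cx))
  ifelse(H > 0, cx / H, 0)
}

#' Predicted reporter-solvent relaxation rate at a given guest concentration
#'
#' In the solvent-reporter titration the bulk reporter solvent (chloroform)
#' exchanges rapidly with the host cavity; its observed longitudinal rate
#' interpolates linearly in host occupancy between the empty-cavity rate
#' `R_empty` (reporter reaches the paramagnetic centre) and the saturated
#' rate `R_sat` (cavity blocked by guest, only outer-sphere effects remain):
#' `R(G) = R_sat + (R_empty - R_sat) * (1 - theta(G))`.
#'
#' @param Ka Association constant of the guest (M^-1).
#' @param R_empty Reporter rate at zero guest (s^-1).
#' @param R_sat Reporter rate at full occupancy (s^-1); `R_empty >= R_sat`.
#' @param host_total,guest_total Total concentrations (M).
#' @return Predicted reporter rate(s) in s^-1.
#' @export
predict_reporter_rate <- function(Ka, R_empty, R_sat, host_total,
                                  guest_total) {
  if (any(R_empty < R_sat)) stop("R_empty must be >= R_sat")
  if (any(R_sat < 0)) stop("rates must be non-negative")
  theta <- bound_host_fraction(Ka, host_total, guest_total)
  R_sat + (R_empty - R_sat) * (1 - theta)
}

#' Fit a PRE solvent-reporter binding titration
#'
#' Nonlinear least-squares fit of reporter rates versus guest concentration
#' (host fixed) to the 1:1 model of [predict_reporter_rate()], with the
#' association constant parameterised as `log10(Ka)` for stability. Reports
#' `log10(Ka)`, `Ka`, and the binding free energy at the series temperature,
#' with delta-method (covariance) standard errors and, optionally, a seeded
#' Monte-Carlo parametric bootstrap of the residual noise.
#'
#' @param guest_total Numeric vector of total guest concentrations (M), or a
#'   data frame with columns `guest_total_M` (or `guest_total`), `R1_obs`
#'   and optionally `host_total_M`, `temperature_K`.
#' @param R1_obs Reporter rates (s^-1), one per guest concentration.
#' @param host_total Total host concentration (M), constant over the series.
#' @param temperature Series temperature in K (used for the free energy).
#' @param mc_draws Number of Monte-Carlo bootstrap draws (0 to skip);
#'   default 2000.
#' @param mc_seed Seed for the bootstrap (default 20220406); the global RNG
#'   state is restored afterwards.
#' @return An object of class `binding_fit` with elements `Ka`, `logKa`,
#'   `dG` (kcal/mol at `temperature`), `R_empty`, `R_sat`, delta-method
#'   standard errors in `$se`, Monte-Carlo errors in `$mc`, and `n_points`.
#' @export
fit_titration <- function(guest_total, R1_obs = NULL, host_total = NULL,
                          temperature = 298.15, mc_draws = 2000,
                          mc_seed = 20220406) {
  if (is.data.frame(guest_total)) {
    df <- guest_total
    G <- df$guest_total_M %||% df$guest_total
    R <- df$R1_obs
    host_total <- host_total %||% (df$host_total_M %||% df$host_total)[1]
    if (!is.null(df$temperature_K)) temperature <- df$temperature_K[1]
  } else {
    G <- guest_total; R <- R1_obs
  }
  if (length(G) < 5L)
    stop("a titration fit needs at least 5 points")
  if (is.null(host_total) || !is.finite(host_total) || host_total <= 0)
    stop("host_total must be a positive concentration")
  if (length(unique(host_total)) != 1L)
    stop("host_total must be constant across the series")
  span <- diff(range(R))
  if (span <= 0 || span < 1e-6 * max(abs(R)))
    stop("Ka unidentifiable: reporter rate shows no response to guest")

  # coarse grid on log10(Ka); endpoints are linear given occupancy
  grid <- seq(0, 9, by = 0.1)
  sse <- vapply(grid, function(lk) {
    th <- bound_host_fraction(10^lk, host_total, G)
    f <- stats::lm(R ~ I(1 - th))
    sum(stats::resid(f)^2)
  }, numeric(1))
  lk0 <- grid[which.min(sse)]
  th0 <- bound_host_fraction(10^lk0, host_total, G)
  lf <- stats::lm(R ~ I(1 - th0))
  Rs0 <- max(unname(coef(lf)[1]), 0)
  Re0 <- Rs0 + max(unname(coef(lf)[2]), span / 2)

  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15, ptol = 1e-15)
  fit <- minpack.lm::nlsLM(
    R ~ Rs + (Re - Rs) * (1 - bound_host_fraction(10^lk, host_total, G)),
    start = list(lk = lk0, Re = Re0, Rs = Rs0), control = ctrl)
  cf <- coef(fit)
  logKa <- unname(cf[["lk"]]); Ka <- 10^logKa
  R_empty <- unname(cf[["Re"]]); R_sat <- unname(cf[["Rs"]])

  # identifiability: occupancy must actually move over the series
  th <- bound_host_fraction(Ka, host_total, G)
  if (max(th) < 0.2 || min(th) > 0.8)
    stop("Ka unidentifiable: host occupancy spans [",
         signif(min(th), 2), ", ", signif(max(th), 2),
         "]; need both low- and high-occupancy points")
  if (R_empty < R_sat)
    warning("fitted R_empty < R_sat; reporter response has unexpected sign")

  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA, 3, 3))
  se_logKa <- sqrt(vc[1, 1])
  ln10RT <- .pre_constants$R_kcal * temperature * log(10)
  dG <- -ln10RT * logKa
  res_sd <- sqrt(sum(stats::resid(fit)^2) / max(length(G) - 3, 1))

  mc <- list(draws = 0, logKa_se = NA_real_, dG_se = NA_real_)
  if (mc_draws > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(mc_seed)
    mu <- predict_reporter_rate(Ka, R_empty, R_sat, host_total, G)
    draws <- vapply(seq_len(mc_draws), function(i) {
      Ri <- mu + stats::rnorm(length(G), sd = res_sd)
      f <- tryCatch(minpack.lm::nlsLM(
        Ri ~ Rs + (Re - Rs) * (1 - bound_host_fraction(10^lk, host_total, G)),
        start = list(lk = logKa, Re = R_empty, Rs = R_sat),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(f)) NA_real_ else unname(coef(f)[["lk"]])
    }, numeric(1))
    draws <- draws[is.finite(draws)]
    mc <- list(draws = length(draws), logKa_se = stats::sd(draws),
               dG_se = ln10RT * stats::sd(draws))
  }

  structure(list(
    Ka = Ka, logKa = logKa, dG = dG,
    R_empty = R_empty, R_sat = R_sat,
    se = list(logKa = se_logKa, Ka = Ka * log(10) * se_logKa,
              dG = ln10RT * se_logKa,
              R_empty = sqrt(vc[2, 2]), R_sat = sqrt(vc[3, 3])),
    mc = mc, residual_sd = res_sd, n_points = length(G),
    temperature = temperature, host_total = host_total, fit = fit),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> n = %d, T = %.2f K\n", x$n_points, x$temperature))
  cat(sprintf("  log10(Ka) = %.3f +/- %.3f   (Ka = %.4g M^-1)\n",
              x$logKa, x$se$logKa, x$Ka))
  cat(sprintf("  dG = %.3f +/- %.3f kcal/mol\n", x$dG, x$se$dG))
  cat(sprintf("  R_empty = %.3f, R_sat = %.3f s^-1\n", x$R_empty, x$R_sat))
  if (x$mc$draws > 0)
    cat(sprintf("  Monte-Carlo (%d draws): se(logKa) = %.3f\n",
                x$mc$draws, x$mc$logKa_se))
  invisible(x)
}

#' Binding free energy from log10 of the association constant
#'
#' `dG = -R T ln(10) log10(Ka)` with the 1 M standard state,
#' `R = 1.98720425e-3 kcal mol^-1 K^-1`.
#'
#' @param logKa `log10` of the association constant (Ka in M^-1).
#' @param temperature Temperature in K (default 298.15, i.e. 25 C).
#' @return Free energy in kcal/mol.
#' @examples
#' ka_to_dG(3.68) # -5.02 kcal/mol
#' @export
ka_to_dG <- function(logKa, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  -.pre_constants$R_kcal * temperature * log(10) * logKa
}

#' Inverse of [ka_to_dG()]: log10(Ka) from a binding free energy
#' @param dG Free energy in kcal/mol.
#' @inheritParams ka_to_dG
#' @return `log10(Ka)`.
#' @export
dG_to_logka <- function(dG, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  -dG / (.pre_constants$R_kcal * temperature * log(10))
}

#' Association constant from a binding free energy
#' @inheritParams dG_to_logka
#' @return Ka in M^-1.
#' @export
dG_to_ka <- function(dG, temperature = 298.15) 10^dG_to_logka(dG, temperature)

#' Read a titration table from CSV
#'
#' Expects columns `host_total_M, guest_total_M, temperature_K, R1_obs` and
#' optionally `R1_err, host_id, guest_id`.
#'
#' @param path Path to the CSV file.
#' @return A data frame suitable for [fit_titration()].
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("host_total_M", "guest_total_M", "R1_obs")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("titration CSV is missing columns: ", paste(miss, collapse = ", "))
  df
}
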