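#' Construct a relaxation decay series
#'
#' A `decay_series` holds one relaxation experiment: the variable delays and
#' the integrated signal intensities measured at them, plus the metadata
#' needed to key the series (sample, experiment kind, signal, temperature,
#' field).
#'
#' @param delays Numeric vector of delay times in seconds, non-negative and
#'   strictly increasing, length >= 4.
#' @param intensities Numeric vector of signal amplitudes (arbitrary units),
#'   same length as `delays`.
#' @param experiment `"inversion_recovery"` (longitudinal, T1) or `"cpmg"`
#'   (transverse, T2; CPMG or PROJECT-CPMG style).
#' @param sample_id Text label for the sample.
#' @param temperature Sample temperature in K (> 0).
#' @param field Spectrometer frequency in MHz.
#' @param signal_label Label of the observed resonance (e.g. `"meta-H"`).
#' @return An object of class `decay_series`.
#' @export
decay_series <- function(delays, intensities,
                         experiment = c("inversion_recovery", "cpmg"),
                         sample_id = "sample", temperature = 298.15,
                         field = 500, signal_label = "") {
  experiment <- match.arg(experiment)
  delays <- as.numeric(delays)
  intensities <- as.numeric(intensities)
  if (length(delays) != length(intensities))
    stop("delays and intensities must have the same length")
  if (length(delays) < 4L)
    stop("a decay series needs at least 4 points")
  if (anyNA(delays) || anyNA(intensities))
    stop("delays and intensities must not contain NA")
  if (any(delays < 0))
    stop("delays must be non-negative")
  if (any(diff(delays) <= 0))
    stop("delays must be strictly increasing")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive (kelvin)")
  structure(list(delays = delays, intensities = intensities,
                 experiment = experiment, sample_id = sample_id,
                 temperature = temperature, field = field,
                 signal_label = signal_label),
            class = "decay_series")
}

#' @export
print.decay_series <- function(x, ...) {
  cat(sprintf("<decay_series> %s | %s | %s | %.1f K | %g MHz | %d points\n",
              x$sample_id, x$experiment, x$signal_label, x$temperature,
              x$field, length(x$delays)))
  invisible(x)
}

# crude noise estimate from second differences (removes smooth trend)
.curvature_noise <- function(y) {
  if (length(y) < 4L) return(0)
  stats::sd(diff(y, differences = 2)) / sqrt(6)
}

.relaxation_fit <- function(rate = NA_real_, amplitude = NA_real_,
                            inversion_factor = NA_real_, offset = 0,
                            stderr_rate = NA_real_, rms_residual = NA_real_,
                            converged = FALSE, flags = character(),
                            loglinear_rate = NA_real_, series = NULL) {
  structure(list(
    time_constant = if (is.finite(rate) && rate > 0) 1 / rate else NA_real_,
    rate = rate, amplitude = amplitude,
    inversion_factor = inversion_factor, offset = offset,
    stderr_rate = stderr_rate, rms_residual = rms_residual,
    converged = converged, flags = flags,
    loglinear_rate = loglinear_rate,
    experiment = series$experiment, sample_id = series$sample_id,
    temperature = series$temperature, field = series$field,
    signal_label = series$signal_label),
    class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<relaxation_fit> not converged:", paste(x$flags, collapse = "; "), "\n")
    return(invisible(x))
  }
  cat(sprintf("<relaxation_fit> %s: T = %.4g s, R = %.4g +/- %.2g s^-1%s\n",
              x$experiment, x$time_constant, x$rate, x$stderr_rate,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "), "]")
              else ""))
  invisible(x)
}

#' Fit an inversion-recovery series to a mono-exponential recovery
#'
#' Fits `I(t) = I_inf * (1 - B * exp(-R1 * t))` by nonlinear least squares.
#' The inversion factor `B` is free (near 2 for perfect inversion, near 1 for
#' saturation recovery) and is reported for quality control. Standard errors
#' come from the Jacobian-based covariance at the optimum.
#'
#' Initialisation: `I_inf` from the longest-delay intensity, `R1` from the
#' delay at which the intensity crosses half its span. If the intensity span
#' is smaller than `min_span_snr` times a second-difference noise estimate
#' the fit is refused (degenerate, no recovery) and a non-converged result is
#' returned rather than an error.
#'
#' @param series A [decay_series] with `experiment == "inversion_recovery"`.
#' @param min_span_snr Minimum ratio of intensity span to estimated noise
#'   below which the series is considered degenerate.
#' @return A `relaxation_fit` with the rate `R1 = 1/T1`, its standard error,
#'   amplitude `I_inf`, inversion factor `B`, rms residual and a `converged`
#'   flag. An under-sampled recovery (fitted T1 > 100x the longest delay)
#'   is flagged in `$flags`.
#' @export
fit_inversion_recovery <- function(series, min_span_snr = 5) {
  stopifnot(inherits(series, "decay_series"))
  if (series$experiment != "inversion_recovery")
    stop("series is not an inversion-recovery experiment")
  t <- series$delays
  y <- series$intensities
  n <- length(y)

  span <- diff(range(y))
  noise <- .curvature_noise(y)
  if (span <= 0 || (noise > 0 && span < min_span_snr * noise))
    return(.relaxation_fit(flags = "degenerate: intensity span below noise floor",
                           series = series))

  Iinf0 <- y[n]
  if (abs(Iinf0) < span / 100) Iinf0 <- max(abs(y))
  B0 <- (Iinf0 - y[1]) / Iinf0
  if (!is.finite(B0) || B0 <= 0) B0 <- 2

  # half-span crossing time for the rate guess
  target <- y[1] + 0.5 * (Iinf0 - y[1])
  idx <- which((y - target) * (y[1] - target) <= 0)[1]
  t_half <- if (!is.na(idx) && t[idx] > 0) t[idx] else stats::median(t[t > 0])
  R0 <- log(2) / t_half

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Iinf * (1 - B * exp(-R * t)),
                      start = list(Iinf = Iinf0, B = B0, R = R0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit))
    return(.relaxation_fit(flags = "optimizer failed to converge",
                           series = series))
  cf <- coef(fit)
  if (!is.finite(cf[["R"]]) || cf[["R"]] <= 0)
    return(.relaxation_fit(flags = "non-physical rate at optimum",
                           series = series))
  se <- tryCatch(sqrt(diag(vcov(fit)))[["R"]], error = function(e) NA_real_)
  flags <- character()
  if (1 / cf[["R"]] > 100 * max(t))
    flags <- c(flags, "under-sampled recovery: T1 exceeds 100x longest delay")
  .relaxation_fit(rate = unname(cf[["R"]]), amplitude = unname(cf[["Iinf"]]),
                  inversion_factor = unname(cf[["B"]]),
                  stderr_rate = se,
                  rms_residual = sqrt(mean(stats::resid(fit)^2)),
                  converged = TRUE, flags = flags, series = series)
}

#' Fit a CPMG/PROJECT-CPMG decay to a mono-exponential
#'
#' Fits `I(t) = I_0 * exp(-R2 * t)` by nonlinear least squares on the raw
#' intensity scale, and additionally reports the log-linear regression slope
#' as a cross-check (`$loglinear_rate`). PROJECT-CPMG suppresses
#' J-modulation, so a pure mono-exponential is the default model; set
#' `offset = TRUE` to add a constant baseline term for distorted data.
#'
#' @param series A [decay_series] with `experiment == "cpmg"`.
#' @param offset Add a free constant baseline to the model.
#' @return A `relaxation_fit` with `R2 = 1/T2` and its standard error.
#' @export
fit_cpmg_decay <- function(series, offset = FALSE) {
  stopifnot(inherits(series, "decay_series"))
  if (series$experiment != "cpmg")
    stop("series is not a CPMG experiment")
  t <- series$delays
  y <- series$intensities
  pos <- y > 0
  if (sum(pos) < 4L)
    stop("fewer than 4 positive intensities; cannot fit a decay")

  # intensity-squared weights make the log-domain fit consistent with the
  # raw-scale least squares it cross-checks
  ll <- stats::lm(log(y[pos]) ~ t[pos], weights = y[pos]^2)
  R_ll <- -unname(coef(ll)[2])
  I00 <- exp(unname(coef(ll)[1]))
  if (!is.finite(R_ll) || R_ll <= 0)
    stop("series does not decay (log-linear slope non-negative)")

  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
  fit <- if (offset) {
    minpack.lm::nlsLM(y ~ I0 * exp(-R * t) + C,
                      start = list(I0 = I00, R = R_ll, C = 0), control = ctrl)
  } else {
    minpack.lm::nlsLM(y ~ I0 * exp(-R * t),
                      start = list(I0 = I00, R = R_ll), control = ctrl)
  }
  cf <- coef(fit)
  if (!is.finite(cf[["R"]]) || cf[["R"]] <= 0)
    stop("fitted T2 is non-positive")
  .relaxation_fit(rate = unname(cf[["R"]]), amplitude = unname(cf[["I0"]]),
                  offset = if (offset) unname(cf[["C"]]) else 0,
                  stderr_rate = sqrt(diag(vcov(fit)))[["R"]],
                  rms_residual = sqrt(mean(stats::resid(fit)^2)),
                  converged = TRUE, loglinear_rate = R_ll, series = series)
}

#' Convert a relaxation time constant to a rate
#'
#' @param t Time constant(s) in seconds, strictly positive.
#' @return `1/t` in s^-1.
#' @examples
#' rate_from_time_constant(0.5) # 2 s^-1
#' @export
rate_from_time_constant <- function(t) {
  if (any(!is.finite(t)) || any(t <= 0))
    stop("time constants must be positive and finite")
  1 / t
}

#' Read a decay table from CSV
#'
#' Expects columns `sample_id, experiment, signal_label, temperature_K,
#' field_MHz, delay_s, intensity` (one row per point) plus any extra metadata
#' columns (e.g. `condition`, `host_total_M`, `guest_total_M`) that are
#' constant within a series. Series are keyed by
#' (sample_id, experiment, signal_label, temperature_K, field_MHz).
#'
#' @param path Path to the CSV file.
#' @return A data frame (the decay table); pass to [fit_decay_table()] or
#'   [split_decay_table()].
#' @export
read_decay_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "experiment", "signal_label", "temperature_K",
           "field_MHz", "delay_s", "intensity")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("decay CSV is missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Split a decay table into decay_series objects
#'
#' @param df A decay table as returned by [read_decay_csv()] or
#'   [simulate_decays()].
#' @return A list of [decay_series] objects, each carrying the extra metadata
#'   columns of its group in `attr(, "meta")`.
#' @export
split_decay_table <- function(df) {
  key <- interaction(df$sample_id, df$experiment, df$signal_label,
                     df$temperature_K, df$field_MHz, drop = TRUE)
  lapply(split(df, key), function(g) {
    o <- order(g$delay_s)
    s <- decay_series(g$delay_s[o], g$intensity[o],
                      experiment = g$experiment[1],
                      sample_id = g$sample_id[1],
                      temperature = g$temperature_K[1],
                      field = g$field_MHz[1],
                      signal_label = g$signal_label[1])
    extra <- setdiff(names(g), c("delay_s", "intensity"))
    attr(s, "meta") <- g[1, extra, drop = FALSE]
    s
  })
}

#' Fit every series in a decay table and assemble a rate table
#'
#' For each (sample, signal, temperature, field) group the
#' inversion-recovery rows give `R1_obs` and the CPMG rows give `R2_obs`.
#' Extra metadata columns constant within a group (such as `condition`,
#' `host_total_M`, `guest_total_M`, `host_id`, `guest_id`) are carried
#' through.
#'
#' @param df A decay table (see [read_decay_csv()]).
#' @return A rate table data frame with columns `sample_id, signal_label,
#'   temperature_K, field_MHz, R1_obs, R1_err, R2_obs, R2_err` plus carried
#'   metadata.
#' @export
fit_decay_table <- function(df) {
  series <- split_decay_table(df)
  meta_cols <- setdiff(names(df), c("experiment", "delay_s", "intensity"))
  key <- vapply(series, function(s)
    paste(s$sample_id, s$signal_label, s$temperature, s$field, sep = "\r"),
    character(1))
  rows <- lapply(split(series, key), function(grp) {
    out <- attr(grp[[1]], "meta")[, intersect(meta_cols, names(attr(grp[[1]], "meta"))),
                                  drop = FALSE]
    out$R1_obs <- out$R1_err <- out$R2_obs <- out$R2_err <- NA_real_
    for (s in grp) {
      if (s$experiment == "inversion_recovery") {
        f <- fit_inversion_recovery(s)
        if (!f$converged)
          stop("inversion-recovery fit failed for sample '", s$sample_id,
               "' at ", s$temperature, " K: ", paste(f$flags, collapse = "; "))
        out$R1_obs <- f$rate; out$R1_err <- f$stderr_rate
      } else {
        f <- fit_cpmg_decay(s)
        out$R2_obs <- f$rate; out$R2_err <- f$stderr_rate
      }
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
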