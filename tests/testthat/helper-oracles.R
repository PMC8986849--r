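# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

# brute-force 1:1 mass-action equilibrium: root of Ka(H-c)(G-c) - c = 0
eq_complex_oracle <- function(Ka, H, G) {
  if (Ka == 0 || H == 0 || G == 0) return(0)
  g <- function(c) Ka * (H - c) * (G - c) - c
  stats::uniroot(g, c(0, min(H, G)), tol = .Machine$double.eps)$root
}

# exhaustive grid search over (T1, Iinf, B) minimising the SSE of the
# inversion-recovery model
ir_grid_oracle <- function(t, y, T1_grid, Iinf_grid, B_grid) {
  best <- NULL
  best_sse <- Inf
  for (T1 in T1_grid) for (Ii in Iinf_grid) for (B in B_grid) {
    sse <- sum((y - Ii * (1 - B * exp(-t / T1)))^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- c(T1 = T1, Iinf = Ii, B = B)
    }
  }
  best
}

# simple series builders
make_ir_series <- function(T1 = 1, Iinf = 1, B = 2, n = 8, sigma = 0,
                           ...) {
  t <- exp(seq(log(0.02 * T1), log(4 * T1), length.out = n))
  y <- Iinf * (1 - B * exp(-t / T1))
  if (sigma > 0) y <- y + rnorm(n, sd = sigma)
  decay_series(t, y, experiment = "inversion_recovery", ...)
}

make_cpmg_series <- function(T2 = 0.25, I0 = 1, n = 10, sigma = 0, ...) {
  t <- exp(seq(log(0.05 * T2), log(3 * T2), length.out = n))
  y <- I0 * exp(-t / T2)
  if (sigma > 0) y <- y + rnorm(n, sd = sigma)
  decay_series(t, y, experiment = "cpmg", ...)
}
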