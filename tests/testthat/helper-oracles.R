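# Independent oracles and small shared fixtures for the test suite.

# Damped fixed-point / bisection solver of the implicit random-predator
# equation Ne = N0 * (1 - exp(a * (b * Ne - t))), independent of the
# Lambert-W evaluation used by the package.
rogers_fixed_point <- function(N0, a, b, t, tol = 1e-12) {
  g <- function(Ne) Ne - N0 * (1 - exp(a * (b * Ne - t)))
  # g(0) <= 0 and g(N0) >= 0, so bisection on [0, N0] always brackets.
  lo <- 0; hi <- N0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Endpoint of the depletion ODE via deSolve's lsoda, as an implementation-
# independent check on the package's Runge-Kutta integrator.
lsoda_endpoint <- function(N0, c, b, h, m, t_end) {
  rhs <- function(t, y, parms) {
    N <- max(y[1], 0)
    list(-c * N^h / (1 + c * b * N^h) - m * N)
  }
  out <- deSolve::lsoda(c(N = N0), c(0, t_end), rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  unname(out[nrow(out), "N"])
}

# A small, fast, well-identified functional-response truth (low handling
# time, so feeding is attack-limited and all parameters are informative),
# used where tests need reliable parameter recovery rather than the
# published study conditions.
toy_truth <- function() {
  list(fr = list(A = fr_params("II", c0 = 0.4, E_c = 0.7, b0 = 0.25),
                 B = fr_params("II", c0 = 1.0, E_c = 0.7, b0 = 0.25)),
       mort = list(A = mortality_params(0), B = mortality_params(0.1)))
}

toy_design <- function(replicates = 4) {
  fr_design(datasets = list(A = c(5, 10, 15, 18), B = c(4, 6, 10, 18)),
            densities = c(2, 4, 6, 10, 16, 24, 40, 60),
            replicates = replicates, dropout = 0)
}

quick_control <- function(seed = 1, n_starts = 3) {
  fr_control(n_starts = n_starts, seed = seed)
}
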