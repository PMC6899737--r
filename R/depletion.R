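#' Functional-response parameters
#'
#' A functional-response parameter set for one dataset: the response type
#' (I linear, II hyperbolic, III sigmoidal), the attack coefficient `c0` at
#' the reference temperature with activation energy `E_c`, and the handling
#' time `b0` (days/individual) with activation energy `E_b`.  The Hill
#' exponent is fixed by type (1 for I/II, 2 for III), never a free
#' parameter, and type I is encoded as zero handling time.
#'
#' The attack rate at prey density `N` is `a = c(T) * N^(h-1)`, so for
#' types I/II `c` is the attack rate itself.
#'
#' @param type Functional-response type: `"I"`, `"II"` or `"III"`.
#' @param c0 Attack coefficient at `T0` (> 0), per-arena units/day.
#' @param E_c Activation energy of the attack coefficient, eV.
#' @param b0 Handling time at `T0`, days/individual (0 for type I).
#' @param E_b Activation energy of handling time, eV.
#' @return An object of class `fr_params`.
#' @examples
#' p <- fr_params("II", c0 = 1, b0 = 0.5)
#' feeding_rate(2, p, T_K = fr_constants()$T0_K)  # 2/(1 + 1) = 1 prey/day
#' @export
fr_params <- function(type = c("II", "I", "III"), c0, E_c = 0,
                      b0 = if (type == "I") 0 else NULL, E_b = 0) {
  type <- match.arg(type)
  if (!is.numeric(c0) || c0 <= 0) stop("attack coefficient c0 must be > 0")
  if (type == "I") {
    if (!is.null(b0) && any(b0 != 0))
      stop("type I has no handling time; b0 must be 0")
    b0 <- 0
    E_b <- 0
  } else {
    if (is.null(b0) || b0 <= 0)
      stop("types II/III require handling time b0 > 0")
  }
  structure(list(type = type,
                 hill_h = if (type == "III") 2 else 1,
                 c0 = c0, E_c = E_c, b0 = b0, E_b = E_b),
            class = "fr_params")
}

#' @export
print.fr_params <- function(x, ...) {
  cat(sprintf("Type %s functional response (h = %d)\n", x$type, x$hill_h))
  cat(sprintf("  c0 = %.4g (E_c = %.3g eV)\n", x$c0, x$E_c))
  if (x$type != "I")
    cat(sprintf("  b0 = %.4g days/ind (E_b = %.3g eV)\n", x$b0, x$E_b))
  invisible(x)
}

#' Natural-mortality parameters
#'
#' Background prey mortality rate `m0` (per day, at the reference
#' temperature) with activation energy `E_m`.  `m0 = 0` encodes arenas with
#' no natural prey mortality.
#'
#' @param m0 Mortality rate at `T0`, 1/day (>= 0).
#' @param E_m Activation energy, eV.
#' @return An object of class `mortality_params`.
#' @export
mortality_params <- function(m0 = 0, E_m = 0) {
  if (m0 < 0) stop("mortality rate m0 must be >= 0")
  structure(list(m0 = m0, E_m = E_m), class = "mortality_params")
}

#' Per capita feeding rate
#'
#' Instantaneous feeding rate `F = a N / (1 + a b N)` (individuals/day) at
#' prey density `N`, with attack rate `a = c(T) N^(h-1)` and handling time
#' `b(T)`, both Arrhenius-scaled to temperature `T_K`.  `F(0) = 0` and, for
#' `b > 0`, `F` saturates at `1/b` as `N` grows.
#'
#' @param N Prey density, individuals/arena (>= 0, vectorized).
#' @param params An [fr_params()] object.
#' @param T_K Absolute temperature, Kelvin.
#' @param constants An [fr_constants()] object.
#' @return Feeding rate, individuals/day.
#' @export
feeding_rate <- function(N, params, T_K = fr_constants()$T0_K,
                         constants = fr_constants()) {
  stopifnot(inherits(params, "fr_params"))
  if (any(N < 0)) stop("prey density must be >= 0")
  k <- constants$boltzmann_eV_K
  cT <- params$c0 * arrhenius_factor(params$E_c, T_K, constants$T0_K, k)
  bT <- params$b0 * arrhenius_factor(params$E_b, T_K, constants$T0_K, k)
  a <- cT * N^(params$hill_h - 1)
  a * N / (1 + a * bT * N)
}

#' Expected prey remaining after a depletion trial
#'
#' Numerically integrates the prey-depletion ODE
#' `dN/dt = -c N^h / (1 + c b N^h) - m N` (the feeding term is dropped when
#' no predator is present) from the initial density over the trial duration,
#' using an adaptive Runge-Kutta 4(5) scheme evaluated at the endpoint.
#' Parameters are Arrhenius-scaled to the trial temperature before
#' integration.
#'
#' @param N0 Initial prey count(s).
#' @param params An [fr_params()] object, or `NULL` for predator-free arenas.
#' @param mort A [mortality_params()] object (default: no mortality).
#' @param T_K Absolute temperature, Kelvin (recycled against `N0`).
#' @param duration Trial duration, days.
#' @param predator_present Logical; when `FALSE` the feeding term is dropped
#'   and the result depends only on mortality.
#' @param constants An [fr_constants()] object.
#' @param rtol,atol Solver relative/absolute tolerances.
#' @return Expected prey remaining, same length as `N0`, in `[0, N0]`.
#' @examples
#' # no predator: exponential decline exp(-0.1) of 30 prey
#' integrate_depletion(30, NULL, mortality_params(0.1), predator_present = FALSE)
#' @export
integrate_depletion <- function(N0, params = NULL,
                                mort = mortality_params(),
                                T_K = fr_constants()$T0_K,
                                duration = 1,
                                predator_present = !is.null(params),
                                constants = fr_constants(),
                                rtol = 1e-8, atol = 1e-10) {
  if (any(N0 < 0)) stop("initial prey count must be >= 0")
  if (any(duration <= 0)) stop("duration must be > 0")
  stopifnot(inherits(mort, "mortality_params"))
  n <- length(N0)
  T_K <- rep_len(T_K, n)
  duration <- rep_len(duration, n)
  pred <- rep_len(predator_present, n)
  k <- constants$boltzmann_eV_K
  mT <- mort$m0 * arrhenius_factor(mort$E_m, T_K, constants$T0_K, k)
  if (any(pred)) {
    stopifnot(inherits(params, "fr_params"))
    cT <- params$c0 * arrhenius_factor(params$E_c, T_K, constants$T0_K, k)
    bT <- params$b0 * arrhenius_factor(params$E_b, T_K, constants$T0_K, k)
    h <- params$hill_h
  } else {
    cT <- bT <- numeric(n)
    h <- 1
  }
  cT[!pred] <- 0
  bT[!pred] <- 0
  out <- .cpp_depletion_endpoint(as.numeric(N0), cT, bT, h, mT,
                                 as.numeric(duration), rtol, atol)
  if (any(out < -atol))
    warning("depletion solver undershot below zero; clipping to 0")
  pmin(pmax(out, 0), N0)
}

# Internal vectorized endpoint used by the likelihood: per-element c, b, m
# already evaluated at temperature.  Controls are encoded as c = 0.
depletion_endpoint_raw <- function(N0, cT, bT, h, mT, duration,
                                   rtol = 1e-8, atol = 1e-10) {
  out <- .cpp_depletion_endpoint(as.numeric(N0), as.numeric(cT),
                                 as.numeric(bT), h, as.numeric(mT),
                                 as.numeric(duration), rtol, atol)
  pmin(pmax(out, 0), N0)
}

#' Rogers random-predator closed form for type II depletion
#'
#' Closed-form number of prey eaten in a depletion trial with a hyperbolic
#' (type II) response and no background mortality: the solution `Ne` of the
#' implicit equation `Ne = N0 (1 - exp(a (b Ne - t)))`, evaluated through
#' the principal branch of the Lambert W function.  Serves as the
#' independent oracle for the ODE solver.
#'
#' @param N0 Initial prey count.
#' @param a Attack rate (per-arena/day), > 0.
#' @param b Handling time, days/individual (>= 0).
#' @param t Trial duration, days.
#' @return Number of prey eaten, in `[0, N0]` (vectorized over `N0`).
#' @examples
#' rogers_closed_form(10, a = 1, b = 0, t = 1)  # reduces to N0 (1 - exp(-a t))
#' @export
rogers_closed_form <- function(N0, a, b, t) {
  if (any(a <= 0)) stop("attack rate a must be > 0")
  if (any(b < 0)) stop("handling time b must be >= 0")
  if (any(t <= 0)) stop("duration t must be > 0")
  n <- max(length(N0), length(a), length(b), length(t))
  N0 <- rep_len(N0, n); a <- rep_len(a, n)
  b <- rep_len(b, n); t <- rep_len(t, n)
  survivors <- numeric(n)
  for (i in seq_len(n)) {
    if (N0[i] == 0) { survivors[i] <- 0; next }
    if (b[i] == 0) { survivors[i] <- N0[i] * exp(-a[i] * t[i]); next }
    # survivors N(t) = W(a b N0 exp(a b N0 - a t)) / (a b);
    # evaluated in the log domain when the W argument would overflow.
    ab <- a[i] * b[i]
    L <- log(ab * N0[i]) + ab * N0[i] - a[i] * t[i]
    survivors[i] <- lambertW_exp(L) / ab
  }
  eaten <- N0 - survivors
  pmin(pmax(eaten, 0), N0)
}

# Principal-branch Lambert W evaluated in the log domain: returns W0(exp(L))
# by Newton iteration on w + log(w) = L, which stays finite for any real L
# (the argument exp(L) itself may overflow).  W0(x) > 0 for x > 0, so the
# iteration lives on w > 0 with guaranteed-positive damped steps.
lambertW_exp <- function(L) {
  if (!is.finite(L)) stop("non-finite argument in Lambert W evaluation")
  w <- if (L > 1) L - log(L) else exp(L) / (1 + exp(L))
  for (it in 1:100) {
    f <- w + log(w) - L
    step <- f * w / (w + 1)        # Newton step for g(w) = w + log w - L
    w_new <- w - step
    while (w_new <= 0) { step <- step / 2; w_new <- w - step }
    if (abs(w_new - w) <= 1e-15 * max(w_new, 1)) return(w_new)
    w <- w_new
  }
  w
}
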