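# Per-stream energetic efficiency: assimilated energy intake relative to
# metabolic expenditure, combining the fitted functional response (field
# setting), the fitted metabolic-rate model and the temperature-dependent
# assimilation efficiency.

#' Prey energetic constants
#'
#' Ash-free dry mass per Simuliidae individual and energy content, used to
#' convert a feeding rate in individuals/day into an energy flux.
#'
#' @param M_S_mg Ash-free dry mass per prey individual, mg.
#' @param E_S_J_per_mg Energy content, J/mg.
#' @return An object of class `prey_energetics`.
#' @export
prey_energetics <- function(M_S_mg = 0.546, E_S_J_per_mg = 23.1) {
  stopifnot(M_S_mg > 0, E_S_J_per_mg > 0)
  structure(list(M_S_mg = M_S_mg, E_S_J_per_mg = E_S_J_per_mg),
            class = "prey_energetics")
}

#' Per capita energy feeding rate
#'
#' Converts a feeding rate in prey individuals/day into J/h:
#' `F_E = F * M_S * E_S / 24`.
#'
#' @param F_ind_per_day Feeding rate, individuals/day (>= 0).
#' @param prey A [prey_energetics()] object.
#' @return Energy feeding rate, J/h.
#' @examples
#' energy_feeding_rate(1)  # one prey/day ~ 0.53 J/h
#' @export
energy_feeding_rate <- function(F_ind_per_day, prey = prey_energetics()) {
  if (any(F_ind_per_day < 0)) stop("feeding rate must be >= 0")
  F_ind_per_day * prey$M_S_mg * prey$E_S_J_per_mg / 24
}

#' Per-stream energetic efficiency of a predator population
#'
#' For each stream, evaluates the predator's feeding rate at the stream's
#' Simuliidae density and mean temperature (using the field-setting attack
#' coefficient and the fitted handling time), converts it to an energy flux,
#' multiplies by the temperature-dependent assimilation efficiency, and
#' divides by the predicted metabolic rate at the stream temperature:
#' `y = omega * F_E / I`.  `y < 1` flags streams where feeding cannot meet
#' metabolic demand.
#'
#' @param streams Data.frame with columns `stream_id`, `mean_temp_C`,
#'   `simuliidae_abundance` and optionally `predator_abundance`.
#' @param fr_fit An `fr_fit` (the BIC winner), or an [fr_params()] object.
#' @param met_fit A `metabolic_fit`.
#' @param dataset Which dataset's attack coefficient to use when `fr_fit`
#'   is a fitted model (the field setting).
#' @param prey A [prey_energetics()] object.
#' @param assim An [assimilation_params()] object.
#' @param predator_mass_mg Dry mass used for metabolic prediction when the
#'   metabolic model includes mass; defaults to the mean respirometry mass.
#' @param field_rate_multiplier Multiplier applied to the measured routine
#'   metabolic rate to approximate field rates (default 1: measured rates
#'   used directly).
#' @param area_scaling Factor converting survey abundance (individuals/m^2)
#'   to the per-arena density scale of the attack coefficient (default 1,
#'   identity).
#' @param constants An [fr_constants()] object.
#' @return Data.frame of class `efficiency_result` with one row per stream:
#'   feeding rate (individuals/day), energy feeding rate (J/h),
#'   assimilation efficiency, metabolic rate (J/h) and efficiency `y`.
#' @export
energetic_efficiency <- function(streams, fr_fit, met_fit,
                                 dataset = "Field2015",
                                 prey = prey_energetics(),
                                 assim = assimilation_params(),
                                 predator_mass_mg = NULL,
                                 field_rate_multiplier = 1,
                                 area_scaling = 1,
                                 constants = fr_constants()) {
  req <- c("stream_id", "mean_temp_C", "simuliidae_abundance")
  miss <- setdiff(req, names(streams))
  if (length(miss))
    stop("streams are missing column(s): ", paste(miss, collapse = ", "))
  if (any(streams$simuliidae_abundance < 0))
    stop("prey abundance must be >= 0")
  prm <- if (inherits(fr_fit, "fr_fit")) {
    constants <- fr_fit$constants
    fr_params_for(fr_fit, dataset)
  } else fr_fit
  stopifnot(inherits(prm, "fr_params"), inherits(met_fit, "metabolic_fit"))
  if (is.null(predator_mass_mg)) predator_mass_mg <- met_fit$mean_mass_mg

  T_K <- celsius_to_kelvin(streams$mean_temp_C)
  N <- streams$simuliidae_abundance * area_scaling
  Fjk <- feeding_rate(N, prm, T_K, constants)
  FE <- energy_feeding_rate(Fjk, prey)
  omega <- assimilation_efficiency(T_K, assim, constants$boltzmann_eV_K)
  I <- predict(met_fit, streams$mean_temp_C,
               dry_mass_mg = if (met_fit$has_mass &&
                                 "ln_mass" %in%
                                 all.vars(formula(met_fit$fit)))
                 predator_mass_mg else NULL) * field_rate_multiplier
  if (any(I <= 0)) stop("metabolic rate is zero; efficiency undefined")
  out <- data.frame(stream_id = streams$stream_id,
                    mean_temp_C = streams$mean_temp_C,
                    prey_density = streams$simuliidae_abundance,
                    feeding_rate = Fjk,
                    energy_feeding_rate = FE,
                    assimilation = omega,
                    metabolic_rate = I,
                    efficiency = omega * FE / I,
                    deficit = omega * FE / I < 1)
  if ("predator_abundance" %in% names(streams))
    out$predator_abundance <- streams$predator_abundance
  class(out) <- c("efficiency_result", "data.frame")
  out
}

#' Smoothed efficiency-temperature and efficiency-abundance relationships
#'
#' Fits penalized regression smoothers (thin-plate GAMs) of energetic
#' efficiency against stream temperature, and, when predator abundance is
#' available, against predator abundance.  With fewer than 5 streams a
#' linear trend is fitted instead, with a warning.
#'
#' @param eff An `efficiency_result` data.frame.
#' @param k Smoother basis dimension.
#' @return An object of class `efficiency_profiles` with the fitted
#'   smoothers and their summaries (edf, F, r-squared).
#' @export
efficiency_profiles <- function(eff, k = 5) {
  stopifnot(inherits(eff, "data.frame"), "efficiency" %in% names(eff))
  n <- nrow(eff)
  smooth_one <- function(xname) {
    d <- data.frame(y = eff$efficiency, x = eff[[xname]])
    linear <- function() {
      fit <- lm(y ~ x, data = d)
      s <- suppressWarnings(summary(fit))  # degenerate inputs: perfect fit
      list(fit = fit, type = "linear", r.squared = s$r.squared,
           F = if (is.null(s$fstatistic)) NA_real_
               else unname(s$fstatistic[1]),
           slope = unname(coef(fit)[2]))
    }
    if (n < 5) {
      warning("fewer than 5 streams; fitting a linear trend instead of a GAM")
      linear()
    } else if (sd(d$y) < 1e-10) {
      # degenerate constant response: the smoother has nothing to estimate
      linear()
    } else {
      kk <- min(k, n - 1)
      fit <- mgcv::gam(y ~ s(x, k = kk), data = d, method = "REML")
      s <- summary(fit)
      list(fit = fit, type = "gam", r.squared = s$r.sq,
           F = unname(s$s.table[1, "F"]),
           p = unname(s$s.table[1, "p-value"]),
           edf = unname(s$s.table[1, "edf"]))
    }
  }
  out <- list(temperature = smooth_one("mean_temp_C"))
  if ("predator_abundance" %in% names(eff))
    out$abundance <- smooth_one("predator_abundance")
  out$n <- n
  out$eff <- eff
  class(out) <- "efficiency_profiles"
  out
}

#' Fitted smoother values on a grid
#'
#' @param object An `efficiency_profiles` object.
#' @param which `"temperature"` or `"abundance"`.
#' @param n Grid size.
#' @param ... Unused.
#' @return Data.frame with the predictor grid and fitted efficiency.
#' @export
predict.efficiency_profiles <- function(object, which = "temperature",
                                        n = 100, ...) {
  sm <- object[[which]]
  if (is.null(sm)) stop("no smoother for ", which)
  xvar <- if (which == "temperature") "mean_temp_C" else "predator_abundance"
  grid <- data.frame(x = seq(min(object$eff[[xvar]]),
                             max(object$eff[[xvar]]), length.out = n))
  data.frame(x = grid$x, fitted = as.numeric(predict(sm$fit, newdata = grid)))
}

#' @export
print.efficiency_profiles <- function(x, ...) {
  cat(sprintf("Energetic-efficiency smoothers over %d streams\n", x$n))
  for (nm in intersect(c("temperature", "abundance"), names(x))) {
    s <- x[[nm]]
    cat(sprintf("  y ~ %s (%s): F = %.2f, r2 = %.3f\n", nm, s$type,
                s$F, s$r.squared))
  }
  n_def <- sum(x$eff$deficit)
  if (n_def > 0)
    cat(sprintf("  %d stream(s) below y = 1 (energetic deficit)\n", n_def))
  invisible(x)
}

#' @export
plot.efficiency_profiles <- function(x, which = "temperature", ...) {
  xvar <- if (which == "temperature") "mean_temp_C" else "predator_abundance"
  plot(x$eff[[xvar]], x$eff$efficiency,
       xlab = if (which == "temperature") "stream temperature (C)"
              else "predator abundance (ind/m^2)",
       ylab = "energetic efficiency y", ...)
  g <- predict(x, which = which)
  lines(g$x, g$fitted)
  abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}
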