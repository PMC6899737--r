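# Mass and temperature scaling of routine metabolic rate from respirometry,
# with BIC selection among candidate log-linear regressions and
# thermal-optimum extraction from the quadratic temperature model.

#' Convert oxygen consumption to energetic equivalents
#'
#' Converts a respirometry rate in umol O2/h to J/h using the molar mass of
#' O2 (31.9988 g/mol), its gas density (1.429 g/L) and the standard
#' oxycalorific conversion (1 ml O2 = 20.1 J).  The combined constant is
#' about 0.4501 J per umol O2.
#'
#' @param rate Oxygen consumption rate, umol O2/h (>= 0, vectorized).
#' @return Metabolic rate, J/h.
#' @examples
#' o2_to_joules(1)  # ~0.450 J/h
#' @export
o2_to_joules <- function(rate) {
  if (any(rate < 0, na.rm = TRUE)) stop("O2 consumption rate must be >= 0")
  # umol -> ug of O2, / (ug/ul) -> ul, * J/ml / 1000 -> J
  rate * (31.9988 / 1.429) * 20.1 / 1000
}

# The candidate design set: full crossing of mass in/out, mass:temperature
# interaction (requires both mains) and quadratic temperature (requires the
# linear term).  x is the Arrhenius abscissa, so temperature coefficients
# are activation energies in eV.
metabolic_candidates <- function() {
  list(
    intercept_only   = ln_rate ~ 1,
    temp             = ln_rate ~ x,
    mass             = ln_rate ~ ln_mass,
    temp_mass        = ln_rate ~ x + ln_mass,
    temp_mass_int    = ln_rate ~ x + ln_mass + x:ln_mass,
    temp_quad        = ln_rate ~ x + I(x^2),
    temp_quad_mass   = ln_rate ~ x + I(x^2) + ln_mass,
    temp_quad_mass_int = ln_rate ~ x + I(x^2) + ln_mass + x:ln_mass
  )
}

#' Fit metabolic-rate scaling models to respirometry records
#'
#' Converts O2 consumption to J/h, then regresses `ln(rate)` on the
#' Arrhenius temperature abscissa `x = (T - T0)/(k T T0)` and `ln(dry mass)`
#' by ordinary least squares, over all candidate combinations of the main
#' and interactive effects of temperature and mass plus a quadratic
#' temperature term.  Because the regression runs on `x` rather than raw
#' temperature, the temperature coefficient is the activation energy in eV
#' and the mass coefficient is the allometric exponent.  Candidates are
#' ranked by BIC.
#'
#' @param records Data.frame with columns `temperature_C`, `o2_umol_per_h`
#'   and optionally `dry_mass_mg` (and `species`, ignored here: fit one
#'   species at a time).  Alternatively supply `metabolic_rate_J_h` directly.
#' @param constants An [fr_constants()] object.
#' @return An object of class `metabolic_fit`: all candidate `lm` fits, the
#'   BIC ranking, and the winner.
#' @examples
#' rec <- simulate_respirometry(truth = metabolic_truth_limnophora(),
#'                              sigma_ln = 0, seed = 1)
#' fit <- fit_metabolism(rec)
#' coef(fit)  # exact recovery on noise-free data
#' @export
fit_metabolism <- function(records, constants = fr_constants()) {
  if (!"temperature_C" %in% names(records))
    stop("records must contain temperature_C")
  if ("metabolic_rate_J_h" %in% names(records)) {
    rate <- records$metabolic_rate_J_h
  } else if ("o2_umol_per_h" %in% names(records)) {
    rate <- o2_to_joules(records$o2_umol_per_h)
  } else stop("records must contain o2_umol_per_h or metabolic_rate_J_h")
  if (any(rate <= 0))
    stop("metabolic rates must be positive after control correction")
  if (length(unique(records$temperature_C)) < 2 || nrow(records) < 3)
    stop("need >= 3 records spanning >= 2 temperatures")

  k <- constants$boltzmann_eV_K; T0 <- constants$T0_K
  T_K <- celsius_to_kelvin(records$temperature_C)
  df <- data.frame(ln_rate = log(rate),
                   x = (T_K - T0) / (k * T_K * T0))
  has_mass <- "dry_mass_mg" %in% names(records) &&
    all(is.finite(records$dry_mass_mg)) &&
    sd(log(records$dry_mass_mg)) > 0
  if (has_mass) df$ln_mass <- log(records$dry_mass_mg)

  cands <- metabolic_candidates()
  if (!has_mass) {
    dropped <- grepl("mass", names(cands))
    if ("dry_mass_mg" %in% names(records))
      warning("dry mass missing or constant; dropping mass candidates")
    cands <- cands[!dropped]
  }
  fits <- lapply(cands, function(f) lm(f, data = df))
  bic <- vapply(fits, BIC, numeric(1))
  ranking <- data.frame(model = names(fits), k = vapply(
    fits, function(f) length(coef(f)) + 1L, integer(1)),
    BIC = unname(bic))
  ranking <- ranking[order(ranking$BIC, ranking$k, ranking$model), ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  winner <- ranking$model[1]
  structure(list(candidates = fits, ranking = ranking, winner = winner,
                 fit = fits[[winner]], has_mass = has_mass,
                 constants = constants, n = nrow(df), data = df,
                 mean_mass_mg = if (has_mass) mean(records$dry_mass_mg)
                                else NA_real_),
            class = "metabolic_fit")
}

#' @export
print.metabolic_fit <- function(x, ...) {
  cat("Metabolic-rate scaling (BIC-selected):", x$winner, "\n")
  cat(sprintf("  n = %d records; r2 = %.3f\n", x$n,
              summary(x$fit)$r.squared))
  print(round(coef(x$fit), 4))
  invisible(x)
}

#' @export
summary.metabolic_fit <- function(object, ...) {
  s <- summary(object$fit)
  tab <- as.data.frame(s$coefficients)
  names(tab) <- c("estimate", "se", "t", "p")
  tab <- cbind(term = relabel_metabolic_terms(rownames(tab)), tab)
  rownames(tab) <- NULL
  structure(list(winner = object$winner, table = tab,
                 r.squared = s$r.squared, fstatistic = s$fstatistic,
                 n = object$n, ranking = object$ranking),
            class = "summary.metabolic_fit")
}

relabel_metabolic_terms <- function(nm) {
  map <- c("(Intercept)" = "ln_I0", "x" = "E_I", "I(x^2)" = "E_I2",
           "ln_mass" = "d_I", "x:ln_mass" = "E_I:d_I")
  out <- map[nm]
  ifelse(is.na(out), nm, out)
}

#' @export
print.summary.metabolic_fit <- function(x, ...) {
  cat("Best metabolic-rate model by BIC:", x$winner, "\n")
  cat(sprintf("n = %d, r2 = %.3f\n\n", x$n, x$r.squared))
  print(format(x$table, digits = 4), row.names = FALSE)
  cat("\nBIC ranking:\n")
  print(x$ranking, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
coef.metabolic_fit <- function(object, ...) {
  cf <- coef(object$fit)
  setNames(cf, relabel_metabolic_terms(names(cf)))
}

#' Predict metabolic rate in J/h
#'
#' Exponentiates the fitted linear predictor at the given temperature (and
#' dry mass, when the selected model includes mass terms).
#'
#' @param object A `metabolic_fit`.
#' @param temperature_C Temperature, degrees Celsius.
#' @param dry_mass_mg Dry body mass, mg (required iff the winning model
#'   includes mass).
#' @param model Candidate name to predict from (default: the BIC winner).
#' @param ... Unused.
#' @return Metabolic rate, J/h.
#' @export
predict.metabolic_fit <- function(object, temperature_C, dry_mass_mg = NULL,
                                  model = object$winner, ...) {
  fit <- object$candidates[[model]]
  if (is.null(fit)) stop("unknown candidate model: ", model)
  k <- object$constants$boltzmann_eV_K; T0 <- object$constants$T0_K
  T_K <- celsius_to_kelvin(temperature_C)
  nd <- data.frame(x = (T_K - T0) / (k * T_K * T0))
  if ("ln_mass" %in% all.vars(formula(fit))) {
    if (is.null(dry_mass_mg))
      stop("this model requires dry_mass_mg")
    nd$ln_mass <- log(rep_len(dry_mass_mg, nrow(nd)))
  }
  exp(as.numeric(predict(fit, newdata = nd)))
}

#' Thermal optimum of a quadratic metabolic-rate model
#'
#' For a fitted (or directly supplied) quadratic Arrhenius model
#' `ln I = ln I0 + E x + q x^2` with `q < 0`, the predicted rate peaks at
#' `x* = -E/(2q)`, i.e. at absolute temperature `T* = T0/(1 - x* k T0)`.
#' Returns `NA` when there is no quadratic term or the curvature is
#' non-negative (monotone response).
#'
#' @param object A `metabolic_fit`, or (default method) the linear
#'   temperature coefficient `E` in eV.
#' @param ... Passed to methods.
#' @return Optimal temperature in Kelvin (`NA_real_` if none), with the
#'   Celsius value as attribute `"celsius"`.
#' @examples
#' thermal_optimum(1.072, quad = -0.339)  # ~294.5 K, ~21.4 C
#' @export
thermal_optimum <- function(object, ...) UseMethod("thermal_optimum")

#' @rdname thermal_optimum
#' @param quad Quadratic coefficient on the Arrhenius abscissa.
#' @param constants An [fr_constants()] object.
#' @export
thermal_optimum.default <- function(object, quad,
                                    constants = fr_constants(), ...) {
  E <- object
  if (!is.finite(quad) || quad >= 0) return(NA_real_)
  x_star <- -E / (2 * quad)
  k <- constants$boltzmann_eV_K; T0 <- constants$T0_K
  T_star <- T0 / (1 - x_star * k * T0)
  structure(T_star, celsius = kelvin_to_celsius(T_star))
}

#' @rdname thermal_optimum
#' @param model Candidate name (default: the BIC winner).
#' @export
thermal_optimum.metabolic_fit <- function(object, model = object$winner,
                                          ...) {
  cf <- coef(object$candidates[[model]])
  if (!"I(x^2)" %in% names(cf)) return(NA_real_)
  thermal_optimum.default(unname(cf["x"]), unname(cf["I(x^2)"]),
                          object$constants)
}
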