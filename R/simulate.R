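# Synthetic-data generators: feeding trials with binomial prey survival
# driven by the depletion ODE, respirometry records with multiplicative
# lognormal noise around the log-linear mass x temperature model, and a
# stream-survey gradient with prey abundance increasing with temperature.
# All generators are pure functions of (configuration, seed).

#' Feeding-trial experimental design
#'
#' Describes a multi-dataset prey-depletion experiment: per-dataset trial
#' temperatures, the ladder of initial prey densities, per-dataset replicate
#' counts, whether predator-free controls are included, trial duration, and
#' the rate at which arenas are invalidated (predator death/pupation) and
#' flagged excluded.
#'
#' @param datasets Named list of temperature vectors (degrees C), one per
#'   dataset.
#' @param densities Strictly increasing initial prey counts.
#' @param replicates Named integer vector of predator-arena replicates per
#'   dataset x temperature x density cell.
#' @param include_controls Add a predator-free control for every cell.
#' @param control_replicates Control replicates per cell (defaults to the
#'   predator replicates).
#' @param duration_days Trial duration.
#' @param dropout Bernoulli probability that a predator arena is flagged
#'   excluded (predator died or pupated).
#' @return An object of class `fr_design`.
#' @export
fr_design <- function(datasets, densities = c(2, 4, 6, 10, 16, 24, 40, 60),
                      replicates = 2, include_controls = TRUE,
                      control_replicates = NULL, duration_days = 1,
                      dropout = 0.05) {
  stopifnot(is.list(datasets), length(names(datasets)) == length(datasets))
  if (any(diff(densities) <= 0))
    stop("prey densities must be strictly increasing")
  if (length(replicates) == 1)
    replicates <- setNames(rep(replicates, length(datasets)),
                           names(datasets))
  stopifnot(all(names(datasets) %in% names(replicates)),
            all(replicates >= 1))
  if (is.null(control_replicates)) control_replicates <- replicates
  structure(list(datasets = datasets, densities = densities,
                 replicates = replicates,
                 include_controls = include_controls,
                 control_replicates = control_replicates,
                 duration_days = duration_days, dropout = dropout),
            class = "fr_design")
}

#' Generator truths and designs for the two Hengill predators
#'
#' Convenience constructors carrying the published study conditions for the
#' two stream predators: *Limnophora riparia* (three datasets: Lab 2013,
#' Lab 2015 and Field 2015) and *Potamophylax cingulatus* (two datasets).
#' The functional-response truths are the best-fitting type II models with
#' separate attack-coefficient intercepts per dataset, a shared activation
#' energy of attack, a shared temperature-independent handling time; natural
#' mortality is absent in Lab 2013 and a modest temperature-independent
#' rate (0.1/day) in the 2015 datasets.  Replicate counts reproduce the
#' studies' arena totals (about 250 and 270 predator arenas respectively).
#'
#' @return `fr_design_*`: an [fr_design()]; `fr_truth_*`: a list with
#'   elements `fr` (per-dataset [fr_params()]) and `mort` (per-dataset
#'   [mortality_params()]); `metabolic_truth_*`: coefficient list
#'   (`ln_I0`, `d_I`, `E_I`, `quad`) on the Arrhenius-abscissa scale.
#' @export
fr_design_limnophora <- function() {
  fr_design(datasets = list(Lab2013 = c(5, 10, 15, 18),
                            Lab2015 = c(4, 6, 10, 18),
                            Field2015 = c(5, 8, 11, 14, 17)),
            replicates = c(Lab2013 = 3, Lab2015 = 2, Field2015 = 2))
}

#' @rdname fr_design_limnophora
#' @export
fr_design_potamophylax <- function() {
  fr_design(datasets = list(Lab2015 = c(4, 6, 10, 18),
                            Field2015 = c(5, 8, 11, 14, 17)),
            replicates = c(Lab2015 = 6, Field2015 = 2))
}

#' @rdname fr_design_limnophora
#' @export
fr_truth_limnophora <- function() {
  Ec <- 0.704; b0 <- 4.033
  list(fr = list(
    Lab2013 = fr_params("II", c0 = 0.241, E_c = Ec, b0 = b0),
    Lab2015 = fr_params("II", c0 = 0.802, E_c = Ec, b0 = b0),
    Field2015 = fr_params("II", c0 = 1.889, E_c = Ec, b0 = b0)),
    mort = list(Lab2013 = mortality_params(0),
                Lab2015 = mortality_params(0.1),
                Field2015 = mortality_params(0.1)))
}

#' @rdname fr_design_limnophora
#' @export
fr_truth_potamophylax <- function() {
  Ec <- 0.229; b0 <- 0.644
  list(fr = list(
    Lab2015 = fr_params("II", c0 = 1.529, E_c = Ec, b0 = b0),
    Field2015 = fr_params("II", c0 = 5.515, E_c = Ec, b0 = b0)),
    mort = list(Lab2015 = mortality_params(0.1),
                Field2015 = mortality_params(0.1)))
}

#' @rdname fr_design_limnophora
#' @export
metabolic_truth_limnophora <- function() {
  list(ln_I0 = -4.171, d_I = 0.525, E_I = 0.687, quad = 0)
}

#' @rdname fr_design_limnophora
#' @export
metabolic_truth_potamophylax <- function() {
  list(ln_I0 = -1.056, d_I = 0, E_I = 1.072, quad = -0.339)
}

#' Simulate a prey-depletion feeding experiment
#'
#' For every arena in the design, the expected eaten fraction comes from
#' integrating the depletion ODE under the truth's Arrhenius-scaled
#' functional-response and mortality parameters; survivors are then drawn as
#' `n0 - Binomial(n0, p_eaten)`.  Predator-free controls deplete under
#' mortality alone.  A small Bernoulli fraction of predator arenas is
#' flagged excluded, mimicking predator death/pupation.
#'
#' @param design An [fr_design()].
#' @param truth A truth list with `fr` and `mort` per-dataset components
#'   (see [fr_truth_limnophora()]).
#' @param seed RNG seed.
#' @param constants An [fr_constants()] object.
#' @return A feeding-trial data.frame (schema of [read_trials()]).
#' @export
simulate_fr_experiment <- function(design, truth, seed = 1,
                                   constants = fr_constants()) {
  stopifnot(inherits(design, "fr_design"))
  rows <- list()
  for (ds in names(design$datasets)) {
    prm <- truth$fr[[ds]]
    if (is.null(prm)) stop("truth has no fr params for dataset ", ds)
    mt <- truth$mort[[ds]]
    if (is.null(mt)) mt <- mortality_params()
    grid <- expand.grid(temperature_C = design$datasets[[ds]],
                        n0 = design$densities)
    T_K <- celsius_to_kelvin(grid$temperature_C)
    surv_pred <- integrate_depletion(grid$n0, prm, mt, T_K,
                                     design$duration_days,
                                     predator_present = TRUE,
                                     constants = constants)
    grid$p_pred <- (grid$n0 - surv_pred) / grid$n0
    surv_ctrl <- integrate_depletion(grid$n0, NULL, mt, T_K,
                                     design$duration_days,
                                     predator_present = FALSE,
                                     constants = constants)
    grid$p_ctrl <- (grid$n0 - surv_ctrl) / grid$n0
    grid$dataset_id <- ds
    grid$reps <- design$replicates[[ds]]
    grid$ctrl_reps <- design$control_replicates[[ds]]
    rows[[ds]] <- grid
  }
  grid <- do.call(rbind, rows)

  with_preserved_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      eaten <- rbinom(g$reps, g$n0, g$p_pred)
      out[[length(out) + 1L]] <- data.frame(
        dataset_id = g$dataset_id, predator_present = TRUE,
        temperature_C = g$temperature_C, n0 = g$n0,
        n_survivors = g$n0 - eaten,
        duration_days = design$duration_days,
        excluded = rbinom(g$reps, 1, design$dropout))
      if (design$include_controls) {
        died <- rbinom(g$ctrl_reps, g$n0, g$p_ctrl)
        out[[length(out) + 1L]] <- data.frame(
          dataset_id = g$dataset_id, predator_present = FALSE,
          temperature_C = g$temperature_C, n0 = g$n0,
          n_survivors = g$n0 - died,
          duration_days = design$duration_days, excluded = 0L)
      }
    }
    trials <- do.call(rbind, out)
    rownames(trials) <- NULL
    attr(trials, "truth") <- truth
    attr(trials, "seed") <- seed
    trials
  })
}

#' Simulate respirometry records
#'
#' Draws dry masses log-uniform over `mass_range_mg`, evaluates the
#' log-linear metabolic model `ln I = ln_I0 + d_I ln M + E_I x + quad x^2`
#' on the Arrhenius abscissa `x`, adds Normal(0, `sigma_ln`) noise on the
#' log scale, and back-converts the J/h rate to umol O2/h so the records
#' enter the pipeline through the same unit conversion as real data.
#'
#' @param n_per_temp Individuals per temperature (recycled).
#' @param temps_C Measurement temperatures, degrees C.
#' @param mass_range_mg Dry-mass range for the log-uniform draw.
#' @param truth Coefficient list (see [metabolic_truth_limnophora()]).
#' @param sigma_ln Lognormal noise SD on the log scale.
#' @param seed RNG seed.
#' @param constants An [fr_constants()] object.
#' @return Data.frame with `species`-free respirometry schema columns:
#'   `temperature_C`, `dry_mass_mg`, `o2_umol_per_h`.
#' @export
simulate_respirometry <- function(n_per_temp = c(10, 9, 9, 9, 9),
                                  temps_C = c(5, 10, 15, 20, 25),
                                  mass_range_mg = c(0.5, 5),
                                  truth = metabolic_truth_limnophora(),
                                  sigma_ln = 0.4, seed = 1,
                                  constants = fr_constants()) {
  stopifnot(all(n_per_temp >= 1))
  n_per_temp <- rep_len(n_per_temp, length(temps_C))
  temperature_C <- rep(temps_C, times = n_per_temp)
  n <- length(temperature_C)
  k <- constants$boltzmann_eV_K; T0 <- constants$T0_K
  T_K <- celsius_to_kelvin(temperature_C)
  x <- (T_K - T0) / (k * T_K * T0)
  with_preserved_seed(seed, {
    mass <- exp(runif(n, log(mass_range_mg[1]), log(mass_range_mg[2])))
    ln_rate <- truth$ln_I0 + truth$d_I * log(mass) + truth$E_I * x +
      truth$quad * x^2 + rnorm(n, 0, sigma_ln)
    data.frame(temperature_C = temperature_C,
               dry_mass_mg = mass,
               o2_umol_per_h = exp(ln_rate) / o2_to_joules(1))
  })
}

#' Simulate a stream-survey temperature gradient
#'
#' Stream mean temperatures are spread evenly over the range; Simuliidae
#' abundance follows a saturating increase with temperature (logistic in
#' temperature, scaled to a cap near the observed maximum) with
#' multiplicative lognormal noise, never exceeding the cap; predator
#' abundance follows either an increasing or a hump-shaped temperature
#' response.
#'
#' @param n_streams Number of streams (>= 2).
#' @param temp_range_C Survey temperature range, degrees C.
#' @param prey_cap Maximum Simuliidae abundance, individuals/m^2.
#' @param prey_midpoint_C,prey_slope Logistic midpoint/slope of the prey
#'   response.
#' @param predator_shape `"increasing"` or `"hump"`.
#' @param predator_max Predator abundance scale, individuals/m^2.
#' @param hump_peak_C,hump_width_C Peak and width of the hump response.
#' @param noise_sd_ln Lognormal noise SD (0 gives the exact response
#'   curves).
#' @param seed RNG seed.
#' @return Data.frame with `stream_id`, `mean_temp_C`,
#'   `simuliidae_abundance`, `predator_abundance`.
#' @export
simulate_streams <- function(n_streams = 14, temp_range_C = c(4, 25),
                             prey_cap = 8500, prey_midpoint_C = 12,
                             prey_slope = 0.35,
                             predator_shape = c("increasing", "hump"),
                             predator_max = 120, hump_peak_C = 10,
                             hump_width_C = 4, noise_sd_ln = 0.3,
                             seed = 1) {
  stopifnot(n_streams >= 2)
  predator_shape <- match.arg(predator_shape)
  temp <- seq(temp_range_C[1], temp_range_C[2], length.out = n_streams)
  prey_mu <- prey_cap * plogis(prey_slope * (temp - prey_midpoint_C))
  pred_mu <- switch(predator_shape,
    increasing = predator_max * plogis(0.4 * (temp - 12)),
    hump = predator_max * exp(-(temp - hump_peak_C)^2 / (2 * hump_width_C^2)))
  with_preserved_seed(seed, {
    prey <- pmin(prey_cap, prey_mu * exp(rnorm(n_streams, 0, noise_sd_ln)))
    pred <- pred_mu * exp(rnorm(n_streams, 0, noise_sd_ln))
    data.frame(stream_id = sprintf("S%02d", seq_len(n_streams)),
               mean_temp_C = temp,
               simuliidae_abundance = prey,
               predator_abundance = pred)
  })
}
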