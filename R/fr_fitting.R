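# Maximum-likelihood fitting of temperature-dependent functional responses
# to prey-depletion trials, with BIC selection over parameter-sharing
# structures across experimental datasets.

FR_STRUCTURES <- c("shared", "shared_E", "separate",
                   "separate_sharedE", "separate_E")

# ---------------------------------------------------------------------------
# Trial validation

validate_trials <- function(trials, require_predator = FALSE) {
  req <- c("dataset_id", "predator_present", "temperature_C",
           "n0", "n_survivors")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("trials are missing column(s): ", paste(miss, collapse = ", "))
  if (!"duration_days" %in% names(trials)) trials$duration_days <- 1
  if ("excluded" %in% names(trials)) {
    n_ex <- sum(trials$excluded %in% c(1, TRUE))
    if (n_ex > 0)
      message("dropping ", n_ex, " excluded arena(s)")
    trials <- trials[!(trials$excluded %in% c(1, TRUE)), , drop = FALSE]
  }
  bad <- which(trials$n0 < 0 | trials$n_survivors < 0)
  if (length(bad))
    stop("negative counts in trial row(s): ", paste(bad, collapse = ", "))
  bad <- which(trials$n_survivors > trials$n0)
  if (length(bad))
    stop("survivors exceed initial prey in trial row(s): ",
         paste(bad, collapse = ", "))
  bad <- which(trials$duration_days <= 0)
  if (length(bad))
    stop("non-positive duration in trial row(s): ", paste(bad, collapse = ", "))
  trials$predator_present <- as.logical(trials$predator_present)
  trials$dataset_id <- as.character(trials$dataset_id)
  trials
}

# Aggregate predator trials into likelihood cells.  Trials sharing
# (dataset, temperature, N0, duration) have identical eaten-probability, so
# their binomial contributions collapse onto summed eaten/survivor counts;
# the combinatorial lchoose term is a data constant added once.
build_cells <- function(trials, dataset_levels) {
  key <- interaction(trials$dataset_id, trials$temperature_C, trials$n0,
                     trials$duration_days, drop = TRUE)
  idx <- !duplicated(key)
  cells <- data.frame(
    ds = match(trials$dataset_id[idx], dataset_levels),
    T_K = celsius_to_kelvin(trials$temperature_C[idx]),
    N0 = trials$n0[idx],
    duration = trials$duration_days[idx]
  )
  g <- match(key, key[idx])
  eaten <- trials$n0 - trials$n_survivors
  cells$eaten <- as.numeric(tapply(eaten, g, sum))
  cells$surv <- as.numeric(tapply(trials$n_survivors, g, sum))
  attr(cells, "lchoose_sum") <- sum(lchoose(trials$n0, eaten))
  attr(cells, "n_obs") <- nrow(trials)
  cells
}

# ---------------------------------------------------------------------------
# Model zoo

#' Enumerate the functional-response model zoo
#'
#' Builds every candidate model for one predator: functional-response types
#' II and III crossed with all five parameter-sharing structures for the
#' attack coefficient and, independently, for the handling time (5 x 5
#' each), plus type I (no handling time) with the five attack-coefficient
#' structures - 55 candidates in total, for any number of datasets.
#'
#' The five sharing structures for a parameter family are: one intercept
#' with no temperature dependence (`shared`); one intercept with one
#' activation energy (`shared_E`); separate per-dataset intercepts with no
#' temperature dependence (`separate`); separate intercepts with a shared
#' activation energy (`separate_sharedE`); and separate intercepts with
#' separate activation energies (`separate_E`).  Separate activation
#' energies require separate intercepts, which is what keeps the count at
#' 55 regardless of how many datasets are combined.
#'
#' @param n_datasets Number of experimental datasets being combined (>= 1).
#' @return A data.frame of class `fr_model_zoo` with columns `type`,
#'   `c_structure`, `b_structure` (NA for type I) and `k`, the free-parameter
#'   count given `n_datasets`.
#' @examples
#' nrow(fr_model_zoo(3))  # 55
#' @export
fr_model_zoo <- function(n_datasets) {
  stopifnot(n_datasets >= 1)
  two <- expand.grid(c_structure = FR_STRUCTURES,
                     b_structure = FR_STRUCTURES,
                     type = c("II", "III"),
                     stringsAsFactors = FALSE)
  one <- data.frame(c_structure = FR_STRUCTURES, b_structure = NA_character_,
                    type = "I", stringsAsFactors = FALSE)
  zoo <- rbind(one, two)[, c("type", "c_structure", "b_structure")]
  zoo$k <- structure_npar(zoo$c_structure, n_datasets) +
    ifelse(is.na(zoo$b_structure), 0L,
           structure_npar(zoo$b_structure, n_datasets))
  class(zoo) <- c("fr_model_zoo", "data.frame")
  attr(zoo, "n_datasets") <- n_datasets
  zoo
}

structure_npar <- function(s, D) {
  unname(vapply(s, function(si) {
    if (is.na(si)) return(0L)
    switch(si,
           shared = 1L, shared_E = 2L, separate = as.integer(D),
           separate_sharedE = as.integer(D + 1L),
           separate_E = as.integer(2L * D),
           stop("unknown sharing structure: ", si))
  }, integer(1)))
}

# Parameter-vector layout for one family (intercepts on the log scale,
# activation energies linear).  Returns a data.frame describing each free
# parameter, used for packing/unpacking and labelling.
family_layout <- function(structure, family, datasets) {
  int_name <- paste0("log_", family, "0")
  E_name <- paste0("E_", family)
  switch(structure,
    shared = data.frame(name = int_name, kind = "log_intercept",
                        family = family, dataset = NA),
    shared_E = data.frame(name = c(int_name, E_name),
                          kind = c("log_intercept", "energy"),
                          family = family, dataset = NA),
    separate = data.frame(name = paste0(int_name, "[", datasets, "]"),
                          kind = "log_intercept", family = family,
                          dataset = datasets),
    separate_sharedE = data.frame(
      name = c(paste0(int_name, "[", datasets, "]"), E_name),
      kind = c(rep("log_intercept", length(datasets)), "energy"),
      family = family, dataset = c(datasets, NA)),
    separate_E = data.frame(
      name = c(paste0(int_name, "[", datasets, "]"),
               paste0(E_name, "[", datasets, "]")),
      kind = rep(c("log_intercept", "energy"), each = length(datasets)),
      family = family, dataset = rep(datasets, 2)),
    stop("unknown sharing structure: ", structure))
}

spec_layout <- function(type, c_structure, b_structure, datasets) {
  lay <- family_layout(c_structure, "c", datasets)
  if (type != "I")
    lay <- rbind(lay, family_layout(b_structure, "b", datasets))
  lay
}

# Expand a packed parameter vector into per-dataset (log c0, E_c, log b0,
# E_b) vectors according to the layout.
unpack_params <- function(par, layout, datasets) {
  D <- length(datasets)
  out <- list(log_c0 = numeric(D), E_c = numeric(D),
              log_b0 = rep(-Inf, D), E_b = numeric(D))
  for (i in seq_len(nrow(layout))) {
    fam <- layout$family[i]
    slot <- if (layout$kind[i] == "log_intercept")
      paste0("log_", fam, "0") else paste0("E_", fam)
    if (is.na(layout$dataset[i])) out[[slot]][] <- par[i]
    else out[[slot]][match(layout$dataset[i], datasets)] <- par[i]
  }
  out
}

# ---------------------------------------------------------------------------
# Likelihood

#' Negative log-likelihood of feeding trials under a depletion model
#'
#' Binomial likelihood on eaten counts: for each trial the expected eaten
#' fraction is obtained by integrating the depletion ODE (with the dataset's
#' functional-response and mortality parameters, Arrhenius-scaled to the
#' trial temperature), clipped away from 0 and 1, and the eaten count
#' `n0 - n_survivors` is scored against `Binomial(n0, p_eaten)`.
#'
#' @param trials Data.frame of feeding trials (see [read_trials()] for the
#'   schema); only rows with `predator_present == TRUE` contribute feeding,
#'   control rows are scored under mortality alone.
#' @param fr Named list of [fr_params()], one per dataset.
#' @param mort Named list of [mortality_params()], one per dataset.
#' @param constants An [fr_constants()] object.
#' @param eps Probability clip bound.
#' @param rtol,atol Solver tolerances.
#' @return The summed negative log-likelihood (scalar).
#' @export
fr_neg_log_likelihood <- function(trials, fr, mort,
                                  constants = fr_constants(),
                                  eps = 1e-12, rtol = 1e-8, atol = 1e-10) {
  trials <- validate_trials(trials)
  if (any(trials$n0 < 1)) stop("all trials must have n0 >= 1")
  k <- constants$boltzmann_eV_K; T0 <- constants$T0_K
  T_K <- celsius_to_kelvin(trials$temperature_C)
  dT <- (T_K - T0) / (k * T_K * T0)
  get_p <- function(ds) {
    if (!ds %in% names(mort)) stop("no mortality parameters for dataset ", ds)
    rows <- trials$dataset_id == ds
    m <- mort[[ds]]
    mT <- m$m0 * exp(m$E_m * dT[rows])
    pred <- trials$predator_present[rows]
    if (any(pred) && !ds %in% names(fr))
      stop("no functional-response parameters for dataset ", ds)
    if (any(pred)) {
      p <- fr[[ds]]
      cT <- ifelse(pred, p$c0 * exp(p$E_c * dT[rows]), 0)
      bT <- ifelse(pred, p$b0 * exp(p$E_b * dT[rows]), 0)
      h <- p$hill_h
    } else {
      cT <- bT <- numeric(sum(rows)); h <- 1
    }
    Nend <- depletion_endpoint_raw(trials$n0[rows], cT, bT, h, mT,
                                   trials$duration_days[rows], rtol, atol)
    list(rows = which(rows),
         p = pmin(pmax((trials$n0[rows] - Nend) / trials$n0[rows], eps),
                  1 - eps))
  }
  nll <- 0
  for (ds in unique(trials$dataset_id)) {
    res <- get_p(ds)
    eaten <- trials$n0[res$rows] - trials$n_survivors[res$rows]
    ll <- lchoose(trials$n0[res$rows], eaten) + eaten * log(res$p) +
      trials$n_survivors[res$rows] * log1p(-res$p)
    if (any(!is.finite(ll))) stop("non-finite likelihood contribution")
    nll <- nll - sum(ll)
  }
  nll
}

# ---------------------------------------------------------------------------
# Mortality stage

#' Fit natural prey mortality from predator-free control arenas
#'
#' For each dataset, fits three nested candidates for the background
#' mortality rate by binomial maximum likelihood on control survivors under
#' exponential prey decline: no mortality (`m0 = 0`), a
#' temperature-independent rate, and an Arrhenius temperature-dependent rate.
#' The candidate with the lowest BIC is selected per dataset; its point
#' estimates are frozen into all downstream functional-response fits.
#' Datasets whose controls show no deaths at all select `m0 = 0` directly,
#' without an optimizer call.
#'
#' @param trials Data.frame of feeding trials; only rows with
#'   `predator_present == FALSE` are used.
#' @param constants An [fr_constants()] object.
#' @param eps Probability clip bound.
#' @return An object of class `mortality_fit`: a per-dataset selection table
#'   plus the full candidate set.
#' @export
fit_mortality <- function(trials, constants = fr_constants(), eps = 1e-12) {
  trials <- validate_trials(trials)
  controls <- trials[!trials$predator_present, , drop = FALSE]
  if (nrow(controls) == 0) stop("no predator-free control arenas found")
  k <- constants$boltzmann_eV_K; T0 <- constants$T0_K

  fit_one <- function(dat) {
    T_K <- celsius_to_kelvin(dat$temperature_C)
    dT <- (T_K - T0) / (k * T_K * T0)
    eaten <- dat$n0 - dat$n_survivors
    n <- nrow(dat)
    ll_at <- function(m0, E_m) {
      p_die <- 1 - exp(-m0 * exp(E_m * dT) * dat$duration_days)
      p_die <- pmin(pmax(p_die, eps), 1 - eps)
      sum(lchoose(dat$n0, eaten) + eaten * log(p_die) +
            dat$n_survivors * log1p(-p_die))
    }
    cand <- list()
    ll0 <- ll_at(0, 0)
    cand$none <- list(m0 = 0, E_m = 0, se = c(NA, NA), logLik = ll0, k = 0)
    if (sum(eaten) > 0) {
      o1 <- optimize(function(lm0) -ll_at(exp(lm0), 0),
                     interval = c(log(1e-8), log(50)))
      h1 <- optim(o1$minimum, function(lm0) -ll_at(exp(lm0), 0),
                  method = "BFGS", hessian = TRUE,
                  control = list(maxit = 200))
      se1 <- se_from_hessian(h1$hessian)
      cand$constant <- list(m0 = exp(h1$par), E_m = 0,
                            se = c(se1, NA), logLik = -h1$value, k = 1)
      o2 <- optim(c(h1$par, 0),
                  function(p) -ll_at(exp(p[1]), p[2]),
                  method = "L-BFGS-B",
                  lower = c(log(1e-8), -5), upper = c(log(50), 5),
                  hessian = TRUE, control = list(maxit = 300))
      se2 <- se_from_hessian(o2$hessian)
      cand$arrhenius <- list(m0 = exp(o2$par[1]), E_m = o2$par[2],
                             se = se2, logLik = -o2$value, k = 2)
    }
    tab <- do.call(rbind, lapply(names(cand), function(nm) {
      ci <- cand[[nm]]
      data.frame(model = nm, m0 = ci$m0, E_m = ci$E_m,
                 logLik = ci$logLik, k = ci$k, n = n,
                 BIC = ci$k * log(n) - 2 * ci$logLik)
    }))
    tab$selected <- seq_len(nrow(tab)) == which.min(tab$BIC)
    list(table = tab, candidates = cand)
  }

  per_ds <- lapply(split(controls, controls$dataset_id), fit_one)
  sel <- do.call(rbind, lapply(names(per_ds), function(ds) {
    tab <- per_ds[[ds]]$table
    row <- tab[tab$selected, , drop = FALSE]
    cbind(data.frame(dataset_id = ds), row[, c("model", "m0", "E_m",
                                               "logLik", "k", "n", "BIC")])
  }))
  rownames(sel) <- NULL
  structure(list(selected = sel, detail = per_ds, constants = constants),
            class = "mortality_fit")
}

#' @export
print.mortality_fit <- function(x, ...) {
  cat("Natural-mortality fits (BIC-selected per dataset):\n")
  print(x$selected, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Extract mortality parameters per dataset
#'
#' @param fit A `mortality_fit` object.
#' @return Named list of [mortality_params()], one per dataset.
#' @export
mortality_params_list <- function(fit) {
  stopifnot(inherits(fit, "mortality_fit"))
  setNames(lapply(seq_len(nrow(fit$selected)), function(i)
    mortality_params(fit$selected$m0[i], fit$selected$E_m[i])),
    fit$selected$dataset_id)
}

se_from_hessian <- function(H) {
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) return(rep(NA_real_, nrow(H)))
  d <- diag(as.matrix(V))
  out <- rep(NA_real_, length(d))
  out[is.finite(d) & d > 0] <- sqrt(d[is.finite(d) & d > 0])
  out
}

# ---------------------------------------------------------------------------
# Functional-response stage

#' Optimizer settings for functional-response fitting
#'
#' @param n_starts Number of multi-start optimizer runs.
#' @param seed RNG seed for drawing starting values (fixed so fits are
#'   reproducible); starts draw `c0`, `b0` log-uniform over `start_range`
#'   and activation energies uniform over `E_start_range`.
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @param start_range Range for log-uniform intercept starts.
#' @param E_start_range Range for uniform activation-energy starts.
#' @param lower_log,upper_log Box bounds for log intercepts.
#' @param E_bounds Box bounds for activation energies.
#' @param rtol,atol Depletion-solver tolerances.
#' @param eps Eaten-probability clip bound.
#' @return A list of class `fr_control`.
#' @export
fr_control <- function(n_starts = 10, seed = 1, maxit = 300,
                       start_range = c(1e-3, 1e2),
                       E_start_range = c(-1, 2),
                       lower_log = log(1e-6), upper_log = log(1e4),
                       E_bounds = c(-1, 2),
                       rtol = 1e-8, atol = 1e-10, eps = 1e-12) {
  structure(as.list(environment()), class = "fr_control")
}

make_cell_nll <- function(cells, type, layout, datasets, mort_list,
                          constants, control) {
  k <- constants$boltzmann_eV_K; T0 <- constants$T0_K
  dT <- (cells$T_K - T0) / (k * cells$T_K * T0)
  m0 <- vapply(mort_list[datasets], `[[`, numeric(1), "m0")
  E_m <- vapply(mort_list[datasets], `[[`, numeric(1), "E_m")
  mT <- m0[cells$ds] * exp(E_m[cells$ds] * dT)
  h <- if (type == "III") 2 else 1
  lch <- attr(cells, "lchoose_sum")
  eps <- control$eps
  function(par) {
    u <- unpack_params(par, layout, datasets)
    cT <- exp(u$log_c0[cells$ds] + u$E_c[cells$ds] * dT)
    bT <- if (type == "I") numeric(nrow(cells))
          else exp(u$log_b0[cells$ds] + u$E_b[cells$ds] * dT)
    Nend <- tryCatch(
      depletion_endpoint_raw(cells$N0, cT, bT, h, mT, cells$duration,
                             control$rtol, control$atol),
      error = function(e) NULL)
    if (is.null(Nend)) return(1e10)
    p <- pmin(pmax((cells$N0 - Nend) / cells$N0, eps), 1 - eps)
    nll <- -(lch + sum(cells$eaten * log(p) + cells$surv * log1p(-p)))
    if (!is.finite(nll)) 1e10 else nll
  }
}

#' Fit one temperature-dependent functional-response model
#'
#' Maximizes the binomial depletion likelihood over the free parameters of a
#' single candidate model: a functional-response type (I/II/III) together
#' with sharing structures for the attack coefficient and handling time
#' across datasets.  Intercepts (`c0`, `b0`) are fitted on the natural-log
#' scale, activation energies on the linear scale, by bounded quasi-Newton
#' (L-BFGS-B) from multiple random starts.  Standard errors come from the
#' inverse Hessian at the optimum; Wald z-statistics are on the fitting
#' scale, so for intercepts `z = ln(estimate)/SE`.
#'
#' Mortality point estimates (from [fit_mortality()]) are frozen into the
#' depletion ODE, never re-estimated jointly.
#'
#' @param trials Feeding-trial data.frame; predator rows form the
#'   likelihood, control rows are used only if `mortality` is `NULL`.
#' @param type `"I"`, `"II"` or `"III"`.
#' @param c_structure,b_structure Sharing structures (see [fr_model_zoo()]);
#'   `b_structure` is ignored for type I.
#' @param mortality A `mortality_fit`, a named list of [mortality_params()],
#'   or `NULL` (fit from the controls in `trials`, or assume none).
#' @param constants An [fr_constants()] object.
#' @param control An [fr_control()] object.
#' @return An object of class `fr_fit`.
#' @examples
#' \donttest{
#' tr <- simulate_fr_experiment(fr_design_limnophora(),
#'                              fr_truth_limnophora(), seed = 1)
#' fit <- fit_fr(tr, type = "II", c_structure = "separate_sharedE",
#'               b_structure = "shared", control = fr_control(n_starts = 3))
#' summary(fit)
#' }
#' @export
fit_fr <- function(trials, type = c("II", "I", "III"),
                   c_structure = "separate_sharedE",
                   b_structure = "shared",
                   mortality = NULL,
                   constants = fr_constants(),
                   control = fr_control()) {
  type <- match.arg(type)
  stopifnot(c_structure %in% FR_STRUCTURES)
  if (type != "I") stopifnot(b_structure %in% FR_STRUCTURES)
  trials <- validate_trials(trials)
  pred <- trials[trials$predator_present, , drop = FALSE]
  if (nrow(pred) == 0) stop("no predator arenas in trials")
  if (any(pred$n0 < 1)) stop("all predator trials must have n0 >= 1")
  datasets <- sort(unique(pred$dataset_id))

  mort_list <- resolve_mortality(mortality, trials, datasets, constants)
  cells <- build_cells(pred, datasets)
  layout <- spec_layout(type, c_structure, b_structure, datasets)
  npar <- nrow(layout)
  nll <- make_cell_nll(cells, type, layout, datasets, mort_list,
                       constants, control)

  lower <- ifelse(layout$kind == "log_intercept", control$lower_log,
                  control$E_bounds[1])
  upper <- ifelse(layout$kind == "log_intercept", control$upper_log,
                  control$E_bounds[2])
  starts <- with_preserved_seed(control$seed, {
    t(replicate(control$n_starts, ifelse(
      layout$kind == "log_intercept",
      runif(npar, log(control$start_range[1]), log(control$start_range[2])),
      runif(npar, control$E_start_range[1], control$E_start_range[2]))))
  })
  if (npar == 1) starts <- matrix(starts, ncol = 1)

  best <- NULL
  n_conv <- 0L
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[s, ], nll, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = control$maxit)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || n_conv == 0)
    stop("functional-response fit failed to converge from any start")

  polish <- tryCatch(
    optim(best$par, nll, method = "L-BFGS-B", lower = lower, upper = upper,
          hessian = TRUE, control = list(maxit = control$maxit)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish
  H <- if (!is.null(polish)) polish$hessian else NULL
  se <- if (is.null(H)) rep(NA_real_, npar) else se_from_hessian(H)
  if (anyNA(se))
    warning("Hessian not positive-definite; some standard errors missing")

  est <- best$par
  natural <- ifelse(layout$kind == "log_intercept", exp(est), est)
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  n_obs <- attr(cells, "n_obs")
  ll <- -best$value
  out <- list(
    spec = list(type = type, c_structure = c_structure,
                b_structure = if (type == "I") NA_character_ else b_structure),
    datasets = datasets,
    layout = layout,
    coefficients = setNames(est, layout$name),
    natural = setNames(natural, layout$name),
    se = setNames(se, layout$name),
    z = setNames(z, layout$name),
    p.value = setNames(p, layout$name),
    logLik = ll, k = npar, n_obs = n_obs,
    BIC = npar * log(n_obs) - 2 * ll,
    convergence = list(n_starts = nrow(starts), n_converged = n_conv),
    mortality = mort_list,
    constants = constants,
    control = control,
    trials = trials
  )
  class(out) <- "fr_fit"
  out
}

resolve_mortality <- function(mortality, trials, datasets, constants) {
  if (is.null(mortality)) {
    if (any(!trials$predator_present)) {
      mf <- fit_mortality(trials, constants)
      mort_list <- mortality_params_list(mf)
    } else {
      mort_list <- setNames(replicate(length(datasets), mortality_params(),
                                      simplify = FALSE), datasets)
    }
  } else if (inherits(mortality, "mortality_fit")) {
    mort_list <- mortality_params_list(mortality)
  } else {
    mort_list <- mortality
  }
  miss <- setdiff(datasets, names(mort_list))
  for (ds in miss) mort_list[[ds]] <- mortality_params()
  mort_list
}

#' Fit the full model zoo and rank by BIC
#'
#' Fits every candidate in `specs` (by default the complete 55-model zoo for
#' the datasets present in `trials`) and ranks the successful fits by BIC.
#' Candidates that fail to converge are flagged and excluded from selection.
#'
#' @param trials Feeding-trial data.frame.
#' @param mortality As in [fit_fr()] (fitted once, shared by all candidates).
#' @param specs A [fr_model_zoo()] data.frame, or a subset of its rows.
#' @param constants An [fr_constants()] object.
#' @param control An [fr_control()] object.
#' @param verbose Print per-candidate progress.
#' @return An object of class `fr_zoo`: the ranked BIC table, all fits and
#'   the winning fit.
#' @export
fit_fr_zoo <- function(trials, mortality = NULL, specs = NULL,
                       constants = fr_constants(), control = fr_control(),
                       verbose = FALSE) {
  trials <- validate_trials(trials)
  datasets <- sort(unique(trials$dataset_id[trials$predator_present]))
  if (is.null(specs)) specs <- fr_model_zoo(length(datasets))
  mort_list <- resolve_mortality(mortality, trials, datasets, constants)

  fits <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    if (verbose)
      message(sprintf("[%d/%d] type %s, c: %s, b: %s", i, nrow(specs),
                      specs$type[i], specs$c_structure[i],
                      specs$b_structure[i]))
    fits[[i]] <- tryCatch(
      fit_fr(trials, type = specs$type[i],
             c_structure = specs$c_structure[i],
             b_structure = if (is.na(specs$b_structure[i])) "shared"
                           else specs$b_structure[i],
             mortality = mort_list, constants = constants, control = control),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "fr_fit_failure"))
  }
  ranked <- select_by_bic(fits)
  structure(list(specs = specs, fits = fits, bic_table = ranked$table,
                 winner = ranked$winner, mortality = mort_list),
            class = "fr_zoo")
}

#' Rank functional-response fits by BIC
#'
#' Sorts fits ascending by BIC; ties are broken by fewer free parameters,
#' then by the lexicographic order of the model descriptor.  Failed fits are
#' excluded (and reported in the table with `NA` BIC).
#'
#' @param fits A list of `fr_fit` objects (failures allowed), or an `fr_zoo`.
#' @return A list with `table` (ranked data.frame) and `winner` (the best
#'   `fr_fit`).
#' @export
select_by_bic <- function(fits) {
  if (inherits(fits, "fr_zoo")) fits <- fits$fits
  if (inherits(fits, "fr_fit")) fits <- list(fits)
  if (length(fits) == 0) stop("no fits supplied")
  rows <- lapply(fits, function(f) {
    if (inherits(f, "fr_fit_failure") || !inherits(f, "fr_fit"))
      return(data.frame(type = NA, c_structure = NA, b_structure = NA,
                        k = NA, n = NA, logLik = NA, BIC = NA,
                        converged = FALSE))
    data.frame(type = f$spec$type, c_structure = f$spec$c_structure,
               b_structure = f$spec$b_structure, k = f$k, n = f$n_obs,
               logLik = f$logLik, BIC = f$BIC, converged = TRUE)
  })
  tab <- do.call(rbind, rows)
  tab$fit_index <- seq_len(nrow(tab))
  ok <- which(tab$converged)
  if (length(ok) == 0) stop("no successful fits to rank")
  label <- paste(tab$type, tab$c_structure, tab$b_structure)
  ord <- ok[order(tab$BIC[ok], tab$k[ok], label[ok])]
  tab <- tab[c(ord, setdiff(seq_len(nrow(tab)), ord)), , drop = FALSE]
  tab$rank <- c(seq_along(ord), rep(NA, nrow(tab) - length(ord)))
  rownames(tab) <- NULL
  list(table = tab, winner = fits[[tab$fit_index[1]]])
}

#' @export
print.fr_zoo <- function(x, n = 10, ...) {
  cat(sprintf("Functional-response model zoo: %d candidates, %d converged\n",
              nrow(x$specs), sum(x$bic_table$converged)))
  cat("Top models by BIC:\n")
  print(utils::head(x$bic_table[, c("rank", "type", "c_structure",
                                    "b_structure", "k", "logLik", "BIC")], n),
        row.names = FALSE, digits = 6)
  invisible(x)
}

# ---------------------------------------------------------------------------
# fr_fit methods

#' @export
print.fr_fit <- function(x, ...) {
  cat(sprintf("Type %s functional response (c: %s%s)\n", x$spec$type,
              x$spec$c_structure,
              if (is.na(x$spec$b_structure)) ""
              else paste0(", b: ", x$spec$b_structure)))
  cat(sprintf("  datasets: %s\n", paste(x$datasets, collapse = ", ")))
  cat(sprintf("  logLik = %.3f, k = %d, n = %d, BIC = %.3f\n",
              x$logLik, x$k, x$n_obs, x$BIC))
  cat("  estimates (natural scale):\n")
  print(round(x$natural, 4))
  invisible(x)
}

#' @export
summary.fr_fit <- function(object, ...) {
  lay <- object$layout
  tab <- data.frame(
    parameter = ifelse(lay$kind == "log_intercept",
                       paste0(lay$family, "0"), paste0("E_", lay$family)),
    dataset = ifelse(is.na(lay$dataset), "Combined", lay$dataset),
    estimate = unname(object$natural),
    se = unname(object$se),
    z = unname(object$z),
    p = unname(object$p.value)
  )
  structure(list(spec = object$spec, table = tab, logLik = object$logLik,
                 k = object$k, n = object$n_obs, BIC = object$BIC,
                 convergence = object$convergence),
            class = "summary.fr_fit")
}

#' @export
print.summary.fr_fit <- function(x, ...) {
  cat(sprintf("Type %s functional response (c: %s%s)\n", x$spec$type,
              x$spec$c_structure,
              if (is.na(x$spec$b_structure)) ""
              else paste0(", b: ", x$spec$b_structure)))
  cat("Estimates are on the natural scale; SE and z on the fitting scale\n")
  cat("(log for intercepts, so z = ln(estimate)/SE; linear for energies):\n\n")
  print(format(x$table, digits = 4), row.names = FALSE)
  cat(sprintf("\nlogLik = %.3f, k = %d, n = %d arenas, BIC = %.3f\n",
              x$logLik, x$k, x$n, x$BIC))
  cat(sprintf("%d/%d optimizer starts converged\n",
              x$convergence$n_converged, x$convergence$n_starts))
  invisible(x)
}

#' @export
coef.fr_fit <- function(object, scale = c("natural", "fitting"), ...) {
  scale <- match.arg(scale)
  if (scale == "natural") object$natural else object$coefficients
}

#' @export
logLik.fr_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n_obs,
            class = "logLik")
}

#' Per-dataset functional-response parameters from a fit
#'
#' @param fit An `fr_fit` object.
#' @param dataset Dataset label (one of `fit$datasets`).
#' @return An [fr_params()] object with that dataset's fitted parameters.
#' @export
fr_params_for <- function(fit, dataset) {
  stopifnot(inherits(fit, "fr_fit"))
  if (!dataset %in% fit$datasets)
    stop("dataset ", dataset, " not in fit (",
         paste(fit$datasets, collapse = ", "), ")")
  u <- unpack_params(fit$coefficients, fit$layout, fit$datasets)
  i <- match(dataset, fit$datasets)
  if (fit$spec$type == "I")
    fr_params("I", c0 = exp(u$log_c0[i]), E_c = u$E_c[i])
  else
    fr_params(fit$spec$type, c0 = exp(u$log_c0[i]), E_c = u$E_c[i],
              b0 = exp(u$log_b0[i]), E_b = u$E_b[i])
}

#' Predict from a fitted functional response
#'
#' @param object An `fr_fit` object.
#' @param newdata Data.frame with columns `dataset_id`, `temperature_C`,
#'   `n0` and optionally `duration_days` (default 1).
#' @param type `"survivors"` (expected prey remaining), `"p_eaten"`, or
#'   `"feeding_rate"` (instantaneous rate at density `n0`).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.fr_fit <- function(object, newdata,
                           type = c("survivors", "p_eaten", "feeding_rate"),
                           ...) {
  type <- match.arg(type)
  if (!"duration_days" %in% names(newdata)) newdata$duration_days <- 1
  T_K <- celsius_to_kelvin(newdata$temperature_C)
  out <- numeric(nrow(newdata))
  for (ds in unique(newdata$dataset_id)) {
    rows <- newdata$dataset_id == ds
    prm <- fr_params_for(object, ds)
    mt <- object$mortality[[ds]]
    if (is.null(mt)) mt <- mortality_params()
    if (type == "feeding_rate") {
      out[rows] <- feeding_rate(newdata$n0[rows], prm, T_K[rows],
                                object$constants)
    } else {
      surv <- integrate_depletion(newdata$n0[rows], prm, mt, T_K[rows],
                                  newdata$duration_days[rows],
                                  predator_present = TRUE,
                                  constants = object$constants,
                                  rtol = object$control$rtol,
                                  atol = object$control$atol)
      out[rows] <- if (type == "survivors") surv
                   else (newdata$n0[rows] - surv) / newdata$n0[rows]
    }
  }
  out
}

#' Simulate feeding trials from a fitted functional response
#'
#' Draws binomial survivor counts at the fitted eaten probabilities for the
#' trials the model was fitted to (or for `newdata`).
#'
#' @param object An `fr_fit` object.
#' @param nsim Number of simulated replicate tables.
#' @param seed RNG seed.
#' @param newdata Optional trial layout (as in [predict.fr_fit()]).
#' @param ... Unused.
#' @return A list of `nsim` data.frames matching the trial schema.
#' @export
simulate.fr_fit <- function(object, nsim = 1, seed = 1, newdata = NULL, ...) {
  layout <- if (is.null(newdata))
    object$trials[object$trials$predator_present, , drop = FALSE]
  else newdata
  p_eaten <- predict(object, layout, type = "p_eaten")
  with_preserved_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      out <- layout
      out$n_survivors <- layout$n0 - rbinom(nrow(layout), layout$n0, p_eaten)
      out
    })
  })
}

#' @export
residuals.fr_fit <- function(object, ...) {
  pred <- object$trials[object$trials$predator_present, , drop = FALSE]
  p <- predict(object, pred, type = "p_eaten")
  eaten <- pred$n0 - pred$n_survivors
  (eaten - pred$n0 * p) / sqrt(pred$n0 * p * (1 - p))
}

#' Plot fitted functional-response curves
#'
#' Observed eaten counts against initial prey density, one panel per
#' dataset, with the fitted expected-eaten curve at each trial temperature.
#'
#' @param x An `fr_fit` object.
#' @param ... Passed to [plot()].
#' @export
plot.fr_fit <- function(x, ...) {
  pred <- x$trials[x$trials$predator_present, , drop = FALSE]
  old <- par(mfrow = c(1, length(x$datasets)))
  on.exit(par(old))
  for (ds in x$datasets) {
    d <- pred[pred$dataset_id == ds, , drop = FALSE]
    temps <- sort(unique(d$temperature_C))
    cols <- grDevices::hcl.colors(length(temps), "Zissou 1")
    plot(d$n0, d$n0 - d$n_survivors,
         col = cols[match(d$temperature_C, temps)],
         xlab = "initial prey density", ylab = "prey eaten in trial",
         main = ds, ...)
    Ngrid <- seq(1, max(d$n0), length.out = 60)
    for (j in seq_along(temps)) {
      nd <- data.frame(dataset_id = ds, temperature_C = temps[j], n0 = Ngrid)
      lines(Ngrid, Ngrid * predict(x, nd, type = "p_eaten"), col = cols[j])
    }
    legend("topleft", legend = paste0(temps, " C"), col = cols,
           lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Wald z-statistic convention used in the fit tables
#'
#' Intercept parameters are estimated on the natural-log scale, so the
#' Wald statistic for an intercept tests `ln(estimate) = 0`:
#' `z = ln(estimate)/SE`.  Activation energies are linear: `z = estimate/SE`.
#'
#' @param estimate Natural-scale estimate.
#' @param se Standard error on the fitting scale.
#' @param log_scale Whether the parameter was fitted on the log scale.
#' @return The Wald z-value.
#' @export
wald_z <- function(estimate, se, log_scale = TRUE) {
  if (log_scale) log(estimate) / se else estimate / se
}
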