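test_that("O2-to-joule conversion combines the three printed constants", {
  expect_equal(o2_to_joules(0), 0)
  expect_equal(o2_to_joules(1), (31.9988 / 1.429) * 20.1 / 1000)
  expect_equal(o2_to_joules(1), 0.4501, tolerance = 1e-3)
  expect_equal(o2_to_joules(10), 10 * o2_to_joules(1))
  expect_error(o2_to_joules(-1), ">= 0")
})

test_that("noise-free mass + temperature data are recovered exactly", {
  truth <- metabolic_truth_limnophora()  # ln I0 = -4.171, d = 0.525, E = 0.687
  rec <- simulate_respirometry(truth = truth, sigma_ln = 0, seed = 2)
  fit <- fit_metabolism(rec)
  cf <- coef(fit$candidates$temp_mass)
  expect_equal(unname(cf), c(-4.171, 0.687, 0.525), tolerance = 1e-6)
  # with small realistic noise the generating structure wins BIC
  recn <- simulate_respirometry(truth = truth, sigma_ln = 0.1, seed = 2)
  expect_equal(fit_metabolism(recn)$winner, "temp_mass")
})

test_that("quadratic temperature-only data select the quadratic model", {
  truth <- metabolic_truth_potamophylax()
  rec <- simulate_respirometry(n_per_temp = 8, truth = truth, sigma_ln = 0,
                               seed = 3)
  fit <- fit_metabolism(rec)
  cf <- coef(fit$candidates$temp_quad)
  expect_equal(unname(cf), c(-1.056, 1.072, -0.339), tolerance = 1e-6)
  # under realistic noise the quadratic temperature-only model wins BIC in
  # the clear majority of replicates
  wins <- vapply(1:5, function(s) {
    recn <- simulate_respirometry(n_per_temp = 8, truth = truth,
                                  sigma_ln = 0.3, seed = 30 + s)
    fit_metabolism(recn)$winner == "temp_quad"
  }, logical(1))
  expect_gte(sum(wins), 3)
})

test_that("every candidate structure is recovered exactly without noise", {
  # interaction model: generate directly on the design scale
  k <- fr_constants()$boltzmann_eV_K; T0 <- fr_constants()$T0_K
  rec <- simulate_respirometry(truth = metabolic_truth_limnophora(),
                               sigma_ln = 0, seed = 7)
  T_K <- celsius_to_kelvin(rec$temperature_C)
  x <- (T_K - T0) / (k * T_K * T0)
  lnM <- log(rec$dry_mass_mg)
  rec$metabolic_rate_J_h <- exp(-2 + 0.6 * x + 0.4 * lnM + 0.1 * x * lnM)
  rec$o2_umol_per_h <- NULL
  fit <- fit_metabolism(rec)
  est <- coef(fit$candidates$temp_mass_int)
  expect_equal(unname(est), c(-2, 0.6, 0.4, 0.1), tolerance = 1e-8)
})

test_that("constant or missing mass drops the mass candidates", {
  rec <- simulate_respirometry(truth = metabolic_truth_potamophylax(),
                               sigma_ln = 0.1, seed = 4)
  rec$dry_mass_mg <- 2
  expect_warning(fit <- fit_metabolism(rec), "constant")
  expect_false(any(grepl("mass", fit$ranking$model)))
})

test_that("BIC ranking is invariant to record order", {
  rec <- simulate_respirometry(truth = metabolic_truth_limnophora(),
                               sigma_ln = 0.4, seed = 5)
  f1 <- fit_metabolism(rec)
  f2 <- fit_metabolism(rec[rev(seq_len(nrow(rec))), ])
  expect_equal(f1$ranking$model, f2$ranking$model)
  expect_equal(f1$ranking$BIC, f2$ranking$BIC)
})

test_that("noisy recovery is calibrated against its standard errors", {
  # Wald calibration: across seeds, estimates fall within 2 SE of truth at
  # roughly nominal frequency (checked as a clear majority of 5 replicates)
  hits <- vapply(1:5, function(s) {
    rec <- simulate_respirometry(n_per_temp = 10, sigma_ln = 0.4, seed = s)
    tab <- summary(fit_metabolism(rec))$table
    E_row <- tab[tab$term == "E_I", ]
    d_row <- tab[tab$term == "d_I", ]
    c(E = nrow(E_row) == 1 && abs(E_row$estimate - 0.687) < 2 * E_row$se,
      d = nrow(d_row) == 1 && abs(d_row$estimate - 0.525) < 2 * d_row$se)
  }, logical(2))
  expect_gte(sum(hits["E", ]), 3)
  expect_gte(sum(hits["d", ]), 3)
})

test_that("thermal optimum matches the closed-form vertex and a grid search", {
  topt <- thermal_optimum(1.072, quad = -0.339)
  expect_equal(as.numeric(topt), 294.51, tolerance = 1e-4)
  expect_equal(attr(topt, "celsius"), 21.36, tolerance = 1e-3)
  # ratio invariance: doubling both coefficients leaves the vertex fixed
  expect_equal(as.numeric(thermal_optimum(2 * 1.072, quad = -0.678)),
               as.numeric(topt))
  # monotone model has no optimum
  expect_true(is.na(thermal_optimum(1.072, quad = 0.1)))
  # grid-search oracle on the predicted curve
  rec <- simulate_respirometry(truth = metabolic_truth_potamophylax(),
                               sigma_ln = 0.2, seed = 8)
  fit <- fit_metabolism(rec)
  grid_T <- seq(270, 310, by = 0.001)
  pred <- predict(fit, kelvin_to_celsius(grid_T), model = "temp_quad")
  t_fit <- thermal_optimum(fit, model = "temp_quad")
  expect_true(is.finite(t_fit))
  expect_lt(abs(as.numeric(t_fit) - grid_T[which.max(pred)]), 0.01)
})

test_that("metabolic predictions follow the fitted power laws", {
  rec <- simulate_respirometry(truth = metabolic_truth_limnophora(),
                               sigma_ln = 0, seed = 9)
  fit <- fit_metabolism(rec)
  # reference point: at T0 and unit mass the rate is I0
  expect_equal(predict(fit, kelvin_to_celsius(283.15), dry_mass_mg = 1,
                       model = "temp_mass"),
               exp(-4.171), tolerance = 1e-6)
  # allometric scaling: doubling mass multiplies the rate by 2^0.525
  r1 <- predict(fit, 12, dry_mass_mg = 1, model = "temp_mass")
  r2 <- predict(fit, 12, dry_mass_mg = 2, model = "temp_mass")
  expect_equal(r2 / r1, 2^0.525, tolerance = 1e-6)
  expect_error(predict(fit, 12, model = "temp_mass"), "requires dry_mass_mg")
  # mass-free model ignores mass entirely
  recq <- simulate_respirometry(truth = metabolic_truth_potamophylax(),
                                sigma_ln = 0.1, seed = 10)
  fq <- fit_metabolism(recq)
  expect_equal(predict(fq, 12, dry_mass_mg = 1, model = "temp_quad"),
               predict(fq, 12, model = "temp_quad"))
})
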