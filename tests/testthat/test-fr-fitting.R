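make_trial <- function(ds, pred, T_C, n0, surv, dur = 1) {
  data.frame(dataset_id = ds, predator_present = pred, temperature_C = T_C,
             n0 = n0, n_survivors = surv, duration_days = dur)
}

test_that("binomial likelihood contribution matches the pmf directly", {
  # control arena at 10 C with m = log(2)/day gives p_eaten = 0.5 exactly
  tr <- make_trial("A", FALSE, 10, 10, 5)
  nll <- fr_neg_log_likelihood(tr, fr = list(),
                               mort = list(A = mortality_params(log(2))))
  expect_equal(nll, -dbinom(5, 10, 0.5, log = TRUE))
  expect_equal(nll, 1.402, tolerance = 1e-3)
})

test_that("likelihood is additive and order-invariant", {
  truth <- toy_truth()
  tr <- simulate_fr_experiment(toy_design(2), truth, seed = 3)
  one <- fr_neg_log_likelihood(tr, truth$fr, truth$mort)
  two <- fr_neg_log_likelihood(rbind(tr, tr), truth$fr, truth$mort)
  expect_equal(two, 2 * one)
  shuf <- tr[sample.int(nrow(tr)), ]
  expect_equal(fr_neg_log_likelihood(shuf, truth$fr, truth$mort), one)
})

test_that("near-certain survival contributes almost nothing", {
  tr <- make_trial("A", FALSE, 10, 10, 10)  # no deaths, m = 0
  nll <- fr_neg_log_likelihood(tr, list(), list(A = mortality_params(0)))
  expect_lt(abs(nll), 1e-9)
})

test_that("trial validation catches impossible counts", {
  bad <- make_trial("A", TRUE, 10, 10, 11)
  expect_error(fr_neg_log_likelihood(bad, toy_truth()$fr, toy_truth()$mort),
               "survivors exceed")
  neg <- make_trial("A", TRUE, 10, -2, 0)
  expect_error(fit_mortality(neg), "negative counts")
})

test_that("the model zoo has 55 candidates regardless of dataset count", {
  for (D in c(2, 3)) {
    zoo <- fr_model_zoo(D)
    expect_equal(nrow(zoo), 55)
    expect_equal(sum(zoo$type == "I"), 5)
    expect_equal(sum(zoo$type == "II"), 25)
    expect_equal(anyDuplicated(zoo[, 1:3]), 0)
  }
  # free parameters: separate c0 (3 datasets) + shared E_c + shared b0
  zoo3 <- fr_model_zoo(3)
  row <- zoo3[zoo3$type == "II" & zoo3$c_structure == "separate_sharedE" &
                zoo3$b_structure == "shared", ]
  expect_equal(row$k, 5)
  # separate everything for both families doubles per dataset
  row2 <- zoo3[zoo3$type == "III" & zoo3$c_structure == "separate_E" &
                 zoo3$b_structure == "separate_E", ]
  expect_equal(row2$k, 12)
})

test_that("mortality with zero deaths selects m0 = 0 without optimization", {
  tr <- do.call(rbind, lapply(c(5, 10, 18), function(T_C)
    make_trial("Lab2013", FALSE, T_C, c(5, 20, 40), c(5, 20, 40))))
  mf <- fit_mortality(tr)
  expect_equal(mf$selected$m0, 0)
  expect_equal(mf$selected$model, "none")
  expect_equal(length(mf$detail$Lab2013$candidates), 1L)
})

test_that("constant mortality is recovered from large synthetic controls", {
  des <- fr_design(datasets = list(A = c(4, 8, 12, 16, 20)),
                   replicates = c(A = 40), dropout = 0)
  truth <- list(fr = list(A = fr_params("II", 0.5, 0, 0.3)),
                mort = list(A = mortality_params(0.1)))
  tr <- simulate_fr_experiment(des, truth, seed = 11)
  mf <- fit_mortality(tr)
  expect_equal(mf$selected$m0, 0.1, tolerance = 0.1)
})

test_that("strong temperature dependence of mortality wins BIC", {
  des <- fr_design(datasets = list(A = c(4, 8, 12, 16, 20)),
                   replicates = c(A = 40), dropout = 0)
  truth <- list(fr = list(A = fr_params("II", 0.5, 0, 0.3)),
                mort = list(A = mortality_params(0.1, E_m = 0.6)))
  wins <- vapply(1:5, function(s) {
    tr <- simulate_fr_experiment(des, truth, seed = 100 + s)
    fit_mortality(tr)$selected$model == "arrhenius"
  }, logical(1))
  expect_gte(sum(wins), 4)
})

test_that("sharing structures collapse for a single dataset", {
  truth <- list(fr = list(A = toy_truth()$fr$A),
                mort = list(A = mortality_params(0)))
  des <- fr_design(datasets = list(A = c(5, 10, 15, 18)),
                   replicates = c(A = 4), dropout = 0)
  tr <- simulate_fr_experiment(des, truth, seed = 5)
  f_sh <- fit_fr(tr, "II", "shared_E", "shared", control = quick_control())
  f_sep <- fit_fr(tr, "II", "separate_sharedE", "shared",
                  control = quick_control())
  expect_equal(f_sh$logLik, f_sep$logLik, tolerance = 1e-3)
  expect_equal(f_sh$k, f_sep$k)  # one dataset: same free-parameter count
})

test_that("Wald convention reproduces the published triplet arithmetic", {
  expect_equal(wald_z(0.241, 0.171), -8.325, tolerance = 0.01)
  expect_equal(wald_z(4.033, 0.394), 3.543, tolerance = 0.01)
  expect_equal(wald_z(0.704, 0.152, log_scale = FALSE), 4.615,
               tolerance = 0.05)
})

test_that("fitted objects use the log-scale Wald convention internally", {
  tr <- simulate_fr_experiment(toy_design(3), toy_truth(), seed = 9)
  fit <- fit_fr(tr, "II", "separate_sharedE", "shared",
                control = quick_control())
  lay <- fit$layout
  ints <- lay$kind == "log_intercept"
  expect_equal(unname(fit$z[ints]),
               unname(log(fit$natural[ints]) / fit$se[ints]))
  expect_equal(unname(fit$z[!ints]),
               unname(fit$natural[!ints] / fit$se[!ints]))
  expect_equal(fit$BIC, fit$k * log(fit$n_obs) - 2 * fit$logLik)
})

test_that("BIC selection ranks by the k*ln(n) - 2*logLik arithmetic", {
  fake <- function(type, cs, k, ll, n) {
    structure(list(spec = list(type = type, c_structure = cs,
                               b_structure = "shared"),
                   k = k, n_obs = n, logLik = ll,
                   BIC = k * log(n) - 2 * ll),
              class = "fr_fit")
  }
  # equal logLik, k = 3 vs 5 at n = 100: Delta BIC = 2 ln(100) ~ 9.21
  sel <- select_by_bic(list(fake("II", "shared", 5, -50, 100),
                            fake("II", "separate", 3, -50, 100)))
  expect_equal(sel$winner$k, 3)
  expect_equal(diff(sel$table$BIC[1:2]), 2 * log(100), tolerance = 1e-10)
  # single fit is returned as winner
  single <- select_by_bic(list(fake("I", "shared", 2, -10, 50)))
  expect_equal(single$winner$logLik, -10)
  expect_error(select_by_bic(list()), "no fits")
})

test_that("parameters are recovered under an identifiable design", {
  tr <- simulate_fr_experiment(toy_design(6), toy_truth(), seed = 21)
  fit <- fit_fr(tr, "II", "separate_sharedE", "shared",
                mortality = toy_truth()$mort, control = quick_control())
  expect_equal(unname(fit$coefficients["E_c"]), 0.7, tolerance = 0.45)
  cn <- fit$natural[grep("log_c0", names(fit$natural))]
  expect_equal(unname(cn[grep("\\[A\\]", names(cn))]), 0.4, tolerance = 0.5)
  expect_equal(unname(fit$natural["log_b0"]), 0.25, tolerance = 0.5)
})

test_that("standard errors shrink roughly as 1/sqrt(n)", {
  f1 <- fit_fr(simulate_fr_experiment(toy_design(2), toy_truth(), seed = 2),
               "II", "separate_sharedE", "shared",
               mortality = toy_truth()$mort, control = quick_control())
  f4 <- fit_fr(simulate_fr_experiment(toy_design(8), toy_truth(), seed = 2),
               "II", "separate_sharedE", "shared",
               mortality = toy_truth()$mort, control = quick_control())
  ratio <- f1$se["E_c"] / f4$se["E_c"]
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.2)
})

test_that("plug-in vs true mortality gives consistent activation energy", {
  tr <- simulate_fr_experiment(toy_design(6), toy_truth(), seed = 31)
  f_true <- fit_fr(tr, "II", "separate_sharedE", "shared",
                   mortality = toy_truth()$mort, control = quick_control())
  f_plug <- fit_fr(tr, "II", "separate_sharedE", "shared",
                   control = quick_control())  # mortality fitted internally
  expect_lte(abs(f_true$coefficients["E_c"] - f_plug$coefficients["E_c"]),
             f_true$se["E_c"])
})

test_that("predict and simulate round-trip the fitted model", {
  tr <- simulate_fr_experiment(toy_design(3), toy_truth(), seed = 13)
  fit <- fit_fr(tr, "II", "separate_sharedE", "shared",
                control = quick_control())
  nd <- data.frame(dataset_id = "A", temperature_C = 10, n0 = c(5, 20))
  p <- predict(fit, nd, type = "p_eaten")
  expect_true(all(p > 0 & p < 1))
  s <- predict(fit, nd, type = "survivors")
  expect_equal(s, nd$n0 * (1 - p))
  sim <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sim, 2)
  expect_true(all(sim[[1]]$n_survivors <= sim[[1]]$n0))
  expect_identical(sim[[1]], simulate(fit, nsim = 1, seed = 4)[[1]])
  r <- residuals(fit)
  expect_length(r, sum(fit$trials$predator_present))
})
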