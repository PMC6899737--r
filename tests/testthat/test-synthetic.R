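test_that("generators are deterministic given the seed", {
  d <- toy_design(2); tr <- toy_truth()
  expect_identical(simulate_fr_experiment(d, tr, seed = 5),
                   simulate_fr_experiment(d, tr, seed = 5))
  expect_false(identical(simulate_fr_experiment(d, tr, seed = 5)$n_survivors,
                         simulate_fr_experiment(d, tr, seed = 6)$n_survivors))
  expect_identical(simulate_respirometry(seed = 3),
                   simulate_respirometry(seed = 3))
  expect_identical(simulate_streams(seed = 9), simulate_streams(seed = 9))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_fr_experiment(toy_design(2), toy_truth(),
                                                  seed = 1))
  expect_identical(runif(1), before)
})

test_that("trial bookkeeping matches the design", {
  d <- fr_design_limnophora()
  tr <- simulate_fr_experiment(d, fr_truth_limnophora(), seed = 1)
  # predator arenas: (4+4+5 temps) x 8 densities x per-dataset replicates
  expect_equal(sum(tr$predator_present), (4 * 3 + 4 * 2 + 5 * 2) * 8)
  expect_equal(sum(!tr$predator_present), (4 * 3 + 4 * 2 + 5 * 2) * 8)
  expect_setequal(unique(tr$dataset_id),
                  c("Lab2013", "Lab2015", "Field2015"))
  expect_true(all(tr$n_survivors >= 0 & tr$n_survivors <= tr$n0))
  expect_true(all(tr$excluded[!tr$predator_present] == 0))
  # controls in the no-mortality dataset lose no prey
  lab13 <- tr[!tr$predator_present & tr$dataset_id == "Lab2013", ]
  expect_true(all(lab13$n_survivors == lab13$n0))
})

test_that("simulated eaten fractions are binomial around the ODE mean", {
  des <- fr_design(datasets = list(A = 12), densities = 16,
                   replicates = c(A = 10000), include_controls = FALSE,
                   dropout = 0)
  truth <- list(fr = list(A = fr_params("II", 0.5, 0.7, 0.2)),
                mort = list(A = mortality_params(0.05)))
  tr <- simulate_fr_experiment(des, truth, seed = 17)
  p_hat <- mean((tr$n0 - tr$n_survivors) / tr$n0)
  surv <- integrate_depletion(16, truth$fr$A, truth$mort$A,
                              celsius_to_kelvin(12))
  p_true <- (16 - surv) / 16
  mc_se <- sqrt(p_true * (1 - p_true) / (16 * 10000))
  expect_lt(abs(p_hat - p_true), 3 * mc_se)
})

test_that("tiny attack coefficients produce essentially no feeding", {
  expect_error(fr_params("II", c0 = 0, b0 = 1), "> 0")
  des <- fr_design(datasets = list(A = c(10, 18)), densities = c(5, 20),
                   replicates = c(A = 30), include_controls = FALSE,
                   dropout = 0)
  truth <- list(fr = list(A = fr_params("II", 1e-8, 0.7, 0.2)),
                mort = list(A = mortality_params(0)))
  tr <- simulate_fr_experiment(des, truth, seed = 2)
  expect_equal(sum(tr$n0 - tr$n_survivors), 0)
})

test_that("respirometry generator honours design and noise settings", {
  rec <- simulate_respirometry(seed = 1)
  expect_equal(nrow(rec), 46)  # 10 + 9 + 9 + 9 + 9
  expect_equal(sort(unique(rec$temperature_C)), c(5, 10, 15, 20, 25))
  rec50 <- simulate_respirometry(n_per_temp = 10, seed = 1)
  expect_equal(nrow(rec50), 50)
  # zero noise: records lie exactly on the model surface
  truth <- metabolic_truth_limnophora()
  rec0 <- simulate_respirometry(truth = truth, sigma_ln = 0, seed = 4)
  k <- fr_constants()$boltzmann_eV_K; T0 <- fr_constants()$T0_K
  T_K <- celsius_to_kelvin(rec0$temperature_C)
  x <- (T_K - T0) / (k * T_K * T0)
  expect_equal(log(o2_to_joules(rec0$o2_umol_per_h)),
               truth$ln_I0 + truth$d_I * log(rec0$dry_mass_mg) +
                 truth$E_I * x)
  expect_true(all(rec0$dry_mass_mg >= 0.5 & rec0$dry_mass_mg <= 5))
})

test_that("noise calibration reproduces the target fit quality", {
  r2 <- vapply(1:20, function(s) {
    rec <- simulate_respirometry(seed = s)
    summary(fit_metabolism(rec)$candidates$temp_mass)$r.squared
  }, numeric(1))
  expect_gt(mean(r2), 0.7)
  expect_lt(mean(r2), 0.9)
})

test_that("stream generator respects range, cap and response shapes", {
  st <- simulate_streams(n_streams = 14, seed = 1)
  expect_equal(nrow(st), 14)
  expect_equal(range(st$mean_temp_C), c(4, 25))
  big <- simulate_streams(n_streams = 200, noise_sd_ln = 1, seed = 2)
  expect_true(all(big$simuliidae_abundance <= 8500))
  # zero noise: abundance is exactly the stated logistic response
  st0 <- simulate_streams(n_streams = 10, noise_sd_ln = 0, seed = 3)
  expect_equal(st0$simuliidae_abundance,
               8500 * plogis(0.35 * (st0$mean_temp_C - 12)))
  expect_true(all(diff(st0$simuliidae_abundance) > 0))
  hump <- simulate_streams(n_streams = 15, noise_sd_ln = 0,
                           predator_shape = "hump", seed = 4)
  peak <- which.max(hump$predator_abundance)
  expect_gt(peak, 1); expect_lt(peak, 15)
})
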