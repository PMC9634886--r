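test_that("protein generation is reproducible and respects the dispersion", {
  p1 <- generate_protein(2e4, seed = 99)
  p2 <- generate_protein(2e4, seed = 99)
  expect_identical(p1, p2)

  # dispersion 0 gives the plain rounded averagine (plus hydrogen rebalance)
  p0 <- generate_protein(2e4, dispersion = 0, seed = 1)
  am <- averagine_model()
  expect_equal(unclass(p0$formula[[1]])[c("C", "N", "O", "S")],
               round(2e4 / am$unit_avg_mass * unclass(am$unit))[c("C", "N", "O", "S")])
  expect_lte(abs(p0$m_avg - 2e4), 0.55)

  # per-element coefficients of variation track the dispersion parameter
  draws <- purrr::map(1:400, ~ generate_protein(2e4, seed = 1000 + .x))
  counts <- vapply(draws, function(d) unclass(d$formula[[1]]), numeric(5))
  cv <- apply(counts, 1, function(x) sd(x) / mean(x))
  for (e in c("C", "N", "O")) {
    expect_gt(cv[[e]], 0.03 * 0.7)
    expect_lt(cv[[e]], 0.03 * 1.3)
  }
  # sulfur counts are small (~8 at 20 kDa), so integer rounding inflates the
  # spread beyond the nominal dispersion
  expect_lt(cv[["S"]], 0.1)
})

test_that("proteome simulation covers the band reproducibly", {
  pr <- simulate_proteome(50, seed = 7)
  expect_identical(pr, simulate_proteome(50, seed = 7))
  expect_gte(min(pr$target_avg), 8e3)
  expect_lte(max(pr$target_avg), 4e5)
  expect_true(all(vapply(pr$formula, monoiso:::is_integral_formula, logical(1))))
  expect_true(all(pr$m_mono < pr$m_avg))
})

test_that("the initial-model refit recovers exact linear truth", {
  # inject noiseless linear data through the same lm path
  pr <- simulate_proteome(120, mass_range = c(8e3, 3e4), seed = 5)
  spectra <- purrr::map(pr$formula, aggregated_spectrum, coverage = 0.99)
  mom <- dplyr::bind_rows(purrr::map(spectra, spectrum_moments))
  pr$m_mono <- -0.2 + 0.9995 * mom$m_avg - 0.6 * mom$m_var
  fit <- refit_initial_model(pr, seed = 1)
  expect_equal(unname(fit$coefficients),
               c(-0.2, 0.9995, -0.6), tolerance = 1e-7)
  expect_equal(fit$cv_fraction, 1)
  expect_equal(nrow(fit$cv), 10)
  expect_error(refit_initial_model(pr[1:20, ]), "at least 100")
})

test_that("the grid-step refit recovers injected linear truth and weak correlation", {
  pr <- simulate_proteome(60, mass_range = c(8e3, 2e4), seed = 13)
  fit <- refit_grid_model(pr)
  # the fitted line reproduces each spectrum's optimal step to sub-mDa level
  pred_zeta <- fit$coefficients[["gamma0"]] + fit$coefficients[["gamma_avg"]] * fit$data$m_avg
  expect_lt(max(abs(pred_zeta - fit$data$zeta_star)), 2e-3)
  # the genuine optimal step is only weakly related to mass
  expect_lt(abs(fit$correlations[["pearson"]]), 0.9)
  expect_gte(fit$coefficients[["gamma0"]], 0.99)
  expect_lte(fit$coefficients[["gamma0"]], 1.02)
})

test_that("lambda calibration centres the rounding errors", {
  pr <- simulate_proteome(150, mass_range = c(8e3, 4e4), seed = 23)
  lam <- calibrate_lambda(pr)
  expect_lt(abs(lam), 1e-6)
  # applying the calibrated lambda recentres the signed relative error
  co <- default_coefficients()
  co$lambda <- lam
  ev <- evaluate_predictor(pr, co)
  free <- dplyr::filter(ev$results, off_by_one_free)
  expect_lt(abs(mean(free$error / free$m_mono)), 5e-8)
})

test_that("evaluation reports coherent overall and per-band statistics", {
  pr <- simulate_proteome(120, mass_range = c(8e3, 6e4), seed = 37)
  ev <- evaluate_predictor(pr)
  g <- glance(ev)
  expect_equal(g$n, 120)
  expect_equal(g$mae_ppm, mean(ev$results$ppm))
  expect_equal(g$off_by_one_free_fraction, mean(abs(ev$results$error) < 0.5))
  expect_gte(g$off_by_one_free_fraction, 0)
  expect_lte(g$off_by_one_free_fraction, 1)
  expect_lte(g$cond_mae_da, g$mae_da)
  bands <- tidy(ev)
  expect_equal(sum(bands$n), 120)
  expect_equal(sum(bands$n * bands$mae_ppm) / 120, g$mae_ppm, tolerance = 1e-12)
  expect_s3_class(autoplot(ev), "ggplot")
})

test_that("fixtures are deterministic and match their advertised structure", {
  f1 <- tempfile()
  f2 <- tempfile()
  make_fixture("comb", f1, seed = 3)
  make_fixture("comb", f2, seed = 3)
  expect_identical(readLines(f1), readLines(f2))
  comb <- read_peaklist(f1)
  expect_equal(optimal_zeta(comb), 1.0023, tolerance = 1e-5)

  make_fixture("noisy-protein", f1, seed = 8, mass = 16940)
  noisy <- read_peaklist(f1)
  expect_spectrum_valid(noisy)
  expect_gt(nrow(noisy), 10)
})

test_that("spectrum perturbation applies bounded noise", {
  sp <- aggregated_spectrum("C254H377N65O75S6", coverage = 0.99)
  noisy <- perturb_spectrum(sp, intensity_cv = 0.05, mass_ppm = 2, seed = 2)
  expect_identical(noisy, perturb_spectrum(sp, 0.05, 2, seed = 2))
  expect_lt(max(abs(noisy$mass / sp$mass - 1)), 2e-5)
  expect_true(all(noisy$intensity >= 0))
})
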