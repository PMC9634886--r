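# Run code under a temporary RNG state so package functions with a `seed`
# argument are reproducible without clobbering the caller's stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic protein-like chemical formula
#'
#' Emulates a database protein of a given average mass: the averagine unit is
#' scaled to the target, each element count receives an independent
#' multiplicative log-normal perturbation (`sdlog = dispersion`) to mimic the
#' compositional spread of real proteomes, counts are rounded and hydrogens
#' rebalanced so the average mass comes back within half a hydrogen of the
#' target.
#'
#' @param target_avg Target average mass, Da.
#' @param dispersion Log-normal standard deviation of the per-element
#'   multiplicative perturbation (default 0.03).
#' @param seed Optional integer seed (reproducible draws).
#' @param model An [averagine_model()].
#' @param isotopes Isotope table.
#' @param max_tries Retry budget for infeasible draws.
#' @return One-row tibble with `target_avg`, `formula` (list column of
#'   `chem_formula`), and closed-form `m_mono`, `m_avg`, `m_var`.
#' @export
#' @examples
#' generate_protein(2e4, seed = 1)
generate_protein <- function(target_avg, dispersion = 0.03, seed = NULL,
                             model = averagine_model(),
                             isotopes = isotope_table(), max_tries = 20) {
  stopifnot(target_avg >= model$unit_avg_mass, dispersion >= 0)
  with_local_seed(seed, {
    n <- target_avg / model$unit_avg_mass
    h_avg <- iso_elements(isotopes)[["H"]]$mean
    for (i in seq_len(max_tries)) {
      f <- round(n * unclass(model$unit) * exp(rnorm(5, 0, dispersion)))
      f[["H"]] <- f[["H"]] + round((target_avg - sum(
        f * vapply(names(f), function(e) iso_elements(isotopes)[[e]]$mean, numeric(1))
      )) / h_avg)
      if (f[["H"]] >= 0) {
        fml <- chem_formula(f)
        return(tibble::tibble(
          target_avg = target_avg,
          formula = list(fml),
          m_mono = monoisotopic_mass(fml, isotopes),
          m_avg = average_mass(fml, isotopes),
          m_var = spectrum_variance(fml, isotopes)
        ))
      }
    }
    stop("could not draw a feasible formula in ", max_tries, " tries", call. = FALSE)
  })
}

#' Simulate a synthetic proteome
#'
#' Draws `n` protein-like formulas with average masses sampled uniformly in
#' log-mass over `mass_range` and per-element compositional dispersion as in
#' [generate_protein()]. Fully reproducible under `seed` (mass sampling and
#' per-protein perturbations share one stream).
#'
#' @param n Number of proteins.
#' @param mass_range Average-mass band in Da (default 8-400 kDa).
#' @param dispersion Per-element log-normal dispersion.
#' @param seed Integer seed.
#' @param model An [averagine_model()].
#' @param isotopes Isotope table.
#' @return Tibble with one row per protein: `target_avg`, `formula` (list),
#'   `m_mono`, `m_avg`, `m_var` (closed-form full moments).
#' @export
simulate_proteome <- function(n, mass_range = c(8e3, 4e5), dispersion = 0.03,
                              seed = NULL, model = averagine_model(),
                              isotopes = isotope_table()) {
  with_local_seed(seed, {
    targets <- exp(runif(n, log(mass_range[1]), log(mass_range[2])))
    dplyr::bind_rows(lapply(targets, function(t) {
      generate_protein(t, dispersion = dispersion, seed = NULL,
                       model = model, isotopes = isotopes)
    }))
  })
}

# Trimmed-spectrum features (moments at the working coverage) per protein.
proteome_spectra <- function(proteome, coverage = 0.99,
                             isotopes = isotope_table()) {
  purrr::map(proteome$formula, aggregated_spectrum, coverage = coverage,
             isotopes = isotopes)
}

#' Refit the initial-estimate linear model on a synthetic proteome
#'
#' Ordinary least squares of the true monoisotopic mass on the average mass
#' and variance of each protein's coverage-trimmed aggregated spectrum - the
#' same features the predictor consumes - plus a seeded k-fold
#' cross-validation reporting the out-of-fold fraction of absolute errors
#' below 0.5 Da (the off-by-one-free criterion).
#'
#' @param proteome Tibble from [simulate_proteome()].
#' @param coverage Spectrum coverage used to build the features.
#' @param folds Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @param isotopes Isotope table.
#' @return An object of class `initial_model_fit`: list with `coefficients`
#'   (`beta0`, `beta_avg`, `beta_var`), the underlying `lm` fit, `cv_fraction`
#'   (overall out-of-fold fraction below 0.5 Da), `cv` (per-fold tibble) and
#'   the feature `data`.
#' @export
refit_initial_model <- function(proteome, coverage = 0.99, folds = 10, seed = 1,
                      isotopes = isotope_table()) {
  if (nrow(proteome) < 100) {
    stop("refit_initial_model() needs at least 100 proteins", call. = FALSE)
  }
  spectra <- proteome_spectra(proteome, coverage, isotopes)
  mom <- dplyr::bind_rows(lapply(spectra, spectrum_moments))
  dat <- tibble::tibble(m_mono = proteome$m_mono,
                        s_avg = mom$m_avg, s_var = mom$m_var)
  fit <- lm(m_mono ~ s_avg + s_var, data = dat)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design in refit_initial_model()", call. = FALSE)
  }
  fold <- with_local_seed(seed, sample(rep(seq_len(folds), length.out = nrow(dat))))
  oof <- numeric(nrow(dat))
  for (f in seq_len(folds)) {
    hold <- fold == f
    m <- lm(m_mono ~ s_avg + s_var, data = dat[!hold, ])
    oof[hold] <- predict(m, newdata = dat[hold, ])
  }
  abs_err <- abs(oof - dat$m_mono)
  cv <- dplyr::summarise(dplyr::group_by(
    tibble::tibble(fold = fold, ok = abs_err < 0.5), .data$fold),
    fraction_below_0.5 = mean(.data$ok), n = dplyr::n(), .groups = "drop")
  structure(list(
    coefficients = setNames(as.numeric(coef(fit)), c("beta0", "beta_avg", "beta_var")),
    fit = fit,
    cv_fraction = mean(abs_err < 0.5),
    cv = cv,
    data = dat
  ), class = "initial_model_fit")
}

#' @export
print.initial_model_fit <- function(x, ...) {
  cat("<initial_model_fit>\n  coefficients:",
      sprintf("beta0 = %.5f, beta_avg = %.5f, beta_var = %.5f",
              x$coefficients[1], x$coefficients[2], x$coefficients[3]),
      sprintf("\n  CV fraction |error| < 0.5 Da: %.4f (n = %d)\n",
              x$cv_fraction, nrow(x$data)))
  invisible(x)
}

#' @export
tidy.initial_model_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
glance.initial_model_fit <- function(x, ...) {
  tibble::tibble(n = nrow(x$data), cv_fraction = x$cv_fraction,
                 sigma = summary(x$fit)$sigma,
                 r.squared = summary(x$fit)$r.squared)
}

#' Refit the universal grid-step model
#'
#' Runs the per-spectrum period optimization [optimal_zeta()] on every
#' protein's trimmed spectrum and fits `zeta* ~ m_avg` by OLS. The
#' correlation between the optimal step and the average mass is weak, which
#' is exactly why a universal (near-constant) step works; Pearson, Kendall
#' and Spearman correlations are reported for that qualitative check. The
#' per-spectrum optimization is the bottleneck, so this is meant for samples
#' of ~100 proteins.
#'
#' @inheritParams refit_initial_model
#' @param search Search interval for the per-spectrum optimal step, Da.
#' @return An object of class `grid_step_fit` with `coefficients` (`gamma0`,
#'   `gamma_avg`), `correlations`, the `lm` fit and the data.
#' @export
refit_grid_model <- function(proteome, coverage = 0.99, search = c(0.998, 1.008),
                      isotopes = isotope_table()) {
  if (nrow(proteome) < 50) {
    stop("refit_grid_model() needs at least 50 proteins", call. = FALSE)
  }
  spectra <- proteome_spectra(proteome, coverage, isotopes)
  zs <- vapply(spectra, optimal_zeta, numeric(1), search = search)
  mavg <- vapply(spectra, function(s) spectrum_moments(s)$m_avg, numeric(1))
  dat <- tibble::tibble(zeta_star = zs, m_avg = mavg)
  fit <- lm(zeta_star ~ m_avg, data = dat)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design in refit_grid_model()", call. = FALSE)
  }
  structure(list(
    coefficients = setNames(as.numeric(coef(fit)), c("gamma0", "gamma_avg")),
    correlations = c(pearson = cor(zs, mavg, method = "pearson"),
                     kendall = cor(zs, mavg, method = "kendall"),
                     spearman = cor(zs, mavg, method = "spearman")),
    fit = fit,
    data = dat
  ), class = "grid_step_fit")
}

#' @export
print.grid_step_fit <- function(x, ...) {
  cat("<grid_step_fit>\n",
      sprintf("  zeta = %.6f + %.4e * M_avg  (n = %d)\n",
              x$coefficients[1], x$coefficients[2], nrow(x$data)),
      sprintf("  correlations: pearson %.3f, kendall %.3f, spearman %.3f\n",
              x$correlations[1], x$correlations[2], x$correlations[3]))
  invisible(x)
}

#' Calibrate the rounding correction on a synthetic proteome
#'
#' Chooses `lambda` so that the mean signed relative error of the grid-rounded
#' prediction (before any correction, restricted to off-by-one-free cases) is
#' centered at zero. Inter-cluster spacing widens slightly in the envelope's
#' left tail, so the uncorrected node sits systematically above the true
#' monoisotopic mass and the calibrated `lambda` is negative.
#'
#' @inheritParams refit_initial_model
#' @param coef Coefficient bundle supplying the linear models.
#' @return The calibrated `lambda` (dimensionless).
#' @export
calibrate_lambda <- function(proteome, coef = default_coefficients(),
                             coverage = 0.99, isotopes = isotope_table()) {
  coef0 <- coef
  coef0$lambda <- 0
  spectra <- proteome_spectra(proteome, coverage, isotopes)
  nodes <- vapply(spectra, function(s) predict_theoretical(s, coef0)$m_mono,
                  numeric(1))
  rel <- (nodes - proteome$m_mono) / proteome$m_mono
  free <- abs(nodes - proteome$m_mono) < 0.5
  if (!any(free)) {
    stop("no off-by-one-free cases to calibrate on", call. = FALSE)
  }
  -mean(rel[free])
}

#' Evaluate the predictor on a synthetic proteome
#'
#' Runs [predict_theoretical()] on every protein's coverage-trimmed spectrum
#' and summarizes the errors: overall mean absolute error (Da and ppm,
#' relative to the true monoisotopic mass), the off-by-one-free fraction
#' (absolute error below 0.5 Da, i.e. the prediction landed on the correct
#' isotope cluster), the conditional MAE on that subset, and a per-mass-band
#' breakdown (8-20, 20-40, 40-60, >60 kDa).
#'
#' @inheritParams calibrate_lambda
#' @return An object of class `mono_eval` with per-protein `results`, the
#'   overall `summary` row and the `by_band` breakdown. `glance()` returns
#'   the summary row, `tidy()` the per-band table.
#' @export
evaluate_predictor <- function(proteome, coef = default_coefficients(),
                               coverage = 0.99, isotopes = isotope_table()) {
  spectra <- proteome_spectra(proteome, coverage, isotopes)
  preds <- vapply(spectra, function(s) predict_theoretical(s, coef)$m_mono,
                  numeric(1))
  res <- dplyr::mutate(
    tibble::tibble(m_mono = proteome$m_mono, m_avg = proteome$m_avg,
                   predicted = preds),
    error = .data$predicted - .data$m_mono,
    abs_error = abs(.data$error),
    ppm = 1e6 * .data$abs_error / .data$m_mono,
    off_by_one_free = .data$abs_error < 0.5,
    band = cut(.data$m_avg / 1e3, c(0, 20, 40, 60, Inf),
               labels = c("8-20 kDa", "20-40 kDa", "40-60 kDa", ">60 kDa"))
  )
  summarise_errors <- function(d) {
    tibble::tibble(
      n = nrow(d),
      mae_da = mean(d$abs_error),
      mae_ppm = mean(d$ppm),
      off_by_one_free_fraction = mean(d$off_by_one_free),
      cond_mae_da = mean(d$abs_error[d$off_by_one_free]),
      cond_mae_ppm = mean(d$ppm[d$off_by_one_free])
    )
  }
  by_band <- dplyr::filter(dplyr::bind_cols(
    tibble::tibble(band = levels(res$band)),
    dplyr::bind_rows(lapply(split(res, res$band), summarise_errors))
  ), .data$n > 0)
  structure(list(results = res, summary = summarise_errors(res),
                 by_band = by_band),
            class = "mono_eval")
}

#' @export
print.mono_eval <- function(x, ...) {
  s <- x$summary
  cat("<mono_eval>", s$n, "proteins\n")
  cat(sprintf("  MAE: %.4f Da (%.3f ppm)\n", s$mae_da, s$mae_ppm))
  cat(sprintf("  off-by-one-free: %.1f%%; conditional MAE %.4f Da (%.4f ppm)\n",
              100 * s$off_by_one_free_fraction, s$cond_mae_da, s$cond_mae_ppm))
  print(x$by_band)
  invisible(x)
}

#' @export
glance.mono_eval <- function(x, ...) {
  x$summary
}

#' @export
tidy.mono_eval <- function(x, ...) {
  x$by_band
}

#' @export
autoplot.mono_eval <- function(object, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(x = .data$error)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", colour = "grey30") +
    ggplot2::facet_wrap(~band, scales = "free_y") +
    ggplot2::labs(x = "prediction error (Da)", y = "proteins") +
    ggplot2::theme_minimal()
}

#' Add measurement noise to a spectrum
#'
#' Applies multiplicative Gaussian intensity noise (coefficient of variation
#' `intensity_cv`) and relative mass jitter (`mass_ppm` parts per million) to
#' a stick spectrum, emulating a well-resolved experimental envelope.
#'
#' @param spectrum Tibble with `mass` and `prob`/`intensity`.
#' @param intensity_cv Coefficient of variation of the intensity noise.
#' @param mass_ppm Standard deviation of the mass jitter, ppm.
#' @param seed Optional seed.
#' @return Tibble with `mass` and `intensity`.
#' @export
perturb_spectrum <- function(spectrum, intensity_cv = 0.05, mass_ppm = 2,
                             seed = NULL) {
  w <- spectrum_weights(spectrum)
  with_local_seed(seed, {
    tibble::tibble(
      mass = spectrum$mass * (1 + rnorm(nrow(spectrum), 0, mass_ppm * 1e-6)),
      intensity = pmax(0, w * (1 + rnorm(nrow(spectrum), 0, intensity_cv)))
    )
  })
}
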