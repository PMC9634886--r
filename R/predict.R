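#' Initial monoisotopic estimate from average mass and spectral variance
#'
#' The linear predictor `beta0 + beta_avg * M_avg + beta_var * M_var`. On its
#' own it is accurate to within half an inter-cluster spacing for most
#' proteins; the grid-rounding step removes the remaining sub-dalton error.
#'
#' @param m_avg Average mass, Da (> 0).
#' @param m_var Spectral variance, Da^2 (>= 0).
#' @param coef Coefficient bundle, see [mono_coefficients()].
#' @return Initial monoisotopic mass estimate, Da.
#' @export
initial_estimate <- function(m_avg, m_var, coef = default_coefficients()) {
  stopifnot(all(m_avg > 0), all(m_var >= 0))
  coef$beta0 + coef$beta_avg * m_avg + coef$beta_var * m_var
}

#' Predict the monoisotopic mass of a theoretical spectrum
#'
#' End-to-end prediction for a noise-free aggregated spectrum: spectrum
#' moments feed the linear initial estimate, the universal grid step and the
#' circular-mean grid shift define the lattice of candidate monoisotopic
#' positions, and the initial estimate is rounded to the nearest node with
#' the `lambda` correction. Deterministic; invariant to uniform rescaling of
#' the probabilities.
#'
#' @param spectrum Tibble with `mass` and `prob` (or `intensity`) columns; at
#'   least two peaks.
#' @param coef Coefficient bundle.
#' @param lambda_mode Passed to [round_to_grid()].
#' @return An object of class `mono_prediction` with fields `m_mono` (final
#'   prediction, Da), `m_initial`, `m_avg`, `m_var`, `zeta`, `delta`,
#'   `lambda`, `spectrum` and (for the experimental path) `candidate`.
#' @export
#' @examples
#' sp <- aggregated_spectrum("C254H377N65O75S6", coverage = 0.99)
#' predict_theoretical(sp)
predict_theoretical <- function(spectrum, coef = default_coefficients(),
                                lambda_mode = c("relative", "absolute")) {
  lambda_mode <- match.arg(lambda_mode)
  if (nrow(spectrum) < 2) {
    stop("predict_theoretical() needs at least two peaks", call. = FALSE)
  }
  mom <- spectrum_moments(spectrum)
  zeta <- universal_zeta(mom$m_avg, coef)
  delta <- estimate_delta(spectrum, zeta)
  m_init <- initial_estimate(mom$m_avg, mom$m_var, coef)
  m_final <- round_to_grid(m_init, zeta, delta, coef$lambda, lambda_mode)
  new_mono_prediction(m_mono = m_final, m_initial = m_init,
                      m_avg = mom$m_avg, m_var = mom$m_var,
                      zeta = zeta, delta = delta, lambda = coef$lambda,
                      spectrum = spectrum, candidate = NULL)
}

#' Predict the monoisotopic mass of an experimental envelope
#'
#' Full experimental pipeline: the spectrum is converted to the neutral
#' dalton axis (if on m/z) and normalized; the grid step comes from the
#' experimental average mass; [fit_candidate()] matches a variance-adjusted,
#' cluster-shifted scaled averagine to the envelope by Wasserstein distance;
#' and the theoretical-spectrum predictor runs on the winning simulated
#' spectrum, which supplies the precisely measured features (average mass,
#' variance, grid shift) that a noisy envelope cannot.
#'
#' @param spectrum Tibble with `mz` or `mass`, and `intensity` (or `prob`)
#'   columns; at least three peaks.
#' @param charge Charge state, required for m/z input.
#' @param model An [averagine_model()].
#' @param coef Coefficient bundle.
#' @param ... Passed to [fit_candidate()] (`k_range`, `rho_bounds`,
#'   `coverage`, ...).
#' @inheritParams predict_theoretical
#' @return A `mono_prediction`; its `candidate` field holds the fitted
#'   simulated spectrum and the Wasserstein diagnostics.
#' @export
predict_experimental <- function(spectrum, charge = NULL,
                                 model = averagine_model(),
                                 coef = default_coefficients(),
                                 lambda_mode = c("relative", "absolute"), ...) {
  lambda_mode <- match.arg(lambda_mode)
  spectrum <- to_dalton(spectrum, charge)
  if (nrow(spectrum) < 3) {
    stop("predict_experimental() needs at least three peaks", call. = FALSE)
  }
  exp_norm <- normalize_spectrum(spectrum)
  zeta <- universal_zeta(spectrum_moments(exp_norm)$m_avg, coef)
  cand <- fit_candidate(exp_norm, model = model, zeta = zeta, ...)
  pred <- predict_theoretical(cand$spectrum, coef, lambda_mode)
  pred$candidate <- cand
  pred$spectrum <- exp_norm
  pred
}

new_mono_prediction <- function(...) {
  structure(list(...), class = "mono_prediction")
}

#' @export
print.mono_prediction <- function(x, ...) {
  cat("<mono_prediction>\n")
  cat(sprintf("  monoisotopic mass: %.4f Da (initial estimate %.4f Da)\n",
              x$m_mono, x$m_initial))
  cat(sprintf("  M_avg = %.4f Da, M_var = %.4f Da^2\n", x$m_avg, x$m_var))
  cat(sprintf("  grid: zeta = %.6f Da, delta = %+.4f Da, lambda = %.4e\n",
              x$zeta, x$delta, x$lambda))
  if (!is.null(x$candidate)) {
    cat(sprintf("  candidate: k = %d, rho = %.3f, W = %.4f Da\n",
                x$candidate$k, x$candidate$rho, x$candidate$w_dist))
  }
  invisible(x)
}

#' @export
tidy.mono_prediction <- function(x, ...) {
  tibble::tibble(
    m_mono = x$m_mono, m_initial = x$m_initial,
    m_avg = x$m_avg, m_var = x$m_var,
    zeta = x$zeta, delta = x$delta, lambda = x$lambda,
    k = if (is.null(x$candidate)) NA_integer_ else x$candidate$k,
    rho = if (is.null(x$candidate)) NA_real_ else x$candidate$rho,
    w_dist = if (is.null(x$candidate)) NA_real_ else x$candidate$w_dist
  )
}

#' @export
glance.mono_prediction <- function(x, ...) {
  tidy.mono_prediction(x)
}

#' @export
autoplot.mono_prediction <- function(object, n_nodes = 8, ...) {
  sp <- normalize_spectrum(object$spectrum)
  nodes <- object$delta +
    object$zeta * seq(floor((object$m_mono - object$delta) / object$zeta),
                      floor((max(sp$mass) - object$delta) / object$zeta))
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$mass, y = .data$prob)) +
    ggplot2::geom_vline(xintercept = nodes, colour = "grey85", linewidth = 0.3) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mass, yend = 0)) +
    ggplot2::geom_vline(xintercept = object$m_mono, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(x = "mass (Da)", y = "probability",
                  title = sprintf("monoisotopic mass %.4f Da", object$m_mono)) +
    ggplot2::theme_minimal()
}

#' Stick plot of a spectrum
#'
#' @param spectrum Tibble with `mass` (or `mz`) and `prob`/`intensity`.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  xcol <- if ("mass" %in% names(spectrum)) "mass" else "mz"
  ycol <- if ("prob" %in% names(spectrum)) "prob" else "intensity"
  ggplot2::ggplot(spectrum, ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]])) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data[[xcol]], yend = 0)) +
    ggplot2::labs(x = paste0(xcol, if (xcol == "mass") " (Da)" else ""), y = ycol) +
    ggplot2::theme_minimal()
}
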