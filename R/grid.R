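#' Map spectrum peaks onto a circle of circumference zeta
#'
#' Wraps every peak mass onto a circle of circumference `zeta` (angle
#' `2*pi*mass/zeta`), rotates so the probability-weighted circular mean sits
#' at zero, and maps angles back to positions in `[-zeta/2, zeta/2]`. When the
#' candidate period matches the true inter-cluster spacing, all peaks collapse
#' onto a narrow arc.
#'
#' @param spectrum Tibble with `mass` and `prob` (or `intensity`) columns.
#' @param zeta Candidate period in Da, > 0.
#' @param weighted Rotate to the probability-weighted circular mean (default);
#'   `FALSE` uses the unweighted mean of peak angles.
#' @return Tibble with columns `position` (Da, in `[-zeta/2, zeta/2]`) and
#'   `prob` (renormalized weights).
#' @export
circular_transform <- function(spectrum, zeta, weighted = TRUE) {
  if (zeta <= 0) {
    stop("zeta must be positive", call. = FALSE)
  }
  w <- spectrum_weights(spectrum)
  w <- w / sum(w)
  theta <- 2 * pi * spectrum$mass / zeta
  rot <- if (weighted) sum(w * exp(1i * theta)) else mean(exp(1i * theta))
  rot_angle <- if (Mod(rot) < 1e-12) {
    # degenerate resultant (e.g. equal peaks half a period apart): fall back
    # to the weighted mean of principal angles
    if (weighted) sum(w * Arg(exp(1i * theta))) else mean(Arg(exp(1i * theta)))
  } else {
    Arg(rot)
  }
  centred <- Arg(exp(1i * (theta - rot_angle)))
  tibble::tibble(position = centred * zeta / (2 * pi), prob = w)
}

# Probability-weighted variance of the circularly transformed positions.
circular_variance <- function(mass, w, zeta) {
  theta <- 2 * pi * mass / zeta
  z <- complex(modulus = w, argument = theta)
  centred <- Arg(exp(1i * (theta - Arg(sum(z)))))
  pos <- centred * zeta / (2 * pi)
  mu <- sum(w * pos)
  sum(w * (pos - mu)^2)
}

#' Per-spectrum optimal grid step
#'
#' Finds the period `zeta*` minimizing the probability-weighted variance of
#' the circularly transformed spectrum, by a dense scan over the search
#' interval followed by local refinement. This per-spectrum optimization takes
#' noticeably longer than the closed-form [universal_zeta()] and is intended
#' for validation and for refitting the universal grid-step model.
#'
#' @param spectrum Tibble with `mass` and `prob` (or `intensity`) columns and
#'   at least two peaks.
#' @param search Numeric length-2 search interval in Da.
#' @param n_grid Number of scan points across the interval.
#' @param tol Absolute refinement tolerance on zeta, Da.
#' @return The optimal period `zeta*` in Da.
#' @export
optimal_zeta <- function(spectrum, search = c(0.998, 1.008), n_grid = 2001,
                         tol = 1e-7) {
  if (nrow(spectrum) < 2) {
    stop("optimal_zeta() needs at least two peaks; ",
         "the transformed variance of a single peak is identically zero",
         call. = FALSE)
  }
  w <- spectrum_weights(spectrum)
  w <- w / sum(w)
  zs <- seq(search[1], search[2], length.out = n_grid)
  vs <- vapply(zs, function(z) circular_variance(spectrum$mass, w, z), numeric(1))
  i <- which.min(vs)
  lo <- zs[max(1L, i - 1L)]
  hi <- zs[min(n_grid, i + 1L)]
  optimize(function(z) circular_variance(spectrum$mass, w, z),
           lower = lo, upper = hi, tol = tol)$minimum
}

#' Universal grid step from the average mass
#'
#' Closed-form inter-cluster spacing `gamma0 + gamma_avg * m_avg`. The slope
#' is tiny (~7e-10 per Da), so measurement error on the average mass has a
#' negligible effect, and the experimental average mass can be used directly.
#'
#' @param m_avg Average mass in Da.
#' @param coef Coefficient bundle, see [mono_coefficients()].
#' @return Grid step in Da.
#' @export
#' @examples
#' universal_zeta(16951.5)
universal_zeta <- function(m_avg, coef = default_coefficients()) {
  coef$gamma0 + coef$gamma_avg * m_avg
}

#' Grid shift from the circular mean of a spectrum
#'
#' Estimates the grid phase as `(zeta / 2 pi) * Arg(sum_p prob *
#' exp(2 pi i mass / zeta))`, canonicalized into `[-zeta/2, zeta/2)`. This is
#' the closed-form minimizer of the probability-weighted squared circular
#' distance between peaks and grid nodes.
#'
#' @inheritParams circular_transform
#' @return Grid shift in Da.
#' @export
estimate_delta <- function(spectrum, zeta) {
  if (zeta <= 0) {
    stop("zeta must be positive", call. = FALSE)
  }
  w <- spectrum_weights(spectrum)
  w <- w / sum(w)
  z <- sum(w * exp(2i * pi * spectrum$mass / zeta))
  if (Mod(z) < 1e-12) {
    stop("grid shift is indeterminate: peak angles are uniformly spread",
         call. = FALSE)
  }
  canonical_delta(Arg(z) * zeta / (2 * pi), zeta)
}

canonical_delta <- function(delta, zeta) {
  delta <- delta - zeta * floor(delta / zeta + 0.5)
  if (delta >= zeta / 2) delta - zeta else delta
}

#' Round a mass to the nearest grid node, with relative correction
#'
#' Snaps `m_hat` to the nearest node of the grid `{delta + k * zeta}` (ties
#' broken toward lower mass: the monoisotopic variant is the lightest), then
#' applies the correction `lambda` for the slight widening of inter-cluster
#' spacing in the envelope's left tail.
#'
#' @param m_hat Mass to round, Da.
#' @param zeta Grid step, Da.
#' @param delta Grid shift, Da.
#' @param lambda Correction term (dimensionless for the default relative
#'   mode).
#' @param lambda_mode `"relative"` multiplies the selected node by
#'   `1 + lambda`; `"absolute"` adds `lambda` Da to it.
#' @return Corrected grid node, Da.
#' @export
#' @examples
#' round_to_grid(100.6, zeta = 1, delta = 0.9) # 100.9
round_to_grid <- function(m_hat, zeta, delta, lambda = 0,
                          lambda_mode = c("relative", "absolute")) {
  lambda_mode <- match.arg(lambda_mode)
  r <- (m_hat - delta) / zeta
  k <- floor(r + 0.5)
  k <- ifelse(r + 0.5 == k, k - 1, k) # exact tie: take the lower node
  node <- delta + k * zeta
  if (lambda_mode == "relative") node * (1 + lambda) else node + lambda
}
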