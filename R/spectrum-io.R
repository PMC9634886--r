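#' Read a centroided peak list
#'
#' Reads a two-column plain-text peak list (whitespace- or comma-separated;
#' position then intensity). Peaks are sorted by position and zero-intensity
#' rows are dropped.
#'
#' @param path Path to the peak list.
#' @param axis `"dalton"` if positions are neutral masses, `"mz"` if they are
#'   mass-to-charge ratios. With `axis = "mz"`, pass the charge to
#'   [to_dalton()] before prediction.
#' @param min_rel_intensity Optional noise filter: drop peaks below this
#'   fraction of the maximum intensity (default 0, off).
#' @return A tibble with columns `mass` (axis `"dalton"`) or `mz` (axis
#'   `"mz"`), and `intensity`.
#' @export
read_peaklist <- function(path, axis = c("dalton", "mz"), min_rel_intensity = 0) {
  axis <- match.arg(axis)
  tab <- tryCatch(
    read_plain_table(path, c("position", "intensity")),
    error = function(e) stop("unparseable peak list: ", conditionMessage(e), call. = FALSE)
  )
  if (ncol(tab) < 2 || !is.numeric(tab$position) || !is.numeric(tab$intensity)) {
    stop("peak list must have two numeric columns (position, intensity)", call. = FALSE)
  }
  tab <- dplyr::filter(tab, .data$intensity > 0)
  if (nrow(tab) == 0) {
    stop("peak list has no positive intensities", call. = FALSE)
  }
  tab <- dplyr::arrange(tab, .data$position)
  if (min_rel_intensity > 0) {
    tab <- dplyr::filter(tab, .data$intensity >= min_rel_intensity * max(.data$intensity))
  }
  names(tab)[1] <- if (axis == "mz") "mz" else "mass"
  tibble::as_tibble(tab)
}

#' Read one scan from an mzML/mzXML container
#'
#' Thin adapter over the `mzR` Bioconductor parser for standard mass-spec XML
#' containers; returns the same shape as [read_peaklist()].
#'
#' @param path Path to an mzML/mzXML file.
#' @param scan Scan number to extract.
#' @inheritParams read_peaklist
#' @return A tibble with columns `mz` (or `mass`) and `intensity`.
#' @export
read_mzml <- function(path, scan = 1L, axis = c("mz", "dalton")) {
  axis <- match.arg(axis)
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package", call. = FALSE)
  }
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  pk <- mzR::peaks(ms, scan)
  tab <- tibble::tibble(position = pk[, 1], intensity = pk[, 2])
  tab <- dplyr::arrange(dplyr::filter(tab, .data$intensity > 0), .data$position)
  if (nrow(tab) == 0) {
    stop("scan has no positive intensities", call. = FALSE)
  }
  names(tab)[1] <- if (axis == "mz") "mz" else "mass"
  tab
}

#' Convert an m/z spectrum to the neutral dalton scale
#'
#' Maps each position to `(mz - m_proton) * z` assuming positive-ion mode
#' (proton mass 1.007276 Da). Spectra already on the dalton axis (a `mass`
#' column) pass through unchanged.
#'
#' @param spectrum Tibble with `mz` (or `mass`) and `intensity` columns.
#' @param charge Positive integer charge state; required for m/z input.
#' @return Tibble with columns `mass` and `intensity`.
#' @export
#' @examples
#' to_dalton(tibble::tibble(mz = 1000, intensity = 1), charge = 1)
to_dalton <- function(spectrum, charge = NULL) {
  if ("mass" %in% names(spectrum)) {
    return(dplyr::arrange(spectrum, .data$mass))
  }
  if (!"mz" %in% names(spectrum)) {
    stop("spectrum must have an 'mz' or 'mass' column", call. = FALSE)
  }
  if (is.null(charge) || length(charge) != 1 || is.na(charge) || charge < 1) {
    stop("a positive integer charge is required to convert m/z to daltons",
         call. = FALSE)
  }
  out <- dplyr::mutate(spectrum, mass = (.data$mz - PROTON_MASS) * charge)
  dplyr::arrange(dplyr::select(out, "mass", dplyr::everything(), -"mz"), .data$mass)
}

#' Normalize a spectrum to a probability distribution
#'
#' @param spectrum Tibble with `mass` and `intensity` (or `prob`) columns.
#' @return Tibble with columns `mass` and `prob`, probabilities summing to 1.
#' @export
normalize_spectrum <- function(spectrum) {
  w <- spectrum_weights(spectrum)
  total <- sum(w)
  if (!is.finite(total) || total <= 0) {
    stop("cannot normalize a spectrum with zero total intensity", call. = FALSE)
  }
  tibble::tibble(mass = spectrum$mass, prob = w / total)
}

#' Mean and variance of a normalized spectrum
#'
#' Probability-weighted mean and central second moment of the peak masses.
#' Weights are renormalized internally, so trimmed spectra (summed probability
#' below 1) are handled consistently.
#'
#' @param spectrum Tibble with `mass` and `prob` (or `intensity`) columns.
#' @return One-row tibble with columns `m_avg` (Da) and `m_var` (Da^2).
#' @export
spectrum_moments <- function(spectrum) {
  if (nrow(spectrum) == 0) {
    stop("empty spectrum", call. = FALSE)
  }
  w <- spectrum_weights(spectrum)
  w <- w / sum(w)
  m <- sum(w * spectrum$mass)
  tibble::tibble(m_avg = m, m_var = sum(w * (spectrum$mass - m)^2))
}

#' First-order Wasserstein distance between two normalized spectra
#'
#' Treats both spectra as discrete probability distributions on the mass axis
#' and integrates the absolute difference of their cumulative distribution
#' functions over the merged support (O(n log n)).
#'
#' @param a,b Tibbles with `mass` and `prob` columns, each summing to 1.
#' @param tol Tolerance for the normalization check.
#' @return Non-negative distance in Da; 0 iff the distributions coincide.
#' @export
#' @examples
#' a <- tibble::tibble(mass = c(0, 1), prob = c(0.5, 0.5))
#' b <- tibble::tibble(mass = 0, prob = 1)
#' wasserstein_distance(a, b) # 0.5
wasserstein_distance <- function(a, b, tol = 1e-6) {
  for (s in list(a, b)) {
    if (nrow(s) == 0) stop("empty spectrum", call. = FALSE)
    if (abs(sum(s$prob) - 1) > tol) {
      stop("wasserstein_distance() expects normalized spectra; ",
           "see normalize_spectrum()", call. = FALSE)
    }
  }
  grid <- sort(unique(c(a$mass, b$mass)))
  cdf_at <- function(s) {
    o <- order(s$mass)
    c(0, cumsum(s$prob[o]))[findInterval(grid, s$mass[o]) + 1L]
  }
  ca <- cdf_at(a)
  cb <- cdf_at(b)
  n <- length(grid)
  if (n == 1) {
    return(0)
  }
  sum(abs(ca[-n] - cb[-n]) * diff(grid))
}
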