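#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write deterministic fixture spectra
#'
#' Generates small peak-list files for testing and demos: a periodic comb
#' (known grid step and shift), a noiseless theoretical protein spectrum, or
#' the same spectrum with 5% multiplicative intensity noise and 2 ppm mass
#' jitter. Identical seeds give byte-identical files.
#'
#' @param kind `"comb"`, `"protein"` or `"noisy-protein"`.
#' @param path Output file path (two-column whitespace text).
#' @param seed Integer seed.
#' @param mass Target average mass for the protein kinds, Da; for the comb,
#'   the approximate centre of the peak positions.
#' @param zeta,delta Comb period and phase, Da.
#' @param n_peaks Number of comb peaks.
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- make_fixture("comb", tempfile())
#' read_peaklist(f)
make_fixture <- function(kind = c("comb", "protein", "noisy-protein"),
                         path, seed = 1, mass = 16940, zeta = 1.0023,
                         delta = 0.3, n_peaks = 15) {
  kind <- match.arg(kind)
  sp <- switch(kind,
    comb = {
      ks <- seq_len(n_peaks) + round(mass / zeta)
      centre <- mean(ks)
      tibble::tibble(mass = delta + ks * zeta,
                     intensity = exp(-0.5 * ((ks - centre) / (n_peaks / 4))^2))
    },
    protein = {
      prot <- generate_protein(mass, seed = seed)
      sp <- aggregated_spectrum(prot$formula[[1]], coverage = 0.99)
      tibble::tibble(mass = sp$mass, intensity = sp$prob)
    },
    `noisy-protein` = {
      prot <- generate_protein(mass, seed = seed)
      sp <- aggregated_spectrum(prot$formula[[1]], coverage = 0.99)
      perturb_spectrum(sp, intensity_cv = 0.05, mass_ppm = 2, seed = seed + 1)
    }
  )
  writeLines(sprintf("%.9f %.9g", sp$mass, sp$intensity), path)
  invisible(path)
}
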