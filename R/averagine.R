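#' Averagine model: fractional residue unit plus variance direction
#'
#' An averagine is a hypothetical average amino-acid residue with fractional
#' CHNOS composition; scaled up it approximates any protein's composition
#' from its mass alone. The default unit takes Senko's classic residue ratios
#' rescaled uniformly so the unit average mass equals 110.4728 Da under the
#' pinned isotope table; supply `unit` to use a re-derived composition (see
#' [averagine_from_fasta()]).
#'
#' The model also carries the variance-adjustment direction: the unique unit
#' vector in CHNOS space along which a formula's spectral variance changes as
#' fast as possible while its average mass stays constant (see
#' [derive_variance_direction()]).
#'
#' @param unit Optional fractional `chem_formula` for one residue.
#' @param unit_avg_mass Target average mass of the unit, Da. Ignored when
#'   `unit` is supplied.
#' @param isotopes Isotope table.
#' @return An object of class `averagine_model` with fields `unit`,
#'   `unit_avg_mass` and `direction`.
#' @export
#' @examples
#' averagine_model()
averagine_model <- function(unit = NULL, unit_avg_mass = AVERAGINE_UNIT_MASS,
                            isotopes = isotope_table()) {
  if (is.null(unit)) {
    raw <- chem_formula(SENKO_UNIT)
    unit <- chem_formula(unclass(raw) * unit_avg_mass / average_mass(raw, isotopes))
  } else {
    unit <- check_formula(unit)
    unit_avg_mass <- average_mass(unit, isotopes)
  }
  structure(list(unit = unit,
                 unit_avg_mass = average_mass(unit, isotopes),
                 direction = derive_variance_direction(isotopes)),
            class = "averagine_model")
}

#' @export
print.averagine_model <- function(x, ...) {
  cat("<averagine_model>\n  unit: ",
      paste(sprintf("%s %.4f", names(x$unit), unclass(x$unit)), collapse = ", "),
      sprintf("\n  unit average mass: %.4f Da\n", x$unit_avg_mass),
      "  variance direction: ",
      paste(sprintf("%s %+.4f", names(x$direction), x$direction), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Fastest variance-changing, mass-preserving direction in formula space
#'
#' In the 5-dimensional space of CHNOS formulas, the gradient of the spectral
#' variance is the vector of per-atom isotopic mass variances, and the
#' gradient of the average mass is the vector of per-element mean masses.
#' Projecting the former orthogonally to the latter (then normalizing) yields
#' the direction that maximizes the first-order change of variance subject to
#' zero change of average mass. Sulfur dominates this direction: it has by
#' far the largest per-atom isotopic variance.
#'
#' @param isotopes Isotope table.
#' @return Named unit-norm numeric 5-vector over C, H, N, O, S, orthogonal to
#'   the per-element average-mass vector.
#' @export
derive_variance_direction <- function(isotopes = isotope_table()) {
  els <- iso_elements(isotopes)
  nm <- c("C", "H", "N", "O", "S")
  v <- vapply(nm, function(e) els[[e]]$var, numeric(1))
  mbar <- vapply(nm, function(e) els[[e]]$mean, numeric(1))
  d <- v - sum(v * mbar) / sum(mbar * mbar) * mbar
  if (sqrt(sum(d^2)) < 1e-12) {
    stop("variance gradient is parallel to the mass gradient; ",
         "direction is degenerate", call. = FALSE)
  }
  d / sqrt(sum(d^2))
}

#' Scale an averagine to a target average mass
#'
#' Takes `n = target_avg / unit_avg_mass` averagine units, optionally
#' displaces the fractional formula by `rho` along the variance-adjustment
#' direction (before rounding), clips negative entries at zero, rounds to
#' integers, and finally adds or removes hydrogens to bring the average mass
#' back within half a hydrogen average mass of the target.
#'
#' @param target_avg Target average mass, Da; at least one unit mass.
#' @param model An [averagine_model()].
#' @param rho Variance-adjustment multiplier (0 = plain Senko-style scaling).
#' @param isotopes Isotope table.
#' @return Integral `chem_formula`.
#' @export
#' @examples
#' scale_averagine(11047.28, averagine_model())
scale_averagine <- function(target_avg, model = averagine_model(), rho = 0,
                            isotopes = isotope_table()) {
  if (target_avg < model$unit_avg_mass) {
    stop("target average mass is below one averagine unit", call. = FALSE)
  }
  n <- target_avg / model$unit_avg_mass
  frac <- n * unclass(model$unit) + rho * model$direction
  clipped <- sum(pmin(frac, 0))
  if (clipped < -0.5 * sqrt(sum((rho * model$direction)^2)) - 1) {
    stop("rho displaces the formula far outside the positive orthant",
         call. = FALSE)
  }
  f <- round(pmax(frac, 0))
  f <- chem_formula(setNames(f, names(model$unit)))
  h_avg <- iso_elements(isotopes)[["H"]]$mean
  f[["H"]] <- max(0, f[["H"]] + round((target_avg - average_mass(f, isotopes)) / h_avg))
  chem_formula(unclass(f))
}

# Residue (amino acid minus water) elemental compositions.
RESIDUE_COMPOSITION <- list(
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0), K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),  W = c(C = 11, H = 10, N = 2, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),  V = c(C = 5, H = 9, N = 1, O = 1, S = 0)
)

#' Derive an averagine unit from protein sequences
#'
#' Computes the residue-frequency-weighted mean elemental composition over
#' all sequences in a protein FASTA file (a chain contributes its residues;
#' the terminal water is spread across the chain's residues), yielding a
#' fractional averagine unit specific to that sequence collection.
#'
#' @param path Path to a protein FASTA file.
#' @return Fractional `chem_formula` for one average residue.
#' @export
averagine_from_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("averagine_from_fasta() requires the 'Biostrings' package", call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) {
    stop("no sequences in FASTA file", call. = FALSE)
  }
  counts <- setNames(numeric(5), c("C", "H", "N", "O", "S"))
  n_res <- 0
  for (i in seq_along(seqs)) {
    aa <- strsplit(as.character(seqs[[i]]), "")[[1]]
    aa <- aa[aa %in% names(RESIDUE_COMPOSITION)]
    if (length(aa) == 0) next
    for (r in aa) counts <- counts + RESIDUE_COMPOSITION[[r]]
    counts <- counts + c(C = 0, H = 2, N = 0, O = 1, S = 0) # terminal water
    n_res <- n_res + length(aa)
  }
  if (n_res == 0) {
    stop("no standard amino-acid residues found", call. = FALSE)
  }
  chem_formula(counts / n_res)
}
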