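#' Parse a chemical formula over C, H, N, O and S
#'
#' Accepts Hill-like element+count strings such as `"C254H377N65O75S6"`.
#' An omitted count means one atom. Repeated element symbols are summed.
#'
#' @param text Formula string.
#' @return A named numeric vector of atom counts (class `chem_formula`),
#'   always carrying all five elements in C, H, N, O, S order.
#' @export
#' @examples
#' parse_formula("C254H377N65O75S6")
#' parse_formula("CH4")
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", text)) {
    stop("malformed chemical formula: '", text, "'", call. = FALSE)
  }
  m <- stringr::str_match_all(text, "([A-Z][a-z]?)([0-9]*)")[[1]]
  els <- m[, 2]
  bad <- setdiff(els, c("C", "H", "N", "O", "S"))
  if (length(bad) > 0) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         " (only C, H, N, O, S are supported)", call. = FALSE)
  }
  counts <- as.numeric(ifelse(m[, 3] == "", "1", m[, 3]))
  chem_formula(tapply(counts, factor(els, levels = c("C", "H", "N", "O", "S")),
                      sum, default = 0))
}

#' Construct a chemical formula from atom counts
#'
#' @param counts Named numeric vector or list of non-negative atom counts over
#'   C, H, N, O, S. Fractional counts are allowed (averagine arithmetic);
#'   operations that simulate spectra require integral counts.
#' @return Named numeric vector of length 5, class `chem_formula`.
#' @export
chem_formula <- function(counts) {
  counts <- unlist(counts)
  bad <- setdiff(names(counts), c("C", "H", "N", "O", "S"))
  if (length(bad) > 0) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- setNames(numeric(5), c("C", "H", "N", "O", "S"))
  out[names(counts)] <- as.numeric(counts)
  if (any(is.na(out)) || any(out < 0)) {
    stop("atom counts must be non-negative numbers", call. = FALSE)
  }
  structure(out, class = "chem_formula")
}

#' @export
format.chem_formula <- function(x, ...) {
  nz <- x[x > 0]
  if (length(nz) == 0) {
    return("")
  }
  paste0(names(nz), ifelse(nz == 1, "", format(unclass(nz), trim = TRUE, scientific = FALSE)),
         collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

is_integral_formula <- function(f, tol = 1e-9) {
  all(abs(f - round(f)) <= tol)
}

check_formula <- function(f) {
  if (!inherits(f, "chem_formula")) {
    f <- chem_formula(f)
  }
  if (sum(f) <= 0) {
    stop("empty chemical formula", call. = FALSE)
  }
  f
}

#' Monoisotopic, average mass and spectral variance of a formula
#'
#' Closed-form moments of a molecule's isotopologue mass distribution, using
#' the pinned isotope table. The monoisotopic mass sums the lightest isotope
#' per element; the average mass sums abundance-weighted mean isotope masses;
#' the spectral variance sums per-atom isotopic mass variances (atoms are
#' independent, so variances add).
#'
#' @param formula A `chem_formula`, a formula string, or a list of either
#'   (vectorized over lists).
#' @param isotopes Isotope table, see [isotope_table()].
#' @return Numeric vector of masses (Da) or variances (Da^2).
#' @export
#' @examples
#' monoisotopic_mass("C254H377N65O75S6") # bovine insulin, 5729.60 Da
#' average_mass("C254H377N65O75S6")
#' spectrum_variance("C100")
monoisotopic_mass <- function(formula, isotopes = isotope_table()) {
  formula_moment(formula, isotopes, "mono")
}

#' @rdname monoisotopic_mass
#' @export
average_mass <- function(formula, isotopes = isotope_table()) {
  formula_moment(formula, isotopes, "mean")
}

#' @rdname monoisotopic_mass
#' @export
spectrum_variance <- function(formula, isotopes = isotope_table()) {
  formula_moment(formula, isotopes, "var")
}

formula_moment <- function(formula, isotopes, what) {
  els <- iso_elements(isotopes)
  one <- function(f) {
    if (is.character(f)) f <- parse_formula(f)
    f <- check_formula(f)
    per_atom <- vapply(names(f), function(e) els[[e]][[what]], numeric(1))
    sum(unclass(f) * per_atom)
  }
  if (is.list(formula) && !inherits(formula, "chem_formula")) {
    vapply(formula, one, numeric(1))
  } else {
    one(formula)
  }
}
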