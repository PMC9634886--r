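#' Predictor coefficient bundle
#'
#' Bundles the coefficients of the two linear models and the rounding
#' correction: the initial monoisotopic estimate
#' `beta0 + beta_avg * M_avg + beta_var * M_var`, the universal grid step
#' `gamma0 + gamma_avg * M_avg`, and the relative correction `lambda` applied
#' to the selected grid node. The defaults are the published values from
#' training on ~1.9 million protein spectra (8-400 kDa); [refit_initial_model()],
#' [refit_grid_model()] and [calibrate_lambda()] produce replacements from a
#' synthetic proteome.
#'
#' @param beta0 Intercept of the initial estimate, Da.
#' @param beta_avg Coefficient on the average mass (dimensionless).
#' @param beta_var Coefficient on the spectral variance, 1/Da.
#' @param gamma0 Grid-step intercept, Da.
#' @param gamma_avg Grid-step slope per Da of average mass.
#' @param lambda Relative rounding correction (dimensionless).
#' @return An object of class `mono_coefficients`.
#' @export
#' @examples
#' default_coefficients()
mono_coefficients <- function(beta0 = -0.14557, beta_avg = 0.99978,
                              beta_var = -0.59817, gamma0 = 1.002355,
                              gamma_avg = 6.9584e-10, lambda = -1.1982e-7) {
  stopifnot(beta_avg > 0.99, beta_avg < 1.01, gamma0 > 0.99, gamma0 < 1.02)
  structure(list(beta0 = beta0, beta_avg = beta_avg, beta_var = beta_var,
                 gamma0 = gamma0, gamma_avg = gamma_avg, lambda = lambda),
            class = "mono_coefficients")
}

#' @rdname mono_coefficients
#' @export
default_coefficients <- function() {
  mono_coefficients()
}

#' @export
print.mono_coefficients <- function(x, ...) {
  cat("<mono_coefficients>\n")
  cat(sprintf("  initial estimate: %.5f + %.5f * M_avg + %.5f * M_var\n",
              x$beta0, x$beta_avg, x$beta_var))
  cat(sprintf("  grid step:        %.6f + %.4e * M_avg\n", x$gamma0, x$gamma_avg))
  cat(sprintf("  node correction:  lambda = %.4e (relative)\n", x$lambda))
  invisible(x)
}

#' @export
tidy.mono_coefficients <- function(x, ...) {
  tibble::tibble(term = names(unclass(x)), estimate = unlist(unclass(x)))
}

#' Read and write coefficient bundles as flat key=value text
#'
#' @param coef A [mono_coefficients()] bundle.
#' @param path File path.
#' @return `read_coefficients()` returns a `mono_coefficients` bundle;
#'   `write_coefficients()` returns `path` invisibly.
#' @export
write_coefficients <- function(coef, path) {
  vals <- unclass(coef)
  writeLines(sprintf("%s = %.17g", names(vals), unlist(vals)), path)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  kv <- read_config(path)
  do.call(mono_coefficients, lapply(kv, as.numeric))
}

# Flat key = value parser (numbers parsed, everything else kept as string).
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- stringr::str_match(lines, "^\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*?)\\s*$")
  if (anyNA(parts[, 1])) {
    stop("malformed config line(s): ", paste(lines[is.na(parts[, 1])], collapse = "; "),
         call. = FALSE)
  }
  setNames(as.list(parts[, 3]), parts[, 2])
}
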