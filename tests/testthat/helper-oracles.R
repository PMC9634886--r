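# Independent oracles and small generators used across the suite.

# Exhaustive enumeration of all isotopologue combinations of a tiny formula
# (every atom assigned independently to one isotope), aggregated by total
# extra nucleon count. Exponential in atom count; use for <= 8 atoms only.
brute_force_spectrum <- function(formula, isotopes = isotope_table()) {
  tab <- split(isotopes, isotopes$element)
  atoms <- rep(names(formula), times = as.integer(unclass(formula)))
  stopifnot(length(atoms) <= 8)
  choices <- lapply(atoms, function(e) seq_len(nrow(tab[[e]])))
  combos <- expand.grid(choices)
  probs <- numeric(nrow(combos))
  masses <- numeric(nrow(combos))
  nucleons <- integer(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    p <- 1
    m <- 0
    nn <- 0L
    for (j in seq_along(atoms)) {
      iso <- tab[[atoms[j]]][combos[i, j], ]
      p <- p * iso$abundance
      m <- m + iso$mass
      nn <- nn + as.integer(round(iso$mass - tab[[atoms[j]]]$mass[1]))
    }
    probs[i] <- p
    masses[i] <- m
    nucleons[i] <- nn
  }
  agg <- lapply(split(seq_along(probs), nucleons), function(idx) {
    tibble::tibble(mass = sum(probs[idx] * masses[idx]) / sum(probs[idx]),
                   prob = sum(probs[idx]))
  })
  out <- dplyr::arrange(dplyr::bind_rows(agg), mass)
  out
}

# Random small integral formula with at least `min_atoms` atoms.
random_formula <- function(max_per_element = 30, min_atoms = 2) {
  repeat {
    f <- chem_formula(setNames(sample(0:max_per_element, 5, replace = TRUE),
                               c("C", "H", "N", "O", "S")))
    if (sum(f) >= min_atoms) {
      return(f)
    }
  }
}

# Periodic comb spectrum on the grid {delta + k * zeta} with a smooth
# intensity profile.
comb_spectrum <- function(zeta = 1.0023, delta = 0.3, k0 = 10000, n = 15) {
  ks <- k0 + seq_len(n)
  tibble::tibble(mass = delta + ks * zeta,
                 prob = exp(-0.5 * ((seq_len(n) - (n + 1) / 2) / (n / 4))^2)) |>
    normalize_spectrum()
}

# Dense-scan minimizer of the probability-weighted squared distance between
# peaks and the grid {delta + k * zeta}; independent oracle for the
# complex-mean grid-shift estimator.
brute_force_delta <- function(sp, zeta) {
  obj <- function(d) {
    r <- (sp$mass - d) / zeta
    resid <- (r - round(r)) * zeta
    sum(sp$prob * resid^2)
  }
  ds <- seq(-zeta / 2, zeta / 2, length.out = 4001)
  best <- ds[which.min(vapply(ds, obj, numeric(1)))]
  optimize(obj, lower = best - 5e-4, upper = best + 5e-4, tol = 1e-10)$minimum
}

expect_spectrum_valid <- function(sp) {
  w <- sp[[intersect(c("prob", "intensity"), names(sp))[1]]]
  expect_true(all(diff(sp$mass) > 0))
  expect_true(all(w > 0))
}
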