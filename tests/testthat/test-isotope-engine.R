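test_that("formula parsing handles counts, implicit ones, and bad input", {
  expect_equal(unclass(parse_formula("C254H377N65O75S6"))[c("C", "H", "N", "O", "S")],
               c(C = 254, H = 377, N = 65, O = 75, S = 6))
  expect_equal(unclass(parse_formula("CH4"))[c("C", "H")], c(C = 1, H = 4))
  expect_error(parse_formula("C2X5"), "unknown element")
  expect_error(parse_formula("12C4"), "malformed")
  # round trip through formatting
  for (txt in c("C254H377N65O75S6", "CH4", "C2S3")) {
    expect_identical(format(parse_formula(txt)), txt)
  }
})

test_that("monoisotopic masses reproduce the reference protein values", {
  expect_equal(monoisotopic_mass("C254H377N65O75S6"), 5729.60, tolerance = 0.01 / 5729.60)
  expect_equal(monoisotopic_mass("C769H1212N210O218S2"), 16940.97, tolerance = 0.01 / 16940.97)
  h <- isotope_table()[isotope_table()$element == "H", ]
  expect_equal(monoisotopic_mass(chem_formula(c(H = 1))), h$mass[1])
  expect_error(monoisotopic_mass(chem_formula(c(C = 0))), "empty")
})

test_that("average mass is the abundance-weighted mean, additive in counts", {
  tab <- isotope_table()
  c_iso <- tab[tab$element == "C", ]
  expect_equal(average_mass(chem_formula(c(C = 1))),
               sum(c_iso$mass * c_iso$abundance), tolerance = 1e-12)
  expect_equal(average_mass(chem_formula(c(C = 1))), 12.0107, tolerance = 1e-3 / 12)
  h_iso <- tab[tab$element == "H", ]
  expect_equal(average_mass(chem_formula(c(H = 2))),
               2 * sum(h_iso$mass * h_iso$abundance), tolerance = 1e-12)
  # the pinned table reproduces the insulin literature average to ~0.1 Da;
  # the residual reflects the atomic-weight revision used by the source
  expect_equal(average_mass("C254H377N65O75S6"), 5733.58, tolerance = 0.1 / 5733.58)
})

test_that("spectral variance matches the two-point hand computation and is additive", {
  tab <- isotope_table()
  c_iso <- tab[tab$element == "C", ]
  mbar <- sum(c_iso$mass * c_iso$abundance)
  hand <- sum(c_iso$abundance * (c_iso$mass - mbar)^2)
  expect_equal(spectrum_variance(chem_formula(c(C = 1))), hand, tolerance = 1e-12)
  expect_equal(spectrum_variance(chem_formula(c(C = 100))), 100 * hand, tolerance = 1e-12)
})

test_that("aggregated spectrum matches exhaustive enumeration on tiny formulas", {
  h_iso <- isotope_table()[isotope_table()$element == "H", ]
  sp <- aggregated_spectrum(chem_formula(c(H = 2)), coverage = 1, prune = 0)
  pH <- h_iso$abundance[1]
  pD <- h_iso$abundance[2]
  expect_equal(sp$prob, c(pH^2, 2 * pH * pD, pD^2), tolerance = 1e-14)
  expect_equal(round(sp$mass), c(2, 3, 4))

  sp1 <- aggregated_spectrum(chem_formula(c(C = 1)), coverage = 1, prune = 0)
  c_iso <- isotope_table()[isotope_table()$element == "C", ]
  expect_equal(sp1$prob, c_iso$abundance, tolerance = 1e-15)
  expect_equal(sp1$mass, c_iso$mass, tolerance = 1e-12)

  set.seed(42)
  for (i in 1:12) {
    f <- random_formula(max_per_element = 2, min_atoms = 2)
    while (sum(f) > 8) f <- random_formula(max_per_element = 2, min_atoms = 2)
    ours <- aggregated_spectrum(f, coverage = 1, prune = 0)
    oracle <- brute_force_spectrum(f)
    expect_equal(nrow(ours), nrow(oracle))
    expect_equal(ours$prob, oracle$prob, tolerance = 1e-12)
    expect_equal(ours$mass, oracle$mass, tolerance = 1e-9)
  }
})

test_that("spectrum moments agree with the closed forms on random formulas", {
  set.seed(7)
  for (i in 1:100) {
    f <- random_formula(max_per_element = 60, min_atoms = 5)
    sp <- aggregated_spectrum(f, coverage = 1)
    mom <- spectrum_moments(sp)
    expect_equal(mom$m_avg, average_mass(f), tolerance = 1e-4 / mom$m_avg)
    # aggregation to cluster centroids discards the (tiny) within-cluster
    # fine-structure variance, so the empirical value sits just below the
    # closed form
    expect_lte(spectrum_variance(f) - mom$m_var, 1e-4)
    expect_gte(spectrum_variance(f) - mom$m_var, 0)
  }
})

test_that("coverage trimming is monotone and keeps the stated probability", {
  f <- parse_formula("C254H377N65O75S6")
  lo <- aggregated_spectrum(f, coverage = 0.9)
  hi <- aggregated_spectrum(f, coverage = 0.999)
  expect_true(all(lo$mass %in% hi$mass))
  expect_gte(sum(lo$prob), 0.9)
  expect_gte(sum(hi$prob), 0.999)
  expect_lte(sum(hi$prob), 1)
  expect_error(aggregated_spectrum(f, coverage = 0), "coverage")
  expect_error(aggregated_spectrum(chem_formula(c(C = 2.5))), "integral")
})

test_that("spectra of summed formulas equal convolutions of spectra", {
  f1 <- chem_formula(c(C = 3, S = 1))
  f2 <- chem_formula(c(H = 4, O = 2))
  sp12 <- aggregated_spectrum(chem_formula(unclass(f1) + unclass(f2)),
                              coverage = 1, prune = 0)
  a <- brute_force_spectrum(f1)
  b <- brute_force_spectrum(f2)
  conv <- dplyr::bind_rows(lapply(seq_len(nrow(a)), function(i) {
    tibble::tibble(nn = round(a$mass[i]) + round(b$mass),
                   prob = a$prob[i] * b$prob,
                   wmass = (a$mass[i] + b$mass) * a$prob[i] * b$prob)
  }))
  conv <- dplyr::summarise(dplyr::group_by(conv, .data$nn),
                           mass = sum(.data$wmass) / sum(.data$prob),
                           prob = sum(.data$prob), .groups = "drop")
  conv <- dplyr::arrange(conv, .data$mass)
  expect_equal(sp12$prob, conv$prob, tolerance = 1e-12)
  expect_equal(sp12$mass, conv$mass, tolerance = 1e-9)
})

test_that("most abundant peak takes the argmax, ties toward lower mass", {
  sp <- tibble::tibble(mass = c(100, 101, 102), prob = c(0.2, 0.5, 0.3))
  expect_equal(most_abundant_peak(sp)$mass, 101)
  tie <- tibble::tibble(mass = c(100, 101), prob = c(0.5, 0.5))
  expect_equal(most_abundant_peak(tie)$mass, 100)
  expect_error(most_abundant_peak(tie[0, ]), "empty")

  # for intact proteins the mode sits a few clusters above the monoisotopic peak
  insulin <- parse_formula("C254H377N65O75S6")
  sp <- aggregated_spectrum(insulin, coverage = 0.9999)
  gap <- most_abundant_peak(sp)$mass - monoisotopic_mass(insulin)
  expect_gte(gap, 3)
  expect_lte(gap, 4)
})
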