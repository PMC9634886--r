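test_that("circular transform collapses periodic peaks and centres means", {
  # a single peak is its own circular mean
  one <- normalize_spectrum(tibble::tibble(mass = 1234.5678, intensity = 1))
  expect_equal(circular_transform(one, 1.0023)$position, 0, tolerance = 1e-12)

  # peaks exactly one period apart collapse to the same point
  two <- normalize_spectrum(tibble::tibble(mass = c(100, 100 + 1.0023),
                                           intensity = c(1, 1)))
  pos <- circular_transform(two, 1.0023)$position
  expect_equal(pos, c(0, 0), tolerance = 1e-9)

  # equal peaks half a period apart sit at +/- zeta/4
  half <- normalize_spectrum(tibble::tibble(mass = c(100, 100.5), intensity = c(1, 1)))
  pos <- sort(circular_transform(half, 1)$position)
  expect_equal(pos, c(-0.25, 0.25), tolerance = 1e-9)

  expect_error(circular_transform(two, -1), "positive")
})

test_that("optimal zeta recovers the period of synthetic combs", {
  comb <- comb_spectrum(zeta = 1.0023, delta = 0.3)
  z <- optimal_zeta(comb)
  expect_equal(z, 1.0023, tolerance = 1e-5 / 1.0023)

  # local optimality at the minimum
  w <- comb$prob
  v0 <- monoiso:::circular_variance(comb$mass, w, z)
  expect_lte(v0, monoiso:::circular_variance(comb$mass, w, z + 0.001))
  expect_lte(v0, monoiso:::circular_variance(comb$mass, w, z - 0.001))

  expect_error(optimal_zeta(comb[1, ]), "at least two")

  # robust to small multiplicative jitter (low-mass comb, so the absolute
  # perturbation stays well below the period)
  set.seed(2)
  for (i in 1:5) {
    zeta <- runif(1, 1.000, 1.005)
    comb <- comb_spectrum(zeta = zeta, delta = runif(1, 0, 1), k0 = 0)
    jittered <- dplyr::mutate(comb, mass = mass * (1 + runif(dplyr::n(), -1e-4, 1e-4)))
    expect_equal(optimal_zeta(jittered), zeta, tolerance = 1e-4 / zeta)
  }
})

test_that("optimal zeta on a protein spectrum sits in the universal band", {
  prot <- generate_protein(12000, seed = 21)
  sp <- aggregated_spectrum(prot$formula[[1]], coverage = 0.99)
  z <- optimal_zeta(sp)
  expect_gte(z, 1.0015)
  expect_lte(z, 1.0035)
})

test_that("universal zeta is the stated affine map of average mass", {
  co <- default_coefficients()
  expect_equal(universal_zeta(0), 1.002355)
  expect_equal(universal_zeta(1e9), co$gamma0 + 0.69584)
  expect_equal(universal_zeta(16951.5), 1.002355 + 6.9584e-10 * 16951.5)
})

test_that("grid shift from the complex mean matches brute-force minimization", {
  circ_diff <- function(a, b, zeta) {
    d <- (a - b) %% zeta
    min(d, zeta - d)
  }
  zeta <- 1.0023
  comb <- comb_spectrum(zeta = zeta, delta = 0.3)
  d <- estimate_delta(comb, zeta)
  expect_lte(circ_diff(d, 0.3, zeta), 1e-6)

  one <- normalize_spectrum(tibble::tibble(mass = 5432.1, intensity = 1))
  d1 <- estimate_delta(one, zeta)
  expect_lte(circ_diff(5432.1, d1, zeta), 1e-9)

  # peaks deviate from the lattice by the few-mDa irregularity seen in real
  # aggregated spectra; in this regime the two estimators coincide
  set.seed(9)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    sp <- normalize_spectrum(tibble::tibble(
      mass = sort(5000 + (1:n) * zeta + rnorm(n, 0, 0.002)),
      intensity = runif(n, 0.2, 1)))
    d_fast <- estimate_delta(sp, zeta)
    d_slow <- monoiso:::canonical_delta(brute_force_delta(sp, zeta), zeta)
    expect_lte(circ_diff(d_fast, d_slow, zeta), 1e-6)
  }
})

test_that("grid shift is equivariant under translation", {
  zeta <- 1.0024
  sp <- comb_spectrum(zeta = zeta, delta = 0.1)
  d0 <- estimate_delta(sp, zeta)
  for (shift in c(0.2, -0.37, 1.7)) {
    d1 <- estimate_delta(dplyr::mutate(sp, mass = mass + shift), zeta)
    diff <- (d1 - d0 - shift) %% zeta
    expect_true(min(diff, zeta - diff) < 1e-9)
  }
})

test_that("rounding snaps to the nearest node with ties toward lower mass", {
  expect_equal(round_to_grid(100.4, zeta = 1, delta = 0.9), 99.9) # exact tie
  expect_equal(round_to_grid(100.6, zeta = 1, delta = 0.9), 100.9)
  # relative correction scales with the node mass
  node <- 16940.97
  corrected <- round_to_grid(node, zeta = 1, delta = node %% 1, lambda = -1.1982e-7)
  expect_equal(corrected - node, -1.1982e-7 * node, tolerance = 1e-9)
  expect_equal(round_to_grid(10, 1, 0, lambda = 0.5, lambda_mode = "absolute"), 10.5)

  # rounding error bound
  set.seed(3)
  for (i in 1:50) {
    m <- runif(1, 1e3, 1e5)
    zeta <- runif(1, 0.999, 1.005)
    delta <- runif(1, -zeta / 2, zeta / 2)
    out <- round_to_grid(m, zeta, delta, lambda = -1.1982e-7)
    expect_lte(abs(out - m), zeta / 2 + 1.1982e-7 * m + 1e-9)
  }
})
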