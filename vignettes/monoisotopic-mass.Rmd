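---
title: "Monoisotopic mass from resolved isotopic envelopes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monoisotopic mass from resolved isotopic envelopes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monoiso)
```

## The problem

An intact protein's isotopic envelope is a set of ~1 Da-spaced aggregated
peaks; the monoisotopic variant itself is essentially never observed above a
few kDa. `monoiso` predicts its mass from the envelope in two steps: a
linear initial estimate from the spectrum's average mass and variance, and a
rounding step onto a lattice of plausible monoisotopic positions estimated
from the peak spacing. For experimental data a third, preliminary step fits
a simulated spectrum to the envelope so that the features feeding the linear
model are noise-free.

## The isotope table

All mass arithmetic rests on one embedded table of isotope masses and
abundances for C, H, N, O and S (`isotope_table()`): masses from the atomic
mass evaluation, abundances from the current IUPAC representative isotopic
composition (1.07% carbon-13). Every tolerance documented in the package
assumes this table, and `isotope_table(path)` swaps in a user table for
sensitivity analyses.

Two things are worth knowing about this choice. First, it reproduces
reference monoisotopic masses exactly (bovine insulin,
`C254H377N65O75S6`, comes out at 5729.60 Da). Second, *average* masses
quoted in older literature were computed with earlier atomic-weight tables
(carbon-13 closer to 1.10%); against such sources our computed averages can
differ by roughly 0.1 Da at insulin scale. Monoisotopic arithmetic is
unaffected — only the lightest isotopes enter it.

## Aggregated spectra

`aggregated_spectrum()` groups isotopologues by total nucleon count and
represents each cluster by its probability-weighted centroid. The
computation convolves per-element distributions (binary exponentiation over
atom counts) carrying a probability vector and a mass-moment vector, so
centroids are exact, not sampled. Numerical choices:

* edge states below `prune = 1e-12` relative probability are dropped during
  convolution; this keeps a 400 kDa protein at a few hundred states and a
  few milliseconds, and is far below every tolerance used elsewhere;
* `coverage` keeps the most probable peaks until their summed probability
  first reaches the requested value (whole clusters only); `coverage = 1`
  keeps everything that survived pruning;
* fractional (averagine) formulas must be rounded before simulation — the
  underlying multinomial model needs integer atom counts.

The working coverage throughout the package is **0.99**. This matters more
than it looks: trimming the envelope's tails reduces the measured spectral
variance by 7–9% relative to the closed-form value, and the shipped linear
coefficients were calibrated against *trimmed* moments. Feeding closed-form
(full) variances into the initial estimate produces a systematically low
prediction. `spectrum_moments()` therefore always computes moments of the
spectrum it is given, renormalizing the retained probability.

## The initial estimate and its calibrated range

`initial_estimate()` is the affine map `beta0 + beta_avg * M_avg +
beta_var * M_var` with shipped values `(-0.14557, 0.99978, -0.59817)`. Two
features cannot span the five degrees of freedom of CHNOS composition, so
the coefficients encode a compromise plane over the proteome they were
trained on — including its *mass distribution*, which concentrates well
below 100 kDa.

Our synthetic evaluation (`evaluate_predictor()`) makes the consequence
measurable: on averagine-like proteins the shipped coefficients are
accurate to well under half a cluster spacing up to roughly 40–60 kDa, and
above that a bias of order 1.3e-5 per dalton of mass accumulates, crossing
the 0.5 Da off-by-one threshold near 60 kDa. Sampling test masses uniformly
in log-mass over the full 8–400 kDa band therefore yields a much lower
off-by-one-free fraction than a database-weighted sample would, even though
the behaviour per mass band is identical. The per-band table from
`tidy(evaluate_predictor(...))` is the honest way to read the method's
accuracy; single overall percentages are statements about the test-set mass
distribution as much as about the method. Refitting on the synthetic
proteome (`refit_initial_model()`) absorbs the linear part of this bias and restores
sub-0.5 Da accuracy across most of the band.

## The grid

The lattice of candidate monoisotopic positions is `{delta + k * zeta}`.

* `universal_zeta()` gives the step as `1.002355 + 6.9584e-10 * M_avg` Da.
  The slope is so small that using an experimental (noisy) average mass is
  harmless. The per-spectrum alternative `optimal_zeta()` minimizes the
  variance of the circularly wrapped spectrum over a default search window
  of [0.998, 1.008] Da (a generous band around the physical ~1.0024 Da
  neutron spacing), scanning 2001 points and refining to 1e-7 Da. It is a
  validation tool and the input to `refit_grid_model()`, not part of the default
  prediction path — it is orders of magnitude slower than the closed form, for a step that differs by well under 2 mDa in 95% of
  synthetic proteins.
* `estimate_delta()` takes the phase as the argument of the
  probability-weighted circular resultant, which coincides with the
  brute-force minimizer of the weighted squared peak-to-grid distance to
  well below 1e-6 Da for realistic (few-mDa) deviations of peaks from the
  lattice; the tests verify both that equivalence and its breakdown scale.
  A spectrum whose peak angles cancel exactly (resultant modulus below
  1e-12) raises an error rather than returning an arbitrary phase.
  `circular_transform()` rotates by the weighted circular mean by default;
  an unweighted variant is available (`weighted = FALSE`), and when the
  resultant vanishes it falls back to the weighted mean of principal
  angles, which reproduces the intuitive symmetric placement for the
  degenerate two-peak case.
* `round_to_grid()` snaps to the nearest node with ties broken toward lower
  mass (the monoisotopic variant is the lightest; when exactly between
  nodes we prefer the conservative, lighter choice). The correction
  `lambda = -1.1982e-7` is applied *relatively* — the node is multiplied by
  `1 + lambda` — because the constant is dimensionless and of ppm scale,
  matching the observation that inter-cluster spacing widens slightly
  toward the light tail so the error grows with the extrapolated distance.
  An additive mode (`lambda_mode = "absolute"`) is provided since the
  algebraic form of the correction is a genuinely open choice;
  `calibrate_lambda()` re-centres the signed relative rounding error on any
  synthetic proteome and reproduces both the negative sign and the sub-1e-6
  magnitude.

## Matching experimental envelopes

`predict_experimental()` converts m/z to neutral daltons with a proton mass
of 1.007276 Da (positive-ion mode assumed), normalizes, and fits a
simulated spectrum with `fit_candidate()`:

* the **averagine unit** defaults to Senko's classic residue ratios
  rescaled uniformly to an average mass of 110.4728 Da under our isotope
  table. A unit re-derived from any protein FASTA
  (`averagine_from_fasta()`) can be swapped in; the exact unit matters much
  less than its average mass, since the variance adjustment below absorbs
  shape differences.
* the **variance direction** (`derive_variance_direction()`) is the
  per-atom isotopic variance vector projected orthogonally to the
  per-element mean-mass vector and normalized — the unique direction that
  maximizes the first-order change of spectral variance at exactly zero
  change of average mass. Sulfur dominates it, as expected from its
  outsized isotopic spread. The displacement `rho` is applied to the
  fractional formula *before* rounding; entries are clipped at zero and
  hydrogens rebalanced afterwards using the average (not monoisotopic)
  hydrogen mass, so the candidate's average mass stays within half a
  hydrogen of the target.
* candidates are anchored so that the simulated spectrum's first aggregated
  peak at or below its own average mass sits on the envelope's most
  abundant peak, then shifted by integer multiples `k` of the grid step
  (default `k_range = -3:8`; the monoisotopic peak lies left of the mode,
  so the search reaches further right). For each `k`, `rho` is optimized
  over a default interval of ±5% of the unit count by a 15-point coarse
  scan plus local refinement to 1e-3 — the objective is piecewise constant
  in `rho` (formulas are integers), so the scan guards against the local
  optimizer stalling on a plateau. The Wasserstein distance between
  normalized spectra (exact CDF-difference integral on the merged support)
  scores every candidate, and the winner's spectrum re-enters the
  theoretical pipeline, supplying the precise moments and grid phase an
  experimental envelope cannot.

Intensities are normalized over whatever segment the user supplies; an
optional `min_rel_intensity` filter in `read_peaklist()` is off by default
since the reference workflow assumes already-selected, resolved segments.
Profile-mode peak picking, baseline correction and multi-analyte
deconvolution are out of scope: one charge-state segment of one analyte in,
centroided sticks assumed.

## The synthetic proteome

`simulate_proteome()` emulates a protein database without downloading one:
average masses are drawn uniformly in log-mass over 8–400 kDa, and each
protein is a rounded averagine multiple whose element counts receive
independent multiplicative log-normal perturbations with dispersion 0.03 —
a realistic compositional spread for globular proteins — followed by
hydrogen rebalancing. Under a fixed seed every draw is reproducible
bit-for-bit.

What this emulates well: the mean composition-vs-mass relation, the scale
of compositional scatter, the cluster-spacing irregularities that the grid
and `lambda` respond to. What it does not: real proteomes' *correlated*
composition variation (cysteine/methionine content does not vary
independently of the rest), their non-uniform mass distribution (real
databases concentrate below ~60 kDa, with consequences discussed above),
and sequence-level effects. Passing tests on this generator demonstrate the
pipeline's internal consistency and parameter recovery, not instrument
performance on real spectra.

Desk-scale problem sizes used by the tests and the reproduction script:
2,000 proteins for evaluation, 20,000 for refitting the initial model
(10-fold CV), ~100 for the grid-step refit (the per-spectrum period
optimization is the bottleneck), 30–40 trials for the end-to-end
experimental-path checks.

## Known limitations

* Accuracy with the shipped coefficients degrades beyond ~60 kDa on
  synthetic compositions, as quantified above; refit coefficients
  (`refit_initial_model()`, shipped via the CLI `train` subcommand) are recommended
  when the target mass range is wide.
* The averagine fit assumes the envelope belongs to a single analyte with
  CHNOS composition; adducts, modifications with other elements, and
  overlapping envelopes violate the model silently.
* Spectra with fewer than two (theoretical) or three (experimental) peaks
  are refused — moments and a grid phase cannot be estimated meaningfully.
* The Wasserstein objective compares shapes after normalization; severe
  intensity truncation (e.g. dynamic-range clipping) biases the variance
  match and thus the prediction.
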