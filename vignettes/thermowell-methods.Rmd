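---
title: "Processing and inference for multi-well isothermal microcalorimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing and inference for multi-well isothermal microcalorimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

Isothermal microcalorimeters of the 48-well cartridge type measure the heat
flow (power) of sealed titanium capsules at constant temperature, with
sensitivity in the nW--µW range. The cartridge holds six rows (A--F) by eight
columns; the instrument compares each sample capsule against the reference
capsules of its own column, and the common configuration dedicates the top and
bottom rows to cell-free references (two per column, sixteen in all, leaving
32 experimental wells). Signals are sampled at 1 Hz for on the order of 48 h.

The scientific application bundled with the package is cellular bioenergetics
of articular chondrocytes: 150,000 cells embedded in a 4.5% w/v agarose
hydrogel per capsule, with media whose only carbon source is glucose,
glutamine, or nothing at all, plus cell-free controls. The thermogram of such
a well shows (i) a large positive spike at loading, from friction of
inserting the cartridge, that dissipates over the first ~5 h; (ii) a
quiescent phase in which live cells produce no heat above baseline while
acclimating, typically 12--24 h; and (iii) a slow metabolic rise to a per-cell
peak of a few tens of pW, which either holds to the end of the run (fed
cells) or decays once intracellular reserves are exhausted. The packaged
per-cell heat table (`chondrocyte_heats()`) holds the published totals of
one such 48-h run, four groups of eight replicate gels.

All internal computation uses seconds, µW and µJ (1 µW·s = 1 µJ); hours
appear only in plots.

## Per-well signal processing

`process_plate()` applies four stages to every sample well.

**Reference correction.** The pointwise mean of the same-column reference
traces is subtracted. Because the loading spike, ambient fluctuations and
common instrument drift are shared between a sample channel and its column
references, this stage removes them; what remains is the metabolic signal
plus any *residual* drift of the sample channel relative to its references,
plus a constant offset and noise.

**Trimming.** Samples before `trim_start_s` (default 1800 s, the ~30 min
thermal equilibration after loading) are dropped; an optional `trim_end_s`
discards trailing steady state. The 0--5 h dissipation tail of the spike is
deliberately retained -- it belongs to the analysed record, and reference
subtraction has already removed its common-mode part.

**Baseline / drift correction.** The residual drift is modelled as linear in
time and *shared by the sample wells of a column* (the reference channels of
a column are the common comparator, so what they do not cancel is a
column-level property). With `drift_mode = "per_column_linear"` (default) a
straight line is fitted by least squares to the moving-average-smoothed
same-column traces pooled over the quiescent window (default 5--10 h, after
the spike has dissipated and before metabolic onset at 12+ h), and
subtracted. The smoothed, drift-free trace is then shifted so its minimum is
exactly zero. `"per_well_constant"` applies only the shift, from the well's
own smoothed minimum.

Two numerical choices deserve comment:

* *The smoother defines the baseline.* The minimum is taken on a centred
  moving average (halfwidth `smoothing_halfwidth_s`, default 300 s, partial
  windows at the edges), never on raw samples, so a single noise excursion
  cannot set the baseline.
* *The returned trace is the smoothed one.* Returning the raw trace and
  clipping its negative excursions at zero would add a rectification bias of
  `E[max(noise, 0)] ~ 0.4 * sigma` µW over the entire quiescent phase --
  about 2% of a typical well's total heat at the default noise level, on top
  of the unavoidable shift bias -- while the smoothed trace integrates to the
  same total (a moving average conserves the integral away from the edges)
  with only the shift bias. The minimum-to-zero shift keeps the returned
  powers non-negative by construction; a residual clip at zero is retained
  purely as a numerical guard (tolerance well below 1e-9 µW).

The shift itself is a known, small, positive bias: the smoothed noise
minimum over a ~47 h trace sits a few multiples of
`sigma / sqrt(window length)` below zero, worth roughly 1--2% of a typical
total at 0.2 µW point noise and 1 Hz. It grows with the noise level and with
coarser sampling; at several-fold higher noise the 2% figure is exceeded.
This is inherent to any "shift the minimum to zero" baseline rule, which the
positivity requirement of the corrected signal imposes.

**Integration and normalization.** The trapezoidal rule over the retained
window gives total heat in µJ; at dense uniform 1 Hz sampling higher-order
quadrature has nothing to add, and for piecewise-linear signals sampled on
their breakpoints the trapezoid is exact (this is tested to 1e-9 relative).
Totals are divided by the well's cell count; cell-free wells keep their raw
totals and report `NA` per cell. (The packaged reference table nonetheless
lists the no-cell controls on the per-cell scale, as published; the values
are reproduced verbatim rather than reinterpreted.)

Gaps in sampling wider than twice the nominal interval are errors, never
interpolated: the instrument samples continuously, and silent interpolation
would bias integrals.

## Heteroscedastic one-way inference

Replicate gels show markedly different spread between groups, so the group
comparison uses a one-way generalized least squares model with a separate
variance per group. For a saturated one-way mean model this has a closed
form: the group means estimate themselves, and with plug-in weights
$w_g = n_g / s_g^2$ the Wald statistic

$$F \;=\; \frac{\sum_g w_g\,(\bar y_g - \hat\mu)^2}{k-1},
\qquad \hat\mu = \frac{\sum_g w_g \bar y_g}{\sum_g w_g},$$

is referred to $F_{k-1,\,N-k}$. `gls_wald_f()` implements exactly this; the
test suite verifies it coincides with an iterative `nlme::gls` fit with a
`varIdent` variance structure on the packaged data, so the closed form stands
in for the heavyweight fit without loss. With $k = 2$ the statistic reduces
to the squared Welch statistic, which the tests exploit as an independent
oracle. Groups with fewer than two observations or zero variance are
refused, not regularized -- silent regularization would corrupt $F$.

The plug-in Wald test is known to be anticonservative at $n = 8$ per group;
a property test measures its empirical size under a four-group null with the
study's own variance pattern and requires it to stay within a broad guard
band around the nominal 5% rather than claiming exactness.

Pairwise comparisons use the Games--Howell construction, the
unequal-variance analogue of a Tukey honest-significant-difference
procedure: Welch-type statistic and Satterthwaite degrees of freedom per
pair, with the family-wise adjusted p-value from the studentized range
distribution with $k$ groups ($q = |t|\sqrt 2$). The exact multiplicity
adjustment used in the original analysis is not documented; only the
qualitative significance pattern is asserted against it, and that pattern is
reproduced.

`compact_letters()` turns the significance pattern into a compact letter
display by insert-and-absorb: start with one letter covering all groups; for
each significant pair split every letter column containing both; absorb
columns that became subsets. Two groups share a letter iff their comparison
is non-significant -- a property test verifies this contract on hundreds of
random significance patterns. Letters are assigned in descending-mean order.

## Tissue-level extrapolation and electron balance

`heat_per_area()` multiplies a per-cell total by an areal cell density
(µJ/cell × cells/mm² → mJ/mm²) and `heat_per_depth()` multiplies by tissue
thickness. The worked example scales the glucose-group mean (2.7925 µJ/cell)
by published superficial-zone densities of healthy (4363 cells/mm²) and
osteoarthritic (1622 cells/mm²) human cartilage, and by the osteoarthritic
thickness 3.68 mm. The healthy per-depth figure is *not* reproduced here:
the published number does not equal the plain area × thickness product and
the defining equation is not available, so the package computes and reports
only the direct products.

`donor_acceptor_ratio()` compares electrons available from complete
oxidation of the media carbon sources against electrons the sealed
headspace O₂ can accept. Degrees of reduction follow the standard
bioenergetic convention (glucose 24, pyruvate 10, glutamine 18 e⁻/mol;
4 e⁻/O₂), serum and trace carbon are excluded, and the default geometry is a
656 µL capsule with a 150 µL hydrogel, 186 µL media (donor concentrations
diluted 1:3 from stock) and 320 µL headspace at 6.84 mmol O₂/L. Under these
conventions the glucose media give a ratio of 5.85 -- an oxygen-limited
capsule, in line with the reported near-stoichiometric excess -- while the
glutamine media give 0.44, far below the reported ~2.6; which liquid volumes
entered the original balance is not stated, so neither ratio is treated as a
ground truth, only the computation contract is.

## The synthetic plate generator

`simulate_plate()` replaces the instrument. Its defaults are the study
conditions: a 6 × 8 cartridge with two references per column, 1 Hz sampling
for 48 h, and group kinetics honouring the qualitative record -- cells-only
wells peak at ~48 pW/cell after a ~12 h lag and exhaust near 32 h; fed wells
rise more slowly, approach their plateau near the 38 h mark and hold; all
peaks stay in the 4--50 pW/cell envelope. The kinetic form (delayed
saturating exponential rise with optional exponential exhaustion) is
deliberately simple and configurable; `expected_total_heat()` integrates it
in closed form, giving every simulated well an analytic ground truth.

Nuisance components and their semantics:

* *Loading spike* (default 40 µW, 1 h decay): common-mode across all wells,
  as the physical friction spike is, so reference correction cancels it.
* *Common drift* (0.02 µW/h): shared by every well of a column; also cancels.
* *Residual drift* (`drift_uW_per_h`, default 0.05 µW/h): applied to sample
  wells only, representing the net drift of a sample channel relative to its
  column references -- precisely what the column-wise baseline correction
  must remove. A fully independent per-well drift would be uncorrectable by
  any column-level rule and is not what the column-referencing design
  implies.
* *Per-well offsets* (SD 0.3 µW) and i.i.d. Gaussian point noise
  (`noise_sd_uW`, default 0.2 µW). Real calorimeter noise is mildly
  autocorrelated; the white-noise model is a simplification, documented as a
  limitation, chosen because it is sufficient to exercise every pipeline
  stage.
* *Biological spread*: each sample well's peak is scaled by a lognormal
  multiplier with CV `peak_cv` (default 0.25), matching the within-group
  spread of the published replicate gels. The ground truth records the
  realized per-well integral, so recovery tests are not confounded by this
  variability.

All randomness flows from a single integer seed through per-well substreams
derived from (seed, well index): a fixed seed reproduces the plate
byte-for-byte, and reference traces are unaffected by the group profiles.

**What passing tests show -- and what they do not.** Parameter-recovery tests
(median absolute relative error ≤ 5% at study noise; ≤ 0.1% for noiseless,
driftless plates) validate the pipeline against the generator's assumptions:
linear residual drift, white noise, a quiescent window that is truly
quiescent. They do not certify behaviour under nonlinear drift, correlated
noise, wells whose metabolism starts before 10 h (which would contaminate
the default quiescent window), or O₂-limitation kinetics, none of which the
generator emulates.

## Problem sizes used by the test suite

Chosen to exercise the method at the scale it targets while keeping the
suite quick: full-scale recovery uses ten 48-well plates at 1 Hz × 48 h plus
one noiseless plate; the bias check uses fifty seeded one-column plates at
1 Hz; the closed-loop separation property uses one hundred plates at 0.2 Hz
(the coarser grid raises the baseline-shift bias slightly but leaves group
separation untouched); the type-I-error band uses 2000 simulated null data
sets; unit tests run on compressed 2 h kinetics. The closed-loop check
compares recovered group means with the plate's realized ground-truth means:
with a 25% kinetic CV, a group of eight wells has a ~9% standard error
around its population target, so the population comparison is left to the
100-plate separation property.

## Known limitations

* The baseline's minimum-to-zero shift is a small positive bias that grows
  with noise and with coarser sampling grids (see above); totals from very
  noisy plates are best interpreted comparatively, which the heteroscedastic
  model accommodates.
* Per-cell values for cell-free wells are undefined; the published
  convention of tabulating them on the per-cell scale is reproduced in the
  packaged fixture but not generalized.
* The electron balance depends on an undocumented volume convention; see
  above.
* No vendor-format parser: export thermograms to delimited text (wide
  `time_s` + one column per well, or long `time_s,well_id,power_uW`).
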