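---
title: "Non-steady-state protein turnover from heavy-water labelling: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-steady-state protein turnover from heavy-water labelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(d2oturnover)
```

## The measurement and the model

During D₂O labelling, deuterium in the body water is incorporated into the
non-essential amino acid alanine, and from there into any protein
synthesised while the label is present. The GC-MS observable is the mass
isotopomer distribution (M0…M3) of a protein-bound alanine derivative; the
plasma body-water enrichment is measured separately. Three quantities link
the observable to kinetics:

1. **Excess enrichment** `E`: the molar excess of labelled alanine over the
   natural-abundance baseline.
2. **Precursor enrichment** `p`: the probability that a *newly made*
   alanine is labelled, obtained from body water by the MIDA adjustment.
3. **Fraction new** `f = E/p`: the fraction of the protein pool synthesised
   during the window.

Each protein pool is modelled as a single first-order compartment,

$$\frac{dP}{dt} = k_{syn} - k_{deg}\,P,$$

with zero-order synthesis (mass/day) and first-order degradation (1/day).
The closed-form trajectory, and the mass of window-synthesised protein that
survives to time $t$,

$$P(t) = P_{eq} + (P_0 - P_{eq})e^{-k_{deg}t}, \qquad
  N(t) = P_{eq}\,(1 - e^{-k_{deg}t}), \qquad P_{eq} = k_{syn}/k_{deg},$$

give $f = N(t)/P(t)$. The surviving *original* protein is
$P_0 e^{-k_{deg}t}$, which is the key to inversion: since
$P_0 e^{-k_{deg}t} = P(t)(1-f)$ and the pool ratio $r = P(t)/P_0$ is
observable through a content marker,

$$k_{deg} = -\frac{\ln\!\big(r(1-f)\big)}{t}, \qquad
  k_{syn} = k_{deg}\,P_{eq}, \quad
  P_{eq} = P_0\,\frac{r f}{1 - r(1-f)}.$$

At $r = 1$ these collapse to the familiar steady-state pair
$k_{deg} = -\ln(1-f)/t$ and $k_{syn} = k_{deg}P_0$ — the package tests
assert the reduction exactly, and verify the inversion against numerical
integration of the differential equation (relative agreement ≤ 1e-8 over a
grid of $f$, $r$ and $t$, including an independent nested root-finding
route that never touches the closed form).

**Why non-steady state matters.** In an atrophying muscle a naive
steady-state estimate attributes pool shrinkage to slow synthesis rather
than fast degradation. In the worked example of the README, a pool with
$k_{deg} = 0.0211$/day that loses 5% of its mass in 5 days would be
mis-estimated at 0.0103/day by the steady-state formula — a two-fold error
that the pool ratio corrects.

**Identifiability guard.** An observation with $r(1-f) > 1$ implies a
negative degradation constant. Such samples are flagged invalid and
excluded from group summaries (with surfaced counts); no negative rate is
ever silently produced.

## MIDA choices

The analysis needs two mappings that the underlying chemistry does not fix
uniquely; both are explicit, configurable design decisions.

* **Precursor adjustment.** Alanine exchanges `nSites` of its hydrogens
  with body water during synthesis; the default `nSites = 3.7` is the
  literature-standard effective value for mammalian alanine. In the default
  linear mode `p = nSites × bodyWater`, accurate for body-water enrichments
  below ~5% (the regime of bolus + 8% drinking-water protocols, which
  plateau near 3–4.5%). An exact binomial mode,
  `p = 1 − (1 − bodyWater)^n`, is available for integer `n`; at 3% body
  water the two differ by under 5%.
* **Spectrum mapping.** The forward model treats a molar excess `E` as a
  fraction of molecules shifted up one mass unit (spectrum = baseline
  convolved with a single-label shift, top bin absorbing so the
  distribution remains exactly normalised). Its inverse is implemented two
  ways: an M1-excess estimator, `E = (M1_obs − M1_nat)/(N0 − N1)`, and a
  full shift-convolution matrix solve whose molar-excess readout
  `Σ j·x_j` is exact for any shift composition representable on M0…M3.
  Both invert the generator to 1e-10 at zero noise; against an exact
  integer-site binomial mixture (the multi-label spectrum the single-shift
  model approximates) both agree with the true molar excess to within 7%
  at labelling-protocol enrichments.
* **Baseline.** The natural-abundance M0…M3 baseline is computed by
  elemental isotope-pattern convolution from a stated composition
  (default `C24H10F15NO2`, the tri-pentafluorobenzyl alanine derivative).
  The derivative chemistry was an assumption of this package's
  configuration; because `E` is an *excess* relative to the same baseline
  used in correction, moderate misspecification cancels in the round trip
  and only enters through the (N0 − N1) coefficient.

## Pool-ratio markers

The pool ratio `r` must come from a fraction-specific content marker:

| fraction       | marker                         | method      |
|----------------|--------------------------------|-------------|
| mitochondrial  | CoxIV densitometry ratio       | non-steady  |
| myofibrillar   | muscle wet-mass ratio          | non-steady  |
| cytosolic      | none available                 | steady-state|

The CoxIV convention for mitochondrial content is standard; the
myofibrillar mass proxy and the cytosolic steady-state fallback are
documented package policy (`markerPolicy` argument), and a fraction whose
marker is missing is downgraded to the steady-state method with a logged
count, never dropped. Pools are normalised to $P_0 = 1$, so `ksyn` is in
initial-pool fractions per day — absolute pool masses are not measured.

`f` values in (−0.02, 0) or (1, 1.02) are clamped to the boundary (noise
tolerance); anything further out is flagged invalid. All clamp/clip/
downgrade events are counted in `runLogCounts()` and printed in the
pipeline report.

## What the synthetic cohort emulates — and what it does not

The generator reproduces the study conditions so that every pipeline stage
has a test surface with known truth:

* **Protocol**: ~20 µL/g bolus of 99% D₂O, 8% D₂O drinking water, 5-day
  label. Plasma kinetics follow a one-compartment model (bolus peak
  `bolus × 0.99 / bodyWaterPool` ≈ 3.3%, exponential approach at 0.3/day to
  a plateau of `waterEnrichment × intakeFraction`). The intake fraction
  (default 0.55: food and metabolic water are unlabelled) and the turnover
  rate are assumptions — the study measured plasma directly and stated no
  plateau — and they only affect simulation realism: the analysis pipeline
  always uses the per-animal plasma values carried in the dataset. A
  `constantPlateau` shortcut skips the kinetics. The effective precursor
  uses the exact time average of the curve.
* **Design**: 2×2 factorial (WT/Sod1KO × saline/LLC), n = 6–8 per cell in
  the demo configuration. Group ground truth plants the published
  degradation constants for the myofibrillar and mitochondrial fractions;
  saline groups are simulated at steady state, tumour-bearing groups with
  synthesis below equilibrium (atrophy). Cytosolic rates (0.06–0.08/day),
  the Ct panel (denervation markers Runx1, Gadd45a, AchRa, Sln against an
  Rn18s reference, with a planted knockout effect), conduction-velocity
  means/SDs (group means and SEM-derived SDs for the wild-type cells;
  knockout cells set ~20% below wild type) and lognormal fibre-CSA
  distributions are plausible defaults, not published values.
* **Noise**: Gaussian additive on isotopomer fractions (absolute sd, plus
  an optional component proportional to the true excess — a 10% CV on the
  labelling signal is the package's reading of "10% isotopomer noise",
  since a 10% CV on the raw M1 fraction (~0.2) would be ~25× the signal
  itself), lognormal on marker ratios, Gaussian on Ct values. Negative
  fractions are clipped and renormalised, with clip counts logged.
* **Determinism**: a master seed with per-animal substreams derived by
  counter; identical configuration and seed reproduce the dataset
  bit-identically (asserted byte-wise in the tests).

Passing recovery tests on this generator demonstrates that the estimators
invert the model they assume. It does *not* demonstrate robustness to what
real data add: precursor-pool lag after the bolus, peptide-level turnover
heterogeneity within a fraction, chromatographic interference in the
isotopomer measurement, or marker-specific biases in CoxIV densitometry.
Those require instrument-level validation outside this package's scope.

## Statistics

The study design is a two-way factorial ANOVA (genotype × tumour) with
Tukey–Kramer post hoc at α = 0.05, implemented here from first principles
so it is fully auditable:

* **Sums of squares**: balanced designs use the classical cell-means
  decomposition (the partition `SS_A + SS_B + SS_AB + SS_E = SS_total` is
  asserted exactly); unbalanced designs default to Type II (each main
  effect adjusted for the other — appropriate when the interaction is not
  the primary hypothesis), with Type III available by flag. The original
  analysis did not state its SS type; on the balanced design they coincide.
  A constant response is reported as degenerate (NA F and p), and empty
  cells are rejected outright.
* **Studentized range**: the upper tail is computed by direct numerical
  integration of the range distribution mixed over the chi distribution of
  the pooled-variance scale (nested adaptive quadrature, relative
  tolerance 1e-8/1e-9; achieved absolute accuracy ~1e-7, verified against
  `ptukey`, the analytic k = 2 identity `q = √2·|t|`, and 10⁶-draw
  Monte-Carlo nulls).
* **Tukey–Kramer**: all cell means compared pairwise (6 comparisons in the
  2×2), `q = |Δ| / sqrt(MSE/2·(1/nᵢ + 1/nⱼ))`, which is Tukey's HSD at
  equal n; the post hoc is gated on a significant F ratio as in the study,
  with a `force` override. The per-factor family alternative is
  deliberately not the default, matching the all-cells annotation style of
  the study's figures.
* **Calibration**: under a null simulation (no effects, Gaussian noise,
  n = 8/cell, 10,000 replicates) each factor's type-I error is asserted to
  be 0.05 ± 0.01.

## Problem sizes and numerical tolerances

The test and acceptance workloads were sized to be decisive yet desk-scale:
kinetic grids of 20×20×3 in (f, r, t) for oracle equivalence; 10,000
replicates for ANOVA calibration; 10⁶ draws for the studentized-range
null; 500 replicate cohorts (n = 8, 10% signal-proportional isotopomer
noise) for the rank-order robustness property, which requires the group
ordering of myofibrillar degradation (Sod1KO-LLC highest, WT-saline
lowest, the two intermediate groups unordered, as their planted values
differ by only ~15%) in at least 95% of replicates. ODE oracles run at
rtol 1e-12; closed-form agreement is required at 1e-8 relative, MIDA round
trips at 1e-10, and noise-free end-to-end recovery at 1e-6 relative or
better.

## Known limitations

* Single-compartment precursor: no delay between plasma and the charged
  tRNA pool; at 5-day labels the bias is small but real for very fast
  pools.
* Fraction-level (not protein-level) resolution: `f` is a pool aggregate;
  proteins turning over at different rates within a fraction are averaged.
* The demo's tumour-bearing wild-type mitochondrial rate (0.167/day)
  implies loss of roughly half the mitochondrial pool in five days; it is
  carried as configured ground truth, and users should treat it — like all
  demo kinetics — as a planted scenario, not a biological claim by this
  package.
* The cytosolic fraction has no content marker, so its estimates inherit
  steady-state bias whenever that pool is actually changing; the magnitude
  of the bias is visible in the demo cohort, where the non-steady cytosolic
  plant (Sod1KO-LLC) is recovered ~6% low by design of the fallback.
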