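# d2oturnover

Skeletal muscle wasting — in cancer cachexia, sarcopenia and oxidative-stress
models such as the Sod1-knockout mouse — is a problem of protein *turnover*:
the balance between synthesis and degradation. Heavy-water (D₂O) metabolic
labelling measures that balance in vivo: deuterium from the body water is
incorporated into alanine during de novo protein synthesis, so the mass
isotopomer distribution of protein-bound alanine (measured by GC-MS) reports
how much of each protein pool was made during the labelling window.

`d2oturnover` is an R package for analysing such experiments when the pool is
**not** at steady state — precisely the situation in wasting muscle, where
naive first-order formulas confound atrophy with turnover. It provides:

* **MIDA enrichment analysis** — natural-abundance correction of M0…M3
  alanine isotopomer distributions, precursor enrichment
  `p = n_sites × body-water enrichment` (linear MIDA, exact binomial mode for
  integer site counts), and fraction-new protein `f = E / p`.
* **Non-steady-state kinetics** — for the pool model

  ```
  dP/dt = k_syn − k_deg · P        (k_syn: mass/day, k_deg: 1/day)
  ```

  the surviving original protein satisfies `P₀ e^(−k_deg t) = P(t)(1 − f)`,
  so with the pool ratio `r = P(t)/P₀` (CoxIV densitometry for the
  mitochondrial fraction, muscle mass for the myofibrillar fraction):

  ```
  k_deg = −ln(r·(1 − f)) / t
  k_syn = k_deg · P_eq,   P_eq = P₀ · r·f / (1 − r·(1 − f))
  ```

  At `r = 1` these reduce to the steady-state pair
  `k_deg = −ln(1 − f)/t`, `k_syn = k_deg·P₀`. Observations implying a
  negative rate (`r·(1 − f) > 1`) are flagged, never silently emitted.
* **Study assay computations** — 2^(−ΔΔCT) relative expression,
  antimycin-A-corrected respirometry per mg wet weight, fibre
  cross-sectional-area binning (small 200–1200 µm², large > 2400 µm²), and
  tumour-free mass normalisation.
* **Self-contained statistics** — two-way factorial ANOVA (Type II/III) with
  Tukey–Kramer post hoc built on the package's own numerically integrated
  studentized range distribution (cross-checked against `ptukey` and
  Monte-Carlo nulls in the tests).
* **A synthetic-cohort generator** — full 2×2 (WT/Sod1KO × saline/LLC)
  labelling experiments with planted ground truth, so every stage of the
  pipeline is testable without any experimental data.

## Worked example

One noise-free animal planted at a degradation constant of 0.0211/day with
an atrophying myofibrillar pool, pushed through the whole chain:

```r
library(d2oturnover)

pool <- simulatePool(ksyn = 0.01, kdeg = 0.0211, P0 = 1, t = 5)
pool
#> PoolTrajectory
#>   ksyn = 0.01 /day, kdeg = 0.0211 /day, t = 5 d
#>   P0 = 1 -> P(t) = 0.947327 (r = 0.947327), new mass N(t) = 0.0474529
#>   equilibrium pool = 0.473934

p <- precursorEnrichment(0.03, 3.7)     # plasma body water 3%, 3.7 sites
#> PrecursorEnrichment: p = 0.111 (linear mode, body water 0.03, 3.7 sites)

E   <- simulateAlanineEnrichment(pool, p@p)        # 0.005560134
obs <- isotopomerize(E)                            # the GC-MS observable
#> IsotopomerDistribution: M0=0.760772  M1=0.205967  M2=0.0299228  M3=0.00333882

f  <- fractionNew(correctNaturalAbundance(obs), p) # 0.0500913
kdegNonsteady(as.numeric(f), poolRatio(pool), 5)   # 0.0211  (the plant)
```

The 5% of the pool that is new would naively suggest
`−ln(1 − f)/5 = 0.0103/day`; the pool ratio of 0.947 tells the non-steady
estimator that half of that apparent stability is atrophy, and it returns
the true 0.0211/day.

A full simulated cohort (n = 8 per group, mild measurement noise):

```r
res <- runPipeline(demoConfig(seed = 1), outDir = "demo_run")
subset(res$summary, fraction_id == "myofibrillar")
#>  genotype treatment  fraction_id n excluded kdeg_mean kdeg_sem
#>    Sod1KO       LLC myofibrillar 8        0   0.04815 0.002549
#>    Sod1KO    saline myofibrillar 8        0   0.01851 0.000776
#>        WT       LLC myofibrillar 8        0   0.02350 0.001550
#>        WT    saline myofibrillar 8        0   0.00709 0.001831
```

Group means recover the planted degradation constants (0.049, 0.018,
0.0211, 0.00847/day), and `res$comparisons` holds the Tukey–Kramer table —
e.g. Sod1KO/LLC vs WT/saline: q = 22.9, adjusted p = 6.1e-15.

`runPipeline()` writes every stage as CSV (simulated cohort, turnover
estimates, group summary, ΔΔCT expression, CSA frequencies, ANOVA and
post hoc tables) plus a report and a config snapshot that re-executes to
identical outputs. `inst/scripts/d2oturnover` wraps the same functions as
shell verbs (`simulate`, `enrich`, `estimate`, `assays`, `stats`, `run`,
`demo`).

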