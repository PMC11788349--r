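---
title: "Scoring saline-soil quality and multifunctionality in amendment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring saline-soil quality and multifunctionality in amendment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilqual)
```

## The analysis problem

Coastal saline soils carry high soluble salt (dominated by Na+) and low
nutrient availability, depressing both biological function and crop yield.
A common short-term intervention is returning corn straw — either directly
(CS) or after pyrolysis to biochar (CB) — and comparing against an
unamended control (CK) in a small randomized field trial (three treatments,
triplicate plots). The analytical questions are: does the amendment improve
*overall* soil quality and *overall* enzymatic function, not just individual
properties, and which soil properties drive the yield response?

`soilqual` implements that analysis chain as reusable, tested functions:

1. **Directional scoring and SQI.** Each soil property $i$ is scored
   linearly onto $(0, 1]$: $L_i = v / v_{\max}$ where more is better
   (total N; available N, P, K; SOC), and $L_i = v_{\min} / v$ where less
   is better (salt). The soil quality index is the radar-polygon area of
   the scores,
   $$\mathrm{SQI} = \tfrac12 \sin\!\left(\tfrac{2\pi}{n}\right) \sum_{i=1}^{n} L_i^2 ,$$
   bounded by $\tfrac12\, n \sin(2\pi/n)$, attained iff every $L_i = 1$.
2. **Ecosystem multifunctionality.** Each enzyme activity (BG, CE, NAG,
   LAP) is Z-standardised over the analysed plots,
   $Z_i = (x - m_i)/s_d$ with the sample (N−1) standard deviation, and EMF
   is the per-plot mean of the $Z_i$.
3. **Treatment inference.** One-way fixed-effects ANOVA per variable,
   Fisher's LSD pairwise comparisons at $\alpha = 0.05$ summarised by a
   compact letter display, and percent changes of treatment means versus
   the reference.
4. **Yield drivers.** OLS regressions among SQI, EMF and yield, and
   random-forest permutation importance (%IncMSE) of the physicochemical
   panel for yield.

## The scoring reference set

The min–max extremes ($v_{\max}$, $v_{\min}$) and the Z-score moments
($m_i$, $s_d$) are pooled over **all** plots of the analysed dataset — not
per treatment and not from literature reference ranges. The defining
formulas carry no external reference, so pooling is the only self-contained
reading, and it is what makes treatment contrasts of SQI and EMF
well-defined. A consequence worth knowing: both indices are *relative to
the dataset*; adding plots changes every score.

Two configuration points are deliberately open because the measurement
protocol is ambiguous about them:

* **The SQI property set.** The default is the six-property set
  {salt, TN, avN, avP, avK, SOC} ($n = 6$), salt scored less-is-better and
  the rest more-is-better. The seven soluble ions are measured and
  generated, carry a less-is-better direction, and can be added through
  `sqi_properties=` if a user prefers the larger panel.
* **The aggregation formula.** `sqi()` implements the $\sum L_i^2$ area
  form exactly as printed (default), and also the conventional
  adjacent-spoke radar area $\tfrac12 \sin(2\pi/n) \sum_i L_i L_{i+1}$
  (cyclic) behind `variant = "adjacent"` for sensitivity analysis. The two
  agree at the all-ones bound and the printed form is never smaller
  (by AM–GM on each adjacent pair).

## What the synthetic generator emulates

No plot-level data are published for this kind of trial, so every stage is
exercised on synthetic data from `generate_trial()`:

* **Design.** 3 treatments × 3 replicates, fully randomized, no blocking
  or spatial structure; plots are i.i.d. within treatment.
* **Means.** CK means equal the pre-trial baseline panel (salt 1.88 g/kg,
  soluble Na+ 1.52 g/kg, pH 8.46, SOC 7.6 g/kg, TN 1.01 g/kg, available
  N/P/K 50.41/34.98/393.71 mg/kg). Treating the baseline as the
  end-of-season control is a surrogate assumption — the control's own
  end-of-season panel is not printed — and is the main reason pipeline
  contrasts are expected to land *near*, not *on*, the reported ones.
* **Effects.** Treatment means are baseline × multiplier, the multipliers
  being 1 + (reported percent change)/100 for every significant effect
  (e.g. CS salt ×0.78, avN ×1.91, yield ×1.22) and exactly 1.0 for
  non-significant ones. CB's BG and LAP multipliers are pinned indirectly
  through the reported CS-to-CB activity ratios (1.33/1.70 and 1.13/1.15).
* **Noise.** Within-treatment values are Normal(mean, cv × mean) truncated
  at zero by redraw, default cv = 0.05. Reported dispersions are SE bars
  in figures only, so the CV is a configurable modelling choice: 5% is a
  typical within-treatment CV for composited soil cores and keeps the
  printed contrasts clearly separable at n = 3, which is what the
  original significance pattern implies.
* **Free scales.** Enzyme and yield baselines (BG 50, CE 20, NAG 30,
  LAP 15 nmol g⁻¹ h⁻¹; yield 9 t ha⁻¹) are arbitrary positive scales:
  every downstream result is percent-change-, score- or Z-based, and this
  scale invariance is itself a tested property.

What the generator does **not** emulate: spatial autocorrelation, soil
process dynamics (salt leaching, decomposition), multi-year trajectories,
non-Gaussian tails, or correlated measurement error across variables
within a plot (variables are drawn independently given the treatment).
Passing tests therefore demonstrate that the *analysis chain* recovers
known inputs under idealised sampling — not that the field conclusions
generalise.

## Inference choices

* **Unprotected LSD** by default: pairwise tests run regardless of the
  omnibus F, with `protected = TRUE` available. The source protocol does
  not say which was used; unprotected is the common field-trial practice
  that the package makes explicit rather than silent.
* **Compact letters** by insert-and-absorb: start with one class holding
  all treatments, split any class containing a significantly different
  pair, absorb subset classes, then letter classes in descending-mean
  order (ties broken by design order). Two treatments share a letter iff
  their difference is below the pairwise LSD; this equivalence is tested
  exhaustively for all 3-treatment significance patterns.
* **Percent changes** are contrasts of treatment means of the raw
  variable (not means of per-plot ratios), and the reference-mean ≤ 0
  case is *flagged undefined* rather than reported: a percent change of
  the mean-zero EMF composite has no denominator on the pooled Z scale —
  the control's EMF is necessarily ≤ 0 whenever the amended plots sit
  above it — so the reported "+71%/+39%" EMF contrasts are not
  reproducible quantities and the pipeline reports EMF differences on the
  Z scale instead.
* **Degenerate ANOVA inputs** are resolved explicitly: exactly equal
  sample means give F = 0; zero within-group variance with unequal means
  gives F = ∞, p = 0.

## Forest settings

Hyperparameters follow the conventions of the analysis the protocol names:
500 trees, ⌈p/3⌉ candidate features per split, unlimited depth, bootstrap
size n. Importance is the mean over trees of the relative out-of-bag MSE
increase after permuting the feature's OOB values, ×100 (%IncMSE). Feature
columns are sorted by name before fitting and before the permutation draws
(feature-major, then tree), so a fixed seed gives results independent of
input column order. With 9 plots single-seed importance is high-variance;
the CLI's `relate --repeat-seeds k` reports means ± sd over k seeds.

A property of the calibration worth stating plainly: because the three
available-nutrient pools move only under CS — exactly the treatment with
the yield gain — they are near-collinear with yield, while salt also falls
under CB where yield is flat. On synthetic data the nutrient pools
therefore dominate the forest ranking and salt, though informative, is not
reliably in the top ranks. Recovering a salt-dominated ranking would
require the unpublished plot-level covariance structure.

## Reproducibility and problem sizes

`run_all()` splits one master seed into named substreams per stage
(generation, relating), so a config plus seed reproduces every output
byte-identically, and changing forest settings never perturbs the
generated data. All rounding is deferred to presentation; stored values
keep full precision (CSV written at 15 significant digits).

Simulation-based checks in the test suite use sizes chosen to make the
Monte-Carlo error small relative to the tolerance being asserted:
10,000 null trials for the ANOVA type-I error (binomial SE ≈ 0.002 against
a ±0.01 band), 200 calibrated trials for percent-change recovery and the
yield~SQI significance rate, 10,000 replicates for generator mean
convergence, and 15 seeds for forest rank stability.

## A worked run

```{r, eval = FALSE}
run <- run_all(run_config(seed = 1))
subset(run$comparisons, variable %in% c("SQI", "EMF", "yield"))
run$regressions
head(run$importance)
```

## Known limitations

* CK-as-baseline is a surrogate; the SQI contrast reproduces to within a
  few percentage points, not exactly.
* Pooled scoring makes SQI/EMF dataset-relative quantities.
* With n = 3 per treatment, the LSD has 6 error df; letters are sensitive
  to the pooled-variance estimate.
* Forest importance at 9 plots is indicative, not inferential; no
  permutation p-values are attached.
* No mixed models, blocking, multiple-testing adjustment beyond LSD, or
  structural equation modelling — none belong to this analysis chain.
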