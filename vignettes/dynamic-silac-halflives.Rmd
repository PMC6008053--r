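---
title: "Estimating protein half-lives from dynamic SILAC data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating protein half-lives from dynamic SILAC data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynasilac)
```

## The measurement and the model

In a dynamic SILAC experiment, cells grown in medium with natural ("light")
arginine and lysine are switched to medium containing heavy isotopologues.
From that moment every newly synthesized protein incorporates heavy
residues, while the pre-existing light pool only decays. Mass spectrometry
quantifies, for each peptide and chase timepoint, the heavy/light intensity
ratio H/L. Under first-order degradation the fraction of pre-existing
protein follows

$$\%old(t) = e^{-k t}, \qquad t_{1/2} = \frac{\ln 2}{k},$$

so the log of the pre-existing fraction is linear in time with slope $-k$
and no intercept (at $t = 0$ the fraction is 1 by construction).

Two complications separate the observable H/L ratio from $\%old$:

1. **Residual light label.** To limit cellular stress the medium switch
   leaves a 4:1 mixture of heavy to light amino acids, so a nascent protein
   incorporates a heavy residue only with probability $P(H) \approx 0.8$.
   Part of the "light" signal is therefore newly synthesized protein.
2. **Channel visibility.** SILAC quantification pairs the all-light and
   all-heavy forms of a peptide. For missed-cleavage peptides (two
   labelable residues) the mixed one-light-one-heavy species falls outside
   the quantified doublet.

### Label purity from missed-cleavage peptides

Missed-cleavage peptides turn complication 2 into an asset: among nascent
molecules the mixed (LH) and all-heavy (HH) species occur with probabilities
$2P(L)P(H)$ and $P(H)^2$. The all-light nascent class is indistinguishable
from pre-existing peptide and cancels from the ratio of the two observable
classes, giving the closed form implemented in `estimate_purity()`:

$$P(H) = \frac{2\,HH/LH}{1 + 2\,HH/LH}.$$

Counting is by number of detections (spectral-count style), per sample, with
t0 samples excluded; a pooled estimator over all samples is available for
low-count data.

### From ratios to pre-existing fractions

`fraction_light()` computes $\%L = 1/(1 + H/L)$, with $\%L = 1$ for t0
peptides detected only in light form. `fraction_old()` then corrects for
nascent light incorporation:

$$\%old = 1 - \frac{1 - \%L}{P(H)^{\,n}}.$$

The exponent $n$ is configurable. The default rule `"MC+1"` uses the number
of labelable Arg/Lys residues (missed cleavages + 1): with the alternative
rule `"MC"` a fully tryptic peptide would receive no correction at all, even
though a fraction $P(L)$ of its nascent copies is light. Under the
visible-channel model above, `"MC+1"` makes the correction exact for
fully tryptic peptides, which dominate a tryptic digest. For
missed-cleavage peptides neither power-law exponent is exact (the mixed
species distorts both channels); the residual late-timepoint bias of those
peptides is in practice removed by the per-timepoint outlier fences (below),
as the package's noiseless and noisy recovery tests verify. Results should
state the rule used; `"MC"` reproduces the alternative convention.
Corrected values below zero (possible when noise meets a strong correction)
are excluded, not clamped.

## The fitting pipeline

`run_pipeline()` chains the stages in a fixed order, logging every
exclusion:

1. **Peptide filtering** (`filter_peptides()`): within each biological
   replicate a peptide must be quantified at every design timepoint and
   have a mean $\%old > 0.9$ at t0; peptides shared between protein groups
   are dropped; replicates are then merged (pooled).
2. **Outlier removal** (`remove_outliers()`): per protein and timepoint,
   Tukey fences at quartile ± 1.5 IQR. Quartiles use linear interpolation
   between order statistics (R type 7) — stated explicitly because quartile
   conventions differ across software and move the fences.
3. **Monotonic-decay exclusion** (`check_monotonic_decay()`): per-timepoint
   means must be non-increasing within an additive tolerance, default 0.05.
   The source procedure names no tolerance; 0.05 admits ordinary
   measurement jitter on a plateau while rejecting genuinely non-decaying
   profiles.
4. **Fast-turnover censoring** (`cluster_fast_turnover()`): k-means
   (default 6 clusters, fixed seed) on per-protein mean profiles; clusters
   whose centroid retains ≤ 50% pre-existing protein at the chase timepoint
   nearest one day are assigned "<1 day" instead of a fitted value —
   with only one point on the informative part of the decay such fits are
   not reliable. The describing procedure is labelled "hierarchical
   clustering (kmeans method)", which names two algorithms; the
   parenthetical k-means is implemented. When clustering is degenerate
   (fewer distinct profiles than clusters) the direct per-protein rule is
   used. Censored records carry no rate constant.
5. **Fitting** (`fit_halflife()`): ordinary least squares of
   $\ln \%old$ on $t$ with **no intercept**, over all pooled peptide-level
   points. $R^2$ is the uncentered coefficient of determination
   $1 - RSS/\sum y^2$, the appropriate quantity for a no-intercept fit
   (the centered version can be negative here). t0 points are included by
   default; they cannot change the no-intercept slope (their regressor is
   zero) but legitimately enter the residual error and $R^2$. A flag
   excludes them, since the original description leaves their inclusion
   open.

## Cross-condition comparison

`compare_culture_turnover()` reproduces the screening logic for culture-type
contrasts: a protein is considered only if its mean $\%old$ is strictly on
the same side at every chase timepoint; a two-sided t-test (Welch by
default — only "a t-test" is specified, and Welch is the safer default;
a flag restores Student) is run per chase timepoint; Bonferroni correction
uses the total number of tests performed (tested proteins × chase
timepoints); the verdict requires at least 2 of 3 chase timepoints
significant. Peptide-level values are pooled across injections by default.
`compare_paired_decay()` implements the paired design for
conditioned-medium contrasts: per-peptide relative decay
$\%old(t_0) - \%old(7\,d)$, negative decays removed, peptides matched by
sequence, paired t-test per protein, Bonferroni over proteins.
`type_one_error_audit()` generates matched null (or spiked-effect) datasets
and measures the realized family-wise error rate and power.

## Complex cohesion

`complex_sd()` computes within-complex sample standard deviations of
half-lives for complexes with ≥ 5 annotated members and ≥ 3 measured
half-lives (censored members have no numeric value and are excluded).
`random_sd_null()` draws size-matched random groups from the measured
half-life population — without replacement within a group, independently
across groups, 1000 repetitions by default; the repetition count and the
replacement policy are unspecified in the source procedure and are exposed
as options. `cohesion_test()` compares the two SD distributions with a
two-sided Mann-Whitney test (tie-corrected normal approximation; fully tied
samples return the saturation statistic with p = 1).

## Imaging-based validation

`fit_puncta_decay()` fits pulse-chase puncta counts: per-day arithmetic
means over cells (zero-puncta cells included — dropping them would bias
counts upward), then OLS of ln(mean) on chase day **with** a free
intercept, since absolute puncta numbers are not normalised to 1 at t = 0.
A nonlinear least-squares option (`method = "nls"`) fits
$n_0 e^{-kt}$ directly; the two differ only slightly under noise.
`correlate_halflives()` computes the Pearson correlation between imaging-
and MS-derived half-lives of the same proteins.

## The synthetic-data generator

`generate_proteome()` and `simulate_silac_experiment()` emulate the study
design so that every stage is testable against known ground truth:

* timepoints 0/1/3/7 days, 3 biological replicates × 3 injections;
* heavy-incorporation probability 0.8 (4:1 heavy:light medium);
* log-normal half-lives, median 5.4 days, log-sd 0.55 — right-skewed and
  spanning <1 to >20 days without tails so heavy they break fits;
* peptides per protein: shifted geometric, mean 6, minimum 1;
  missed-cleavage probability 0.2 — plausible tryptic-digest values;
* multiplicative log-normal ratio noise, log-sd 0.1. The source work does
  not quantify H/L measurement noise; 0.1 is a stated assumption in the
  range typical of SILAC ratio repeatability;
* dropout probability 0.1, implemented as per-peptide beta-distributed
  detectability so that some peptides are systematically harder to see;
* optional conditions as rate multipliers (e.g. glia-like 1.4× faster) and
  complexes whose members share a common log-rate component
  (intra-class correlation 0.5 by default);
* label-species counts drawn multinomially from the two-residue labeling
  model, 2000 events per chase sample by default.

The forward model emits the *expected* heavy/light quotient times noise
rather than sampling molecule counts, so with noise 0 the measured ratio is
exactly $(1 - e^{-kt})/e^{-kt}$ for fully tryptic peptides and the entire
pipeline recovers $k$ to machine precision — the strongest available
end-to-end oracle. What the generator does **not** emulate: intensity-
dependent noise, arginine-to-proline conversion, co-eluting interference,
protein-group ambiguity beyond shared-peptide flags, non-exponential decay,
and cell growth or dilution. Passing recovery tests therefore demonstrate
correctness of the estimation procedure under its own assumptions, not
robustness to every artefact of real LC-MS data.

## Numerical choices and degenerate inputs

* All randomized helpers take explicit seeds and restore the caller's RNG
  state; the same seed reproduces the same tables.
* Purity estimation with `LH = 0, HH > 0` returns the saturation value
  $P(H) = 1$ with a warning; both counts zero is an error.
* $\%old \le 0$ values never reach the log transform (excluded upstream).
* Fits require ≥ 3 positive points; non-decaying profiles (fitted
  $k \le 0$) are reported as unfittable rather than given negative
  half-lives.
* Tukey fences with $n \ge 1$ can never empty a group (the quartiles lie
  inside the data range), so outlier removal preserves timepoint coverage.
* Problem sizes in the validation suite — 2000-protein recovery runs,
  200-run error-rate audits, 40-run cohesion calibrations — were chosen as
  the smallest sizes at which the checked quantities (medians, family-wise
  error rates) are stable to well within their test tolerances.

## Worked-example data

The imaging worked examples (GM130, t½ ≈ 1.9 d over chase days 0–3;
LaminB1, t½ ≈ 4.4 d over days 0/1/3/7) use synthetic stand-in tables from
`simulate_puncta()` generated at those reference half-lives with the
matching chase designs (200 cells/day, mean 120 initial puncta, chosen so
Poisson error is small against a ±0.1 day tolerance). They validate that
the fitting procedure recovers the reference values from data of the
published design; they are not the original per-cell measurements.

## Limitations

Half-lives assume a single-exponential decay of a homogeneous pool; mixed
cell-type cultures in reality superimpose cell-type-specific rates. The
"<1 day" censoring boundary depends on the earliest chase timepoint. The
Bonferroni-based comparison is conservative; no FDR alternative is
provided because the verdict rule is defined in terms of family-wise error.
Protein-group merging heuristics used to rescue peptides in specific cases
are intentionally not generalized: only the unique-peptide filter is
applied.
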