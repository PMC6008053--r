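# dynasilac

Protein turnover analysis for **dynamic SILAC** experiments: estimate
per-protein degradation rate constants and half-lives from heavy/light
peptide ratios measured over a labeling time course, compare turnover
between conditions, test whether protein-complex members degrade
coherently, and fit imaging-based pulse-chase decay for orthogonal
validation. A built-in synthetic-data generator with known ground truth
makes every stage testable end to end.

## Who this is for

Proteomics groups running pulsed metabolic-labeling experiments (e.g. in
primary neuronal or glial cultures) who have MaxQuant-style peptide
evidence tables and want a tested, scriptable route from H/L ratios to
half-lives and downstream statistics.

## The model

After a light-to-heavy medium switch, pre-existing protein decays with
first-order kinetics,

    %old(t) = exp(-k t),        t_1/2 = ln(2) / k,

while nascent protein incorporates heavy Arg/Lys with probability P(H) < 1
(a 4:1 heavy:light medium gives P(H) = 0.8). The package:

1. estimates **P(H)** per sample from missed-cleavage peptide species
   counts, `P(H) = (2 HH/LH) / (1 + 2 HH/LH)`;
2. converts each peptide ratio into the fraction of **pre-existing**
   protein, `%old = 1 - (1 - %L) / P(H)^n` with `%L = 1/(1 + H/L)`;
3. filters peptides (full timepoint coverage, mean t0 %old > 0.9, unique
   peptides), removes Tukey-fence outliers per protein and timepoint,
   excludes non-monotonic profiles, censors fast-turnover proteins
   ("<1 day") by k-means clustering, and fits `ln(%old) = -k t` by
   no-intercept least squares with SE(k) and uncentered R²;
4. compares turnover across conditions (direction-consistent per-timepoint
   t-tests, Bonferroni, ≥2-of-3 rule; paired peptide-level decay test);
5. tests complex cohesion (within-complex SD of half-lives vs a
   size-matched resampling null, Mann-Whitney);
6. fits puncta-count pulse-chase decay (free-intercept ln-linear fit) and
   correlates imaging- with MS-derived half-lives.

See `vignettes/dynamic-silac-halflives.Rmd` for the full methods account.

## Worked example

```r
library(dynasilac)

cfg  <- silac_config(seed = 42, n_complexes = 25)   # 0/1/3/7 d design
prot <- generate_proteome(400, cfg)
ex   <- simulate_silac_experiment(prot)

pur <- estimate_purity(ex$label_counts)             # per-sample P(H)
res <- run_pipeline(ex$peptides, pur)
res
#> dynamic SILAC half-life pipeline result
#>   mixed: 396 proteins (0 censored '<1 day'); median t1/2 5.05 d

head(res$halflives[, c("protein_group", "k_per_day", "se_k",
                       "r_squared", "half_life_days")], 3)
#>   protein_group k_per_day      se_k r_squared half_life_days
#> 1       PG00001 0.1208853 0.0020473 0.9672628       5.733924
#> 2       PG00002 0.1189853 0.0008085 0.9905790       5.825487
#> 3       PG00003 0.0975574 0.0005298 0.9931470       7.105022

# complex cohesion against a size-matched resampling null
gt  <- subset(ex$ground_truth, condition == "mixed")
cx  <- subset(gt, !is.na(complex_id))[, c("complex_id", "protein_group")]
sds <- complex_sd(res$halflives, cx)
nul <- random_sd_null(res$halflives$half_life_days, sds$n_measured,
                      n_rep = 1000, seed = 1)
cohesion_test(sds, nul)[c("p_value", "median_complex", "median_null")]
#> $p_value        [1] 0.0213
#> $median_complex [1] 2.28
#> $median_null    [1] 3.02
```

The fitted half-lives track the generator's ground truth (median absolute
relative error 2.3% in this run), and complex members are measurably more
coherent than random size-matched groups (complex SD median 2.28 d vs
3.02 d, p = 0.021).

A thin command-line front end wraps the same functions:

```sh
Rscript exec/dynasilac simulate --seed 5 --out out/ n_proteins=400
Rscript exec/dynasilac purity   in=out/label_counts.tsv --out out/
Rscript exec/dynasilac halflife in=out/peptides.tsv purity=out/purity.tsv --out out/
```

Subcommands: `simulate`, `purity`, `halflife`, `compare`, `compare-paired`,
`complexes`, `funcat`; global flags `--config <yaml>`, `--seed`, `--out`,
`--log-level`.

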