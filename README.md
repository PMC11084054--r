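# gutlvdd

Multi-omics inference linking gut bacterial species, circulating
metabolites, and left ventricular diastolic dysfunction (LVDD).

LVDD — impaired left-ventricular filling and relaxation, graded 0–III —
is a common, usually silent precursor of heart failure. Cohort studies
with paired gut metagenomes, serum metabolomes, and echocardiography can
ask which gut species differ in people with LVDD, which circulating
metabolites carry that signal, and whether those metabolites predict who
develops LVDD next. `gutlvdd` packages that whole inference chain for
epidemiologists and microbiome researchers, together with a synthetic
cohort generator with planted ground truth, so every stage can be
validated end to end even though cohorts of this kind are
access-restricted.

## What it computes

- **ANCOM-II differential abundance** (from scratch, covariate-adjusted):
  for taxa *i*, *j*, fit log(*x<sub>i</sub>*/*x<sub>j</sub>*) ~ outcome +
  covariates and count W<sub>i</sub> = #{ *j* : BH-corrected p < α }.
  Detection at W ≥ 0.7(m−1), with zeros classified as structural /
  outlier / sampling and handled accordingly.
- **Transforms**: centered log-ratio for taxa (log x minus the per-sample
  mean log); rank-based inverse normal transform for metabolites with
  half-minimum imputation and the Blom offset (r − 3/8)/(n + 1/4);
  strict >20% prevalence, >75% detection, and KO floor filters.
- **Association layer**: logistic odds ratios under three nested
  covariate models; metabolome-wide linear association (MWAA) per
  species; modified Poisson regression (log-link Poisson + HC0 sandwich
  SE) for relative risks of incident LVDD; DerSimonian–Laird
  random-effects pooling with a sign-concordance retention rule;
  Benjamini–Hochberg FDR; ordinal grade trends; partial correlations.
- **Proxy association**: Spearman correlation between metabolite-level
  Z-scores (β/SE) from species-side and incident-outcome-side models —
  an indirect species → incident-disease link through shared metabolite
  signatures.
- **Risk prediction**: elastic net with 10 × 10-fold nested
  cross-validation, exact linear SHAP attributions
  (φ<sub>ij</sub> = β<sub>j</sub>(x<sub>ij</sub> − x̄<sub>j</sub>)),
  Mann–Whitney AUC with percentile-bootstrap CI, DeLong test for the
  AUC change.
- **KO triangle**: species–KO–metabolite edges with sign-concordance,
  linking microbial gene functions to the metabolite signal.

## Worked example

```r
library(gutlvdd)

cohort <- generate_cohort(default_paper_scale(), seed = 1)
report <- run_study(cohort$species, cohort$metabolites, cohort$kos,
                    cohort$meta, run_config(seed = 1))
report$summary$proxy
```

The run logs each stage (~1 minute on one CPU):

```
[ancom2] discovery set n = 1496
[ancom2] 14 candidate species detected
[meta] 10 species retained after pooling
[mwaa] 239 species-associated metabolites
[prevalent-metabolites] 151 prevalent-associated metabolites
[incident-metabolites] 37 incident-associated metabolites
[prediction] AUC 0.644 (traditional) vs 0.818 (augmented), p = 1.2e-12
[ko-triangle] 3080 edges (3069 concordant)
```

and the proxy table reads:

```
   species           R            p significant
1   sp0041  0.45400664 4.765010e-03        TRUE
3   sp0093 -0.61474633 5.162783e-05        TRUE
6   sp0247 -0.61474633 5.162783e-05        TRUE
7   sp0357 -0.85087719 2.562687e-11        TRUE
10  sp0453  0.74490280 1.241863e-07        TRUE
...
```

Reading: of the species retained after ANCOM-II discovery, logistic
replication and meta-analytic pooling, those with negative proxy R
(their metabolite signatures oppose the incident-risk signature) are
indirectly protective — here that includes both planted protective
proxy species (sp0093, sp0247) and the two structural-zero species
(sp0357, sp0362, depleted in cases by construction) — while sp0453, the
planted risk proxy species, shows R = +0.74. All 7 planted differential
species were recovered, and the metabolite-augmented model improves
incident prediction over the traditional-risk-factor model (AUC 0.818
vs 0.644, DeLong p ≈ 1e-12).

A thin CLI wrapper is installed with the package:

```sh
Rscript inst/scripts/run_study.R simulate --out cohort --seed 1
Rscript inst/scripts/run_study.R run-study \
  --species cohort/species_counts.tsv \
  --metabolites cohort/metabolite_intensities.tsv \
  --kos cohort/ko_relabund.tsv --meta cohort/sample_metadata.tsv \
  --out study_out --seed 1
```

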