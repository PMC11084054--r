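---
title: "Methods: linking gut bacterial species, circulating metabolites, and diastolic dysfunction"
author: "gutlvdd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking gut bacterial species, circulating metabolites, and diastolic dysfunction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The inference chain

`gutlvdd` implements a cross-sectional-plus-prospective inference chain
for left ventricular diastolic dysfunction (LVDD), a graded (0–III)
precursor of heart failure that is consumed here purely as a set of
labels: a prevalent binary outcome, an ordinal grade, and an incident
binary outcome defined only among baseline-negative subjects. The chain
runs:

1. **Species discovery (ANCOM-II).** Covariate-adjusted compositional
   differential abundance on the discovery set, at a 20% prevalence
   filter.
2. **Quantification and replication.** Per-species logistic fits in
   discovery and validation sets, pooled by DerSimonian–Laird
   random-effects meta-analysis; a species is retained when the pooled
   p-value is below 0.05 *and* the two set-level coefficients agree in
   sign.
3. **Final models.** Logistic quantification under three nested
   covariate sets (Model 1: sociodemographic + lifestyle; Model 2:
   + BMI and systolic blood pressure; Model 3: + three medication
   indicators), plus a linear trend of CLR abundance across LVDD
   grades.
4. **Metabolome-wide association (MWAA).** One linear model per
   metabolite against each retained species' CLR abundance on the
   subset with concurrent microbiome and metabolome data, BH-corrected
   per species at FDR 0.1.
5. **Metabolite–outcome models.** Species-associated metabolites are
   tested against prevalent LVDD (logistic, baseline-visit metabolome,
   FDR 0.1) and then against incident LVDD (modified Poisson, nominal
   p < 0.05).
6. **Proxy association.** Per species, the Spearman correlation between
   the metabolite-level Z-scores (β/SE) from species-side models and
   from incident-outcome models. A negative correlation reads as an
   indirect protective association of the species with incident
   disease.
7. **Risk prediction.** Elastic-net logistic regression with nested
   cross-validation comparing a traditional-risk-factor model with a
   metabolite-augmented model: honest out-of-fold AUCs, percentile
   bootstrap intervals, and a DeLong test for the AUC change.
8. **KO triangle.** KO gene families link retained species to
   incident-associated metabolites when both linear paths pass FDR 0.1
   and the sign product of the two paths matches the direct
   species–metabolite sign.

# Statistical components and their assumptions

## ANCOM-II

For taxa $i \ne j$ with abundances $x_i, x_j$, we fit
$\log(x_i/x_j) \sim \text{outcome} + \text{covariates}$ by OLS and count
for each taxon $W_i$, the number of partners $j$ whose outcome
coefficient survives within-taxon BH correction at $\alpha = 0.05$.
Detection requires $W_i \ge 0.7\,(m-1)$, the convention of the reference
implementation (the detection fraction is configurable). Because every
pairwise fit shares one design matrix, the coefficient of a pair is the
difference of per-taxon projections and the pair RSS is
$Q_{ii} + Q_{jj} - 2Q_{ij}$ for the residual cross-product matrix $Q$;
the production path exploits this identity and is tested for exact
equality against a naive double loop.

Zeros are classified before testing: *structural* zeros (a taxon absent
from ≥ 99% of one outcome group) auto-detect the taxon and remove it
from the pairwise pool; *outlier* zeros (zeros incompatible with the
group's nonzero log-abundance distribution, judged against a
quantile-minus-IQR fence) are set to missing; remaining *sampling*
zeros are imputed with the shared pseudocount (default 0.5 on counts).
The pseudocount default is a documented choice — the convention of
adding half a count — and is configurable; CLR results for zero-free
compositions are pseudocount-free and scale-invariant.

## Transforms

CLR: per sample, $\log(x + c)$ minus its mean over retained features,
computed after filtering (the filtered feature set is the denominator).
INT: below-detection intensities are replaced by half the minimum
detected value per metabolite, then average ranks are mapped through
$\Phi^{-1}\left((r - 3/8)/(n + 1/4)\right)$ (the Blom offset, the common
convention in omics). Detection ("> 75%") and prevalence ("> 20%")
filters are strict inequalities, and prevalence is computed on the
analysis set in use, since each stage defines its own included samples.

## Regression layer

Odds ratios come from maximum-likelihood logistic fits (separation is
flagged as non-converged rather than reported); relative risks from
Poisson regression with log link on the binary incident outcome and
HC0 sandwich standard errors — the modified Poisson estimator, whose
2×2 closed forms (RR and robust variance) the tests reproduce exactly.
Metabolite exposures are scaled per 1 SD on the analysis set; species
exposures are per CLR unit. The DerSimonian–Laird $\tau^2$ is the
non-iterative moment estimator floored at zero. All intervals and
p-values are Wald-type. BH families follow the per-analysis structure:
one family per species across the metabolome, one family per
metabolite–outcome analysis.

## Proxy association

Z-scores are $\beta/\mathrm{SE}$ on both sides. The Spearman p-value is
exact (permutation enumeration) for panels of ≤ 9 metabolites without
ties and uses the t approximation otherwise — at the study's panel size
(k ≈ 21) only the approximation is feasible, and reported p-values as
small as $10^{-7}$ imply the analytic form. All incident-associated
metabolites enter every species' test, not only metabolites significant
for that species.

## Prediction

The elastic-net mixing parameter is searched over
$\{0.1, 0.3, 0.5, 0.7, 0.9\}$ in the inner loop (the penalty path is
glmnet's); "10 × 10-fold" is read as 10 outer × 10 inner folds, with a
`repeats` option for the alternative reading. Reported AUCs use the
honest out-of-fold predictions (the in-sample AUC of the refit model is
also returned, but cross-validated performance is primary). SHAP values
for the refit linear model are exact:
$\phi_{ij} = \hat\beta_j (x_{ij} - \bar x_j)$, which satisfies the
efficiency property by construction and is asserted to $10^{-10}$.
AUC uses the Mann–Whitney rank identity with tie correction; its 95%
interval is a percentile bootstrap over (prediction, label) pairs
(10,000 iterations by default); the AUC change is tested with DeLong's
method for paired ROC curves.

# The synthetic cohort generator

Real cohort data of this kind are access-restricted, so the package
ships a generator whose defaults emulate the study conditions: n = 2000
subjects; 550 species of which ~95% pass the 20% prevalence filter
(log-normal latent abundances, between-species SD 2.0 log units,
within-species SD 1.0, pushed through per-sample multinomials at a mean
depth of 25,000 reads); 700 metabolites of which ~95% pass the 75%
detection filter (left-censored at the 10th percentile, a 4.5% subset
censored at 30% so the filter has work to do); 2,042 KO gene families
as row-normalized relative abundances.

Planted structure: 7 differential species (3 protective, 4 risk) at
±0.5 log-odds per SD of CLR abundance — the smallest effect at which
the W ≥ 0.7(m−1) rule reliably recovers ≥ 5 of 7 at the discovery
sample size — plus 2 species hard-zeroed in the prevalent stratum
(structural zeros). 220 metabolites receive species edges
(standardized slopes 0.12–0.30); nested subsets of 46 and 21 carry
direct prevalent (±0.25/SD log-odds) and incident (log-RR ±0.10–0.22,
i.e. RR ≈ 0.80–1.25) effects. Three "proxy" species carry metabolite
signatures anti-aligned (the two protective) or aligned (one risk
species) with the incident-effect vector, so the planted proxy
correlations are negative, negative, positive. Covariates follow simple
parametric families at the study's published margins (mean age 59.4,
67% female, prevalent rate 45.9%, incident rate 212/594 among
baseline-negative subjects under follow-up); outcome intercepts are
calibrated numerically to those rates at generation time. The incident
model uses a log link capped at risk 0.95, so the planted coefficient's
exponent is the true relative risk.

Deliberate simplifications (what passing tests do *not* show about real
data): no real taxonomy or phylogenetic correlation, no survey design
or batch structure, metabolite noise is Gaussian and independent given
species, one metabolite matrix serves both the baseline-visit and the
concurrent analyses, and the incident risk among metabolites is driven
by independent per-metabolite effects rather than shared biological
factors — which makes the planted joint metabolite signal (and hence
the augmented model's AUC, ~0.82 vs ~0.67 for the traditional model)
stronger than a real cohort's. Because planted species also drive
prevalent disease directly, non-planted species-associated metabolites
acquire genuine mediated associations with the prevalent outcome, so
the prevalent-metabolite stage typically flags ~100–150 metabolites
rather than only the 46 with direct planted effects.

The analysis sets overlap (the concurrent microbiome+metabolome
subset sits inside the visit-2 cohort, and the baseline-visit
metabolome overlaps both), so membership is encoded as boolean flags
(`set_discovery`/`set_validation` partition, `in_concurrent`,
`in_baseline_v1`, `has_followup`) rather than a single exclusive label.

# Numerical choices and degenerate inputs

- One RNG stream per entry point, seeded from the `run_config`/function
  seed and restored afterwards; identical seeds give byte-identical
  cohorts, fold assignments, bootstrap draws, and therefore outputs.
- Intercept calibration for outcome rates is a 1-d root find on the
  realized linear predictor (tolerance 1e-10), which pins the marginal
  rate without touching planted slopes.
- All-zero samples, all-below-detection metabolites, constant grades,
  single-class outcomes, rank-deficient designs, non-positive SEs and
  empty sample intersections raise immediate errors; logistic
  separation is flagged (`converged = FALSE`) and such candidate
  species are dropped from pooling rather than propagated.
- Proxy panels need k ≥ 3; a species with fewer usable metabolites is
  skipped. Bootstrap AUC iterations that lose an outcome class are
  redrawn.
- Pairwise ANCOM p-values with outlier-zero missingness fall back to
  per-pair complete-case fits; the fast shared-projection path is used
  only where no entries are missing, and the two paths are tested to
  agree exactly.

# Problem sizes used in validation

The shipped checks run ANCOM-II calibration at n = 200 × m = 50 over
100 null replicates (detected fraction vs the nominal level) and 50
planted replicates (a 1-SD latent shift must attain the maximum W in ≥
90%); modified-Poisson coverage at n = 594 with 1000 replicates per
design (planted RR 1.0 and 1.5, coverage within 0.93–0.97); MWAA FDR
control over 200 replicates (fully null and 25%-signal designs);
proxy-association sign recovery at k = 21 over 20 mediation replicates
plus a Kolmogorov–Smirnov uniformity check over 250 nulls; prediction
power at n = 594 over 15 replicates (augmented model must beat the
traditional model by DeLong p < 0.05 in ≥ 90%); and one full-scale
pipeline run (n = 2000, 550 species, 700 metabolites,
2,042 KOs) that must recover ≥ 5 of 7 planted species with all three
planted proxy directions.

# Known limitations

- The ANCOM-II covariate formulation is log-ratio-on-outcome
  regression; the W cutoff, zero-handling thresholds and within-taxon
  correction (BH) are the reference implementation's conventions, all
  configurable.
- No survey weighting, mixed models, time-to-event modeling, batch
  correction, or causal mediation — the proxy analysis is a correlation
  of Z-vectors and nothing more.
- Cross-validated and in-sample AUCs are both reported; the
  cross-validated value is primary.
- The KO triangle mixes FDR-controlled linear layers with a nominal
  p < 0.05 outcome layer, mirroring the analysis design it reproduces;
  edge lists should be read as hypothesis-generating.
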