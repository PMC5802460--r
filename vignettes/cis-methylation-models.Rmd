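---
title: "Cis-genetic methylation models and summary-statistic association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cis-genetic methylation models and summary-statistic association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismeth)
```

## The problem

A fraction of inter-individual variation in whole-blood DNA methylation is
driven by nearby common genetic variation (cis-mQTLs). That genetically
driven component can be *predicted from genotypes alone*, which enables two
things: testing a trait against the genetic component of a CpG's
methylation in any genotyped cohort, and — more importantly — testing it in
cohorts where only GWAS summary statistics exist, by re-expressing the
association statistic in terms of per-SNP z-scores and a reference-panel
SNP covariance. This package implements that full chain: QC and
transforms, per-CpG elastic-net model training and selection, individual-
level and summary-level association, the simulation machinery to validate
both, and downstream expression/enrichment integration.

## The model

For a CpG with adjusted methylation signal $y$ (M-values residualized on
covariates) and cis-SNP dosage matrix $X$ (all imputed SNPs within
$\pm 1\,$Mbp, closed interval), we fit the elastic net

$$\min_{b_0, b}\; \frac{1}{2n}\lVert y - b_0 - X b\rVert^2 +
\lambda\left(\alpha \lVert b\rVert_1 + \frac{1-\alpha}{2}\lVert b\rVert^2\right)$$

with the mixing parameter fixed at $\alpha = 0.5$ and $\lambda$ tuned by
10-fold cross-validation (`glmnet`). Predictors are standardized
internally and coefficients are returned on the original dosage scale.
Only CpGs flanked by more than one cis-SNP are eligible; a fit selecting
zero SNPs at the tuned penalty is a *null model* and is not stored. The
genetic methylation estimate for individual $i$ is the linear score
$\hat g_i = b_0 + \sum_k w_k d_{ik}$.

Model quality is summarized as $r^2$, the squared Pearson correlation
between an estimate and the observed adjusted signal: `cv_r2` uses the
*prevalidated* cross-validation estimate (each sample predicted by the
fold model not trained on it), `test_r2` uses an independent panel.
Robust models must pass a double FDR screen: Benjamini–Hochberg-adjusted
cross-validation p below 0.05 across all stored models, BH-adjusted test p
below 0.05 among the survivors, and a *positive* test correlation.

## Association statistics

With individual genotypes, the estimate is tested against a trait by the
exact Pearson correlation test, $T_g = r\sqrt{n-2}/\sqrt{1-r^2}$.

With only GWAS summary statistics, $T_g$ is re-expressed per SNP. The
exact identity

$$T_g = \sum_k w_k \frac{\hat\sigma_k}{\hat\sigma_g}
\frac{\hat\beta_k}{se(\hat\beta_k)}
\sqrt{\frac{1-R_k^2}{1-R_g^2}},
\qquad \hat\sigma_g = \sqrt{W'\Sigma_p W}$$

holds when the SNP standard deviations $\hat\sigma_k$, the covariance
$\Sigma_p$, the marginal statistics and the variance fractions
$R_k^2, R_g^2$ all come from the study sample itself (`exact_z`; the test
suite checks the identity to $10^{-6}$). Without genotypes neither
$R_g^2$ nor $\Sigma_p$ is observable, which motivates the approximation

$$Z_g = \sum_k w_k \frac{\hat\sigma_k}{\hat\sigma_{g,\mathrm{ref}}}
\frac{\hat\beta_k}{se(\hat\beta_k)}, \qquad
\hat\sigma_{g,\mathrm{ref}} = \sqrt{W'\,\Sigma_\mathrm{ref}\,W}$$

with $\Sigma_\mathrm{ref}$ estimated from a reference panel (`sumstat_z`).
Two caveats follow. Dropping the $R^2$ ratio deflates the statistic when
effects are large ($R_g^2 > \max_k R_k^2$), which is the conservative
direction. Reference/study covariance mismatch, by contrast, can inflate
it; we therefore penalize the denominator with a diagonal shrinkage,
$\Sigma_\mathrm{ref} \leftarrow \Sigma_\mathrm{ref} +
\lambda_s\,\mathrm{diag}(\Sigma_\mathrm{ref})$ with $\lambda_s = 0.1$,
applied *only* inside $\hat\sigma_{g,\mathrm{ref}}$ — the numerator
$\hat\sigma_k$ stays unshrunk. The type-I error study
(`type1_study`) verifies the resulting conservatism: across repeated null
scans, the 5% quantile of the per-scan minimum p sits at or above the
Bonferroni threshold.

### Harmonization and coverage

Models and external data (GWAS tables, genotype panels) are matched by SNP
id and allele pair. The default policy also accepts swapped alleles,
negating the external z (or reflecting the dosage as $2-d$); any other
pair is an allelic mismatch and is discarded. Strand-ambiguous A/T and C/G
SNPs are retained by default (they are matched by id and alleles, never by
frequency) and can be dropped by flag. Coverage is the matched fraction of
a model's SNPs: predictions require $\geq 50\%$, summary-statistic scans
$\geq 80\%$, both configurable. Inside `sumstat_z` the statistic is
computed over the matched subset in both numerator and denominator — i.e.
it is the truncated model's own properly standardized association — while
coverage is always reported against the full model.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.5 | elastic-net mixing (L1 vs L2) |
| `n_folds` | 10 | cross-validation folds |
| `lambda_rule` | min-cv-error | penalty choice (one-SE available) |
| `window_bp` | 1e6 | cis half-window, closed interval, bp |
| `maf_min` | 0.05 train / 0.01 eval | MAF pass rule (strict `>`) |
| `hwe_p_min` | 1e-4 | HWE chi-square p pass rule |
| `imp_r2_min` | 0.8 train / 0.5 eval | imputation quality rule |
| `cpg_missing_max` | 0.05 | CpG missing-rate rule (`>=` fails) |
| `lambda_s` | 0.1 | covariance diagonal shrinkage |
| `coverage_min` | 0.5 predict / 0.8 scan | matched-SNP floor |
| `fdr_q` | 0.05 | BH threshold in model selection |

Thresholds are strict inequalities: a SNP with MAF exactly 0.05 fails.
The HWE test is the 1-df chi-square goodness of fit on hard-calls (rounded
dosages), with monomorphic markers assigned p = 1; an exact test is a
possible extension. M-values use $\log_2$; the base only rescales the
signal and cannot change any correlation-based quantity.

## The synthetic-data generator

Real training data for this method are individual-level genotype and
methylation panels, which cannot ship with a package. The generator
(`sim_config`, `simulate_genotypes`, `simulate_methylation`,
`simulate_trait`, `simulate_gwas_summary`) emulates the statistical
structure the method relies on:

* **Genotypes.** A Gaussian copula: per haplotype, a latent AR(1) normal
  vector with adjacent correlation `ld_rho` (default 0.7) is thresholded
  at MAF-matched quantiles (MAF drawn uniformly on 0.05–0.5), and two
  haplotypes are summed to a dosage. This produces blocky, decaying LD
  and realistic allele-frequency spectra, but not recombination hotspots,
  coalescent allele-frequency correlations, or imputation dosage noise.
* **Methylation.** One CpG per region with `n_causal` (default 3) causal
  cis-SNPs, effects standard normal, and Gaussian noise scaled on the
  realized panel so the genetic variance fraction hits the target `h2`.
  The default `h2 = 0.09` matches the average SNP-based cis-heritability
  at CpGs where a model can be fitted; 0.04 emulates those where it
  cannot. Causal architecture is a deterministic function of the
  population seed, so independently drawn panels (training, testing,
  reference, GWAS cohort) share the same ground truth.
* **Traits.** Null traits are standard normal; correlated traits are
  `r * standardized(estimate) + sqrt(1-r^2) * noise`, so the population
  estimate–trait correlation is exactly `r`.
* **Summary statistics.** Per-SNP OLS of a cohort trait on each dosage,
  yielding effect, SE, z, $R_k^2$ and n.

What passing tests on these data show: the algebraic identities, the
calibration and conservatism of the statistics, and the recovery of known
heritability. What they cannot show: robustness to real LD pathology,
population stratification, batch structure, or array artefacts.

## Numerical and design choices

* **Penalty rule.** The cross-validation loss is mean squared error and
  the default rule is the CV-minimizing $\lambda$; the one-SE rule is a
  flag. Fold assignment is a seeded unstratified random partition.
* **FDR sequencing.** The test-stage FDR is computed among survivors of
  the cross-validation stage (the stricter sequential reading); computing
  it across all models instead would only loosen criterion 2.
* **Missing dosages** are mean-imputed per SNP before fitting and
  prediction, for determinism; model SNPs entirely absent from a panel
  contribute zero to the score.
* **Zero-variance matched SNPs** keep a zero covariance row/column and
  contribute nothing to either side of the statistic.
* **Ties** in the best-univariate-mQTL search break to the lowest
  position, then lexicographic id. BH uses the standard step-up with
  cumulative minima (`p.adjust`).
* **Window boundaries** are inclusive at exactly $\pm 1\,$Mbp; gene cis
  windows extend from gene boundaries, not the TSS.
* **Power sidedness.** The 50%-power design point ($r^2 = 7.1\%$ at
  $n = 319$, $\alpha = 0.05/86{,}518$) is consistent with a one-sided
  Fisher-z calculation — `fisher_design_r2(0.5, 319, 0.05/86518)` returns
  0.071, while the two-sided version lands near 6% — so the power
  machinery defaults to one-sided rejection, with two-sided available.
* **Permutation p-values** use the add-one estimator, flooring at
  $1/(n_\mathrm{perm}+1)$.
* **Batch adjustment** enters as a categorical covariate in
  `residualize` (one-hot, one level dropped) rather than as a separate
  empirical-Bayes step.
* **kNN imputation** of missing methylation (k = 10) uses Euclidean
  distances over shared observed samples, rescaled by the shared count,
  falling back to the column mean when fewer than k usable neighbours
  exist.

## Problem sizes used by the test suite

The simulation studies in the tests run at desk scale, chosen to keep the
whole suite near half a minute while leaving Monte-Carlo noise well inside
the asserted tolerances: 50 regions × 40 SNPs at n = 500 for the shared
study fixture (cis-h² 0.25), n = 2,000 with 100 SNPs per region for
heritability recovery at h² = 0.09, 1,000 null scans for the type-I error
study, and 3,000 total replicates (50 CpGs × 60) for the power checks at
the designed effect size.

## Known limitations

Trans-genetic components are out of scope, as are genotype imputation,
liftover, case-control liability-scale traits, conditional multi-CpG
fine-mapping, colocalization, and correction for sample overlap between
the GWAS and the reference panel. The model store is a plain-text format
original to this package. Reproducing published real-data hit counts
requires the corresponding cohort genotypes and consortium GWAS downloads;
the scan driver supports them, but nothing in this package depends on
external data.
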