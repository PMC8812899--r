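---
title: "Drug-target cis MR with correlated instruments: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target cis MR with correlated instruments: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctmr)
```

## The estimation problem

Drug-target mendelian randomization asks what long-term pharmacological
modulation of a protein target would do to disease risk, using germline
variants in or near the target's gene as instruments. Because cis variants
influencing the same target are frequently in linkage disequilibrium with one
another, the package's central estimator is the LD-aware inverse-variance
weighted (IVW) model: a generalized weighted regression of variant–outcome on
variant–exposure associations through the origin, with weighting matrix
$\Omega = D\rho D$ built from the outcome standard errors $D$ and the
*signed* LD correlation matrix $\rho$. Signs matter: $\rho$ built from
$r^2$ alone can misstate $\Omega$ badly, so `ivw_correlated()` requires
signed correlations and the LD reader preserves them.

Three modelling conventions are worth stating explicitly.

* **Normal inference.** P-values and confidence intervals use the normal
  distribution, not the t — the convention of summary-data MR where the
  contributing GWAS have five to six figure sample sizes. P-values are
  computed on the log scale and clamped at the smallest normal double, so a
  pooled association at $z \approx 31$ (p near $10^{-213}$) survives
  arithmetic.
* **Multiplicative random effects with an under-dispersion floor.** The
  residual scale $\hat\varphi^2$ is the $\Omega$-weighted residual mean
  square on $j-1$ degrees of freedom. Over-dispersion inflates the standard
  error by $\hat\varphi$; under-dispersion ($\hat\varphi < 1$) is truncated
  to 1 rather than allowed to shrink the fixed-effect standard error. The
  multivariable extension uses $j - E$ residual degrees of freedom for $E$
  exposures — the standard weighted-regression convention, chosen because
  no alternative is stated in the drug-target MR literature.
* **Orientation.** Estimates are computed per unit *higher* exposure
  internally; the `orientation` argument flips the sign at reporting so that
  results can be framed per unit of target *inhibition* (e.g. per 1 mm Hg
  lower systolic blood pressure, per SD lower serum enzyme concentration).
  The flip is exact: $\theta \mapsto -\theta$, OR $\mapsto$ 1/OR, SE
  unchanged. `scale_odds_ratio()` multiplies $\theta$, its SE and the CI
  bounds on the log-odds scale, e.g. by 8 to express an effect per the
  8 mm Hg blood-pressure reduction typical of treatment trials; it is
  exactly equivariant under composition.

## Instrument construction choices

`select_cis_candidates()` treats "within ±100 kb" as a *closed* interval
measured from the gene's start and end (not its midpoint); a variant exactly
at the boundary is retained. Genome-wide significance is strict
(`p < 5e-8`). Pruning is greedy and p-value-ranked (clumping-style): sweep
candidates from most to least significant and accept a variant only if its
$r^2$ with everything already accepted is strictly below the threshold, so a
pair at exactly $r^2 = 0.10$ is pruned. Ties on p break on smaller standard
error, then lexicographic variant id — the output is deterministic. Greedy
ranking was chosen because only the $r^2$ threshold, not the algorithm, is
conventionally reported with such analyses; the procedure always retains the
top signal and is a fixed point under re-application.

Instrument strength uses two estimators of per-variant variance explained:
`eaf_beta` ($2f(1-f)\beta^2$, valid when the trait is standardized) and
`z_n` ($z^2/(z^2+n-2)$, the univariable regression identity, usable from a
p-value and sample size alone). Multi-variant $r^2$ sums per-variant
contributions — valid under the weak LD that pruning enforces and documented
as approximate; an LD-adjusted quadratic-form variant
(`r2_method = "ld_adjusted"`) is available. $F = r^2(n-k-1)/((1-r^2)k)$ with
$k$ exposed explicitly, because published F ranges for multi-variant
instruments are not always reproducible without knowing the $k$ convention
used.

When two exposure GWAS cover the same trait they are pooled by
inverse-variance fixed effects (weights $1/\mathrm{se}^2$), and instrument
candidacy additionally requires the same nonzero effect direction in both
inputs. A beta of exactly zero fails that concordance test — the sign is
undefined, and exclusion is the conservative choice. The
genome-wide-significance and concordance filters are applied jointly, which
makes their order irrelevant.

## Harmonization

Exposure and outcome tables are aligned per variant to a common effect
allele: a swapped pair flips the outcome beta and complements its EAF;
strand complements (A↔T, C↔G) are tried for non-palindromic variants before
a pair is declared incompatible (incompatibility is flagged, never silent).
Palindromic variants carry no strand information in their letters, so
orientation falls back on allele frequency: within the ambiguity band
EAF $\in 0.5 \pm 0.08$ the variant is dropped and flagged; outside it, the
side of 0.5 decides. The 0.08 half-width is the common harmonization default
and is configurable; ambiguity is assessed in the *outcome* table, since the
exposure GWAS from which instruments are drawn typically reports frequencies
more reliably. Harmonizing an already-aligned pair is a no-op (idempotence),
and pre-flipping the outcome's alleles and sign leaves the output unchanged
(anti-symmetry) — both are enforced by tests.

## Colocalization

`coloc_posteriors()` enumerates single-causal-variant configurations over
the variants shared by two traits. Per variant, the Wakefield log
approximate Bayes factor is $\tfrac12\log(1-r) + rz^2/2$ with shrinkage
$r = W/(V+W)$; hypothesis weights are accumulated entirely in log space
(log-sum-exp), so a region with $|z| = 40$ in both traits yields finite,
normalized posteriors. Priors default to $p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$, the field's conventional values, with a sensitivity
sweep over $p_{12}$ provided (`coloc_prior_sensitivity()`); effect-scale
prior SDs default to 0.15 for quantitative traits and 0.20 for log-odds
traits. The single-causal-variant-per-trait assumption is inherent to the
enumeration; regions harbouring secondary signals need conditioning, which
is out of scope and flagged as a limitation. Variants present in only one
trait are dropped with a logged count. The posterior support threshold of
0.80 for declaring a shared (H4) or distinct (H3) causal variant is the
conventional reading adopted throughout the pipeline.

## The synthetic-data generators

The generators exist so that every stage can be validated against known
ground truth without consortium data.

* **Genotypes** follow a Gaussian copula: a latent AR(1) multivariate normal
  (parameter `ld_rho`) thresholded per variant at the Hardy–Weinberg
  quantiles of its allele frequency. This gives direct control of pairwise
  LD at desk scale but does not reproduce haplotype block structure,
  recombination hotspots, or allele-frequency/LD coupling; dosage
  correlations are attenuated relative to the latent parameter (about 0.76
  at `ld_rho = 0.9`), which the tests measure empirically rather than
  assume.
* **Cohorts**: the exposure is $X = G\beta + \varepsilon$ with the noise
  variance set so $\mathrm{Var}(X) = 1$; case status is logistic with
  intercept tuned by root-finding to the target case fraction. Summary
  statistics are *marginal* per-variant regressions — linear for the
  exposure, logistic for the outcome — matching what consortia publish. By
  default both GWAS use the same simulated cohort (cohort-style
  case-control); an ascertained-sampling option draws a balanced
  case-control subset from a five-fold pool for studying outcome-dependent
  sampling. Because the exposure and outcome are measured in one cohort and
  the outcome model is logistic, the IVW estimate carries a small positive
  finite-sample bias (sample overlap plus non-collapsibility); across 200
  replicates at $n = 20{,}000$, $m = 8$, $\theta = 0.1$ it measures ~2–4%
  and stays under the 10% bound asserted in the acceptance suite, with 95%
  CI coverage between 0.90 and 0.98.
* **Regional pairs** for colocalization place one shared causal variant,
  two distinct ones (separated until their latent correlation is below
  0.3), or none, over a common panel analysed in two independently drawn
  cohorts of 5,000.
* **Expression panels** plant per-gene effects of a standardized weighted
  dosage score, add covariate contributions (one binary, the rest
  Gaussian), calibrate the pre-transform variance to 1, and apply a
  rank-based inverse normal transform per gene (Blom offset). For Gaussian
  data the transform is nearly the identity, so a planted effect of −0.42
  at $n = 445$ is recovered within 2 standard errors in ≈96% of
  replicates. What passing these suites shows is that the estimators are
  correct under their own assumptions; real GWAS add population structure,
  imputation error and haplotype complexity that the copula model does not
  emulate.

Every generator is deterministic given `seed` and all simulation sizes
above (200 cohort replicates, 100 regions per colocalization scenario,
2,000 expression replicates) are the package's chosen validation scale.

## Numerical and degenerate-input policy

LD matrices must be symmetric to $10^{-6}$ and are repaired to positive
semi-definiteness by eigenvalue clipping (clip at zero, rescale to unit
diagonal) when the smallest eigenvalue falls below $-10^{-8}$; missing
long-format pairs default to $r = 0$ with a warning, a safe default only
because pruned instruments are weakly correlated by construction. A singular
$\Omega$ after repair is an error, as are a zero exposure beta in the Wald
ratio, a single variant passed to leave-one-out, rank-deficient exposure
matrices in multivariable MR (reported as collinear), rank-deficient
covariates in the transcriptome scan (reported by column name), and an empty
eQTL intersection. Reported p-values are sanity-checked against beta/se with
a tolerance that widens with significance — published tables round their
betas, which moves the implied p by several orders of magnitude at extreme z
— and inconsistency warns rather than rejects. Genotype dosages with missing
entries are mean-imputed per variant before scoring. Evidence tiers follow
the Bonferroni heuristic: strong below $\alpha/\text{tests}$, weak up to
p = 0.20, little otherwise.

## Known limitations

Pleiotropy-robust estimators (MR-Egger, weighted median/mode), Steiger
filtering, fine-mapping and conditional analysis, coexpression-module
detection, and hidden-expression-factor estimation are deliberately out of
scope; covariates for the transcriptome scan are accepted as a user-supplied
matrix. Colocalization power is limited at realistic effect sizes — a low
PP.H4 is not evidence of distinct variants when both traits' signals are
weak, which is why the pipeline reports the full posterior vector rather
than a binary call.
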