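---
title: "Methods: two-sample Mendelian randomization from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmr)
```

## The problem

Observational associations between circulating lipid levels and disease
risk are confounded by lifestyle, medication and reverse causation.
Mendelian randomization (MR) sidesteps this by using genetic variants as
instrumental variables: alleles are assorted at conception, so a variant
that robustly raises a lipid trait provides a quasi-randomized contrast
of lifelong exposure. `lipidmr` implements the full summary-statistics
workflow of a modern lipid-to-disease MR study: instrument construction,
single-exposure estimators with diagnostics, multivariable MR,
locus-restricted MR with cross-gene meta-analysis, per-SNP GWAS
meta-analysis, and cross-trait LD-score regression — together with a
generator of synthetic two-sample GWAS data so that every stage is
verifiable by parameter recovery without access to cohort data.

## Model and estimators

For instrument $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its
association with the exposure and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) its
association with the outcome, estimated in non-overlapping samples
("two-sample" design). Outcome effects for case-control traits are log
odds ratios. The per-SNP Wald ratio is $r_j = \hat\beta_{Yj} /
\hat\beta_{Xj}$ with first-order SE $\sigma_{Yj}/|\hat\beta_{Xj}|$ and
inverse-variance weight $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$.

* **IVW**: $\hat\theta = \sum w_j r_j / \sum w_j$, fixed-effects SE
  $(\sum w_j)^{-1/2}$. The default *multiplicative random-effects* model
  scales that SE by $\max(1, \sqrt{Q/(k-1)})$ where $Q = \sum w_j (r_j -
  \hat\theta)^2$ is Cochran's heterogeneity statistic. The floor at 1
  means underdispersion never shrinks the SE.
* **MR-Egger**: weighted regression of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$ *with* an intercept (weights $1/\sigma_{Yj}^2$), after
  orienting all instruments to positive exposure effects. A nonzero
  intercept estimates the average directional pleiotropic effect; the
  slope is a pleiotropy-robust causal estimate under the InSIDE
  assumption.
* **Weighted median**: the ratio value at cumulative weight midpoint 0.5
  (linear interpolation between order statistics); consistent while at
  least half the weight comes from valid instruments.
* **Mode-based**: the argmax of a normal-kernel density over the ratios
  with bandwidth $0.9\,\min(\mathrm{sd}, \mathrm{IQR}/1.349)\,k^{-1/5}$
  (tunable by a multiplier); consistent when the largest homogeneous
  cluster is valid. The argmax is refined by root-finding on the
  density's analytic derivative, which is numerically far better
  conditioned than comparing density values near the flat peak.

SEs for median and mode come from a parametric bootstrap (normal
resampling of both exposure and outcome betas, default 1000 draws,
seeded and bit-reproducible). All p-values are two-sided normal, the
convention for large-instrument summary-data MR; ORs and 95% CIs are
$\exp(\hat\theta \pm 1.959964\,\mathrm{SE})$.

**Multivariable MR** regresses outcome betas on the $m \times K$ matrix
of exposure betas without intercept, weights $1/\sigma_{Yj}^2$, giving
each exposure's *direct* effect conditional on the others. Global
heterogeneity $Q_A$ (df $m-K$) feeds the same multiplicative dispersion
rule. Instrument strength per exposure is summarised by a conditional
F statistic in the Sanderson-Windmeijer style: the exposure's betas are
regressed on the other exposures' betas and the residual association,
standardised by the exposure SEs, is divided by $m-K+1$. F < 10 flags a
weak exposure; the flag is reported, never auto-enforced.

**Diagnostics.** The Steiger test compares instrument $r^2$ in exposure
versus outcome ($r^2_j = t_j^2/(t_j^2+n-2)$; case-control traits use the
effective size $4/(1/n_\text{case}+1/n_\text{control})$) and reports a
Fisher-z p-value for the difference — a guard against reverse causation.
Analytic power for a binary outcome uses the noncentrality
$|\ln \mathrm{OR}|\sqrt{N r^2 \varphi(1-\varphi)}$ with case fraction
$\varphi$; we use the two-sided form, which equals $\alpha$ at the null
(the common one-tailed shortcut gives $\alpha/2$ and understates power
slightly near the null).

## Instrument construction

Instruments are genome-wide significant SNPs ($p < 5\times10^{-8}$,
strict) thinned by greedy LD clumping: SNPs ranked by ascending p (ties
broken lexicographically by rsID for reproducibility), best SNP
accepted, everything with $r^2 \ge 0.001$ to an accepted SNP discarded.
SNPs absent from the LD matrix are dropped rather than assumed
independent. Passing `ld = NULL` declares the universe unlinked — the
synthetic studies simulate unlinked SNPs, and this avoids materialising
large identity matrices in replicate loops.

Two pruning procedures mirror common sensitivity analyses:
*cross-trait pruning* removes instruments associated ($p < 10^{-3}$)
with any competing trait; *heterogeneity pruning* iteratively removes
the instrument with the largest Cochran's Q contribution
$w_j(r_j-\hat\theta)^2$, refitting each round, until the Q p-value
reaches 0.05 (configurable) or a floor of 3 instruments. Because the
refitted estimate minimises the new Q, each removal strictly decreases
Q, so termination is guaranteed. The multivariable analogue prunes on
$Q_A$ contributions with a floor of $K+2$ instruments.

## Harmonization

Tables are aligned SNP-by-SNP (rsID-keyed) to the first exposure's
effect allele: identical pairs are kept; swapped alleles flip the beta
sign and complement the frequency; reverse-complement pairs are
strand-flipped first. Palindromic SNPs (A/T, C/G) cannot be resolved
from alleles alone: when both allele frequencies lie outside
$0.5 \pm 0.08$ the strand is inferred from frequency concordance,
otherwise the SNP is dropped. Every shared SNP receives exactly one
action (`kept`, `flipped`, `dropped_palindromic`, `dropped_mismatch`),
so filtering counts always reconcile. Multi-allelic rsIDs (duplicated
IDs) are rejected at read time; coordinates are 1-based inclusive and
used only for locus windows.

## Locus-specific MR and meta-analysis

Gene-specific analyses take *conditionally independent* association
statistics (from prior stepwise conditional analysis; trusted as
independent, no clumping) within a gene's span extended by a 100 kb
flank on both sides, harmonize them to the outcome, and run
fixed-effects IVW per locus. Loci with fewer than two surviving
instruments are excluded, not errored. Per-locus estimates are pooled by
fixed-effects inverse-variance meta-analysis with a cross-locus Q. The
package ships a 16-gene core HDL/LDL pathway locus table
(`inst/extdata/core_lipid_loci.tsv`, hg19 RefSeq spans); the
conditional statistics themselves must be supplied (or simulated). The
same pooling kernel drives the per-SNP fixed-effects meta-analysis of
two GWAS, with allele alignment and pass-through (flagged) of
single-study SNPs.

## Cross-trait LD-score regression

For trait heritability, squared z-scores are regressed on LD scores,
$E[z_j^2] = a + (n h^2/M)\,\ell_j$; for genetic covariance, z-score
products, $E[z_{1j} z_{2j}] = a_c + (\sqrt{n_1 n_2}\,\rho_g/M)\,\ell_j$,
with the intercept absorbing confounding inflation and sample overlap
respectively (overlap is never fixed, always estimated). Estimation is
the standard two-step: intercept from the $\chi^2 < 30$ subset
(symmetric $|y| < 30$ for products), then the slope on all SNPs with the
intercept fixed. Weights combine the oversampling ($1/\ell$) and
heteroskedasticity ($1/\mathrm{Var}$) terms, fixed from an OLS prefit;
univariate and cross-trait fits share one kernel, and the cross-trait
weights reduce exactly to the univariate ones when the two traits are
identical, so that degenerate case reproduces the univariate fit to
machine precision. Uncertainty comes from a delete-one-block jackknife
over 200 contiguous blocks, with all three regressions sharing one block
partition so the jackknife propagates the full uncertainty of
$r_g = \rho_g/\sqrt{h^2_1 h^2_2}$ (reported only when both
heritabilities are positive). The Bonferroni threshold helper
(`alpha/n_tests`) covers partitioned per-locus scans; the number of
LD-independent partitions is an argument, since published partition
counts differ by one between sources.

## The synthetic-data generator

`simulation_config()` defines the generative model; defaults emulate
the design of a large lipids-to-breast-cancer MR study:

* five exposures (`hdl`, `ldl`, `tg`, `bmi`, `menarche`) measured in
  GWAS of n = 200,000 each; a case-control outcome of 120,000 cases /
  100,000 controls;
* m = 2,000 unlinked SNPs with MAF uniform on (0.05, 0.5) — a
  scaled-down genome sized so that a replicate study simulates and fits
  in well under a second;
* a shared spike-and-slab architecture: 5% of SNPs form a common causal
  pool; their effects on the K exposures are multivariate normal with a
  correlation matrix whose defaults carry the signs and rough magnitudes
  of reported genetic correlations among these traits (HDL-TG strongly
  negative, HDL-BMI negative, LDL-TG positive, menarche linked to BMI);
  effects are rescaled so each exposure's realized variance explained is
  exactly `h2_x` (default 0.1);
* direct (true) effects on the outcome's log-OR scale,
  $\theta = (0.06, 0.04, -0.02, -0.10, -0.04)$;
* optional pleiotropy: a fraction of causal SNPs receives a direct
  outcome effect, drawn normal, or scaled with instrument strength when
  the InSIDE assumption should be violated;
* summary statistics are simulated directly at the summary level:
  $\hat\beta \sim N(\beta, \sigma)$ with
  $\sigma_X = (2p(1-p)\,n)^{-1/2}$ for SD-unit traits and
  $\sigma_Y = (2p(1-p)\,N\varphi(1-\varphi))^{-1/2}$ for the
  case-control outcome (logistic-GWAS approximation). Exposure and
  outcome noise are independent, as in a two-sample design. All draws
  derive from the config seed; an optional separate noise seed allows
  replicate studies of one fixed true model.

**What single-trait MR estimates here.** Because the exposures' true
effects are correlated, a single-trait analysis of exposure $k$
consistently targets the *marginal* (total) effect
$\theta_k + \sum_{l \ne k} \theta_l\, \langle\beta_l,
\beta_k\rangle/\langle\beta_k,\beta_k\rangle$ (heterozygosity-weighted
projection), not the direct $\theta_k$ — this is precisely why
multivariable MR exists. The generator books both quantities
(`theta_marginal`, `theta`), and recovery checks compare each estimator
to its own estimand. Expecting single-trait MR to recover the direct
effect on correlated-exposure data would fail for a *correct*
implementation.

**What the generator does not emulate:** linkage disequilibrium between
causal and tag SNPs (blocks are available but default off; clumping on
real data does real work that is only lightly exercised here),
population stratification, allele-frequency differences between
cohorts, binary-trait noncollapsibility beyond the logistic
approximation, and winner's-curse effects of discovery-sample overlap.
Passing recovery tests therefore demonstrates correctness of the
estimators and plumbing under the stated model, not robustness to every
pathology of real GWAS data.

## Numerical choices and degenerate inputs

* Dispersion floors at 1 for all multiplicative random-effects SEs.
* Clumping tie-breaks are lexicographic; all pruning is deterministic.
* Zero exposure betas are rejected before ratio estimation (a
  single-instrument Wald helper covers k = 1).
* The mode estimator returns the common value when all ratios coincide
  (zero bandwidth); otherwise the argmax is a derivative root, with a
  value-comparison fallback if the bracket fails.
* Out-of-range allele frequencies are treated as missing rather than
  fatal; missing sample sizes make Steiger/LDSC error rather than
  impute.
* Bootstrap and simulation RNG is always locally seeded and restored,
  so package calls never perturb the caller's RNG stream.

## Verification conditions

The acceptance suite runs: closed-form oracle equivalence on
toy sets of up to 7 instruments (1e-10 relative tolerance); CI coverage
of the generative effects over 100 replicates of the 5-exposure fixture;
Egger-intercept size and IVW type-I error over 1000 single-exposure
replicates (m = 300, strong instruments); genetic-correlation recovery
over 100 seeds of 50,000-SNP panels representing a 500,000-SNP genome
(that scaling keeps the mean chi-square near 1.3, the realistic regime
for the two-step fit — when the panel represents only itself the signal
density is far above anything seen in real GWAS and the chi-square
truncation visibly biases the univariate slopes); and analytic-vs-Monte
Carlo power agreement at three instrument-strength settings with a
near-noiseless exposure GWAS, matching the assumptions of the analytic
formula. These sizes keep the full suite under a minute on one CPU.

## Limitations

Correlated instruments (generalized IVW), MR-PRESSO-style outlier
tests, contamination-mixture estimators, MVMR-Egger, partitioned
heritability and local genetic-correlation estimation are out of scope.
LD matrices define the clumping universe; the package never computes LD
from genotypes. Real-data reproduction of published lipid results
requires the corresponding public summary statistics; the pipeline
emits tables shaped so that comparison is a single join.
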