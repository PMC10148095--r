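---
title: "Methods: summary-statistics MR with ratio-phenotype exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics MR with ratio-phenotype exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratiomr)
```

## The problem

Enzyme activities are rarely measured directly in population cohorts, but
the ratio of an enzyme's product to its substrate is a standard activity
biomarker: for the delta-5 and delta-6 desaturases (FADS1/FADS2) the
ratios AA:DGLA and GLA:LA proxy activity on the omega-6 polyunsaturated
fatty acid pathway. Two-sample Mendelian randomization (MR) can then ask
whether genetically proxied desaturase activity affects disease risk,
using GWAS summary statistics only. `ratiomr` implements that entire
workflow — inferring a ratio-phenotype GWAS from its components,
instrument selection, Wald/IVW estimation, overlap-aware meta-analysis,
colocalisation, effect decomposition, heterogeneity meta-regression and
phenome-wide scanning — together with a ground-truth-known synthetic-data
generator used to validate every stage.

## Inferred ratio GWAS (delta method)

Given per-SNP effects $\beta_1, \beta_2$ (standard errors $s_1, s_2$) on
the numerator and denominator phenotypes and their raw-scale moments
$(\mu_1, \mu_2, \sigma_1, \sigma_2, \rho)$, a first-order expansion of
$R = X_1/X_2$ about the means gives

$$\beta_R = \frac{\beta_1\mu_2 - \mu_1\beta_2}{\mu_2^2},\qquad
\mathrm{Var}(\beta_R) = \frac{s_1^2\mu_2^2 + \mu_1^2 s_2^2
  - 2\mu_1\mu_2\,\rho_b\, s_1 s_2}{\mu_2^4},$$

with $\rho_b = \rho \times$ (fraction of shared samples) approximating
the correlation of the two estimated betas. Dividing by the delta-method
SD of the ratio,

$$\sigma_R^2 = \left(\frac{\mu_1}{\mu_2}\right)^2
 \left(\frac{\sigma_1^2}{\mu_1^2} + \frac{\sigma_2^2}{\mu_2^2}
 - \frac{2\rho\,\sigma_1\sigma_2}{\mu_1\mu_2}\right),$$

standardizes the output to ratio-SD units, matching the "per SD
increase" exposure scale used throughout. P-values are recomputed from
`beta/se` (two-sided normal), never carried over from the inputs.

Numerical choices: a first-order (not second-order) expansion, declared
accurate while the denominator's coefficient of variation is below 0.3
(a warning is emitted above that); the beta-correlation $\rho_b$ is
supplied through the moments file and never estimated from the summary
statistics themselves; degenerate denominators
($|\mu_2| \le 3\sigma_2/\sqrt{n}$) and non-positive $\sigma_R^2$ are
errors rather than silent propagation. The transform is validated against
individual-level regression of the standardized ratio on genotype in a
simulated cohort of 20,000 (60 SNPs): the two sets of betas regress with
slope 1 within a few percent and $R^2 > 0.98$ (see
`tests/testthat/test-acceptance.R`).

## Instruments

Selection follows common two-sample MR practice: genome-wide significance
($P < 5\times10^{-8}$) plus greedy LD clumping (retain the smallest-P
SNP, prune everything with $r^2 \ge$ threshold within the window, repeat).
Defaults $r^2 = 0.001$ and window 10,000 kb are the conventional clumping
defaults; both are arguments. Ties in P — including P-values that
underflow to zero for very strong signals — are broken by descending
$|z|$ and then SNP id, so the result is deterministic and invariant to
row order. Region exclusion (`exclude_region()`) supports analyses that
must avoid a locus with known widespread effects, such as building
secondary-exposure instruments independent of the FADS region. Instrument
strength is summarized as $\sum_j 2f_j(1-f_j)\beta_j^2$, the variance
explained under independence (which clumping enforces).

## Causal estimation

The single-instrument Wald ratio is
$\hat\beta_{IV} = \hat\beta_{ZY}/\hat\beta_{ZX}$ with standard error
$se(\hat\beta_{ZY})/|\hat\beta_{ZX}|$ — deliberately first-order,
ignoring instrument uncertainty, which is appropriate when the
instrument association has $|z|$ in the tens to hundreds (here the
exposure association has $z \approx 90$); this matches how the estimator
is conventionally specified for a strong single instrument. With
multiple instruments, IVW pools per-SNP ratios with weights
$w_i = \beta_{ZX,i}^2/se_{ZY,i}^2$ (identically, WLS of outcome on
exposure effects through the origin). The variance rule is multiplicative
random effects: the fixed-effects SE is inflated by
$\sqrt{Q/(k-1)}$ only when $k \ge 3$ and the dispersion exceeds 1;
with two SNPs or under-dispersion the fixed-effects SE is used. The
additive (DerSimonian–Laird) random-effects IVW variant is a deliberate
non-goal at the SNP level; multiplicative dispersion realizes the
"under-dispersion falls back to fixed effects" rule cleanly.

Binary-outcome power uses the normal approximation
$\Phi\!\big(\sqrt{N r^2 \phi(1-\phi)}\,|\log OR| - z_{1-\alpha/2}\big)$
(plus the symmetric lower tail, so the null returns exactly $\alpha$),
with $\phi$ the case fraction and $r^2$ the instrument variance
explained.

## Meta-analysis with shared subjects

Case-control consortia reuse control pools, so per-study log-OR
estimates are correlated. The pooled fixed-effects estimate is GLS with
covariance $\Sigma_{ij} = r_{ij} s_i s_j$, where the shared-subject
correlation between studies $a$ and $b$ is approximated by

$$r = \frac{n_0^{shared}\sqrt{n_{1a}n_{1b}/(n_{0a}n_{0b})}
 + n_1^{shared}\sqrt{n_{0a}n_{0b}/(n_{1a}n_{1b})}}{\sqrt{N_a N_b}}$$

clipped to $[0, 0.99]$ (a Lin–Sullivan-style allowance). With zero
declared overlap this reduces exactly (to machine precision) to
classical inverse-variance pooling. The approximation is validated by
simulation: with two balanced studies of 20,000 sharing half their
controls the analytic $r = 0.25$ matches the empirical correlation of
the two log-OR estimates within $\pm 0.03$ (both under the null and
under OR 1.1 per SD), and GLS pooling attains ~95% CI coverage where
naive pooling drops to ~92%.

One reproducibility note for simulation studies of correlations: the
replicate loops draw per-replicate seeds from a single master-seeded
stream (`sample.int`) rather than using consecutive seed values —
structured per-replicate reseeding can induce cross-replicate
dependence that quietly invalidates the nominal Monte-Carlo precision
of an empirical correlation.

Across related outcomes (e.g. cancers of one biological system), pooling
is DerSimonian–Laird random effects — the method-of-moments $\tau^2$
with IVW weights $1/(s_i^2+\tau^2)$ — chosen over REML to match the
common defaults of standard meta-analysis tooling; heterogeneity is
reported as Cochran's Q. Differences between two outcomes use the normal
Z test with optional covariance; more than two groups use Q.

Meta-regression models outcome-level estimates on one moderator at a
time, $\beta_c = \gamma_0 + \gamma_1 x_c + u_c + \varepsilon_c$ with
$u_c \sim N(0, \tau^2)$, $\tau^2$ by the residual method of moments
($\max(0, (Q_E - (k-2))/\mathrm{tr}(P))$), coefficients re-estimated by
GLS (adding overlap covariance when declared) and the slope tested by
Wald z. Continuous moderators are standardized before fitting so slopes
are per moderator-SD; one-at-a-time fitting mirrors the reporting of
per-characteristic P-values and keeps $k \ge 4$ requirements mild. The
Wald z test is mildly anti-conservative at small $k$; at the panel sizes
used here (40 outcomes) the simulated type-I error is within Monte-Carlo
error of 0.05.

## Colocalisation

Single-causal-variant colocalisation over five hypotheses H0–H4. Per-SNP
evidence is the Wakefield approximate Bayes factor
$\log ABF = \tfrac12(\log(1-r) + r z^2)$, $r = w^2/(w^2+se^2)$, with
effect-prior SDs $w$ of 0.15 (quantitative, SD units) and 0.2
(case-control, log-odds) — the conventional choices, both configurable.
Hypothesis sums use per-SNP priors $p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$ and are accumulated in log space with log-sum-exp; the
H3 term $\sum A \sum B - \sum A_iB_i$ is computed as a guarded log-space
difference. The implementation is checked to $10^{-6}$ against exhaustive
enumeration of the $(m+1)^2$ causal-configuration grid on small regions.
A region pair is labelled colocalised at $PP_{H4} > 0.80$. Multi-trait
questions are answered by all pairwise runs (`coloc_pairwise()`); a
joint multi-trait model and multiple causal variants per region are
out of scope (the single-variant assumption is the method's main known
limitation).

## Effect decomposition and scans

The product-of-coefficients decomposition treats a candidate mediator
path as $indirect = a \times b$ ($a$: instrument-to-mediator per SD of
exposure; $b$: mediator-to-outcome per mediator SD) with Sobel variance
$a^2 s_b^2 + b^2 s_a^2 (+\,2ab\,\mathrm{cov})$, and
$direct = total - indirect$ by construction (the identity holds to
machine precision). The total-vs-indirect comparison treats the two as
independent unless a covariance is supplied — the conservative-or-not-
knowable choice, since their sampling overlap cannot be recovered from
summary data; a user-supplied covariance overrides it.
`required_b = total/a` (with a delta-method CI) reports how strong the
mediator-outcome effect would need to be to explain the whole total
effect; judging whether that is implausibly large is left to comparison
with a user-supplied plausible bound, not automated.

`trait_scan()`/`phewas()` run the Wald/IVW machinery across an outcome
panel with a Bonferroni threshold $\alpha/m$, returning the full table
regardless of significance; `phewas()` adds a sign-flipped
("intervention-mimicking") column, since negating the exposure beta
negates every log OR without changing P-values.

## The synthetic-data generator

`simulate_cohort()` produces the data structure the analysis assumes,
with every generative parameter recorded:

* **Haplotypes** are binary AR(1) Markov chains: adjacent alleles have
  correlation `ld_decay` exactly (lag-$k$ correlation `ld_decay^k`,
  adjacent dosage $r^2$ = `ld_decay`$^2$), clamped per pair to the
  feasibility bound LD imposes when allele frequencies differ. A
  thresholded Gaussian copula was considered and rejected because
  thresholding attenuates allele-level correlation, breaking the
  closed-form LD structure the validation tests rely on.
* **Latent activity** $D$ has unit variance with a single causal SNP of
  per-allele effect `gamma` (default 0.9 at eaf 0.33).
* **Fatty-acid pools** are log-normal — positive by construction, so
  ratios are well defined and the delta method's moment requirements
  hold (Gaussian pools would allow denominator sign flips). The
  log-scale loadings on $D$ and the biomarker noise are solved so the
  per-allele effect on the standardized AA:DGLA ratio hits a configured
  target (default 0.87 SD, explaining ~33% of biomarker variance —
  a strong single-locus instrument), with GLA:LA targeting 0.38 SD.
* **Outcomes** are log-additive logistic (or quantitative for mediation
  studies), with optional mediator, confounder and two-subpopulation
  stratification (allele-frequency, baseline-risk and biomarker-mean
  offsets). Case-control studies are sampled retrospectively from the
  population so logistic estimates match the generative log ORs
  asymptotically. `split_studies()` realizes requested shared-control
  counts exactly and emits the matching overlap declaration.
* **Determinism**: all randomness flows from the single config seed.

What the generator does *not* emulate: genome-scale realistic LD,
assortative mating or family structure, measurement platforms'
batch effects, or selection/survival bias. Passing tests therefore show
the estimators are correct under their stated assumptions, not that
those assumptions hold in any particular real cohort.

Two scale conventions are worth noting. The generator's `theta` is the
log OR per SD of latent activity $D$; the Wald estimand is per SD of the
*measured biomarker*, and the two differ by the factor
`gamma / ratio_target` (≈ 0.9/0.87). `pipeline_two_study()` sets
`theta` so the biomarker-scale estimand equals the requested OR exactly,
which is what its recovery test targets.

## Validation-study problem sizes

The package's own validation studies (the acceptance tests and
`scripts/acceptance.R`) use: exposure cohorts of 8,631 (a typical
measured-fatty-acid GWAS) and outcome populations of 60,000 from which
two studies of 6,000 cases / 6,000 controls sharing 3,000 controls are
sampled, 600 replicates for parameter recovery and coverage; 3,000
replicates for Wald-test size; 500 replicates of an 84-outcome null
panel for family-wise error; 4,000 replicate study pairs for the
shared-control correlation and pooled-interval coverage (an empirical
correlation needs that many replicates before its own Monte-Carlo error
is small against a ±0.03 band); 200 replicates of n = 50,000 for
mediation; 300 for
meta-regression. Monte-Carlo error, not the implementations, limits the
precision of these checks, so the recovery assertions are "within a few
Monte-Carlo SEs" rather than arbitrarily tight constants.

## Known limitations

* Single-causal-variant colocalisation; allelic series in one region
  will dilute $PP_{H4}$.
* The shared-subject correlation is an approximation for log-OR
  estimates; extreme case:control imbalance with near-total overlap can
  exceed its accuracy.
* First-order Wald/GWIS standard errors understate uncertainty for weak
  instruments or high-CV denominators; both conditions are warned about
  or excluded rather than modelled.
* MR-Egger and median/mode estimators are not provided; the design
  centres on a strong single instrument plus sensitivity analyses
  (colocalisation, decomposition) rather than pleiotropy-robust
  multi-instrument estimators.
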