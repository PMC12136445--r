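---
title: "Population structure-aware association testing for microbial pangenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population structure-aware association testing for microbial pangenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangmix)
```

# The problem

Microbiome association studies usually relate a host trait (disease status,
a quantitative phenotype) to the relative abundance of species. Abundance
tests miss a second, finer layer of signal: within one species, different
strains carry different accessory genes, and either a *lineage* of related
strains or an *individual* gene family may track the trait. Because genes
are inherited together along strain lineages, their presence/absence
profiles are strongly correlated across hosts; a naive per-gene logistic
regression then behaves exactly like an association study that ignores
genetic ancestry — large blocks of strain-defining genes all come out
significant, and the false positive rate explodes with the degree of
population structure.

pangmix addresses both layers with a generalized linear mixed model per
species, taking a binary sample-by-gene presence/absence matrix (from any
pangenome profiler) as the genotype:

1. **Relatedness.** The genetic relatedness matrix (GRM) between samples is
   \(\Psi_{ij} = 1 - \tfrac1p \sum_k |G_{ik} - G_{jk}|\): one minus the
   Manhattan distance of the binary gene profiles, normalized by the number
   of gene families so values lie in \([0,1]\). Identical gene repertoires
   score 1; complementary repertoires score 0. Normalization matters:
   without it the variance component below would scale with the pangenome
   size.
2. **Structure-trait (tau) test.** The null model
   \(f(E[y]) = X\alpha + b\), \(b \sim N(0, \tau\Psi)\) is fit by penalized
   quasi-likelihood (PQL) with AI-REML updates for \(\tau\) (logit link for
   binary traits, identity link with a free residual variance \(\sigma^2\)
   for quantitative ones). The statistic \(T = \tfrac1n\sum_i b_i^2\)
   measures how much trait variation the structure absorbs; its null
   distribution is obtained by permuting the trait and refitting, because
   the usual asymptotic tests for a variance component on the boundary are
   unreliable at these sample sizes.
3. **Gene (beta) test.** Each gene family is score-tested in
   \(f(E[y]) = X\alpha + \beta g + b\) *without* refitting the null model:
   \(S = \tilde g^\top (y - \mu)\) with the covariate-adjusted genotype
   \(\tilde g = g - X(X^\top WX)^{-1}X^\top W g\), exact variance
   \(g^\top P g\), and a saddlepoint-corrected tail when the normal
   approximation would misbehave. Fitting the null once per species keeps
   the per-gene cost at a pair of \(O(n^2)\) projections.
4. **localFDR.** Per-gene p-values are mapped to signed z-values
   (\(z = \pm\Phi^{-1}(1-p/2)\), signed by the effect direction) and
   adjusted with an empirically fitted null, because gene-gene correlation
   invalidates rank-based FDR procedures.

# Model fitting

## PQL + AI-REML

For a binary trait the working response is
\(\tilde Y = \eta + (y-\mu)/W\) with \(\mu = \text{logit}^{-1}(\eta)\),
\(W = \mu(1-\mu)\), and the working covariance is
\(V = W^{-1} + \tau\Psi\). Each outer iteration alternates:

* a weighted mixed-model solve: \(\alpha = (X^\top V^{-1}X)^{-1}X^\top
  V^{-1}\tilde Y\), \(b = \tau\Psi V^{-1}(\tilde Y - X\alpha)\);
* one AI-REML update of \(\tau\) using the REML score
  \(\tfrac12(\tilde Y^\top P\Psi P\tilde Y - \mathrm{tr}(P\Psi))\) and the
  average information \(\tfrac12\tilde Y^\top P\Psi P\Psi P\tilde Y\), with
  \(P = V^{-1} - V^{-1}X(X^\top V^{-1}X)^{-1}X^\top V^{-1}\).

The residual term a logistic model would add is absorbed into the PQL
working variance — no free dispersion parameter is estimated for binary
traits, matching the standard GMMAT/SAIGE formulation. For the identity
link, \((\sigma^2, \tau)\) are updated jointly with the 2-by-2 AI matrix.

Numerical choices, all tunable:

* **Initialization:** \(\alpha\) from a plain GLM fit, \(b = 0\),
  \(\tau_0 = 0.5\,\mathrm{var}(\text{working residuals}) / \overline{
  \mathrm{diag}(\Psi)}\). Separation in the initial GLM triggers a warning
  and a ridge-penalized start.
* **Convergence:** maximum relative change of \((\alpha, \tau, \sigma^2)\)
  below `1e-4`, at most 50 outer iterations; non-convergence is flagged on
  the returned object, not thrown.
* **Boundary:** a step that would make \(\tau < 0\) is halved toward the
  boundary; when the joint identity-link step leaves the parameter space
  the offending component is clamped and the free one takes a 1-D AI step
  (otherwise halving the joint step stalls \(\sigma^2\)). \(\tau < 10^{-6}\)
  with a negative score is reported as exactly 0.
* **PSD ridge:** one-minus-Manhattan relatedness is not guaranteed positive
  semidefinite, so the minimal diagonal ridge
  \(\delta = \max(0, -\lambda_{\min}) + 10^{-6}\) is added before fitting
  and recorded on the fit. The GRM is used on its raw scale (no
  centering/scaling) — the ridge, not a rescaling, is what REML requires.
* **Aliasing:** with \(\Psi \approx I\), \(\tau\) and \(\sigma^2\) are only
  jointly identified; the AI solve falls back to an SVD pseudo-inverse and
  the fit is flagged in `diagnostics`.
* All solves are dense Cholesky; \(V^{-1}\) is formed explicitly so that
  traces and per-gene projections are \(O(n^2)\). This is the right
  trade-off for the hundreds-of-samples regime the package targets; no
  sparse-GRM or variance-ratio approximations are used, so per-gene
  variances are exact.

## Permutation test for tau

Only the trait vector is permuted; covariates and \(\Psi\) stay attached to
their samples. This is the natural exchangeability null for "is structure
associated with the trait", though it also breaks any trait-covariate
association — a documented property, not an accident. The p-value uses the
add-one rule \(p = (1 + \#\{T^{(b)} > T_{\mathrm{obs}}\})/(B+1)\), so
\(p \ge 1/(B+1)\) always. Tie handling matters here: under the null a
sizeable fraction of fits land exactly on the \(\tau = 0\) boundary, so
\(T\) has an atom at zero and observed and permuted statistics tie often.
Counting only *strict* exceedances keeps the rejection rate at the
nominal level (counting ties as exceedances would send every
boundary-tied dataset to \(p = 1\) and make the test markedly
conservative); the type-I error simulations confirm calibration near 5%.
The null p-value distribution is still not exactly uniform — the boundary
atom distorts its shape away from the tails — so the p-values should be
read as valid for rejection decisions, not as uniform null scores.
Defaults: \(B = 1000\) for analyses, \(B = 100\) inside simulation
harnesses. Because the random effects are per-sample parameters, the
training AUC reported alongside \(\hat\tau\) is in-sample only.

## Saddlepoint correction

Under the null the score is a weighted sum of centered Bernoulli variables
with cumulant generating function
\(K(t) = \sum_i \log(1 - \mu_i + \mu_i e^{\tilde g_i t}) - t\sum_i \tilde
g_i \mu_i\). \(\tilde g\) is rescaled so \(K''(0)\) equals the exact
variance \(g^\top Pg\), the saddlepoint is solved by safeguarded Newton,
and the Barndorff-Nielsen formula gives each tail. The two-sided p-value
adds the upper tail at \(|s|\) and the lower tail at \(-|s|\): under the
skewed nulls produced by unbalanced case/control ratios this correctly
*increases* the anti-conservative normal p-value. The correction triggers
at \(|z| > 2\) (the published SAIGE default); below that the normal
approximation is returned, and root-finding failure falls back to the
normal p with a flag. Known limitation: when the adjusted genotype takes
very few distinct values at very small \(n\), the exact score distribution
is a coarse lattice and *any* continuous tail approximation has large
relative error at atoms and extreme tails; accuracy claims are therefore
validated at off-atom moderate tails and on heterogeneous (non-lattice)
adjusted genotypes, which is the regime covariate adjustment produces in
practice.

The score test does not estimate \(\beta\); the reported effect is the
one-step approximation \(\hat\beta = S/\mathrm{Var}(S)\) (log-odds scale
for binary traits), which supplies the sign for localFDR and a direction
for users — it is documented as approximate. For quantitative traits the
spec-level statistic \(S = \tilde g^\top(y - X\alpha - b)/\hat\sigma^2\) is
used; it equals \(g^\top P y\) identically (substitute
\(b = \tau\Psi P y\) and \(VPy = y - X\hat\alpha\)), so the Gaussian score
is exact and no saddlepoint correction is needed.

## Empirical-null localFDR

The marginal z-density is estimated by Poisson regression of histogram
counts (120 equal-width bins) on a natural-spline basis with 7 degrees of
freedom — the canonical defaults of the standard localFDR implementation.
The empirical null \(N(\delta_0, \sigma_0^2)\) is fit by truncated-normal
maximum likelihood on the z-values between the 10th and 90th percentiles,
and \(\pi_0\) is the central-window fraction divided by the null mass of
the window, capped at 1. Then
\(\mathrm{fdr}(z) = \pi_0\,\varphi_{\delta_0,\sigma_0}(z)/\hat f(z)\),
clipped to \([0,1]\). "Converting p-values to quantiles" is interpreted as
the standard signed two-sided map \(z = \pm\Phi^{-1}(1-p/2)\); a literal
rank-quantile transform would destroy the \(N(0,1)\) null reference the
maximum-likelihood fit requires. One-sided tests (tau, abundance) are
adjusted on the \(|z|\) scale with positive sign. Null fits are per test
family, pooled across species. Default significance cutoffs (strict `<`):
0.2 for gene tests, 0.1 for structure and abundance tests. The spline
density smooths the transition between the null bulk and any signal
component, so localFDR values in the transition region are less sharp than
the true posterior — calls at the defaults are unaffected in the
simulations, but thresholds should not be read as exact posteriors.

# The synthetic-data suite

The generators define the package's study conditions; their defaults are
fixed and are not tuning knobs.

**Structure-level simulation.** Each sample carries a strain with
probability 0.5; the matrix has 400 core genes (presence 0.8), 400
accessory genes (presence 0.2) and 200 strain-linked genes that are absent
without the strain and otherwise present with per-gene probability
\(p_g \sim U(0.643 - 0.15,\, 0.643 + 0.15)\), centered so the mean
presence odds are 1.8 against an even-odds reference. (The "average odds
ratio 1.8" condition is under-determined because the genes are always
absent without the strain; this uniform interval is the package's
documented resolution.) A host age covariate is \(N(45, 15^2)\). Under the
null the binary trait is Bernoulli(0.5) independent of everything; under
the alternative \(y \sim \text{Bernoulli}((1-s)(1-\theta) + s\theta)\)
with strain indicator \(s\), giving a strain-trait odds ratio
\(\theta/(1-\theta)\).

**Gene-level simulation.** An observed or generated GRM is decomposed into
its first 10 principal components (double-centered principal-coordinates
convention with a deterministic sign fix); each standardized component is
mapped through \(\Phi\) to per-sample presence probabilities and 90 genes
are drawn per component, plus 100 unstructured genes with presence
probabilities \(U(0.2, 0.8)\). The trait is 1 when the loadings on the
first two components have opposite signs — a nonlinear function of the
structure, so structured genes associate with the trait only *through*
structure. Positives are 100 appended genes with presence probability
\((1-y)(1-\theta) + y\theta\). The false-positive denominator excludes the
180 PC1/PC2 genes (820 negatives). At desk scale the base GRM comes from a
generated pangenome with two independent strain blocks, so the base
structure has two meaningful dimensions feeding the trait rule; observed
GRMs can be supplied instead to reproduce the full protocol. Power is
compared to a plain-GLM baseline at a matched empirical false positive
rate of 0.05 computed from the negatives.

What these simulations emulate: block-correlated accessory genomes,
strain-linked gene blocks, realistic case/control imbalance through the
trait rules, and covariates uncorrelated with structure. What they do not:
read-mapping noise in presence calls, cross-mapping between species,
compositional effects, covariates confounded with structure, and
multi-species batch structure. Passing tests therefore demonstrate
statistical calibration of the model, not robustness to profiling error.

**Problem sizes.** The packaged experiments run the type-I error study at
300 iterations (the full protocol uses 1000) and the power study at the
full 125 iterations per cell; gene-level comparisons use a handful of
replicates per effect size at \(n = 100\). These sizes give binomial
Monte-Carlo intervals tight enough for the calibration claims while
keeping the whole suite runnable on a laptop in minutes.

# Design choices on open points

* Samples with missing trait or covariate values are dropped with a
  warning; imputation is out of scope for a testing package.
* Filter thresholds (core: absent in fewer than 10 samples; rare: present
  in fewer than 30) follow common pangenome-MWAS practice and are
  configurable; both cuts are strict inequalities, so a gene absent in
  exactly 10 and present in exactly 30 samples is retained.
* \(\hat\tau\) is reported as fit on the working-response scale, without
  rescaling.
* The permutation count is configurable because published analyses at
  p-values near \(10^{-4}\) imply \(B \ge 10^4\); the package defaults to
  \(B = 1000\) for analysis use.
* Relative abundance enters its regression untransformed by default (a
  `log10(x + pseudocount)` option exists) with a 0.05% mean-abundance
  floor.
* The command-line driver is a thin wrapper over the exported functions;
  everything it does can be reproduced in an R session, and the pipeline
  writes a manifest recording seed, filter counts and convergence
  diagnostics for every run.

# Known limitations

* PQL variance components for binary traits are known to be slightly
  biased downward; the permutation test is calibrated regardless because
  observed and permuted statistics share the bias.
* The training AUC does not generalize to unseen hosts (random effects are
  per-sample parameters).
* localFDR needs a few hundred pooled z-values to be stable; the pipeline
  skips the adjustment below 200 testable genes and says so in the
  manifest.
* The same gene matrix estimates both the GRM and the per-gene tests;
  with SNP-style data this double use is known to cost power, and no
  leave-one-block-out GRM is implemented here.
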