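---
title: "Genomic selection with GBLUP: model, implementation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection with GBLUP: model, implementation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsblup)
```

## The problem

Breeders of self-pollinating crops such as spring wheat want to rank
candidate varieties by their *breeding value* (BV) — the additive genetic
merit for a trait such as the grain content of K, Ca, Mg, Mn, Fe, Zn or Cu
(mg/kg) — using genome-wide SNP genotypes and replicated field phenotypes.
With a few hundred lines and >10,000 array markers, single-marker methods
are underpowered; the standard tool is **GBLUP**: best linear unbiased
prediction of a genomic random effect whose covariance is the realized
genomic relationship matrix (GRM). `gsblup` implements that analysis end to
end — panel simulation, genotype QC, GRM, REML variance components, BLUP,
back-solved per-SNP coefficients, k-fold cross-validated accuracy, and
expected response to selection — with every stage exposed as a tested
function.

## The model

For one trait, let $y$ be the $n$-vector of per-line phenotype means (each
line's records averaged over years and replicates). The mixed model is

$$y = 1\mu + g + e, \qquad
  g \sim N(0, A\sigma^2_g), \qquad e \sim N(0, I\sigma^2_e),$$

where $A$ is the $n \times n$ GRM computed from standardized dosages
$w_{ij} = (x_{ij} - 2p_j)/\sqrt{2p_j(1-p_j)}$. Off-diagonals are
$A_{jk} = \frac{1}{m_{jk}}\sum_i w_{ij} w_{ik}$ over SNPs called in both
lines; the diagonal is either the same formula (`standard`, giving
$A = WW^\top/m$ with complete data) or the Yang estimator
$A_{jj} = 1 + \frac{1}{m}\sum_i
\frac{x_{ij}^2 - (1+2p_i)x_{ij} + 2p_i^2}{2p_i(1-p_i)}$ (`yang`, the
default, matching common GREML tooling). Missing-data handling is
pairwise-complete, which keeps $A$ exactly symmetric without imputation.

Variance components are estimated by REML; the BLUPs are

$$\hat\mu = (1^\top V^{-1} 1)^{-1} 1^\top V^{-1} y, \qquad
  \hat g = \hat\sigma^2_g A V^{-1}(y - 1\hat\mu), \qquad
  V = A\hat\sigma^2_g + I\hat\sigma^2_e.$$

Because GBLUP is algebraically identical to ridge regression on
standardized markers (SNP-BLUP with $\lambda = \sigma^2_e/\sigma^2_g$), the
line-level solution can be *back-solved* into per-SNP effects
$\hat u = (\hat\sigma^2_g/m) W^\top V^{-1}(y - 1\hat\mu)$ and per-allele
coefficients $b_i = \hat u_i / \sqrt{2p_i(1-p_i)}$. The coefficients, the
effect-allele labels and the training allele frequencies together form a
portable score file: any genotyped line — including lines never seen in
training — is scored as $\sum_i b_i d_i$ from its allele dosages alone.
`ridge_snp_blup()` provides the direct marker-space solve as an independent
route to the same numbers; the test suite checks the equivalence to 1e-8
and the Henderson mixed-model-equation solution to 1e-10 (on unit-scaled
data).

### Heritability on inbred panels

Heritability is reported as $h^2 = V(G)/V(P)$ with
$V(G) = \bar A_{jj}\,\hat\sigma^2_g$ and $V(P) = V(G) + \hat\sigma^2_e$,
where $\bar A_{jj}$ is the mean GRM diagonal. For outbred samples
$\bar A_{jj}\approx 1$ and this reduces to the familiar
$\sigma^2_g/(\sigma^2_g+\sigma^2_e)$. The distinction matters here: a fully
inbred panel has $\bar A_{jj} \approx 1+f \approx 2$, and the per-line
genetic variance under the model is $A_{jj}\sigma^2_g$, not $\sigma^2_g$.
Without the mean-diagonal factor, $h^2$ on dosage-scale GRMs of selfing
varieties systematically underestimates
$\mathrm{Var(BV)}/\mathrm{Var(line\ means)}$ by roughly a factor of two;
with it, the estimator recovers the generator's target $h^2$ without bias
(checked at $n = 500$, $m = 2000$, 20 replicates, tolerance 0.05).

## REML implementation

`reml_fit()` maximizes the restricted log-likelihood
$\ell_R = -\frac{1}{2}[\log|V| + \log|1^\top V^{-1} 1| + y^\top P y]$.
A one-time eigendecomposition $A = U\Lambda U^\top$ turns every
$\ell_R$ evaluation into $O(n)$ diagonal arithmetic, which is also what
makes the brute-force grid oracle in the tests affordable. Numerical
choices, in order of consequence:

* **Optimizer.** Three EM warm-up iterations (the classical
  $\sigma_k^{2\,(t+1)} = \sigma_k^{2\,(t)} + 2\sigma_k^{4\,(t)}
  \partial\ell_R/\partial\sigma_k^2 / n$ update, monotone by construction),
  then average-information (AI) steps
  $\theta \leftarrow \theta + \mathrm{AI}^{-1}\nabla\ell_R$ with
  $\mathrm{AI}_{jk} = \frac{1}{2} y^\top P A_j P A_k P y$.
* **Damping and feasibility.** Yang-diagonal GRMs can be slightly
  indefinite (smallest eigenvalues around $-10^{-4}$ in practice), so the
  feasible region is $\{\lambda_i\sigma^2_g + \sigma^2_e > 0\ \forall i\}$
  rather than the positive quadrant. Any proposed step is halved toward
  the current point until $V$ is positive definite and (for AI steps) the
  likelihood does not decrease; when no ascent step exists the iteration
  falls back to EM, and a damped EM move is taken as a last resort so the
  iteration can terminate.
* **Floor.** Components are floored at $10^{-6}\,\mathrm{Var}(y)$ instead
  of zero so $V$ stays invertible; fits at the floor set `boundary = TRUE`.
* **Convergence.** $|\Delta\ell_R| < 10^{-8}$ together with a maximum
  relative parameter change below $10^{-6}$, or five consecutive
  sub-tolerance likelihood changes (a flat ridge or a boundary pin carries
  no further information — common when $A$ is close to a multiple of $I$).
  Failure to converge in 200 iterations is reported via `converged =
  FALSE` plus a warning, never an exception, and cross-validation flags
  and excludes such folds instead of aborting.
* **Degenerate inputs.** $A = I$ makes only $\sigma^2_g + \sigma^2_e$
  identifiable; the fit warns and flags `identifiable = FALSE`. Standard
  errors come from the inverse AI matrix at the optimum, $se(h^2)$ by the
  delta method, and are `NA` when the AI matrix is singular.

## Cross-validation and inference

`kfold_split()` partitions lines uniformly at random into $k$ folds whose
sizes differ by at most one — for 149 lines and $k = 5$ that is
30/30/30/30/29, so a fold with a 30-line test set trains on 119 lines.
For each fold, *everything* is recomputed from the training lines only:
allele frequencies, the GRM, REML, BLUPs and the back-solved coefficients.
Held-out lines are scored from their genotypes; missing calls are imputed
at $2p_i$ using the training frequencies stored in the model, so no
test-set information leaks into training (an automated test perturbs
test-fold phenotypes and asserts the trained model is bit-identical).

Per fold we report the Pearson correlation $r$ between scores and observed
line means, the Fisher-z 95% interval
$\tanh(\mathrm{atanh}(r) \pm 1.96/\sqrt{n-3})$, and the two-sided p-value
from $t = r\sqrt{n-2}/\sqrt{1-r^2}$. Whether such p-values should be one-
or two-sided is a genuine convention choice; two-sided is implemented as
the conservative default. A trait's prediction is declared significant by
a two-tier rule: at least one of its $k$ models must pass an adjusted
threshold of 0.001 — essentially a Bonferroni correction of 0.05 across
35 models, fixed rather than recomputed — *and* every model must pass the
nominal 0.05. Monte-Carlo checks (2000 simulations at $n = 30$) confirm
94–96% CI coverage and a 4–6% type-I error for the correlation test.

Scores are sums over SNPs rather than averages over non-missing SNPs;
correlation-based evaluation is invariant to this affine choice, and sums
are what standard external scorers produce by default.

## Response to selection

`response_to_selection()` reports two summaries for a selected top-$k$ set
(default $k = 30$), chosen either by estimated BV or by phenotype:

* the **BV differential**, mean estimated BV of the selected lines minus
  the population mean BV — already on the genetic scale, so no further
  heritability weighting is applied;
* the **breeder's-equation response** $(P_{top} - P_{mean})\,h^2$ on the
  phenotype scale.

Ties at the selection cutoff are broken by the stable sample-ID order, so
selections are deterministic. When traits are selected independently, the
top-30 set is recomputed per trait.

## What the synthetic panel does and does not emulate

`panel_config()` defaults encode the study design the package targets:
149 fully inbred lines, 11,405 biallelic array SNPs on 21 chromosomes,
7 correlated element-content traits, 2 years × 2 replicates = 596 records
per trait. Design choices, chosen once on realism grounds:

* **Genotypes.** Per-SNP counted-allele frequencies uniform on
  [0.05, 0.5] (array SNPs are ascertained common variants). Local LD via a
  first-order autoregressive latent Gaussian copula with adjacent-SNP
  correlation 0.9 — the strong-LD regime expected when ~11,000 markers tile
  a huge, low-recombination selfing-crop genome (sub-cM marker spacing);
  chromosome boundaries break the correlation. Fully inbred dosages
  \{0, 2\} by default (`inbreeding` is configurable), giving a Yang-GRM
  diagonal near 2 as observed on real selfing panels.
* **Phenotypes.** Per trait, `n_causal` (default 300) SNPs get i.i.d.
  normal effects on the standardized scale — an infinitesimal-like
  architecture matching the GBLUP working model, since nothing stronger is
  known about these traits. A `pleiotropy_frac` share of causal SNPs (and
  their effects) is shared across traits, inducing positive genetic
  correlations. True BVs are rescaled so Var(BV)/Var(line mean) hits the
  target $h^2$ exactly in the genetic part; targets (0.45–0.70 across the
  seven elements) are in the range typically reported for grain mineral
  content. Population means are literature-typical grain contents (e.g.
  K ≈ 4300, Ca ≈ 420, Cu ≈ 5 mg/kg); the phenotypic scale is set by
  `trait_sds` (default a 10% coefficient of variation) because $h^2$,
  year variance and residual variance are only jointly determined once a
  scale is fixed.
* **Year effects** are drawn per (line, year) cell — not globally per
  year — so averaging a line's four records reduces but does not eliminate
  non-genetic variance, mirroring how across-year means behave in real
  multi-environment trials. The default year SD is 5% of the trait mean;
  `h2 = 1` is allowed and simply leaves zero residual variance (an error
  is raised only when the year variance alone already exceeds the
  non-genetic budget).

**Not emulated:** pedigree and population structure (the simulated lines
are exchangeable draws from one population), selection/drift history,
epistasis, and genotyping error beyond random missingness. The first
omission matters most: real variety panels contain families and shared
ancestry, which inflate GRM off-diagonals and are a large part of why
GBLUP reaches accuracies of 0.4–0.7 at $n \approx 150$ on real data. On
this generator the off-diagonal relatedness is only what ~600 effective
independent markers produce (SD ≈ 0.04–0.05), so cross-validated
accuracies at the study's sample size are markedly lower, and per-trait
$h^2$ is weakly identified ($se(h^2) \approx 0.5$ at $n = 149$; estimates
can pin at 0 or 1). Passing tests therefore demonstrate the correctness of
the machinery — oracle equivalences, calibration, parameter recovery at
informative sizes — not that $n = 149$ suffices for accurate prediction in
an unstructured population.

## Problem sizes used by the test suite

Oracle comparisons run on panels up to 50 × 200 (exhaustive double-loop
GRM, dense Henderson solves, 50 × 50 restricted-likelihood grids at
$n = 30$). Parameter-recovery checks use $n = 500$, $m = 2000$ over 20
seeds; calibration checks use 2000 Monte-Carlo replicates at $n = 30$.
These sizes make the statistical assertions sharp (Monte-Carlo error well
below the tested tolerances) while the whole suite stays fast.

## Known limitations

Single-trait, intercept-only REML (no covariates, no multi-trait or
Bayesian models); no dominance or epistatic relationship matrices; no
imputation beyond mean-dosage; the PLINK *text* dialect cannot encode
which allele is counted, so text round trips are exact only after one
read/write canonicalization (the binary dialect round-trips bit-exactly);
and the GRM binary triple stores float32, so those files round-trip to
~1e-7 relative precision.
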