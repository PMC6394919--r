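---
title: "Genomic prediction with genopred: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with genopred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genopred)
```

## The problem

Genomic selection ranks candidate animals by genome-wide estimated
breeding values (GEBVs) computed from dense SNP genotypes, without
requiring pedigree records. `genopred` implements the full analysis chain
used in beef-cattle evaluation studies — quality control, fixed-effect
pre-adjustment, and three families of predictors (GBLUP, BayesB, elastic
net) under common 5-fold and forward-in-time validation — together with a
seeded simulator so that every claim the package makes can be tested
without access to proprietary cattle data.

All predictors see the same response: the residual $y^*$ of an ordinary
least-squares fit of the raw phenotype on sex, birth-year contemporary
group and two covariates (fattening duration, initial body weight).
Genotypes are coded $1, 0, -1$ for the genotypes 11/12/22 (minor-allele
dosage minus one).

## Models

**GBLUP.** $y^* = 1\mu + g + e$ with $g \sim N(0, K\sigma_g^2)$ and
$e \sim N(0, I\sigma_e^2)$. The genomic relationship matrix is
$K = \tfrac{1}{d} Z Z^\top$, $d = \tfrac{1}{n}\mathrm{tr}(Z Z^\top)$, so
that $\mathrm{mean}(\mathrm{diag}(K)) = 1$. Variance components come from
restricted maximum likelihood (below); GEBVs solve the mixed-model
equations using training phenotypes, with test individuals linked through
the off-diagonal blocks of $K$.

**RR-BLUP duality.** Ridge regression of $y^*$ on all markers with
per-marker prior variance $\sigma_g^2 / d$ yields marker effects whose
genomic sum $Z\hat{\gamma}$ reproduces GBLUP exactly;
`rrblup_predict()` is tested against `gblup_predict()` at $10^{-6}$
relative tolerance on every simulated dataset.

**BayesB.** Marker effects are zero with prior probability $\pi$ and
otherwise normal with locus-specific variance
$\sigma_{gk}^2 \sim$ scaled-inv-$\chi^2(\nu_g, S_g)$. The Gibbs sampler
updates, per sweep: the mean; each marker's inclusion indicator with the
effect integrated out (conditional on $\sigma_{gk}^2$), the effect and
the locus variance; and the residual variance. Posterior-mean effects
(not MAP) feed the GEBV $\sum_k Z_k \bar{\gamma}_k$. Default protocol:
50,000 iterations, 2,500 burn-in, thinning 10 (4,750 retained);
$\pi \in \{0.9, 0.99, 0.999\}$ are the supported presets and $\pi$ is
never estimated.

**Elastic net.** Coordinate descent minimizes
$\tfrac{1}{2n}\lVert y^* - Z\gamma\rVert^2 +
\lambda \sum_k \big(\tfrac{1-\alpha}{2}\gamma_k^2 + \alpha|\gamma_k|\big)$
with warm starts down a log-spaced $\lambda$ grid from
$\lambda_{\max} = \max_k |Z_k^\top y^*| / (n\alpha)$ (standardized
markers). $\alpha = 1$ is the lasso; small $\alpha$ approaches ridge.
$\lambda$ is chosen by internal $k$-fold cross-validation at minimum MSE
(`minMSE`, the default); the sparser `minMSE_1SE` rule — the largest
$\lambda$ within one standard error of the minimum — is available for
users worried about training-set overfitting.
$\alpha = 0$ requires an explicit grid and is
flagged experimental (pure-ridge runs are prone to non-convergence
reports).

## REML by eigendecomposition

Heritability is profiled in one dimension: with an orthonormal basis $k$
of the intercept-orthogonal contrast space, $k^\top K k = U \Theta
U^\top$, and the restricted likelihood of the rotated contrasts
$\eta = U^\top k^\top y^*$ is maximized over
$h^2 \in [10^{-4}, 1 - 10^{-4}]$ by bounded 1-D search; the genetic scale
has a closed-form profile. This is exact, deterministic and fast at
$n \approx 1200$. The explicit contrast basis matters: diagonalizing the
doubly-centered $K$ and dropping its smallest eigenvalue silently breaks
when $K$ is rank-deficient ($m < n$), which is routine at simulation
scale. Standard errors of $\hat{h}^2$ come from the numerical curvature
of the profile likelihood and are flagged (not fatal) at boundary
estimates; they need not match the Fisher-information standard errors
that commercial REML software reports.

## Centering and what "heritability" refers to

The package default builds $K$ from the raw $\{-1,0,1\}$ coding,
uncentered, exactly as written in the model section above. When minor
allele frequencies differ from $\tfrac12$, the columns of $Z$ have
nonzero means, and the uncentered $K$'s diagonal absorbs that
allele-frequency offset: REML's $\sigma_g^2$ then estimates the
*uncentered* second moment of the genetic values, which exceeds their
variance. Prediction is unaffected (for data generated under the additive
model the uncentered covariance is exactly correct, and the mean shift is
absorbed by $\mu$), but $\hat{h}^2$ is inflated relative to the
conventional variance-ratio definition.

`build_grm(center = TRUE)` subtracts marker means first and restores the
conventional estimand. Consequently:

- prediction and method comparisons use the uncentered default;
- parameter-recovery tests (simulated $h^2$ versus $\hat{h}^2$) use the
  centered form, because the simulator's target is the variance ratio
  $\mathrm{var}(g) / (\mathrm{var}(g) + \mathrm{var}(e))$.

## What the simulator emulates — and what it does not

`simulate_genotypes()` draws each marker's MAF uniformly on
$[0.05, 0.5]$ (the post-QC spectrum is unknown, so a flat spectrum over
the retained range is assumed), samples genotypes in Hardy–Weinberg
proportions, and places missing calls independently per entry.
`simulate_effects()` supports a polygenic architecture (all markers
causal) and a sparse one (a fraction $\pi_{\text{null}}$ exactly zero,
with nonzero effects rescaled so total squared effect matches the
polygenic expectation — architectures are then comparable at equal
$h^2$). `simulate_phenotypes()` sets the noise variance from the
*realized* $\mathrm{var}(g)$, so the target $h^2$ holds per dataset, not
only in expectation; this keeps parameter-recovery tests sharp at modest
$n$. Fixed effects default to magnitudes plausible for a carcass-weight
scale trait: sex effect $-20$ kg, a mild birth-year trend (0–12 kg over
seven cohorts), fattening duration $300 \pm 25$ d with slope 0.05 kg/d,
initial weight $250 \pm 30$ kg with slope 0.4.

Deliberately *not* emulated: linkage disequilibrium (markers are
independent), pedigree structure, sample-level missingness clustering,
genotyping error, and multi-trait genetic correlations. A green test
therefore establishes correctness of the estimators under the assumed
additive, linkage-equilibrium world — it does not establish that real
cattle accuracies are reproduced, which is impossible without the
original (undeposited) data.

## Numerical choices

- **QC order and strictness.** Marker filters (call rate, MAF, HWE on a
  1-df Pearson chi-square) run on pre-imputation calls, then the sample
  filter, then mean imputation. All threshold comparisons are strict
  inequalities ("higher than" / "more than"). The iterative QC described
  for the original pipeline is unspecified; a single fixed pass is
  implemented, and re-running it on its own output is a no-op on test
  fixtures.
- **Imputation.** Sporadic missing calls become marker means (preserving
  allele-frequency expectations). Haplotype-phasing imputation is out of
  scope; at post-QC missingness rates (< 5%) the effect on additive GEBVs
  is negligible.
- **Mixed-model solves** use Cholesky factorizations with an automatic,
  logged $10^{-8}$ diagonal ridge on singularity.
- **Coordinate descent** converges when the largest coefficient change
  in a sweep falls below $10^{-7} \cdot \mathrm{sd}(y)$; non-convergence
  at $10^5$ sweeps is flagged per $\lambda$, not fatal. The objective is
  verified non-increasing per sweep.
- **$\lambda$ grid floor.** $\lambda_{\max}$ scales as $1/\alpha$, so at
  $\alpha = 0.001$ the default grid floor
  ($10^{-2}\lambda_{\max}$ for $m > n$) truncates the path above the CV
  optimum — the selection lands on the grid boundary. Near-ridge runs
  therefore pass `lambda_min_ratio = 1e-4`; selections are checked to be
  interior. The defaults are left as stated for ordinary $\alpha$.
- **BayesB hyperpriors.** $\nu_g = 4.2$; $S_g$ solved so the prior mean
  genetic variance equals half the phenotypic variance spread over the
  expected $(1-\pi)m$ nonzero loci; $\nu_e = 4$ with $S_e$ set from the
  phenotypic variance. All overridable. Exact numerical equivalence to
  any particular packaged sampler is a non-goal; equivalence is asserted
  at the level of predictive behavior on simulations.
- **Per-fold re-estimation.** Variance components (GBLUP) and $\lambda$
  (EN) are re-estimated within each training fold; BayesB runs a fresh
  chain per fold. The whole-data $\hat{h}^2$ used for realized accuracy
  is estimated once, treating heritability as a trait property.
- **Degenerate cases.** Monomorphic markers get HWE $p = 1$; constant
  responses are rejected (or folds skipped, with warnings); correlation
  against a constant GEBV vector is an error and the fold is reported
  missing rather than zero.

## Validation and accuracy

`kfold_split()` partitions individuals into $k$ seeded folds whose sizes
differ by at most one (1,217 individuals in 5 folds gives
244/244/243/243/243); `generation_split()` trains on individuals born up
to a cutoff year and tests on those born after. Accuracy is the Pearson
correlation $r(y^*_{\text{test}}, \mathrm{GEBV}_{\text{test}})$;
realized accuracy divides by $\sqrt{h^2}$ and may exceed 1 (reported
as-is, with a warning). The fold-to-fold coefficient of variation
$C_v = \mathrm{sd}(r) / \mathrm{mean}(r)$ is computed across the outer
folds — the only replicate structure available. All methods see
byte-identical splits, fingerprinted in the report.

## Known limitations

- Linkage equilibrium makes simulated prediction accuracies optimistic
  relative to real panels of equal size.
- The uncentered-$K$ heritability inflation (above) is inherent to the
  stated construction; use the centered switch when $\hat{h}^2$ itself is
  the quantity of interest.
- MCMC settings in the test suite are reduced relative to the 50,000-
  iteration production protocol; the protocol's bookkeeping is asserted
  arithmetically and the samplers' statistical behavior at CI chain
  lengths.
- Single-step GBLUP, BayesA/C/R, $\pi$ estimation, bivariate models and
  genetic-correlation estimation are out of scope.
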