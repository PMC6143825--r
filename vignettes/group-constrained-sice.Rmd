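---
title: "Group-constrained sparse inverse covariance networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-constrained sparse inverse covariance networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sicenet)
```

## The problem

Resting-state functional MRI yields, per subject, one mean time series per
brain region (e.g. the 90 regions of the AAL atlas, each with on the order
of a couple of hundred time points). Functional connectivity analysis asks
which regions interact *conditionally* — after the influence of all other
regions is removed — and whether those interaction patterns separate a
patient group from controls. Two obstacles dominate at this scale: the
number of candidate connections (P² = 8,100 at P = 90) dwarfs typical
cohort sizes (tens of subjects), and estimating each subject's network
independently produces supports so variable across subjects that a
classifier mostly learns estimation noise.

`sicenet` addresses both with a two-stage construction:

1. **Group-constrained topology detection.** For each target region `p`,
   all subjects' regressions of that region on the remaining regions are
   fitted *jointly* under an ℓ2,1 penalty:

   $$\hat\beta_p = \arg\min_{\beta_p}\;
     \sum_{m=1}^{M} \lVert x_p^m - X_p^m \beta_p^m \rVert_2^2
     + \varphi \lVert \beta_p \rVert_{2,1},$$

   where column `m` of the `(P-1) × M` matrix `β_p` holds subject `m`'s
   coefficients and the ℓ2,1 norm sums the Euclidean norms of the *rows*.
   Because the penalty acts on whole rows, a predictor region is either
   dropped for every subject or kept for every subject: the selected
   subset `E_p` (the rows surviving a numeric-zero threshold) is one
   topology shared by the group, while the surviving coefficients remain
   subject-specific. The penalty weight φ is chosen per target by the
   Bayesian information criterion

   $$\mathrm{BIC} = \sum_{m=1}^{M} \ln \mathrm{ESS}(m)
     + d\,\frac{\ln n_t}{n_t},$$

   with `ESS(m)` subject `m`'s residual sum of squares and `d` the number
   of nonzero coefficients.

2. **Sparse inverse covariance estimation (SICE / graphical lasso).** For
   each subject and target, the expanded set `[y_p, E_p]` gets a penalized
   maximum-likelihood precision estimate

   $$\hat\Theta = \arg\min_{\Theta \succ 0}\;
     -\log\det\Theta + \mathrm{tr}(S\Theta) + \lambda\lVert\Theta\rVert_1,$$

   where the ℓ1 norm sums the absolute values of **all** entries
   (diagonal included; `penalize_diag = FALSE` switches to the
   off-diagonal-only convention). The first column of `Θ̂`, diagonal
   dropped, is the weight vector of the sub-network around `p`; scattered
   into column `p` of a `P × P` matrix it yields the subject's
   connectivity matrix — generally asymmetric, and deliberately left so,
   since the row-major vectorization keeps both `(i,j)` and `(j,i)` as
   classifier features.

Two non-sparse comparison variants replace stage 2 with partial
correlation, `Π_ij = -Ω_ij / \sqrt{Ω_ii Ω_jj}`, `Ω = Σ^{-1}`: whole-brain
(`partial`) or restricted to the selected subsets (`group-partial`).
`sice` applies the graphical lasso directly to the whole-brain covariance
without topology detection. Classification uses a CART decision tree on
the vectorized matrices under nested leave-one-out cross-validation
(LOOCV): the inner loop picks λ by inner-LOOCV accuracy, the outer loop
estimates generalization, and ACC/SEN/SPE are computed from the pooled
outer confusion counts with ROC/AUC from the tree's leaf-proportion
scores.

## Numerical choices

**Topology solver.** Block coordinate descent over rows of `β_p` with the
exact group soft-thresholding update. Columns of each design matrix (and
the responses) are mean-centered and scaled to unit Euclidean norm first;
this makes penalized fits comparable across φ and, because every usable
column then has unit Gram diagonal, makes the row update available in
closed form. Zero-variance columns are flagged and pinned at zero; a
zero-variance response is an error. Each sweep is followed by an exact
majorization–minimization refit of the currently-active rows: holding the
row norms fixed, the half-quadratic bound
`|b| ≤ b²/(2r) + r/2` turns the penalty into a quadratic whose minimizer
is a per-subject linear solve, giving a guaranteed-descent step that
resolves the ill-conditioned small-φ (near-least-squares) regime where
plain row sweeps converge slowly; the row sweeps still own all support
changes and exact zeros. Iteration stops when the Frobenius
norm of the coefficient change falls below `1e-6`, or after 100 sweeps.
The update is a descent method, so the recorded objective trace is
non-increasing; the solution at φ above the analytic threshold
`phi_max()` (from the subgradient condition at zero) is exactly the zero
matrix, and as φ → 0 each column converges to the subject's least-squares
solution — both limits are tested.

**Numeric zero.** A coefficient row counts as zero when its ℓ2 norm is
below `1e-6` times the largest row norm (relative, hence scale-robust).
The same rule defines `d` in the BIC and the membership of `E_p`.

**BIC details.** Residual sums of squares below `1e-12` are floored there
with a warning (an interpolating fit would otherwise send the log to
−∞). Ties on the φ grid go to the smallest φ — the denser, more
conservative topology. The default grid is 19 points, 0.05 to 0.95 in
steps of 0.05.

**Graphical lasso.** Block coordinate descent over columns of the working
covariance; each column update is a lasso subproblem solved by coordinate
descent, warm-started across sweeps. The precision is reconstructed from
the block-inverse identities after each sweep and iteration stops when
the sum of absolute entrywise changes drops below `1e-6` (default cap 200
sweeps — comfortable headroom, as synthetic runs converge in under 20).
`λ = 0` returns the closed-form unpenalized estimate `solve(S)`. Every
return is checked symmetric positive definite. Sub-network covariances
are computed on mean-centered raw series with the `n_t − 1` denominator;
standardization is confined to the topology regression.

**Partial correlation.** Requires a condition number below `1e12`;
anything worse raises a dedicated error (`sicenet_singular_covariance`)
rather than returning noise amplified by a near-singular inverse.

**Decision tree.** CART with Gini impurity, `minsplit = 2`,
`minbucket = 1`, `cp = 0`, no cross-validation pruning — i.e. trees grown
to purity, appropriate when the inner LOOCV already provides the
model-selection signal. Decision scores are positive-class leaf
proportions; ROC ties are grouped into single sweep steps, which is
equivalent to midpoint interpolation, and AUC is the trapezoidal
integral (equal to Mann–Whitney concordance, tested by brute-force
enumeration). Inner-accuracy ties across λ go to the smallest λ.

**Topology placement in cross-validation.** `topology_scope =
"all_subjects"` (default) runs topology detection once on the full cohort
before cross-validation, reproducing pipelines in which region selection
precedes CV. Note that this leaks test-subject information into the
selection step, so the resulting accuracy estimates are optimistic;
`topology_scope = "train_only"` refits `E_p` inside every outer fold for
a leakage-free estimate at roughly `M` times the topology cost. With the
default scope, a subject's network at a given λ does not depend on fold
membership, so networks are built once per λ and shared across folds —
an exact reorganization, not an approximation.

**Seeding.** Every pipeline run derives per-stage seeds from one master
seed through named substreams (`substream(seed, "panel")`, `"classifier"`,
…), so adding or re-ordering stages never perturbs another stage's draws,
and identical configurations reproduce results bit for bit.

## What the synthetic cohorts emulate — and what they do not

The generator draws each subject's `n_t × P` matrix i.i.d. across time
from a zero-mean multivariate normal whose precision matrix is the
subject's group-level sparse precision with jittered edge magnitudes:

- the **support** (which edges exist) is shared within a group — the
  premise the ℓ2,1 penalty exploits;
- the **magnitudes** differ by subject: each nonzero entry is multiplied
  by `(1 + u)`, `u ~ U[−jitter, +jitter]` (default 0.2), modelling
  individual connectivity strengths on a common topology;
- the two groups differ on a small set of flipped edges (default 6), the
  planted signal a classifier must find;
- positive definiteness is enforced by diagonal loading (add `δI` until
  the smallest eigenvalue reaches `1e-3`) — simple and reproducible.

A Gaussian graphical model is the natural choice here because the
penalized objective above *is* the Gaussian log-likelihood: ground truth
coincides exactly with the estimand. What the generator deliberately does
**not** reproduce: temporal autocorrelation (the estimators treat time
points as exchangeable, so i.i.d. sampling matches their assumptions but
real fMRI's effective sample size is smaller than `n_t`), hemodynamics,
scanner drift and motion artifacts, and non-Gaussian tails. Passing
recovery tests on these cohorts therefore validates the estimation
machinery, not robustness to fMRI preprocessing residue.

Default cohort: 20 regions, 10 subjects per group, 300 time points, 30
shared edges of magnitude 0.3, 6 flipped, jitter 0.2. These sizes keep a
full four-variant nested-LOOCV comparison in the minutes range while
leaving the planted difference detectable but not trivial; the region
count is deliberately smaller than a whole-brain atlas, with the
whole-brain dimensionality (8,100 features at P = 90) exercised in the
vectorization layer, which is scale-independent.

For the support-recovery validation of the graphical lasso itself
(P = 10, n_t = 2,000) the ground-truth graph uses 6 of 45 possible edges
(≈ 13% density) with partial correlations ≈ 0.33 — the sparse-benchmark
regime of the graphical-model literature. Support recovery is *expected*
to degrade on substantially denser graphs, where the irrepresentability
conditions underpinning lasso-type support consistency fail; that is a
property of the estimator class, not of this implementation.

## Worked example

```{r example, eval = FALSE}
library(sicenet)

# a harder-than-default cohort: 120 time points, subject jitter 0.4
cfg <- run_config(seed = 1, lambda_pool = c(0.1, 0.3, 0.5, 0.7, 0.9),
                  sim = list(n_t = 120L, subject_jitter = 0.4))
cmp <- compare_modes(cfg)
cmp$table
#> # A tibble: 4 x 5
#>   mode            acc   sen   spe   auc
#>   <chr>         <dbl> <dbl> <dbl> <dbl>
#> 1 partial          85    80    90  0.85
#> 2 group-partial    95   100    90  0.95
#> 3 sice             95   100    90  0.95
#> 4 group-sice       90    90    90  0.9

res <- cmp$results[["group-sice"]]
glance(res$cv)                 # confusion counts + metrics
head(res$frequency)            # most frequently selected connections
autoplot(res$metrics)          # ROC curve
autoplot(res$convergence)      # solver traces
```

On the generator's default cohort (300 time points, jitter 0.2) all four
variants reach perfect leave-one-out accuracy — the planted 6-edge
difference is easy at that sample size. The harder cohort above is where
the variants separate: whole-brain partial correlation trails the sparse
and group-constrained constructions, which suppress the inter-subject
support variability before the classifier sees the features.

## Known limitations

- LOOCV has high variance at small `M`; the per-fold λ choices and
  selected connections should be read as descriptive, not inferential.
- With `topology_scope = "all_subjects"` accuracies are optimistic (see
  above); the flag exists precisely to quantify that gap.
- The decision tree is the framework's fixed classifier by design; no
  other classifiers are provided.
- Connectivity matrices are asymmetric by construction. The
  `symmetrize` flag averages the two triangles for graph-theoretic
  post-processing, but classification always uses the raw asymmetric
  matrix.
- Runtime is dominated by the inner LOOCV's tree fits
  (`M × (M−1) × |pool|` fits per run) and, under `train_only`, by
  repeated topology detection.
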