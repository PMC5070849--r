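---
title: "Decomposing expression dynamics with metagene state-space models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing expression dynamics with metagene state-space models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssdyn)
```

## The model and its assumptions

`ssdyn` treats the expression of a gene group of interest (the *internal*
group, N₁ genes) as the state of a linear, time-invariant, first-order
difference system driven by an *external* regulator group (N₂ genes):

$$X_{t+1} = A X_t + B U_t, \qquad t = 1, \ldots, T.$$

Three assumptions matter and should be kept in mind when interpreting
output:

1. **Linearity and time invariance.** One fixed $(A, B)$ acts across the
   whole time course. Regulatory rewiring during the process (switching
   systems) and saturating or combinatorial regulation are outside the
   model; with the handful of time samples typical of developmental
   time courses, a richer model would not be estimable anyway.
2. **First-order dynamics on the measured grid.** The state one step
   ahead depends only on the current state and control. Time labels are
   deliberately metadata: all computation uses the sample index
   t = 1..T, which is what makes a 25-sample and a 12-sample time course
   comparable — by relative position in the process, not absolute hours.
   Unevenly spaced samples are therefore reinterpreted as evenly spaced
   in "developmental progress", a modelling choice, not a bug.
3. **No observation-noise model.** Estimation is plain least squares on
   the one-step transitions; there is no Kalman filter or EM step.
   Measurement noise biases eigenvalue estimates continuously (a property
   the test suite smoke-tests at three noise levels); the leave-one-out
   sensitivity analysis is the package's instrument for judging whether
   the spectrum is stable enough to interpret.

Expression values are used as-is by default (the pipeline is routinely
applied directly to RPKM-scale data); `log2` and per-gene centering are
available in `expression_dataset()` but off by default so that the default
path has no hidden transforms. Missing values abort — the estimator has no
missing-data mechanism, and silent imputation would corrupt the spectrum.
Zero-variance genes are retained (removal would silently change N₁) with a
warning.

## Metagene reduction

With N₁ ≫ T the gene-level $(A, B)$ is hopelessly underdetermined, so both
groups are projected onto the top SVD components ("metagenes") of their
genes × time matrices, and the model is estimated between the metagene
series $\tilde X_t = W_X^\top X_t$, $\tilde U_t = W_U^\top U_t$. Numerical
choices:

* **Uncentered SVD.** The decomposition is of the raw matrix
  $[X_1 \cdots X_T]$; explained fractions are of total squared singular
  value mass, not variance about the mean. This keeps the projection and
  the state-space algebra in the same coordinates.
* **Sign convention.** Each loading column is flipped so its
  largest-magnitude entry is positive. SVD signs are otherwise arbitrary
  and platform-dependent; fixing them makes every downstream artifact
  bitwise reproducible.
* **Left inverse.** Loading columns are orthonormal, so the projection
  pseudo-inverse is exactly $W^\top$ — no general pseudo-inverse is
  needed, and $W^\top W = I$ holds to round-off.
* **Dimension choice.** Explicit `M1`, `M2` take precedence. Otherwise
  the smallest dimension reaching the covariation target (default 0.98,
  the conventional "capture essentially all covariation" level) is used,
  clamped so that M₁ + M₂ ≤ T − 2: the regression uses T − 1 transitions
  and needs at least as many columns as rows for a right inverse, and the
  clamp keeps one spare sample. The floor is M = 1; the clamp never
  errors.

## Estimating the effective model

Stacking transitions gives $Z = [\tilde A\ \tilde B]\,\Upsilon$ with
$Z \in \mathbb{R}^{M_1 \times (T-1)}$,
$\Upsilon \in \mathbb{R}^{(M_1+M_2) \times (T-1)}$, solved by
$[\tilde A\ \tilde B] = Z\,\Upsilon^{+}$. The Moore–Penrose inverse is
computed from one SVD with singular values below $10^{-10}\sigma_{\max}$
treated as zero; the same SVD provides the reported numerical rank, so the
rank diagnostic and the solution can never disagree. When
$\Upsilon$ is rank deficient (for instance an external group whose
metagene series are linearly dependent) the exact right-inverse condition
fails; the minimum-norm least-squares solution is returned with a warning
rather than an error, because the fitted one-step predictions are still
well defined. Estimability is enforced as M₁ + M₂ ≤ T − 1 — a sharper
bound than the loose "dimensions below T" rule of thumb, because only
T − 1 transitions exist.

## Patterns and their indexing convention

Diagonalizing $\tilde A H = H E$ and setting $S = H^{-1}\tilde X_1$,
$\tilde K_p = s_p H_p$, the internally driven component expands as one
pattern per eigenvalue, with pattern p contributing
$\tilde K_p \lambda_p^{\,t-1}$ at time t, so contributions sum to
$\tilde A^{t-1}\tilde X_1$ *exactly, including t = 1*. The displayed
trajectory of a pattern is $\lambda^1..\lambda^T$ (and the merged
$2|\lambda|^t\cos(t\arg\lambda)$ for conjugate pairs). The exponent
offset between display and contribution is deliberate: anchoring the
expansion at the observed first sample avoids dividing by $\lambda$
(undefined for an impulse eigenvalue at 0) while keeping the defining
reconstruction identity exact — the identity is asserted in the test
suite for every extraction.

Other choices made where the mathematics is genuinely open:

* **Ordering.** Eigenvalues (and hence patterns) sort by modulus
  descending, ties by real part descending, then imaginary part
  descending. Modulus governs long-run dominance; the full rule makes
  leave-one-out pairing and cross-dataset matching deterministic.
* **Conjugate merging.** Real system matrices produce conjugate pairs;
  each pair becomes one real pattern, keeping the positive-imaginary
  member as representative. Merged trajectories are real by
  construction; the realness of the contribution sum is tested to 1e-10.
* **Diagonalizability guard.** Extraction refuses eigenvector matrices
  with condition number above 1e8 rather than attempting a Jordan-form
  expansion: exactly defective matrices have measure zero in estimated
  models, and a near-defective one means the pattern expansion is
  numerically meaningless — the cure is perturbing M₁ and refitting.
* **Classification tolerances.** An eigenvalue within `unit_tol = 1e-6`
  of the unit circle (or of 0) is classed "constant"/"sustained"
  ("impulse"); imaginary parts below `real_tol = 1e-9` are treated as
  real. Both are exposed arguments and echoed into the run manifest.
* **Merged-pair gene coefficients.** A merged pattern's gene coefficient
  is reported as magnitude $2|C_p(i)|$ plus phase $\arg C_p(i)$ — which
  fully determines the real contribution
  $2|C|\,|\lambda|^t\cos(t\arg\lambda + \arg C)$ — with $2\,\mathrm{Re}\,C$
  as the signed value. Downstream ranking uses absolute coefficients by
  default, with a signed option.

The externally driven component splits by lag: $B U_{t-1}$ is "external",
older lags $A^k B U_{t-1-k}$ ($k \ge 1$) are "interaction". Any regrouping
of the lagged terms is algebraically equivalent; `external_lags` moves the
first L lags into the external component for users who prefer a different
convention, and the component sum is invariant (tested).

## Comparison statistics

* Cross-dataset pattern matching is by class label in eigenvalue order —
  never by resampling time grids, so datasets with different T compare
  cleanly.
* Coefficient agreement uses Spearman correlation (mid-ranked ties) with
  the asymptotic t-approximation p-value; rank invariance makes it immune
  to the arbitrary overall scaling of coefficients between fits.
* The gene-set internal-vs-external test ranks genes within each pattern
  column (ascending), pools the set's ranks across all internal columns
  and across all external columns, and applies Welch's unequal-variance
  t-test — the pooled samples have different sizes (M₁·|set| vs
  M₂·|set|) and no reason for equal variances, so the pooled-variance
  test would be wrong. Positive t means "more internally driven". With
  the set equal to all genes both pooled means are exactly (N₁+1)/2 and
  t is exactly 0, a conservation identity the tests assert.

## The synthetic generator

`make_synthetic_dataset()` is the package's ground-truth instrument: it
plants an exact eigenvalue spectrum (real block-diagonal form conjugated
by a random orthogonal similarity — a well-conditioned "random invertible"
similarity that preserves the spectrum exactly), draws
$\tilde B \sim N(0, 0.5^2)$, generates smooth external inputs (three-term
random Fourier series plus a linear trend, smooth like real expression
profiles and generically full-rank in the regression), propagates the
state, and lifts both groups through random orthonormal gene loadings
with optional i.i.d. Gaussian gene-level noise.

What it emulates: the low-rank structure, smooth temporal profiles, and
exact state-space consistency of the modelled process. What it does not:
RPKM-style mean–variance coupling and nonnegativity, outlier genes,
regulatory saturation, or any model misspecification — so passing
recovery tests demonstrates correctness of the estimator and algebra, not
that real expression data follow the model. Inference on real data should
lean on the leave-one-out ranges and the residual diagnostics, not on the
synthetic recovery results.

## Problem sizes and tolerances used in validation

The test suite and the acceptance script validate at sizes chosen to be
decisively informative while remaining quick: metagene dimensions 2–6,
T = 10–30, gene counts up to 300, 50–200 replicate random systems per
property. Noiseless recovery is asserted at 1e-7 or tighter (the algebra
is exact; only round-off remains), algebraic identities (decomposition
conservation, pattern reconstruction, unit norms) at 1e-8 to 1e-12, and
statistics against first-principles computations at 1e-10. Larger gene
counts change nothing structurally — all computation is at metagene
dimension after one SVD.

## Known limitations

* Uniform sampling in "process time" is assumed; strongly uneven
  sampling distorts eigenvalue moduli.
* One $(A, B)$ per dataset: staged processes violating time invariance
  will show as large one-step residuals, not as an error.
* The split into external vs interaction components is convention
  (see `external_lags`); only their sum is canonical.
* Near unit-circle eigenvalues, class labels flip with estimation noise;
  consult the leave-one-out ranges before interpreting a single label.
* No gene-level $(A, B)$ is ever reported: the method identifies
  metagene-level dynamics and per-gene pattern coefficients, not a
  gene–gene regulatory network.
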