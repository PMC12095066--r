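---
title: "Methods: genomic prediction of trait dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic prediction of trait dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dynamicGP)
```

## The model and its assumptions

A genotype's phenome at day $t$ is a vector $x_t \in \mathbb{R}^p$ of
trait values. We assume a time-invariant linear day-to-day map

$$x_{t+1} = A\,x_t,$$

estimated per genotype by dynamic mode decomposition (DMD). Linearity of
the *map* does not mean traits change linearly in time: a linear operator
generates exponential growth and decay, damped oscillations and
rotations among traits. What the model does assume is (i) stationarity —
one operator for the whole observed window — and (ii) that a low-rank
operator captures the coordinated part of development. Both are
approximations; the cross-validated accuracies are the measure of how
much they cost.

Classical DMD solves the least-squares problem
$\min_A \lVert A X_1 - X_2 \rVert_F$ via $A = X_2 X_1^+$. The Schur-based
variant restricts the operator to the $r$ leading POD modes of $X_1$
(left singular vectors), which filters measurement noise, and factors the
reduced operator with a **real** Schur decomposition
$\tilde A = Q^\mathsf{T} R Q$ rather than an eigendecomposition: the
reduced operator is non-symmetric, the real Schur form always exists, is
numerically stable, and keeps every stored quantity a real number —
complex-conjugate eigenvalue pairs appear as $2\times 2$ diagonal blocks
of $R$. We store $Q$ so that the identity $\tilde A = Q^\mathsf{T} R Q$
holds, i.e. the transpose of the factor most libraries return; the
projected modes are $\Phi = X_2 V_r \Sigma_r^{-1} Q^\mathsf{T}$, which
makes $A_r = \Phi R \Phi^+$ share its nonzero spectrum with $\tilde A$ —
an identity the test suite asserts to $10^{-8}$.

### Measurement gaps

Phenotyping platforms often image five consecutive days and then skip
two. Snapshot pairs are therefore built only *within* blocks of
consecutive days, so every regression pair spans exactly one day. A block
with a single timepoint contributes nothing (a warning is raised); a
design with at least one usable pair is accepted, because even a single
pair defines a rank-one least-squares operator — degenerate, but exactly
what the pseudoinverse contract promises.

Forecasting across a gap of $g$ missing days offers two readings:
apply $A$ once per *measurement step* (`unit_step`) or once per
*calendar day* (`power`, $A^{g+1}$). Both are implemented; `unit_step`
is the default for field data, where per-step application is the
convention, while the synthetic benchmarks use `power` because the
generator's ground truth advances through calendar days — the physically
literal reading. The generator deliberately advances latent states
through gap days so the two policies can be compared meaningfully.

## Canonicalization: making entries comparable across genotypes

The SVD and the Schur form are unique only up to column signs and block
order. Left alone, those indeterminacies assign entry $(i,j)$ of $R$ or
$\Phi$ a different meaning — or a random sign — in every genotype, which
destroys the heritability of the entries and with it the whole method.
The canonical form applied after every fit is:

1. **Block order.** Diagonal blocks of $R$ are sorted by descending
   eigenvalue modulus through orthogonal similarities (adjacent-block
   swaps via a small Sylvester solve and QR, the standard reordering
   construction). Mode 1 is always the most persistent mode.
2. **Mode signs.** Each Schur-vector column (with its column of $\Phi$)
   is flipped so that the *sum of the mode's elements* is nonnegative.
3. **Singular-vector signs.** Each pair $(u_j, v_j)$ is flipped so that
   the projection $\langle u_j, \phi_j\rangle$ is nonnegative.

The choice of anchors matters more than it may look. A tempting
convention — make the largest-magnitude element of each column
positive — is unstable in exactly the regime this method lives in: two
genotypes with nearly identical mode vectors can have their two largest
elements almost tied with opposite signs, so the selected element (and
hence the sign of a whole column of entries) flips from line to line.
Aggregate anchors (a column sum; a projection onto the matched POD
direction, whose typical size is the eigenvalue modulus) vary smoothly
across genotypes and flip only in non-generic geometries. The rules are
odd under the respective sign freedom, so canonicalization is idempotent,
a fact the tests check along with the invariance of $A_r$ (Frobenius
distance below $10^{-10}$).

Whether any such convention is applied before entry-wise genomic
prediction is a genuinely open modelling choice; ours is documented here
and its effect is visible in the synthetic benchmarks: with a shared mode
basis and canonical factors, entries of $R$ are recovered across
genotypes exactly, which is what allows the perfect-information scenario
to approach accuracy 1.

## Marker-based models

**GRM.** VanRaden method 1: markers centred by twice the allele
frequency, cross-product scaled by $2\sum_j p_j(1-p_j)$. This is the
"centered" kinship most GP toolchains produce; the scaling is documented
so users can compare against other tools. Monomorphic markers are
excluded from the scaling (an all-monomorphic panel is an error).

**GREML.** The single-component model
$y = \mu\mathbf{1} + g + e,\; g \sim N(0, \sigma_g^2 K)$ is fitted by
restricted maximum likelihood, profiled down to a one-dimensional search
over $h^2 \in [0,1]$ in the eigenbasis of $K$ (each likelihood
evaluation is $O(k)$ after one eigendecomposition, which is shared
across the thousands of entry- and trait-level fits the screens
require). Brent-type bounded optimisation with tolerance $10^{-8}$;
the boundary values 0 and 1 are evaluated explicitly and reported with a
flag when optimal, otherwise estimates are clipped to
$[10^{-6}, 1-10^{-6}]$.

**RR-BLUP.** Same spectral machinery on the marker kernel
$M M^\mathsf{T}$, REML-optimising $\log\lambda \in [-10, 10]$ where
$\lambda = \sigma_e^2/\sigma_u^2$. The intercept is handled by
generalised least squares inside the restricted likelihood (projected
out, not penalised). At fixed $\lambda$ the solution equals the primal
ridge closed form $(M^\mathsf{T}M + \lambda I)^{-1}M^\mathsf{T}(y-\mu)$,
asserted to $10^{-10}$ in the tests; the kernel form is used because the
pipelines have $n$ in the hundreds and $m$ up to thousands, and because
one eigendecomposition per training fold serves all ~40–100 entry
models. Markers are centred but not scaled; centring vectors are stored
in the fit so prediction is exactly reproducible. A standardisation
switch was considered and rejected as a default because entry traits are
already on a common scale.

## Trait-panel reduction

Large image-derived panels are heavily redundant. Per trait, lines are
compared by the Euclidean distance between their full time profiles; the
Mantel correlation between two traits is the Pearson correlation of the
strict lower triangles of their $k \times k$ distance matrices. This is
the reading that makes the Mantel name literal; a flat
correlation-of-profiles alternative is available behind
`method = "flat"`. Thresholding (default 0.96, signed; an absolute-value
mode exists) gives an unweighted graph — threshold-then-cluster, so edges
carry no weights — and deterministic greedy modularity maximisation
(agglomerative, as implemented in igraph) partitions it. A stochastic
community method would make the representative set depend on the RNG;
determinism was preferred. Each cluster is represented by its trait with
the highest mean SNP heritability over the analysed timepoints, ties
broken lexicographically with a message. Min–max normalisation (per
trait, over all lines and timepoints jointly) puts traits on a common
[0, 1] scale before modelling; it is an explicit upstream step rather
than something the pipeline applies silently, because the affine shift
it introduces slightly misspecifies a purely linear operator model and
the user should know it happened.

## Rank selection

The retained rank $r$ is a hyperparameter chosen *before* training, from
the training–testing lines only (the plan's validation slice is
excluded). For each candidate $r \in \{2,\dots,6\}$ the screen computes
the heritability of every factor entry and the cross-validated genomic
predictability of the reduced-operator entries; the chosen rank is the
largest candidate whose mean reduced-operator predictability exceeds a
floor (default 0.1). Candidates whose $r$-th singular value vanishes are
infeasible and drop out; if no feasible candidate clears the floor the
smallest is returned with a no-signal flag. On noise-free synthetic data
of true rank $q$ this recovers $q$ exactly, because rank $q+1$ is
infeasible; on noisy data the floor does the work.

## Cross-validation design

A `cv_plan` draws all fold assignments up front from a seed, so any two
evaluations sharing a plan are compared on identical test lines
(paired). The optional validation slice is drawn **once per plan**, not
per iteration: a fixed train/test-vs-validation split is simpler to
reason about, and the slice's only role is to stay out of the rank
screen. Per-trait, per-timepoint accuracy is the Pearson correlation
across a fold's test lines (undefined correlations — fewer than three
lines, or a constant vector — are stored as missing and excluded from
means, never coerced to zero, which would bias averages toward the
null). Fold-level correlations are averaged over folds and iterations.
Per-line factor models depend only on that line's own data, so they are
computed once and subset per fold; no information crosses the
train/test boundary.

## The synthetic-data generator

The generator is the package's study system. Its ground truth is exactly
the model's data-generating assumption: per line,
$A(g) = \Phi_0 R(g) \Phi_0^\mathsf{T}$ with a shared orthonormal mode
basis $\Phi_0$ and an upper-triangular reduced operator $R(g)$ whose
entries are `base + genetic + residual`. Since any operator with those
eigen-directions can be written this way, generating $R(g)$ directly in
canonical (triangular, ordered, sign-fixed) form loses no generality and
makes the planted entries the exact targets of the fitting pipeline.
Genetic parts are sparse (default 20 causal markers per entry, an
oligogenic architecture); genetic and residual parts are rescaled to
exact sample variances so the realised entry heritability equals the
target. Eigenvalue moduli live in a configurable spectral interval
(default [0.7, 1.08], capped at 1.1 so 25-day trajectories cannot
diverge); a line whose radius leaves the interval is rescaled to the
nearest bound and flagged (`truth$rescaled`) — rescaling breaks the exact
linearity of that line's entries in its markers, so parameter choices
keep it rare. Latent states advance through gap days; observations add
i.i.d. Gaussian noise at measured days only. Starting states are drawn in
mode space with a common centre, optional non-genetic line deviations
and an optional genetically shifted component.

Preset scenarios (dimensions chosen once, to mirror a large maize
phenomics design at desk scale):

| scenario    | k   | m    | p  | entry h² | noise sd | start variation |
|-------------|-----|------|----|----------|----------|-----------------|
| `perfect`   | 200 | 100  | 20 | 1.0      | 0        | none            |
| `heritable` | 300 | 1000 | 20 | 0.5      | 0.05     | line + genetic  |
| `null`      | 300 | 1000 | 20 | 0.0      | 0.05     | none            |
| `maize_like`| 330 | 2000 | 50 | 0.3      | 0.05     | line + genetic  |

Two presets deserve their rationale. In `perfect`, $m < $ training-fold
size so ridge regression can identify the (exactly linear) entry maps;
the starting state is common to all lines so every fitted factor is a
function of genotype alone — the regime where genomic operator
prediction can be exact, giving the pipeline's upper bound. In `null`,
the *latent* start is common and operators vary non-genetically: measured
starting states differ only by measurement noise, so recursive forecasts
carry no line-specific information and accuracy must centre on zero. If
the null start varied biologically, recursive forecasts would inherit
genuine (non-genomic) information from the measured initial state and
the null would not be a null.

What the generator does **not** emulate: linkage disequilibrium and
population structure (markers are unlinked, lines unrelated beyond
chance), genotype-by-environment interaction, time-varying operators,
missing-data patterns, and the upstream experimental-design adjustment
that produces line-level values from replicated plots. Passing the
synthetic benchmarks therefore demonstrates the correctness of the
machinery and its behaviour under the model's own assumptions — not that
field data satisfy those assumptions.

## Numerical choices

- Pseudoinverse cutoff: singular values below
  `max(dim) * .Machine$double.eps` (relative to the largest) are
  truncated; configurable per call.
- Schur block comparisons treat moduli within $10^{-12}$ as tied (no
  swap), keeping reordering stable under noise.
- `fit_schur_dmd` refuses an $r$ whose singular value is numerically
  zero, with advice to lower $r$.
- Constant entry columns (e.g. the structural zero below the diagonal of
  a real $2\times 2$ $R$) get constant-value "models" so predicted
  factors stay well formed; constant responses elsewhere are errors.
- Rank-deficient predicted mode matrices fall back to the pseudoinverse
  with a warning.
- Serialization (factor models, trained bundles) writes 17 significant
  digits; report CSVs likewise. Both round-trip doubles exactly, and the
  tests assert bit-identity.

## Problem sizes used in the test suite

The suite validates oracle equivalences at tiny sizes (hand-worked
examples, $n \le 10$), parameter recovery at $k = 500$, $m = 2000$ with
50 replicates per heritability level, and the full pipeline on the
preset scenarios with 1–5 iterations of 5-fold cross-validation — sizes
chosen so the entire suite runs in a few minutes on one CPU while
keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

- One operator per genotype: stage-specific dynamics (e.g. juvenile vs
  adult) are averaged.
- Entries are predicted independently; correlations between entry traits
  are ignored at training time (a multi-trait BLUP would exploit them).
- The canonicalization anchors, while robust, can still flip in
  non-generic geometries (a mode orthogonal to the ones vector, a
  near-zero eigenvalue); such entries show up as non-heritable and are
  harmless downstream, but they waste a model.
- The iterative mode requires measured states of the *test* line up to
  the forecast time; it answers "can markers predict tomorrow given
  today", not "can markers replace phenotyping".
- REML here is single-kernel; environmental covariates and multi-kernel
  extensions are out of scope.
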