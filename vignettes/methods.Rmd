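---
title: "Models and methods behind cladeshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cladeshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cladeshift implements a complete comparative analysis of habitat
transitions and continuous trait evolution on a phylogeny. This vignette is
the package's own account of the statistical machinery: the models, their
assumptions, the tunable parameters, the numerical choices, and what the
synthetic data generator does and does not emulate.

## The habitat character: Mk models

Habitat is a discrete character with states CS (cold steppe at high
elevation or latitude), HF (humid forest) and WA (warm arid–semiarid
shrubland). Its evolution is modelled as a continuous-time Markov chain on
the tree. Two generators are fitted by maximum likelihood:

* **ER** (equal rates): one rate $q$ for every transition, generator
  off-diagonal $q$, diagonal $-(K-1)q$. The transition matrix has the
  closed form $P_{ii}(t) = 1/K + (1 - 1/K)e^{-Kqt}$,
  $P_{ij}(t) = 1/K - (1/K)e^{-Kqt}$.
* **SYM**: one rate per unordered state pair ($K(K-1)/2 = 3$ parameters),
  exponentiated through the symmetric eigendecomposition of the generator.

The likelihood is computed by Felsenstein pruning with indicator partials
at the tips, per-node rescaling against underflow, and a **uniform root
prior** $1/K$. The prior is a deliberate choice: the models are symmetric,
their stationary distribution is uniform, and the reconstruction method
cited below assumes a flat prior; it is configurable nowhere because every
downstream result holds under it.

ER is nested in SYM, so the models are compared with a likelihood-ratio
test, $2(\ln L_{SYM} - \ln L_{ER}) \sim \chi^2_{df}$. The degrees of
freedom come from the parameter counts: $3 - 1 = 2$ at $K = 3$.

**Optimization.** Rates are optimized on the log scale within
$[10^{-8}, 10^3]$ (per unit branch length). ER uses a 10-point log-spaced
grid refined by golden-section search; SYM runs L-BFGS-B from the same
grid of equal-rate starts plus the ER solution, which guarantees
$\ln L_{SYM} \ge \ln L_{ER}$. The start grid is deterministic, so fits
consume no randomness. Estimates within a factor of two of a bound are
flagged as boundary fits (monomorphic data drive $\hat q$ to the lower
bound).

**Marginal ancestral states.** For every node the package reports
$P(\text{state} \mid \text{all tip data})$ with the rates held fixed at
their global ML estimates (empirical Bayes — re-optimizing per node would
change the question being asked). The computation is the two-pass
message-passing form of the re-rooting method: downward pruning partials
are combined with upward messages from the rest of the tree. For symmetric
generators with a uniform prior this is exactly what one obtains by
re-rooting the tree at each node and reading the root marginals, and it
equals the brute-force conditional probability — the test suite verifies
both statements against exhaustive enumeration on small trees to $10^{-9}$.
Most-probable states break ties by state order (CS, HF, WA) with a
warning; switch counts are parent→child changes along edges under that
assignment.

## Continuous traits: contrasts, rates, signal, PGLS

Traits (PH, LA, LMA, LT, LD, AR, RSR) are natural-log transformed and
z-scored per column **across the full taxon set once**, before any clade
extraction, so that per-clade rates remain on one common scale. The log
base is irrelevant after z-scoring; natural log is the field convention.

**Independent contrasts** follow the standard pruning recursion: at a node
with children values $(x_i, x_j)$ on working branches $(b_i, b_j)$ the
standardized contrast is $(x_i - x_j)/\sqrt{b_i + b_j}$, the node value is
the precision-weighted average, and the parent branch grows by
$b_i b_j/(b_i + b_j)$. Under Brownian motion the contrasts are i.i.d.
$N(0, \sigma^2)$; the package uses
$\beta = \sum c_i^2/(n-1)$ as the rate estimator, which is unbiased for
$\sigma^2$ (verified by simulation calibration in the tests) and equals the
REML quadratic-form estimator computed directly from the phylogenetic
covariance (verified algebraically on random trees to $10^{-8}$).

Rate comparisons use $F = \beta_a/\beta_b$ with df $(n_a-1, n_b-1)$ and
**two-tailed** p-values, since no direction is hypothesized. Among-trait
comparisons on the same tree ignore cross-trait dependence; this is a
documented limitation shared with the classical procedure. The per-clade
rate table summarizes pairwise tests at $\alpha = 0.05$ as compact letters
(maximal cliques of the "not significantly different" graph) with **no
multiplicity correction** — the multiple-comparison handling of such
tables is conventionally unstated, so the plainest choice is implemented
and said out loud here.

**Pagel's λ** multiplies the off-diagonal of the Brownian covariance $C$:
$\lambda = 0$ is a star phylogeny (no signal), $\lambda = 1$ pure Brownian
motion. The per-trait signal fit profiles the intercept-only GLS likelihood
over $\lambda \in [0,1]$ (golden-section plus explicit endpoint checks; the
search is bounded at 1 because estimates above 1 are not interpretable on
ultrametric trees and the reported values it emulates all lie in
$[0, 1]$). AIC counts 3 parameters at $\hat\lambda$ (mean, $\sigma^2$,
$\lambda$) and 2 at the fixed endpoints.

**PGLS** regresses PC axes on habitat (dummy-coded, reference level CS) or
climate (wMAT + wMAP jointly), with error covariance $C(\lambda)$ and
$\lambda$ profiled by ML; `method = "ols"` fits the identity-covariance
model for the AIC comparison. ML (not REML) is used throughout because
AICs are compared across models with different fixed $\lambda$. The
overall F is computed on the GLS-whitened problem with df
$(p, n - p - 1)$, $R^2 = 1 - RSS_w/TSS_w$ on the same whitened scale, and
AIC counts one parameter per coefficient, one for $\sigma^2$, and one for
$\lambda$ when estimated. Unused factor levels are dropped before fitting,
so fixtures that happen to lack a habitat state fit cleanly.

## Phylogenetic PCA

The evolutionary covariance
$R = (X - 1a)^\top C^{-1} (X - 1a)/(n-1)$, taken about the GLS phylogenetic
mean $a = (1^\top C^{-1} 1)^{-1} 1^\top C^{-1} X$, is eigendecomposed;
scores are $(X - 1a)V$. The analysis runs in covariance mode because the
traits are already z-scored upstream, and in plain Brownian mode
($\lambda$ is not re-estimated inside the PCA — signal estimation is a
separate question answered by the signal table). Components are oriented
deterministically: the largest-magnitude loading of each component is made
positive, so repeated runs are comparable.

One consequence of that orientation rule matters for interpretation: when
cold-steppe taxa are shifted upward on the "slow" traits (LMA, LT, LD,
RSR), those traits dominate PC1 with positive loadings and CS taxa sit
*high* on PC1. Wherever the pipeline reports the cold-steppe-versus-rest
contrast it therefore anchors the orientation first (PC1 is flipped if the
LMA loading is positive), so that low PC1 always reads as
"resource-conservative strategy" and the contrast's sign is comparable
across runs. The PCA object itself keeps the neutral largest-loading
convention.

## Modularity: the covariance ratio

For a partition of the traits into a leaf module (LA, LMA, LT, LD, AR) and
a life-form module (PH, RSR), the covariance ratio is
$$CR = \sqrt{\frac{\operatorname{tr}(S_{12}S_{21})}
{\sqrt{\operatorname{tr}(\tilde S_{11}\tilde S_{11})\,
       \operatorname{tr}(\tilde S_{22}\tilde S_{22})}}},$$
where $S$ is the trait covariance of the independent contrasts and the
within-module blocks $\tilde S_{ii}$ have their diagonals zeroed. $S$ is
computed **about zero** (contrasts have zero expectation under Brownian
motion); centering is available behind a flag because the convention is
not universal. Low CR means modules covary less with each other than
traits do within modules.

The null reassigns traits to modules at random with module sizes fixed,
and the p-value is one-tailed for low CR. With 7 traits and module sizes
(5, 2) there are only $\binom{7}{2} = 21$ distinct assignments, so the
package **enumerates the assignment space exactly** whenever it is no
larger than the requested number of permutations, reporting
$p = \#\{CR_{perm} \le CR_{obs}\}/N$ (the observed assignment is one of
the $N$, so $p \ge 1/N$). Random sampling of a 21-element space would make
the attainable p-values hover around the $0.05$ threshold by coin flip;
enumeration gives the exact permutation p-value and is strictly more
accurate. Sampled permutation (with the $+1/+1$ rule) is used only when
the space is genuinely large.

Per-clade tests extract each clade's subtree and recompute contrasts
inside it; clades under 4 taxa are reported as NA with a reason.

## The synthetic data generator

`make_fixture()` emulates the study design the pipeline targets:

* **Tree**: three Yule subtrees (default sizes 10/12/12, birth rate 1)
  scaled to depth 0.6 and grafted onto a fixed two-split backbone, total
  depth 1 (relative time). The clade sizes are a configurable convention —
  the real clade memberships are not public.
* **Habitat**: an exact ER simulation (root uniform, transitions sampled
  from the analytic $P(t)$ per branch), with rate $q = 0.35$ chosen so
  that histories with 5–9 true changes are common; histories outside that
  range are redrawn (at most 500 times) so fixtures always carry a
  realistic handful of switches.
* **Traits**: multivariate Brownian motion with covariance `R` (default:
  unit variances, correlation 0.6 within the blocks {LMA, LT, LD, RSR} and
  {PH, LA, AR}, zero between — the fixture's truth, not a claim about real
  data), per-trait $\lambda$ ($\lambda = 0$ for AR, 1 otherwise, matching
  the one trait conventionally reported without signal), and an additive
  habitat effect $+\delta$ (default 3 log-units, i.e. effect-dominates-
  noise) on the slow traits for CS taxa. Per-trait $\lambda$ is simulated
  as $x_j = L_j w_j$ with $L_j = \operatorname{chol}(C_{\lambda_j})$ and
  cross-trait covariance carried by $w$; marginals are exact, and the
  construction reduces to the matrix-normal model when all $\lambda$
  agree. Scenario fixtures can give each clade its own `R` via a recursive
  per-branch simulator (backbone branches use the base `R`).
* **Climate**: wMAT (°C) and wMAP (mm) drawn around habitat-specific means
  (CS cold, WA warm and dry, HF wet) with Brownian noise.

What the generator does **not** emulate: birth–death extinction, fossil
calibration, intraspecific sampling error, polymorphic habitat scoring,
Ornstein–Uhlenbeck attraction (habitat effects are additive tip shifts, so
the generative model stays inside the Brownian family the analyses
assume), and measurement error in traits. Passing tests therefore
demonstrate correctness of the machinery under the stated model, not
robustness to real-data pathologies.

## Tree handling and numerics

* Newick I/O delegates to ape after cheap structural pre-checks that
  report character offsets for unbalanced parentheses and missing
  semicolons; duplicate or empty tip labels and single-tip trees are
  rejected everywhere.
* Polytomies are resolved randomly (seeded) into bifurcations whose new
  internal branches get length $\epsilon = 10^{-4}$ — the value
  conventionally used when a consensus tree carries a single polytomy — so
  any root-to-tip distance moves by at most $(k-2)\epsilon$.
* `force_ultrametric(method = "extend")` (default) lengthens terminal
  branches only; `"scale_paths"` moves every node at depth $d$ with
  deepest tip $D$ below it to depth $dT/D$, which rescales each
  root-to-tip path monotonically and can never create a negative branch.
  The method actually used by any given published tree is usually
  unstated, so both are provided and the default is the least invasive.
* GLS solves go through Cholesky whitening (`backsolve`), never explicit
  inverses; likelihood comparisons in the tests use independent dense
  `solve()`/`determinant()` oracles.
* All simulation functions restore the caller's RNG state and are
  bit-reproducible under a fixed seed; pipeline stages derive their seeds
  from one master seed, so two runs with the same seed produce
  byte-identical tables.

## Problem sizes in the test suite

The calibration tests run at sizes chosen to make their Monte Carlo error
small relative to the asserted bands: 1000 replicates for rate-estimator
unbiasedness ($n = 50$), 2000 for the F-test size ($n = 30$ per clade),
200 each for $\lambda$ recovery ($n = 100$), 1000/200 for the CR size and
power ($n = 34$), and 200 scenario fixtures for the qualitative-pattern
reproduction. Oracle-equivalence tests (pruning likelihood, re-rooting
marginals) enumerate all internal-node assignments on trees of 4–6 tips,
where exhaustive enumeration is exact and fast.

## Known limitations

* The modularity null has coarse granularity with a (5, 2) partition
  (21 assignments; the smallest attainable p is $1/21 \approx 0.048$), so
  per-clade conclusions at $\alpha = 0.05$ are all-or-nothing. This is a
  property of the statistic's permutation space, not of the
  implementation.
* A habitat effect that spans both modules (the slow-strategy shift
  touches RSR in the life-form module and LMA/LT/LD in the leaf module)
  adds between-module covariance wherever habitat switches occur inside a
  clade, and so *masks* modularity in exactly the clades with the most
  transitions. Strong habitat effects and clean modular detection are
  therefore competing signals in the scenario fixtures; the pipeline
  reports what the data contain.
* Among-trait rate F tests ignore the dependence induced by trait
  correlations; per-clade rate comparisons assume the global
  standardization.
* No OU or early-burst alternatives, no ARD habitat model by default, no
  measurement-error-aware signal estimation.
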