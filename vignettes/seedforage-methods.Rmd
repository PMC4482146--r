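---
title: "Methods: partitioning foraging investment between seed traits and tree phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning foraging investment between seed traits and tree phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedforage)
```

## The question

Scatter-hoarding rodents decide, seed by seed, how long to handle a food
item and how far to carry it before eating or caching it. Seed traits
(nutrient content, shell defenses, tannins, dormancy) plausibly drive those
decisions — but related tree species make similar seeds, so a correlation
between a trait and a behavior can reflect shared ancestry of the trees
rather than the trait itself. `seedforage` implements the comparative
toolkit for separating those signals when the data are a rooted phylogeny
of seed species, a species-by-trait table, and per-species behavioral
summaries (times and distances to consume and cache, interference counts).

Three complementary analyses are provided:

1. **Phylogenetic signal tests** per trait (Moran's I with the Abouheif
   proximity, permutation null).
2. **Phylogenetic eigenvector regression (PVR)** with partial-regression
   variance partitioning of each behavior into *traits alone*, *shared*,
   *phylogeny alone*, and *unexplained* fractions.
3. **Phylogenetic PCA (pPCA)** producing *global* (positive-eigenvalue,
   clade-structured) and *local* (negative-eigenvalue) trait axes, followed
   by permutation-inference regressions of behaviors on the retained axes.

## Statistics

### Moran's I and the Abouheif proximity

For tip values $x$ with $z = x - \bar x$ and weight matrix $W$,

$$I = \frac{n}{S_0}\,\frac{z^\top W z}{z^\top z},\qquad S_0 = \sum_{ij} w_{ij}.$$

Under random relabelling of tips, $E[I] = -1/(n-1)$; the test suite checks
this exactly by full enumeration for $n \le 7$. The phylogenetic weights
are Abouheif proximities: $a_{ij}$ is the reciprocal of the product of the
numbers of direct descendants of the internal nodes on the path between
tips $i$ and $j$. This is topology-only, handles polytomies naturally (a
polytomy's child count enters the product as-is, which is why the
collapsed-clade robustness rerun needs no special casing), and is invariant
to branch-length rescaling. The matrix is row-normalized before testing, so
$S_0 = n$ and the leading factor drops out.

Significance comes from permuting the trait across tips $B$ times with the
add-one estimator $p = (1 + \#\{I^\ast \ge I\})/(B+1)$ (mirrored for lower
tails; doubled-and-capped for two-sided). The add-one rule keeps $p > 0$
and is mildly conservative. Trait signal tests default to the upper tail —
the convention under which a positive-autocorrelation alternative is the
interesting one — and local pPCA axes are tested lower-tailed.

### PVR and variance partitioning

Patristic distances $D$ are squared and double-centered in the
principal-coordinates sense, $G = -\tfrac12 C D^{(2)} C$ with
$C = I - \mathbf{1}\mathbf{1}^\top/n$. (Centering raw distances instead is
available via `squared = FALSE`; squared distances are the default because
they make $G$ the Gram matrix of principal coordinates.) Eigenvectors of
$G$ with eigenvalue above $10^{-8}$ of the maximum form the candidate
basis: leading vectors contrast deep clades, later ones structure near the
tips.

Eigenvector selection minimizes residual autocorrelation: starting from the
empty set, while a two-sided permutation Moran test on the current
regression residuals is significant at `alpha`, the candidate whose
inclusion most reduces $|I_{\mathrm{resid}}|$ is added (ties to the lower
index, i.e. the coarser phylogenetic scale; stop when nothing reduces
$|I|$ or at $n-3$ predictors). The stated objective fixes *what* to
minimize but not the search; greedy-coarse-first was chosen because it
matches the coarse-to-fine semantics of the eigenvector ordering and is
deterministic. The residual-autocorrelation weights default to
row-normalized inverse patristic distances ($1/d_{ij}$, zero diagonal),
with the Abouheif proximity as the config alternative; defaults are
documented here precisely because either is defensible.

With $R^2_T$ (traits), $R^2_P$ (selected eigenvectors) and $R^2_{TP}$
(both) from ordinary least squares, the partition is

$$\text{traits alone} = R^2_{TP} - R^2_P,\quad
  \text{phylo alone} = R^2_{TP} - R^2_T,\quad
  \text{shared} = R^2_T + R^2_P - R^2_{TP},\quad
  \text{unexplained} = 1 - R^2_{TP}.$$

The four fractions sum to one identically. The shared fraction can be
slightly negative (classical suppression); it is flagged below $-10^{-6}$
rather than truncated.

### pPCA and the eigenvalue identity

Traits are standardized to mean 0 and **divisor-\(n\)** variance 1: the 11
seed traits mix units (%, g, kg, µm, days), so an unscaled analysis would
be dominated by numerically large columns, and the divisor-$n$ convention
is what makes the identity below exact. With $X$ ($n \times p$,
standardized) and $W_s$ the row-normalized *and then symmetrized* Abouheif
proximity, the analysis eigen-decomposes

$$H = \tfrac1n X^\top W_s X.$$

For a unit loading vector $u$ with score $s = Xu$ (automatically centered),

$$\lambda = u^\top H u = \tfrac1n s^\top W_s s
  = \underbrace{\tfrac{s^\top s}{n}}_{\operatorname{var}_n(s)}
    \cdot \underbrace{\tfrac{n}{S_0}\tfrac{s^\top W_s s}{s^\top s}}_{I(s)}$$

because row normalization gives $S_0 = n$ (symmetrization preserves the
total). Each eigenvalue is therefore exactly *variance times Moran's I* of
its scores — positive eigenvalues are high-variance, positively
autocorrelated ("global") axes; negative eigenvalues are axes along which
close relatives diverge ("local"). The package asserts this identity on
every fit to $10^{-8}$. With $W_s = I$ the analysis collapses to ordinary
PCA of the correlation matrix, which the tests exploit as an oracle.

Axes are ordered positive-descending then most-negative-first, each axis's
sign is fixed by making its largest-magnitude loading positive (so biplots
are deterministic), and the default retention is 2 global + 1 local.
Variance shares are reported as $|\lambda_k| / \sum_j |\lambda_j|$; because
shares of total trait variance are an alternative reading, `tidy(fit,
"eigenvalues")` exposes the raw signed eigenvalues so either normalization
can be recovered. Loadings above the per-axis 75th percentile of absolute
loadings are flagged "dominant" for biplot annotation.

### Permutation-inference regression

Each behavior is regressed on the retained axis scores by OLS. Because
per-species behavioral means routinely violate normal-theory residual
assumptions, coefficient inference permutes the **response vector** $B$
times (the plain permutation scheme, not Freedman–Lane) and compares
$|t^\ast|$ against the observed $|t|$, two-sided, with the add-one rule.
Permuting the response makes the intercept's permutation null nearly
degenerate — intercept p-values are reported but should not be
interpreted. The post-hoc interference analysis is a plain log-link
Poisson regression (no overdispersion correction) plus a paired t-test.

### Distance-matrix concordance

`cadm_concordance()` implements Kendall's W over the midranked upper
triangles of $m$ distance matrices, with the standard tie correction; the
null permutes the species labels of all matrices but the first. It is the
generic congruence check used upstream of tree inference (e.g. per-gene
distance matrices) and is validated in the tests against an independent
implementation.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `B` | 1000 (pipeline), 999 (functions) | permutations per test; add-one p floor is $1/(B+1)$ |
| `alpha` | 0.05 | stopping level for eigenvector selection |
| `k_global`, `k_local` | 2, 1 | retained pPCA axes |
| `tannin_floor` | 0.35 (% TAE) | replaces assay zeros before the log transform |
| `residual_weights` | `inv_patristic` | weights for residual Moran's I in selection |
| `squared` | `TRUE` | square distances inside Gower centering |
| `seed` | — | one run seed; stages derive substreams by hashing the stage name, so adding a stage never perturbs another stage's draws |

The 11-column design matrix is fixed by construction — percent lipids,
carbohydrates, proteins, caloric concentration and dormancy untransformed;
hardness, shell thickness, their product, kernel mass, shell mass and
tannin as natural logs; moisture excluded. Operationalizing the transform
set as a fixed list (rather than a data-driven skew test) makes the design
matrix exactly reproducible. The transform list is treated as exhaustive:
caloric concentration and dormancy stay untransformed.

## What the simulators emulate — and what they do not

`simulate_yule_tree()` is a forward pure-birth process with exponential
waiting times, cut at the present after the $n$-th lineage appears, so
trees are exactly ultrametric. `simulate_traits()` draws each trait from
$\mathcal N(0, \sigma^2 V(\lambda))$ where $V(1)$ is the Brownian
covariance (shared path length) and $\lambda$ attenuates off-diagonals
only — the standard signal-strength construction, chosen over
branch-length stretching because it is equivalent for simulation and
simpler. `simulate_behaviors()` adds linear axis effects and Gaussian
noise, plus independent Poisson interference counts.

`simulate_paperlike()` reproduces the *design* of the motivating study: 23
species in three nested clades (8/10/5, standing in for the
family/genus/section structure of the hardwood phylogeny), 10 raw traits in
blocks of strong (λ = 1) and absent (λ = 0) signal mapped monotonically
onto natural scales (logistic maps for percentages, log-normal for masses
and hardness), three zero tannin values to exercise the detection floor,
and four behaviors generated from the fitted pPCA scores with effects
$\beta = (-3, 0, +3)$ on (global_1, global_2, local_1), residual SD 0.5
and interference rate 0.6 per species (about 14 expected events across 23
species, the order observed in this kind of trial design). Because the
behaviors are generated from the *same* processed design matrix the
analysis reconstructs, effect recovery is exact at zero noise — which is
the point: it isolates pipeline correctness from biological realism.

What passing these simulations does **not** show: robustness to
measurement error in traits (the real tables average 3 seeds per species),
to within-species behavioral variance folded into per-species means, to
tree uncertainty (a posterior sample is summarized by one tree), or to
trait distributions that no monotone map makes near-normal. Conclusions
about real data rest on the method, not on these checks.

## Numerical choices

* Eigen-decompositions symmetrize their inputs (`(M + t(M))/2`) before
  calling the symmetric solver; eigenvalues below $10^{-8}\times$ max are
  treated as null space.
* Eigenvector sign conventions: first non-zero loading positive (PVR
  basis), largest-|loading| trait positive (pPCA axes).
* Selection ties break toward the lower eigenvector index; selection stops
  on perfect fits (residual variance below $10^{-12}$) before Moran's I
  would divide by zero.
* Constant vectors are errors everywhere a statistic would be undefined
  (Moran's I, standardization, paired differences, Spearman columns are
  NA-flagged), never silent NaN or 0.
* The all-zero Poisson response is rejected explicitly (its intercept MLE
  is at $-\infty$); IRLS runs with tolerance $10^{-10}$, 100 iterations.
* Permutation streams: every permutation test takes an explicit integer
  seed and restores the caller's RNG state, so results are reproducible
  and composable; derived seeds stay below $2^{31}$.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on simulated data at
the study's scale: oracle comparisons at $n \le 30$; exhaustive
permutation enumeration at $n \le 7$; type-I calibration with 1000
replicates at $n = 20$–23 and $B = 999$; power with 200 Brownian
replicates on 20-tip trees; end-to-end recovery with 100 study-like
replicates. These sizes give binomial standard errors of under one
percentage point on calibration rates while keeping a full run in the
low minutes on a single core.

## Known limitations

* Eigenvector selection is greedy; it can miss a jointly-optimal
  non-greedy subset (broken-stick and exhaustive-subset criteria are out
  of scope by design).
* Whether distances should come from a time-calibrated tree or a
  cladogram is a modelling choice the package does not make for you; both
  are accepted inputs.
* Intercept permutation p-values under response permutation are
  implementation-defined (see above).
* No phylogenetic GLS/PGLS alternatives, no tree inference, no missing
  trait imputation.

## A minimal session

```{r example, eval = FALSE}
sim <- simulate_paperlike(seed = 1)
design <- build_design_matrix(apply_floors(sim$traits, "tannin_pct_tae"))
w <- normalize_weights(abouheif_proximity(sim$tree),
                       "symmetrized_row_normalized")
fit <- label_axes(fit_ppca(standardize(design), w), k_global = 2, k_local = 1)
score_signal(fit, sim$tree, B = 999, seed = 2)
behavior_regressions(sim$behaviors[-6], fit, B = 999, seed = 3)
pvr_partition(sim$behaviors[-6], design, sim$tree, B = 999, seed = 4)
```
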