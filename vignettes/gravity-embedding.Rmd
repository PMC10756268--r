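---
title: "Trajectory embeddings and the gravity law of mobility"
author: "mobvec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory embeddings and the gravity law of mobility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobvec)
```

## The model

The gravity law of mobility predicts the flow between two locations from
their masses and a decreasing function of their distance,

$$\hat T_{ij} = C\, m_i m_j f(r_{ij}),$$

with either a power decay $f(r) = r^{-\alpha}$ (the convention for
geographic distance) or an exponential decay $f(r) = e^{-\beta r}$ (the
convention for embedding distance).  `mobvec` is built around the
observation that skip-gram negative sampling (SGNS, word2vec) trained on
location trajectories optimizes a *biased* conditional,

$$P_{NS}(j \mid i) = \frac{P^\gamma(j)\, e^{u_j \cdot v_i}}{Z'_i},$$

because the noise distribution $P^\gamma$ enters the numerator.  With
window $w = 1$ (so the model sees exactly the first-order flux) and noise
exponent $\gamma = 1$ (which admits a symmetric optimum $v_i = u_i$), the
implied flow takes the gravity form

$$\hat T_{ij} = C\, P(i)\, P(j)\, e^{v_j \cdot v_i},$$

i.e. an embedding trained on trajectories *is* a gravity model whose
masses are token frequencies and whose distance lives in the vector
space.  `impliedConditional()` and `impliedFlux()` expose both objects
from a trained `EmbeddingModel`.

## Training procedure and its parameters

`trainSGNS()` is a from-scratch, single-worker SGNS implementation (the
inner loop is C++):

* **dim** (default 300): embedding dimension. The synthetic benchmark uses
  64, plenty for a 2-D latent geometry.
* **window** (default 1): the equivalence above is exact only at $w = 1$;
  larger windows mix higher-order flux.
* **negatives** (default 5), **gamma** (default 1.0): number of noise
  draws and the noise exponent. $\gamma = 1$ is the theoretically special
  choice; 0.75 (the word2vec legacy value) is available.
* **alpha0** (default 0.025): initial learning rate, decayed linearly to
  `alpha0 / 1e4` over all scheduled pairs.  The floor is a package choice;
  only the starting value is conventional.
* **epochs** (default 5), **minCount** (default 50): passes over the
  corpus and the minimum token frequency $f_{min}$.
* **seed**: training is bit-reproducible from this seed.  Negatives are
  drawn i.i.d. from $P^\gamma$ (collisions with the true context allowed,
  the reference behavior); in-vectors start uniform in $(-0.5/d, 0.5/d)$,
  out-vectors at zero.  No frequent-token subsampling is applied — it
  would distort $P(i)$ and with it the gravity correspondence.

Per epoch, each trajectory is re-streamed with fresh *within-year
shuffling* (`epochTokenStream()`): stays sharing a year are permuted
uniformly, because simultaneous co-affiliations carry no meaningful
order.  Shuffling is applied before pair extraction, matching what
training sees.

Published embeddings are the in-vectors; `diagnoseInOut()` reports how
far the trained model is from the symmetric optimum.  In practice the two
families differ, and the in-vector *cosine* distance tends to be the most
useful dissimilarity, with the raw inner product second — `mobvec`
exposes cosine, inner-product (as an order-reversing dissimilarity) and
Euclidean metrics in `embeddingDistance()`.

## What the synthetic generator emulates

`sampleWorld()` + `expectedFlux()` + `sampleTrajectories()` build corpora
from a world where the gravity law holds *exactly*: locations uniform on
the unit square, masses log-normal (log-sd `massSigma`, heavy-tailed like
real location populations), and a chosen decay.  The default `"pairs"`
scheme draws length-2 trajectories with probability proportional to the
flux — exactly the first-order co-occurrence distribution that $w = 1$
training consumes; the `"walk"` scheme provides longer Markov
trajectories for realism experiments.

The registered study conditions for the benchmark (chosen once, as a
desk-scale setting a mobility modeler would call realistic):
**300 locations, `massSigma` = 1, exponential decay $\beta = 5$
(flux spans a few decades across the unit square), $2 \times 10^5$ pair
trajectories, training at d = 64, w = 1, k = 5, $\gamma$ = 1, 5 epochs,
minCount = 1** (synthetic tokens are all frequent; the $f_{min} = 50$
default is for real corpora).  `runSyntheticBenchmark()` runs the whole
pipeline and correlates embedding distances with the latent Euclidean
distances; under these conditions the cosine metric reaches roughly 0.88
and the inner-product metric roughly 0.75–0.79 across seeds (the
benchmark is stochastic).

What the generator does *not* emulate: asymmetric flows (the SGNS model
is symmetric by construction), multi-year structure, co-affiliation
bursts, and the heavy zero-inflation of real migration tables.  Passing
the synthetic benchmark shows the trainer recovers a latent gravity
geometry from realized flux; it does not certify performance on any real
corpus.

## Fitting and evaluating gravity models

`fitGravity()` follows the standard log-linear recipe: OLS of
$\ln(T_{ij}/(m_i m_j))$ on $-\ln g_{ij}$ (power) or $-d_{ij}$
(exponential) over unordered pairs with $T_{ij} > 0$.  Zero flows are
excluded, masses must be positive, and each unordered pair enters once.
Geographic distances are haversine on a sphere of radius 6371.0088 km
with a floor (1 km default; 0.01 km for intra-city corpora) so co-located
pairs do not blow up the power law.  `evaluateFit()` reports the log-log
$R^2$, the RMSE in $\log_{10}$ space (the axes flux plots are drawn in;
whether the original analyses used log or linear space is not decidable
from the figures, so the choice is configurable), and the common part of
commuters $\mathrm{CPC} = 2\sum\min(T,\hat T)/(\sum T + \sum \hat T)$.

One honest caveat, verified on the simulator: with sparse counts the
zero-flow exclusion *biases the fitted decay downward*, because far pairs
are kept only when a lucky count survives ($E[\ln T \mid T \ge 1]$
flattens where $E[T] < 1$).  At 200 locations the recovered $\beta$ is
~15% low at $2\times10^5$ trajectories, ~8% at $5\times10^5$, and ~4% at
$10^6$; the package's recovery test therefore runs at $5\times10^5$.
This is a property of the standard fitting recipe, not of the embedding.

## SemAxis and clustering comparisons

`makeAxis()` builds $V_{axis} = \bar V^+ - \bar V^-$ from pole token
sets; `projectOnAxis()` scores tokens by $\cos(v_a, V_{axis})$ — scores
are invariant to positive rescaling of either side, and rankings break
ties lexicographically so outputs are deterministic.
`matchedPoles()` constructs the bottom pole by scanning the ranking from
the worst token upward, filling the exact region quota of the top pole —
the construction that keeps a prestige axis from degenerating into a
geographic one.

`hclusterCosine()` clusters group centroids (unweighted member means,
with a minimum group size) by average linkage on $1 - \cos$; average
linkage is the conventional choice for similarity matrices and is the
package's (configurable) default.  Hierarchy levels are topological:
root 0, leaves 1, internal nodes at depth over the maximum root-to-leaf
depth; leaf singletons are pinned to level 1 even in unbalanced trees so
the level scale is comparable across dendrograms.

Element-centric similarity (`ecsScore()`, `rScan()`) compares a
dendrogram against flat partitions: affiliations are weighted by
$e^{r l_\beta}$, projected to a row-stochastic element graph

$$w_{ij} = \frac{1}{\sum_\kappa a_{i\kappa}} \sum_\gamma
  \frac{a_{i\gamma} a_{j\gamma}}{\sum_m a_{m\gamma}},$$

and compared through personalized-PageRank profiles,
$S_i = 1 - \tfrac12 \lVert p_i^A - p_i^B \rVert_1$.  Two published
formulas are typographically ambiguous; the package implements the
readings that make $W$ row-stochastic and $S_i \in [0,1]$ (the
alternative groupings produce a non-stochastic kernel and unbounded
scores).  The damping factor defaults to 0.9, the value conventional in
the element-centric similarity literature.  PPR systems are solved by a
dense direct solve — exact at the group-level sizes (tens to hundreds of
elements) the measure is used for.

## Numerical choices and degenerate inputs

* Conditional rows are computed with per-row max subtraction; implied
  flux in log space with a global shift — both overflow-safe.
* `impliedFlux()` normalizes the unordered-pair total to the corpus's
  window-pair count so entries are comparable to observed counts.
* Coincident latent locations are floored at $r = 10^{-9}$ under power
  decay; geographic floors are 1 km / 0.01 km as above.
* Zero-norm vectors are hard errors wherever cosine is involved, naming
  the offending tokens.
* A fitted decay that comes out non-increasing is clamped to a vanishing
  exponent with a warning rather than silently reported.
* Consecutive repeated tokens yield self pairs, tracked in `selfCounts`
  and excluded from both the flux matrix diagonal and gravity fits.

## Design decisions worth knowing

* **In-vector similarity needs shared contexts.**  On a degenerate corpus
  of two disjoint always-co-occurring pairs, the in-vector cosine between
  partners is *unidentified* at the SGNS optimum (their context
  distributions are disjoint), and the trained geometry systematically
  favors the implied-conditional separation instead.  The package's
  separation tests therefore assert $P_{NS}$ separation on that corpus
  and cosine separation on a two-community corpus where second-order
  structure exists.
* **Equivalence is measured against the generating flux.**  The affine
  relation between $\ln(T/(P_iP_j))$ and $v_j \cdot v_i$ is blurred by
  Poisson noise in the logarithm of small sampled counts; against the
  generating expected flux the correlation exceeds 0.85 at 200 locations,
  and the in-out dot form (what the trainer directly optimizes) tracks
  even raw counts at that level.
* **Problem sizes.**  Tests and the acceptance pipeline run at 200–300
  locations and $10^5$–$5\times10^5$ trajectories — sizes where every
  stage's statistical behavior is already visible and a full run takes
  well under a minute of training.

## Limitations

Flows are symmetric by construction; directional migration (radiation-style
asymmetry) is out of scope.  The embedding is only meaningful for discrete
location vocabularies, not continuous coordinates.  Results on corpora
whose vocabulary is large relative to the data volume are stochastic;
train with multiple seeds before interpreting fine structure.
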