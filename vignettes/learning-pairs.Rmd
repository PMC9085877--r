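---
title: "Learning pairs: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning pairs: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(learnpair)
```

## The learning-pair process

A *learning pair* holds two non-negative integer values $x_A$ and $x_B$ —
abstractly, the activation degrees of two functionally related factors,
e.g. the chromatin openness of two family genes. The pair repeats a
stochastic cycle:

1. **Increase.** With probability $\alpha_{inc}$ one branch is selected
   and incremented by 1. With probability $\gamma$ the selection is
   uniform (*additive increase*); otherwise it is *competitive
   amplification*: branch $A$ wins with probability
   $(x_A + \beta_A) / (x_A + \beta_A + x_B + \beta_B)$.
2. **Decrease.** Each unit of both branches independently dies with a
   probability proportional to the error
   $\varepsilon$ between the current and target fractions,
   $MSE = \left(\tfrac{x_A}{x_A + x_B} - \tfrac{T_A}{T_A + T_B}\right)^2$.
   In *scaled* mode the per-unit survival is $1 - \alpha_{dec}\,
   \varepsilon$ applied every repetition; in *gated* mode the pair
   enters decay with probability $\alpha_{dec}$ and then survival is
   $1 - \varepsilon$. Both give the same mean loss
   $x\,\alpha_{dec}\,\varepsilon$ per repetition, with larger variance
   in gated mode.

No individual per-factor rates are prescribed: the ratio $x_A : x_B$
approaches the target ratio because deviations raise the decay
probability and destabilise the current ratio, while competitive
amplification reproduces whatever ratio currently holds. The bias
$\beta$ is essential: with $\beta = 1$ a branch at 0 can still be
selected, whereas $\beta = 10^{-7}$ approximates pure competition, in
which a branch can be absorbed at 0 (the homeostatic regime).

Key defaults (changeable via `learning_params()`): $\alpha_{inc} =
\alpha_{dec} = 0.1$, $\beta = 1$, $\gamma = 0$, scaled decay, exact
error. These are the parameters of the study conditions the simulators
emulate, not fitted quantities.

## Error approximation

A cell cannot be expected to evaluate the error with full accuracy, so
the raw MSE can be reduced to an order-of-magnitude level
(`approx_error()`):

* **stepwise** — the mantissa is reduced to 1 and only the base-10
  exponent is kept, giving levels $10^{-1}, 10^{-2}, \dots$, capped
  above at $10^{-1}$; exact zero stays zero.
* **k-step** — the stepwise level clamped from below at $10^{-k}$, so
  only $k$ distinct decay probabilities exist.

Two numerical choices here are deliberate. First, "mantissa reduced to
1" is implemented as truncation, $\varepsilon = 10^{\lfloor \log_{10}
MSE \rfloor}$, so the approximated error never exceeds the raw error;
round-half-up is available via `rounding = "half_up"` since the
direction of rounding for mantissas ≥ 5 is a genuinely open choice.
Second, in k-step mode the lower clamp applies even when the MSE is
exactly zero, so decay — and hence turnover of contents — never ceases;
this is what lets a homeostatic pool keep renewing its transcripts while
maintaining its pattern.

A degenerate pair with $x_A + x_B = 0$ reads as current fraction $1/2$:
an empty pair carries no ratio information and $1/2$ is the symmetric
prior. A pair whose *target* sums to zero (possible with arbitrary
user profiles) is fixed at a 1:1 local target and excluded from
error-driven decay.

## Hierarchical pairs

A flat list of $n > 2$ factors sharing one competition and one error
fails to learn: the single scalar error cannot attribute blame. The
remedy is a full binary tree (`build_balanced_tree()`,
`history_to_tree()`) in which each of the $n - 1$ internal nodes is an
independently learning pair. Local targets are subtree sums of the leaf
profile (`set_targets()`), and a leaf's expression ratio is the product
of branch ratios along its root path (`leaf_ratios()`), which
telescopes to a probability vector. With this architecture, 64 factors
reach Pearson $r \approx 0.99$ against a linear target after $10^5$
repetitions per pair, and 4096 factors reach $r \gtrsim 0.97$
(`run_hierarchy()`; the acceptance script recomputes these).

Implementation notes:

* Pairs are indexed in preorder, so a parent's index is always smaller
  than its children's; path products and coverages are then single
  passes over the pair arrays.
* All pairs advance on a shared repetition clock inside one compiled
  loop drawing from one seeded R RNG stream. Independence is in the
  randomness, not the schedule; runs are bit-reproducible after
  `set.seed()`.
* The error is recomputed from the post-increase state within the same
  repetition; after decay it is refreshed lazily at the next
  repetition. At the default rates the stationary behaviour is
  insensitive to this ordering, but it is fixed so results are exactly
  reproducible.
* `alpha_inc_mode = "coverage_linear"` maps a pair's coverage (the
  product of branch ratios from the root down to it, computed from
  *current* values) to $\alpha_{inc} = \alpha_{min} + 0.1 \times
  \text{coverage}$, with $\alpha_{min} = 0.001$ by default (0.01 gives
  the alternative published range). Coverage is refreshed every 100
  repetitions by default; no refresh rule is prescribed by the model,
  and at these rates coverages move slowly.

## Architectures from expression data

`cluster_expression()` builds the pair architecture from a genes ×
cells matrix by greedy agglomeration, with the cluster representative
defined as the *sum* of member rows — pairing is a split of total
expression, so the sum is the faithful summary. Three linkage distances
are native to this package:

* **AreaSum** — the triangle area between the two representatives seen
  as vectors from the origin, $\tfrac12\sqrt{\|U\|^2\|V\|^2 -
  (U \cdot V)^2}$. Zero iff the vectors are parallel (constant
  expression ratio across cells). Vectors are deliberately *not*
  normalised: a large magnitude delays merging, letting highly
  expressed genes join near the root and skip many layers. The
  $\tfrac12$ factor is cosmetic (any constant rescaling leaves merge
  order unchanged) but documented for bit-exactness.
* **CvSum** — the coefficient of variation across cells of the summed
  vector $U + V$; zero for complementary, constant-sum family genes.
  Population (n-denominator) standard deviation by default, sample sd
  by option.
* **Cvarea** — the product of the two.

Ties among equal minimal distances are broken by the lexicographically
smallest cluster-id pair, making dendrograms deterministic. The three
baselines — Ward (Euclidean), WCO (cosine distance with WPGMA linkage)
and Single (Euclidean) — delegate to `stats::hclust()`; they exist for
comparison and no claim is made about their internals. The incremental
distance bookkeeping is tested against a from-scratch $O(n^3)$ re-scan
oracle for exact equality.

## The mRNA-pool model

`run_pool()` replaces the per-pair $\alpha_{inc}$ by a Monte-Carlo-like
tree descent: each repetition one entry pair among the top seven layers
is drawn with probability proportional to coverage, competitive
amplification descends from it to a single leaf gene (incrementing each
branch on the path; ancestors above the entry pair are untouched), and
a fixed-size mRNA pool (default 360,000) replaces one uniformly chosen
transcript with one of the selected gene. Removal precedes addition, so
the pool size is exactly conserved and the new transcript is always
present. Pairs decay in gated mode ("every 10 repetitions on average"),
each pair gated independently by default; a `decay_event = "global"`
switch gates all pairs at once, since the prose admits both readings.

The *expression probability* (identical to `leaf_ratios()`) responds
within $\sim 10^4$ repetitions, while the pool ratio follows slowly —
it must physically exchange transcripts — which reproduces the
two-time-scale behaviour of transcription probability versus mRNA
content. Internally the pool is a flat vector of gene ids, so each
replacement is O(1); per-gene counts are maintained alongside for
recording.

## Synthetic data

The generators (`synth_targets()`, `synth_paired_profiles()`) stand in
for expression-derived inputs:

* linear and shuffled-linear integer profiles for the benchmark runs;
* log-normal profiles, $\exp N(0, \sigma^2)$ with $\sigma = 1.5$ by
  default, giving the several-orders-of-magnitude spread typical of
  TPM-normalised single-cell profiles;
* correlated initial/target pairs built from shared plus independent
  log-scale components. The mixing weight inverts the exact
  linear-scale correlation of bivariate log-normals,
  $r = (e^{\rho\sigma^2} - 1)/(e^{\sigma^2} - 1)$, so the requested
  correlation is attained in expectation (sample correlations of
  heavy-tailed profiles remain noisy at moderate $n$).

What the synthetic inputs do *not* emulate: dropout and technical zeros
of real single-cell counts, gene–gene dependence beyond the single
shared component, batch structure, and any mapping of repetitions to
physical time. Tests passing on synthetic profiles show the learning
machinery behaves as designed; they do not validate any particular
gene pairing on real data.

## Problem sizes and tolerances in the shipped tests

The test suite exercises the study conditions directly: single pairs at
$10^5$–$2\times10^6$ repetitions, 64-factor hierarchies at $10^5$
repetitions with 10 replicate seeds, 4096-factor hierarchies at $10^5$
repetitions with 5 seeds, and 1024-leaf pool runs at $5\times10^5$
repetitions with 5 seeds. Stochastic reproduction checks assert that
the reported value lies within the replicate spread; analytic checks
(one-step transition laws, stationary means, conservation laws, oracle
equality) use goodness-of-fit at the $10^{-3}$ level, 5% relative
error, and exact equality respectively. Correlations are Pearson on
linear relative ratios (both sides normalised to sum 1); a log-space
option with a $10^{-6}$ offset exists for plotting-style comparisons.

## Known limitations

* Counts are simulated unit-by-unit; runtimes grow linearly in
  repetitions × pairs (compiled loops make the 4096-pair benchmark take
  tens of seconds per run on one core).
* No continuous-time (Gillespie) formulation, no delay between a
  ratio change and its feedback, no translation/protein layer, no cell
  division.
* The final-repetition correlation of a single run is a fluctuating
  quantity: a near-root pair mid-excursion can transiently depress it,
  which is why replicate summaries (`replicate_summary()`) rather than
  single runs should be reported.
* Architecture inference by clustering is a heuristic: shuffled
  pairings learn nearly as well when $\beta = 1$, so high final
  correlation does not certify that an inferred pairing is the true
  regulatory architecture.

```{r quick-demo, eval = FALSE}
# one learning pair approaching the 1:2 target
tr <- run_pair(c(1, 2), learning_params(), n_repeats = 1e5)
tail(tr, 2)

# 64 factors in a balanced hierarchy
tree <- set_targets(build_balanced_tree(64), 1:64)
run <- run_hierarchy(tree, learning_params(), n_repeats = 1e5)
tail(run$records, 1)  # Pearson r vs target
```
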