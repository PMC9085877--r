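# learnpair

Simulators and architecture-building tools for **learning-pair models**
of stochastic gene regulation.

## The problem

A cell keeps the expression of >10,000 genes at appropriate relative
levels in every context, yet no plausible mechanism tells each gene its
correct level individually. The learning-pair framework explores a
minimal answer: pairs of functionally related factors repeat two crude
stochastic processes —

* **competitive amplification**: branch *A* or *B* of a pair is selected
  at the (x_A + β):(x_B + β) ratio and incremented by one, with
  probability α_inc per repetition;
* **error-dependent decay**: every unit of x_A and x_B dies with
  probability α_dec·ε, where ε is (an order-of-magnitude approximation
  of) the mean squared error between the current and target fractions,
  MSE = (x_A/(x_A+x_B) − T_A/(T_A+T_B))².

Neither branch is told its target; an inappropriate ratio simply
destabilises itself. Repeating the cycle 10⁴–10⁵ times drives
x_A : x_B to the target ratio. Scaled to thousands of genes, the factors
are arranged in a full binary **hierarchical-pair architecture**: each of
the n − 1 internal nodes learns its local ratio independently, and a
gene's expression ratio is the product of branch ratios along its root
path. Decay restricted to as few as three or four discrete probability
levels (10⁻¹ … 10⁻ᵏ, the "k-step error") is already sufficient. An
**mRNA-pool** variant treats the tree as a signal-transduction cascade:
transcription events descend the tree by competitive amplification and
replace one transcript in a fixed-size pool.

The package is aimed at systems-biology modellers who want to simulate,
probe and extend these dynamics: every process probability, bias and
error mode is an explicit parameter, architectures can be built from
expression matrices with the package's sum-representative clustering
distances (AreaSum, CvSum, Cvarea), and all simulators are seeded and
bit-reproducible.

## Worked example

```r
library(learnpair)

# one learning pair, target ratio 1:2, exact MSE
set.seed(1)
tr <- run_pair(c(1, 2), learning_params(), n_repeats = 1e5)
tail(tr, 2)
#>     repeat_  x_A  x_B     ratio
#> 99    99000 1593 3279 0.4858188
#> 100  100000 1612 3338 0.4829239
```

The ratio x_A/x_B has settled near the target 0.5 without either branch
ever being told its level; the absolute counts are free to drift.

```r
# 64 factors, linear targets 1..64, balanced hierarchy of 63 pairs
set.seed(1)
tree <- set_targets(build_balanced_tree(64), 1:64)
run <- run_hierarchy(tree, learning_params(), n_repeats = 1e5)
tail(run$records, 1)
#>     repeat_         r
#> 100   1e+05 0.9944389
```

After 10⁵ repetitions per pair the Pearson correlation between the leaf
ratios and the 64 target weights is 0.99. Swapping
`learning_params(error_mode = "stepwise")` (or `"step:3"` …) degrades
this gracefully to ~0.95 (~0.88), showing that order-of-magnitude error
detection suffices.

```r
# build an architecture from an expression matrix instead
set.seed(1)
m <- matrix(rexp(12 * 5, rate = 1/10), nrow = 12,
            dimnames = list(paste0("g", 1:12), paste0("cell", 1:5)))
h <- cluster_expression(m, "AreaSum")
h
#> merge_history (AreaSum): 12 genes, 11 pairs, 4 layers
tree <- history_to_tree(h)   # ready for set_targets() / run_hierarchy()
```

The mRNA-pool variant (`run_pool()`) runs phase schedules — target
profile, bias β and error mode per phase — and records the correlation
of both the pool ratios and the expression probabilities against the
current target every 250 repeats.

A thin command-line wrapper ships in `exec/learnpair`
(`simulate-pair`, `simulate-flat`, `simulate-hierarchy`,
`build-architecture`, `simulate-pool`, `synth`) with example YAML
configs under `inst/configs/`; every run writes its outputs as CSV plus
a manifest sufficient to re-run it.

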