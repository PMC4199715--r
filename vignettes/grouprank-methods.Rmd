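---
title: "Methods: group-based network prioritization of disease genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group-based network prioritization of disease genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model implemented by `grouprank`, the
reasoning behind its defaults and numerical choices, what the synthetic
benchmark generator does and does not emulate, and the package's known
limitations.

## The model

The working assumption is biological: genes with a shared function or a
shared regulator tend to be co-expressed, and a gene that drives a disease
tends to sit near — in the protein-interaction sense — a whole module of
coordinately differentially expressed (DE) genes, rather than near one
loud gene. The score therefore has three multiplicative ingredients per
candidate/group pair and an additive integration across groups.

**Diffusion similarity.** Proximity on the network is measured by the
discrete heat-diffusion kernel on the random-walk matrix `W = D⁻¹A`:

$$ S = \left(I + \frac{\gamma}{N}(W - I)\right)^{N}, $$

the `N`-step discretization of `exp(γ(W − I))`. `S[i, j]` mixes all walks
of length up to `N` from `i` to `j`, so it is positive exactly when `j`
lies within `N` steps of `i`. When every node has positive degree each
row of `S` sums to 1 (an affine combination of row-stochastic matrices);
the unit tests check this invariant, the positivity/reachability
equivalence, and entry-wise agreement with naive repeated multiplication
and with the matrix exponential limit.

**Group similarity by geometric mean.** The similarity `s` between a
candidate and a group is the geometric mean of its kernel entries to all
members. The geometric mean is the load-bearing choice: a candidate must
be close to *every* member to score well, which is precisely the
robustness-to-single-loud-genes argument for grouping. An arithmetic mean
would let one strong neighbor dominate and collapse the method back
toward its single-gene baseline.

**Group expression level.** `e` is the geometric mean of the members'
`|log2 ratio(case/control)|`. Magnitudes are used because a coordinately
*down*-regulated module is as informative as an up-regulated one, and a
signed geometric mean is undefined for mixed signs; the majority
direction is retained as group metadata. (With log2-scale input — the
default assumption, typical of curated microarray matrices — the per-gene
ratio is the difference of class means; a `linear` flag switches to
`log2` of the ratio of linear-scale means.)

**Penalization.** Hubs are close to everything, and huge groups are close
to something by chance. Both biases are damped multiplicatively:

$$ R_G(c) = s \cdot e \cdot \min(1, \alpha/k) \cdot \min(1, \beta/n), $$

with candidate degree `k` and group size `n`. The caps are inactive for
ordinary genes (`k ≤ α`, `n ≤ β`) and scale contributions down
hyperbolically beyond; smaller `α`, `β` mean stricter penalization. A
smooth variant `exp(−k/α)·exp(−n/β)` is available via
`grouprank_params(penalty = "exp")` for sensitivity analysis. The
integrated score is the plain sum of `R_G` over groups, which keeps an
exact additive attribution of every candidate's score to groups (the
`contributions` matrix) for downstream interpretation.

## Tunable parameters

| parameter | default | units / range | why this default |
|---|---|---|---|
| `gamma` (γ) | 1 | diffusion rate, > 0 | one unit of heat over the full walk; with `n_iter = 5` the per-step rate γ/N = 0.2 keeps each step a proper mixture (non-negative kernel) |
| `n_iter` (N) | 5 | steps, ≥ 1 | the kernel converges quickly in N (tested against the matrix exponential); a few iterations suffice and keep `S > 0` local |
| `d` | 0.5 | correlation distance, [0, 1] | mid-grid default for a fixed-threshold run; `threshold_sweep()` optimizes it per data set on the 0.01 grid |
| `alpha` (α) | 15 | degree cap | lenient relative to the mean degree of curated human PPI networks (≈ 7), so only genuine hubs are damped |
| `beta` (β) | 20 | group-size cap | groups beyond ~20 genes start to behave like unspecific super-modules |
| `de_alpha` | 0.05 | corrected-p threshold | conventional family-wise level; strict inequality |
| `eps` | 1e-12 | floor on geometric-mean factors | see numerical choices |

## The synthetic benchmark

`make_instance()` generates the reference study condition used by the
test suite: a 200-node preferential-attachment network (mean degree ≈ 6,
heavy-tailed), 3 disease genes planted at mid-degree nodes (degree above
the median, at most 15, so they are neither periphery nor penalized
hubs), each with a disjoint module of 8 of its *direct neighbors*; module
genes share a per-module latent factor giving within-module pairwise
correlation ≈ 0.85 and receive a 2-SD class-mean shift (sign per module);
10 cases and 10 controls. Disease genes themselves get plain background
expression by default, which isolates exactly the signal the method
claims to exploit — proximity to a DE module, not own differential
expression (`de_disease_genes = TRUE` reverts this).

One master seed fans out to independent child seeds for the network, the
planting and the expression draw, so every stage is reproducible in
isolation and whole runs are byte-identical under a fixed seed.

What the generator deliberately does **not** emulate: probe-level
microarray noise, batch effects, heteroscedastic intensity-dependent
variance, correlated background co-expression, and the literature-biased
topology of real curated PPI networks. Passing the synthetic benchmark
therefore shows that the implementation recovers planted
proximity-to-module signal under idealized noise — not that the method's
biological assumption holds in any particular real data set.

At the reference condition, per-gene detection power is deliberately
partial: an effect of 2 SD with 10 + 10 samples sits near the Bonferroni
detection boundary for 200 genes, so typically only a fraction of each
planted module is recovered as DE — a realistic stress on the grouping
step rather than a saturated benchmark. Validation problem sizes: 50
replicates for recovery-rate and paired-comparison checks, 100 replicates
for the no-effect null calibration, 200 replicates for DE error-rate
calibration, 1000 (script) / 200 (test suite) resamples for the
random-group null.

## Numerical and protocol choices

* **Geometric-mean floor.** Factors are floored at `eps = 1e-12` before
  the log. A kernel entry of exactly 0 (member unreachable within `N`
  steps) therefore suppresses the group's score by many orders of
  magnitude instead of producing `log(0)`; singleton aggregation
  bypasses the `exp(mean(log(·)))` round trip entirely so the d = 0
  ranking reproduces the single-gene baseline bit for bit.
* **Kernel clipping.** Entries of `S` are clipped at 0 to remove
  floating-point dust; with the default per-step rate ≤ 1 the exact
  kernel is non-negative, so clipping never changes a true value.
* **Isolated nodes.** Degree-0 nodes keep an all-zero `W` row (no
  teleportation is invented); their only positive kernel entry is the
  self term `(1 − γ/N)^N`.
* **Ties.** Ranks use the average-rank convention, making rank ratios
  well defined and order-independent; a fully tied ranking has every
  rank ratio ≈ 0.5 and midrank AUC exactly 0.5, which is what the
  no-signal null should look like. Merge ties in clustering are made
  order-invariant by canonicalizing gene order lexicographically before
  `hclust`; sweep ties resolve to the smallest `d`.
* **Degenerate inputs.** Zero-variance genes: t-test p is set to 1 (with
  a warning) rather than propagating an undefined statistic, and
  correlation distance is set maximal. No DE genes: the grouping is
  empty, all candidates score 0, and evaluation correctly reports the
  uninformative MRR ≈ 0.5. A single DE gene forms one singleton group.
* **Distance mapping.** `d = (1 − r)/2` maps the full correlation range
  onto `[0, 1]`, so the documented 0–1 sweep covers all partitions and
  anti-correlated genes are maximally distant. The alternative
  `1 − |r|`, which groups anti-correlated genes together, is kept behind
  `distance_mode = "abs"` for users who consider negatively co-regulated
  genes one module.
* **Linkage.** Average linkage (UPGMA), the conventional choice for
  correlation-based expression clustering; cut heights then stay
  commensurate with pairwise distances, which makes the `[0, 1]` sweep
  grid meaningful.
* **Candidate universe.** All network nodes by default, known disease
  genes included: the method uses no training set, so known genes can be
  scored as ordinary candidates and the MRR is their mean normalized
  position. A user-supplied candidate file overrides.
* **Off-network genes.** The kernel exists only on network nodes, so DE
  genes outside the network are excluded before grouping and candidates
  outside it are reported unranked, in both cases visibly (log + side
  list) rather than silently.
* **Random-group null.** Resampled groups copy the observed group sizes,
  draw uniformly (without replacement within a group) from network nodes
  that carry expression data, and are mutually independent. The
  empirical p uses the add-one convention `(b + 1)/(m + 1)`, so p is
  never exactly 0.
* **Paired comparison.** The Wilcoxon signed-rank comparison of grouped
  vs single-gene rankings is paired on matched performance values —
  per-known-gene rank ratios within a data set, or per-instance MRRs
  across replicates; exact distribution up to 25 pairs, normal
  approximation with continuity correction beyond.

## Limitations

* The t-test assumes approximately normal, equal-variance (by default)
  log-scale expression; no normalization or batch correction is
  performed upstream.
* Groups are hard partitions; a gene belongs to exactly one module, with
  no overlapping or soft assignments.
* The score is only as good as the network: missing interactions make
  true disease genes unreachable from their modules, and the
  hub-degree cap only mitigates, not removes, study-bias toward
  well-annotated genes.
* Kernel computation is dense up to 20k nodes (sparse powers beyond), so
  memory grows quadratically with network size.
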