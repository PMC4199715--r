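# grouprank

Disease-gene prioritization in a protein–protein interaction (PPI) network
from differentially **co-expressed gene groups**.

## The problem and the method

Given a case/control expression study and a PPI network, which candidate
genes are most likely involved in the disease? Methods that score a
candidate by its network proximity to *individual* differentially
expressed (DE) genes are vulnerable to false positives: a single gene
with a dramatic expression change pulls up every one of its neighbors.
`grouprank` instead scores candidates against *groups* of coordinately
differentially expressed genes, on the premise that a strong disease gene
tends to sit close (in the network) to a whole co-expressed DE module.

The pipeline:

1. **Differential expression.** Per-gene two-sample Student t-test,
   Bonferroni correction; genes with corrected p < 0.05 are DE
   (`de_test()`).
2. **Co-expression grouping.** DE genes are clustered agglomeratively
   (average linkage) on the Pearson-correlation distance
   d(i,j) = (1 − r(i,j)) / 2 and the tree is cut at a threshold d ∈ [0, 1]
   (`correlation_distance()`, `cluster_groups()`).
3. **Diffusion kernel.** From the row-normalized random-walk matrix
   W = D⁻¹A the discrete heat-diffusion kernel

   S = (I + (γ/N)(W − I))ᴺ

   gives a smoothed similarity between every pair of network genes
   (`diffusion_kernel()`; defaults γ = 1, N = 5).
4. **Group scoring.** A candidate gene c with network degree k scores
   against a group G of size n with expression level e:

   R_G(c) = s · e · min(1, α/k) · min(1, β/n)

   where s is the geometric mean of the kernel similarities S[c, g] over
   members g ∈ G, e is the geometric mean of the members'
   |log2 ratio (case/control)|, and α = 15, β = 20 damp hub candidates and
   oversized groups. The integrated score is the sum of R_G over all
   groups, and candidates are ranked by it (`rank_candidates()`). The
   baseline `single_rank()` is the degenerate case where every DE gene is
   its own singleton group — identical to cutting the tree at d = 0.
5. **Evaluation.** A known disease gene at rank r among N_c candidates has
   rank ratio r/N_c; the mean rank ratio (MRR) over known genes is the
   primary metric (lower is better), complemented by midrank
   Mann–Whitney ROC/AUC, a 0.01-step sweep of the distance threshold, a
   size-matched random-group permutation null (1000 resamples), and a
   paired Wilcoxon comparison against the baseline
   (`mean_rank_ratio()`, `roc_auc()`, `threshold_sweep()`,
   `random_group_null()`, `compare_methods()`).

A seeded synthetic benchmark generator (`make_instance()`) builds
scale-free networks with planted disease genes whose direct neighbors form
coordinately DE, mutually correlated modules — so the whole method can be
validated end to end with known ground truth and no external data.

## Worked example

```r
library(grouprank)

inst <- make_instance(seed = 42)        # 200-gene network, 3 planted disease genes
cfg  <- grouprank_config(ppi = inst$network, expr = inst$expression,
                         known = inst$truth$disease_genes)
res  <- run_pipeline(cfg)
#> pipeline: 200 network nodes, 200 genes x 20 samples
#> pipeline: 10 DE genes at corrected p < 0.05 (0 off-network excluded)
#> pipeline: 1 group(s) at d = 0.5
#> pipeline: ranked 200 candidate(s); 0 off-network
#> pipeline: MRR = 0.2450, AUC = 0.7614 over 3 known gene(s)

head(res$ranking$ranking, 3)
#>   gene      score rank rank_ratio top_group top_contrib
#> 1 g079 0.05462039    1      0.005        G1           1
#> 2 g083 0.02823969    2      0.010        G1           1
#> 3 g082 0.02401836    3      0.015        G1           1
```

The top-ranked gene `g079` is one of the three planted disease genes
(`inst$truth$disease_genes` is `g079 g019 g024`): it is not itself
differentially expressed, but its direct neighbors form a co-expressed DE
module, which is exactly the signal the score rewards. The MRR of 0.245
says the planted genes sit, on average, in the top quarter of the 200
ranked candidates; sweeping the clustering threshold
(`threshold_sweep()`) improves this instance to MRR 0.195 at d = 0.05.

A thin command-line front end over the same functions is installed at
`inst/cli/grouprank.R`:

```sh
Rscript inst/cli/grouprank.R simulate --nodes 200 --seed 42 --out demo/
Rscript inst/cli/grouprank.R rank --ppi demo/edges.tsv --expr demo/expr.tsv \
    --labels demo/labels.tsv --distance 0.5 --out demo/ranking.tsv
```

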