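# fatedrivers

Identify the driver regulators of cell fate decisions along a single-cell
lineage, by combining attention-based gene regulatory network (GRN)
inference with network control theory.

## The problem

A differentiating cell lineage — ordered by pseudotime from progenitors to
a committed fate — is shaped by a regulatory program: a directed network of
regulator → target interactions among genes. Two questions matter to anyone
studying such a lineage:

1. **Which interactions from a global, context-free prior network are
   actually active in this lineage?** (GRN construction)
2. **Which genes steer the system between cell states?** (driver
   regulator identification)

`fatedrivers` answers both from two inputs: a prior gene-interaction
network (edge list) and a log-normalized cells × genes expression matrix
with a per-cell pseudotime for one lineage.

## The method

**Lineage GRN.** A two-layer graph-attention encoder runs over the prior
network in two directional channels per layer — an *in-coming* network
(genes attend to their regulators) and an *out-going* network (genes attend
to their targets) — with K = 4 heads per channel. The unnormalized
attention between genes i and j is

    e_ij = D_j · | cos( W_a h_i , W_b h_j ) |

the absolute cosine of learned projections of their expression profiles
(only the strength of regulation matters, not its sign), scaled by
D_j = sigmoid(c·l_j + d), a learned encoding of gene j's
differential-expression magnitude l_j along the lineage (mean |log2 fold
change| of each later pseudotime state versus the start state, Wilcoxon +
BH significance). Scores are softmax-normalized over each neighborhood with
temperature τ = 0.25. The encoder is trained unsupervised with a
contrastive mutual-information objective (deep graph infomax: real gene
embeddings versus feature-shuffled negatives against a global summary
vector). After training, attention coefficients are made globally
comparable by scaling with the central node's degree,

    β_ij = ( α_ij^in · indeg(j) + α_ij^out · outdeg(i) ) / 2,

layer-combined with μ = 0.5, and the top k_d·N edges (k_d = 8) form the
cell-lineage-specific GRN.

**Driver regulators.** Treating each cell fate as an attractor of the
nonlinear dynamics implied by the GRN, two network-control computations
give candidate driver genes: the **minimum feedback vertex set** (MFVS;
controlling all feedback loops plus all source nodes steers the system
between attractors) and the **minimum dominating set** (MDS; every gene is
a driver or directly regulated by one). Both are solved exactly via safe
graph reductions plus branch-and-bound. Candidates are ranked by an
attention-derived **influence score**

    S_i = λ·ln(1 + Σ_succ β^in_ij) + (1−λ)·ln(1 + Σ_pred β^out_ji),  λ = 0.8,

and the final driver regulators are the candidates inside the top-100
influence shortlist. Controllability metrics (1 − |drivers|/|genes|,
Jaccard index between the MFVS and MDS sets, candidate coverage) summarize
how controllable the lineage network is.

**Regulon-like gene modules.** Each driver's GRN successors (out-degree
type) and predecessors (in-degree type), filtered to significantly
differentially expressed genes (modules under 10 members are dropped) and
signed by expression correlation, are scored per cell with an AUCell-style
area under the recovery curve of module genes among the top 5% expressed
genes.

## Worked example

The package ships a fully synthetic study: a planted scale-free regulatory
program with 5 driver hubs wired into feedback loops, buried in a 4:1
decoy prior, with logistic driver programs along pseudotime.

```r
library(fatedrivers)

sc  <- make_scenario(seed = 1)          # 200 genes x 500 cells, 5 drivers
res <- run_pipeline(sc$prior, sc$expression,
                    run_config(seed = 1, repeats = 1, epochs = 150,
                               time_limit = 10))
print(res)
#> pipeline_result
#> lineage_grn: 200 genes, 1600 weighted edges (k_d = 8)
#> driver_report: 55 MFVS / 25 MDS candidates, 57 driver regulator(s)
#>   controllability: MFVS 0.725, MDS 0.875; Jaccard 0.231; coverage 0.877
#>   46 regulon-like module(s); activity matrix 500 x 46
sum(sc$drivers_truth %in% head(res$report$drivers, 20))
#> [1] 5                                  # all 5 planted drivers in the top 20
```

The GRN lands at the `k_d·N` edge budget (1600 edges over 200 genes); the
MDS needs far fewer genes than the MFVS on this cyclic, hub-rich network
(controllability scores 0.875 vs 0.725); and all five planted driver hubs
are recovered among the top-20 ranked driver regulators.

A deterministic 12-gene instance with hand-checkable control solutions
(MFVS size 2, MDS size 3) is available as `tiny_worked_example()`.

A thin command-line front end over the same functions is installed at
`inst/scripts/fatedrivers-cli.R`
(`simulate`, `grn`, `control`, `drivers`, `eval`, `run-all`).

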