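# metamir

Meta-path fusion graph embeddings for miRNA–disease association
prediction.

Most miRNA–disease links are still unverified, and screening candidate
pairs experimentally is slow and expensive. `metamir` prioritises
candidates computationally: it builds a heterogeneous network from
verified associations, miRNA functional similarity and disease semantic
similarity, enumerates all meta-path instances connecting its nodes,
and learns node embeddings in which associated miRNA–disease pairs sit
close together. Who it is for: computational biologists triaging
candidate miRNAs for a disease of interest, and method developers who
want a self-contained, fully testable reference implementation of
meta-path attention embeddings on bipartite biomedical data.

## The model

Let `A ∈ {0,1}^(m×n)` hold verified associations. Integrated
similarities combine curated sources with the Gaussian interaction
profile kernel `GM(r_i, r_j) = exp(−α‖IV(r_i) − IV(r_j)‖²)` (profiles
are rows/columns of `A`; `α` is 1 over the mean squared profile norm),
and disease DAGs yield Wang (decayed-contribution) and Xuan
(information-content) semantic similarities, averaged. Thresholded
similarities and the associations form an undirected network with
`M-D`, `M-M` and `D-D` edges.

Every simple path of length ≤ `max_length` (default 3) is a meta-path
instance. For a target node `u` with transformed features
`h_u = W·x_u`:

1. each instance `p` is mean-encoded: `h_u^p = mean of h_t over nodes
   t in p`;
2. instances of one type are fused by graph attention:
   `e_p = ReLU(att_P·[h_u ‖ h_u^p])`, softmax over the type's
   instances, `h_u^P = sigmoid(Σ e'_p h_u^p)`;
3. types are fused by a second attention:
   `w_P = softmax(ReLU(att_P·h_u^P))`, `h_u^ℙ = Σ w_P h_u^P`.

Training minimises the Manhattan-distance contrastive loss
`Σ_pos log σ(d(u,v)) − Σ_neg log σ(d(u,v))` by mini-batch gradient
descent with hand-derived analytic gradients (verified against finite
differences in the test suite). A pair's association score is
`−d(h_r^ℙ, h_d^ℙ)`.

## Worked example

```r
library(metamir)

syn <- generate_synthetic(synthetic_config(n_mirnas = 20, n_diseases = 14,
                                           seed = 42))
fit <- metamir(syn$A, fs = syn$fs, dags = syn$dags, embed_dim = 32,
               max_length = 2, epochs = 20, batch_size = 512,
               learning_rate = 0.02, seed = 1)
print(fit)
#> meta-path fusion graph embedding model
#> heterogeneous network: 20 miRNAs + 14 diseases; edges: 42 M-D, 90 M-M, 0 D-D
#> embedding dim 32, max meta-path length 2, attention on
#> 2664 meta-path instances; tracked loss -56.7351 (initial -45.0737)

rank_candidates(fit, "disease-003", top_k = 5)
#>   rank   mirna     disease     score
#> 1    1 mir-005 disease-003 -3.037216
#> 2    2 mir-007 disease-003 -3.050426
#> 3    3 mir-010 disease-003 -3.060132
#> 4    4 mir-009 disease-003 -3.070751
#> 5    5 mir-004 disease-003 -3.092800

run_cv(syn$A, fs = syn$fs, dags = syn$dags,
       scheme = cv_scheme("kfold", k = 5, seed = 1),
       embed_dim = 32, max_length = 2, epochs = 20, batch_size = 512,
       learning_rate = 0.02)
#> kfold cross-validation: AUC 0.6517 (5-fold, 1 repeat)
```

The tracked loss falls from −45.07 to −56.74: connected pairs are pulled
together and sampled negatives pushed apart. The top candidates for
`disease-003` are the same-block miRNAs not yet linked to it — exactly
the planted structure. The cross-validated AUC summarises how well
held-out verified pairs outrank all unverified pairs; on this small,
sparse example it is 0.65, and on the default-sized generator
(40 × 30) it reaches the design's information ceiling of ≈ 0.76 (see
the methods vignette for why 0.76 means *full* recovery of the planted
blocks, not mediocre performance).

For real data, `read_associations()`, `read_similarity()` and
`read_dags()` ingest HMDD-style pair lists, labelled similarity CSVs
and MeSH-like `child<TAB>parent` hierarchies; `inst/cli/metamir` wraps
the same pipeline as a command line (`synth`, `similarity`,
`build-net`, `paths`, `train`, `cv`, `predict`, `case-study`).

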