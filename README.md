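# poolparti

Transformer protein language models (PLMs) such as ESM2 or protBERT emit one
embedding per residue, but most sequence-level bioinformatics tasks — fold
retrieval, enzyme-class retrieval, interaction and localization prediction —
need a single fixed-length vector per protein. The common parameter-free
poolers (mean, max, sum, the CLS token) either dilute or discard the signal
carried by a handful of functionally critical residues, and learned pooling
layers tie the embedding to one downstream task.

`poolparti` implements **Pool PaRTI** (Pooling by PageRank Token Importance),
a parameter-free pooler that uses the PLM's own attention to decide which
residues matter:

1. Run a forward pass to obtain the token embedding matrix
   `E_tok ∈ R^(n×d)` and the attention matrices `A_(l,h) ∈ R^(n×n)` for
   every layer `l` and head `h`.
2. Collapse the stack by **pixelwise max pooling**:
   `M_att[i,j] = max_(l,h) A_(l,h)[i,j]`.
3. Treat `M_att` as the adjacency matrix of a **directed weighted graph**
   over tokens (edge i→j from query to key, weight `M_att[i,j]`).
4. Run **PageRank** (damping 0.85, ≤100 iterations, tolerance 1e-6) on the
   graph; the stationary distribution is the per-residue importance `α`.
5. Normalize `α` to sum to one and pool:
   `E_seq = Σ_i α_i · E_tok,i`.

Because `α` sums to one, the embedding scale is independent of sequence
length; because no parameters are trained, the same embedding serves any
downstream task. The package also ships the surrounding analyses:
top-percentile Jaccard agreement with an exact hypergeometric null and an
empirical same-length null, percentile-rank profiles of annotated (e.g.
catalytic) residues with a KS uniformity test, interface-overlap
classification at the top-15% threshold, cosine retrieval evaluation
(Precision@10% of class size, mean reciprocal rank, class-balanced sampling
rounds, Mann–Whitney comparisons), seeded synthetic fixtures, and
HDF5/TSV/FASTA/PDB interfaces (including streaming attention aggregation and
B-factor structure coloring).

## Worked example

Pool a synthetic planted-hub protein (50 residues, hubs at positions 12 and
30 whose attention-logit columns are boosted by 3):

```r
library(poolparti)

spec  <- fixture_spec(n_tokens = 50, hub_indices = c(12, 30),
                      hub_strength = 3, seed = 42)
stack <- gen_attention_stack(spec)          # 4 layers x 4 heads, row-stochastic
emb   <- token_embeddings(matrix(rnorm(50 * 8), 50, 8))

res <- pool_parti(stack, emb)
top_percentile_set(res$importance, k = 10)$indices
#> [1] 12 20 30 34 46
signif(res$importance$weights[12], 3)       # vs uniform 1/50 = 0.02
#> [1] 0.131
percentile_rank(res$importance, 30)
#> [1] 98
res$embedding$vector[1:4]
#> [1]  0.07148145 -0.09222642  0.02400353  0.23180924
```

Both planted hubs land in the top-10% importance set (residue 12 carries
6.5x the uniform weight), and the sequence embedding is their
importance-weighted average with the rest of the sequence. For comparison,
two random importance assignments of length 50 would share a top-10% set
with expected Jaccard `expected_jaccard_random(50, 10)` ≈ 0.058.

File-to-file runs use the `cmd_*` functions or the thin wrapper in
`inst/scripts/poolparti` (subcommands `pool`, `analyze`, `eval-retrieval`,
`synth`, `annotate-structure`).

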