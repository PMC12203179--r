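---
title: "Attention-graph PageRank pooling: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-graph PageRank pooling: model, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolparti)
```

## The model

An encoder protein language model maps a sequence of $n$ tokens to a token
embedding matrix $E_{tok} \in \mathbb{R}^{n \times d}$ and, for every layer
$l$ and head $h$, a row-stochastic attention matrix
$A_{l,h} \in \mathbb{R}^{n \times n}$ whose row $i$ distributes query $i$'s
attention over key positions. Pool PaRTI converts these frozen internals
into a sequence embedding in five deterministic steps:

1. **Special-token removal.** Rows/columns of non-residue tokens (CLS/BOS,
   SEP/EOS, padding) are dropped jointly from the attention matrices and the
   embedding matrix, so importance is defined over residues only.
2. **Pixelwise max pooling.** $M_{att}[i,j] = \max_{l,h} A_{l,h}[i,j]$. The
   maximum (rather than a mean) preserves the strongest pairwise
   relationship expressed anywhere in the model; intermediate layers are
   known to carry functionally relevant attention patterns, so no layer is
   privileged.
3. **Graph construction.** $M_{att}$ is read as the adjacency matrix of a
   directed weighted graph: edge $i \to j$ (query to key) with weight
   $M_{att}[i,j]$.
4. **PageRank.** The stationary distribution of a damped random surfer on
   that graph assigns each residue an importance $\alpha_i$; a residue is
   important when heavily attended by residues that are themselves
   important.
5. **Weighted pooling.** After renormalizing $\alpha$ to sum to one,
   $E_{seq} = \sum_i \alpha_i E_{tok,i}$.

The method trains nothing, so the embedding is task-agnostic, and since
$\sum_i \alpha_i = 1$ its scale does not grow with $n$ (sum pooling, by
contrast, grows linearly — asserted in the test suite on constant-row
fixtures).

The underlying assumption is that softmax attention concentrates on
residues that matter for the model's internal prediction task and that this
concentration correlates with biological importance. The package tests this
*mechanism* (hub tokens that receive planted extra attention are recovered
as top-importance residues); whether real PLM attention encodes biological
importance is an empirical question about the model, not about this
implementation.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `damping` | 0.85 | probability of following an attention edge rather than teleporting uniformly; the standard PageRank value, dimensionless |
| `max_iterations` | 100 | power-iteration cap |
| `tolerance` | 1e-6 | per-node L1 convergence tolerance; iteration stops when the total L1 change falls below `n * tolerance`, so the criterion has the same per-residue meaning at every sequence length |
| `on_nonconvergence` | `"fail"` | raise rather than silently return a drifting iterate; `"return-last"` is available with a warning |
| `head_average` | `FALSE` | average heads within a layer before max-pooling across layers |
| `drop_self_loops` | `FALSE` | remove the attention diagonal before graph construction |
| Jaccard cutoffs | 3, 10, 20 | top-percentile set sizes used in agreement analyses |
| interface threshold | 15 | top-percentile used in the TP/FN/FP/TN interface classification |
| retrieval depth | `ceiling(0.10 * class size)`, min 1 | neighbors retrieved per query |
| `n_rounds` | 50 | class-balanced sampling rounds |

## Design choices where the design was open

* **Heads.** Encoder PLMs emit $H$ attention matrices per layer. The
  default max-pools over all $L \cdot H$ matrices, treating every head as
  an independent witness of pairwise structure; `head_average = TRUE`
  averages heads within a layer first for sensitivity analyses.
* **Special tokens** are removed before graph construction and pooling.
  CLS/SEP columns often absorb large attention mass for reasons unrelated
  to residue identity; keeping them would siphon importance away from
  residues. The CLS embedding is still available as the `cls` baseline.
* **Self-loops** (the attention diagonal) are kept: PageRank handles them
  naturally and they encode genuine self-attention. A flag removes them.
* **Dangling nodes** cannot occur with softmax attention (rows are strictly
  positive) but synthetic or pre-pooled inputs may contain zero rows; their
  rank mass is redistributed uniformly, the standard random-surfer
  treatment.
* **Redundant normalization.** PageRank output already sums to one;
  the explicit renormalization step is kept as a cheap guard against
  accumulated floating-point error and makes the sum-to-one invariant
  (checked to 1e-9) unconditional.
* **Top-set size** is $m = \max(1, \lceil k n / 100 \rceil)$: the ceiling
  guarantees non-empty sets for short proteins; ties at the cutoff are
  broken toward the lower index so the set is deterministic.
* **Percentile ranks** use midrank tie handling: equal importances receive
  equal percentiles, avoiding order-dependent results; the top residue of a
  tie-free vector scores exactly 100.
* **Uniformity test.** The skew of annotated residues' percentile ranks is
  tested with the one-sample two-sided Kolmogorov–Smirnov test against
  uniform(0, 100] — the standard omnibus uniformity test. With midrank
  percentiles on tie-free vectors the ranks live on a uniform grid, which
  biases the KS statistic by at most $1/(2n')$; negligible at the lengths
  used.
* **Theoretical Jaccard null.** Under random importance assignment the two
  top-$k$ sets are independent uniform $m$-subsets of $n$, the overlap $X$
  is hypergeometric$(n, m, m)$, and
  $\mathbb{E}[J] = \sum_x P(X = x) \, x / (2m - x)$ exactly. This closed
  form is validated in the tests against exhaustive subset enumeration for
  all $n \le 12$ and against Monte-Carlo sampling at $n \in \{50, 100,
  500\}$.
* **Empirical null length matching** is exact by default; a `length_tol`
  fallback exists for sparse databases.
* **Retrieval semantics.** Metrics are computed *within* each sampled
  sub-corpus (that is what "class-balanced sampling rounds" balances), the
  query itself is never retrievable, cosine ties are broken by ascending
  protein id, and reported uncertainty is the standard error across rounds.
  The per-round per-class sample size is a required parameter; analyses in
  this package use 10 per class, large enough for a non-trivial retrieval
  depth ($r = 1$ at class size 10) while leaving real sampling variance
  across rounds.
* **Mann–Whitney comparisons** use the exact distribution when both samples
  have at most 8 tie-free values and the tie-corrected normal approximation
  otherwise.

## The synthetic generator

`gen_attention_stack()` draws i.i.d. standard-normal attention logits,
boosts the columns of designated *hub* tokens by `hub_strength` (in softmax
logit units; the default 3 multiplies a hub's pre-normalization attention
by $e^3 \approx 20$), and maps each row through softmax. Hubs are planted on
key columns because the graph's edges run query→key: a token everyone
attends to should become important. `gen_labeled_corpus()` additionally
gives each protein class a fixed signal direction (norm `signal_norm = 5`)
carried only by that protein's hub rows on top of unit-variance Gaussian
noise, with 5 classes × 20 proteins, 100 tokens, 3 hubs, and 4 × 4
attention stacks as the default study condition. `gen_importance_db()`
yields normalized uniform random importance vectors for null analyses. All
generators are pure functions of their spec (identical spec ⇒ identical
bytes).

What the fixtures emulate: row-stochastic multi-layer multi-head attention,
attention concentration on a few positions, class signal carried by the
attended positions. What they do not emulate: realistic contact topology,
position-dependent attention structure (locality, CLS sinks), correlated
heads, or realistic embedding geometry. Passing tests therefore demonstrate
that the pipeline recovers planted attention structure and that its
statistics are correct — not that any particular PLM's attention is
biologically meaningful.

The embedding dimension of the corpus fixture is 32: large enough that
random noise directions are nearly orthogonal to the class signal, small
enough to keep the suite fast. Fixture sizes throughout (50–100 tokens,
4 × 4 stacks, 100-protein corpora, 50 rounds) were chosen as the smallest
instances that still exercise multi-layer pooling and give stable
statistics.

## Numerical choices

* All computation is in double precision; the HDF5 exchange format stores
  floats as 32-bit for storage economy, so values round-trip at single
  precision while every derived quantity is computed in doubles.
* The PageRank iterate starts uniform and nothing in the core pipeline uses
  randomness, so results are bit-reproducible; repeated `cmd_pool` runs
  produce byte-identical TSVs.
* Degenerate inputs fail loudly: empty stacks, all-special masks, all-zero
  importance vectors, singleton classes, and non-convergence under the
  `"fail"` policy all raise informative errors.

## Interfaces

Tensor input uses an HDF5 layout (one group per protein: `embeddings`,
`attention` or `attention_pooled`, `special_mask`, plus `sequence`/`model`/
`prepooled` attributes) written and read with `rhdf5`;
`streaming_max_pool()` aggregates attention one (layer, head) slice at a
time so full stacks for long sequences never need to be resident.
Sequence embeddings and per-residue importance are emitted as plain TSV
(1-based positions, stated in each file header) — text outputs keep runs
byte-reproducible and diffable, and retrieval evaluation reads these TSVs
plus a labels TSV. Structure coloring writes `100 * importance` into the
PDB B-factor column via `bio3d`, matching by residue number and reporting
unmatched residues, since deposited structures usually resolve only part of
the sequence.

## Limitations

* The package does not run PLM inference; it consumes tensors produced
  elsewhere (or its own synthetic fixtures). An adapter driving a real
  model belongs outside the core and its tests.
* The hypergeometric null models *random* importance assignment; it is not
  a model of the correlation structure of real attention.
* Retrieval evaluation assumes the corpus fits in memory as a dense matrix.
* Percentile analyses assume the annotation coordinates refer to the same
  full-length sequence the importance was computed on; no alignment is
  attempted beyond residue numbering.
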