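---
title: "Imputing incomplete phylogenetic distance matrices"
author: "distimpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing incomplete phylogenetic distance matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distimpute)
```

## The problem

Distance methods build a phylogeny from the matrix of pairwise
evolutionary distances among `N` taxa.  The matrix is symmetric with a
zero diagonal, so it carries `N(N-1)/2` informative values — and in
multi-gene datasets some of them are routinely *undefined*.  The cleanest
mechanism is gene-level: if taxon A was sequenced only for gene 1 and
taxon B only for gene 2, the pair (A, B) shares no homologous sites and no
distance can be estimated.  Deleting gene 1 from `n1` taxa and gene 2 from
a disjoint `n2` taxa therefore produces exactly `n1 × n2` missing matrix
entries; distances can also go missing one pair at a time through
alignment problems or saturation.  Neighbor joining and its relatives
refuse incomplete input, so the missing entries must either be worked
around or imputed.  This package imputes them, with two methods that make
no rate-constancy (molecular clock) assumption and keep working even when
more than half of the entries are gone.

Throughout, the central type is the *masked distance matrix*: taxon
labels, a symmetric value matrix, and a symmetric boolean mask marking the
missing pairs.  The diagonal is never missing.  The on-disk format is a
relaxed square PHYLIP dialect — a count line, then `label v1 ... vN` rows —
with an explicit `NA` marker for missing cells and full-precision values;
this dialect is this package's own contract, chosen because distance-file
conventions for *masked* matrices vary by tool and none is standard.

## Matrix factorization

The missing-distance problem is formally the matrix-completion problem of
recommender systems: distances, like ratings, are generated by a modest
number of latent features (here, positions in the underlying tree).  We
approximate `R ≈ X Yᵀ` with `X, Y` both `N × K` and fit only the observed
entries.  Because `R` is symmetric, training visits the observed
*lower-triangular* entries; a full pass in fixed row-major order is one
epoch.  For the visited entry `(i, j)` with residual
`e = r_ij − x_i · y_j`, both latent rows move simultaneously from their
pre-update values:

$$x_{ik} \leftarrow x_{ik} + \alpha\,(2 e y_{jk} - \beta x_{ik}), \qquad
  y_{jk} \leftarrow y_{jk} + \alpha\,(2 e x_{ik} - \beta y_{jk}).$$

This is exact stochastic gradient descent on the per-entry objective
$(r_{ij} - x_i\cdot y_j)^2 + \tfrac{\beta}{2}(\lVert x_i\rVert^2 +
\lVert y_j\rVert^2)$ — the regularized squared error whose gradient
reproduces the update rules above; the test suite verifies the direction
against central finite differences to $10^{-6}$ relative error.

Parameters and defaults:

| parameter | default | meaning |
|---|---|---|
| `K` | `N` | latent dimension; `K = N` makes the model full-rank, able to interpolate any complete matrix |
| `alpha` | 0.002 | SGD learning rate (per entry visit) |
| `beta` | 0.02 | L2 shrinkage, guards against overfitting the few observed entries |
| `max_iter` | 10,000 | maximum epochs |
| `tol` | 1e-6 | stop when the per-epoch total squared error `E` drops below this |
| `seed` | — | drives the Uniform[0, 1) initialization of `X`, `Y` |

Interpretation choices that the update rules force or determinism
requires: `E` is the *sum of squared* residuals over observed
lower-triangular entries, accumulated during the epoch (signed residuals
could cancel); entries are visited in fixed row-major order rather than
shuffled, so a seed fully determines the fit; predictions are clamped at
zero because distances are non-negative; observed entries are copied
verbatim into the output, never replaced by their reconstruction.  An `E`
exceeding $10^{12}$ (possible with a learning rate too large for the
matrix's scale) aborts with a divergence error rather than returning
garbage.  The inner loop is compiled (Rcpp): one epoch is
`O(#observed × K)`, and the default configuration on a 20-taxon matrix
trains in a few seconds.

## Autoencoder

The second method treats each *row* of the matrix as a sample: taxon i's
distance profile to everyone else.  An undercomplete autoencoder — input
width `N`, three hidden ReLU layers of widths `N`, `⌈N/2⌉`, `N`, sigmoid
output — is trained to reproduce its input through a bottleneck,
forcing it to learn the salient structure of the profiles rather than the
identity map; dropout at rate 0.75 on the hidden activations constrains
capacity further (the expected active width of every hidden layer is at
most `N/2`).  No explicit weight regularization is used.

Because the output activation is a sigmoid, distances are first scaled by
`1.05 × max(observed)` so observed values lie in `[0, 1/1.05]`, safely
inside the sigmoid's range.  The loss is masked, and a sum rather than a
mean (the stopping threshold is interpreted against this sum):

$$L(R, R') = \sum_{i \in \mathcal{NM}} |R_i - R'_i|^2$$

over the non-missing cells $\mathcal{NM}$ (diagonal zeros are observed
cells and participate).  Missing cells are initialized with seeded uniform
draws from the observed range, and each iteration performs one full-batch
Adam step (step size $10^{-3}$) with dropout active, then blends the
*deterministic* (no-dropout) predictions `p` into the missing cells:

$$x' = (1 - w)\,x + w\,p, \qquad w = 0.5 \text{ by default}.$$

The recorded loss trace uses the deterministic forward pass, so it is
reproducible; training stops below `tol` ($10^{-6}$) or at `max_iter`
(10,000).  The network's output is not exactly symmetric, so imputed
cells are symmetrized by averaging $(i,j)$ and $(j,i)$; observed cells are
restored verbatim after unscaling, making the imputer bit-exact on
observed data.  All stochasticity — weight initialization (Glorot
uniform), the random fill, and every dropout mask — derives from one seed.

Design points that were genuinely open and how they were resolved: the
row-as-sample representation (matches the vector-in/vector-out shape of
the architecture; the natural alternative, whole-matrix flattening, scales
poorly); hidden widths `(N, ⌈N/2⌉, N)` (only the count of hidden layers is
canonical; the bottleneck makes the network undercomplete); full-batch
rather than minibatch steps (at `N ≤` a few hundred rows there is nothing
to gain from minibatching, and determinism is simpler); and blending with
deterministic predictions only (blending dropout-noised outputs would make
the imputed values depend on the dropout draw of the final iteration).

## Distances from sequences

Both estimators use pairwise deletion: for each pair, alignment columns
where either sequence has a gap, `?`, or an ambiguity code are dropped.
A distance that cannot be computed is *missing*, a value, not an error —
that is precisely the input the imputers exist for.

* **TN93** implements the closed-form Tamura–Nei (1993) estimator, which
  distinguishes the two transition classes (A↔G, C↔T) from transversions.
  Base frequencies are pooled across both sequences of the pair over
  their shared sites — pooling keeps the estimator exactly symmetric in
  its arguments.  The estimate is missing at saturation (a logarithm
  argument ≤ 0) or when a required frequency product vanishes.  Note this
  is the moment estimator, not MEGA's composite-likelihood variant of the
  same model: the closed form is deterministic and desk-verifiable, and on
  simulated data the two agree in expectation.
* **LogDet** builds the `K × K` divergence matrix `F` of site-pattern
  proportions and returns `−ln det F` (no additional normalization), for
  nucleotide (`K = 4`) or amino-acid (`K = 20`) data; missing when `F` is
  singular.  Its identity-pattern value for uniform composition,
  `ln 256 ≈ 5.5452`, is one of the package's analytic anchors.

The minimum number of shared sites to call a distance defaults to 1 and is
configurable; tiny negative estimates from sampling noise near zero
divergence are clamped to 0.

## Trees and evaluation

Trees are built with neighbor joining (the standard Q-criterion
agglomeration, via ape) and compared by the normalized Robinson–Foulds
rate: the symmetric difference of the two trees' non-trivial bipartition
sets divided by its maximum, `|B1| + |B2|` — equal to `2(n − 3)` for two
binary trees, and well-defined for multifurcating ones too.  Bipartitions
are canonicalized as the lexicographically smaller side.  The test suite
checks the RF implementation against a brute-force
delete-an-edge-and-flood-fill oracle on all 15 five-leaf topologies and
against phangorn's implementation on random trees.  Note that minimum
evolution tree builders (for example FastME) can be substituted for NJ by
exporting the imputed matrix with `write_dist_matrix()`; the evaluation
machinery is builder-agnostic.  NJ was chosen as the built-in because it
is deterministic, dependency-light, and provably consistent on additive
matrices — which the test suite exercises directly.

## Synthetic data

The generators make every claim testable without external data:

* `random_tree()` draws a binary topology by sequential random leaf
  attachment (uniform over the three quartet topologies at `n = 4`,
  verified by a multinomial test) with i.i.d. uniform branch lengths,
  default `[0.05, 0.5]` substitutions/site — the range that puts pairwise
  distances in the regime distance methods are typically applied to.
* `perturbed_matrix()` multiplies each additive distance by
  `1 + Normal(0, σ²)` noise (redrawn to stay positive), emulating the
  estimation error of real matrices; `σ = 0` is the exact additive case.
* `simulate_alignment()` evolves i.i.d. sites down the tree under HKY85
  (Jukes–Cantor as the `κ = 1`, uniform-frequency special case), with the
  transition matrix computed exactly by spectral decomposition of the
  explicit rate matrix, normalized to one expected substitution per unit
  branch length.  Output is organized as named gene blocks (default two
  genes) so the indirect missingness mechanism applies directly; per-gene
  lengths of several hundred to a few thousand sites mirror typical
  mitochondrial multi-gene datasets.

What the generators deliberately do *not* emulate: incomplete lineage
sorting and gene-tree discordance (all genes share one tree; noisy
matrices stand in for discordance), indels and alignment error, and
among-site rate variation.  Passing benchmarks on these fixtures
demonstrates correctness of the machinery and recovery under additive and
mildly noisy conditions — not performance on discordant multi-locus data.

## Benchmark pipeline and problem sizes

`run_pipeline()` chains generation → masking → imputation → NJ → RF for
`r` replicates, with per-replicate seeds derived from one master seed by
fixed offsets and recorded in the report, and summarizes each method by
mean RF rate ± standard error (`sd/√r`).  The reference tree is the model
tree for synthetic data and the complete-data NJ tree otherwise.  A
failing replicate is logged and skipped, never silently dropped.

The shipped benchmarks run at sizes a laptop handles in minutes: 20-taxon
matrices with 5–10% of pairs deleted and ten replicates for the recovery
and loss-trend checks, and 37- and 201-taxon alignments for the indirect
missingness counts.  The methods themselves scale further (the MF epoch is
compiled; the AE trains on `N`-row batches), with the caveat that MF's
default `K = N` makes its cost per epoch quadratic in `N`.

## Known limitations

* TN93 here is the closed-form estimator; datasets produced with
  composite-likelihood TN93 distances will differ slightly in the inputs,
  though not in the imputation machinery.
* With `K = N` and small `m`, MF can fit the observed entries essentially
  exactly; its regularization, not rank, is what controls generalization.
  Very sparse matrices (most entries missing) push both methods toward
  their priors — imputed values remain in the observed range but carry
  little phylogenetic signal, mirroring the degradation any method shows
  there.
* The AE loss threshold `1e-6` is rarely reached on real-scale inputs
  within the default iteration budget; the iteration cap is the effective
  stopping rule, as the loss is a sum over up to `N²` cells.
* `rf_rate()` treats trees as unrooted and label-matched; no attempt is
  made to reconcile differing leaf sets.
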