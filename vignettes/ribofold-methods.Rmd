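---
title: "ribofold: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribofold: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ribofold is a desk-scale toolkit for coarse-grained RNA tertiary structure
prediction and assessment. Each nucleotide is reduced to three atoms — the
backbone phosphorus (P), the sugar C4' and the glycosidic nitrogen of the
base (N9 for purines, N1 for pyrimidines) — and represented by a rigid frame
(a rotation plus a translation) that maps an idealized local atom template
into global coordinates. This vignette explains the statistical models, the
losses, the numerical choices and the limits of what the package's synthetic
experiments can show.

## The composite-likelihood language model

A masked RNA language model observes a sequence with a subset `M` of
positions replaced by a dedicated mask symbol and is trained to reconstruct
them. The conventional (pseudo-likelihood) objective assumes masked tokens
are conditionally independent and maximizes `prod_{i in M} P(X_i = x_i)`.
Base-paired nucleotides violate that assumption strongly, so ribofold also
models ordered pairs: the training objective is the negative
log-composite-likelihood

```
L = - sum_{i in M} log P(X_i = x_i)
    - sum_{(i,j): i != j, i in M or j in M} log P(X_i = x_i, X_j = x_j)
```

with a 4-class nucleotide head and a 16-class ordered-pair head
(`class = 4 (a - 1) + b` for states `X_i = a`, `X_j = b`; the ordered
convention means `(x_i, x_j)` and `(x_j, x_i)` fall in different, related
classes). `composite_loss()` reports exactly this sum. Pairs with both
positions unmasked are excluded, following the index condition of the
objective. Probabilities are floored at `1e-9` before logarithms, so the
loss is always finite.

Two details are deliberate choices rather than givens:

* **Masking.** The default mask fraction is 0.15 and masked positions are
  replaced by a 5th one-hot channel. Both are standard masked-LM practice;
  the underlying model family prescribes the one-hot encoding but not the
  rate or the replacement scheme.
* **Term weighting during training.** Each masked token contributes one row
  to the first sum but about `2(L-1)` rows to the second, so an unweighted
  sum lets the pair term dominate the gradient. `train_clm()` therefore
  weights the pair cross-entropy by `1/(2(L-1))` by default
  (`clm_config(pair_weight = ...)` overrides this; `pair_weight = 1`
  restores the plain sum). The *reported* objective, `composite_loss()`,
  is always the unweighted sum.

### Architecture

The trunk is a stack of RNA transformer blocks over a sequence
representation `s` (`L x d_s`) and a pair representation `z`
(`L x L x d_z`). The embedder maps one-hot input through a linear layer and
forms the initial pair representation by broadcasting two independent
projections of `s` along rows and columns (`z[i, j] = rowproj(i) +
colproj(j)`); it is position-free, which `embed_sequence()` exposes
directly. Positional information enters at the entry of the block stack:
a learned relative-offset table (clipped at ±64) added to `z`, plus a
learned absolute positional table added to `s`. The absolute table is a
deliberate addition: a purely relative-position model is translation
invariant and cannot represent the column-specific couplings of a single
sequence family with fixed planted pair columns, which is precisely what
the synthetic recovery experiments probe.

Each block applies, in order: multi-head attention over `s` whose logits
receive a per-head linear projection of the (LayerNormed) pair
representation as a bias; a two-layer ReLU transition on `s`; an
outer-product-mean update injecting sequence content into `z`; and a set of
pair sub-modules — triangle multiplications (outgoing and incoming, gated
on output) and a pair transition — which read one shared LayerNormed view
of `z` and add their updates in parallel. The language-model variant omits
the two triangle-attention sub-modules; the folding stack keeps them.
Sharing a single pair LayerNorm per block and gating only the output are
desk-scale simplifications of the reference two-representation
architecture, chosen to keep a pure-R training step affordable; the
sub-module inventory and the information flow are unchanged.

Desk-scale defaults are 2 blocks with `d_s = 32`, `d_z = 16`, two attention
heads and an outer-product bottleneck of 8 channels (`clm_config()`), about
2 x 10^5 parameters; the full-scale configuration (18 blocks, 512/128) is
expressible through the same config but is not a test target. Training uses
Adam at `1e-3` with mini-batches of 4 and crops sequences beyond 256
positions to random contiguous windows.

All training runs on a small reverse-mode autodiff tape written for this
package (`R/tape.R`): coarse-grained ops (attention, triangle updates,
outer products, the gFAPE kernel) carry hand-derived backward rules and are
checked against central finite differences in the test suite.

## Contact extraction with the categorical Jacobian

Given any function `f` mapping a complete sequence to an `L x 4`
position-wise distribution, the categorical Jacobian measures how the
prediction at `j` reacts to a point mutation at `i`:

```
J[i, a, j, b] = f(X with x_i -> a)[j, b] - f(X)[j, b]
```

computed from `4L + 1` forward passes (the identity mutation `a = x_i` is
served from the cached base evaluation, since it reproduces the input
exactly). The coupling tensor is collapsed by the Frobenius norm of each
4 x 4 block, `M[i, j] = sqrt(sum_ab J^2)`, and the average product
correction `C = M - rowsum colsum / total` removes the background
component; APC annihilates any rank-1 contribution exactly. Ranking
symmetrizes `C` as `(C + C')/2` and excludes `|i - j| < 4`; both are
recorded in the map's metadata and configurable, since neither convention
is pinned down by the method itself. Mutant passes always use mask-free
inputs. The same pipeline accepts the marginalized pair head
(`marginalize_pair()` composed with the 16-class head) as the scoring
model, the marginal-pair evaluation path.

## Rigid frames, denoising and the folding losses

Frames are fitted to observed atom triples by least squares through
symmetric (Löwdin) orthogonalization, `R = M (M'M)^(-1/2)`, which the test
suite cross-checks against the SVD construction `U diag(1,1,det) V'`.
The local template is a packaged synthetic three-atom geometry generated
parametrically from standard A-form helix dimensions (file
`inst/extdata/template_aform_synthetic.tsv` documents its provenance); it
is shared across the four nucleotide types and configurable everywhere.

The denoising structure module iterates pair-biased attention over the
sequence representation and predicts per-nucleotide quaternion/translation
updates that left-compose onto the current frames, starting from the
black-hole initialization (identity rotations, zero translations).
Quaternion parameterization keeps every intermediate rotation exact;
outputs are re-orthogonalized once more on exit. During training the
initialization is perturbed — rotations slerped toward uniform random
rotations with weight 0.1, translations jittered with 0.1 Å Gaussian noise
— so the module learns to map a neighborhood of initializations to the
target rather than a single point. The update head is deliberately lean:
it reads the pair bias but carries no invariant-point terms, and the
iterations share weights; head counts, widths and iteration counts are all
config-driven.

Training minimizes

```
Loss_total = Loss_structure + 0.2 Loss_dist
Loss_structure = gFAPE(T, T_exp, lambda, dcut) - 0.1 gFAPE(T, T_0, 1, 2)
```

where the generalized frame-aligned point error sums, over all ordered
nucleotide pairs (including `i = j`) and the three template atoms, the
clamped deviation `lambda_ij min(dcut_ij, sqrt(||T_i^-1 T_j(r) -
T_i^exp-1 T_j^exp(r)||^2 + eps))` with `eps = 1e-3`. Pairs closer than
20 Å in the reference (C4'–C4' distance; the atom for this rule is a
documented choice) get `lambda = 3` and no clamp, all others `lambda = 1`
and a 30 Å clamp; a distance of exactly 20 Å falls in the far branch. The
inner norm is applied per atom, terms are summed (not averaged), and the
subtracted black-hole term (clamped at 2 Å) pushes predictions away from
the degenerate all-at-origin start. The identity floor
`sum(lambda) * 3 * sqrt(eps)` and rigid-motion invariance are asserted in
the tests.

Distances are supervised over 40 bins: 38 one-Ångström bins spanning
2–40 Å plus two open bins below 2 and at/above 40, over three atom-pair
channels (P–P, C4'–C4', N–N). The distance loss is implemented as a
cross-entropy (negative log-likelihood of the observed bin); written
without the sign it would be degenerate to minimize. The overfit
experiment in the test suite uses a 12-nucleotide hairpin, 500 Adam steps
at `3e-3` with the rate decayed linearly to 10% — the decay damps the
gradient noise injected by attention dropout and the denoising
perturbations, without which the loss plateaus above the 10% criterion.

## Consensus selection and optimization

Inference-time post-processing consumes a decoy pool: `N` candidate
conformations, each with a predicted distogram and a per-pair error-weight
map (uniform weights are substituted when a decoy carries none, and the
weight map enters the frame energy as the per-pair `lambda`). The global
energy is

```
E_global = E_e2e + E_dist
E_e2e  = sum_n gFAPE(T_conf, T_n, w_n, inf)
E_dist = - sum_n sum_{i != j} sum_channels
           log((P_n(bin(d_ij)) + 0.001) / (P_n(g_M) + 0.001))
```

with `g_M` the last closed bin below 40 Å. The distance term is a
reference-state log-ratio potential; the leading negative sign is
essential — without it, selecting the lowest `E_global` would favor
conformations that *avoid* the predicted distance bins. Pairs are summed
over both orders, the diagonal excluded.

The protocol (`csor_pipeline()`): for targets beyond 150 nucleotides,
decoys whose detected base-pair count falls below 90% of the pool maximum
are removed; every decoy is scored against the (filtered) pool and the five
lowest-energy decoys form the optimization consensus; the best decoy, and
every center from a greedy RMSD clustering of the pool, is refined by
L-BFGS over per-nucleotide quaternion + translation parameters; the
refined conformations are ranked by their final optimization energy, so
model 1 always has the lowest. Up to five models are emitted, and a
full-atom refinement hook (identity by default) is applied to each.

Numerical choices worth knowing:

* The binned `E_dist` is piecewise constant in the coordinates, so the
  optimizer uses a piecewise-linear interpolation of the per-bin scores
  across bin centers; reported energies use the exact binned form.
* The scored conformation's atoms are represented by the *starting
  structure's own* per-nucleotide local coordinates, and final models move
  the starting decoy's atoms by the per-nucleotide frame deltas. Using the
  shared template instead would add its projection error (about 1 Å on the
  toy structures) both to the optimum and to the emitted coordinates.
* L-BFGS runs in restarted chunks with the best value kept, which makes
  the recorded energy history non-increasing by construction and
  guarantees the returned energy never exceeds the starting one.
* Clustering is a greedy neighbor-count scheme: repeatedly take the decoy
  with the most neighbors within the cutoff as a center and remove its
  cluster. The cutoff adapts over {2, 4, 6, 8} Å until the top cluster
  holds at least 30% of the pool. This reproduces the *shape* of standard
  decoy-clustering protocols without their full schedule.
* Whether `E_dist` sums ordered or unordered pairs, and whether cluster
  centers are re-scored against the full or filtered pool, are not pinned
  down by the protocol description; ribofold sums both orders and scores
  against the filtered pool.

## Assessment metrics

`tm_score()` implements the length-normalized template-modeling score on P
atoms with the published RNA distance scale `d0 = 0.6 sqrt(L - 0.5) - 2.5`
(clamped below at 0.5 Å), seeding superpositions from contiguous fragments
of lengths `L`, `L/2`, `L/4` (minimum 4) and refining each by iterative
distance thresholding; the reported score is the maximum over all searched
superpositions and provably dominates a single whole-chain Kabsch fit. The
conventional interpretation thresholds (0.45 shared fold, 0.21 random
expectation) are exposed for labeling only. `kabsch_rmsd()` superposes
with a proper rotation (no reflection). `inf_score()` is the geometric
mean of base-pair precision and recall, `deformation_index()` is
RMSD / INF_all (undefined at INF 0, which is signalled rather than
imputed). The internal geometric base-pair detector matches N–N and
C4'–C4' distance windows calibrated to the toy-structure geometry and
assigns at most one partner per nucleotide, greedily by deviation from the
ideal pair geometry; it reports category "any" — Watson–Crick versus
non-canonical versus stacking distinctions require externally supplied
annotations (a three-column TSV), since they are not decidable from three
atoms per nucleotide.

## The synthetic data generator

`sample_structure_spec()` draws uniformly among nested sets of exactly `k`
disjoint column pairs with separation at least 4, via dynamic-programming
counts. `sample_family()` fills unpaired columns i.i.d. from a background
composition and draws planted columns jointly complementary (uniform over
AU/UA/GC/CG/GU/UG) with probability `complement_prob`, else independently;
per-symbol mutation noise is applied last. Families are generated from this
explicit complementarity model rather than a fitted coupling model because
it gives controllable signal strength and analytic expectations for the
recovery tests. Defaults chosen once and documented here:

* background `(A, C, G, U) = (0.26, 0.21, 0.31, 0.22)` — a mildly G-rich
  composition typical of structured non-coding RNA. A skewed background
  also makes the unpaired-column recovery baseline (the majority-class
  frequency, 0.31) meaningfully separable from the uniform 0.25.
* `complement_prob = 0.9` and `mutation_rate = 0`: covariation strength is
  controlled through the single complementarity dial; the mutation knob
  exists for experiments that want symbol-level noise on top.

`build_toy_structure()` embeds a nested structure deterministically in 3D:
maximal helices as idealized A-form segments (twist 32.7°, rise 2.81 Å,
paired C4'–C4' 10.40 Å, paired N–N 9.42 Å), bulges and small internal
loops as coaxial continuations with a stretched rise, larger loops as
circles sized to their content with helices extending radially, and P
atoms bridging consecutive C4' atoms with a short relaxation pass that
keeps adjacent P–P spacing inside 4–8 Å. The geometry is calibrated
against the base-pair detector so that planted stems are recovered
exactly on clean structures. `make_decoy_pool()` perturbs the reference
per nucleotide (rotation slerped toward a uniform random rotation about
the nucleotide centroid plus Gaussian translation noise, cycling through
the requested scales) and attaches synthetic distograms that put a
`sharpness` fraction of mass on the reference's true bin.

### What the synthetic experiments do and do not show

The family generator plants pairwise complementarity at fixed columns;
real alignments carry phylogenetic correlation, indels, non-canonical
pairs and tertiary contacts, none of which are emulated. The toy 3D folds
are idealized helix arrangements without sugar pucker, base identity
beyond the glycosidic nitrogen, or realistic loop torsions. Passing the
recovery criteria therefore demonstrates that the objective, the Jacobian
pipeline, the losses and the consensus protocol are implemented correctly
and interact as designed — not that the desk-scale model approaches the
accuracy of the full-scale system on experimental RNA. Quantities that
require released full-scale weights and experimental test sets (benchmark
precision and TM-score tables) are out of scope by construction.

One scale note on the headline experiment: at `L = 40` the maximum number
of disjoint nested pairs with the minimum separation is 18, so the
contact-recovery family plants 18 pairs and top-L precision against the
planted pairs alone is bounded by 0.45; the 0.5 criterion is evaluated
against geometric contacts (N–N < 12 Å in the toy structure), the same
contact definition used for reported precision figures. Problem sizes used
by the tests and the acceptance script — 3000 sequences, 2000 training
steps, 20-decoy pools at 0.5/1/2 Å, a 12-nucleotide overfit target — are
the package's chosen desk-scale study conditions.
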