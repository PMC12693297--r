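---
title: "mepsim: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mepsim: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The similarity model

`mepsim` learns a molecular similarity metric from two image-derived
modalities instead of bond topology. Each compound contributes an MEP
(molecular electrostatic potential) surface render and an RDG (reduced
density gradient) non-covalent-interaction diagram. A convolutional branch
summarizes the MEP image; the RDG diagram is first reduced to an 8×8
gray-level co-occurrence matrix (GLCM) — a classic second-order texture
statistic — whose 64 entries feed a perceptron branch. The two feature
vectors are concatenated and projected into a shared embedding space of
dimension $L$.

The network is Siamese: one set of weights embeds every compound, so
distances in the embedding space are comparable across compounds. Training
minimizes the triplet loss
$$\mathcal{L}(a,p,n) = \max\!\big(0,\; d(a,p) - d(a,n) + m\big),$$
with $d$ the Euclidean distance between embeddings and $m$ the margin.
Triplets are mined *statically* from structural similarity: Tanimoto
scores $S_T = |A\cap B|/|A\cup B|$ over 2048-bit radius-2 binary Morgan
fingerprints, with per-anchor thresholds $S_T \ge 0.70$ for positives and
$S_T \le 0.40$ for negatives (compounds in between are discarded). A
hard-triplet regime simply narrows the gap (e.g. 0.13/0.12); no special
machinery is attached to it — the harder optimization landscape is an
emergent property of the thresholds, not a mechanism.

Reported similarity is the inverse distance
$d^{-1} = 1/(1+d) \in (0,1]$, a strictly decreasing bijection of the
embedding distance with $d^{-1}=1$ exactly for coincident embeddings.

Assumptions worth stating explicitly:

- structural (fingerprint) similarity is a usable *supervision signal*
  even though the point of the model is to disagree with it on
  electronically similar, structurally distinct pairs — the thresholds
  only pin down clear positives/negatives;
- images of one compound are rendered consistently (colormap,
  orientation, background) within a dataset; the model has no built-in
  invariance to rendering conventions;
- the GLCM discards all spatial layout of the RDG diagram beyond
  two-pixel co-occurrence statistics; that is intentional (texture, not
  geometry, is the signal carried by that branch).

## Tunable parameters

All defaults live in `siamese_model()`, `triplet_config()` and
`fit_siamese()`:

| parameter | default | why |
|---|---|---|
| fingerprint bits / radius | 2048 / 2 | the standard ECFP4-equivalent setting; chirality flags off by default (`chiral = FALSE`), configurable |
| triplet thresholds | 0.70 / 0.40 | clear positives and negatives; narrow the gap for hard triplets |
| GLCM levels | 8 | an 8×8 matrix (64 features) balances texture resolution against MLP input size |
| GLCM offsets | (0,1),(1,0),(1,1),(1,−1), distance 1, symmetric, normalized | the standard rotation-robust set; all configurable, including `mask_background` for white-page scatter plots (off by default) |
| CNN input | 64×64 px, values in [0,1] | see "numerical choices" below |
| conv blocks | 32/64/128 filters, 3×3, ReLU, 2×2 pool | smallest standard stack that separates smooth color fields |
| MLP | 64 → 64 → 32, ReLU | two small layers suffice for 64 inputs |
| projector | concat(128+32) → 128 → L, L = 128 | one hidden layer decouples fusion from the embedding dimension |
| margin $m$ | 1.0 | order-unity margin for unnormalized embeddings |
| optimizer | Adam, lr 1e-3 | the conventional default; full-batch, so no batch-size knob |
| epochs / patience | 20 / 5 | 20 epochs is ample for datasets of tens of compounds; patience 5 with `min_delta` 1e-4 on the validation triplet loss |
| `val_fraction` | 0.2 | one held-out split; see below on its granularity |

## Numerical and design choices

**Embedding normalization is off by default.** With unit-norm embeddings,
Euclidean distances are capped at 2 and $d^{-1}$ cannot drop much below
0.33; meaningful dissimilarity scores (well under 0.5) require
unnormalized embeddings. The option exists (`normalize_embeddings = TRUE`,
with the exact Jacobian in the backward pass) for users who prefer
bounded distances.

**Distance metric.** Euclidean. Nothing in the architecture depends on
this choice, but $1/(1+d)$ calibrates differently under other metrics, so
it is fixed rather than exposed.

**Input resolution 64×64.** The CNN consumes smooth, large-scale color
fields; 64×64 retains them while keeping the pure-R forward/backward
passes fast enough for interactive use and for the test suite
(the 2×8-compound benchmark trains in well under a minute on one CPU).
The resolution is configurable; GLCMs are always computed at native image
resolution, since co-occurrence statistics are resolution-robust and
resampling would blur texture.

**Luminance and quantization.** Gray levels use the BT.601 luma
(0.299 R + 0.587 G + 0.114 B, rounded) binned into equal-width bins over
[0, 255]; an all-white pixel lands in the top bin, which is also what
`mask_background` masks.

**Training scheme.** Weight sharing makes the full-batch gradient cheap:
each unique compound is embedded once per epoch, per-triplet loss
gradients are accumulated on the embeddings, and one backward pass per
compound produces the exact parameter gradient. Training is therefore
deterministic given the seed (weight init, split) — there is no
minibatch ordering to randomize. The best-validation checkpoint is
restored at the end.

**Degenerate cases, ties, tolerances.** Tanimoto of two empty
fingerprints is 0/0 and is defined as 0 with a warning. Triplets with
coincident embeddings use a zero subgradient for the $d=0$ distance
terms. Max-pooling breaks ties by a fixed first-winner order
(top-left, bottom-left, top-right, bottom-right). Grad-CAM and saliency
maps are min-max normalized to [0, 1]; if the objective gradient is
identically zero (e.g. the sample is compared against its own embedding)
an all-zero map is returned with a warning instead of dividing by zero.
Early stopping requires an improvement of at least `min_delta` (1e-4) to
reset the patience counter. Normalized GLCMs sum to 1 within 1e-9.

**Grad-CAM in a metric model.** Grad-CAM needs a scalar to differentiate;
classification logits do not exist here. The scalar is
$-\lVert \mathrm{embed}(x) - r\rVert^2$ for a reference embedding $r$
(typically the anchor), so high-attention regions are those pulling the
sample *toward* the reference. The target layer is the last convolutional
block's ReLU activation map — the standard choice, as deeper layers have
no spatial extent left. Saliency on the texture branch is the absolute
input gradient of the same scalar with respect to the 64 GLCM entries.
Both visualizations carry their own 0–1 scale, independent of the
underlying image's colors.

**Validation granularity.** The held-out 20% is drawn at the *triplet*
level. A compound can therefore appear in both sets (in different
triplets), which makes the validation loss an optimistic generalization
estimate; compound-level holdout is stricter but starves small datasets
of triplets. Triplet-level is the implemented default; compound-level
splitting can be emulated by filtering the triplet table before calling
`fit_siamese()`.

**Fingerprint backend.** Morgan fingerprints and SMILES canonicalization
are delegated to RDKit through a batched `python` subprocess, so scores
agree exactly with the standard cheminformatics toolchain; results are
cached per session. No R-native Morgan implementation is involved.

## The synthetic benchmark: what it does and does not show

`make_benchmark()` produces two (up to three) visual families:

- **MEP surrogates** — sums of signed Gaussian blobs rendered through a
  red–white–blue diverging colormap: smooth, family-specific layouts with
  small per-member jitter (SD 0.02 of the image side) in blob centers and
  widths;
- **RDG surrogates** — white-background scatter diagrams with dense
  vertical point clusters at family-specific horizontal positions,
  mimicking the spike structure of density/gradient plots;
- **SMILES pools** — curated homologous series (linear alkanes C6–C13;
  oligo(ethylene glycol)s; long-chain anilines as a third family). Within
  a series binary Morgan fingerprints nearly saturate (pairwise
  $S_T \ge 0.87$), across series $S_T \le 0.37$, so the 0.70/0.40 mining
  contract holds by construction. The generator re-validates this and
  the GLCM-space family separation at generation time and aborts with
  the offending pairs if either fails.

Everything is bit-for-bit reproducible: each image's RNG stream is
derived from (seed, family, member), and generation never disturbs the
caller's random state.

What passing on this benchmark shows: every pipeline stage is wired
correctly, the loss decreases, embeddings separate visually coherent
families, and attention maps satisfy their contracts. What it does not
show: performance on real DFT-derived imagery. Real MEP surfaces encode
chemistry in subtle colormap transitions, molecular orientation varies,
RDG diagrams share a common global layout across compounds, and — most
importantly — real series contain bioisosteric pairs where structural and
electronic similarity *disagree*, which is the regime the method exists
for. Homologous SMILES pools also make the Tanimoto matrix nearly
two-valued, so triplet mining is much easier than on a real series. The
benchmark is a correctness harness, not an evaluation.

## Known limitations

- Published per-pair similarity values from trained models (e.g. specific
  $d^{-1}$ scores for named inhibitor pairs) are not reproducible without
  the original images and trained weights; only the fingerprint-based
  Tanimoto scores are recomputable from structures, and only for
  compounds whose structures are public.
- The pure-R network is practical for tens-to-hundreds of compounds at
  64×64; it is not a large-scale training framework.
- Static triplet mining never refreshes during training (no online hard
  mining); this mirrors the intended workflow, where supervision comes
  from a fixed fingerprint matrix.
- JPEG input requires the EBImage package; PNG is the native format
  throughout.
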