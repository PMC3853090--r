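---
title: "Methods: structure-aware kinase-specific phosphosite prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-aware kinase-specific phosphosite prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialphos)
```

## The problem and the model

Protein kinases phosphorylate serine, threonine and tyrosine residues of
their substrates. Which acceptor residues a given kinase group modifies is
determined partly by the linear sequence motif around the site (e.g.
basophilic kinases prefer arginine/lysine at positions −3/−2) and partly by
the three-dimensional context of the site on the folded protein. This
package predicts kinase-specific phosphosites with one binary RBF-kernel
SVM per kinase group, trained on a hybrid feature vector:

* **PWM block** (13 values): each letter of the 13-mer window (offsets
  −6…+6, padded with the terminal symbol `-` at protein ends, a 21-letter
  alphabet) is replaced by its positional relative frequency in a
  positional weighted matrix estimated from positive windows.
* **AAC block** (20 values): relative amino acid composition of the
  window's non-terminal letters.
* **ASA block** (13 values): relative solvent accessibility per window
  offset, in [0, 1]; offsets beyond the protein encode as 0.
* **SS block** (39 values): one-hot three-state secondary structure
  (H/E/C) per offset; out-of-range offsets give a zero triplet.
* **Spatial block** (20 × R values): the spatial amino acid composition —
  for each radius r in 3…12 Å, the relative frequencies of the 20 residue
  types among residues whose Cα lies within r Å of the site's Cα
  (cumulative spheres, the centre excluded).

Negative examples are all S/T/Y residues of the phosphoproteins that carry
no positive annotation. Three presets mirror the natural model comparison:
`sequence_only` (PWM+AAC+ASA+SS), `structure_only` (spatial), `combined`
(all blocks).

## Feature statistics

Candidate features are ranked by the F-score

$$F_i = \frac{(\bar{x}_i^{(+)}-\bar{x}_i)^2 + (\bar{x}_i^{(-)}-\bar{x}_i)^2}
{\tfrac{1}{n_+-1}\sum_k (x^{(+)}_{k,i}-\bar{x}_i^{(+)})^2 +
 \tfrac{1}{n_--1}\sum_k (x^{(-)}_{k,i}-\bar{x}_i^{(-)})^2},$$

with $\bar{x}_i$ the mean over the pooled positive and negative values (not
the mean of the two class means). Degenerate inputs are resolved so the
ranking stays total: 0/0 gives 0, a positive numerator over a zero
denominator gives `Inf`. The statistic is reported, not used as an
automatic feature-elimination gate — no principled cutoff exists, so gating
is left to the user.

For interpretation, `radial_cumulative_propensity()` contrasts the pooled
spatial composition of positives and negatives per residue type and radius
as a pseudocounted log2 ratio (pseudocount 0.5 per cell by default). The
exact normalisation of this display is a reconstruction: we use additive
smoothing on both class frequencies, which is antisymmetric under class
exchange and zero for identical classes.

## Evaluation protocol

* **Balance.** In each cross-validation repeat, negatives are randomly
  subsampled to match the positives (1:1). The subsample is redrawn per
  repeat so the ten repeats exercise different balanced sets. Independent
  testing subsamples negatives to twice the positives (1:2), the customary
  ratio for comparisons between published site predictors.
* **Folds.** Groups with ≥ 30 positive sites use 5 stratified folds;
  smaller groups use a jackknife. We implement the jackknife as a *paired*
  leave-one-out — each fold holds out one positive together with its
  matched negative — so every training fold stays exactly balanced and the
  fold count equals the number of positives.
* **Repeats.** Ten repeats by default; confusion counts are pooled within
  a repeat, the four metrics computed per repeat, and means (with the SD
  of accuracy) reported. Metrics with zero denominators are `NA`, never 0.
* **Leakage control.** The PWM is a function of the positive training
  windows, so it is re-estimated on each training fold, and the per-feature
  min–max scaling is likewise fit on training folds only. Building either
  on the full dataset lets every held-out positive inform its own encoding
  and biases null-data accuracy above chance; with per-fold refitting,
  label-permuted data scores ~0.5 (verified in the test suite).
* **Determinism.** Per-repeat seeds are drawn once from the master seed;
  a rerun with the same seed is bit-identical.
* **Hyperparameters.** The classifier is libsvm C-classification with the
  RBF kernel. Defaults are C = 1 and γ = 1/d (d = feature count);
  `grid_search()` offers an inner 3-fold CV over log-scale grids with ties
  broken toward smaller C then smaller γ, making the result independent of
  grid ordering.

**Cross-classification.** To quantify motif confusion between kinase
groups, each group's model is evaluated on every other group's true
positives treated as negatives; entry [m, g] of the matrix is the fraction
of group-g sites that model m rejects. Higher off-diagonal specificity
means better kinase-level discrimination.

## Structural conventions

Distances are measured Cα–Cα by default. Cβ (with Cα fallback for glycine)
and nearest-heavy-atom modes are available, but Cα is the most robust
choice on structures with incomplete side chains. Spheres are cumulative;
a per-annulus mode exists for diagnostics. The central residue is excluded
from its own composition; sequence neighbours are included by default and
can be excluded (`exclude_seq_window`) to isolate spatially-close-only
contacts. Radii default to the ten integers 3–12 Å; the count and spacing
are configurable.

PDB input is reduced to a defensible subset: first model, first alternate
location, HETATM and non-standard residues dropped, residues without a Cα
discarded. DSSP output is parsed directly; relative ASA is
`min(1, ACC / maxASA)` with the Tien et al. (2013) theoretical maxima
(shipped as `MAX_ASA`, replaceable), and 8-state secondary structure is
collapsed H,G,I→H; E,B→E; else→C.

Sites are mapped onto chains by ungapped alignment of the 13-mer window
against the chain sequence derived from the residues in residue-number
order. The default demands exact identity over the aligned window — a
deliberately conservative choice that avoids silently transferring site
annotations across homologs; the identity threshold and minimum overlap
are configurable. Ties between equally good placements go to the first
chain in lexicographic order, then the leftmost placement.

## The synthetic benchmark

Real curated phosphosite corpora require database downloads, so the
package's testable claims are made on synthetic data whose generating
signal is known:

* Proteins of length 48 with i.i.d. letters (uniform background by
  default; a natural-abundance preset exists), one protein per positive
  site, the acceptor forced at a mid-sequence position so the 13-mer
  window never needs padding and enough chain remains downstream for
  spatial planting.
* Sequence motifs are planted per offset with a stated probability
  (default: R at −3 and −2 with probability 0.9, a caricature of the
  basophilic motif).
* Structures are self-avoiding Cα random walks (3.8 Å steps, 3.5 Å clash
  floor, resampling on clash) confined to a 14 Å sphere so the fold is
  compact enough for spatial neighbourhoods to be populated; an ideal
  helix model is also available.
* Spatial enrichments (default: 3 extra methionines within 6 Å of the
  site) are planted by relabelling sequence-distal residues already inside
  the sphere, or — when too few exist — by re-walking the chain with steps
  steered so that chosen sequence-distal residues land inside the sphere.
  Steering preserves the step-length and clash invariants exactly, which
  is why relocation is implemented as a constrained re-walk rather than by
  moving atoms. Near the confinement boundary the steering sphere may be
  clipped, so steered chains may hover slightly outside the confinement
  ball; hard geometries are retried under derived seeds.
* ASA/SS annotations are drawn without any class signal, so in benchmarks
  they act as pure nuisance dimensions.

What the generator does *not* emulate: real secondary-structure and
accessibility preferences of phosphosites (loops, exposed residues),
correlated backbone geometry, homology between proteins, shared substrates
between kinase groups, and label noise. Passing benchmarks therefore
demonstrate that the machinery recovers signals of the stated kind and
calibrates to chance on null data — not field performance on curated
corpora.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 50 positives per group
(100 for the null-calibration check), ten-repeat CV for headline numbers
and five repeats inside multi-seed averages, five seeds for paired
comparisons (structural-gain and cross-classification checks) and ten
seeds for the F-score recovery rate. These sizes keep every check
well-resolved while the whole pipeline remains cheap on a single CPU.

Other numerical conventions: PWM pseudocount defaults to 0 (configurable
for small groups); empty spatial spheres yield all-zero frequency columns
rather than NaNs; min–max scaling maps constant features to 0; prediction
rejects any feature matrix whose schema does not match the model's stored
schema; independent testing refuses any (protein, position) overlap with
the training set.

## Known limitations

* Exact-identity window mapping will miss sites on structures with point
  substitutions; lower `min_identity` deliberately when homology transfer
  is acceptable.
* The jackknife interpretation (paired leave-one-out) is one of several
  defensible readings of leave-one-out on balanced data; it was chosen so
  fold counts equal positive counts and training folds stay balanced.
* The spatial composition sees only Cα positions; side-chain orientation
  and solvent exposure of the 3D neighbourhood are not captured beyond the
  ASA block.
* With ten radii the spatial block has 200 features; for kinase groups
  with very few mapped structures the SVM may need the PWM pseudocount and
  grid search to avoid degenerate fits.
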