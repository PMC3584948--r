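---
title: "Single-model protein quality assessment with per-residue S-scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-model protein quality assessment with per-residue S-scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proqr)
```

## The problem

Protein structure prediction pipelines produce many alternative models of a
target sequence, and the practical question is rarely "what is the average
accuracy of the method" but "how good is *this* model, and which parts of it
can be trusted". `proqr` addresses this as a *single-model* quality
assessment problem: it predicts, from one model's coordinates and
sequence-derived predictions alone, how far each residue sits from its
position in the (unknown) native structure. Because no ensemble or template
information enters the score, the same predictor can drive conformational
sampling and refinement, not just ranking.

## The local quality measure

Per-residue correctness is expressed as the S-score

$$ S_i = \frac{1}{1 + (d_i/d_0)^2}, $$

where $d_i$ is the deviation of residue $i$ after optimal superposition of
model and native, and $d_0 = 3\ \text{Å}$ is the distance at which the score
is exactly 0.5. The score is 1 for a perfectly placed residue and decays
smoothly to 0; it can be inverted to a distance, $d = d_0\sqrt{1/S - 1}$,
which is how per-residue predictions are reported in QA output files.
$S_i$ is computed from the superposition maximizing $\sum_i S_i$ over the
whole model, found with a MaxSub-style seed-and-extend search: every
contiguous 7-residue window seeds a least-squares (Kabsch) fit that is
iteratively extended with all residues within an inclusion threshold
($3.5\,d_0$ by default, configurable) until a fixed point. The all-residue
fit is always among the candidates, so the reported sum can never fall below
a plain global superposition. GDT_TS is computed with the same machinery,
per threshold (1, 2, 4, 8 Å), normalized by the reference residue count and
reported on a 0–100 scale; this is a heuristic search, not the exhaustive
LGA enumeration, and can only underestimate the true optimum — the test
suite asserts it dominates any single fixed superposition.

The global quality of a model is the sum of its local scores divided by the
*target* sequence length, so unmodeled residues count as zero and a
half-length model cannot score above 0.5.

## Features

Each residue is described by a 160-component vector computed over sliding
sequence windows (truncated at the termini — denominators always count real
residues, never phantom positions):

* **Atom–atom contacts** (91): heavy atoms are mapped onto 13 chemical
  classes (backbone N/CA/C/O, CB, aliphatic C, sp2-polar C, aromatic C,
  polar side-chain N, aromatic N, hydroxyl/carboxylate/amide O, S — the
  full table is `atom_class_table()`). Two atoms are in contact below 4 Å;
  pairs from sequence-adjacent residues ($|i-j| \le 1$) are ignored.
  Contacts touching a 21-residue window (including spatial partners outside
  it) form a normalized histogram over unordered class pairs.
* **Residue–residue contacts** (21): residues group into six classes
  (Arg/Lys; Asp/Glu; His/Phe/Trp/Tyr; Asn/Gln/Ser/Thr;
  Ala/Ile/Leu/Met/Val/Cys; Gly/Pro). Contact means any Cα/side-chain atom
  pair within 6 Å with sequence separation > 5.
* **Exposure pattern** (24): relative side-chain accessibility binned into
  <25%, 25–50%, 50–75%, ≥75% (boundaries closed on the left) per residue
  group, normalized by window size.
* **Secondary structure** (19): predicted class probabilities at the center,
  the fraction of a 21-window where the predicted class matches the
  assigned one, and the assigned classes one-hot over a 5-window.
* **Surface agreement** (2): burial-class agreement (25% threshold) over a
  21-window and mean relative exposure over a 13-window.
* **Conservation** (1): mean information-per-position from the PSSM over a
  3-window.
* **Global agreements** (2): the secondary-structure and burial agreement
  fractions computed over the whole model, identical for every residue of
  one model. These whole-model descriptors materially improve *local*
  prediction: a residue's local environment can look right while the model
  is globally wrong.

**Profile weighting.** The residue-specific blocks (residue contacts and
exposure) can spread each residue's contribution across amino-acid types
according to its sequence-profile frequencies: a position that is 40%
alanine and 60% serine contributes 40% of its contact mass as alanine
contacts and 60% as serine contacts. Weighting is linear by construction:
features of a mixed profile equal the frequency-weighted average of
pure-residue features, and a one-hot profile on the model sequence
reproduces the unweighted features exactly (both are asserted in the
tests). Frequencies come from the PSSM's weighted-observed-percentage
columns, not the log-odds, because the weighting is defined on occurrence
fractions.

## Design choices in open territory

* **Base window size.** Window lengths are printed only for the
  agreement/area/conservation features (21/13/3); the contact and exposure
  histograms use 21 by default, consistent with the printed windows, and
  the value is configurable (`proq_config(window = ...)`).
* **Solvent accessibility** is computed internally with the Shrake–Rupley
  method (probe 1.4 Å, 960 deterministic quasi-uniform sphere points per
  atom; quadrupling the point count changes per-residue areas by well under
  2%). Relative exposure divides side-chain SASA (backbone for Gly) by the
  Miller et al. (1987) tripeptide maxima, clamped to [0,1]. The reference
  table is an argument of `compute_sasa()` and therefore swappable. With
  the CB-placeholder side chains of the synthetic fixtures these ratios are
  conservative (a truncated side chain can never reach the full-side-chain
  reference); this compresses the exposure scale but preserves its
  ordering, which is what the binned features consume.
* **Secondary structure** is assigned internally from backbone dihedrals
  (alpha region → H, beta region → E, else C, with minimum run lengths 4
  and 2; termini are coil). Readers for external STRIDE and DSSP output
  files are provided and map eight-state codes as {H,G,I}→H, {E,B}→E,
  else C. Tests use the internal assigner, so no external binary is needed.
* **Feature standardization.** Features are standardized to zero mean and
  unit variance before regression; the parameters are fit on training folds
  only during cross-validation and stored inside the trained model. The
  method description is silent on scaling; linear SVR is not
  scale-invariant across features with ranges as different as counts and
  probabilities, so this is the conservative choice.
* **Exposure bin boundaries** are closed on the left ([25,50) etc.); a
  residue at exactly 25% therefore opens the second bin. The rule is
  asserted explicitly in the tests.

## The regressor

Local scores are predicted by linear epsilon-SVR (via `e1071`, which wraps
libsvm). The cost C and tube width epsilon are chosen by grid search —
defaults C ∈ {0.01, 0.1, 1, 10}, ε ∈ {0.05, 0.1, 0.2}, since the original
optimization printed no values — scored by mean five-fold cross-validated
Pearson correlation with folds split *by target*: residues of one target
never straddle folds, and one (C, ε) pair is chosen for all folds jointly.
The final model is refit on all data and serialized as versioned JSON with
a fingerprint of the feature layout; prediction refuses a mismatched
layout. Raw linear outputs are clamped to [0,1] (the minimal policy; no
rescaling). Nonlinear kernels are deliberately out of scope — they were
tried for this method and brought no gain over the linear kernel.

## Consensus and combination

`pcons_score()` implements a structural-consensus scorer: the local
consensus score of residue r in one model is the mean S-score similarity at
r over the S-score-optimal superpositions onto every other model of the
ensemble, and the global score is the length-normalized sum. The published
internals of the original consensus predictor are not restated here; mean
pairwise S-score similarity with the same superposition machinery as the
target function is the standard construction and is documented as an
approximation. The single-model and consensus scores combine linearly,
$S = (1-k)\,S_{\text{single}} + k\,S_{\text{consensus}}$ with $k = 0.8$ by
default; `optimize_k()` re-fits k on any labeled ensemble set by maximizing
the summed quality of first-ranked models.

## Synthetic data: what it does and does not show

All tests run offline on generated fixtures: ideal-geometry natives (helix,
extended strand, irregular coil, or two helical domains with an extended
linker; backbone plus CB placeholders), ensembles produced by per-residue
Gaussian displacements of scale σ plus a random rigid motion, and
sequence-derived predictions that agree with the native's assigned classes
with a configured accuracy (default 0.85, roughly the accuracy of modern
secondary-structure predictors) and a profile blending 60% of the mass on
the native residue with 40% spread uniformly. The end-to-end check trains
on 10 synthetic targets (10 models × 60 residues each, σ spaced 0–8 Å;
every second residue enters the training matrix, mirroring the idea of
subsampling models per target to keep the training set tractable) and
requires pooled held-out correlation above 0.5 on the other 10 targets.

These fixtures exercise every code path with known ground truth, but they
are not physically realistic decoys: side chains are truncated, the
displacement noise is unstructured, and the sequence predictions have
independent errors. Passing them demonstrates that the machinery is
internally consistent and that the regressor recovers signal that is
genuinely present — not that the trained toy model transfers to real
prediction-experiment data, which would require real models, profiles from
an iterative sequence search, and external secondary-structure/burial
predictors.

## Numerical notes and limitations

* All generators and the trainer take explicit seeds; identical seeds give
  bit-identical outputs (asserted for written PDB fixtures and trained
  weights).
* Degenerate inputs have defined behavior: windows with no contacts yield
  all-zero histogram blocks; an all-zero PSSM percentage row falls back to
  one-hot on the query residue; targets with zero quality variance are
  excluded from Z-score sums and counted; consensus over a single model is
  an error.
* Fewer than 7 matched residues collapses the superposition search to the
  all-residue fit; fewer than 3 is an error.
* The seed/extension constants of the superposition search (seed length 7,
  inclusion threshold 3.5 d0, 10 iterations) affect tie-breaking only on
  the fixtures used here; they are exposed as arguments.
* First chain only, heavy atoms only, standard residues only; mmCIF and
  nucleic acids are out of scope.
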