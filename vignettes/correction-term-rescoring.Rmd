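---
title: "Correction-term rescoring of docked protein–ligand poses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correction-term rescoring of docked protein–ligand poses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Docking engines optimize an approximate physical scoring function. That
function is usually good enough to *sample* a near-native pose somewhere
in the output ensemble, but its energy ranking frequently puts a wrong
pose first. Rescoring attacks the second problem without touching the
first: keep the engine's poses and scores, and add an independent,
learned assessment of each pose's geometric plausibility.

`sfct` implements this as a *correction term*. A regressor is trained to
predict the heavy-atom RMSD of a pose from the (unknown, at inference
time) native binding mode, using only contact statistics between the
pose and the receptor. The final ranking score is the linear blend

$$E = \alpha P + \beta S,$$

where $P$ is the docking engine's score (lower is better), $S$ is the
predicted RMSD in ångströms, and $\alpha = \beta = 0.5$ by default. With
$\beta = 0$ the pipeline reproduces the engine ranking exactly; the
default equal weighting was chosen for engine scores on a
kcal/mol-like scale (roughly $-12$ to $-4$), where a few ångströms of
predicted error are commensurate with a few score units. The weights are
exposed so users can retune them for engines on other scales.

## Features: multi-shell contact counts

Each pose is reduced to an integer vector of contact counts. Every
(protein heavy atom, ligand heavy atom) pair is assigned to a bin by
three coordinates:

* the **residue class** of the protein atom — the 20 standard amino
  acids plus `OTH` for anything else (21 classes);
* the **element class** of the ligand atom — C, N, O, S, P, `HAL`
  (F/Cl/Br/I pooled) and `OTH` (7 classes);
* the **distance shell** — 14 consecutive shells of width 1.5 Å
  starting at 0, so the outermost boundary is 21 Å. Shells are
  half-open, `[lo, hi)`, and pairs at 21 Å or beyond are ignored.

This yields $21 \times 7 \times 14 = 2058$ features per pose. The layout
is fixed (residue class slowest, shell fastest) and fingerprinted by a
schema hash; models refuse to predict on features built under a
different schema. The multi-shell design lets the model see both
short-range packing (inner shells) and the longer-range context that
distinguishes a pose sitting in the pocket from one drifting out of it.

Hydrogens are excluded throughout: they are absent or unreliable in most
crystallographic and docked structures, and heavy-atom contacts carry
the ranking signal.

## Model: boosted random forests on RMSD labels

`train_sfct()` fits AdaBoost.R2 with random-forest base learners
(via `ranger`). The defaults in `sfct_hyperparams()` are:

* 10 boosting rounds, 50 trees per forest;
* 512 candidate features per split (`mtry`), a quarter of the feature
  space, which decorrelates trees while keeping enough signal per split;
* maximum tree depth 50, effectively unconstrained for the problem
  sizes involved, letting the forests fit sharp contact thresholds;
* linear AdaBoost loss and out-of-bag error tracking.

Training labels are symmetry-corrected RMSDs of each pose from its
native binding mode. Poses with RMSD above 10 Å are excluded before
training (strictly above: a 10.0 Å pose is retained): beyond that range
the pose no longer occupies the pocket, and regression targets there are
noise. Predictions are clamped at zero, since a negative RMSD is
meaningless. Boosting weights are updated per AdaBoost.R2 (losses scaled
by the maximum error; rounds with average loss ≥ 0.5 stop the
ensemble), and inference uses the weighted median of the rounds'
predictions, which is robust to a single bad round.

Training is deterministic for a fixed seed: each round's forest receives
a derived seed and runs single-threaded.

## Symmetry-corrected RMSD

Naive atom-by-atom RMSD overestimates the error of poses of symmetric
ligands (a flipped benzene ring is chemically identical but numerically
far). `symmetry_corrected_rmsd()` minimizes the RMSD over all
automorphisms of the ligand's colored bond graph (vertices colored by
element, edges by bond order), computed with VF2 via `igraph`. No
superposition is applied: poses are compared in the receptor frame,
because a rigid shift of a docked pose *is* an error. Ligands with more
than 10,000 automorphisms fall back to the identity mapping with a
warning.

## The synthetic benchmark

Real benchmark corpora require curated crystal structures and large
docking runs. To keep the package self-contained and testable offline,
it ships a synthetic generator:

* `generate_toy_complex()` builds a random tree-shaped ligand (5–40
  heavy atoms over a drug-like element distribution) and a shell of
  5-atom residue stubs around it, with guaranteed 1.5 Å minimum
  separations.
* `generate_decoys()` produces poses at stratified target RMSDs
  (0.2–12 Å by default) using torsional perturbation about rotatable
  bonds, bounded rigid rotation, and an orthogonal translation that
  tops the deformation up to the exact target; labels are then
  *recomputed* from coordinates, not taken from the targets.
* `simulate_training_corpus()` assembles complexes × (crystal pose +
  decoys) into a ready-to-train feature table; the packaged benchmark
  uses 200 complexes with 20 decoys each, a size chosen so a full
  train/evaluate cycle runs in minutes on one CPU while leaving a
  40-complex held-out set large enough for stable statistics.

What the synthetic data does emulate: the geometry of the task (contact
features that decay with RMSD, pocket-shaped receptors, symmetric-ligand
ambiguity, a realistic RMSD spectrum) and the statistical shape of the
learning problem. What it does not: real chemistry. There are no
hydrogen bonds, charges, or physics in the generator, so absolute
performance numbers on it say nothing about performance on experimental
complexes — they demonstrate that the pipeline recovers a learnable
pose-quality signal end to end. `pseudo_docking_score()` similarly
fabricates engine scores with controllable RMSD coupling and noise, so
rescoring experiments can interpolate between a perfect and a useless
engine.

## Screening metrics

`success_rate()` (top-1 pose within 2 Å, boundary inclusive),
`average_topk_rmsd()`, `enrichment_factor()` (ratio of the active rate
in the top fraction to the overall active rate, with a `ceiling` bucket
size) and `roc_auc()` (Mann–Whitney formulation, ties counted half) are
implemented in closed form and cross-checked in the test suite against
independent implementations and analytic examples. `screening_scores()`
collapses pose tables to per-ligand scores using the best of at most 20
poses, and `rank_proteins_reverse()` ranks receptors for one ligand by
their best pocket score (target fishing).

## Limitations

* The shipped benchmark is synthetic; models trained on it are not
  transferable to real complexes. To use the correction term in
  earnest, featurize your own docked poses with RMSD labels from
  redocking experiments and retrain.
* The featurizer ignores protein atom types within a residue, ligand
  connectivity, and all hydrogens; it is a coarse descriptor by design.
* The automorphism search is exact but can be slow for highly symmetric
  ligands near the 10,000-mapping cap.
* `read_receptor()` keeps only standard residues plus selenomethionine
  by default; exotic cofactors count as `OTH` residue class if retained
  via `keep_hetero`.

## A minimal session

```{r example}
library(sfct)

cpx    <- generate_toy_complex(seed = 7, n_residues = 12, n_ligand_atoms = 14)
decoys <- generate_decoys(cpx$ligand, n_decoys = 8, seed = 8)

corpus <- simulate_training_corpus(n_natives = 12, n_decoys_per_native = 10,
  seed = 7, n_residues = c(6, 12), n_ligand_atoms = c(6, 14))
model  <- train_sfct(filter_training_poses(corpus),
  sfct_hyperparams(n_boost_rounds = 3, trees_per_forest = 20, seed = 5))

scores <- tibble::tibble(pose_id = pose_ids(decoys$poses),
  score = pseudo_docking_score(decoys$labels$rmsd, seed = 9))
rescore_poses(cpx$receptor, decoys$poses, model, scores)

autoplot(model)            # feature-importance map
glance(model)              # one-row training summary
```
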