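# sfct

Machine-learned scoring-function correction terms for protein–ligand
docking rescoring.

Docking engines are good at generating near-native ligand poses but
notoriously unreliable at *ranking* them: the pose with the best engine
score is often several ångströms from the crystallographic binding mode.
`sfct` implements a corrective rescoring strategy: a boosted
random-forest regressor is trained to predict each pose's heavy-atom
RMSD from the native pose, using only cheap residue–atom contact
features, and that predicted RMSD is blended linearly with the engine
score:

```
E = alpha * P + beta * S        (default alpha = beta = 0.5)
```

where `P` is the docking score (lower is better), `S` is the predicted
RMSD in Å, and poses are re-ranked by `E`. Because `S` penalizes poses
that *look* geometrically wrong regardless of their engine score, the
hybrid score recovers near-native poses that the engine alone misranks.

## What is in the package

- **Featurization** — each pose is described by counting
  (protein residue class × ligand element class) heavy-atom contacts in
  14 concentric distance shells of width 1.5 Å (21 residue classes × 7
  element classes × 14 shells = 2058 integer features). See
  `featurize_complex()`, `featurize_poses()`, `feature_schema()`.
- **Model** — AdaBoost.R2 over random-forest base learners
  (10 boosting rounds × 50 trees, 512 candidate features per split,
  depth ≤ 50), with out-of-bag error tracking. Poses with RMSD > 10 Å
  are excluded from training; predictions are clamped at 0. See
  `train_sfct()`, `predict_sfct()`, `sfct_hyperparams()`,
  `feature_importance()`, plus broom-style `tidy()`/`glance()` and
  `ggplot2::autoplot()`.
- **Pose metrics** — symmetry-corrected heavy-atom RMSD (minimum over
  all graph automorphisms of the ligand, no superposition), docking
  success rates, and mean top-k RMSD. See `symmetry_corrected_rmsd()`,
  `rmsd_to_reference()`, `success_rate()`.
- **Scoring and screening** — hybrid rescoring of pose sets, best-of-20
  per-ligand screening scores, enrichment factors, ROC-AUC, and reverse
  (target-fishing) ranking. See `rescore_poses()`, `screening_scores()`,
  `enrichment_factor()`, `roc_auc()`, `rank_proteins_reverse()`.
- **Structure I/O** — readers for PDB and PDBQT receptors and SDF, MOL2
  and (multi-model Vina) PDBQT ligand pose files, plus writers for PDB
  and SDF. See `read_receptor()`, `read_ligand_poses()`.
- **Synthetic benchmark** — a fully self-contained generator of toy
  receptor–ligand complexes and RMSD-stratified decoy poses, so the
  entire pipeline can be trained and evaluated offline with no external
  data. See `generate_toy_complex()`, `generate_decoys()`,
  `simulate_training_corpus()`, `simulate_screening_library()`.
- **Command line** — a thin CLI over the same functions at
  `system.file("cli", "sfct.R", package = "sfct")` with subcommands
  `simulate`, `featurize`, `train`, `rmsd`, `rescore`, `eval-docking`,
  `eval-screening` and `reverse-rank`.

## Worked example

Generate a toy complex with eight decoy poses, train a small correction
model on a simulated corpus, and rescore the decoys:

```r
library(sfct)

cpx    <- generate_toy_complex(seed = 7, n_residues = 12, n_ligand_atoms = 14)
decoys <- generate_decoys(cpx$ligand, n_decoys = 8, seed = 8)
decoys$labels
#> # A tibble: 8 × 3
#>   pose_id     rmsd naive_rmsd
#>   <chr>      <dbl>      <dbl>
#> 1 decoy_001  9.48       9.48
#> 2 decoy_002  8.64       8.64
#> 3 decoy_003  0.888      0.888
#> 4 decoy_004  6.57       6.57
#> 5 decoy_005  1.98       1.98
#> 6 decoy_006  4.33       4.33
#> 7 decoy_007 11.9       11.9
#> 8 decoy_008  5.59       5.59

corpus <- simulate_training_corpus(n_natives = 12, n_decoys_per_native = 10,
  seed = 7, n_residues = c(6, 12), n_ligand_atoms = c(6, 14))
model  <- train_sfct(filter_training_poses(corpus),
  sfct_hyperparams(n_boost_rounds = 3, trees_per_forest = 20, seed = 5))
#> filter_training_poses: removed 22 pose(s) with label > 10 A
glance(model)
#> # A tibble: 1 × 6
#>   n_poses n_features n_rounds label_min label_max mean_oob_mse
#>     <int>      <int>    <int>     <dbl>     <dbl>        <dbl>
#> 1     110       2058        3         0      9.78         3.77

scores <- tibble::tibble(pose_id = pose_ids(decoys$poses),
  score = pseudo_docking_score(decoys$labels$rmsd, seed = 9))
rescore_poses(cpx$receptor, decoys$poses, model, scores)
#> # A tibble: 8 × 5
#>   pose_id       P     S       E  rank
#>   <chr>     <dbl> <dbl>   <dbl> <int>
#> 1 decoy_003 -7.88  5.90 -0.986      1
#> 2 decoy_005 -6.97  5.72 -0.624      2
#> 3 decoy_006 -7.89  7.47 -0.207      3
#> 4 decoy_004 -6.31  6.04 -0.133      4
#> 5 decoy_001 -5.92  5.77 -0.0775     5
#> 6 decoy_002 -6.23  6.76  0.267      6
#> 7 decoy_008 -6.34  7.80  0.730      7
#> 8 decoy_007 -3.24  6.51  1.64       8
```

The hybrid ranking puts the 0.89 Å near-native pose (`decoy_003`)
first, ahead of `decoy_006`, which the engine score alone would have
preferred despite its 4.3 Å RMSD.

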