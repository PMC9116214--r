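test_that("toy complex generation is deterministic and clash-free", {
  a <- generate_toy_complex(19, 10, 12)
  b <- generate_toy_complex(19, 10, 12)
  expect_identical(a$receptor, b$receptor)
  expect_identical(a$ligand$atoms, b$ligand$atoms)
  dmin <- min(sfct:::cross_distances(
    as.matrix(a$receptor[, c("x", "y", "z")]),
    pose_coords(a$ligand, "native")))
  expect_gte(dmin, 1.5)
  # ligand bond graph is connected
  g <- igraph::graph_from_edgelist(
    as.matrix(a$ligand$bonds[, c("from", "to")]), directed = FALSE)
  expect_true(igraph::is_connected(g))
})

test_that("generated pockets produce contacts within 6 A of the ligand", {
  for (seed in c(2, 14, 27)) {
    cpx <- generate_toy_complex(seed, 10, 12)
    f <- featurize_complex(cpx$receptor, pose_atoms(cpx$ligand, "native"))
    inner <- f[feature_schema()$shell <= 4] # shells 1-4 cover 0-6 A
    expect_gt(sum(inner), 0)
  }
})

test_that("decoy labels are self-consistent with recomputed RMSDs", {
  cpx <- generate_toy_complex(23, 8, 12)
  dec <- generate_decoys(cpx$ligand, n_decoys = 10, seed = 3)
  recomputed <- rmsd_to_reference(dec$poses, cpx$ligand)
  expect_equal(dec$labels$rmsd, recomputed$rmsd, tolerance = 1e-12)
})

test_that("pure translations yield exactly their target RMSD", {
  cpx <- generate_toy_complex(29, 8, 10)
  dec <- generate_decoys(cpx$ligand, n_decoys = 6, rmsd_range = c(1, 6),
    torsion_sd = 0, rotation = FALSE, seed = 5)
  # naive label equals the translation magnitude; symmetry can only tie
  expect_true(all(dec$labels$rmsd <= dec$labels$naive_rmsd + 1e-12))
  expect_true(all(dec$labels$naive_rmsd >= 1 - 1e-9 &
    dec$labels$naive_rmsd <= 6 + 1e-9))
  # displacement vector identical for all atoms in each pose
  for (id in pose_ids(dec$poses)) {
    disp <- pose_coords(dec$poses, id) - pose_coords(cpx$ligand, "native")
    col_spread <- apply(disp, 2, function(v) max(v) - min(v))
    expect_lt(max(col_spread), 1e-9)
    expect_equal(sqrt(sum(disp[1, ]^2)),
      dec$labels$naive_rmsd[dec$labels$pose_id == id], tolerance = 1e-9)
  }
})

test_that("the default decoy spectrum spans near-native to far-off poses", {
  cpx <- generate_toy_complex(31, 10, 15)
  dec <- generate_decoys(cpx$ligand, n_decoys = 90, seed = 13)
  labs <- dec$labels$rmsd
  expect_equal(n_poses(dec$poses), 90)
  expect_lt(min(labs), 0.5)
  expect_gt(max(labs), 10)
  expect_gte(mean(labs <= 2), 0.10)
  expect_gte(mean(labs >= 8), 0.10)
  # determinism
  dec2 <- generate_decoys(cpx$ligand, n_decoys = 90, seed = 13)
  expect_identical(dec$poses$atoms, dec2$poses$atoms)
})

test_that("pseudo docking scores follow the affine model", {
  rmsd <- c(0, 1, 2, 5, 10)
  exact <- pseudo_docking_score(rmsd, base_affinity = -8, rmsd_coupling = 0.5,
    noise_sd = 0)
  expect_equal(exact, -8 + 0.5 * rmsd)
  decoupled <- pseudo_docking_score(rep(c(0, 10), 50), rmsd_coupling = 0,
    noise_sd = 1, seed = 21)
  expect_lt(abs(cor(decoupled, rep(c(0, 10), 50))), 0.5)
  set.seed(22)
  r <- runif(500, 0, 10)
  coupled <- pseudo_docking_score(r, rmsd_coupling = 0.5, noise_sd = 1, seed = 23)
  expect_gt(cor(coupled, r), 0.5)
  expect_error(pseudo_docking_score(-1), class = "sfct_error_domain")
})

test_that("screening libraries separate perfectly without noise", {
  lib <- simulate_screening_library(n_actives = 10, n_decoy_ligands = 190,
    seed = 3, rmsd_coupling = 0, noise_sd = 0)
  per_ligand <- screening_scores(lib, score = "score")
  ef <- enrichment_factor(per_ligand[, c("score", "active")], 0.05)
  n <- nrow(per_ligand)
  expect_equal(ef, min(n / ceiling(0.05 * n), n / 10)) # theoretical max
  expect_equal(roc_auc(per_ligand[, c("score", "active")]), 1.0)
})

test_that("heavy score noise drives enrichment toward chance", {
  set.seed(24)
  efs <- vapply(1:30, function(i) {
    lib <- simulate_screening_library(n_actives = 20, n_decoy_ligands = 180,
      seed = 100 + i, rmsd_coupling = 0, noise_sd = 50)
    per_ligand <- screening_scores(lib, score = "score")
    enrichment_factor(per_ligand[, c("score", "active")], 0.1)
  }, numeric(1))
  expect_equal(mean(efs), 1.0, tolerance = 0.35)
})

test_that("screening library generation is reproducible bitwise", {
  a <- simulate_screening_library(n_actives = 5, n_decoy_ligands = 20, seed = 77)
  b <- simulate_screening_library(n_actives = 5, n_decoy_ligands = 20, seed = 77)
  expect_identical(a, b)
})

test_that("the training corpus carries labels, groups and schema intact", {
  corpus <- small_corpus()
  expect_equal(nrow(corpus), 12 * 11) # native + 10 decoys per complex
  expect_equal(sum(corpus$label == 0), 12) # one crystal pose per complex
  expect_identical(attr(corpus, "schema_id"), schema_id())
  expect_true(all(corpus$label >= 0))
  expect_equal(length(unique(corpus$complex_id)), 12)
})
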