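test_that("shell indexing follows half-open 1.5 A bins over 14 shells", {
  sc <- shell_scheme()
  expect_equal(max_shell_distance(sc), 21)
  expect_equal(shell_index(0, sc), 1L)
  expect_equal(shell_index(2.0, sc), 2L) # 1.5 <= 2.0 < 3.0
  expect_equal(shell_index(1.5, sc), 2L) # boundary goes to the outer shell
  expect_true(is.na(shell_index(21.0, sc)))
  expect_true(is.na(shell_index(300, sc)))
  expect_error(shell_index(-0.1, sc), class = "sfct_error_domain")
})

test_that("the feature schema is ordered and sized by its alphabets", {
  schema <- feature_schema()
  expect_equal(nrow(schema), 21 * 7 * 14)
  expect_equal(schema$residue_class[[1]], "ALA")
  expect_equal(schema$element_class[[1]], "C")
  expect_equal(schema$shell[[1]], 1L)
  # residue slowest, element next, shell fastest
  expect_equal(schema$shell[1:14], 1:14)
  expect_equal(schema$element_class[15], "N")
  expect_equal(unique(schema$residue_class), residue_classes())
  expect_equal(nrow(feature_schema(shell_scheme(n_shells = 2))), 21 * 7 * 2)
})

test_that("a hand-placed glycine/carbon pair populates the expected bins", {
  rec <- tibble::tibble(
    chain = "A", resno = 1L, resid = "GLY",
    atom = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
    x = c(2.9, 2.0, 3.2, 4.1), y = 0, z = 0
  )
  lig <- tibble::tibble(element = "C", x = 0, y = 0, z = 0)
  f <- featurize_complex(rec, lig)
  expect_equal(unname(f[["GLY_C_s02"]]), 2) # distances 2.0 and 2.9
  expect_equal(unname(f[["GLY_C_s03"]]), 2) # distances 3.2 and 4.1
  expect_equal(sum(f), 4)
})

test_that("a ligand far outside the shells produces an all-zero vector", {
  cpx <- generate_toy_complex(11, 8, 10)
  far <- translate_pose_set(cpx$ligand, c(500, 0, 0))
  f <- featurize_complex(cpx$receptor, pose_atoms(far, "native"))
  expect_length(f, 2058)
  expect_true(all(f == 0))
})

test_that("empty structures are rejected", {
  cpx <- generate_toy_complex(12, 8, 10)
  expect_error(
    featurize_complex(cpx$receptor[0, ], pose_atoms(cpx$ligand, "native")),
    class = "sfct_error_empty")
  expect_error(
    featurize_complex(cpx$receptor, pose_atoms(cpx$ligand, "native")[0, ]),
    class = "sfct_error_empty")
})

test_that("featurization agrees bin-for-bin with the brute-force oracle", {
  for (seed in 1:25) {
    cpx <- random_toy_complex(seed)
    lig <- pose_atoms(cpx$ligand, "native")
    fast <- featurize_complex(cpx$receptor, lig)
    slow <- brute_force_featurize(cpx$receptor, lig)
    expect_identical(unname(fast), unname(as.integer(slow)))
  }
})

test_that("feature counts are invariant under a common rigid transform", {
  cpx <- generate_toy_complex(21, 10, 14)
  lig <- pose_atoms(cpx$ligand, "native")
  f0 <- featurize_complex(cpx$receptor, lig)
  rot <- sfct:::rotation_about_axis(c(1, 2, 3), 1.1)
  shift <- c(5, -3, 2)
  transform <- function(m) sweep(as.matrix(m) %*% t(rot), 2, shift, "+")
  rec2 <- cpx$receptor
  rec2[, c("x", "y", "z")] <- transform(rec2[, c("x", "y", "z")])
  lig2 <- lig
  lig2[, c("x", "y", "z")] <- transform(lig[, c("x", "y", "z")])
  expect_equal(featurize_complex(rec2, lig2), f0)
})

test_that("shell-1 occupancy tracks the minimum receptor-ligand distance", {
  sc <- shell_scheme()
  shell1_count <- function(f) sum(f[grepl("_s01$", names(f))])
  for (seed in 31:36) {
    cpx <- random_toy_complex(seed)
    rec_xyz <- as.matrix(cpx$receptor[, c("x", "y", "z")])
    centroid <- colMeans(rec_xyz)
    lig <- pose_atoms(cpx$ligand, "native")
    dir <- colMeans(as.matrix(lig[, c("x", "y", "z")])) - centroid
    dir <- dir / sqrt(sum(dir^2))
    for (step in c(0, 2, 5, 10)) {
      moved <- translate_pose_set(cpx$ligand, dir * step)
      lig_m <- pose_atoms(moved, "native")
      f1 <- shell1_count(featurize_complex(cpx$receptor, lig_m, sc))
      dmin <- min(sfct:::cross_distances(rec_xyz,
        as.matrix(lig_m[, c("x", "y", "z")])))
      if (dmin >= 1.5) expect_equal(f1, 0L) else expect_gte(f1, 1L)
    }
  }
})

test_that("featurize_poses returns one labelled row per pose with schema id", {
  cpx <- generate_toy_complex(41, 8, 10)
  dec <- generate_decoys(cpx$ligand, n_decoys = 4, seed = 2)
  feats <- featurize_poses(cpx$receptor, dec$poses)
  expect_equal(nrow(feats), 4)
  expect_equal(ncol(feats), 2059)
  expect_equal(feats$pose_id, pose_ids(dec$poses))
  expect_identical(attr(feats, "schema_id"), schema_id())
})
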