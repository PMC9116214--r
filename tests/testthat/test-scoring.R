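test_that("hybrid score is the stated linear combination", {
  expect_equal(hybrid_score(-8, 4), -2)
  expect_equal(hybrid_score(-8, 4, alpha = 1, beta = 0), -8)
  expect_equal(hybrid_score(-8, 4, alpha = 0, beta = 1), 4)
  P <- rnorm(50); S <- abs(rnorm(50))
  expect_equal(hybrid_score(P, S), 0.5 * P + 0.5 * S)
  expect_error(hybrid_score(NA, 1), class = "sfct_error_domain")
  expect_error(hybrid_score(Inf, 1), class = "sfct_error_domain")
})

test_that("pose ranking is stable with documented tie-breaking", {
  data <- tibble::tibble(
    pose_id = c("pose1", "pose2", "pose3"),
    P = c(-4, -6.2, -4),
    S = c(0, 0, 0)
  )
  ranked <- rank_poses(data) # E = [-2, -3.1, -2]
  expect_equal(ranked$pose_id, c("pose2", "pose1", "pose3"))
  expect_equal(ranked$rank, 1:3)
  # equal E, different P: lower P wins
  data2 <- tibble::tibble(pose_id = c("a", "b"), P = c(-2, -4), S = c(2, 4))
  expect_equal(rank_poses(data2, alpha = 1, beta = 1)$pose_id, c("b", "a"))
})

test_that("beta = 0 reproduces the engine ranking exactly", {
  set.seed(4)
  data <- tibble::tibble(
    pose_id = as.character(1:30),
    P = rnorm(30),
    S = abs(rnorm(30))
  )
  ranked <- rank_poses(data, alpha = 1, beta = 0)
  expect_equal(ranked$pose_id, data$pose_id[order(data$P)])
})

test_that("shifting every docking score by a constant preserves rankings", {
  set.seed(5)
  data <- tibble::tibble(
    pose_id = as.character(1:25),
    P = rnorm(25),
    S = abs(rnorm(25))
  )
  r0 <- rank_poses(data)
  for (c_shift in c(-10, 3.7, 100)) {
    shifted <- dplyr::mutate(data, P = P + c_shift)
    r1 <- rank_poses(shifted)
    expect_equal(r1$pose_id, r0$pose_id)
    expect_equal(r1$E, r0$E + 0.5 * c_shift)
  }
})

test_that("rescoring a pose set with a model returns a full ranked table", {
  corpus_cpx <- generate_toy_complex(55, 8, 10)
  dec <- generate_decoys(corpus_cpx$ligand, n_decoys = 6, seed = 3)
  model <- small_model()
  scores <- tibble::tibble(
    pose_id = pose_ids(dec$poses),
    score = pseudo_docking_score(dec$labels$rmsd, seed = 8)
  )
  res <- rescore_poses(corpus_cpx$receptor, dec$poses, model, scores)
  expect_named(res, c("pose_id", "P", "S", "E", "rank"))
  expect_equal(nrow(res), 6)
  expect_equal(res$E, 0.5 * res$P + 0.5 * res$S)
  expect_true(all(res$S >= 0))
  expect_equal(res$rank, 1:6)
  # engine-only mode needs no model and matches score order
  engine <- rescore_poses(corpus_cpx$receptor, dec$poses, NULL, scores,
    alpha = 1, beta = 0)
  expect_equal(engine$pose_id, scores$pose_id[order(scores$score)])
  # missing scores are an error when alpha != 0
  expect_error(
    rescore_poses(corpus_cpx$receptor, dec$poses, model, scores[1:3, ]),
    class = "sfct_error_missing_score")
})

test_that("ligand screening scores take the best of at most 20 poses", {
  expect_equal(ligand_screening_score(c(-1, -4, -2)), -4)
  expect_equal(ligand_screening_score(-7), -7)
  scores <- c(seq(-1, -3, length.out = 22), -9, 0, 0)
  scores <- scores[1:25]
  scores[23] <- -99 # global best past the cap
  expect_gt(ligand_screening_score(scores), -99)
  expect_equal(ligand_screening_score(scores), min(scores[1:20]))
  expect_error(ligand_screening_score(numeric(0)), class = "sfct_error_empty")
})

test_that("screening_scores collapses pose tables per ligand with metadata", {
  data <- tibble::tibble(
    ligand_id = rep(c("a", "b"), each = 3),
    active = rep(c(TRUE, FALSE), each = 3),
    pose_id = as.character(rep(1:3, 2)),
    E = c(-1, -4, -2, -3, -1, -2)
  )
  out <- screening_scores(data)
  expect_equal(out$score[out$ligand_id == "a"], -4)
  expect_equal(out$score[out$ligand_id == "b"], -3)
  expect_equal(out$active, c(TRUE, FALSE))
})

test_that("reverse screening ranks proteins by their best pocket score", {
  data <- tibble::tibble(
    protein_id = c("A", "A", "B"),
    score = c(-3, -5, -4)
  )
  out <- rank_proteins_reverse(data)
  expect_equal(out$protein_id, c("A", "B"))
  expect_equal(out$best_score, c(-5, -4))
  # ties resolve lexicographically
  tied <- tibble::tibble(protein_id = c("zeta", "alpha", "mid"), score = -2)
  expect_equal(rank_proteins_reverse(tied)$protein_id,
    c("alpha", "mid", "zeta"))
  single <- rank_proteins_reverse(tibble::tibble(protein_id = "X", score = 1))
  expect_equal(single$rank, 1L)
  expect_error(rank_proteins_reverse(tibble::tibble(protein_id = character(),
    score = numeric())), class = "sfct_error_empty")
})
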