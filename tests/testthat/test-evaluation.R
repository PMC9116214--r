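top1_cases <- function(rmsds) {
  tibble::tibble(case_id = as.character(seq_along(rmsds)), rmsd = rmsds)
}

test_that("success rate counts top-ranked poses against the 2 A cutoff", {
  cases <- top1_cases(c(1.2, 3.5, 0.8, 2.0))
  expect_equal(success_rate(cases), 0.75) # inclusive boundary
  expect_equal(success_rate(cases, strict = TRUE), 0.5)
  expect_equal(success_rate(top1_cases(rep(0, 5))), 1.0)
  multi <- tibble::tibble(case_id = rep("c1", 3), rmsd = c(5, 1.9, 8))
  expect_equal(success_rate(multi, top_n = 1), 0)
  expect_equal(success_rate(multi, top_n = 3), 1)
  expect_error(success_rate(top1_cases(numeric(0))), class = "sfct_error_empty")
})

test_that("success rate is monotone in top_n and cutoff", {
  set.seed(6)
  cases <- tibble::tibble(
    case_id = rep(as.character(1:20), each = 5),
    rmsd = runif(100, 0, 10)
  )
  sr <- vapply(1:5, function(k) success_rate(cases, top_n = k), numeric(1))
  expect_true(all(diff(sr) >= 0))
  sc <- vapply(c(1, 2, 4, 8), function(cut) success_rate(cases, cutoff = cut),
    numeric(1))
  expect_true(all(diff(sc) >= 0))
})

test_that("average top-k RMSD averages the best-ranked poses", {
  expect_equal(average_topk_rmsd(top1_cases(c(1, 2, 3))), 2.0)
  expect_equal(average_topk_rmsd(top1_cases(4.2)), 4.2)
  multi <- tibble::tibble(case_id = rep(c("a", "b"), each = 2),
    rmsd = c(1, 3, 2, 6))
  expect_equal(average_topk_rmsd(multi, k = 2), mean(c(2, 4)))
  expect_error(average_topk_rmsd(multi, k = 3), class = "sfct_error_domain")
})

test_that("enrichment factor matches its closed form", {
  # 1000 ligands, 10 actives, 5 of them inside the top-1% bucket
  score <- seq_len(1000) / 100
  active <- rep(FALSE, 1000)
  active[c(1, 3, 5, 7, 9, 900, 920, 940, 960, 980)] <- TRUE
  set <- tibble::tibble(score = score, active = active)
  expect_equal(enrichment_factor(set, 0.01), 50)
  # all actives ranked last
  worst <- tibble::tibble(score = score,
    active = c(rep(FALSE, 990), rep(TRUE, 10)))
  expect_equal(enrichment_factor(worst, 0.01), 0)
  expect_error(enrichment_factor(tibble::tibble(score = 1:3,
    active = rep(FALSE, 3))), class = "sfct_error_domain")
})

test_that("enrichment factor respects its theoretical upper bound", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(50:500, 1)
    n_act <- sample(1:20, 1)
    set <- tibble::tibble(score = rnorm(n),
      active = sample(c(rep(TRUE, n_act), rep(FALSE, n - n_act))))
    frac <- sample(c(0.01, 0.05, 0.1, 0.5), 1)
    ef <- enrichment_factor(set, frac)
    bucket <- ceiling(frac * n)
    expect_lte(ef, min(n / bucket, n / n_act) + 1e-9)
    expect_gte(ef, 0)
  }
})

test_that("random scores give enrichment near one on average", {
  set.seed(9)
  efs <- vapply(1:200, function(i) {
    set <- tibble::tibble(score = rnorm(500),
      active = sample(c(rep(TRUE, 25), rep(FALSE, 475))))
    enrichment_factor(set, 0.05)
  }, numeric(1))
  expect_equal(mean(efs), 1.0, tolerance = 0.2)
})

test_that("ROC-AUC follows the Mann-Whitney formulation with ties at half", {
  perfect <- tibble::tibble(score = c(1, 2, 3, 10, 11, 12),
    active = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(roc_auc(perfect), 1.0)
  tied <- tibble::tibble(score = rep(5, 6),
    active = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(roc_auc(tied), 0.5)
  toy <- tibble::tibble(score = c(1, 3, 2, 4),
    active = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc_auc(toy), 0.75)
  expect_error(roc_auc(tibble::tibble(score = 1:3, active = rep(TRUE, 3))),
    class = "sfct_error_domain")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(10)
  base <- tibble::tibble(score = rnorm(200),
    active = sample(c(rep(TRUE, 40), rep(FALSE, 160))))
  a0 <- roc_auc(base)
  for (f in list(function(x) 3 * x - 7, function(x) exp(x),
    function(x) x^3 + x)) {
    expect_equal(roc_auc(dplyr::mutate(base, score = f(score))), a0)
  }
})

test_that("our AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  set <- tibble::tibble(score = rnorm(300) + rep(c(-1, 0), c(60, 240)),
    active = rep(c(TRUE, FALSE), c(60, 240)))
  ours <- roc_auc(set)
  # pROC: direction ">" means controls (decoys) have higher scores
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = set$active, predictor = set$score,
    direction = ">", levels = c(FALSE, TRUE), quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("screening_report assembles EF curves and AUC in one table", {
  set.seed(12)
  set <- tibble::tibble(score = rnorm(400),
    active = sample(c(rep(TRUE, 20), rep(FALSE, 380))))
  rep_tbl <- screening_report(set)
  expect_equal(nrow(rep_tbl), 4)
  expect_equal(rep_tbl$value[rep_tbl$metric == "AUC"], roc_auc(set))
  expect_equal(rep_tbl$value[1], enrichment_factor(set, 0.01))
})
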