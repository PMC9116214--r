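#' Docking success rate
#'
#' Fraction of cases whose best pose among the `top_n` highest-ranked poses
#' is within `cutoff` Å of the native pose. The boundary is inclusive
#' (`<= 2` Å by default, the CASF convention); set `strict = TRUE` for a
#' strict `<` comparison.
#'
#' @param cases Tibble with columns `case_id` and `rmsd`; within each case,
#'   rows must be in rank order (best-ranked pose first).
#' @param top_n Number of top-ranked poses considered per case.
#' @param cutoff Success cutoff in Å (default 2.0).
#' @param strict Use `<` instead of `<=` at the boundary.
#' @return Fraction in `[0, 1]`.
#' @examples
#' cases <- tibble::tibble(case_id = c("a", "b", "c", "d"),
#'                         rmsd = c(1.2, 3.5, 0.8, 2.0))
#' success_rate(cases) # 0.75
#' @export
success_rate <- function(cases, top_n = 1L, cutoff = 2.0, strict = FALSE) {
  check_cases(cases)
  if (top_n < 1) sfct_abort("top_n must be >= 1", "sfct_error_domain")
  per_case <- tapply(cases$rmsd, factor(cases$case_id, levels = unique(cases$case_id)),
    function(r) min(r[seq_len(min(length(r), top_n))]))
  hit <- if (strict) per_case < cutoff else per_case <= cutoff
  mean(hit)
}

#' Mean RMSD of the top-ranked poses
#'
#' Averages, over cases, the RMSD of each case's `k` best-ranked poses
#' (with `k = 1`, the top pose's RMSD). Lower values indicate a scoring
#' function that ranks near-native poses first.
#'
#' @inheritParams success_rate
#' @param k Number of top-ranked poses averaged within each case.
#' @return Mean RMSD in Å.
#' @export
average_topk_rmsd <- function(cases, k = 1L) {
  check_cases(cases)
  per_case <- tapply(cases$rmsd, factor(cases$case_id, levels = unique(cases$case_id)),
    function(r) {
      if (length(r) < k) {
        sfct_abort("a case has fewer poses than k", "sfct_error_domain")
      }
      mean(r[seq_len(k)])
    })
  mean(per_case)
}

check_cases <- function(cases) {
  if (is.null(cases) || nrow(cases) == 0) {
    sfct_abort("no docking cases supplied", "sfct_error_empty")
  }
  if (!all(c("case_id", "rmsd") %in% names(cases))) {
    sfct_abort("cases need columns case_id and rmsd", "sfct_error_domain")
  }
  if (any(cases$rmsd < 0)) {
    sfct_abort("RMSD values must be non-negative", "sfct_error_domain")
  }
}

#' Enrichment factor at a screening fraction
#'
#' Concentration of active ligands among the top-scoring fraction of the
#' ranked library, relative to their concentration in the whole library:
#' `EF = (actives in top bucket / bucket size) / (total actives / N)`, with
#' bucket size `ceiling(fraction * N)`. Ranking is ascending by score (lower
#' is better), ties broken by stable input order.
#'
#' @param data Tibble with numeric `score` (lower = better) and logical
#'   `active` columns, one row per ligand.
#' @param fraction Top fraction of the library (default 0.01, i.e. EF1%).
#' @return The enrichment factor (`>= 0`).
#' @examples
#' set.seed(1)
#' lib <- tibble::tibble(score = rnorm(1000),
#'                       active = c(rep(TRUE, 10), rep(FALSE, 990)))
#' enrichment_factor(lib, 0.01)
#' @export
enrichment_factor <- function(data, fraction = 0.01) {
  check_screening(data)
  if (fraction <= 0 || fraction > 1) {
    sfct_abort("fraction must be in (0, 1]", "sfct_error_domain")
  }
  n <- nrow(data)
  n_active <- sum(data$active)
  if (n_active == 0) {
    sfct_abort("enrichment factor is undefined with no actives",
      "sfct_error_domain")
  }
  bucket <- ceiling(fraction * n)
  ord <- order(data$score) # stable: ties keep input order
  top_active <- sum(data$active[ord][seq_len(bucket)])
  (top_active / bucket) / (n_active / n)
}

#' ROC-AUC for active/decoy screening
#'
#' Probability that a randomly chosen active scores better (lower) than a
#' randomly chosen decoy, with ties counted one half (the Mann-Whitney
#' formulation). Invariant under any strictly monotone transform of the
#' scores.
#'
#' @param data Tibble with numeric `score` (lower = better) and logical
#'   `active` columns.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(tibble::tibble(score = c(1, 3, 2, 4),
#'                        active = c(TRUE, TRUE, FALSE, FALSE))) # 0.75
#' @export
roc_auc <- function(data) {
  check_screening(data)
  n_active <- sum(data$active)
  n_decoy <- sum(!data$active)
  if (n_active == 0 || n_decoy == 0) {
    sfct_abort("AUC needs at least one active and one decoy",
      "sfct_error_domain")
  }
  r <- rank(data$score, ties.method = "average")
  # pairs where the active scores worse than the decoy (ties count 1/2)
  u_worse <- sum(r[data$active]) - n_active * (n_active + 1) / 2
  1 - u_worse / (n_active * n_decoy)
}

check_screening <- function(data) {
  if (is.null(data) || nrow(data) == 0) {
    sfct_abort("empty screening set", "sfct_error_empty")
  }
  if (!all(c("score", "active") %in% names(data))) {
    sfct_abort("screening set needs columns score and active",
      "sfct_error_domain")
  }
  if (!is.logical(data$active)) {
    sfct_abort("column 'active' must be logical", "sfct_error_domain")
  }
}

#' Screening metric report
#'
#' Convenience wrapper computing the enrichment factor at several fractions
#' plus the ROC-AUC for one ranked library.
#'
#' @param data Tibble with `score` and `active` columns.
#' @param fractions Numeric vector of top fractions.
#' @return Tibble `metric`, `fraction`, `value`.
#' @export
screening_report <- function(data, fractions = c(0.01, 0.05, 0.10)) {
  ef <- tibble(
    metric = "EF",
    fraction = fractions,
    value = vapply(fractions, function(f) enrichment_factor(data, f), numeric(1))
  )
  bind_rows(ef, tibble(metric = "AUC", fraction = NA_real_, value = roc_auc(data)))
}
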