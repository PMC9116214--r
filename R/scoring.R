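#' Hybrid pose score
#'
#' Linear combination of a docking score `P` (kcal/mol, lower is better) and
#' the correction term `S` (predicted pose RMSD, Å):
#' `E = alpha * P + beta * S`. Despite the unit mismatch, the predicted RMSD
#' behaves as a pseudo-free-energy penalty: it is zero only for the native
#' pose and grows as a pose strays from it. The default weights
#' `alpha = beta = 0.5` were calibrated for the Vina score; for other engines
#' they are usable but not tuned.
#'
#' @param P Numeric docking score(s).
#' @param S Numeric predicted RMSD(s), Å (`>= 0`).
#' @param alpha,beta Combination weights.
#' @return `E = alpha * P + beta * S`, lower is better.
#' @examples
#' hybrid_score(-8, 4) # -2
#' @export
hybrid_score <- function(P, S, alpha = 0.5, beta = 0.5) {
  if (any(!is.finite(P)) || any(!is.finite(S)) ||
    !is.finite(alpha) || !is.finite(beta)) {
    sfct_abort("hybrid_score requires finite inputs", "sfct_error_domain")
  }
  alpha * P + beta * S
}

#' Rank a pose table by hybrid score
#'
#' Adds `E = alpha*P + beta*S` and a deterministic rank: ascending `E`, ties
#' broken by lower `P`, then stable input order.
#'
#' @param data Tibble with columns `pose_id`, `P`, `S`.
#' @param alpha,beta Combination weights (see [hybrid_score()]).
#' @return The input tibble with `E` and `rank` columns, sorted by rank.
#' @export
rank_poses <- function(data, alpha = 0.5, beta = 0.5) {
  if (!all(c("pose_id", "P", "S") %in% names(data))) {
    sfct_abort("rank_poses needs columns pose_id, P, S", "sfct_error_domain")
  }
  out <- data |>
    mutate(
      E = hybrid_score(.data$P, .data$S, alpha, beta),
      .input_order = row_number()
    ) |>
    arrange(.data$E, .data$P, .data$.input_order) |>
    mutate(rank = row_number()) |>
    select(-".input_order")
  out
}

#' Rescore docked poses with the correction term
#'
#' Featurizes every pose against the receptor, predicts each pose's RMSD
#' with the trained model, combines it with the docking score, and returns
#' the poses ranked by the hybrid score. With `beta = 0` the ranking reduces
#' exactly to the docking engine's; with `alpha = 0` poses are ranked by the
#' correction term alone (pure RMSD-predicted rescoring).
#'
#' @param receptor Receptor tibble from [read_receptor()].
#' @param poses An `sfct_poses` object.
#' @param model A trained [sfct_model][train_sfct()] (may be `NULL` when
#'   `beta = 0`).
#' @param scores Tibble `pose_id`, `score` with the engine scores; when
#'   `NULL`, `source_score` embedded in the pose file is used. Required
#'   (non-missing for every pose) unless `alpha = 0`.
#' @param alpha,beta Combination weights.
#' @param scheme The [shell_scheme()] matching the model.
#' @return Tibble `pose_id`, `P`, `S`, `E`, `rank`, sorted by rank.
#' @export
rescore_poses <- function(receptor, poses, model, scores = NULL,
                          alpha = 0.5, beta = 0.5, scheme = shell_scheme()) {
  ids <- pose_ids(poses)
  P <- if (is.null(scores)) {
    poses$poses$source_score
  } else {
    scores$score[match(ids, scores$pose_id)]
  }
  if (alpha != 0 && any(is.na(P))) {
    sfct_abort("docking scores missing for some poses and alpha != 0",
      "sfct_error_missing_score")
  }
  P[is.na(P)] <- 0
  S <- if (beta != 0) {
    if (is.null(model)) {
      sfct_abort("a trained model is required when beta != 0",
        "sfct_error_state")
    }
    predict(model, featurize_poses(receptor, poses, scheme))
  } else {
    rep(0, length(ids))
  }
  rank_poses(tibble(pose_id = ids, P = P, S = S), alpha, beta)
}

#' Ligand-level screening score
#'
#' In virtual screening each ligand is represented by the best (lowest)
#' hybrid score among its generated poses, capped at the first `max_poses`
#' poses in input order (engines emit poses best-first; the reference
#' protocol caps at 20).
#'
#' @param scores Numeric vector of per-pose scores in engine output order.
#' @param max_poses Pose cap (default 20).
#' @return The minimum score among the first `max_poses` entries.
#' @export
ligand_screening_score <- function(scores, max_poses = 20L) {
  if (length(scores) == 0) {
    sfct_abort("ligand has no poses", "sfct_error_empty")
  }
  min(scores[seq_len(min(length(scores), max_poses))])
}

#' Per-ligand screening scores for a pose table
#'
#' Tidy wrapper: collapses a pose-level table to one best score per ligand
#' via [ligand_screening_score()], preserving per-ligand metadata columns
#' (e.g. the active/decoy label) that are constant within a ligand.
#'
#' @param data Tibble with `ligand_id`, a score column, poses in engine
#'   output order within each ligand.
#' @param score Name of the score column (default `"E"`).
#' @param max_poses Pose cap per ligand.
#' @return Tibble with one row per ligand: `ligand_id`, `score`, plus any
#'   constant metadata columns.
#' @export
screening_scores <- function(data, score = "E", max_poses = 20L) {
  if (!"ligand_id" %in% names(data) || !score %in% names(data)) {
    sfct_abort(sprintf("screening_scores needs columns ligand_id and %s", score),
      "sfct_error_domain")
  }
  meta_cols <- setdiff(names(data), c("ligand_id", "pose_id", score))
  constant <- vapply(meta_cols, function(col) {
    all(tapply(data[[col]], data$ligand_id, function(v) length(unique(v)) == 1))
  }, logical(1))
  meta <- meta_cols[constant]
  out <- data |>
    group_by(.data$ligand_id) |>
    summarise(
      score = ligand_screening_score(.data[[score]], max_poses),
      across(all_of(meta), first),
      .groups = "drop"
    )
  out
}

#' Rank proteins in a reverse (target-fishing) screen
#'
#' In reverse screening one ligand is docked into candidate pockets of many
#' proteins; each protein's affinity for the ligand is summarized as the
#' lowest score over all of its pockets, and proteins are ranked ascending
#' (ties broken lexicographically by protein id).
#'
#' @param data Tibble with columns `protein_id` and `score` (one row per
#'   pocket-level best score).
#' @return Tibble `protein_id`, `best_score`, `rank`, sorted by rank.
#' @export
rank_proteins_reverse <- function(data) {
  if (nrow(data) == 0) {
    sfct_abort("no protein scores supplied", "sfct_error_empty")
  }
  data |>
    group_by(.data$protein_id) |>
    summarise(best_score = min(.data$score), .groups = "drop") |>
    arrange(.data$best_score, .data$protein_id) |>
    mutate(rank = row_number())
}
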