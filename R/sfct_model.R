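#' Hyperparameters of the boosted-forest RMSD regressor
#'
#' The correction-term model is an AdaBoost.R2 ensemble of random forests.
#' Defaults follow the reference configuration: 10 boosting rounds, each a
#' 50-tree forest drawing 512 candidate features per split with maximum tree
#' depth 50 and out-of-bag error tracking.
#'
#' @param n_boost_rounds Number of boosting rounds (base forests).
#' @param trees_per_forest Trees per random forest.
#' @param max_features Candidate features per split (`mtry`); must not
#'   exceed the feature-vector length at training time.
#' @param max_depth Maximum tree depth.
#' @param use_oob Track out-of-bag error of each forest.
#' @param boosting_loss AdaBoost.R2 loss: `"linear"`, `"square"` or
#'   `"exponential"`.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return An object of class `sfct_hyperparams`.
#' @export
sfct_hyperparams <- function(n_boost_rounds = 10L, trees_per_forest = 50L,
                             max_features = 512L, max_depth = 50L,
                             use_oob = TRUE,
                             boosting_loss = c("linear", "square", "exponential"),
                             seed = 42L) {
  boosting_loss <- match.arg(boosting_loss)
  hp <- list(
    n_boost_rounds = as.integer(n_boost_rounds),
    trees_per_forest = as.integer(trees_per_forest),
    max_features = as.integer(max_features),
    max_depth = as.integer(max_depth),
    use_oob = isTRUE(use_oob),
    boosting_loss = boosting_loss,
    seed = as.integer(seed)
  )
  counts <- c(hp$n_boost_rounds, hp$trees_per_forest, hp$max_features, hp$max_depth)
  if (any(is.na(counts)) || any(counts < 1)) {
    sfct_abort("all hyperparameter counts must be >= 1", "sfct_error_domain")
  }
  structure(hp, class = "sfct_hyperparams")
}

#' Exclude far-off poses from a training set
#'
#' Poses whose RMSD label exceeds `max_label` are generally far outside the
#' binding site and add label noise, so they are excluded before training.
#' The rule is strict: a label exactly at `max_label` (default 10 Å) is
#' retained, only labels `> max_label` are dropped.
#'
#' @param data Tibble with a numeric `label` column (RMSD, Å).
#' @param max_label Retention threshold in Å.
#' @return The filtered tibble (attributes preserved); the number of removed
#'   rows is reported via a message.
#' @export
filter_training_poses <- function(data, max_label = 10.0) {
  if (!"label" %in% names(data)) {
    sfct_abort("training data must have a 'label' column", "sfct_error_domain")
  }
  keep <- data$label <= max_label
  removed <- sum(!keep)
  if (removed > 0) {
    inform(sprintf("filter_training_poses: removed %d pose(s) with label > %g A",
      removed, max_label))
  }
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    sfct_abort("no poses remain after label filtering", "sfct_error_empty")
  }
  attr(out, "schema_id") <- attr(data, "schema_id")
  out
}

feature_columns <- function(data, scheme) {
  bins <- feature_schema(scheme)$bin
  missing <- setdiff(bins, names(data))
  if (length(missing) > 0) {
    sfct_abort(sprintf(
      "training data is missing %d feature column(s) of the schema (e.g. %s)",
      length(missing), missing[[1]]), "sfct_error_schema")
  }
  bins
}

#' Train the boosted-forest RMSD regressor
#'
#' Fits an AdaBoost.R2 ensemble of random forests mapping contact-count
#' feature vectors to pose RMSD (Å). Each round fits a forest with the
#' current sample weights as bootstrap sampling weights, computes the
#' weight-averaged loss of the round, derives the round's confidence
#' `log(1/beta)`, and concentrates weight on poorly predicted poses.
#' Prediction is the ensemble's weighted median, clamped at 0 Å.
#'
#' @param data Tibble containing a numeric `label` column (RMSD, Å), the
#'   feature columns named by [feature_schema()], and optionally `pose_id` /
#'   `complex_id` bookkeeping columns (ignored by the fit).
#' @param hyperparams An [sfct_hyperparams()] object.
#' @param scheme The [shell_scheme()] the features were computed with.
#' @return An object of class `sfct_model`.
#' @seealso [predict.sfct_model()], [feature_importance()], [save_sfct()]
#' @export
train_sfct <- function(data, hyperparams = sfct_hyperparams(),
                       scheme = shell_scheme()) {
  bins <- feature_columns(data, scheme)
  if (hyperparams$max_features > length(bins)) {
    sfct_abort(sprintf(
      "max_features (%d) exceeds the feature length (%d)",
      hyperparams$max_features, length(bins)), "sfct_error_domain")
  }
  y <- data$label
  if (any(!is.finite(y)) || any(y < 0)) {
    sfct_abort("labels must be finite and non-negative", "sfct_error_domain")
  }
  if (length(unique(y)) < 2) {
    sfct_abort("labels are degenerate (all equal); nothing to regress",
      "sfct_error_domain")
  }
  x <- as.matrix(data[, bins])
  storage.mode(x) <- "double"
  n <- nrow(x)

  w <- rep(1 / n, n)
  forests <- list()
  est_weights <- numeric(0)
  oob <- numeric(0)
  avg_losses <- numeric(0)
  for (m in seq_len(hyperparams$n_boost_rounds)) {
    fit <- ranger::ranger(
      x = x, y = y,
      num.trees = hyperparams$trees_per_forest,
      mtry = hyperparams$max_features,
      max.depth = hyperparams$max_depth,
      importance = "impurity",
      oob.error = hyperparams$use_oob,
      case.weights = w,
      seed = hyperparams$seed + m,
      num.threads = 1,
      verbose = FALSE
    )
    pred <- predict(fit, data = x, num.threads = 1)$predictions
    err <- abs(pred - y)
    d_max <- max(err)
    if (d_max <= 0) {
      # perfect fit: keep this round with full confidence and stop
      forests[[length(forests) + 1L]] <- fit
      est_weights <- c(est_weights, log(1 / 1e-10))
      oob <- c(oob, if (hyperparams$use_oob) fit$prediction.error else NA_real_)
      avg_losses <- c(avg_losses, 0)
      break
    }
    loss <- switch(hyperparams$boosting_loss,
      linear = err / d_max,
      square = (err / d_max)^2,
      exponential = 1 - exp(-err / d_max)
    )
    l_bar <- sum(w * loss)
    if (l_bar >= 0.5) {
      if (length(forests) == 0) {
        # keep a single weak round rather than fail outright
        forests[[1L]] <- fit
        est_weights <- 1
        oob <- if (hyperparams$use_oob) fit$prediction.error else NA_real_
        avg_losses <- l_bar
      }
      break
    }
    beta <- max(l_bar / (1 - l_bar), 1e-10)
    forests[[length(forests) + 1L]] <- fit
    est_weights <- c(est_weights, log(1 / beta))
    oob <- c(oob, if (hyperparams$use_oob) fit$prediction.error else NA_real_)
    avg_losses <- c(avg_losses, l_bar)
    w <- w * beta^(1 - loss)
    w <- w / sum(w)
  }

  structure(
    list(
      forests = forests,
      estimator_weights = est_weights,
      hyperparams = hyperparams,
      scheme = scheme,
      schema_id = schema_id(scheme),
      feature_names = bins,
      training = list(
        n_poses = n,
        label_range = range(y),
        n_rounds_used = length(forests),
        oob_mse = oob,
        avg_loss = avg_losses
      ),
      version = 1L
    ),
    class = "sfct_model"
  )
}

#' @export
print.sfct_model <- function(x, ...) {
  cat(sprintf(
    "<sfct_model> %d boosting round(s) x %d-tree forests on %d features\n",
    x$training$n_rounds_used, x$hyperparams$trees_per_forest,
    length(x$feature_names)))
  cat(sprintf("  trained on %d poses, labels %.2f-%.2f A\n",
    x$training$n_poses, x$training$label_range[1], x$training$label_range[2]))
  invisible(x)
}

#' Predict pose RMSD with a trained correction-term model
#'
#' Returns the ensemble's weighted-median prediction per pose, clamped to
#' `>= 0` Å (RMSD is non-negative; raw ensemble output can dip below zero on
#' extrapolation). Features must have been computed under the same shell
#' scheme the model was trained with; a `schema_id` mismatch is an error.
#'
#' @param object An `sfct_model`.
#' @param newdata Tibble (or matrix) containing the model's feature columns;
#'   typically the output of [featurize_poses()]. A zero-row input yields a
#'   zero-length result.
#' @param ... Unused.
#' @return Numeric vector of predicted RMSDs (Å), one per row of `newdata`.
#' @export
predict.sfct_model <- function(object, newdata, ...) {
  sid <- attr(newdata, "schema_id")
  if (!is.null(sid) && !identical(sid, object$schema_id)) {
    sfct_abort("feature schema of newdata does not match the model's schema",
      "sfct_error_schema")
  }
  if (is.matrix(newdata)) {
    x <- newdata
    if (!is.null(colnames(x))) x <- x[, object$feature_names, drop = FALSE]
  } else {
    missing <- setdiff(object$feature_names, names(newdata))
    if (length(missing) > 0) {
      sfct_abort(sprintf("newdata is missing %d model feature column(s)",
        length(missing)), "sfct_error_schema")
    }
    x <- as.matrix(newdata[, object$feature_names])
  }
  storage.mode(x) <- "double"
  if (nrow(x) == 0) return(numeric(0))
  preds <- vapply(object$forests, function(f) {
    predict(f, data = x, num.threads = 1)$predictions
  }, numeric(nrow(x)))
  if (nrow(x) == 1) preds <- matrix(preds, nrow = 1)
  out <- weighted_median_rows(preds, object$estimator_weights)
  pmax(out, 0)
}

# AdaBoost.R2 combines rounds by the weighted median of their predictions.
weighted_median_rows <- function(pred_matrix, weights) {
  total <- sum(weights)
  apply(pred_matrix, 1, function(p) {
    o <- order(p)
    cw <- cumsum(weights[o])
    p[o][which(cw >= 0.5 * total)[1]]
  })
}

#' Predict RMSDs as a tibble
#'
#' Tidy wrapper around [predict.sfct_model()] keeping the `pose_id` column.
#'
#' @param model An `sfct_model`.
#' @param features Output of [featurize_poses()] (must contain `pose_id`).
#' @return Tibble `pose_id`, `predicted_rmsd`.
#' @export
predict_sfct <- function(model, features) {
  tibble(
    pose_id = if ("pose_id" %in% names(features)) features$pose_id else
      as.character(seq_len(nrow(features))),
    predicted_rmsd = predict(model, features)
  )
}

#' Per-bin feature importance
#'
#' Impurity importances of each forest, combined across boosting rounds
#' weighted by the rounds' confidences and normalized to sum to one. The
#' result maps directly onto the contact bins, so it can be reshaped into a
#' residue-class x ligand-element x distance-shell importance map.
#'
#' @param model A trained `sfct_model`.
#' @return Tibble `residue_class`, `element_class`, `shell`, `bin`,
#'   `importance` (sums to 1).
#' @seealso [plot_feature_importance()]
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "sfct_model") || length(model$forests) == 0) {
    sfct_abort("feature_importance requires a trained sfct_model",
      "sfct_error_state")
  }
  imp <- Reduce(`+`, lapply(seq_along(model$forests), function(i) {
    v <- model$forests[[i]]$variable.importance
    model$estimator_weights[[i]] * pmax(v, 0)
  }))
  imp <- imp / sum(imp)
  schema <- feature_schema(model$scheme)
  schema$importance <- as.numeric(imp[match(schema$bin, names(imp))])
  schema
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Broom-style methods for the fitted model
#'
#' `tidy()` returns the per-bin feature-importance table;
#' `glance()` a one-row model summary.
#'
#' @param x An `sfct_model`.
#' @param ... Unused.
#' @method tidy sfct_model
#' @export
tidy.sfct_model <- function(x, ...) feature_importance(x)

#' @rdname tidy.sfct_model
#' @method glance sfct_model
#' @export
glance.sfct_model <- function(x, ...) {
  tibble(
    n_poses = x$training$n_poses,
    n_features = length(x$feature_names),
    n_rounds = x$training$n_rounds_used,
    label_min = x$training$label_range[1],
    label_max = x$training$label_range[2],
    mean_oob_mse = mean(x$training$oob_mse, na.rm = TRUE)
  )
}

#' Save / load a correction-term model
#'
#' The artifact is a single versioned file embedding the feature `schema_id`
#' and hyperparameters; `load_sfct()` refuses files with an unknown format
#' tag or (when `expect_schema_id` is given) a mismatching schema.
#'
#' @param model An `sfct_model`.
#' @param path File path for the model artifact.
#' @param expect_schema_id Optional schema id the caller requires.
#' @return `save_sfct()` returns `path` invisibly; `load_sfct()` the model.
#' @export
save_sfct <- function(model, path) {
  stopifnot(inherits(model, "sfct_model"))
  payload <- list(format = "sfct_model", version = model$version, model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_sfct
#' @export
load_sfct <- function(path, expect_schema_id = NULL) {
  payload <- tryCatch(readRDS(path), error = function(e) {
    sfct_abort(paste0("cannot read model file '", path, "': ",
      conditionMessage(e)), "sfct_error_format")
  })
  if (!is.list(payload) || !identical(payload$format, "sfct_model")) {
    sfct_abort("file is not an sfct model artifact", "sfct_error_format")
  }
  if (!identical(payload$version, 1L)) {
    sfct_abort(paste0("unsupported model artifact version: ", payload$version),
      "sfct_error_format")
  }
  model <- payload$model
  if (!is.null(expect_schema_id) && !identical(model$schema_id, expect_schema_id)) {
    sfct_abort("model was trained under a different feature schema",
      "sfct_error_schema")
  }
  model
}
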