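#' Feature-importance heatmap
#'
#' Draws the per-bin importances of a trained model as distance-shell x
#' ligand-element tiles, faceted by residue class -- the standard way to
#' read which residue/element contacts at which distances drive the RMSD
#' prediction (e.g. short-range ligand N or O contacts with charged
#' residues).
#'
#' @param importance Tibble from [feature_importance()] (or a fitted
#'   `sfct_model`, via `autoplot()`).
#' @param scheme The [shell_scheme()] used, for distance axis labels.
#' @return A ggplot object.
#' @export
plot_feature_importance <- function(importance, scheme = shell_scheme()) {
  if (inherits(importance, "sfct_model")) {
    scheme <- importance$scheme
    importance <- feature_importance(importance)
  }
  importance$distance <- scheme$origin + (importance$shell - 0.5) * scheme$shell_width
  importance$element_class <- factor(importance$element_class,
    levels = rev(ELEMENT_CLASSES))
  ggplot2::ggplot(importance,
    ggplot2::aes(x = .data$distance, y = .data$element_class,
      fill = .data$importance)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~residue_class) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "contact distance (Å)", y = "ligand element class",
      fill = "importance"
    ) +
    ggplot2::theme_minimal(base_size = 9)
}

#' @rdname plot_feature_importance
#' @param object A fitted `sfct_model`.
#' @param ... Unused.
#' @export
autoplot.sfct_model <- function(object, ...) {
  plot_feature_importance(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Top-1 RMSD before/after rescoring
#'
#' Scatter of each complex's top-ranked-pose RMSD under the engine score
#' (x) versus under the hybrid score (y); points below the diagonal are
#' complexes the correction term improved. Dashed lines mark the 2 Å
#' success cutoff.
#'
#' @param comparison Tibble from [compare_rankings()].
#' @param cutoff Success cutoff to annotate, Å.
#' @return A ggplot object.
#' @export
plot_rescoring <- function(comparison, cutoff = 2.0) {
  ggplot2::ggplot(comparison,
    ggplot2::aes(x = .data$top1_rmsd_engine, y = .data$top1_rmsd_hybrid)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed",
      color = "grey40") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed",
      color = "grey40") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "top-1 pose RMSD, engine score (Å)",
      y = "top-1 pose RMSD, hybrid score (Å)"
    ) +
    ggplot2::theme_minimal()
}
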