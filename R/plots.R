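#' Plot an enrichment profile with its confidence band
#'
#' @param profile Replicate-averaged enrichment profile
#'   ([average_replicates()]) for one or more genes.
#' @param threshold Optional horizontal reference (e.g. the onset
#'   threshold 1.5).
#' @return A ggplot object (one facet per gene).
#' @export
plot_enrichment <- function(profile, threshold = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$codon, y = .data$ratio)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "darkgreen", alpha = 0.25) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::facet_wrap(~gene_id, scales = "free_x") +
    ggplot2::labs(x = "codon", y = "enrichment (selected / total)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  }
  p
}

#' Plot per-codon model binding profiles
#'
#' @param prediction Output of [binding_profile()] / [predict_gene()].
#' @return A ggplot object with one line per model.
#' @export
plot_binding_profile <- function(prediction) {
  long <- prediction |>
    tidyr::pivot_longer(cols = c("tf_raw", "dnak_raw", "mg_raw"),
                        names_to = "model", values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$codon, y = .data$score,
                                     colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~protein_id, scales = "free") +
    ggplot2::scale_colour_manual(values = c(tf_raw = "darkgreen",
                                            dnak_raw = "darkorange",
                                            mg_raw = "grey40")) +
    ggplot2::labs(x = "codon (nascent length)",
                  y = "raw binding score (atom-count units)") +
    ggplot2::theme_minimal()
}

#' Plot a metagene curve
#'
#' @param mg Output of [metagene()] or [domain_metagene()] (the latter is
#'   plotted on its combined `position` axis).
#' @return A ggplot object.
#' @export
plot_metagene <- function(mg) {
  xvar <- if ("position" %in% names(mg)) "position" else "pos"
  ggplot2::ggplot(mg, ggplot2::aes(x = .data[[xvar]], y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = if (xvar == "pos") "codon (aligned)" else
      "bin (30 domain + 10 linker)", y = "mean enrichment") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.serp_clusters <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$cluster, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4,
                          fill = "grey85") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = "cluster (A = high affinity)",
                  y = "engagement score") +
    ggplot2::theme_minimal()
}
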