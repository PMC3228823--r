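#' Box plot of a standardized enrichment profile
#'
#' The classic single-experiment view: the distribution of standardized
#' enrichment scores as a box (quartiles, 1.5 × IQR whiskers, outlying genes
#' as open circles), the calling threshold as a dashed line on the
#' SD-above-median scale, and optional highlighted genes (the bait's mRNA in
#' black, other called mRNAs in grey).
#'
#' @param object A `ripchip_std_profile`.
#' @param bait_gene Gene drawn as a filled black point (defaults to the
#'   profile's bait).
#' @param highlight Further genes drawn as grey points (e.g. the consensus).
#' @param tau Dashed threshold line in SD-above-median units (default 2).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ripchip_std_profile <- function(object, bait_gene = NULL,
                                         highlight = character(), tau = 2,
                                         ...) {
  bait_gene <- bait_gene %||% attr(object, "bait_gene")
  id <- attr(object, "experiment_id") %||% "profile"
  df <- tibble(experiment = id, gene_id = object$gene_id, s = object$s)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$experiment, y = .data$s)) +
    ggplot2::geom_boxplot(outlier.shape = 1, coef = 1.5, width = 0.4) +
    ggplot2::geom_hline(yintercept = tau, linetype = "dashed") +
    ggplot2::labs(x = NULL,
                  y = "enrichment (SD above median of all mRNAs)") +
    ggplot2::theme_classic()
  hl <- df[df$gene_id %in% highlight & df$gene_id != bait_gene, ]
  if (nrow(hl) > 0) {
    p <- p + ggplot2::geom_point(data = hl, colour = "grey50", size = 2)
  }
  if (!is.null(bait_gene) && !is.na(bait_gene) && bait_gene %in% df$gene_id) {
    p <- p + ggplot2::geom_point(data = df[df$gene_id == bait_gene, ],
                                 colour = "black", size = 2)
  }
  p
}

#' Side-by-side enrichment box plots for several experiments
#'
#' @param profiles List of `ripchip_std_profile`s.
#' @param tau Dashed threshold line (default 2).
#' @return A ggplot object with one box per experiment.
#' @export
plot_enrichment_boxes <- function(profiles, tau = 2) {
  df <- purrr::map_dfr(profiles, function(pr) {
    tibble(
      experiment = attr(pr, "experiment_id") %||% "profile",
      s = pr$s
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$experiment, y = .data$s)) +
    ggplot2::geom_boxplot(outlier.shape = 1, coef = 1.5) +
    ggplot2::geom_hline(yintercept = tau, linetype = "dashed") +
    ggplot2::labs(x = NULL,
                  y = "enrichment (SD above median of all mRNAs)") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
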