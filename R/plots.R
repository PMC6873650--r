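# ggplot2 views of the main result types.

#' Manhattan-style plot of a window enrichment scan
#'
#' Plots -log10 of the empirical randomization p per window midpoint,
#' colored by TE class, with the Z-threshold calls highlighted.
#'
#' @param enrichment Output of [window_enrichment_scan()].
#' @return A ggplot object.
#' @export
plot_window_enrichment <- function(enrichment) {
  df <- dplyr::mutate(enrichment, midpoint = (.data$start + .data$end) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint, y = .data$neg_log10_p,
                                   colour = .data$te_class)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant), size = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom)) +
    ggplot2::labs(x = "window midpoint (bp)",
                  y = expression(-log[10] ~ "empirical p"),
                  colour = "TE class", shape = "Z > 3") +
    ggplot2::theme_minimal()
}

#' Bar plot of class-composition log2 ratios
#'
#' @param ratio Output of [class_ratio_log2()] or a context/biotype
#'   enrichment table with a `log2_ratio` column.
#' @param label Column to place on the x axis (default `te_class`).
#' @return A ggplot object.
#' @export
plot_class_ratio <- function(ratio, label = "te_class") {
  df <- ratio[is.finite(ratio$log2_ratio), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[label]], y = .data$log2_ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = expression(log[2] ~ "ratio")) +
    ggplot2::theme_minimal()
}

#' Heatmap of the RNA-TEV presence matrix
#'
#' Samples are grouped by population on the x axis, RNA-TEVs ordered by
#' genomic coordinate on the y axis.
#'
#' @param presence Output of [presence_matrix()].
#' @return A ggplot object.
#' @export
plot_presence_heatmap <- function(presence) {
  pops <- attr(presence, "sample_populations")
  long <- tidyr::pivot_longer(presence, -"variant_id",
                              names_to = "sample_id", values_to = "carrier")
  long$population <- unname(pops[long$sample_id])
  long$sample_id <- factor(long$sample_id, levels = names(pops))
  long$variant_id <- factor(long$variant_id, levels = rev(presence$variant_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$variant_id,
                                     fill = factor(.data$carrier))) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$population),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "darkred"),
                               name = "carrier") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Volcano plot of a cis-eQTL scan
#'
#' @param object A `tev_scan` from [run_scan()].
#' @param ... Unused.
#' @return A ggplot object: effect size against -log10 q, significant
#'   associations highlighted.
#' @method autoplot tev_scan
#' @export
autoplot.tev_scan <- function(object, ...) {
  df <- tidy(object)
  df$neg_log10_q <- -log10(pmax(df$q_value, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$neg_log10_q,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "fdr_threshold")),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "darkred")) +
    ggplot2::labs(x = "effect per presence allele (expression units)",
                  y = expression(-log[10] ~ "q")) +
    ggplot2::theme_minimal()
}

#' Null distribution of the genotype-randomization validation
#'
#' @param object A `tev_perm` from [permutation_validation()].
#' @param ... Unused.
#' @return A ggplot object: histogram of randomized significant counts with
#'   the observed count marked.
#' @method autoplot tev_perm
#' @export
autoplot.tev_perm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_significant)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "darkred") +
    ggplot2::labs(x = "significant associations per randomization",
                  y = "replicates") +
    ggplot2::theme_minimal()
}
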