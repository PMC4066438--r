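# ggplot2 displays for the main result types.

#' Plot a per-locus transmission summary
#'
#' Bar chart of killer-allele transmission per marker with the Mendelian 1/2
#' line; the classic display of transmission-ratio distortion scans.
#'
#' @param summary A [transmission_summary()] tibble.
#' @param killer Label for the measured allele class.
#' @return A ggplot object.
#' @export
plot_transmission <- function(summary, killer = "Sk") {
  stopifnot(all(c("locus", "chrom", "t") %in% names(summary)))
  summary$locus <- factor(summary$locus,
                          levels = summary$locus[order(summary$chrom, summary$pos)])
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$locus, y = .data$t)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "firebrick") +
    ggplot2::facet_grid(~ .data$chrom, scales = "free_x", space = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = sprintf("%s allele transmission", killer)) +
    ggplot2::theme_minimal()
}

#' Plot the exact spore-class distribution
#'
#' @param classes An [enumerate_spore_classes()] tibble.
#' @param top Number of highest-probability classes to show.
#' @return A ggplot object.
#' @export
plot_class_distribution <- function(classes, top = 15L) {
  cls <- classes[order(-classes$prob_post), , drop = FALSE]
  cls <- cls[cls$prob_post > 0, , drop = FALSE]
  cls <- utils::head(cls, top)
  cls$label <- sprintf("%s/%s/%s (%d%d%d)", cls$chr1, cls$chr2, cls$chr3,
                       cls$cn1, cls$cn2, cls$cn3)
  cls$label <- factor(cls$label, levels = rev(cls$label))
  ggplot2::ggplot(cls, ggplot2::aes(x = .data$prob_post, y = .data$label)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "probability (after viability)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname tidy.drive_fit
#' @param object A `drive_fit`.
#' @export
autoplot.drive_fit <- function(object, ...) {
  est <- object$estimates[object$estimates$identifiable, , drop = FALSE]
  ggplot2::ggplot(est, ggplot2::aes(x = .data$locus, y = .data$d_hat)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "killer locus", y = "estimated strength d",
                  subtitle = sprintf("%d%% likelihood-ratio intervals",
                                     round(100 * object$conf_level))) +
    ggplot2::theme_minimal()
}

#' @rdname tidy.driver_map
#' @param object A `driver_map`.
#' @export
autoplot.driver_map <- function(object, ...) {
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = .data$pos / 1e6, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "candidate killer position (Mb)",
                  y = "profile log-likelihood") +
    ggplot2::theme_minimal()
  if (object$identifiable)
    p <- p + ggplot2::geom_vline(xintercept = object$position / 1e6,
                                 linetype = 2, colour = "firebrick")
  p
}
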