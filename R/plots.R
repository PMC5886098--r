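# ggplot2 renderings of exported result tables. Plots are views of the
# tables, never the data of record.

#' Quantile-quantile plot of association p-values
#'
#' @param qq A table from [qq_export()].
#' @return A ggplot object (observed vs expected -log10 p with the identity
#'   line; the genomic inflation factor in the subtitle).
#' @export
plot_qq <- function(qq) {
  lambda <- attr(qq, "lambda")
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      subtitle = if (!is.null(lambda)) sprintf("lambda[GC] = %.3f", lambda)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.overlap_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[is.finite(df$p_perm), ]
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$threshold),
                                   y = -log10(.data$p_perm))) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10](P[t])),
                  y = expression(-log[10](P[perm])),
                  title = "Signal overlap across p-value thresholds") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.coloc_scan <- function(object, top_n = 20, ...) {
  df <- utils::head(tibble::as_tibble(object), top_n)
  long <- tidyr::pivot_longer(
    df[c("block_id", paste0("pp_h", 0:4))],
    cols = dplyr::starts_with("pp_"),
    names_to = "hypothesis", values_to = "pp"
  )
  long$hypothesis <- toupper(sub("pp_", "", long$hypothesis))
  long$block_id <- factor(long$block_id, levels = rev(df$block_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pp, y = .data$block_id,
                                     fill = .data$hypothesis)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = "Posterior probability", y = "Region",
                  fill = "Hypothesis",
                  title = "Regional colocalisation posteriors") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ldsc_rg <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term %in% c("h2_1", "h2_2", "rg", "intercept_cross"), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 1.96 * .data$std.error,
      ymax = .data$estimate + 1.96 * .data$std.error
    )) +
    ggplot2::labs(x = NULL, y = "Estimate (95% CI)",
                  title = "LD score regression estimates") +
    ggplot2::theme_minimal()
}
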