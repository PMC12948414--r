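# Basic figure exports (volcano, KM). ggplot2 is optional.

#' Volcano plot of a scored screen
#'
#' Phenotype (doublings^-1) against -log10 adjusted p, hits colored by call.
#'
#' @param table a `phenotype_table` from [score_screen()].
#' @return a ggplot object.
#' @export
plot_volcano <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- table[table$passes_filter, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phenotype,
                                   y = -log10(.data$p_adj),
                                   colour = .data$call)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(enriched = "#c0392b",
                                            depleted = "#2e86c1",
                                            ns = "grey60")) +
    ggplot2::labs(x = "phenotype (doublings^-1)",
                  y = expression(-log[10] ~ "adjusted p"), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot of a survival association
#'
#' @param result a `survival_result` from [survival_association()].
#' @return a ggplot object.
#' @export
plot_km <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- do.call(rbind, lapply(names(result$km), function(g) {
    k <- result$km[[g]]
    # step-function points, anchored at S(0) = 1
    data.frame(group = g, time = c(0, k$time), survival = c(1, k$survival))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "local PFS",
                  subtitle = sprintf("log-rank p = %.3g", result$p_value)) +
    ggplot2::theme_minimal()
}
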