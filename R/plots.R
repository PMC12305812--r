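# Diagnostic plots; ggplot2 is in Suggests, so each checks for it.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}

#' Plot anaemia prevalence trajectories per arm
#'
#' @param trajectories Named list of `ifc_trajectory` objects.
#' @return A ggplot object.
#' @export
plot_prevalence <- function(trajectories) {
  need_ggplot()
  df <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(cycle = seq_len(nrow(tr)), arm = attr(tr, "arm"),
               prevalence = prevalence(tr))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$prevalence,
                                   colour = .data$arm)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, NA)) +
    ggplot2::labs(x = "six-month cycle", y = "anaemia prevalence",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tornado diagram of one-way sensitivity results
#'
#' @param tornado An `ifc_oneway` table.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado) {
  need_ggplot()
  df <- as.data.frame(tornado)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$low_icer,
                                       xend = .data$high_icer,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$base_icer[1]),
                        linetype = 2) +
    ggplot2::labs(x = "ICER (USD per disability day averted)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane scatter of PSA runs
#'
#' @param psa An `ifc_psa` result.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa) {
  need_ggplot()
  s <- psa$samples[!is.na(psa$samples$icer), ]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$delta_effect,
                                  y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "disability days averted", y = "incremental cost (USD)") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param curve An `ifc_ceac` table.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  need_ggplot()
  ggplot2::ggplot(as.data.frame(curve),
                  ggplot2::aes(x = .data$wtp, y = .data$p_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "willingness to pay (USD per disability day averted)",
                  y = "probability cost-effective") +
    ggplot2::theme_minimal()
}
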