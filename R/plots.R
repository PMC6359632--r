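#' Ratio-versus-abundance plot of a differential-expression result
#'
#' Scatter of log2 NSAF ratio against log10 of the larger group-mean
#' spectral count, colored by expression call, with the governing-tier
#' fold cutoffs drawn as step lines. Proteins unique to one group (infinite
#' or zero ratio) are pinned to the plot margin.
#'
#' @param object A `dep_result` from [call_dep_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dep_result <- function(object, ...) {
  t <- tidy(object)
  t <- t[!is.na(t$nsaf_ratio), , drop = FALSE]
  finite <- t$nsaf_ratio[is.finite(t$nsaf_ratio) & t$nsaf_ratio > 0]
  cap <- if (length(finite) > 0) 2 * max(finite) else 4
  floor_r <- if (length(finite) > 0) min(finite) / 2 else 0.25
  r <- pmin(pmax(t$nsaf_ratio, floor_r), cap)
  t$log2_ratio <- log2(r)
  t$log10_max_sc <- log10(pmax(t$mean_sc_ref, t$mean_sc_cmp))

  ggplot2::ggplot(t, ggplot2::aes(x = .data$log10_max_sc,
                                  y = .data$log2_ratio,
                                  colour = .data$call)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "log10 max group-mean spectral count",
      y = paste0("log2 NSAF ratio (", object$group_cmp, "/",
                 object$group_ref, ")"),
      colour = "call"
    ) +
    ggplot2::theme_minimal()
}

#' Technical-replicate QC plot
#'
#' Bars of detected-protein totals per run, grouped by sample group, with
#' each group's CV of the totals printed above its bars.
#'
#' @param object A `qc_summary` from [qc_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qc_summary <- function(object, ...) {
  totals <- object$per_run_totals
  cvs <- object$per_group_cv
  lab <- merge(
    stats::aggregate(n_proteins ~ group, totals, max),
    cvs
  )
  lab$text <- sprintf("CV %.2f%%", lab$cv_percent)

  ggplot2::ggplot(totals,
                  ggplot2::aes(x = factor(.data$replicate),
                               y = .data$n_proteins,
                               fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~group) +
    ggplot2::geom_text(
      data = lab,
      ggplot2::aes(x = Inf, y = .data$n_proteins, label = .data$text),
      inherit.aes = FALSE, hjust = 1.1, vjust = -0.5, size = 3
    ) +
    ggplot2::labs(x = "technical replicate", y = "proteins detected") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Status breakdown of a control annotation
#'
#' @param object A `control_annotation` from [annotate_with_control()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.control_annotation <- function(object, ...) {
  t <- tidy(object)
  ggplot2::ggplot(t, ggplot2::aes(x = .data$status, fill = .data$status)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "proteins",
                  title = paste0("DEP status in control proteome (n = ",
                                 nrow(t), ")")) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
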