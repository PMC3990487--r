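# ggplot2 helpers for the main result types. These are conveniences, not
# contracts: every number they display comes from the tabular outputs.

#' @exportS3Method ggplot2::autoplot
autoplot.te_abundance <- function(object, ...) {
  df <- as_tibble(object) %>% filter(.data$rpkm_te > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rpkm_te)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~te_class, scales = "free_y") +
    ggplot2::labs(x = "RPKM (log scale)", y = "TE subfamilies",
                  title = paste("TE abundance,",
                                attr(object, "accession_id") %||% ""))
}

#' Empirical distribution of abundances with a log-normal overlay
#'
#' Rank-frequency style view: the empirical distribution function of RPKM
#' values on a log axis with the fitted log-normal curve, the visual check
#' that DNA-element abundances are log-normal while RNA-element abundances
#' are a two-mode mixture.
#'
#' @param values Positive abundance values.
#' @param fit Optional [fit_lognormal_edf()] result (fitted when `NULL`).
#' @return A ggplot object.
#' @export
plot_edf_lognormal <- function(values, fit = NULL) {
  values <- sort(values[values > 0])
  fit <- fit %||% fit_lognormal_edf(values)
  df <- tibble(value = values, edf = seq_along(values) / length(values))
  curve <- tibble(value = exp(seq(log(min(values)), log(max(values)),
                                  length.out = 200)))
  curve$cdf <- plnorm(curve$value, fit$meanlog, fit$sdlog)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$edf)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(y = .data$cdf), linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "RPKM (log scale)", y = "EDF")
}

#' @exportS3Method ggplot2::autoplot
autoplot.rna_split <- function(object, values = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(values)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble(x = log(values[values > 0])),
      ggplot2::aes(x = .data$x), bins = 40, fill = "grey60")
  }
  p +
    ggplot2::geom_vline(xintercept = log(object$split_threshold),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "log RPKM", y = "TE subfamilies",
                  title = sprintf("R1/R2 split at RPKM %.3g",
                                  object$split_threshold))
}

#' @exportS3Method ggplot2::autoplot
autoplot.group_comparison <- function(object, log_y = TRUE, ...) {
  df <- object$data
  lab <- object$summary
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = 4) +
    ggplot2::geom_text(
      data = lab,
      ggplot2::aes(x = .data$group, y = Inf, label = .data$letters),
      vjust = 1.5) +
    ggplot2::labs(x = NULL, y = object$variable)
  if (log_y && all(df$value > 0)) p <- p + ggplot2::scale_y_log10()
  p
}

#' Scatter of expression fold change against the 24:22 siRNA ratio
#'
#' @param matched The `matched` tibble from [join_expression_fc()] (needs a
#'   `ratio_24_22` column).
#' @return A ggplot object.
#' @export
plot_fc_scatter <- function(matched) {
  if (!"ratio_24_22" %in% names(matched)) {
    abort("matched table lacks ratio_24_22; pass `ratio` to join_expression_fc()")
  }
  ggplot2::ggplot(matched,
                  ggplot2::aes(x = .data$ratio_24_22, y = .data$log2_fc,
                               colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "24:22 nt siRNA ratio (log scale)",
                  y = "expression log2 fold change")
}
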