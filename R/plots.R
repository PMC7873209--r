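#' Boxplot of a per-cell measure by cell type
#'
#' Notched boxplots (box = IQR, notch ~ 95% CI of the median, whiskers =
#' 1.5 IQR) of a per-cell statistic, optionally with a reference line
#' (e.g. the parity ratio 1).
#'
#' @param table Per-cell tibble (e.g. from [chromosome_ratio()]).
#' @param labels Tibble with `barcode`, `type`, or a named type vector.
#' @param value Value column to plot.
#' @param ref Optional horizontal reference value.
#' @return A ggplot object.
#' @export
plot_by_type <- function(table, labels, value = "ratio", ref = NULL) {
  if (!is.data.frame(labels)) {
    labels <- tibble(barcode = names(labels), type = as.vector(labels))
  }
  dat <- table %>%
    left_join(labels[, c("barcode", "type")], by = "barcode") %>%
    filter(!is.na(.data[[value]]))
  if ("valid" %in% names(dat)) dat <- filter(dat, .data$valid)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$type, y = .data[[value]])) +
    ggplot2::geom_boxplot(notch = TRUE, outlier.size = 0.3) +
    ggplot2::labs(x = "cell type", y = value) +
    ggplot2::theme_minimal()
  if (!is.null(ref)) {
    p <- p + ggplot2::geom_hline(yintercept = ref, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Grid-search stability plot
#'
#' ARI of each threshold's clustering against the most permissive
#' threshold, with the stability cutoff and the selected threshold marked.
#'
#' @param report A `grid_search_report` from [select_upper_threshold()].
#' @return A ggplot object.
#' @export
plot_grid_search <- function(report) {
  stopifnot(inherits(report, "grid_search_report"))
  dat <- report$summary %>% filter(.data$usable)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$threshold),
                                    y = .data$ari_vs_reference)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$selected), width = 0.6) +
    ggplot2::geom_hline(yintercept = report$stability, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(x = "expressed-gene threshold", y = "ARI vs most permissive") +
    ggplot2::theme_minimal()
}

#' Per-arm sex-bias plot
#'
#' Mean arm expression by sex with bootstrap confidence intervals;
#' elements with significantly reduced male expression are starred.
#'
#' @param bias Output of [arm_sex_bias()].
#' @return A ggplot object.
#' @export
plot_arm_sex_bias <- function(bias) {
  long <- bias %>%
    tidyr::pivot_longer(
      cols = c("mean_female", "mean_male"),
      names_to = "sex", names_prefix = "mean_", values_to = "mean_tpm"
    ) %>%
    mutate(
      ci_lo = ifelse(.data$sex == "female", .data$female_ci_lo, .data$male_ci_lo),
      ci_hi = ifelse(.data$sex == "female", .data$female_ci_hi, .data$male_ci_hi)
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$element, y = .data$mean_tpm,
                                     fill = .data$sex)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                           position = ggplot2::position_dodge(0.8), width = 0.3) +
    ggplot2::geom_text(
      data = bias %>% filter(.data$male_reduced),
      ggplot2::aes(x = .data$element,
                   y = pmax(.data$mean_female, .data$mean_male) * 1.05,
                   label = "*"),
      inherit.aes = FALSE, size = 6
    ) +
    ggplot2::labs(x = "chromosome element", y = "mean TPM per expressed gene") +
    ggplot2::theme_minimal()
}
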