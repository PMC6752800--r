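#' Phenotype factor map
#'
#' Fig-1/2-style scatter of subjects on two FAMD dimensions, coloured by
#' a grouping variable (clinical suspicion or carrier status). With the
#' conventional orientation, more Marfan-like subjects sit on the left
#' (negative Dim 1).
#'
#' @param object A `famd` fit.
#' @param dims Pair of dimensions to plot.
#' @param colour Optional vector (length n) used for colouring.
#' @param colour_lab Legend title.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.famd <- function(object, dims = c(1, 2), colour = NULL,
                          colour_lab = "group", ...) {
  d <- as_tibble(object)
  xs <- paste0("Dim", dims[1])
  ys <- paste0("Dim", dims[2])
  if (!is.null(colour)) d$.col <- colour
  p <- ggplot(d, aes(x = .data[[xs]], y = .data[[ys]])) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey70") +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey70") +
    labs(
      x = sprintf("%s (%.1f%%)", xs, object$percent_variance[dims[1]]),
      y = sprintf("%s (%.1f%%)", ys, object$percent_variance[dims[2]])
    ) +
    theme_minimal()
  if (is.null(colour)) {
    p + geom_point(alpha = 0.8)
  } else {
    p + geom_point(aes(colour = .data$.col), alpha = 0.8) +
      labs(colour = colour_lab)
  }
}

#' Association p-value plot for the common-variant scan
#'
#' Per-sign -log10 unadjusted p-values along the panel, with the
#' nominal and max-T-significant variants highlighted.
#'
#' @param assoc Result of [assoc_common_scan()].
#' @param sign Sign to display (default: first).
#' @param alpha Nominal threshold line.
#' @return A ggplot object.
#' @export
plot_association <- function(assoc, sign = NULL, alpha = 0.05) {
  s <- sign %||% assoc$sign[1]
  d <- filter(assoc, .data$sign == s, !is.na(.data$p_unadjusted)) |>
    mutate(chrom = parse_variant_id(.data$id)$chrom,
           status = case_when(
             .data$p_maxT < alpha ~ "max-T significant",
             .data$p_unadjusted < alpha ~ "nominal",
             TRUE ~ "ns"))
  ggplot(d, aes(x = seq_len(nrow(d)), y = -log10(.data$p_unadjusted),
                colour = .data$chrom, shape = .data$status)) +
    geom_point() +
    geom_hline(yintercept = -log10(alpha), linetype = 2) +
    labs(x = "variant index (panel order)",
         y = expression(-log[10](p)), title = s) +
    theme_minimal()
}

#' Explained-variance comparison plot
#'
#' Dumbbell-style display of per-sign explained variance under the
#' FBN1-only model versus the joint rare-plus-common model.
#'
#' @param object A `model_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_comparison <- function(object, ...) {
  d <- object$table |>
    pivot_longer(c("r2_model1", "r2_model2"), names_to = "model",
                 values_to = "r2") |>
    mutate(model = ifelse(.data$model == "r2_model1", "Model 1 (FBN1 only)",
                          "Model 2 (joint)"))
  ggplot(d, aes(x = .data$r2, y = stats::reorder(.data$sign, .data$r2),
                colour = .data$model)) +
    geom_line(aes(group = .data$sign), colour = "grey60") +
    geom_point(size = 2.5) +
    labs(x = "explained variance (%)", y = NULL, colour = NULL,
         subtitle = sprintf("mean increase %.1f%% (paired p = %.2g)",
                            object$mean_increase, object$p_paired)) +
    theme_minimal()
}
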