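#' Plot methods for mining results
#'
#' `autoplot()` methods: ranked sort-ratio lollipop for a
#' `cooccurrence_result`; -log10 p-value bars with the significance
#' threshold line for a `comorbidity_result`; a disease-by-gene membership
#' tile map for a `multimorbidity_table`.
#'
#' @param object A result object.
#' @param top_n Show only the strongest `top_n` rows (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @name comormine-autoplot
NULL

#' @rdname comormine-autoplot
#' @export
autoplot.cooccurrence_result <- function(object, top_n = 20L, ...) {
  df <- head(tidy(object), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$sort_ratio,
    y = stats::reorder(.data$co_disease, .data$sort_ratio))) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$co_disease),
                          colour = "grey60") +
    ggplot2::geom_point(size = 2.2, colour = "#2c7fb8") +
    ggplot2::labs(
      x = "sort ratio (joint articles / index pairing articles)", y = NULL,
      title = sprintf("Co-occurring diseases for %s",
                      attr(object, "index_disease") %||% "index disease")) +
    ggplot2::theme_minimal()
}

#' @rdname comormine-autoplot
#' @export
autoplot.comorbidity_result <- function(object, top_n = 20L, ...) {
  df <- head(tidy(object), top_n)
  # floor at the double floor so -log10 stays finite for extreme p
  df$neg_log10_p <- -log10(pmax(df$p_value, 1e-310))
  alpha <- attr(object, "alpha")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$neg_log10_p,
    y = stats::reorder(.data$co_disease, .data$neg_log10_p),
    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d95f02", `FALSE` = "grey70")) +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  title = sprintf("Fisher exact comorbidity significance (alpha = %.1g)",
                                  alpha)) +
    ggplot2::theme_minimal()
}

#' @rdname comormine-autoplot
#' @export
autoplot.multimorbidity_table <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(row = paste0(.data$diseases, " (", .data$n_genes, ")")) %>%
    tidyr::separate_rows("genes", sep = ", ") %>%
    tidyr::separate_rows("diseases", sep = ", ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genes, y = .data$diseases)) +
    ggplot2::geom_tile(fill = "#2c7fb8", colour = "white") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Multimorbidity signatures: gene membership") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
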