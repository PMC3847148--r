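#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_vline
#'   geom_col geom_segment labs scale_colour_manual coord_flip
#' @export
ggplot2::autoplot

#' Volcano plot of a per-gene comparison
#'
#' Mean log-expression difference (`c1 - c2`) against `-log10` of the
#' chosen p-value; genes significant at the result's alpha and up in the
#' functional-mutant class are highlighted — these are the genes the
#' candidate screen can retain.
#'
#' @param object An `sls_test_results` tibble.
#' @param p_type `"parametric"` (default) or `"permutation"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sls_test_results <- function(object,
                                      p_type = c("parametric", "permutation"),
                                      ...) {
  p_type <- match.arg(p_type)
  p_col <- if (p_type == "parametric") "parametric_p" else "permutation_p"
  alpha <- attr(object, "alpha") %||% 0.05
  df <- tidy(object) |>
    mutate(
      diff = .data$mean1 - .data$mean2,
      p = .data[[p_col]],
      status = dplyr::case_when(
        .data$p <= alpha & .data$direction == "up_in_c1" ~ "up in c1",
        .data$p <= alpha ~ "up in c2",
        TRUE ~ "not significant"
      )
    )
  ggplot(df, aes(x = .data$diff, y = -log10(.data$p), colour = .data$status)) +
    geom_point(size = 0.8, alpha = 0.7) +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    geom_vline(xintercept = 0, linetype = "dotted") +
    scale_colour_manual(values = c(
      "up in c1" = "#C0392B", "up in c2" = "#2471A3",
      "not significant" = "grey60"
    )) +
    labs(
      x = "mean log-expression difference (c1 - c2)",
      y = sprintf("-log10 %s p", p_type),
      colour = NULL,
      title = attr(object, "dataset_name") %||% NULL
    )
}

#' Bar plot of cross-dataset consensus counts
#'
#' @param object An `sls_consensus` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sls_consensus <- function(object, ...) {
  df <- tidy(object) |>
    mutate(
      gene = factor(.data$gene, levels = rev(.data$gene)),
      consensus = .data$n_datasets >= (attr(object, "min_datasets") %||% 2L)
    )
  ggplot(df, aes(x = .data$gene, y = .data$n_datasets, fill = .data$consensus)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "datasets where candidate", fill = "consensus")
}

#' Class-mean plot of a compound screen
#'
#' One segment per compound from the class-`c2` mean z-score to the
#' class-`c1` mean; rightward segments (higher sensitivity in
#' functional-p53-mutant lines) are the concordant direction.
#'
#' @param object An `sls_drug_results` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sls_drug_results <- function(object, ...) {
  df <- as_tibble(unclass_result(object)) |>
    arrange(.data$one_sided_p) |>
    mutate(compound = factor(.data$compound, levels = rev(.data$compound)))
  ggplot(df, aes(x = .data$compound)) +
    geom_segment(aes(xend = .data$compound, y = .data$mean_c2,
      yend = .data$mean_c1, colour = .data$concordant)) +
    geom_point(aes(y = .data$mean_c1, colour = .data$concordant)) +
    geom_hline(yintercept = 0, linetype = "dotted") +
    coord_flip() +
    labs(
      x = NULL, y = "mean -log(GI50) z-score (segment: c2 mean to c1 mean)",
      colour = "higher sensitivity in c1"
    )
}
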