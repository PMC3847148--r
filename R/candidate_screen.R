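#' Select druggable synthetic-lethal candidate genes
#'
#' Filters a per-gene comparison down to candidates: genes whose selected
#' p-value is at or below `alpha`, whose expression is higher in the
#' functional-mutant class (`direction == "up_in_c1"`), and which encode a
#' kinase. Probe-suffixed identifiers (`GENE#2`) match the kinase list and
#' report candidacy on the base symbol, so a gene is a candidate if any of
#' its probes passes.
#'
#' @param results An `sls_test_results` tibble ([run_class_comparison()]).
#' @param kinases Character vector of kinase gene symbols (matching is
#'   exact and case-sensitive on the base symbol).
#' @param alpha Significance threshold (default 0.05).
#' @param p_type Which p-value the threshold applies to: `"parametric"`
#'   (default), `"permutation"`, or `"q_value"` to threshold the
#'   Benjamini-Hochberg q-value instead.
#' @return A tibble of class `sls_candidates` with columns `gene` (base
#'   symbol), `p_selected`, `mean1`, `mean2`; attributes `dataset_name`,
#'   `alpha`, `criteria`.
#' @export
select_candidates <- function(results, kinases, alpha = 0.05,
                              p_type = c("parametric", "permutation", "q_value")) {
  p_type <- match.arg(p_type)
  if (length(kinases) == 0) {
    sls_abort("kinase set is empty", class = "sls_validation_error")
  }
  p_col <- switch(p_type,
    parametric = "parametric_p",
    permutation = "permutation_p",
    q_value = "q_value"
  )
  if (p_type == "permutation" && all(is.na(results$permutation_p))) {
    sls_abort("results carry no permutation p-values; rerun with a scheme",
      class = "sls_validation_error")
  }
  hits <- results |>
    mutate(base = base_symbol(.data$gene), p_selected = .data[[p_col]]) |>
    filter(
      !is.na(.data$p_selected),
      .data$p_selected <= alpha,
      .data$direction == "up_in_c1",
      .data$base %in% kinases
    )
  out <- hits |>
    group_by(.data$base) |>
    dplyr::slice_min(.data$p_selected, n = 1, with_ties = FALSE) |>
    ungroup() |>
    dplyr::transmute(gene = .data$base, p_selected = .data$p_selected,
      mean1 = .data$mean1, mean2 = .data$mean2) |>
    arrange(.data$gene)
  attr(out, "dataset_name") <- attr(results, "dataset_name") %||% "dataset"
  attr(out, "alpha") <- alpha
  attr(out, "criteria") <- list(
    direction = "up_in_c1", kinase_filter = TRUE, p_type = p_type
  )
  class(out) <- c("sls_candidates", class(out))
  out
}

#' Cross-dataset consensus of candidate sets
#'
#' Counts, for every gene, the datasets in which it was selected as a
#' candidate, and filters at `min_datasets` (default 2: a consensus
#' candidate must recur in at least two independent datasets). The
#' unfiltered union with counts is kept in the `union` attribute. A gene
#' untestable in a dataset simply cannot vote there.
#'
#' @param candidate_sets List of `sls_candidates` tibbles with unique
#'   dataset names.
#' @param min_datasets Minimum number of datasets (default 2).
#' @return A tibble of class `sls_consensus` with columns `gene`,
#'   `n_datasets`, `datasets` (comma-separated names), sorted by
#'   `n_datasets` descending then `gene`; attributes `min_datasets`,
#'   `union` (the unfiltered table), `n_input_datasets`.
#' @export
consensus_candidates <- function(candidate_sets, min_datasets = 2L) {
  if (length(candidate_sets) == 0) {
    sls_abort("need at least one candidate set", class = "sls_validation_error")
  }
  names_ds <- vapply(candidate_sets, function(s) {
    attr(s, "dataset_name") %||% "dataset"
  }, character(1))
  check_unique(names_ds, "dataset names")
  long <- purrr::map2_dfr(candidate_sets, names_ds, function(s, nm) {
    tibble(gene = s$gene, dataset = nm)
  })
  union_tbl <- long |>
    group_by(.data$gene) |>
    summarise(
      n_datasets = dplyr::n_distinct(.data$dataset),
      datasets = paste(sort(unique(.data$dataset)), collapse = ",")
    ) |>
    ungroup() |>
    arrange(desc(.data$n_datasets), .data$gene)
  out <- filter(union_tbl, .data$n_datasets >= min_datasets)
  attr(out, "min_datasets") <- as.integer(min_datasets)
  attr(out, "union") <- union_tbl
  attr(out, "n_input_datasets") <- length(candidate_sets)
  class(out) <- c("sls_consensus", class(out))
  out
}
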