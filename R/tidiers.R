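#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a per-gene comparison
#'
#' Returns the per-gene table as a plain tibble (one row per testable
#' gene), dropping the result class and attributes.
#'
#' @param x An `sls_test_results` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sls_test_results <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' One-row summary of a per-gene comparison
#'
#' @param x An `sls_test_results` tibble.
#' @param ... Unused.
#' @return A one-row tibble: `dataset`, `n_genes`, `n_untestable`,
#'   `alpha`, `n_sig_parametric`, `n_sig_permutation`, `n_sig_q`,
#'   `n_up_in_c1`.
#' @export
glance.sls_test_results <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.05
  tibble(
    dataset = attr(x, "dataset_name") %||% "dataset",
    n_genes = nrow(x),
    n_untestable = length(attr(x, "untestable") %||% character(0)),
    alpha = alpha,
    n_sig_parametric = sum(x$parametric_p <= alpha),
    n_sig_permutation = sum(x$permutation_p <= alpha, na.rm = TRUE),
    n_sig_q = sum(x$q_value <= alpha),
    n_up_in_c1 = sum(x$direction == "up_in_c1")
  )
}

#' Tidy a consensus table
#'
#' Returns the unfiltered cross-dataset union: every gene that was a
#' candidate anywhere, with its dataset count.
#'
#' @param x An `sls_consensus` tibble.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `n_datasets`, `datasets`.
#' @export
tidy.sls_consensus <- function(x, ...) {
  as_tibble(attr(x, "union"))
}

#' One-row summary of a consensus table
#'
#' @param x An `sls_consensus` tibble.
#' @param ... Unused.
#' @return A one-row tibble: `n_input_datasets`, `min_datasets`,
#'   `n_union_genes`, `n_consensus_genes`.
#' @export
glance.sls_consensus <- function(x, ...) {
  tibble(
    n_input_datasets = attr(x, "n_input_datasets"),
    min_datasets = attr(x, "min_datasets"),
    n_union_genes = nrow(attr(x, "union")),
    n_consensus_genes = nrow(x)
  )
}

#' One-row summary of a compound screen
#'
#' @param x An `sls_drug_results` tibble.
#' @param ... Unused.
#' @return A one-row tibble: `n_compounds`, `n_concordant`,
#'   `n_sig_0_05`, `n_untestable`.
#' @export
glance.sls_drug_results <- function(x, ...) {
  tibble(
    n_compounds = nrow(x),
    n_concordant = sum(x$concordant),
    n_sig_0_05 = sum(x$one_sided_p <= 0.05),
    n_untestable = length(attr(x, "untestable") %||% character(0))
  )
}

# Strip the package's result class so dplyr verbs return plain tibbles.
unclass_result <- function(x) {
  class(x) <- setdiff(class(x), c(
    "sls_test_results", "sls_candidates", "sls_consensus",
    "sls_drug_results", "sls_labels", "sls_expr", "sls_drug_matrix"
  ))
  attr(x, "scheme") <- NULL
  x
}
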