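#' Read a log-expression matrix
#'
#' Reads a tab-delimited genes-by-samples matrix of log-scale expression
#' values. The first header cell labels the gene-identifier column; the
#' remaining header cells are sample identifiers. Empty cells, `NA` and
#' `NaN` parse as missing; any other non-numeric cell is a parse error that
#' names the offending row and column. A GCT-like variant whose first line
#' begins `#1.2` is accepted (the two header lines are skipped).
#'
#' Array platforms carry multiple probes per gene; by default duplicated
#' gene identifiers are rejected. With `probe_mode = "suffix"` duplicates
#' are kept and disambiguated as `GENE#1`, `GENE#2`, ...; downstream the
#' candidate screen maps a probe-suffixed identifier back to its base
#' symbol, so a gene is a candidate if any of its probes passes.
#'
#' @param path Path to a tab-delimited file.
#' @param name Dataset name carried through result tables.
#' @param probe_mode `"error"` (default) rejects duplicated gene ids;
#'   `"suffix"` disambiguates them as `GENE#1`, `GENE#2`, ...
#' @return A tibble of class `sls_expr`: a `gene` character column followed
#'   by one numeric column per sample. The dataset name is stored in the
#'   `dataset_name` attribute.
#' @seealso [expression_dataset()] to build the same object from a matrix.
#' @export
read_expression <- function(path, name = basename(path),
                            probe_mode = c("error", "suffix")) {
  probe_mode <- match.arg(probe_mode)
  parsed <- read_wide_tsv(path, col_what = "sample ids")
  samples <- parsed$ids
  if (length(samples) < 2) {
    sls_abort("an expression dataset needs at least 2 samples",
      class = "sls_validation_error")
  }
  raw <- parsed$raw
  genes <- raw[[1]]
  if (anyDuplicated(genes)) {
    if (probe_mode == "error") {
      check_unique(genes, "gene ids (use probe_mode = \"suffix\" for multi-probe data)")
    }
    genes <- probe_suffix(genes)
  }
  cells <- unlist(raw[-1], use.names = FALSE)
  m <- parse_numeric_cells(cells, genes, samples)
  expression_dataset(m, name = name)
}

# Shared reader for id-column + numeric-columns TSVs. Validates the raw
# header itself: read_tsv would silently repair duplicated column names.
read_wide_tsv <- function(path, col_what) {
  head_lines <- readLines(path, n = 3L)
  if (length(head_lines) == 0) {
    sls_abort("empty file", class = "sls_parse_error")
  }
  skip <- if (startsWith(head_lines[1], "#1.2")) 2L else 0L
  if (length(head_lines) <= skip) {
    sls_abort("malformed header: no header line after the GCT preamble",
      class = "sls_parse_error")
  }
  header <- strsplit(head_lines[skip + 1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) {
    sls_abort("malformed header: expected an id column plus value columns",
      class = "sls_parse_error")
  }
  check_unique(header[-1], col_what)
  raw <- readr::read_tsv(
    path,
    skip = skip, na = character(), col_types = readr::cols(.default = "c"),
    show_col_types = FALSE, progress = FALSE
  )
  list(ids = header[-1], raw = raw)
}

# GENE -> GENE#1, GENE#2 for duplicated symbols; unique symbols untouched.
probe_suffix <- function(genes) {
  dup <- genes %in% genes[duplicated(genes)]
  idx <- stats::ave(seq_along(genes), genes, FUN = seq_along)
  ifelse(dup, paste0(genes, "#", idx), genes)
}

# Strip a #<n> probe suffix back to the base gene symbol.
base_symbol <- function(genes) sub("#[0-9]+$", "", genes)

#' Build an expression dataset from a matrix
#'
#' @param values Numeric genes-by-samples matrix with unique row (gene) and
#'   column (sample) names; log-scale expression, `NA` for missing.
#' @param name Dataset name.
#' @return An `sls_expr` tibble (see [read_expression()]).
#' @export
expression_dataset <- function(values, name = "dataset") {
  stopifnot(is.matrix(values))
  check_unique(rownames(values), "gene ids")
  check_unique(colnames(values), "sample ids")
  if (ncol(values) < 2) {
    sls_abort("an expression dataset needs at least 2 samples",
      class = "sls_validation_error")
  }
  out <- matrix_to_wide(values, "gene")
  attr(out, "dataset_name") <- name
  class(out) <- c("sls_expr", class(out))
  out
}

expr_matrix <- function(expr) wide_to_matrix(expr, "gene")

#' Sample identifiers of an expression dataset
#'
#' @param expr An `sls_expr` tibble.
#' @return Character vector of sample ids, in column order.
#' @export
expr_samples <- function(expr) setdiff(names(expr), "gene")

#' Name of an expression dataset
#'
#' @param expr An `sls_expr` tibble.
#' @return The dataset name.
#' @export
dataset_name <- function(expr) attr(expr, "dataset_name") %||% "dataset"

#' Read a TP53 mutation table
#'
#' Reads a TSV with columns `sample_id`, `gene` and `mutation_class`. The
#' mutation class vocabulary is `missense`, `nonsense`, `frameshift`,
#' `silent`, `synonymous`, `noncoding`, `none`; any other token is an
#' error. Rows for genes other than TP53 are retained but flagged (column
#' `tp53 = FALSE`) with a warning; they never contribute to class labels.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `sample_id`, `gene`, `mutation_class`,
#'   `tp53`.
#' @export
read_mutations <- function(path) {
  raw <- readr::read_tsv(
    path,
    na = character(), col_types = readr::cols(.default = "c"),
    show_col_types = FALSE, progress = FALSE
  )
  required <- c("sample_id", "gene", "mutation_class")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    sls_abort(
      sprintf("mutation table lacks required column(s): %s",
        paste(missing_cols, collapse = ", ")),
      class = "sls_parse_error"
    )
  }
  out <- as_tibble(raw[required])
  bad <- setdiff(unique(out$mutation_class), MUTATION_CLASSES)
  if (length(bad) > 0) {
    sls_abort(
      sprintf(
        "unknown mutation_class token(s): %s (allowed: %s)",
        paste(bad, collapse = ", "),
        paste(MUTATION_CLASSES, collapse = ", ")
      ),
      class = "sls_validation_error"
    )
  }
  out$tp53 <- out$gene == "TP53"
  if (any(!out$tp53)) {
    rlang::warn(sprintf(
      "%d mutation record(s) for genes other than TP53; flagged and ignored for labelling",
      sum(!out$tp53)
    ))
  }
  out
}

#' Read a gene list
#'
#' One symbol per line; lines starting with `#` are comments. Symbols are
#' whitespace-stripped, deduplicated and case-preserved. An empty list is
#' an error: a kinase filter with no kinases is a configuration mistake,
#' not an empty result.
#'
#' @param path Path to a newline-delimited text file.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  genes <- unique(lines)
  if (length(genes) == 0) {
    sls_abort("gene list is empty", class = "sls_validation_error")
  }
  genes
}

#' Read a drug-sensitivity z-score matrix
#'
#' Reads a TSV of normalized -log(GI50) z-scores, compounds in rows and
#' cell lines in columns (first header cell labels the compound column).
#' Higher z means higher sensitivity (lower GI50). Missing-value dialect as
#' in [read_expression()].
#'
#' @param path Path to the TSV.
#' @return A tibble of class `sls_drug_matrix`: `compound` column followed
#'   by one numeric column per cell line.
#' @export
read_drug_matrix <- function(path) {
  parsed <- read_wide_tsv(path, col_what = "cell-line ids")
  lines <- parsed$ids
  raw <- parsed$raw
  compounds <- raw[[1]]
  check_unique(compounds, "compound names")
  m <- parse_numeric_cells(unlist(raw[-1], use.names = FALSE), compounds, lines)
  out <- matrix_to_wide(m, "compound")
  class(out) <- c("sls_drug_matrix", class(out))
  out
}

#' Read a compound-to-target map
#'
#' TSV with columns `compound` and `target`, one row per compound-target
#' pair; a compound may map to several target genes.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `compound`, `target`.
#' @export
read_target_map <- function(path) {
  raw <- readr::read_tsv(
    path,
    na = character(), col_types = readr::cols(.default = "c"),
    show_col_types = FALSE, progress = FALSE
  )
  required <- c("compound", "target")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    sls_abort(
      sprintf("target map lacks required column(s): %s",
        paste(missing_cols, collapse = ", ")),
      class = "sls_parse_error"
    )
  }
  out <- distinct(as_tibble(raw[required]))
  if (any(!nzchar(trimws(out$target)))) {
    sls_abort("target map contains an empty target symbol",
      class = "sls_validation_error")
  }
  out
}

#' Write a result table as TSV
#'
#' Writes any of the pipeline's tabular outputs with a deterministic row
#' order so written artifacts are reproducible byte-for-byte. Sort keys by
#' table type: gene test results by permutation p (then parametric p, then
#' gene), candidate sets by gene, consensus tables by descending dataset
#' count then gene, drug comparisons by one-sided p then compound; other
#' tables keep their row order. Written files round-trip through
#' [read_results_table()].
#'
#' @param results A tibble (any pipeline output).
#' @param path Output path.
#' @return `results`, invisibly (sorted as written).
#' @export
write_results_table <- function(results, path) {
  out <- if (inherits(results, "sls_test_results")) {
    arrange(results, .data$permutation_p, .data$parametric_p, .data$gene)
  } else if (inherits(results, "sls_candidates")) {
    arrange(results, .data$gene)
  } else if (inherits(results, "sls_consensus")) {
    arrange(results, desc(.data$n_datasets), .data$gene)
  } else if (inherits(results, "sls_drug_results")) {
    arrange(results, .data$one_sided_p, .data$compound)
  } else {
    results
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}

#' Read back a table written by [write_results_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble with column types guessed by [readr::read_tsv()].
#' @export
read_results_table <- function(path) {
  # Columns are read as text and converted with R's own (correctly rounded)
  # numeric parser so that written doubles round-trip exactly.
  raw <- readr::read_tsv(
    path,
    na = character(), col_types = readr::cols(.default = "c"),
    show_col_types = FALSE, progress = FALSE
  )
  as_tibble(lapply(raw, function(col) {
    utils::type.convert(col, as.is = TRUE, na.strings = "NA")
  }))
}
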