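# Internal helpers shared across modules.

sls_abort <- function(message, class = "sls_error", ...) {
  rlang::abort(message, class = c(class, "sls_error"), ...)
}

# Tokens that parse as a missing value in every tabular dialect the package
# reads. Anything else non-numeric is a hard parse error.
MISSING_TOKENS <- c("", "NA", "NaN")

MUTATION_CLASSES <- c(
  "missense", "nonsense", "frameshift",
  "silent", "synonymous", "noncoding", "none"
)

FUNCTIONAL_CLASSES <- c("missense", "nonsense", "frameshift")

# Parse a character matrix of cells into numeric, mapping missing tokens to
# NA and failing loudly on anything else, naming the offending row/column.
parse_numeric_cells <- function(chr, row_ids, col_ids, what = "cell") {
  chr <- trimws(chr)
  num <- suppressWarnings(as.numeric(chr))
  is_missing <- chr %in% MISSING_TOKENS | is.na(chr)
  bad <- which(is.na(num) & !is_missing)
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% length(row_ids)) + 1
    j <- ((bad[1] - 1) %/% length(row_ids)) + 1
    sls_abort(
      sprintf(
        "non-numeric %s '%s' at row '%s', column '%s'",
        what, chr[bad[1]], row_ids[i], col_ids[j]
      ),
      class = "sls_parse_error"
    )
  }
  num[is_missing] <- NA_real_
  matrix(num, nrow = length(row_ids), dimnames = list(row_ids, col_ids))
}

check_unique <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup) > 0) {
    sls_abort(
      sprintf(
        "duplicate %s: %s", what,
        paste(head(dup, 5), collapse = ", ")
      ),
      class = "sls_validation_error"
    )
  }
  invisible(x)
}

# Wide tibble (id column + numeric columns) -> numeric matrix.
wide_to_matrix <- function(tbl, id_col) {
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  storage.mode(m) <- "double"
  rownames(m) <- tbl[[id_col]]
  m
}

matrix_to_wide <- function(m, id_col) {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- tibble(!!id_col := rownames(m), !!!out)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
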