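#' Classify TP53 mutation classes as functional or non-functional
#'
#' Nonsense (stop codon), frameshift and missense TP53 mutations are
#' treated as functional p53 mutations — changes assumed to abrogate p53
#' function. Silent changes (including synonymous mutations and mutations
#' in noncoding DNA) and wild-type (`none`) are non-functional and are
#' grouped together downstream.
#'
#' @param mutation_class Character vector of vocabulary-valid mutation
#'   classes (`missense`, `nonsense`, `frameshift`, `silent`, `synonymous`,
#'   `noncoding`, `none`).
#' @return Character vector, `"functional"` or `"non_functional"`.
#' @export
#' @examples
#' classify_mutation(c("missense", "synonymous", "none"))
classify_mutation <- function(mutation_class) {
  bad <- setdiff(unique(mutation_class), MUTATION_CLASSES)
  if (length(bad) > 0) {
    sls_abort(
      sprintf("unknown mutation_class token(s): %s", paste(bad, collapse = ", ")),
      class = "sls_validation_error"
    )
  }
  ifelse(mutation_class %in% FUNCTIONAL_CLASSES, "functional", "non_functional")
}

#' Assign two-class labels from a TP53 mutation table
#'
#' Partitions samples into class `c1` (carrying at least one functional
#' TP53 mutation) and class `c2` (everything else: non-functional mutations
#' and wild-type). Samples absent from the mutation table are wild-type and
#' therefore `c2`. A sample with several records is `c1` if any record is
#' functional. Labels depend only on the mutation table, never on
#' expression values.
#'
#' @param mutations Tibble as returned by [read_mutations()] (columns
#'   `sample_id`, `gene`, `mutation_class`; an optional `tp53` flag —
#'   non-TP53 rows are ignored).
#' @param samples Character vector of sample identifiers to label
#'   (typically the expression dataset's samples).
#' @return A tibble of class `sls_labels` with columns `sample_id`,
#'   `class` (`"c1"`/`"c2"`) and `n_functional_records`; class sizes are in
#'   the `class_sizes` attribute.
#' @export
assign_labels <- function(mutations, samples) {
  if (length(samples) == 0) {
    sls_abort("no samples to label", class = "sls_validation_error")
  }
  check_unique(samples, "sample ids")
  mut <- mutations
  if (!"tp53" %in% names(mut)) mut$tp53 <- mut$gene == "TP53"
  non_tp53_only <- setdiff(
    unique(mut$sample_id[!mut$tp53]),
    unique(mut$sample_id[mut$tp53])
  )
  if (length(non_tp53_only) > 0) {
    rlang::warn(sprintf(
      "%d sample(s) appear in the mutation table without any TP53 record; treated as TP53 wild-type (c2)",
      length(intersect(non_tp53_only, samples))
    ))
  }
  tp53 <- filter(mut, .data$tp53, .data$sample_id %in% samples)
  tp53$functional <- classify_mutation(tp53$mutation_class) == "functional"
  counts <- tp53 |>
    group_by(.data$sample_id) |>
    summarise(n_functional_records = sum(.data$functional)) |>
    ungroup()
  out <- tibble(sample_id = samples) |>
    left_join(counts, by = "sample_id") |>
    mutate(
      n_functional_records = dplyr::coalesce(.data$n_functional_records, 0L),
      class = ifelse(.data$n_functional_records > 0, "c1", "c2")
    ) |>
    select("sample_id", "class", "n_functional_records")
  sizes <- c(c1 = sum(out$class == "c1"), c2 = sum(out$class == "c2"))
  if (any(sizes == 0)) {
    sls_abort(
      sprintf("class %s is empty: a two-class comparison needs both classes",
        names(sizes)[sizes == 0][1]),
      class = "sls_validation_error"
    )
  }
  attr(out, "class_sizes") <- sizes
  class(out) <- c("sls_labels", class(out))
  out
}

#' @export
print.sls_labels <- function(x, ...) {
  sizes <- attr(x, "class_sizes")
  cat(sprintf(
    "p53 class labels: %d samples (c1 functional-mutant: %d, c2 other: %d)\n",
    nrow(x), sizes[["c1"]], sizes[["c2"]]
  ))
  NextMethod()
}

# Labels tibble -> named character vector aligned to `samples`.
label_vector <- function(labels, samples) {
  v <- setNames(labels$class, labels$sample_id)
  missing_s <- setdiff(samples, names(v))
  if (length(missing_s) > 0) {
    sls_abort(
      sprintf("labels missing for sample(s): %s",
        paste(head(missing_s, 5), collapse = ", ")),
      class = "sls_validation_error"
    )
  }
  v[samples]
}
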