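#' One-sided drug-sensitivity comparison for one compound
#'
#' Compares a compound's normalized -log(GI50) z-scores between class `c1`
#' (functional p53 mutant) and class `c2` cell lines with a one-sided
#' two-sample t-test of the alternative `mean_c1 > mean_c2`. Higher z means
#' higher sensitivity (lower GI50), so the alternative is higher drug
#' sensitivity in the functional-mutant lines. Missing z-scores are dropped
#' per compound (complete-case).
#'
#' @param zrow Numeric vector of z-scores, may contain `NA`; names are cell
#'   lines when `labels` is an `sls_labels` tibble.
#' @param labels Character vector of `"c1"`/`"c2"` aligned with `zrow`, or
#'   an `sls_labels` tibble covering `names(zrow)`.
#' @param variance_mode `"pooled"` (default) or `"welch"`.
#' @return A one-row tibble: `mean_c1`, `mean_c2`, `n1`, `n2`, `statistic`,
#'   `one_sided_p`.
#' @export
compare_compound <- function(zrow, labels,
                             variance_mode = c("pooled", "welch")) {
  variance_mode <- match.arg(variance_mode)
  if (inherits(labels, "sls_labels")) {
    labels <- label_vector(labels, names(zrow))
  }
  stopifnot(length(zrow) == length(labels))
  keep <- !is.na(zrow)
  z <- zrow[keep]
  lab <- labels[keep]
  x1 <- z[lab == "c1"]
  x2 <- z[lab == "c2"]
  if (length(x1) < 2 || length(x2) < 2) {
    sls_abort("untestable compound: needs >= 2 non-missing values per class",
      class = "sls_untestable")
  }
  tt <- t_test_two_sided(x1, x2, variance_mode)
  one_sided <- pt(tt$statistic, tt$df, lower.tail = FALSE)
  tibble(
    mean_c1 = mean(x1), mean_c2 = mean(x2),
    n1 = length(x1), n2 = length(x2),
    statistic = tt$statistic, one_sided_p = one_sided
  )
}

#' Screen compounds targeting candidate genes
#'
#' Restricts a drug-sensitivity matrix to the compounds whose target genes
#' intersect the candidate set (or all compounds with
#' `all_compounds = TRUE`), runs [compare_compound()] on each, and returns
#' results sorted by one-sided p ascending. Compounds with
#' `mean_c1 > mean_c2` are flagged `concordant`: higher sensitivity in the
#' functional-mutant lines, the direction a synthetic-lethal target
#' predicts. Compound names are matched case-insensitively after
#' whitespace-stripping. No multiple-testing adjustment is applied to the
#' compound p-values.
#'
#' @param drug_matrix An `sls_drug_matrix` tibble ([read_drug_matrix()]).
#' @param target_map Tibble with columns `compound`, `target`
#'   ([read_target_map()]).
#' @param candidates Character vector of candidate gene symbols (e.g. a
#'   consensus table's `gene` column).
#' @param labels An `sls_labels` tibble covering the matrix's cell lines.
#' @param all_compounds Test every compound in the matrix regardless of the
#'   target map (default `FALSE`).
#' @param variance_mode `"pooled"` (default) or `"welch"`.
#' @return A tibble of class `sls_drug_results`: `compound`, `mean_c1`,
#'   `mean_c2`, `n1`, `n2`, `statistic`, `one_sided_p`, `concordant`,
#'   `targets` (comma-separated mapped targets), sorted by `one_sided_p`.
#'   Untestable compounds are dropped with a warning and listed in the
#'   `untestable` attribute.
#' @export
screen_compounds <- function(drug_matrix, target_map, candidates, labels,
                             all_compounds = FALSE,
                             variance_mode = c("pooled", "welch")) {
  variance_mode <- match.arg(variance_mode)
  m <- wide_to_matrix(drug_matrix, "compound")
  lab <- label_vector(labels, colnames(m))

  key <- function(x) tolower(trimws(x))
  map_tbl <- target_map |>
    mutate(compound_key = key(.data$compound)) |>
    group_by(.data$compound_key) |>
    summarise(targets = paste(sort(unique(.data$target)), collapse = ",")) |>
    ungroup()
  target_sets <- strsplit(setNames(map_tbl$targets, map_tbl$compound_key), ",",
    fixed = TRUE)

  compound_keys <- key(rownames(m))
  hits_candidates <- vapply(compound_keys, function(k) {
    length(intersect(target_sets[[k]] %||% character(0), candidates)) > 0
  }, logical(1))
  tested <- if (all_compounds) rep(TRUE, nrow(m)) else hits_candidates
  if (!any(tested)) {
    rlang::warn("no compound targets any candidate gene; empty result")
  }

  rows <- purrr::map(which(tested), function(i) {
    res <- tryCatch(
      compare_compound(m[i, ], lab, variance_mode),
      sls_untestable = function(e) NULL
    )
    if (is.null(res)) {
      return(tibble(compound = rownames(m)[i], untestable = TRUE))
    }
    mutate(res, compound = rownames(m)[i], untestable = FALSE)
  })
  all_rows <- bind_rows(rows)
  untestable <- character(0)
  out <- tibble(
    compound = character(0), mean_c1 = numeric(0), mean_c2 = numeric(0),
    n1 = integer(0), n2 = integer(0), statistic = numeric(0),
    one_sided_p = numeric(0), concordant = logical(0), targets = character(0)
  )
  if (nrow(all_rows) > 0) {
    untestable <- all_rows$compound[all_rows$untestable]
    if (length(untestable) > 0) {
      rlang::warn(sprintf("%d untestable compound(s) dropped: %s",
        length(untestable), paste(untestable, collapse = ", ")))
    }
    kept <- filter(all_rows, !.data$untestable)
    if (nrow(kept) > 0) {
      out <- kept |>
        mutate(
          concordant = .data$mean_c1 > .data$mean_c2,
          targets = vapply(key(.data$compound), function(k) {
            paste(target_sets[[k]] %||% character(0), collapse = ",")
          }, character(1))
        ) |>
        select("compound", "mean_c1", "mean_c2", "n1", "n2", "statistic",
          "one_sided_p", "concordant", "targets") |>
        arrange(.data$one_sided_p, .data$compound)
    }
  }
  attr(out, "untestable") <- untestable
  attr(out, "variance_mode") <- variance_mode
  class(out) <- c("sls_drug_results", class(out))
  out
}
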