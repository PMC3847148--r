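# Independent oracles and tiny fixture builders used across the suite.
# These deliberately avoid the package's own code paths: the enumerator
# uses stats::t.test, the FDR oracle is the literal step-up definition.

# Brute-force exhaustive permutation p: enumerate every distinct class-1
# subset with utils::combn, score each with stats::t.test, count p-values
# at or below the observed one (1e-12 tie slack for mirrored assignments).
oracle_exhaustive_perm_p <- function(values, n1, var.equal = TRUE) {
  n <- length(values)
  obs <- stats::t.test(values[seq_len(n1)], values[-seq_len(n1)],
    var.equal = var.equal)$p.value
  idx <- utils::combn(n, n1)
  ps <- apply(idx, 2, function(i) {
    stats::t.test(values[i], values[-i], var.equal = var.equal)$p.value
  })
  sum(ps <= obs + 1e-12) / ncol(idx)
}

# Literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j,
# capped at 1, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# One-way ANOVA by the definition (between/within mean squares).
oracle_anova <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  grand <- mean(unlist(groups))
  ssb <- sum(ns * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(statistic = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

# Write a small expression TSV from a named matrix; returns the path.
write_expr_fixture <- function(m, path = withr::local_tempfile(fileext = ".tsv",
                                 .local_envir = parent.frame()),
                               id_label = "gene") {
  lines <- c(
    paste(c(id_label, colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      cells <- ifelse(is.na(m[i, ]), "", format(m[i, ], trim = TRUE))
      paste(c(rownames(m)[i], cells), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  path
}

write_mutation_fixture <- function(df, path = withr::local_tempfile(
                                     fileext = ".tsv",
                                     .local_envir = parent.frame())) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# Labels tibble built directly (bypassing assign_labels) for unit tests.
make_labels <- function(samples, c1_samples) {
  mut <- tibble::tibble(
    sample_id = c1_samples, gene = "TP53", mutation_class = "missense"
  )
  assign_labels(mut, samples)
}
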