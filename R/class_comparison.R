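#' Two-sided two-sample t-test
#'
#' Closed-form two-sample t statistic and two-sided p-value, with either
#' the classical pooled-variance form (default) or the Welch
#' unequal-variance form. The statistic's sign follows
#' `mean(x1) - mean(x2)`. Missing values are dropped per vector.
#'
#' Degenerate inputs: if both groups are constant and equal the statistic
#' is 0 and p is 1; if both are constant but unequal the statistic is
#' infinite and p is 0.
#'
#' @param x1,x2 Numeric vectors; each needs >= 2 non-missing values.
#' @param variance_mode `"pooled"` (default) or `"welch"`.
#' @return A list with `statistic`, `parametric_p` and `df`.
#' @export
#' @examples
#' t_test_two_sided(c(1, 2, 3, 4), c(3, 4, 5, 6))
t_test_two_sided <- function(x1, x2, variance_mode = c("pooled", "welch")) {
  variance_mode <- match.arg(variance_mode)
  x1 <- x1[!is.na(x1)]
  x2 <- x2[!is.na(x2)]
  if (length(x1) < 2 || length(x2) < 2) {
    sls_abort("each group needs >= 2 non-missing values",
      class = "sls_untestable")
  }
  v <- c(x1, x2)
  memb <- matrix(rep(c(1, 0), c(length(x1), length(x2))), ncol = 1)
  st <- t_stat_engine(matrix(v, nrow = 1), memb, length(x1), length(x2),
    variance_mode)
  list(statistic = st$stat[1, 1], parametric_p = st$p[1, 1], df = st$df[1, 1])
}

#' One-way ANOVA F-test
#'
#' One-way fixed-effects analysis of variance across two or more groups,
#' returning the F statistic and its upper-tail p-value. With exactly two
#' groups F equals the squared pooled-variance t statistic and the p-values
#' coincide.
#'
#' Degenerate inputs: when every group has zero within-group variance, p is
#' 0 if the group means differ and 1 if they are all equal.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 non-missing
#'   values.
#' @return A list with `statistic`, `parametric_p`, `df1` and `df2`.
#' @export
f_test <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  k <- length(groups)
  if (k < 2 || any(lengths(groups) < 2)) {
    sls_abort("need >= 2 groups, each with >= 2 non-missing values",
      class = "sls_untestable")
  }
  ns <- lengths(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0) {
      return(list(statistic = 0, parametric_p = 1, df1 = df1, df2 = df2))
    }
    return(list(statistic = Inf, parametric_p = 0, df1 = df1, df2 = df2))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(
    statistic = f,
    parametric_p = pf(f, df1, df2, lower.tail = FALSE),
    df1 = df1, df2 = df2
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: the q-value of a p-value is the
#' smallest FDR at which it would be declared significant,
#' `q_i = min over p_(j) >= p_(i) of m * p_(j) / rank(j)`, capped at 1 and
#' returned in the input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.5))
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) {
    return(numeric(0))
  }
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    sls_abort("p-values must lie in [0, 1]", class = "sls_validation_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' Permutation scheme
#'
#' Controls the label-permutation test: number of Monte-Carlo draws, seed,
#' and mode. `"exhaustive"` enumerates every distinct two-class label
#' assignment exactly once; `"monte_carlo"` samples assignments uniformly
#' with replacement; `"auto"` (default) uses exhaustive enumeration
#' whenever the number of distinct assignments does not exceed
#' `n_permutations`.
#'
#' @param n_permutations Number of Monte-Carlo draws (default 10000).
#' @param seed Integer seed; identical seeds give bit-identical permutation
#'   p-values.
#' @param mode `"auto"`, `"monte_carlo"` or `"exhaustive"`.
#' @return A list of class `sls_perm_scheme`.
#' @export
perm_scheme <- function(n_permutations = 10000L, seed = 1L,
                        mode = c("auto", "monte_carlo", "exhaustive")) {
  mode <- match.arg(mode)
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1) {
    sls_abort("n_permutations must be >= 1", class = "sls_validation_error")
  }
  structure(
    list(n_permutations = n_permutations, seed = as.integer(seed), mode = mode),
    class = "sls_perm_scheme"
  )
}

#' Label-permutation p-value for one gene
#'
#' The permutation p-value is the proportion of class-label permutations
#' whose parametric test p-value is at least as small as the one obtained
#' with the true labels. Comparison is on the parametric p (with ties
#' counted, `<=`), which makes t-tested and F-tested genes commensurable.
#' In exhaustive mode every distinct assignment is counted once and the
#' observed assignment is among them, so p is strictly positive; in
#' Monte-Carlo mode the add-one-smoothed estimate
#' `(1 + #\{p_perm <= p_obs\}) / (1 + n_permutations)` is returned, which
#' never yields 0.
#'
#' @param values Numeric vector (one gene's expression), may contain `NA`.
#' @param labels Character vector of `"c1"`/`"c2"` aligned with `values`,
#'   or an `sls_labels` tibble covering `names(values)`.
#' @param scheme A [perm_scheme()].
#' @param variance_mode `"pooled"` or `"welch"`.
#' @return The permutation p-value (scalar in (0, 1]).
#' @export
permutation_p <- function(values, labels, scheme = perm_scheme(),
                          variance_mode = c("pooled", "welch")) {
  variance_mode <- match.arg(variance_mode)
  if (inherits(labels, "sls_labels")) {
    labels <- label_vector(labels, names(values))
  }
  stopifnot(length(values) == length(labels))
  keep <- !is.na(values)
  v <- values[keep]
  lab <- labels[keep]
  n1 <- sum(lab == "c1")
  n2 <- sum(lab == "c2")
  if (n1 < 2 || n2 < 2) {
    sls_abort("untestable gene: needs >= 2 non-missing values per class",
      class = "sls_untestable")
  }
  obs <- t_stat_engine(
    matrix(v, nrow = 1), matrix(as.numeric(lab == "c1"), ncol = 1),
    n1, n2, variance_mode
  )$p[1, 1]
  withr::with_seed(scheme$seed, {
    perm_count_le(matrix(v, nrow = 1), obs, n1, scheme, variance_mode)[1]
  })
}

#' Per-gene two-class comparison across a dataset
#'
#' Runs the full per-gene screen of a dataset: pooled (or Welch)
#' two-sample t statistics between class `c1` (functional p53 mutant) and
#' class `c2`, two-sided parametric p-values, label-permutation p-values
#' under `scheme`, and Benjamini-Hochberg q-values computed over all
#' testable genes of the run.
#'
#' A gene is testable if it has >= 2 non-missing values in each class
#' (per-gene complete-case analysis); untestable genes are dropped with a
#' warning and are listed in the `untestable` attribute. Genes sharing a
#' missingness pattern share the same permutation draws; the whole run is
#' deterministic given `scheme$seed`.
#'
#' @param dataset An `sls_expr` tibble ([read_expression()]).
#' @param labels An `sls_labels` tibble ([assign_labels()]) covering the
#'   dataset's samples.
#' @param scheme A [perm_scheme()], or `NULL` to skip permutation p-values
#'   (the `permutation_p` column is then `NA`).
#' @param alpha Significance level carried in the result (default 0.05).
#' @param variance_mode `"pooled"` (default) or `"welch"`.
#' @param universe Optional character vector of gene symbols restricting
#'   the tested genes — and therefore the multiple-testing universe the
#'   q-values are computed over — e.g. the kinase list. With thousands of
#'   genes tested genome-wide the FDR at a loose threshold is high; because
#'   it depends on the number of tests, restricting the analysis to the
#'   kinome lowers it sharply. Default `NULL` tests every gene.
#' @return A tibble of class `sls_test_results`, one row per testable gene:
#'   `gene`, `n1`, `n2`, `mean1`, `mean2`, `statistic`, `parametric_p`,
#'   `permutation_p`, `q_value`, `direction` (`up_in_c1`/`up_in_c2`/`tie`).
#'   Attributes: `dataset_name`, `alpha`, `variance_mode`, `scheme`,
#'   `untestable`.
#' @export
run_class_comparison <- function(dataset, labels, scheme = perm_scheme(),
                                 alpha = 0.05,
                                 variance_mode = c("pooled", "welch"),
                                 universe = NULL) {
  variance_mode <- match.arg(variance_mode)
  m <- expr_matrix(dataset)
  if (!is.null(universe)) {
    m <- m[base_symbol(rownames(m)) %in% universe, , drop = FALSE]
    if (nrow(m) == 0) {
      sls_abort("no dataset gene falls in the requested universe",
        class = "sls_validation_error")
    }
  }
  lab <- label_vector(labels, colnames(m))
  is_c1 <- lab == "c1"
  if (sum(is_c1) == 0 || sum(!is_c1) == 0) {
    sls_abort("both classes must be non-empty", class = "sls_validation_error")
  }

  present <- !is.na(m)
  n1_gene <- as.integer(present %*% is_c1)
  n2_gene <- as.integer(present %*% (!is_c1))
  testable <- n1_gene >= 2 & n2_gene >= 2
  if (!any(testable)) {
    sls_abort("no testable genes (need >= 2 non-missing values per class)",
      class = "sls_validation_error")
  }
  if (any(!testable)) {
    rlang::warn(sprintf(
      "%d untestable gene(s) excluded (fewer than 2 values in a class)",
      sum(!testable)
    ))
  }
  untestable <- rownames(m)[!testable]
  m <- m[testable, , drop = FALSE]
  n1_gene <- n1_gene[testable]
  n2_gene <- n2_gene[testable]

  # Observed statistics, vectorized per missingness pattern.
  genes <- rownames(m)
  ng <- nrow(m)
  stat <- p_obs <- mean1 <- mean2 <- rep(NA_real_, ng)
  perm_p <- rep(NA_real_, ng)

  pattern <- apply(!is.na(m), 1, function(x) paste(which(!x), collapse = ","))
  pattern_ids <- unique(pattern)

  run_patterns <- function(do_perm) {
    for (pat in pattern_ids) {
      rows <- which(pattern == pat)
      keep_cols <- !is.na(m[rows[1], ])
      V <- m[rows, keep_cols, drop = FALSE]
      memb_obs <- matrix(as.numeric(is_c1[keep_cols]), ncol = 1)
      n1 <- sum(is_c1[keep_cols])
      n2 <- sum(!is_c1[keep_cols])
      st <- t_stat_engine(V, memb_obs, n1, n2, variance_mode)
      stat[rows] <<- st$stat[, 1]
      p_obs[rows] <<- st$p[, 1]
      # the engine centres rows; restore the gene mean so the reported
      # class means are on the log-expression scale
      rm_ <- rowMeans(V)
      mean1[rows] <<- st$m1[, 1] + rm_
      mean2[rows] <<- st$m2[, 1] + rm_
      if (do_perm) {
        perm_p[rows] <<- perm_count_le(V, p_obs[rows], n1, scheme,
          variance_mode)
      }
    }
  }

  if (is.null(scheme)) {
    run_patterns(do_perm = FALSE)
  } else {
    withr::with_seed(scheme$seed, run_patterns(do_perm = TRUE))
  }

  out <- tibble(
    gene = genes,
    n1 = n1_gene, n2 = n2_gene,
    mean1 = mean1, mean2 = mean2,
    statistic = stat,
    parametric_p = p_obs,
    permutation_p = perm_p,
    q_value = bh_fdr(p_obs),
    direction = dplyr::case_when(
      mean1 > mean2 ~ "up_in_c1",
      mean1 < mean2 ~ "up_in_c2",
      TRUE ~ "tie"
    )
  )
  attr(out, "dataset_name") <- dataset_name(dataset)
  attr(out, "alpha") <- alpha
  attr(out, "variance_mode") <- variance_mode
  attr(out, "scheme") <- scheme
  attr(out, "untestable") <- untestable
  class(out) <- c("sls_test_results", class(out))
  out
}

# ---- internal engine -------------------------------------------------------

# Vectorized two-sample t over permutations. V: genes x n values (complete
# columns only); memb: n x B 0/1 matrix, column b giving class-1 membership
# of permutation b. Rows are centred first: the t statistic is
# shift-invariant and centring avoids cancellation in the sum-of-squares
# update. Returns genes x B matrices of statistics and two-sided p-values.
t_stat_engine <- function(V, memb, n1, n2, variance_mode) {
  V <- V - rowMeans(V)
  tot <- rowSums(V) # ~0 after centring, kept for exactness
  s2 <- rowSums(V^2)
  sum1 <- V %*% memb
  m1 <- sum1 / n1
  m2 <- (tot - sum1) / n2
  if (variance_mode == "pooled") {
    ssw <- s2 - n1 * m1^2 - n2 * m2^2
    ssw[ssw < 0] <- 0
    sp2 <- ssw / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- matrix(n1 + n2 - 2, nrow(V), ncol(memb))
  } else {
    sq1 <- V^2 %*% memb
    ss1 <- sq1 - n1 * m1^2
    ss2 <- (s2 - sq1) - n2 * m2^2
    ss1[ss1 < 0] <- 0
    ss2[ss2 < 0] <- 0
    v1 <- ss1 / (n1 - 1)
    v2 <- ss2 / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    se <- sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    df[!is.finite(df)] <- n1 + n2 - 2 # zero-variance fallback, p decided below
  }
  tt <- (m1 - m2) / se
  # se == 0: equal means -> t 0, p 1; unequal -> +-Inf, p 0.
  zero_se <- se == 0
  if (any(zero_se)) {
    tt[zero_se & (m1 == m2)] <- 0
    tt[zero_se & (m1 > m2)] <- Inf
    tt[zero_se & (m1 < m2)] <- -Inf
  }
  p <- 2 * pt(-abs(tt), df)
  p[p > 1] <- 1
  list(stat = tt, p = p, df = df, m1 = m1, m2 = m2)
}

# Tolerance for the tie rule "permutation p as small as the observed p":
# mirrored assignments reproduce the observed p only up to the last ulp, so
# the <= comparison allows this absolute slack.
PERM_P_TOL <- 1e-12

# Permutation p-values for a block of genes sharing complete columns.
# V: genes x n; p_obs: length-genes observed parametric p. Draws (or
# enumerates) class-1 membership columns and counts permutations with
# p <= p_obs. Caller owns the RNG state.
perm_count_le <- function(V, p_obs, n1, scheme, variance_mode) {
  n <- ncol(V)
  n2 <- n - n1
  n_distinct <- choose(n, n1)
  exhaustive <- switch(scheme$mode,
    exhaustive = TRUE,
    monte_carlo = FALSE,
    auto = n_distinct <= scheme$n_permutations
  )
  count <- numeric(nrow(V))
  if (exhaustive) {
    if (!is.finite(n_distinct) || n_distinct > 5e5) {
      sls_abort(sprintf(
        "exhaustive enumeration of %.3g assignments is not feasible; use monte_carlo",
        n_distinct
      ), class = "sls_validation_error")
    }
    idx <- combn(n, n1)
    total <- ncol(idx)
    chunk <- 2500L
    for (start in seq(1L, total, by = chunk)) {
      cols <- start:min(start + chunk - 1L, total)
      memb <- matrix(0, n, length(cols))
      memb[cbind(as.vector(idx[, cols, drop = FALSE]),
        rep(seq_along(cols), each = n1))] <- 1
      p <- t_stat_engine(V, memb, n1, n2, variance_mode)$p
      count <- count + rowSums(p <= p_obs + PERM_P_TOL)
    }
    return(count / total)
  }
  B <- scheme$n_permutations
  chunk <- 2500L
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    memb <- matrix(0, n, b)
    for (j in seq_len(b)) memb[sample.int(n, n1), j] <- 1
    p <- t_stat_engine(V, memb, n1, n2, variance_mode)$p
    count <- count + rowSums(p <= p_obs + PERM_P_TOL)
    done <- done + b
  }
  (1 + count) / (1 + B)
}
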