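test_that("pooled t matches the closed-form oracle and its symmetries", {
  # frozen closed-form value: pooled-variance t with df = 6
  tt <- t_test_two_sided(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(tt$statistic, -2.19089023, tolerance = 1e-8)
  expect_equal(tt$parametric_p, 0.07098765, tolerance = 1e-7)
  expect_equal(tt$df, 6)

  # identical groups: statistic 0, p 1
  same <- t_test_two_sided(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$parametric_p, 1)

  # swapping the groups negates the statistic and keeps p
  set.seed(5)
  for (i in 1:20) {
    x1 <- rnorm(sample(2:8, 1))
    x2 <- rnorm(sample(2:8, 1), mean = runif(1, -2, 2))
    for (mode in c("pooled", "welch")) {
      a <- t_test_two_sided(x1, x2, mode)
      b <- t_test_two_sided(x2, x1, mode)
      expect_equal(a$statistic, -b$statistic)
      expect_equal(a$parametric_p, b$parametric_p)
      # cross-check against the reference implementation
      ref <- stats::t.test(x1, x2, var.equal = (mode == "pooled"))
      expect_equal(a$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(a$parametric_p, ref$p.value, tolerance = 1e-12)
    }
  }

  expect_error(t_test_two_sided(1, c(1, 2)), class = "sls_untestable")
  # missing values are dropped, not propagated
  expect_equal(
    t_test_two_sided(c(1, 2, NA, 3), c(4, 5, 6))$statistic,
    t_test_two_sided(c(1, 2, 3), c(4, 5, 6))$statistic
  )
})

test_that("two-group F equals squared pooled t; k-group F matches ANOVA oracle", {
  set.seed(6)
  for (i in 1:20) {
    g1 <- rnorm(sample(2:6, 1))
    g2 <- rnorm(sample(2:6, 1), 1)
    ft <- f_test(list(g1, g2))
    tt <- t_test_two_sided(g1, g2, "pooled")
    expect_equal(ft$statistic, tt$statistic^2, tolerance = 1e-10)
    expect_equal(ft$parametric_p, tt$parametric_p, tolerance = 1e-10)
  }

  # three identical groups: F 0, p 1
  g <- c(1, 2, 3)
  expect_equal(f_test(list(g, g, g))$statistic, 0)
  expect_equal(f_test(list(g, g, g))$parametric_p, 1)

  # frozen-oracle case plus random k-group instances
  groups <- list(c(1, 2), c(1, 2), c(10, 11))
  want <- oracle_anova(groups)
  got <- f_test(groups)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
  expect_equal(got$parametric_p, want$p, tolerance = 1e-12)
  for (i in 1:10) {
    groups <- replicate(sample(2:4, 1),
      rnorm(sample(2:5, 1), mean = runif(1, 0, 2)), simplify = FALSE)
    want <- oracle_anova(groups)
    got <- f_test(groups)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$parametric_p, want$p, tolerance = 1e-10)
  }

  # zero within-group variance: unequal means -> p 0, equal means -> p 1
  expect_equal(f_test(list(c(1, 1), c(2, 2)))$parametric_p, 0)
  expect_equal(f_test(list(c(1, 1), c(1, 1)))$parametric_p, 1)
  expect_error(f_test(list(c(1, 2))), class = "sls_untestable")
})

test_that("exhaustive permutation p matches brute-force enumeration", {
  # hand-enumerated toy: only the observed split and its mirror are as extreme
  p <- permutation_p(c(5, 6, 1, 2), c("c1", "c1", "c2", "c2"),
    perm_scheme(mode = "exhaustive"))
  expect_equal(p, 2 / 6)

  # constant gene: every assignment ties, p = 1
  expect_equal(
    permutation_p(rep(3, 6), rep(c("c1", "c2"), each = 3),
      perm_scheme(mode = "exhaustive")),
    1
  )

  set.seed(7)
  for (i in 1:25) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    v <- rnorm(n1 + n2, mean = rep(c(0, runif(1, 0, 2)), c(n1, n2)))
    lab <- rep(c("c1", "c2"), c(n1, n2))
    got <- permutation_p(v, lab, perm_scheme(mode = "exhaustive"))
    expect_equal(got, oracle_exhaustive_perm_p(v, n1), tolerance = 0)
  }
})

test_that("Monte-Carlo permutation p is consistent with the exhaustive value", {
  set.seed(8)
  z <- vapply(1:10, function(i) {
    v <- rnorm(10, mean = rep(c(0, 1), each = 5))
    lab <- rep(c("c1", "c2"), each = 5)
    exact <- permutation_p(v, lab, perm_scheme(mode = "exhaustive"))
    mc <- permutation_p(v, lab,
      perm_scheme(10000, seed = i, mode = "monte_carlo"))
    se <- sqrt(exact * (1 - exact) / 10000)
    (abs(mc - exact) - 1 / 10001) / se
  }, numeric(1))
  # 10 simultaneous binomial checks: family-wise 4-SE bound, and the bulk
  # must sit inside 3 SE
  expect_lt(max(z), 4)
  expect_gte(sum(z < 3), 8)
  # auto mode picks exhaustive for small assignment spaces
  v <- rnorm(8)
  lab <- rep(c("c1", "c2"), each = 4)
  expect_equal(
    permutation_p(v, lab, perm_scheme(10000, seed = 1, mode = "auto")),
    permutation_p(v, lab, perm_scheme(mode = "exhaustive"))
  )
})

test_that("permutation p is deterministic given the seed", {
  set.seed(123)
  v <- rnorm(20)
  lab <- rep(c("c1", "c2"), each = 10)
  a <- permutation_p(v, lab, perm_scheme(2000, seed = 99))
  b <- permutation_p(v, lab, perm_scheme(2000, seed = 99))
  c <- permutation_p(v, lab, perm_scheme(2000, seed = 100))
  expect_identical(a, b)
  expect_false(identical(a, c)) # different stream, almost surely different count
})

test_that("BH q-values equal the step-up definition and keep its properties", {
  # hand-worked case
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.1, 1.2)), class = "sls_validation_error")

  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15))
    expect_false(is.unsorted(q[order(p)]))
    expect_true(all(q <= 1))
  }
})

test_that("dataset-level comparison is coherent across its columns", {
  b <- simulate_bundle(sim_config(n_genes = 60, n_kinases = 15,
    n_samples = 20, n_mutant = 12, n_planted = 5, effect_size = 2,
    missing_rate = 0.05, seed = 21))
  labels <- make_labels(expr_samples(b$expression[[1]]), b$truth$c1_samples)
  res <- run_class_comparison(b$expression[[1]], labels,
    perm_scheme(500, seed = 4))

  expect_s3_class(res, "sls_test_results")
  expect_true(all(res$n1 >= 2 & res$n2 >= 2))
  expect_true(all(res$parametric_p >= 0 & res$parametric_p <= 1))
  expect_true(all(res$permutation_p > 0 & res$permutation_p <= 1))
  expect_equal(res$q_value, bh_fdr(res$parametric_p))
  expect_equal(res$direction == "up_in_c1", res$mean1 > res$mean2)
  expect_equal(sign(res$statistic), sign(res$mean1 - res$mean2))

  # per-gene results agree with the scalar operations on extracted vectors
  m <- synlethscreen:::expr_matrix(b$expression[[1]])
  lv <- setNames(labels$class, labels$sample_id)[colnames(m)]
  for (g in sample(res$gene, 5)) {
    v <- m[g, ]
    tt <- t_test_two_sided(v[lv == "c1"], v[lv == "c2"])
    row <- res[res$gene == g, ]
    expect_equal(row$statistic, tt$statistic)
    expect_equal(row$parametric_p, tt$parametric_p)
    # class means are on the log-expression scale, complete-case
    expect_equal(row$mean1, mean(v[lv == "c1"], na.rm = TRUE))
    expect_equal(row$mean2, mean(v[lv == "c2"], na.rm = TRUE))
  }

  # identical seeds give bit-identical permutation p-values
  res2 <- run_class_comparison(b$expression[[1]], labels,
    perm_scheme(500, seed = 4))
  expect_identical(res$permutation_p, res2$permutation_p)

  # a planted strong-effect gene is recovered as significant and up in c1
  planted_rows <- res[res$gene %in% b$truth$planted_genes, ]
  expect_true(all(planted_rows$direction == "up_in_c1"))
  expect_true(all(planted_rows$permutation_p <= 0.05))

  # restricting the universe restricts both the genes and the FDR universe
  restricted <- run_class_comparison(b$expression[[1]], labels,
    scheme = NULL, universe = b$kinases)
  expect_true(all(restricted$gene %in% b$kinases))
  expect_equal(restricted$q_value, bh_fdr(restricted$parametric_p))
  expect_error(
    run_class_comparison(b$expression[[1]], labels, scheme = NULL,
      universe = "NOSUCHGENE"),
    class = "sls_validation_error"
  )
})

test_that("untestable genes are excluded from the run and the FDR universe", {
  m <- matrix(rnorm(40), nrow = 4,
    dimnames = list(paste0("G", 1:4), paste0("S", 1:10)))
  m[1, 1:9] <- NA # one value in total: untestable
  ds <- expression_dataset(m)
  labels <- make_labels(paste0("S", 1:10), paste0("S", 1:5))
  expect_warning(
    res <- run_class_comparison(ds, labels, scheme = NULL),
    "untestable"
  )
  expect_equal(nrow(res), 3)
  expect_equal(attr(res, "untestable"), "G1")
  expect_equal(res$q_value, bh_fdr(res$parametric_p))

  # a single-gene run: q equals p (m = 1)
  one <- expression_dataset(m[4, , drop = FALSE])
  res1 <- run_class_comparison(one, labels, scheme = NULL)
  expect_equal(res1$q_value, res1$parametric_p)

  all_na <- expression_dataset(matrix(NA_real_, 2, 10,
    dimnames = list(c("A", "B"), paste0("S", 1:10))))
  expect_error(
    suppressWarnings(run_class_comparison(all_na, labels, scheme = NULL)),
    class = "sls_validation_error"
  )
})

test_that("type-I error is calibrated at the nominal level under the null", {
  # null generator: no planted effect; parametric rate only (the permutation
  # rate at full width is exercised in the acceptance suite)
  b <- simulate_bundle(sim_config(n_genes = 1500, n_kinases = 50,
    n_samples = 24, n_mutant = 14, n_planted = 0, effect_size = 0,
    missing_rate = 0, n_datasets = 1, seed = 31))
  labels <- make_labels(expr_samples(b$expression[[1]]), b$truth$c1_samples)
  res <- run_class_comparison(b$expression[[1]], labels, scheme = NULL)
  rate <- mean(res$parametric_p <= 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(rate - 0.05), 3 * se)
})
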