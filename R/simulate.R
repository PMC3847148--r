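#' Simulation configuration
#'
#' Validated configuration for [simulate_bundle()]. Defaults emulate the
#' shape of an NCI-60-style study: 60 cell lines of which 41 carry a
#' functional TP53 mutation, a kinome that is a small minority of the
#' genome, a handful of kinase genes truly up-regulated in the mutant
#' class, and a compound panel in which compounds targeting those genes are
#' more active in mutant lines.
#'
#' @param n_genes Total genes (default 1000).
#' @param n_kinases Kinase-annotated genes, a subset of the genes
#'   (default 100).
#' @param n_samples Samples per dataset (default 60).
#' @param n_mutant Samples in class `c1`, i.e. carrying a functional TP53
#'   mutation (default 41).
#' @param n_planted Kinase genes with a true up-shift in `c1`, shared by
#'   every dataset of the bundle (default 10).
#' @param effect_size Mean shift of planted genes in `c1`, in units of
#'   `sigma` (default 1.5).
#' @param sigma Residual Gaussian noise SD on the log-expression scale
#'   (default 1).
#' @param missing_rate Fraction of expression cells set missing
#'   (default 0.02).
#' @param n_datasets Expression datasets sharing the planted genes and the
#'   class structure, drawn independently (default 3).
#' @param n_compounds Compounds in the drug matrix (default 30).
#' @param n_target_compounds Compounds mapped to planted genes
#'   (default 8).
#' @param drug_effect z-score shift of target compounds in `c1` lines
#'   (default 1).
#' @param silent_rate Fraction of `c2` samples given a silent-class TP53
#'   record, exercising the non-functional-plus-wild-type grouping
#'   (default 0.3).
#' @param baseline_range Range of per-gene baseline log-expression,
#'   cosmetic heterogeneity only (default `c(4, 12)`).
#' @param seed Integer seed; the bundle is fully determined by it
#'   (default 1).
#' @return A list of class `sls_sim_config`.
#' @export
sim_config <- function(n_genes = 1000L, n_kinases = 100L, n_samples = 60L,
                       n_mutant = 41L, n_planted = 10L, effect_size = 1.5,
                       sigma = 1, missing_rate = 0.02, n_datasets = 3L,
                       n_compounds = 30L, n_target_compounds = 8L,
                       drug_effect = 1, silent_rate = 0.3,
                       baseline_range = c(4, 12), seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_kinases = as.integer(n_kinases),
    n_samples = as.integer(n_samples), n_mutant = as.integer(n_mutant),
    n_planted = as.integer(n_planted), effect_size = effect_size,
    sigma = sigma, missing_rate = missing_rate,
    n_datasets = as.integer(n_datasets),
    n_compounds = as.integer(n_compounds),
    n_target_compounds = as.integer(n_target_compounds),
    drug_effect = drug_effect, silent_rate = silent_rate,
    baseline_range = as.numeric(baseline_range), seed = as.integer(seed)
  )
  bad <- function(msg) sls_abort(msg, class = "sls_validation_error")
  with(cfg, {
    if (n_planted > n_kinases || n_kinases > n_genes || n_kinases < 1) {
      bad("need n_planted <= n_kinases <= n_genes, with at least one kinase")
    }
    if (missing_rate < 0 || missing_rate >= 1) bad("missing_rate must be in [0, 1)")
    if (effect_size < 0) bad("effect_size must be >= 0")
    if (sigma <= 0) bad("sigma must be > 0")
    if (n_mutant >= n_samples || n_mutant < 1) bad("need 1 <= n_mutant < n_samples")
    if (n_target_compounds > n_compounds) bad("n_target_compounds exceeds n_compounds")
    if (silent_rate < 0 || silent_rate > 1) bad("silent_rate must be in [0, 1]")
    if (n_datasets < 1) bad("need n_datasets >= 1")
  })
  class(cfg) <- "sls_sim_config"
  cfg
}

#' Simulate a complete input bundle
#'
#' Generates everything the pipeline consumes: `n_datasets` log-expression
#' datasets, a TP53 mutation table, a kinase list, a drug-sensitivity
#' z-score matrix over the same cell lines, a compound-to-target map, and
#' the ground truth. Expression is per-gene baseline plus Gaussian noise;
#' exactly `n_planted` kinase genes carry a `+effect_size * sigma` mean
#' shift in class `c1` in every dataset. Each `c1` sample receives one
#' functional TP53 record (missense/nonsense/frameshift mix); a
#' `silent_rate` fraction of `c2` samples receive a silent-class record.
#' Target compounds' z-scores are shifted `+drug_effect` in `c1` lines.
#' Genes are independent given the class (no gene-gene correlation).
#' The output is fully determined by `config$seed`.
#'
#' @param config An [sim_config()].
#' @return A list of class `sls_bundle` with elements `expression` (list of
#'   `sls_expr`), `mutations`, `kinases`, `drug_matrix`, `target_map`,
#'   `truth` (list: `planted_genes`, `target_compounds`, `c1_samples`) and
#'   `config`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sls_sim_config"))
  withr::with_seed(config$seed, {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    samples <- sprintf("S%03d", seq_len(config$n_samples))
    kinases <- sort(sample(genes, config$n_kinases))
    planted <- sort(sample(kinases, config$n_planted))
    c1_samples <- sort(sample(samples, config$n_mutant))
    is_c1 <- samples %in% c1_samples

    expression <- lapply(seq_len(config$n_datasets), function(d) {
      baseline <- runif(config$n_genes, config$baseline_range[1],
        config$baseline_range[2])
      m <- baseline +
        matrix(rnorm(config$n_genes * config$n_samples, sd = config$sigma),
          config$n_genes, config$n_samples)
      shift <- config$effect_size * config$sigma
      m[genes %in% planted, is_c1] <- m[genes %in% planted, is_c1] + shift
      if (config$missing_rate > 0) {
        drop <- runif(length(m)) < config$missing_rate
        m[drop] <- NA_real_
      }
      dimnames(m) <- list(genes, samples)
      expression_dataset(round(m, 6), name = sprintf("sim_dataset_%d", d))
    })

    functional_mix <- sample(FUNCTIONAL_CLASSES, config$n_mutant, replace = TRUE)
    mutations <- tibble(
      sample_id = c1_samples, gene = "TP53", mutation_class = functional_mix
    )
    c2_samples <- setdiff(samples, c1_samples)
    silent_carriers <- c2_samples[
      seq_len(round(config$silent_rate * length(c2_samples)))
    ]
    if (length(silent_carriers) > 0) {
      mutations <- bind_rows(mutations, tibble(
        sample_id = silent_carriers, gene = "TP53",
        mutation_class = sample(c("silent", "synonymous", "noncoding"),
          length(silent_carriers), replace = TRUE)
      ))
    }
    mutations <- arrange(mutations, .data$sample_id)
    mutations$tp53 <- TRUE

    compounds <- sprintf("D%03d", seq_len(config$n_compounds))
    target_compounds <- sort(sample(compounds, config$n_target_compounds))
    z <- matrix(rnorm(config$n_compounds * config$n_samples),
      config$n_compounds, config$n_samples,
      dimnames = list(compounds, samples))
    z[compounds %in% target_compounds, is_c1] <-
      z[compounds %in% target_compounds, is_c1] + config$drug_effect
    drug_matrix <- matrix_to_wide(round(z, 6), "compound")
    class(drug_matrix) <- c("sls_drug_matrix", class(drug_matrix))

    # Non-target compounds map to non-planted kinases so only true target
    # compounds intersect the planted set; if every kinase is planted the
    # distinction is impossible and the whole kinome is the pool.
    non_planted_kinases <- setdiff(kinases, planted)
    if (length(non_planted_kinases) == 0) non_planted_kinases <- kinases
    planted_pool <- if (length(planted) > 0) planted else kinases
    target_map <- purrr::map_dfr(compounds, function(cp) {
      pool <- if (cp %in% target_compounds) planted_pool else non_planted_kinases
      tibble(compound = cp,
        target = sort(sample(pool, sample(1:min(3, length(pool)), 1))))
    })

    bundle <- list(
      expression = expression,
      mutations = mutations,
      kinases = kinases,
      drug_matrix = drug_matrix,
      target_map = target_map,
      truth = list(
        planted_genes = planted,
        target_compounds = target_compounds,
        c1_samples = c1_samples
      ),
      config = config
    )
    class(bundle) <- "sls_bundle"
    bundle
  })
}

#' Write a simulated bundle to disk
#'
#' Writes every artifact in the package's on-disk dialects: one expression
#' TSV per dataset, `mutations.tsv`, `kinases.txt`, `gi50.tsv`,
#' `targets.tsv`, `truth.tsv`, and a `manifest.yaml` recording the full
#' configuration (seed included). Identical configurations produce
#' byte-identical bundles. Written bundles re-read cleanly through the
#' package's readers ([read_bundle()]).
#'
#' @param bundle An `sls_bundle` ([simulate_bundle()]).
#' @param directory Output directory, created if needed.
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "sls_bundle"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  f <- function(...) file.path(directory, ...)
  for (expr in bundle$expression) {
    readr::write_tsv(expr, f(paste0(dataset_name(expr), ".tsv")),
      progress = FALSE)
  }
  readr::write_tsv(bundle$mutations[c("sample_id", "gene", "mutation_class")],
    f("mutations.tsv"), progress = FALSE)
  writeLines(c("# kinase gene symbols", bundle$kinases), f("kinases.txt"))
  readr::write_tsv(bundle$drug_matrix, f("gi50.tsv"), progress = FALSE)
  readr::write_tsv(bundle$target_map, f("targets.tsv"), progress = FALSE)
  truth_tbl <- bind_rows(
    tibble(kind = "planted_gene", id = bundle$truth$planted_genes),
    tibble(kind = "target_compound", id = bundle$truth$target_compounds),
    tibble(kind = "c1_sample", id = bundle$truth$c1_samples)
  )
  readr::write_tsv(truth_tbl, f("truth.tsv"), progress = FALSE)
  manifest <- unclass(bundle$config)
  manifest$dataset_files <- vapply(bundle$expression, function(e) {
    paste0(dataset_name(e), ".tsv")
  }, character(1))
  yaml::write_yaml(manifest, f("manifest.yaml"))
  invisible(directory)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param directory Bundle directory.
#' @return A list with the same elements as [simulate_bundle()] output
#'   (truth is the on-disk tibble form).
#' @export
read_bundle <- function(directory) {
  f <- function(...) file.path(directory, ...)
  manifest <- yaml::read_yaml(f("manifest.yaml"))
  expression <- lapply(manifest$dataset_files, function(fn) {
    read_expression(f(fn), name = sub("\\.tsv$", "", fn))
  })
  truth_tbl <- read_results_table(f("truth.tsv"))
  out <- list(
    expression = expression,
    mutations = read_mutations(f("mutations.tsv")),
    kinases = read_gene_list(f("kinases.txt")),
    drug_matrix = read_drug_matrix(f("gi50.tsv")),
    target_map = read_target_map(f("targets.tsv")),
    truth = list(
      planted_genes = truth_tbl$id[truth_tbl$kind == "planted_gene"],
      target_compounds = truth_tbl$id[truth_tbl$kind == "target_compound"],
      c1_samples = truth_tbl$id[truth_tbl$kind == "c1_sample"]
    ),
    config = manifest
  )
  class(out) <- "sls_bundle"
  out
}
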