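#' End-to-end ontology-guided association pipeline
#'
#' Orchestrates a full run from a config: build (or simulate) the SNV and
#' gene matrices, compute ontotypes, cross-validate the chosen model, score
#' features by permutation importance, estimate the empirical FDR of the
#' consensus set, burden-test the top consensus systems, and partition
#' phenotypic variance (heritability and variance explained by the top
#' systems' genes). All outputs are written under `output_dir` together with
#' a manifest enabling bit-identical re-runs.
#'
#' @param config a named list or path to a YAML file. Recognized fields:
#'   `seed`, `output_dir`, `feature_level` (`"snv"`, `"gene"` or
#'   `"ontotype"`), `backend`, `alpha` (0.01), `n_perm` (100),
#'   `n_random_sets` (1000), `n_folds` (5), `model` (backend config list),
#'   `simulate` (list of [simulation_config()] fields) **or** `inputs` (list
#'   with `variants`, `ontology`, `annotations`, `phenotype` paths and
#'   optional `trait`), `max_burden_systems` (default 3).
#' @param quiet suppress progress messages.
#' @return The run manifest (list), invisibly written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  alpha <- config$alpha %||% 0.01
  n_perm <- config$n_perm %||% 100
  n_random <- config$n_random_sets %||% 1000
  n_folds <- config$n_folds %||% 5
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (n_folds < 2) abort("n_folds must be >= 2")
  feature_level <- match.arg(config$feature_level %||% "ontotype",
                             c("ontotype", "gene", "snv"))
  backend <- config$backend %||% "rf"
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) inform(paste0("[ontotyper] ", ...))
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e))))
  }
  outputs <- list()
  emit <- function(name, path) outputs[[name]] <<- path

  # stage 1: inputs --------------------------------------------------------
  say("stage 1/7: inputs")
  dat <- stage("inputs", {
    if (!is.null(config$simulate)) {
      cfg <- do.call(simulation_config,
                     c(config$simulate, list(seed = derive_seed(seed, "simulate"))))
      simulate_study(cfg)
    } else if (!is.null(config$inputs)) {
      inp <- config$inputs
      geno <- read_variants(inp$variants)
      ont <- load_ontology(inp$ontology, inp$annotations)
      if (is.na(ont$root)) ont <- join_under_root(ont)
      ont <- prune_ontology(ont)
      ph <- as_tibble(read.delim(inp$phenotype, check.names = FALSE))
      names(ph)[1] <- "strain"
      list(genotypes = geno, genes = collapse_to_genes(geno), ontology = ont,
           phenotype = ph, subpops = NULL, truth = NULL,
           trait = inp$trait)
    } else abort("config needs either `simulate` or `inputs`")
  })
  trait <- dat$trait %||% setdiff(names(dat$phenotype), "strain")[1]

  # stage 2: matrices ------------------------------------------------------
  say("stage 2/7: SNV and gene matrices")
  stage("matrices", {
    emit("snv_matrix", write_matrix_tsv(dat$genotypes, file.path(out_dir, "snv_matrix.tsv")))
    emit("gene_matrix", write_matrix_tsv(dat$genes, file.path(out_dir, "gene_matrix.tsv")))
  })

  # stage 3: ontotype ------------------------------------------------------
  say("stage 3/7: ontotype")
  onto <- stage("ontotype", {
    o <- dat$ontotype %||% compute_ontotype(dat$genes, dat$ontology)
    emit("ontotype_matrix", write_matrix_tsv(o, file.path(out_dir, "ontotype_matrix.tsv")))
    readr_write_tsv(tidy(o), file.path(out_dir, "ontotype_terms.tsv"))
    emit("ontotype_terms", file.path(out_dir, "ontotype_terms.tsv"))
    o
  })
  features <- switch(feature_level, ontotype = onto, gene = dat$genes,
                     snv = dat$genotypes)
  kinship <- if (backend == "mixed_rf")
    additive_grm(dat$genotypes, source = "pipeline snv set") else NULL

  # stage 4: cross-validated model -----------------------------------------
  say("stage 4/7: ", backend, " cross-validation on ", feature_level, " features")
  cv <- stage("models", {
    res <- cross_validate(features, dat$phenotype, trait = trait,
                          backend = backend, config = config$model %||% list(),
                          seed = seed, kinship = kinship, n_folds = n_folds)
    jsonlite::write_json(
      list(backend = res$backend, per_fold_r2 = res$per_fold_r2,
           mean_r2 = res$mean_r2, seed = res$seed),
      file.path(out_dir, "cv_result.json"), auto_unbox = TRUE, digits = NA)
    emit("cv_result", file.path(out_dir, "cv_result.json"))
    res
  })

  # stage 5: permutation importance ----------------------------------------
  say("stage 5/7: permutation importance (", n_perm, " permutations x ",
      n_folds, " folds)")
  imp <- stage("importance", {
    res <- cv_importance(features, dat$phenotype, trait = trait,
                         backend = if (backend %in% c("rf", "mixed_rf")) backend else "rf",
                         n_perm = n_perm, alpha = alpha, seed = seed,
                         config = config$model %||% list(), kinship = kinship,
                         n_folds = n_folds)
    readr_write_tsv(res$table, file.path(out_dir, "importance.tsv"))
    emit("importance", file.path(out_dir, "importance.tsv"))
    res
  })

  # stage 6: empirical FDR --------------------------------------------------
  say("stage 6/7: empirical FDR (scrambled feature matrix)")
  fdr <- stage("fdr", {
    res <- empirical_fdr(features, dat$phenotype, trait = trait,
                         backend = if (backend %in% c("rf", "mixed_rf")) backend else "rf",
                         n_perm = n_perm, alpha = alpha, seed = seed,
                         config = config$model %||% list(), kinship = kinship,
                         n_folds = n_folds, observed = imp)
    jsonlite::write_json(
      list(alpha = alpha, n_observed = res$n_observed, n_null = res$n_null,
           empirical_fdr = res$fdr, consensus = imp$consensus),
      file.path(out_dir, "consensus_fdr.json"), auto_unbox = TRUE, digits = NA)
    emit("consensus_fdr", file.path(out_dir, "consensus_fdr.json"))
    res
  })

  # stage 7: burden tests + heritability ------------------------------------
  say("stage 7/7: burden validation and variance partitioning")
  herit <- stage("genetics", {
    top_terms <- if (feature_level == "ontotype")
      head(imp$consensus, config$max_burden_systems %||% 3) else character()
    burdens <- lapply(top_terms, function(t) {
      sys_genes <- intersect(dat$ontology$propagated[[t]],
                             colnames(dat$genes$values))
      if (length(sys_genes) < 1) return(NULL)
      b <- burden_test(dat$genes, sys_genes, dat$phenotype, trait = trait,
                       n_random = n_random, seed = derive_seed(seed, "burden", t))
      c(list(term = t), glance(b))
    })
    K_add <- additive_grm(dat$genotypes, source = "pipeline snv set")
    K_epi <- epistatic_grm(K_add)
    h2 <- estimate_variance_components(dat$phenotype, K_add, K_epi, trait = trait)
    ve <- NULL
    if (feature_level == "ontotype" && length(imp$consensus)) {
      top_genes <- unique(unlist(lapply(head(imp$consensus, 10), function(t)
        intersect(dat$ontology$propagated[[t]], colnames(dat$genes$values)))))
      n_strains <- nrow(dat$genes$values)
      if (length(top_genes) && length(top_genes) <= n_strains / 2)
        ve <- variance_explained(dat$genes, top_genes, dat$phenotype, trait = trait)
    }
    jsonlite::write_json(
      list(burden = burdens, heritability = unclass(glance(h2)),
           variance_explained = if (!is.null(ve)) unclass(ve)),
      file.path(out_dir, "genetics.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    emit("genetics", file.path(out_dir, "genetics.json"))
    h2
  })

  manifest <- list(
    package = as.character(utils::packageVersion("ontotyper")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config[setdiff(names(config), "output_dir")],
    trait = trait,
    feature_level = feature_level,
    backend = backend,
    input_digests = if (!is.null(config$inputs))
      as.list(tools::md5sum(unlist(config$inputs[vapply(config$inputs, is.character,
                                                        logical(1))]))) else NULL,
    results = list(mean_r2 = cv$mean_r2,
                   n_consensus = length(imp$consensus),
                   empirical_fdr = fdr$fdr,
                   h2 = herit$h2),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("done: ", length(outputs), " stage outputs in ", out_dir)
  invisible(manifest)
}

readr_write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
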