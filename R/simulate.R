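#' Synthetic structured populations with planted causal systems
#'
#' The generator emulates the statistical structure of a panel of natural
#' haploid isolates: a population split into subpopulations whose allele
#' frequencies have drifted apart (Balding-Nichols model), binary
#' non-synonymous SNV calls mapped onto genes, a rooted DAG ontology over
#' those genes, and quantitative phenotypes driven by the mutation burden of
#' planted systems plus a polygenic background, subpopulation offsets and
#' Gaussian noise. Every pipeline stage can therefore be exercised, with
#' known ground truth, without any external download.
#'
#' @name synthetic-data
NULL

#' Simulation configuration
#'
#' @param n_strains number of haploid strains (default 500).
#' @param n_subpops number of subpopulations (default 3).
#' @param differentiation Balding-Nichols drift parameter in (0, 1); larger
#'   values give stronger subpopulation allele-frequency divergence
#'   (default 0.1, moderate structure for a species-wide isolate panel).
#' @param n_snvs number of binary SNVs (default 2000).
#' @param n_genes number of genes SNVs are assigned to (default 200).
#' @param ontology_depth,ontology_branching shape of the simulated DAG:
#'   levels below the root and children per term (defaults 3 and 3).
#' @param n_planted number of planted causal systems (default 1).
#' @param effect_size per-mutated-gene effect of each planted system before
#'   variance scaling; sign is kept (default -1, deleterious burden).
#' @param target_h2 target genetic fraction of phenotypic variance in
#'   \[0, 1\] (default 0.5).
#' @param structure_effect variance of subpopulation phenotype offsets
#'   relative to unit residual noise (default 0, no confounding).
#' @param polygenic_frac fraction of genes carrying a small additive
#'   background effect (default 0.1).
#' @param seed integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_strains = 500, n_subpops = 3,
                              differentiation = 0.1, n_snvs = 2000,
                              n_genes = 200, ontology_depth = 3,
                              ontology_branching = 3, n_planted = 1,
                              effect_size = -1, target_h2 = 0.5,
                              structure_effect = 0, polygenic_frac = 0.1,
                              seed = 1) {
  stopifnot(n_strains >= 1, n_subpops >= 1, n_snvs >= 1, n_genes >= 1,
            ontology_depth >= 1, ontology_branching >= 1)
  if (differentiation <= 0 || differentiation >= 1)
    abort("differentiation must be in (0, 1)")
  if (target_h2 < 0 || target_h2 > 1) abort("target_h2 must be in [0, 1]")
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a structured haploid population of binary SNV calls
#'
#' Ancestral allele frequencies are Uniform(0.05, 0.5); each subpopulation's
#' frequency is drawn from the Balding-Nichols Beta distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = differentiation`; haploid calls
#' are Bernoulli per strain. Each SNV is assigned to a gene uniformly at
#' random and labelled missense or (10\%) nonsense.
#'
#' @param cfg a [simulation_config()].
#' @return A list: `genotypes` (a `genotype_matrix`), `subpops` (named
#'   factor of strain subpopulation labels).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(derive_seed(cfg$seed, "population"), {
    strains <- sprintf("strain%04d", seq_len(cfg$n_strains))
    genes <- sprintf("GENE%03d", seq_len(cfg$n_genes))
    subpop <- factor(sprintf("pop%d", rep_len(seq_len(cfg$n_subpops), cfg$n_strains)))
    p_anc <- runif(cfg$n_snvs, 0.05, 0.5)
    F <- cfg$differentiation
    freq <- sapply(seq_len(cfg$n_subpops), function(s)
      rbeta(cfg$n_snvs, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F))
    values <- matrix(0L, cfg$n_strains, cfg$n_snvs)
    for (i in seq_len(cfg$n_strains))
      values[i, ] <- rbinom(cfg$n_snvs, 1, freq[, as.integer(subpop[i])])
    gene_of <- sample(genes, cfg$n_snvs, replace = TRUE)
    effect <- sample(c("missense", "nonsense"), cfg$n_snvs, replace = TRUE,
                     prob = c(0.9, 0.1))
    vid <- sprintf("chr1:%d:A>T", seq_len(cfg$n_snvs) * 10L)
    dimnames(values) <- list(strains, vid)
    ann <- tibble(variant_id = vid, chrom = "chr1", pos = seq_len(cfg$n_snvs) * 10L,
                  ref_allele = "A", alt_allele = "T", gene = gene_of,
                  effect_class = effect)
    list(genotypes = new_genotype_matrix(values, ann),
         subpops = setNames(subpop, strains))
  })
}

#' Simulate a rooted DAG ontology over the simulated genes
#'
#' Builds a layered hierarchy: `ontology_branching` children per term down
#' to `ontology_depth` levels, each non-top term also gaining a second
#' parent with small probability (so the result is a DAG, not a tree).
#' Genes are attached to the deepest-level terms, each gene to one leaf.
#'
#' @param cfg a [simulation_config()].
#' @return An `ontology` rooted at `"T:root"`, terms named `T:<level>.<k>`.
#' @export
simulate_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(derive_seed(cfg$seed, "ontology"), {
    genes <- sprintf("GENE%03d", seq_len(cfg$n_genes))
    levels_ <- vector("list", cfg$ontology_depth)
    edges <- list()
    parent_pool <- "T:root"
    for (d in seq_len(cfg$ontology_depth)) {
      n_terms <- length(parent_pool) * cfg$ontology_branching
      terms <- sprintf("T:%d.%d", d, seq_len(n_terms))
      first_parent <- rep(parent_pool, each = cfg$ontology_branching)
      edges[[d]] <- tibble(child = terms, parent = first_parent)
      # occasional second parent makes it a genuine DAG
      if (length(parent_pool) > 1) {
        extra <- terms[runif(n_terms) < 0.15]
        if (length(extra)) {
          second <- vapply(extra, function(t) {
            cand <- setdiff(parent_pool,
                            edges[[d]]$parent[edges[[d]]$child == t])
            cand[sample.int(length(cand), 1)]
          }, character(1))
          edges[[d]] <- bind_rows(edges[[d]],
                                  tibble(child = extra, parent = unname(second)))
        }
      }
      levels_[[d]] <- terms
      parent_pool <- terms
    }
    leaves <- levels_[[cfg$ontology_depth]]
    direct <- split(genes, sample(leaves, length(genes), replace = TRUE))
    new_ontology(bind_rows(edges), direct,
                 setNames(c("artificial", rep("data-driven",
                                              length(unlist(levels_)))),
                          c("T:root", unlist(levels_))))
  })
}

#' Simulate phenotypes driven by planted system burdens
#'
#' The genetic signal is `sum_planted beta * burden(strain, term)` plus a
#' small additive polygenic background over a random `polygenic_frac` of
#' genes; the genetic component is rescaled so that its realized share of
#' the phenotypic variance (against subpopulation offsets of variance
#' `structure_effect` and unit Gaussian noise) matches `target_h2`. Signs of
#' the planted effects are preserved by the rescaling.
#'
#' @param genes a `gene_matrix` for the simulated strains.
#' @param ont the simulated `ontology`.
#' @param cfg a [simulation_config()].
#' @param subpops named subpopulation factor from [simulate_population()]
#'   (optional; defaults to no structure offsets).
#' @param planted_terms optional character vector of terms to plant; default
#'   draws `cfg$n_planted` mid-sized terms (5-50 propagated genes).
#' @return A list: `phenotype` tibble (`strain`, `trait`), `truth` list
#'   (`planted` tibble of term/beta, `polygenic` tibble, `realized_h2`,
#'   `genetic`, `structure`, `noise` component vectors).
#' @export
simulate_phenotype <- function(genes, ont, cfg, subpops = NULL,
                               planted_terms = NULL) {
  stopifnot(inherits(cfg, "simulation_config"), inherits(ont, "ontology"))
  gvals <- if (inherits(genes, "gene_matrix")) genes$values else as.matrix(genes)
  onto <- compute_ontotype(genes, ont)
  with_seed(derive_seed(cfg$seed, "phenotype"), {
    sizes <- vapply(ont$propagated, length, integer(1))
    if (is.null(planted_terms)) {
      candidates <- ont$terms[sizes >= 5 & sizes <= 50 & ont$terms != ont$root]
      if (length(candidates) < cfg$n_planted)
        candidates <- setdiff(ont$terms, ont$root)
      planted_terms <- sample(candidates, cfg$n_planted)
    }
    if (!all(planted_terms %in% colnames(onto$values)))
      abort("planted terms missing from the ontotype matrix")
    beta <- rep_len(cfg$effect_size, length(planted_terms))
    planted_signal <- as.numeric(
      onto$values[, planted_terms, drop = FALSE] %*% beta)
    poly_genes <- sample(colnames(gvals),
                         max(1, round(cfg$polygenic_frac * ncol(gvals))))
    poly_beta <- rnorm(length(poly_genes), sd = 0.1 * max(abs(beta), 1e-8))
    polygenic <- as.numeric(gvals[, poly_genes, drop = FALSE] %*% poly_beta)
    genetic <- planted_signal + polygenic
    vg <- var(genetic)
    if (vg == 0 && cfg$target_h2 > 0)
      abort("zero genetic variance: cannot reach a positive target_h2")
    struct <- rep(0, nrow(gvals))
    if (!is.null(subpops) && cfg$structure_effect > 0) {
      offsets <- rnorm(nlevels(subpops), sd = sqrt(cfg$structure_effect))
      struct <- offsets[as.integer(subpops[rownames(gvals)])]
    }
    noise <- rnorm(nrow(gvals))   # unit residual noise
    v_env <- var(struct + noise)
    scale_g <- if (cfg$target_h2 == 0 || vg == 0) 0
      else if (cfg$target_h2 == 1) { noise <- noise * 0; v_env <- var(struct);
        if (v_env == 0) 1 else sqrt(1e6) }
      else sqrt(cfg$target_h2 / (1 - cfg$target_h2) * v_env / vg)
    genetic <- genetic * scale_g
    y <- genetic + struct + noise
    truth <- list(
      planted = tibble(term = planted_terms, beta = beta * scale_g),
      polygenic = tibble(gene = poly_genes, beta = poly_beta * scale_g),
      realized_h2 = if (var(y) > 0) var(genetic) / var(y) else 0,
      genetic = genetic, structure = struct, noise = noise)
    list(phenotype = tibble(strain = rownames(gvals), trait = y),
         truth = truth)
  })
}

#' Simulate a complete study (population + ontology + phenotype)
#'
#' Convenience wrapper chaining [simulate_population()],
#' [collapse_to_genes()], [simulate_ontology()] (pruned) and
#' [simulate_phenotype()].
#'
#' @param cfg a [simulation_config()].
#' @param prune prune the simulated ontology before use (default TRUE).
#' @return A list: `genotypes`, `subpops`, `genes`, `ontology`, `ontotype`,
#'   `phenotype`, `truth`, `config`.
#' @export
simulate_study <- function(cfg, prune = TRUE) {
  pop <- simulate_population(cfg)
  genes <- collapse_to_genes(pop$genotypes)
  ont <- simulate_ontology(cfg)
  if (prune) ont <- prune_ontology(ont)
  ph <- simulate_phenotype(genes, ont, cfg, subpops = pop$subpops)
  list(genotypes = pop$genotypes, subpops = pop$subpops, genes = genes,
       ontology = ont, ontotype = compute_ontotype(genes, ont),
       phenotype = ph$phenotype, truth = ph$truth, config = cfg)
}
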