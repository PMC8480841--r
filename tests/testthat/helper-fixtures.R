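# Programmatic fixtures shared across tests. Everything is generated in code
# so the suite is self-contained.

# --- toy VCF with SnpEff-style ANN annotations -----------------------------
# 5 sites: 2 missense, 1 stop_gained (nonsense), 1 synonymous, 1 intergenic.
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  ann <- function(allele, eff, gene)
    sprintf("ANN=%s|%s|MODERATE|%s|%s|transcript|t1|protein_coding|1/1|c.1A>T|p.X1Y",
            allele, eff, gene, gene)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    paste("chr1", "100", ".", "A", "T", ".", ".", ann("T", "missense_variant", "GENE1"),
          "GT", "0/0", "1/1", "0/1", sep = "\t"),
    paste("chr1", "200", "rs7", "C", "G", ".", ".", ann("G", "missense_variant", "GENE2"),
          "GT", "0", "0", "1", sep = "\t"),
    paste("chr1", "300", ".", "G", "A", ".", ".", ann("A", "stop_gained", "GENE2"),
          "GT", "1/1", "0/0", "./.", sep = "\t"),
    paste("chr1", "400", ".", "T", "C", ".", ".", ann("C", "synonymous_variant", "GENE3"),
          "GT", "0/1", "0/1", "0/0", sep = "\t"),
    paste("chr1", "500", ".", "A", "G", ".", ".", ann("G", "intergenic_region", ""),
          "GT", "0/0", "0/1", "0/0", sep = "\t"))
  writeLines(lines, path)
  path
}

# --- toy OBO + GAF ----------------------------------------------------------
write_toy_obo <- function(path = tempfile(fileext = ".obo")) {
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]", "id: GO:0001", "name: root process", "namespace: biological_process",
    "",
    "[Term]", "id: GO:0002", "name: child A", "namespace: biological_process",
    "is_a: GO:0001 ! root process",
    "",
    "[Term]", "id: GO:0003", "name: child B", "namespace: biological_process",
    "relationship: part_of GO:0001 ! root process",
    "",
    "[Term]", "id: GO:0004", "name: dead", "namespace: biological_process",
    "is_a: GO:0001", "is_obsolete: true",
    "",
    "[Typedef]", "id: part_of"), path)
  path
}

write_toy_gaf <- function(path = tempfile(fileext = ".gaf")) {
  row <- function(gene, term, qual = "") {
    paste(c("SGD", gene, gene, qual, term, "PMID:1", "IDA", "", "P",
            gene, "", "protein", "taxon:559292", "20200101", "SGD", "", ""),
          collapse = "\t")
  }
  writeLines(c("!gaf-version: 2.1",
               row("g1", "GO:0002"),
               row("g2", "GO:0003"),
               row("g3", "GO:0001"),
               row("g4", "GO:0002", qual = "NOT"),
               row("g5", "GO:9999")), path)  # unknown term -> skipped
  path
}

# --- random DAG ontology + brute-force propagation oracle -------------------
random_dag_ontology <- function(n_terms, n_genes, seed,
                                p_extra_edge = 0.3) {
  set.seed(seed)
  terms <- paste0("t", seq_len(n_terms))
  # guarantee connectivity: each non-root term gets one parent among
  # earlier terms, plus random extra parents (earlier index => no cycles)
  edges <- do.call(rbind, lapply(2:n_terms, function(i) {
    n_par <- min(i - 1L, 1 + stats::rbinom(1, 2, p_extra_edge / 2))
    parents <- sample(seq_len(i - 1L), n_par, replace = FALSE)
    data.frame(child = terms[i], parent = terms[parents])
  }))
  genes <- paste0("g", seq_len(n_genes))
  n_ann <- max(n_genes, round(n_genes * 1.5))
  direct <- split(sample(genes, n_ann, replace = TRUE),
                  sample(terms[-1], n_ann, replace = TRUE))
  direct <- lapply(direct, unique)
  new_ontology(edges, direct)
}

# descendant-set union oracle, independent of the package's propagation
brute_force_propagated <- function(ont) {
  desc_genes <- function(t) {
    seen <- character(); stack <- t
    while (length(stack)) {
      cur <- stack[1]; stack <- stack[-1]
      if (cur %in% seen) next
      seen <- c(seen, cur)
      stack <- c(stack, ont$edges$child[ont$edges$parent == cur])
    }
    out <- unlist(ont$direct[seen], use.names = FALSE)
    if (is.null(out)) character() else sort(unique(out))
  }
  setNames(lapply(ont$terms, desc_genes), ont$terms)
}

# --- small simulated study used by several test files -----------------------
small_study <- function(seed = 1, n_strains = 150, target_h2 = 0.6,
                        structure_effect = 0, ...) {
  cfg <- simulation_config(n_strains = n_strains, n_snvs = 400, n_genes = 60,
                           ontology_depth = 2, ontology_branching = 4,
                           target_h2 = target_h2,
                           structure_effect = structure_effect,
                           seed = seed, ...)
  simulate_study(cfg)
}
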