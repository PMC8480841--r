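#' Ontotype: system-level mutation-burden features
#'
#' The ontotype of a strain is the vector of mutated-gene counts per ontology
#' term: entry (strain, term) is the number of the strain's mutated genes that
#' fall in the term's propagated gene set. Counts are raw integers — the
#' encoding is deliberately parameter-free — so a parent term's count is
#' always at least each child's, and the root counts every mutated gene that
#' appears anywhere in the ontology.
#'
#' @param genes a `gene_matrix` from [collapse_to_genes()] (or a binary
#'   strains x genes matrix with dimnames).
#' @param ont a pruned, rooted [new_ontology()] object.
#' @param normalize divide each term's count by its propagated gene-set size
#'   (off by default; the canonical encoding is the raw count).
#' @param min_genes,max_genes optional term-size filters on the propagated
#'   gene-set size (default: keep every term).
#' @return An `ontotype_matrix`: non-negative integer `values`
#'   (strains x terms, terms in lexicographic order) and a `terms` tibble
#'   (`term`, `namespace`, `n_genes`).
#' @export
compute_ontotype <- function(genes, ont, normalize = FALSE,
                             min_genes = 1L, max_genes = Inf) {
  stopifnot(inherits(ont, "ontology"))
  gvals <- if (inherits(genes, "gene_matrix")) genes$values
           else assert_binary_matrix(genes, "gene mutation")
  ont_genes <- unique(unlist(ont$propagated, use.names = FALSE))
  shared <- intersect(colnames(gvals), ont_genes)
  if (!length(shared))
    abort(paste0(
      "no overlap between gene-matrix and ontology gene IDs\n",
      "  gene matrix e.g.: ", paste(head(colnames(gvals), 5), collapse = ", "), "\n",
      "  ontology e.g.:    ", paste(head(ont_genes, 5), collapse = ", ")))
  sizes <- vapply(ont$propagated, length, integer(1))
  terms <- sort(ont$terms[sizes[ont$terms] >= min_genes & sizes[ont$terms] <= max_genes])
  # membership matrix over the shared gene universe; genes outside the
  # ontology contribute to no term
  memb <- matrix(0L, length(shared), length(terms),
                 dimnames = list(shared, terms))
  for (t in terms) {
    g <- intersect(ont$propagated[[t]], shared)
    if (length(g)) memb[g, t] <- 1L
  }
  values <- gvals[, shared, drop = FALSE] %*% memb
  storage.mode(values) <- if (normalize) "double" else "integer"
  if (normalize) values <- sweep(values, 2, pmax(sizes[terms], 1L), "/")
  structure(list(
    values = values,
    terms = tibble(term = terms,
                   namespace = unname(ont$namespace[terms]),
                   n_genes = unname(sizes[terms]))),
    class = "ontotype_matrix")
}

#' @export
print.ontotype_matrix <- function(x, ...) {
  cat("<ontotype_matrix> ", nrow(x$values), " strains x ", ncol(x$values),
      " terms\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.ontotype_matrix <- function(x, ...) {
  bind_cols(tibble(strain = rownames(x$values)),
            as_tibble(x$values, .name_repair = "minimal"))
}

#' Term metadata of an ontotype matrix
#' @param x an `ontotype_matrix`.
#' @param ... unused.
#' @return The `terms` tibble (`term`, `namespace`, `n_genes`).
#' @export
tidy.ontotype_matrix <- function(x, ...) x$terms
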