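#' Ontology objects
#'
#' An `ontology` is a rooted directed acyclic graph of terms (biological
#' systems) carrying gene annotations. Each term has *direct* annotations
#' (genes assigned to it in the input) and *propagated* annotations (the union
#' of its direct genes and all genes of its descendant terms), so a parent
#' system always contains the genes of its child systems. This containment is
#' what makes per-system mutation-burden counts monotone along the hierarchy.
#'
#' @param edges two-column data frame of `child`, `parent` term IDs.
#' @param direct named list mapping term ID to a character vector of gene IDs.
#' @param namespace named character vector mapping term ID to one of
#'   `"BP"`, `"MF"`, `"CC"`, `"data-driven"`, `"artificial"`.
#' @return An object of class `ontology` with fields `terms`, `edges`,
#'   `direct`, `propagated`, `root` (NA when the DAG has several roots) and
#'   `namespace`.
#' @export
new_ontology <- function(edges, direct = list(), namespace = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("child", "parent") %in% names(edges)))
    abort("edges must have columns 'child' and 'parent'")
  edges <- distinct(edges, .data$child, .data$parent)
  if (any(edges$child == edges$parent)) abort("self-loop edge in ontology")
  terms <- sort(unique(c(edges$child, edges$parent, names(direct))))
  if (!length(terms)) abort("ontology has no terms")
  check_acyclic(edges)
  direct <- direct[intersect(names(direct), terms)]
  direct <- lapply(direct, function(g) sort(unique(as.character(g))))
  if (is.null(namespace)) namespace <- setNames(rep("data-driven", length(terms)), terms)
  namespace <- namespace[terms]
  names(namespace) <- terms
  namespace[is.na(namespace)] <- "data-driven"
  roots <- ontology_roots(terms, edges)
  ont <- structure(
    list(terms = terms, edges = edges, direct = direct,
         propagated = NULL, root = if (length(roots) == 1) roots else NA_character_,
         namespace = namespace),
    class = "ontology")
  ont$propagated <- propagate_annotations(ont)
  ont
}

check_acyclic <- function(edges) {
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")], directed = TRUE)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- names(comp$membership)[comp$membership == which(comp$csize > 1)[1]]
    abort(paste0("ontology structure is cyclic; one cycle involves: ",
                 paste(bad, collapse = " -> ")))
  }
  invisible(TRUE)
}

ontology_roots <- function(terms, edges) {
  sort(setdiff(terms, edges$child))
}

# Union direct annotations up the DAG: process terms children-before-parents
# (topological order of the child -> parent edge graph).
propagate_annotations <- function(ont) {
  g <- igraph::graph_from_data_frame(ont$edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = ont$terms))
  ord <- names(igraph::topo_sort(g, mode = "out"))
  children <- split(ont$edges$child, ont$edges$parent)
  prop <- setNames(vector("list", length(ont$terms)), ont$terms)
  for (t in ord) {
    sets <- c(list(ont$direct[[t]]), prop[children[[t]]])
    prop[[t]] <- sort(unique(unlist(sets, use.names = FALSE))) %||% character()
  }
  lapply(prop, function(x) if (is.null(x)) character() else x)
}

#' @export
print.ontology <- function(x, ...) {
  n_genes <- length(unique(unlist(x$propagated, use.names = FALSE)))
  cat("<ontology> ", length(x$terms), " terms, ", nrow(x$edges), " edges, ",
      n_genes, " annotated genes\n", sep = "")
  cat("  root: ", if (is.na(x$root)) "<multiple>" else x$root, "\n", sep = "")
  ns <- table(x$namespace)
  cat("  namespaces: ", paste(names(ns), ns, sep = ":", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Load an ontology with gene annotations
#'
#' Reads hierarchy structure from an OBO file (`is_a` and `part_of` edges are
#' both used; obsolete terms are dropped) or from a generic three-column
#' edge-list (`parent`, `child`, `type`) in which `type` is `"gene"` for
#' term-to-gene assignments and anything else (conventionally `"default"`)
#' for term-to-term containment — the dialect used by data-driven ontology
#' exports. Gene annotations may also come from a GAF 2.x file (column 2 =
#' gene, column 5 = term; rows whose qualifier contains `NOT` are skipped) or
#' a two-column gene/term TSV.
#'
#' @param structure_source path to an OBO file or an edge-list TSV.
#' @param annotation_source optional path to a GAF or two-column TSV of
#'   gene, term. Not needed when the edge-list embeds `gene` rows.
#' @param format `"auto"` (by file extension), `"obo"` or `"edgelist"`.
#' @return An [new_ontology()] object with propagated annotations.
#' @export
load_ontology <- function(structure_source, annotation_source = NULL,
                          format = c("auto", "obo", "edgelist")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.obo$", structure_source, ignore.case = TRUE))
      "obo" else "edgelist"
  parsed <- if (format == "obo") parse_obo(structure_source)
            else parse_ontology_edgelist(structure_source)
  direct <- parsed$direct
  if (!is.null(annotation_source)) {
    ann <- read_gene_annotations(annotation_source)
    known <- ann$term %in% c(parsed$edges$child, parsed$edges$parent, names(parsed$namespace))
    if (any(!known)) {
      warn(paste0(sum(!known), " annotation rows reference unknown terms; skipped"))
      ann <- ann[known, , drop = FALSE]
    }
    extra <- split(ann$gene, ann$term)
    for (t in names(extra))
      direct[[t]] <- unique(c(direct[[t]], extra[[t]]))
  }
  if (!length(direct) || !length(unlist(direct, use.names = FALSE)))
    abort("no gene annotations found: an ontology without genes is unusable")
  new_ontology(parsed$edges, direct, parsed$namespace)
}

obo_namespace_code <- c(biological_process = "BP", molecular_function = "MF",
                        cellular_component = "CC")

parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  if (!length(starts)) abort("no stanzas found in OBO file")
  bounds <- c(starts, length(lines) + 1L)
  edges <- list()
  namespace <- character()
  obsolete <- character()
  for (i in seq_along(starts)) {
    if (lines[starts[i]] != "[Term]") next
    block <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    id <- sub("^id: *", "", grep("^id: ", block, value = TRUE)[1])
    if (is.na(id)) next
    if (any(grepl("^is_obsolete: *true", block))) { obsolete <- c(obsolete, id); next }
    ns <- sub("^namespace: *", "", grep("^namespace: ", block, value = TRUE)[1])
    namespace[id] <- if (!is.na(ns) && ns %in% names(obo_namespace_code))
      obo_namespace_code[[ns]] else "data-driven"
    isa <- sub(" *!.*$", "", sub("^is_a: *", "", grep("^is_a: ", block, value = TRUE)))
    po <- grep("^relationship: *part_of ", block, value = TRUE)
    po <- sub(" *!.*$", "", sub("^relationship: *part_of *", "", po))
    parents <- c(isa, po)
    if (length(parents))
      edges[[id]] <- tibble(child = id, parent = parents)
  }
  edges <- bind_rows(edges)
  if (length(obsolete) && nrow(edges))
    edges <- filter(edges, !.data$child %in% obsolete, !.data$parent %in% obsolete)
  list(edges = edges, direct = list(), namespace = namespace)
}

parse_ontology_edgelist <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("parent", "child", "type"),
                   colClasses = "character")
  # tolerate a header row
  if (nrow(df) && !df$type[1] %in% c("default", "term", "gene", "is_a", "part_of"))
    df <- df[-1, , drop = FALSE]
  if (!nrow(df)) abort("empty ontology edge-list")
  gene_rows <- df$type == "gene"
  edges <- tibble(child = df$child[!gene_rows], parent = df$parent[!gene_rows])
  direct <- lapply(split(df$child[gene_rows], df$parent[gene_rows]), unique)
  list(edges = edges, direct = direct, namespace = NULL)
}

read_gene_annotations <- function(path) {
  first <- readLines(path, n = 50, warn = FALSE)
  body <- first[!startsWith(first, "!")]
  ncol1 <- length(strsplit(body[1], "\t", fixed = TRUE)[[1]])
  if (ncol1 >= 15) {                       # GAF 2.x
    df <- read.delim(path, header = FALSE, comment.char = "!",
                     stringsAsFactors = FALSE, quote = "")
    keep <- !grepl("(^|\\|)NOT($|\\|)", df[[4]])
    tibble(gene = as.character(df[[2]][keep]), term = as.character(df[[5]][keep]))
  } else {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) && (df[[1]][1] %in% c("gene", "gene_id")))
      df <- df[-1, , drop = FALSE]
    tibble(gene = as.character(df[[1]]), term = as.character(df[[2]]))
  }
}

#' Prune empty and redundant ontology terms
#'
#' Removes terms with no propagated genes and terms whose propagated gene set
#' is identical to that of at least one of their children (such a parent adds
#' no information beyond the more specific child). Parents of a removed term
#' are rewired to its children so paths through the hierarchy are preserved;
#' propagated gene sets of retained terms are unchanged. The root is always
#' retained.
#'
#' @param ont an [new_ontology()] object.
#' @return A pruned `ontology`.
#' @export
prune_ontology <- function(ont) {
  stopifnot(inherits(ont, "ontology"))
  prop <- ont$propagated
  children <- split(ont$edges$child, ont$edges$parent)
  removable <- vapply(ont$terms, function(t) {
    if (length(prop[[t]]) == 0) return(TRUE)
    any(vapply(children[[t]], function(ch) identical(prop[[ch]], prop[[t]]), logical(1)))
  }, logical(1))
  if (!is.na(ont$root) && removable[ont$root]) {
    inform("root term is redundant with a child but is retained as the single root")
    removable[ont$root] <- FALSE
  }
  edges <- ont$edges
  for (t in ont$terms[removable]) {
    pa <- edges$parent[edges$child == t]
    ch <- edges$child[edges$parent == t]
    edges <- edges[edges$child != t & edges$parent != t, , drop = FALSE]
    if (length(pa) && length(ch))
      edges <- bind_rows(edges, tidyr::expand_grid(child = ch, parent = pa))
  }
  keep <- ont$terms[!removable]
  edges <- distinct(filter(edges, .data$child %in% keep, .data$parent %in% keep))
  new_ontology(edges, ont$direct[intersect(names(ont$direct), keep)],
               ont$namespace[keep])
}

#' Join ontologies (or a multi-rooted ontology) under one artificial root
#'
#' Adds a new root term with one containment edge to each former root, so a
#' single hierarchy can span several ontology branches (e.g. the three GO
#' namespaces). Term namespaces and annotations are preserved; the new root's
#' propagated set is the union of every gene annotated anywhere.
#'
#' @param onts a single `ontology` or a list of them.
#' @param root_id ID for the artificial root.
#' @return A single-rooted `ontology`.
#' @export
join_under_root <- function(onts, root_id = "ROOT") {
  if (inherits(onts, "ontology")) onts <- list(onts)
  stopifnot(length(onts) >= 1, all(vapply(onts, inherits, logical(1), "ontology")))
  all_terms <- unlist(lapply(onts, `[[`, "terms"), use.names = FALSE)
  roots <- unlist(lapply(onts, function(o) ontology_roots(o$terms, o$edges)))
  if (length(roots) == 1 && roots == root_id && length(onts) == 1)
    return(onts[[1]])
  if (root_id %in% all_terms)
    abort(paste0("root_id '", root_id, "' collides with an existing term"))
  edges <- bind_rows(c(lapply(onts, `[[`, "edges"),
                       list(tibble(child = roots, parent = root_id))))
  direct <- do.call(c, lapply(onts, `[[`, "direct"))
  namespace <- c(do.call(c, lapply(onts, `[[`, "namespace")),
                 setNames("artificial", root_id))
  new_ontology(edges, direct, namespace)
}

#' Write an ontology as a three-column edge-list
#'
#' Emits the generic `parent  child  type` TSV dialect ([load_ontology()]
#' reads it back losslessly): one `default` row per containment edge and one
#' `gene` row per direct gene annotation.
#'
#' @param ont an `ontology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ontology_edgelist <- function(ont, path) {
  term_rows <- tibble(parent = ont$edges$parent, child = ont$edges$child,
                      type = "default")
  gene_rows <- purrr::map_dfr(names(ont$direct), function(t) {
    if (!length(ont$direct[[t]])) return(NULL)
    tibble(parent = t, child = ont$direct[[t]], type = "gene")
  })
  write.table(bind_rows(term_rows, gene_rows), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Ontology term summary table
#'
#' @param x an `ontology`.
#' @param ... unused.
#' @return A tibble with one row per term: `term`, `namespace`, `n_genes`
#'   (propagated), `n_direct`, `n_children`, `n_parents`.
#' @export
tidy.ontology <- function(x, ...) {
  tibble(
    term = x$terms,
    namespace = unname(x$namespace[x$terms]),
    n_genes = vapply(x$propagated[x$terms], length, integer(1)),
    n_direct = vapply(x$terms, function(t) length(x$direct[[t]]), integer(1)),
    n_children = vapply(x$terms, function(t) sum(x$edges$parent == t), integer(1)),
    n_parents = vapply(x$terms, function(t) sum(x$edges$child == t), integer(1)))
}
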