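#' Variant and gene mutation matrices
#'
#' The SNV matrix encodes each strain's genotype as presence/absence of each
#' retained non-synonymous variant (1 = any non-reference allele). Collapsing
#' variant columns by gene with an OR gate gives the binary gene-mutation
#' matrix: a gene scores 1 in a strain if it harbors at least one qualifying
#' variant there, regardless of how many.
#'
#' @name genotype-matrices
NULL

snpeff_effect_class <- function(effect) {
  out <- rep("other", length(effect))
  out[grepl("missense", effect)] <- "missense"
  out[grepl("stop_gained|\\bnonsense\\b", effect)] <- "nonsense"
  out[grepl("synonymous_variant|\\bsynonymous\\b", effect) &
        !grepl("non_synonymous|missense", effect)] <- "synonymous"
  # allow pre-classified inputs to pass through
  direct <- effect %in% c("missense", "nonsense", "synonymous", "other")
  out[direct] <- effect[direct]
  out
}

new_genotype_matrix <- function(values, annotations) {
  assert_binary_matrix(values, "genotype")
  storage.mode(values) <- "integer"
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    abort("strain and variant IDs must be unique")
  annotations <- as_tibble(annotations)
  if (!setequal(annotations$variant_id, colnames(values)))
    abort("every variant column needs exactly one annotation row")
  annotations <- annotations[match(colnames(values), annotations$variant_id), ]
  structure(list(values = values, annotations = annotations),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$values), " strains x ", ncol(x$values),
      " variants (", sum(x$values), " non-reference calls)\n", sep = "")
  print(count(x$annotations, .data$effect_class))
  invisible(x)
}

#' Read annotated variants into a binary SNV matrix
#'
#' Accepts a VCF 4.x with SnpEff-style `ANN` annotations, or a long-format
#' annotation TSV with columns `strain_id`, `variant_id`, `gene`, `effect`,
#' `value`. Only variants whose effect class is in `effect_filter` are
#' retained (default: the non-synonymous classes, missense and nonsense).
#' Any genotype carrying a non-reference allele scores 1; homozygous
#' reference scores 0; missing genotypes score 0 (with a reported count) or
#' drop the variant, per `missing_policy`. Multi-allelic sites are decomposed
#' into one column per alternate allele.
#'
#' @param source path to a VCF (`.vcf`) or annotation TSV.
#' @param effect_filter character subset of
#'   `c("missense", "nonsense", "synonymous", "other")`.
#' @param missing_policy `"as_reference"` (score 0) or `"drop_variant"`.
#' @return A `genotype_matrix`: binary `values` (strains x variants) plus an
#'   `annotations` tibble (`variant_id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `gene`, `effect_class`).
#' @export
read_variants <- function(source, effect_filter = c("missense", "nonsense"),
                          missing_policy = c("as_reference", "drop_variant")) {
  missing_policy <- match.arg(missing_policy)
  bad <- setdiff(effect_filter, c("missense", "nonsense", "synonymous", "other"))
  if (length(bad)) abort(paste0("unknown effect classes: ", paste(bad, collapse = ", ")))
  is_vcf <- grepl("\\.vcf(\\.gz)?$", source, ignore.case = TRUE) ||
    startsWith(readLines(source, n = 1, warn = FALSE), "##fileformat=VCF")
  gm <- if (is_vcf) read_variants_vcf(source, missing_policy)
        else read_variants_tsv(source)
  keep <- gm$annotations$effect_class %in% effect_filter
  if (!any(keep))
    abort("no variants survive the effect filter")
  new_genotype_matrix(gm$values[, gm$annotations$variant_id[keep], drop = FALSE],
                      gm$annotations[keep, , drop = FALSE])
}

read_variants_vcf <- function(path, missing_policy) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!ncol(vcf@gt) || ncol(vcf@gt) < 2) abort("VCF has no sample genotype columns")
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  ann <- vcfR::extract.info(vcf, element = "ANN")
  strains <- colnames(gt)
  cols <- list(); annotations <- list(); n_missing <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ann_entries <- if (!is.na(ann[i])) strsplit(ann[i], ",", fixed = TRUE)[[1]] else character()
    ann_fields <- lapply(ann_entries, function(e) strsplit(e, "|", fixed = TRUE)[[1]])
    gts <- gt[i, ]
    miss <- is.na(gts) | gts %in% c(".", "./.", ".|.")
    n_missing <- n_missing + sum(miss)
    for (a in seq_along(alts)) {
      if (alts[a] == fix[i, "REF"]) next
      hit <- Filter(function(f) length(f) >= 4 && f[1] == alts[a], ann_fields)
      eff <- if (length(hit)) snpeff_effect_class(hit[[1]][2]) else "other"
      gene <- if (length(hit)) hit[[1]][4] else NA_character_
      if (length(hit) && (is.na(gene) || gene == "") && length(hit[[1]]) >= 5)
        gene <- hit[[1]][5]
      vid <- fix[i, "ID"]
      synth <- paste0(fix[i, "CHROM"], ":", fix[i, "POS"], ":",
                      fix[i, "REF"], ">", alts[a])
      vid <- if (is.na(vid) || vid == ".") synth
             else if (length(alts) > 1) paste0(vid, ":", alts[a]) else vid
      carries <- vapply(strsplit(gts, "[/|]"), function(al) as.character(a) %in% al,
                        logical(1))
      carries[miss] <- if (missing_policy == "as_reference") FALSE else NA
      if (missing_policy == "drop_variant" && any(is.na(carries))) next
      cols[[vid]] <- as.integer(carries)
      annotations[[vid]] <- tibble(
        variant_id = vid, chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref_allele = fix[i, "REF"], alt_allele = alts[a],
        gene = gene, effect_class = eff)
    }
  }
  if (!length(cols)) abort("no usable variant records in VCF")
  if (n_missing > 0)
    inform(paste0(n_missing, " missing genotypes handled by policy '",
                  missing_policy, "'"))
  values <- do.call(cbind, cols)
  rownames(values) <- strains
  list(values = values, annotations = bind_rows(annotations))
}

read_variants_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain_id", "variant_id", "gene", "effect")
  if (!all(need %in% names(df)))
    abort(paste0("annotation TSV needs columns: ", paste(need, collapse = ", ")))
  if (!"value" %in% names(df)) df$value <- 1L
  strains <- unique(df$strain_id)
  variants <- unique(df$variant_id)
  values <- matrix(0L, length(strains), length(variants),
                   dimnames = list(strains, variants))
  values[cbind(match(df$strain_id, strains), match(df$variant_id, variants))] <-
    as.integer(df$value > 0)
  ann <- distinct(as_tibble(df), .data$variant_id, .keep_all = TRUE)
  annotations <- tibble(
    variant_id = ann$variant_id,
    chrom = if ("chrom" %in% names(ann)) ann$chrom else NA_character_,
    pos = if ("pos" %in% names(ann)) as.integer(ann$pos) else NA_integer_,
    ref_allele = if ("ref" %in% names(ann)) ann$ref else NA_character_,
    alt_allele = if ("alt" %in% names(ann)) ann$alt else NA_character_,
    gene = ann$gene,
    effect_class = snpeff_effect_class(ann$effect))
  list(values = values, annotations = annotations)
}

new_gene_matrix <- function(values) {
  assert_binary_matrix(values, "gene mutation")
  storage.mode(values) <- "integer"
  structure(list(values = values), class = "gene_matrix")
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat("<gene_matrix> ", nrow(x$values), " strains x ", ncol(x$values),
      " genes (", sum(x$values), " mutated gene calls)\n", sep = "")
  invisible(x)
}

#' Collapse an SNV matrix to a binary gene-mutation matrix (OR gate)
#'
#' @param gm a `genotype_matrix` from [read_variants()].
#' @return A `gene_matrix` whose `values` cell (strain, gene) is 1 iff at
#'   least one retained variant of that gene is present in that strain.
#'   Genes are ordered lexicographically; strain order is preserved.
#' @export
collapse_to_genes <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gene <- gm$annotations$gene
  if (anyNA(gene) || any(gene == ""))
    abort("every variant needs a gene assignment to collapse to genes")
  genes <- sort(unique(gene))
  ind <- matrix(0L, ncol(gm$values), length(genes),
                dimnames = list(colnames(gm$values), genes))
  ind[cbind(seq_along(gene), match(gene, genes))] <- 1L
  vals <- (gm$values %*% ind > 0) * 1L
  new_gene_matrix(vals)
}

#' @export
as_tibble.genotype_matrix <- function(x, ...) {
  bind_cols(tibble(strain = rownames(x$values)),
            as_tibble(x$values, .name_repair = "minimal"))
}

#' @export
as_tibble.gene_matrix <- function(x, ...) {
  bind_cols(tibble(strain = rownames(x$values)),
            as_tibble(x$values, .name_repair = "minimal"))
}

#' Write a strains-by-features matrix record as TSV (strains in rows)
#' @param x a `genotype_matrix`, `gene_matrix` or `ontotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- as.data.frame(x$values)
  df <- cbind(strain = rownames(x$values), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
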