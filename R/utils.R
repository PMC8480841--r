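#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats var sd setNames predict aov TukeyHSD phyper fisher.test
#'   p.adjust optim rnorm runif rbinom rbeta coef lm anova quantile median
#' @importFrom utils head read.delim write.table
#' @import dplyr
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# Deterministic substream seeds: every source of randomness in the package
# draws its seed from the user's single seed plus a stream label, so stages
# can be re-run independently and still reproduce a full pipeline run.
derive_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(labels)) h <- (h * 131 + cp) %% 2147483563L
  as.integer((as.numeric(seed) %% 2147483563 * 48271 + h) %% 2147483562 + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

assert_binary_matrix <- function(m, what = "matrix") {
  if (!is.matrix(m) || !all(m %in% c(0L, 1L)))
    abort(paste0(what, " must be a binary matrix"))
  invisible(m)
}

# Coerce a strains-by-features input to a numeric matrix with strain rownames.
# Accepts the package's matrix records, plain matrices, or a data frame whose
# first column (or a column named strain/strain_id) holds strain IDs.
as_feature_matrix <- function(x) {
  if (inherits(x, c("genotype_matrix", "gene_matrix", "ontotype_matrix")))
    return(x$values)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("feature matrix must have strain rownames")
    return(x)
  }
  if (is.data.frame(x)) {
    id_col <- intersect(c("strain", "strain_id"), names(x))
    id_col <- if (length(id_col)) id_col[1] else names(x)[1]
    m <- as.matrix(x[setdiff(names(x), id_col)])
    rownames(m) <- as.character(x[[id_col]])
    storage.mode(m) <- "double"
    return(m)
  }
  abort("cannot interpret input as a strains x features matrix")
}

# Phenotype input: tibble with a strain column plus trait columns, or a named
# numeric vector (single trait). Returns named numeric vector for `trait`.
extract_trait <- function(pheno, trait = NULL) {
  if (is.numeric(pheno) && !is.null(names(pheno))) return(pheno)
  if (!is.data.frame(pheno)) abort("phenotype must be a data frame or named vector")
  id_col <- intersect(c("strain", "strain_id"), names(pheno))
  if (!length(id_col)) abort("phenotype table needs a 'strain' column")
  traits <- setdiff(names(pheno), id_col[1])
  if (is.null(trait)) {
    if (length(traits) != 1)
      abort("multiple traits present; supply `trait`")
    trait <- traits
  }
  if (!trait %in% traits) abort(paste0("trait '", trait, "' not in phenotype table"))
  setNames(as.numeric(pheno[[trait]]), as.character(pheno[[id_col[1]]]))
}

r_squared <- function(obs, pred) {
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) abort("R^2 undefined for a constant response")
  1 - ss_res / ss_tot
}
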