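#' Burden validation, relationship matrices and heritability
#'
#' Once a system is flagged as important, its effect is validated directly:
#' strains are stratified by how many of the system's genes are mutated, the
#' phenotype is compared across strata with a one-way ANOVA and Tukey's HSD,
#' and the stratified means are referenced against strata built from random
#' gene sets of the same size drawn outside the system. Variance partitioning
#' uses genomic relationship matrices: the additive GRM `K = Z Z'/m` from
#' standardized genotypes and its Hadamard square for pairwise epistasis.
#'
#' @name genetics
NULL

#' Additive genomic relationship matrix
#'
#' Centers and scales each polymorphic SNV column to unit variance
#' (monomorphic columns are dropped with a message) and returns
#' `K = Z Z' / m`.
#'
#' @param Z strains x SNVs binary matrix (or a `genotype_matrix`).
#' @param source short descriptor of the SNV set.
#' @return A `kinship` object: `matrix`, `kind = "additive"`, `source`, `m`.
#' @export
additive_grm <- function(Z, source = "snv") {
  if (inherits(Z, "genotype_matrix")) Z <- Z$values
  Z <- as.matrix(Z)
  sds <- apply(Z, 2, sd)
  mono <- sds == 0
  if (all(mono)) abort("all SNV columns are monomorphic")
  if (any(mono))
    inform(paste0(sum(mono), " monomorphic columns dropped from GRM"))
  Zs <- scale(Z[, !mono, drop = FALSE])
  m <- ncol(Zs)
  K <- tcrossprod(Zs) / m
  dimnames(K) <- list(rownames(Z), rownames(Z))
  new_kinship(K, kind = "additive", source = source, m = m)
}

#' Epistatic relationship matrix (Hadamard square of the additive GRM)
#'
#' @param K an additive `kinship` (or plain matrix).
#' @return A `kinship` with `kind = "epistatic"`; entrywise square of `K`,
#'   positive semi-definite by the Schur product theorem.
#' @export
epistatic_grm <- function(K) {
  Km <- if (inherits(K, "kinship")) K$matrix else as.matrix(K)
  new_kinship(Km * Km, kind = "epistatic",
              source = if (inherits(K, "kinship")) K$source else "unknown",
              m = if (inherits(K, "kinship")) K$m else NA_integer_)
}

new_kinship <- function(matrix, kind, source = "unknown", m = NA_integer_) {
  if (!isSymmetric(matrix, tol = 1e-8)) abort("kinship matrix must be symmetric")
  ev <- min(eigen((matrix + t(matrix)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values)
  if (ev < -1e-8 * max(1, max(abs(matrix))))
    abort("kinship matrix is not positive semi-definite")
  structure(list(matrix = (matrix + t(matrix)) / 2, kind = kind,
                 source = source, m = m),
            class = "kinship")
}

#' @export
print.kinship <- function(x, ...) {
  cat("<kinship> ", x$kind, ", ", nrow(x$matrix), " strains",
      if (!is.na(x$m)) paste0(", ", x$m, " markers"),
      " (", x$source, ")\n", sep = "")
  invisible(x)
}

#' Mutation-burden test of a system against random gene sets
#'
#' Strains are binned by their number of mutated genes within
#' `system_genes`; bins with fewer than `min_group_size` strains are merged
#' into the nearest lower bin (bin 0 merges upward). Phenotype differences
#' across bins are tested by one-way ANOVA with Tukey HSD post-hoc
#' comparisons. A null reference repeats the binning for `n_random` gene
#' sets of the same size drawn (without replacement per draw) from genes
#' outside the system.
#'
#' @param genes a `gene_matrix` (or binary strains x genes matrix).
#' @param system_genes character vector of the system's genes.
#' @param pheno named numeric trait vector or phenotype tibble.
#' @param trait trait name when `pheno` is a table.
#' @param n_random number of random gene-set draws (default 1000).
#' @param seed integer seed.
#' @param min_group_size minimum strains per retained bin (default 5).
#' @return A `burden_result`: `groups` tibble (`bin`, `n`, `mean`),
#'   `anova_F`, `anova_df`, `anova_p`, `tukey` tibble, and `random_null`
#'   tibble of per-draw per-bin means.
#' @export
burden_test <- function(genes, system_genes, pheno, trait = NULL,
                        n_random = 1000, seed = 1, min_group_size = 5) {
  gvals <- if (inherits(genes, "gene_matrix")) genes$values else as.matrix(genes)
  y <- extract_trait(pheno, trait)
  shared <- intersect(rownames(gvals), names(y[!is.na(y)]))
  gvals <- gvals[shared, , drop = FALSE]; y <- y[shared]
  missing_genes <- setdiff(system_genes, colnames(gvals))
  if (length(missing_genes))
    abort(paste0("system genes absent from gene matrix: ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  bin <- bin_burden(rowSums(gvals[, system_genes, drop = FALSE]), min_group_size)
  if (length(unique(bin)) < 2) abort("system burden non-informative: < 2 usable bins")
  fit <- aov(y ~ bin, data = data.frame(y = y, bin = bin))
  an <- anova(fit)
  tk <- TukeyHSD(fit)$bin
  tukey <- tibble(comparison = rownames(tk), difference = tk[, "diff"],
                  lower = tk[, "lwr"], upper = tk[, "upr"],
                  p_adjusted = tk[, "p adj"])
  bin_n <- as.integer(table(bin))
  bin_mean <- as.numeric(tapply(y, bin, mean))
  groups <- tibble(bin = levels(bin), n = bin_n, mean = bin_mean)
  outside <- setdiff(colnames(gvals), system_genes)
  k <- length(system_genes)
  random_null <- NULL
  if (n_random > 0 && length(outside) >= k) {
    random_null <- purrr::map_dfr(seq_len(n_random), function(d) {
      draw <- with_seed(derive_seed(seed, "burden_draw", d),
                        sample(outside, k))
      b <- bin_burden(rowSums(gvals[, draw, drop = FALSE]), min_group_size)
      tibble(draw = d, bin = levels(b)[as.integer(b)], value = y) |>
        group_by(.data$draw, .data$bin) |>
        summarise(n = dplyr::n(), mean = mean(.data$value), .groups = "drop")
    })
  } else if (n_random > 0) {
    warn("not enough genes outside the system for random draws; null skipped")
  }
  structure(list(groups = groups, anova_F = an$`F value`[1],
                 anova_df = c(an$Df[1], an$Df[2]), anova_p = an$`Pr(>F)`[1],
                 tukey = tukey, random_null = random_null,
                 system_genes = system_genes, n_random = n_random, seed = seed),
            class = "burden_result")
}

# Bin integer burden counts; sparse bins (< min_group_size) merge into the
# nearest lower bin, so the top bin reads ">=k". Bin 0 merges upward if thin.
bin_burden <- function(counts, min_group_size) {
  lev <- sort(unique(counts))
  repeat {
    b <- lev[findInterval(counts, lev)]
    tab <- table(factor(b, levels = lev))
    small <- which(tab < min_group_size)
    if (!length(small) || length(lev) <= 2) break
    i <- small[length(small)]
    lev <- if (i == 1) lev[-2] else lev[-i]
  }
  b <- lev[findInterval(counts, lev)]
  labels <- ifelse(lev == max(lev) & max(counts) > max(lev),
                   paste0(">=", lev), as.character(lev))
  factor(labels[match(b, lev)], levels = labels)
}

#' @export
print.burden_result <- function(x, ...) {
  cat("<burden_result> ", length(x$system_genes), "-gene system, bins: ",
      paste0(x$groups$bin, " (n=", x$groups$n, ")", collapse = ", "), "\n",
      "  one-way ANOVA: F(", x$anova_df[1], ",", x$anova_df[2], ") = ",
      formatC(x$anova_F, digits = 3, format = "g"), ", p = ",
      formatC(x$anova_p, digits = 3, format = "g"), "\n", sep = "")
  invisible(x)
}

#' @rdname burden_test
#' @param x a `burden_result`.
#' @param ... unused.
#' @export
tidy.burden_result <- function(x, ...) x$tukey

#' @rdname burden_test
#' @export
glance.burden_result <- function(x, ...) {
  tibble(anova_F = x$anova_F, df1 = x$anova_df[1], df2 = x$anova_df[2],
         anova_p = x$anova_p, n_bins = nrow(x$groups),
         n_random = x$n_random)
}

#' @rdname burden_test
#' @param object a `burden_result`.
#' @export
autoplot.burden_result <- function(object, ...) {
  df <- object$groups
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$mean)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "mutated genes in system", y = "mean phenotype") +
    ggplot2::theme_minimal()
  if (!is.null(object$random_null))
    p <- p + ggplot2::geom_boxplot(
      data = object$random_null,
      ggplot2::aes(.data$bin, .data$mean),
      alpha = 0.3, colour = "steelblue", outlier.size = 0.3)
  p
}

#' REML variance components and narrow-sense heritability
#'
#' Fits `y = mu + g_a + g_i + e` with `cov(g_a) = sigma2_a * K_add`,
#' `cov(g_i) = sigma2_i * K_epi` (omitted when `K_epi` is `NULL`) and
#' `cov(e) = sigma2_e * I` by restricted maximum likelihood, all variances
#' constrained non-negative. Narrow-sense heritability is the additive share
#' `h2 = sigma2_a / (sigma2_a + sigma2_i + sigma2_e)`.
#'
#' @param y named numeric trait vector (or phenotype tibble plus `trait`).
#' @param K_add additive `kinship`.
#' @param K_epi optional epistatic `kinship`.
#' @param trait trait name when `y` is a table.
#' @return A `heritability_estimate`: `sigma2_a`, `sigma2_i`, `sigma2_e`,
#'   `h2`, `snv_set`, `method`, `converged`.
#' @export
estimate_variance_components <- function(y, K_add, K_epi = NULL, trait = NULL) {
  yv <- extract_trait(y, trait)
  yv <- yv[!is.na(yv)]
  if (var(yv) == 0) abort("constant phenotype")
  Ka <- if (inherits(K_add, "kinship")) K_add$matrix else as.matrix(K_add)
  strains <- intersect(names(yv), rownames(Ka))
  if (length(strains) < 10) abort("too few strains shared with the kinship matrix")
  yv <- yv[strains]; Ka <- Ka[strains, strains]
  K_list <- list(Ka)
  if (!is.null(K_epi)) {
    Ke <- if (inherits(K_epi, "kinship")) K_epi$matrix else as.matrix(K_epi)
    K_list <- c(K_list, list(Ke[strains, strains]))
  }
  vc <- reml_fit(yv, K_list)
  if (!vc$converged) warn("REML did not fully converge; returning boundary estimate")
  s_a <- vc$sigma2[1]
  s_i <- if (length(vc$sigma2) > 1) vc$sigma2[2] else 0
  s_e <- vc$sigma2_e
  structure(list(sigma2_a = s_a, sigma2_i = s_i, sigma2_e = s_e,
                 h2 = s_a / (s_a + s_i + s_e),
                 snv_set = if (inherits(K_add, "kinship")) K_add$source else "unknown",
                 method = "REML (L-BFGS-B on log variances)",
                 n_strains = length(strains), converged = vc$converged),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat("<heritability_estimate> h2 = ", formatC(x$h2, digits = 3, format = "f"),
      "  (sigma2_a=", formatC(x$sigma2_a, digits = 3, format = "g"),
      ", sigma2_i=", formatC(x$sigma2_i, digits = 3, format = "g"),
      ", sigma2_e=", formatC(x$sigma2_e, digits = 3, format = "g"), ")\n", sep = "")
  invisible(x)
}

#' @rdname estimate_variance_components
#' @param x a `heritability_estimate`.
#' @param ... unused.
#' @export
tidy.heritability_estimate <- function(x, ...) {
  tibble(component = c("additive", "epistatic", "residual"),
         variance = c(x$sigma2_a, x$sigma2_i, x$sigma2_e))
}

#' @rdname estimate_variance_components
#' @export
glance.heritability_estimate <- function(x, ...) {
  tibble(h2 = x$h2, sigma2_a = x$sigma2_a, sigma2_i = x$sigma2_i,
         sigma2_e = x$sigma2_e, n_strains = x$n_strains,
         converged = x$converged)
}

#' Phenotypic variance explained by a gene set
#'
#' In-sample coefficient of determination of ordinary least squares of the
#' trait on the selected genes' binary mutation indicators (with intercept).
#' Collinear columns are handled through the pseudoinverse.
#'
#' @param genes a `gene_matrix` (or binary matrix).
#' @param gene_set non-empty character vector of genes in the matrix.
#' @param y named numeric trait vector or phenotype tibble.
#' @param trait trait name when `y` is a table.
#' @return A tibble: `r2`, `n_genes`, `n_strains`.
#' @export
variance_explained <- function(genes, gene_set, y, trait = NULL) {
  gvals <- if (inherits(genes, "gene_matrix")) genes$values else as.matrix(genes)
  if (!length(gene_set)) abort("gene_set is empty")
  missing_genes <- setdiff(gene_set, colnames(gvals))
  if (length(missing_genes))
    abort(paste0("genes absent from matrix: ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  yv <- extract_trait(y, trait)
  shared <- intersect(rownames(gvals), names(yv[!is.na(yv)]))
  yv <- yv[shared]
  if (length(gene_set) > length(shared))
    abort("more genes than strains: in-sample R^2 would be vacuous")
  X <- cbind(1, gvals[shared, gene_set, drop = FALSE])
  # pseudoinverse OLS: robust to collinear indicator columns
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-10
  beta <- sv$v[, pos, drop = FALSE] %*%
    (crossprod(sv$u[, pos, drop = FALSE], yv) / sv$d[pos])
  fitted <- as.numeric(X %*% beta)
  tibble(r2 = max(0, r_squared(yv, fitted)),
         n_genes = length(gene_set), n_strains = length(shared))
}
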