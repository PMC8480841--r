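#' Permutation-null feature importance and empirical FDR
#'
#' Which systems drive prediction is decided by response-permutation tests:
#' the observed out-of-bag permutation importance of each feature is compared
#' with its importance distribution over refits on a permuted response. With
#' `R` permutations the empirical P value is `(1 + #{null >= observed}) /
#' (1 + R)` (one is added to numerator and denominator so P is never zero).
#' Features with P below `alpha` in every cross-validation fold are the
#' consensus set; an empirical FDR for that set is obtained by rerunning the
#' identical pipeline on a scrambled feature matrix and counting how many
#' features still pass.
#'
#' @name importance
NULL

#' Single-fold permutation importance
#'
#' Fits the model, records each feature's importance, then repeats the fit
#' `n_perm` times on a response permuted with deterministically derived
#' seeds; the empirical P value per feature uses the add-one rule above.
#'
#' @param X strains x features numeric matrix.
#' @param y numeric response.
#' @param backend `"rf"` or `"mixed_rf"` (importance is taken from the forest
#'   component after structure adjustment).
#' @param n_perm number of response permutations (default 100).
#' @param seed integer seed; permutation `r` uses a seed derived from
#'   `(seed, r)`.
#' @param config forest options, see [fit_random_forest()].
#' @param kinship kinship matrix, required for `mixed_rf`.
#' @return An `importance_fold`: tibble `$table` (`feature`, `importance`,
#'   `p_value`), `$null` matrix (n_perm x features), `n_perm`, `seed`.
#' @export
permutation_importance <- function(X, y, backend = "rf", n_perm = 100,
                                   seed = 1, config = list(), kinship = NULL) {
  stopifnot(n_perm >= 1)
  backend <- match.arg(backend, c("rf", "mixed_rf"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  imp_of <- function(yy, fit_seed) {
    fit <- fit_backend(backend, X, yy, config, seed = fit_seed, K = kinship)
    if (backend == "mixed_rf") fit$forest$importance else fit$importance
  }
  obs <- imp_of(y, derive_seed(seed, "observed"))
  null <- matrix(NA_real_, n_perm, ncol(X), dimnames = list(NULL, colnames(X)))
  for (r in seq_len(n_perm)) {
    y_perm <- with_seed(derive_seed(seed, "perm", r), sample(y))
    null[r, ] <- imp_of(y_perm, derive_seed(seed, "perm_fit", r))
  }
  p <- (1 + colSums(sweep(null, 2, obs, ">=") )) / (1 + n_perm)
  structure(list(table = tibble(feature = colnames(X),
                                importance = unname(obs),
                                p_value = unname(p)),
                 null = null, n_perm = n_perm, seed = seed, backend = backend),
            class = "importance_fold")
}

#' Per-fold permutation importance across a cross-validation split
#'
#' Runs [permutation_importance()] on each training split of the same seeded
#' fold assignment used by [cross_validate()], then forms the consensus set.
#'
#' @inheritParams permutation_importance
#' @inheritParams cross_validate
#' @param alpha per-fold empirical P threshold (default 0.01).
#' @return An `importance_cv`: `$folds` (list of `importance_fold`),
#'   `$table` (feature, fold, importance, p_value), `$consensus` (ordered by
#'   mean importance, ties lexicographic), `$normalized` (min-max scaled mean
#'   importance in [0, 1]), plus `alpha`, `n_perm`, `seed`.
#' @export
cv_importance <- function(features, pheno, trait = NULL, backend = "rf",
                          n_perm = 100, alpha = 0.01, seed = 1,
                          config = list(), kinship = NULL, n_folds = 5) {
  X <- as_feature_matrix(features)
  y_all <- extract_trait(pheno, trait)
  y_all <- y_all[!is.na(y_all)]
  shared <- intersect(rownames(X), names(y_all))
  X <- X[shared, , drop = FALSE]; y <- y_all[shared]
  folds <- make_folds(shared, n_folds, seed)
  fold_of <- setNames(folds$fold, folds$strain)[shared]
  per_fold <- lapply(seq_len(n_folds), function(k) {
    tr <- shared[fold_of != k]
    permutation_importance(
      X[tr, , drop = FALSE], y[tr], backend = backend, n_perm = n_perm,
      seed = derive_seed(seed, "importance_fold", k), config = config,
      kinship = if (!is.null(kinship)) {
        Km <- if (inherits(kinship, "kinship")) kinship$matrix else kinship
        Km[tr, tr]
      })
  })
  build_importance_cv(per_fold, alpha = alpha, seed = seed)
}

build_importance_cv <- function(per_fold, alpha = 0.01, seed = NA_integer_) {
  universes <- lapply(per_fold, function(f) f$table$feature)
  if (length(unique(lapply(universes, sort))) != 1)
    abort("per-fold importance tables have different feature universes")
  table <- purrr::imap_dfr(per_fold, function(f, k) mutate(f$table, fold = k)) |>
    select("feature", "fold", "importance", "p_value")
  cons <- consensus_features(per_fold, alpha = alpha)
  mean_imp <- table |> group_by(.data$feature) |>
    summarise(importance = mean(.data$importance), .groups = "drop")
  rng <- range(mean_imp$importance)
  normalized <- if (diff(rng) > 0) (mean_imp$importance - rng[1]) / diff(rng)
                else rep(0, nrow(mean_imp))
  structure(list(folds = per_fold, table = table, consensus = cons,
                 normalized = setNames(normalized, mean_imp$feature),
                 alpha = alpha, n_perm = per_fold[[1]]$n_perm, seed = seed),
            class = "importance_cv")
}

#' @export
print.importance_cv <- function(x, ...) {
  cat("<importance_cv> ", length(unique(x$table$feature)), " features, ",
      length(x$folds), " folds, ", x$n_perm, " permutations\n", sep = "")
  cat("  consensus (P < ", x$alpha, " in all folds): ",
      length(x$consensus), " features\n", sep = "")
  if (length(x$consensus))
    cat("  top: ", paste(head(x$consensus, 5), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Consensus features across folds
#'
#' @param per_fold list of `importance_fold` objects over an identical
#'   feature universe (or an `importance_cv`).
#' @param alpha empirical P threshold applied in every fold.
#' @return Character vector of features with P < `alpha` in all folds,
#'   ordered by mean importance (descending; ties broken lexicographically).
#' @export
consensus_features <- function(per_fold, alpha = 0.01) {
  if (inherits(per_fold, "importance_cv")) per_fold <- per_fold$folds
  universes <- lapply(per_fold, function(f) sort(f$table$feature))
  if (length(unique(universes)) != 1)
    abort("per-fold importance tables have different feature universes")
  tab <- bind_rows(lapply(per_fold, `[[`, "table"))
  sel <- tab |> group_by(.data$feature) |>
    summarise(all_sig = all(.data$p_value < alpha),
              mean_imp = mean(.data$importance), .groups = "drop") |>
    filter(.data$all_sig) |>
    arrange(desc(.data$mean_imp), .data$feature)
  sel$feature
}

#' Scramble a feature matrix for the empirical FDR null
#'
#' `"columns"` permutes every feature column independently across strains
#' (destroys feature-phenotype and feature-feature structure, preserves
#' marginals); `"rows"` permutes the strain labels jointly (preserves
#' feature-feature correlation).
#'
#' @param X strains x features matrix.
#' @param seed integer seed (per-column streams are derived from it).
#' @param how `"columns"` or `"rows"`.
#' @return A matrix of the same shape and dimnames.
#' @export
scramble_matrix <- function(X, seed = 1, how = c("columns", "rows")) {
  how <- match.arg(how)
  X <- as.matrix(X)
  if (how == "rows") {
    perm <- with_seed(derive_seed(seed, "scramble_rows"), sample(nrow(X)))
    out <- X[perm, , drop = FALSE]
    rownames(out) <- rownames(X)
    return(out)
  }
  out <- X
  for (j in seq_len(ncol(X))) {
    perm <- with_seed(derive_seed(seed, "scramble_col", j), sample(nrow(X)))
    out[, j] <- X[perm, j]
  }
  out
}

#' Empirical FDR of the consensus feature set
#'
#' Reruns the full per-fold permutation-importance pipeline (same folds, same
#' permutation count) on a scrambled copy of the feature matrix, counts the
#' features passing the consensus filter there (`n_null`), and reports
#' `n_null / n_observed`.
#'
#' @inheritParams cv_importance
#' @param scramble_seed seed for the scrambling.
#' @param scramble `"columns"` or `"rows"` (see [scramble_matrix()]).
#' @param observed an `importance_cv` from the real data; computed here when
#'   not supplied.
#' @return An `fdr_result`: `fdr`, `n_observed`, `n_null`, and the two
#'   `importance_cv` objects.
#' @export
empirical_fdr <- function(features, pheno, trait = NULL, backend = "rf",
                          n_perm = 100, alpha = 0.01, seed = 1,
                          scramble_seed = seed + 1, scramble = "columns",
                          config = list(), kinship = NULL, n_folds = 5,
                          observed = NULL) {
  if (is.null(observed))
    observed <- cv_importance(features, pheno, trait, backend, n_perm, alpha,
                              seed, config, kinship, n_folds)
  X <- as_feature_matrix(features)
  Xs <- scramble_matrix(X, seed = scramble_seed, how = scramble)
  null_run <- cv_importance(Xs, pheno, trait, backend, n_perm, alpha,
                            seed, config, kinship, n_folds)
  n_obs <- length(observed$consensus)
  n_null <- length(null_run$consensus)
  fdr <- fdr_value(n_obs, n_null)
  structure(list(fdr = fdr, n_observed = n_obs, n_null = n_null,
                 observed = observed, null_run = null_run, alpha = alpha),
            class = "fdr_result")
}

fdr_value <- function(n_obs, n_null) {
  if (n_obs == 0 && n_null == 0) return(0)
  if (n_obs == 0) {
    warn("no observed consensus features; FDR capped at 1")
    return(1)
  }
  n_null / n_obs
}

#' @export
print.fdr_result <- function(x, ...) {
  cat("<fdr_result> ", x$n_observed, " observed vs ", x$n_null,
      " scrambled-matrix consensus features -> empirical FDR = ",
      formatC(x$fdr, digits = 4, format = "g"), "\n", sep = "")
  invisible(x)
}

#' Term over-representation of a gene set (hypergeometric test)
#'
#' One-sided over-representation P per ontology term, using propagated
#' annotations restricted to the analysis universe, with Benjamini-Hochberg
#' adjustment across terms.
#'
#' @param gene_set character vector of selected genes (subset of `universe`).
#' @param ont an `ontology`.
#' @param universe background gene set.
#' @return A tibble: `term`, `n_term` (term genes in universe), `overlap`,
#'   `p_raw`, `p_bh`, sorted by `p_raw`.
#' @export
enrich_features <- function(gene_set, ont, universe) {
  stopifnot(inherits(ont, "ontology"))
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!length(gene_set)) abort("empty gene set")
  if (!all(gene_set %in% universe)) abort("gene_set must be a subset of universe")
  N <- length(universe); n <- length(gene_set)
  rows <- purrr::map_dfr(ont$terms, function(t) {
    term_genes <- intersect(ont$propagated[[t]], universe)
    K <- length(term_genes)
    if (K == 0) return(NULL)
    k <- length(intersect(term_genes, gene_set))
    tibble(term = t, n_term = K, overlap = k,
           p_raw = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  rows$p_bh <- p.adjust(rows$p_raw, method = "BH")
  arrange(rows, .data$p_raw, .data$term)
}

#' Overlap of two top-k feature lists (odds ratio + Fisher's exact test)
#'
#' Builds the 2x2 membership table of the feature universe (in A x in B) and
#' reports the sample odds ratio (with a Haldane 0.5 correction when any cell
#' is zero) and the two-sided Fisher exact P value.
#'
#' @param top_a,top_b character vectors of equal length `k`.
#' @param universe_size size of the feature universe both lists were drawn
#'   from.
#' @return A tibble: `odds_ratio`, `fisher_p`, `n_overlap`, `k`,
#'   `universe_size`.
#' @export
compare_top_features <- function(top_a, top_b, universe_size,
                                 k = length(top_a)) {
  stopifnot(length(top_a) == length(top_b))
  if (k > universe_size) abort("k cannot exceed the universe size")
  a <- length(intersect(top_a, top_b))
  b <- length(setdiff(top_a, top_b))
  cc <- length(setdiff(top_b, top_a))
  d <- universe_size - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
  or <- if (any(tab == 0)) ((a + .5) * (d + .5)) / ((b + .5) * (cc + .5))
        else (a * d) / (b * cc)
  tibble(odds_ratio = or,
         fisher_p = fisher.test(tab)$p.value,
         n_overlap = a, k = k, universe_size = universe_size)
}

#' @rdname importance
#' @param x an `importance_cv`.
#' @param ... unused.
#' @export
tidy.importance_cv <- function(x, ...) x$table

#' @rdname importance
#' @export
glance.importance_cv <- function(x, ...) {
  tibble(n_features = length(unique(x$table$feature)),
         n_folds = length(x$folds), n_perm = x$n_perm, alpha = x$alpha,
         n_consensus = length(x$consensus), seed = x$seed)
}

#' @rdname importance
#' @param object an `importance_cv`.
#' @param top_n number of features to display.
#' @export
autoplot.importance_cv <- function(object, top_n = 20, ...) {
  lv <- names(sort(object$normalized, decreasing = TRUE))[
    seq_len(min(top_n, length(object$normalized)))]
  df <- filter(object$table, .data$feature %in% lv) |>
    mutate(feature = factor(.data$feature, levels = rev(lv)))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$fold), .data$feature,
                                   fill = .data$importance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "red") +
    ggplot2::labs(x = "fold", y = NULL, fill = "importance") +
    ggplot2::theme_minimal()
}
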