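#' Phenotype prediction models
#'
#' Backends for regressing a quantitative trait on SNV, gene or ontotype
#' features: plain random forest, mixed random forest (forest plus a kinship
#' random effect absorbing population structure), GBLUP, ridge and lasso, and
#' an optional multilayer perceptron. All are evaluated with the same seeded
#' 5-fold cross-validation and held-out coefficient of determination.
#'
#' @name models
NULL

# ---- fold assignment -------------------------------------------------------

#' Seeded cross-validation folds
#'
#' Strains are shuffled with the seed, then split into `n_folds` contiguous
#' near-equal groups; remainder strains go to the earliest folds.
#'
#' @param strains character vector of strain IDs.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return A tibble with columns `strain`, `fold`.
#' @export
make_folds <- function(strains, n_folds = 5, seed = 1) {
  stopifnot(n_folds >= 2, length(strains) >= n_folds)
  ord <- with_seed(derive_seed(seed, "folds"), sample(strains))
  base <- length(strains) %/% n_folds
  rem <- length(strains) %% n_folds
  sizes <- rep(base, n_folds) + (seq_len(n_folds) <= rem)
  tibble(strain = ord, fold = rep(seq_len(n_folds), times = sizes)) |>
    arrange(match(.data$strain, strains))
}

# ---- random forest ---------------------------------------------------------

#' Fit a regression random forest
#'
#' Bootstrap-sampled regression forest (via ranger) exposing out-of-bag
#' permutation importance — the importance measure used throughout the
#' feature-selection pipeline.
#'
#' @param X numeric strains x features matrix.
#' @param y numeric response.
#' @param config list: `n_trees` (default 1000), `min_node_size`, `mtry`,
#'   `seed`.
#' @return An `rf_fit` with `$model`, `$importance` (named numeric) and
#'   out-of-bag predictions `$oob`.
#' @export
fit_random_forest <- function(X, y, config = list()) {
  n_trees <- config$n_trees %||% 1000
  if (n_trees < 1) abort("n_trees must be >= 1")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  fit <- ranger::ranger(
    x = X, y = y, num.trees = n_trees,
    importance = "permutation", scale.permutation.importance = FALSE,
    min.node.size = config$min_node_size %||% 5,
    mtry = config$mtry, seed = config$seed %||% 1, num.threads = 1)
  oob <- fit$predictions
  oob[is.na(oob)] <- mean(y)
  structure(list(model = fit, importance = fit$variable.importance, oob = oob,
                 features = colnames(X)),
            class = "rf_fit")
}

#' @export
predict.rf_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$features
  predict(object$model, data = newdata, num.threads = 1)$predictions
}

# ---- REML variance components (shared by mixed RF, GBLUP, heritability) ----

# Restricted maximum likelihood for y = mu + sum_k u_k + e with
# cov(u_k) = sigma2_k * K_k, cov(e) = sigma2_e * I. Optimizes the restricted
# log-likelihood over log variances (L-BFGS-B), which keeps every component
# non-negative. Dense n x n algebra: intended for n up to a few thousand.
reml_fit <- function(y, K_list, max_iter = 200) {
  n <- length(y)
  K_list <- lapply(K_list, function(K) if (inherits(K, "kinship")) K$matrix else K)
  vy <- var(y)
  if (vy == 0) return(list(sigma2 = rep(0, length(K_list)), sigma2_e = 0,
                           mu = y[1], converged = TRUE))
  ones <- matrix(1, n, 1)
  nll <- function(logv) {
    v <- exp(logv)
    V <- diag(v[length(v)], n)
    for (k in seq_along(K_list)) V <- V + v[k] * K_list[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdetV <- 2 * sum(log(diag(ch)))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_1 <- backsolve(ch, forwardsolve(t(ch), ones))
    xvx <- sum(ones * Vi_1)
    mu <- sum(Vi_y) / xvx
    r <- y - mu
    Vi_r <- Vi_y - mu * Vi_1
    0.5 * (logdetV + log(xvx) + sum(r * Vi_r))
  }
  nk <- length(K_list)
  lb <- log(vy) - 18
  # several starts (balanced / genetic-dominant / residual-dominant) guard
  # against local optima of the restricted likelihood surface
  starts <- list(log(rep(vy / (nk + 1), nk + 1)),
                 log(c(rep(vy * 0.95 / nk, nk), vy * 0.05)),
                 log(c(rep(vy * 0.05 / nk, nk), vy * 0.95)))
  opt <- NULL
  for (init in starts) {
    o <- optim(init, nll, method = "L-BFGS-B",
               lower = lb, upper = log(vy) + 8,
               control = list(maxit = max_iter, factr = 1e5))
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  v <- exp(opt$par)
  v[v < vy * 1e-7] <- 0
  # recompute GLS mean at the optimum
  V <- diag(max(v[length(v)], vy * 1e-8), n)
  for (k in seq_along(K_list)) V <- V + v[k] * K_list[[k]]
  Vi_1 <- solve(V, ones)
  mu <- sum(solve(V, y)) / sum(Vi_1)
  list(sigma2 = v[-length(v)], sigma2_e = v[length(v)], mu = mu,
       converged = opt$convergence == 0, V = V)
}

# ---- mixed random forest ---------------------------------------------------

#' Fit a mixed random forest
#'
#' Models `y = f(X) + g + e` with a nonparametric forest `f` and a genetic
#' random effect `g ~ N(0, sigma2_g * K)` whose covariance is a kinship
#' matrix, so heritable resemblance between related strains is absorbed by
#' `g` rather than mistaken for feature effects. Fitting alternates (i) a
#' forest on the structure-adjusted response `y - g_hat` and (ii) REML
#' variance components plus BLUP of `g` on the forest residual `y - f_oob`
#' (out-of-bag predictions, to avoid absorbing the forest's training fit),
#' until the relative change in `sigma2_g` drops below `tol`.
#'
#' @param X numeric strains x features matrix.
#' @param y numeric response.
#' @param K kinship matrix (or [additive_grm()] result) aligned to rows of X.
#' @param config list: forest options as in [fit_random_forest()], plus
#'   `max_iter` (default 20) and `tol` (default 1e-4).
#' @return A `mixed_rf_fit` with the final forest, `sigma2_g`, `sigma2_e`,
#'   `g_hat`, and what is needed to kinship-project `g` onto new strains.
#' @export
fit_mixed_random_forest <- function(X, y, K, config = list()) {
  Km <- if (inherits(K, "kinship")) K$matrix else as.matrix(K)
  n <- length(y)
  stopifnot(nrow(Km) == n, ncol(Km) == n)
  ev_min <- min(eigen(Km, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-6 * max(1, max(abs(Km))))
    abort("kinship matrix is not positive semi-definite")
  max_iter <- config$max_iter %||% 20
  tol <- config$tol %||% 1e-4
  if (var(y) == 0) {
    forest <- fit_random_forest(X, y, config)
    return(structure(list(forest = forest, sigma2_g = 0, sigma2_e = 0,
                          g_hat = rep(0, n), alpha = rep(0, n), mu = y[1],
                          converged = TRUE, n_iter = 0),
                     class = "mixed_rf_fit"))
  }
  g <- rep(0, n)
  sg_prev <- Inf
  converged <- FALSE
  forest <- NULL; vc <- NULL; alpha <- rep(0, n); mu <- mean(y)
  for (it in seq_len(max_iter)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed %||% 1, "mixed_rf_iter", it)
    forest <- fit_random_forest(X, y - g, cfg)
    r <- y - forest$oob
    vc <- reml_fit(r, list(Km))
    sg <- vc$sigma2[1]; se <- vc$sigma2_e
    if (sg + se == 0) { g <- rep(0, n); converged <- TRUE; break }
    V <- sg * Km + diag(se + 1e-10 * var(y), n)
    alpha <- solve(V, r - vc$mu)
    mu <- vc$mu
    g <- as.numeric(sg * Km %*% alpha)
    if (is.finite(sg_prev) && abs(sg - sg_prev) <= tol * max(sg_prev, 1e-12)) {
      converged <- TRUE; break
    }
    sg_prev <- sg
  }
  if (!converged && max_iter > 1)
    warn("mixed random forest did not converge; returning last iterate")
  structure(list(forest = forest, sigma2_g = vc$sigma2[1], sigma2_e = vc$sigma2_e,
                 g_hat = g, alpha = as.numeric(alpha), mu = mu,
                 converged = converged, n_iter = it),
            class = "mixed_rf_fit")
}

#' Predict from a mixed random forest
#'
#' @param object a `mixed_rf_fit`.
#' @param newdata feature matrix for new strains.
#' @param K_cross new-strains x training-strains kinship block; when `NULL`
#'   only the forest component is used.
#' @param ... unused.
#' @export
predict.mixed_rf_fit <- function(object, newdata, K_cross = NULL, ...) {
  f <- predict(object$forest, newdata)
  if (is.null(K_cross) || object$sigma2_g == 0) return(f)
  f + object$sigma2_g * as.numeric(as.matrix(K_cross) %*% object$alpha)
}

# ---- GBLUP -----------------------------------------------------------------

#' Fit GBLUP (genomic best linear unbiased prediction)
#'
#' Columns of `Z` are standardized (training statistics), the genomic
#' relationship matrix `K = Z Z' / m` is formed, and genetic values are
#' predicted as `g_hat = K (K + delta I)^{-1} (y - ybar)` with shrinkage
#' `delta = sigma2_e / sigma2_g` — estimated by REML when not supplied.
#' Algebraically identical to ridge regression on `Z` with penalty
#' `m * delta`.
#'
#' @param Z strains x markers (or features) numeric matrix.
#' @param y numeric response.
#' @param delta optional non-negative shrinkage ratio.
#' @param standardize center/scale columns first (monomorphic columns are
#'   dropped).
#' @return A `blup_fit` with fitted values, `delta`, and projection state.
#' @export
fit_blup <- function(Z, y, delta = NULL, standardize = TRUE) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  stopifnot(n == length(y), n >= 10)
  center <- colMeans(Z)
  scale_ <- apply(Z, 2, sd)
  keep <- scale_ > 0
  if (standardize) {
    Zs <- sweep(sweep(Z[, keep, drop = FALSE], 2, center[keep]), 2, scale_[keep], "/")
  } else {
    Zs <- Z[, keep, drop = FALSE]
  }
  m <- ncol(Zs)
  if (m == 0) abort("no polymorphic columns in Z")
  K <- tcrossprod(Zs) / m
  if (is.null(delta)) {
    vc <- reml_fit(y, list(K))
    delta <- if (vc$sigma2[1] <= 0) 1e8 else vc$sigma2_e / vc$sigma2[1]
  }
  ybar <- mean(y)
  A <- K + diag(delta, n)
  alpha <- tryCatch(solve(A, y - ybar), error = function(e)
    abort("K + delta*I is singular; supply delta > 0"))
  g_hat <- as.numeric(K %*% alpha)
  structure(list(ybar = ybar, alpha = as.numeric(alpha), g_hat = g_hat,
                 fitted = ybar + g_hat, delta = delta, m = m,
                 Ztrain = Zs, center = center[keep], scale = scale_[keep],
                 standardize = standardize, keep = names(center)[keep]),
            class = "blup_fit")
}

#' @export
predict.blup_fit <- function(object, newdata, ...) {
  Z <- as.matrix(newdata)
  if (!is.null(colnames(Z)) && !is.null(object$keep))
    Z <- Z[, object$keep, drop = FALSE]
  if (object$standardize)
    Z <- sweep(sweep(Z, 2, object$center), 2, object$scale, "/")
  Kc <- tcrossprod(Z, object$Ztrain) / object$m
  object$ybar + as.numeric(Kc %*% object$alpha)
}

# ---- penalized linear models ----------------------------------------------

fit_glmnet_backend <- function(X, y, alpha, config, seed) {
  # glmnet requires >= 2 columns; pad single-feature inputs with a zero column
  pad <- ncol(X) < 2
  if (pad) X <- cbind(X, .pad. = 0)
  lambda <- config$lambda
  if (is.null(lambda)) {
    foldid <- with_seed(derive_seed(seed, "glmnet_inner"),
                        sample(rep_len(1:3, length(y))))
    cvfit <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                               nlambda = config$n_lambda %||% 50)
    lambda <- cvfit$lambda.min
  }
  fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = lambda)
  structure(list(model = fit, lambda = lambda, pad = pad), class = "glmnet_fit")
}

#' @export
predict.glmnet_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$pad) newdata <- cbind(newdata, .pad. = 0)
  as.numeric(predict(object$model, newdata, s = object$lambda))
}

# ---- multilayer perceptron -------------------------------------------------

#' Fit a sigmoid multilayer perceptron (optional backend)
#'
#' Small feed-forward regression network with three sigmoid hidden layers
#' (default widths 1000, 400, 100) and a linear output, trained with Adam on
#' standardized inputs/response. Provided for completeness; the tree and
#' linear backends are the recommended ones at typical cohort sizes.
#'
#' @param X,y training data.
#' @param config list: `layers`, `epochs` (default 200), `learning_rate`
#'   (default 1e-3), `seed`.
#' @return An `mlp_fit`.
#' @export
fit_mlp <- function(X, y, config = list()) {
  X <- as.matrix(X)
  layers <- config$layers %||% c(1000, 400, 100)
  epochs <- config$epochs %||% 200
  lr <- config$learning_rate %||% 1e-3
  cx <- colMeans(X); sx <- pmax(apply(X, 2, sd), 1e-8)
  Xs <- sweep(sweep(X, 2, cx), 2, sx, "/")
  cy <- mean(y); sy <- max(sd(y), 1e-8)
  ys <- (y - cy) / sy
  sizes <- c(ncol(X), layers, 1)
  W <- list(); b <- list()
  with_seed(config$seed %||% 1, {
    for (l in seq_len(length(sizes) - 1)) {
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(1 / sizes[l])),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
  })
  sig <- function(z) 1 / (1 + exp(-z))
  L <- length(W)
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  n <- nrow(Xs)
  for (ep in seq_len(epochs)) {
    a <- list(Xs)
    for (l in seq_len(L)) {
      z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
      a[[l + 1]] <- if (l < L) sig(z) else z
    }
    delta <- 2 * (a[[L + 1]] - ys) / n
    t <- t + 1
    for (l in rev(seq_len(L))) {
      gW <- crossprod(a[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(W[[l]])) * a[[l]] * (1 - a[[l]])
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
      W[[l]] <- W[[l]] - lr * (mW[[l]] / (1 - b1^t)) / (sqrt(vW[[l]] / (1 - b2^t)) + eps)
      b[[l]] <- b[[l]] - lr * (mb[[l]] / (1 - b1^t)) / (sqrt(vb[[l]] / (1 - b2^t)) + eps)
    }
  }
  structure(list(W = W, b = b, center_x = cx, scale_x = sx,
                 center_y = cy, scale_y = sy),
            class = "mlp_fit")
}

#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  a <- sweep(sweep(as.matrix(newdata), 2, object$center_x), 2, object$scale_x, "/")
  L <- length(object$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% object$W[[l]], 2, object$b[[l]], "+")
    a <- if (l < L) 1 / (1 + exp(-z)) else z
  }
  as.numeric(a) * object$scale_y + object$center_y
}

# ---- cross-validation ------------------------------------------------------

model_backends <- c("rf", "mixed_rf", "blup", "ridge", "lasso", "mlp")

fit_backend <- function(backend, X, y, config, seed, K = NULL) {
  cfg <- config
  cfg$seed <- seed
  switch(backend,
    rf = fit_random_forest(X, y, cfg),
    mixed_rf = fit_mixed_random_forest(X, y, K, cfg),
    blup = fit_blup(X, y, delta = config$delta),
    ridge = fit_glmnet_backend(X, y, alpha = 0, config, seed),
    lasso = fit_glmnet_backend(X, y, alpha = 1, config, seed),
    mlp = fit_mlp(X, y, cfg),
    abort(paste0("unknown backend '", backend, "'; use one of: ",
                 paste(model_backends, collapse = ", "))))
}

#' Cross-validate a phenotype predictor
#'
#' Seeded 5-fold cross-validation: each fold is held out once, the model is
#' trained on the remaining folds and scored on the held-out strains by the
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot`; the model score
#' is the mean over folds. Deterministic given (inputs, config, seed).
#'
#' @param features strains x features input: an `ontotype_matrix`,
#'   `gene_matrix`, `genotype_matrix`, a matrix with strain rownames, or a
#'   data frame with a `strain` column.
#' @param pheno phenotype table (tibble with `strain` plus trait columns) or
#'   a named numeric vector. Missing values are dropped per trait.
#' @param trait trait column name (optional when the table has one trait).
#' @param backend one of `"rf"`, `"mixed_rf"`, `"blup"`, `"ridge"`,
#'   `"lasso"`, `"mlp"`.
#' @param config backend options (see the fit functions).
#' @param seed integer; drives fold assignment and every stochastic backend.
#' @param kinship full strains x strains kinship ([additive_grm()] result or
#'   matrix) — required for `mixed_rf`, subset per fold internally.
#' @param n_folds number of folds (default 5).
#' @return A `cv_result`: `backend`, `per_fold_r2`, `mean_r2`,
#'   `fold_assignment` tibble, `seed`.
#' @export
cross_validate <- function(features, pheno, trait = NULL, backend = "rf",
                           config = list(), seed = 1, kinship = NULL,
                           n_folds = 5) {
  backend <- match.arg(backend, model_backends)
  X <- as_feature_matrix(features)
  y_all <- extract_trait(pheno, trait)
  y_all <- y_all[!is.na(y_all)]
  shared <- intersect(rownames(X), names(y_all))
  if (length(shared) < 10)
    abort("fewer than 10 strains shared between features and phenotype")
  if (length(shared) < 2 * n_folds)
    abort("trait needs at least 2 strains per fold")
  X <- X[shared, , drop = FALSE]
  y <- y_all[shared]
  if (var(y) == 0) abort("constant phenotype: R^2 undefined")
  Km <- NULL
  if (backend == "mixed_rf") {
    if (is.null(kinship)) abort("mixed_rf requires a kinship matrix")
    Km <- if (inherits(kinship, "kinship")) kinship$matrix else as.matrix(kinship)
    if (!all(shared %in% rownames(Km)))
      abort("kinship matrix does not cover all strains")
    Km <- Km[shared, shared]
  }
  folds <- make_folds(shared, n_folds, seed)
  fold_of <- setNames(folds$fold, folds$strain)[shared]
  per_fold <- vapply(seq_len(n_folds), function(k) {
    tr <- shared[fold_of != k]; te <- shared[fold_of == k]
    fit <- fit_backend(backend, X[tr, , drop = FALSE], y[tr], config,
                       seed = derive_seed(seed, "fold", k),
                       K = if (!is.null(Km)) Km[tr, tr])
    pred <- if (backend == "mixed_rf")
      predict(fit, X[te, , drop = FALSE], K_cross = Km[te, tr, drop = FALSE])
    else predict(fit, X[te, , drop = FALSE])
    r_squared(y[te], pred)
  }, numeric(1))
  structure(list(backend = backend, per_fold_r2 = per_fold,
                 mean_r2 = mean(per_fold), fold_assignment = folds,
                 n_strains = length(shared), seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> backend=", x$backend, "  mean R^2 = ",
      formatC(x$mean_r2, digits = 3, format = "f"),
      "  (", length(x$per_fold_r2), " folds, ", x$n_strains, " strains)\n", sep = "")
  invisible(x)
}

#' @rdname cross_validate
#' @param x a `cv_result`.
#' @param ... unused.
#' @export
tidy.cv_result <- function(x, ...) {
  tibble(fold = seq_along(x$per_fold_r2), r2 = x$per_fold_r2)
}

#' @rdname cross_validate
#' @export
glance.cv_result <- function(x, ...) {
  tibble(backend = x$backend, mean_r2 = x$mean_r2,
         n_folds = length(x$per_fold_r2), n_strains = x$n_strains,
         seed = x$seed)
}

#' @rdname cross_validate
#' @param object a `cv_result`.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(factor(.data$fold), .data$r2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_r2, linetype = 2) +
    ggplot2::labs(x = "fold", y = expression(R^2),
                  title = paste0(object$backend, " cross-validation")) +
    ggplot2::theme_minimal()
}
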