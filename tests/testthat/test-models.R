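sim_xy <- function(n = 200, p = 20, seed = 1, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%03d", 1:n), paste0("x", 1:p)))
  y <- X[, 1] + rnorm(n, sd = noise)
  pheno <- tibble::tibble(strain = rownames(X), trait = y)
  list(X = X, y = y, pheno = pheno)
}

test_that("folds partition strains into near-equal groups, remainder to earliest folds", {
  strains <- sprintf("s%02d", 1:23)
  f <- make_folds(strains, n_folds = 5, seed = 3)
  expect_setequal(f$strain, strains)
  expect_equal(as.integer(sort(table(f$fold))), c(4L, 4L, 5L, 5L, 5L))
  expect_equal(as.integer(table(f$fold)[1:3]), c(5L, 5L, 5L))
  expect_identical(f, make_folds(strains, n_folds = 5, seed = 3))
})

test_that("ridge with near-zero penalty recovers a copied-feature signal almost perfectly", {
  d <- sim_xy(n = 100, p = 1, noise = 0)
  cv <- cross_validate(d$X, d$pheno, backend = "ridge",
                       config = list(lambda = 1e-6), seed = 1)
  expect_gt(cv$mean_r2, 0.99)
})

test_that("pure-noise phenotypes give near-zero cross-validated R^2 in expectation", {
  r2 <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(120 * 10), 120, 10,
                dimnames = list(sprintf("s%03d", 1:120), paste0("x", 1:10)))
    pheno <- tibble::tibble(strain = rownames(X), trait = rnorm(120))
    cross_validate(X, pheno, backend = "ridge", seed = s)$mean_r2
  }, numeric(1))
  expect_lte(mean(r2), 0.05)
  expect_true(all(abs(r2) <= 0.35))   # no single catastrophic fold average
})

test_that("cross-validation is deterministic given inputs, config and seed", {
  d <- sim_xy(n = 80, p = 5, seed = 2)
  a <- cross_validate(d$X, d$pheno, backend = "rf",
                      config = list(n_trees = 50), seed = 11)
  b <- cross_validate(d$X, d$pheno, backend = "rf",
                      config = list(n_trees = 50), seed = 11)
  expect_identical(a[c("per_fold_r2", "mean_r2", "fold_assignment")],
                   b[c("per_fold_r2", "mean_r2", "fold_assignment")])
})

test_that("unknown backend and constant phenotype are errors", {
  d <- sim_xy(n = 40, p = 3)
  expect_error(cross_validate(d$X, d$pheno, backend = "boost"))
  const <- tibble::tibble(strain = rownames(d$X), trait = 1)
  expect_error(cross_validate(d$X, const, backend = "rf"), "constant")
})

test_that("random forest ranks a planted feature first and fits noiseless signal in-sample", {
  d <- sim_xy(n = 200, p = 20, seed = 5, noise = 0)
  fit <- fit_random_forest(d$X, d$y, config = list(n_trees = 300, seed = 5))
  expect_equal(names(which.max(fit$importance)), "x1")
  pred <- predict(fit, d$X)
  expect_gte(r_sq <- 1 - sum((d$y - pred)^2) / sum((d$y - mean(d$y))^2), 0.9)
  # constant response -> constant predictions
  cfit <- fit_random_forest(d$X, rep(2.5, 200), config = list(n_trees = 20))
  expect_true(all(abs(predict(cfit, d$X) - 2.5) < 1e-8))
  expect_error(fit_random_forest(d$X, d$y, config = list(n_trees = 0)), "n_trees")
})

test_that("mixed RF matches plain RF when kinship is the identity", {
  d <- sim_xy(n = 150, p = 10, seed = 8, noise = 0.3)
  K <- diag(150); dimnames(K) <- list(rownames(d$X), rownames(d$X))
  rf <- fit_random_forest(d$X, d$y, config = list(n_trees = 200, seed = 1))
  mrf <- suppressWarnings(
    fit_mixed_random_forest(d$X, d$y, K, config = list(n_trees = 200, seed = 1)))
  expect_gte(cor(predict(rf, d$X), predict(mrf, d$X)), 0.9)
})

test_that("mixed RF recovers a purely structural signal in its variance components", {
  set.seed(21)
  n <- 150
  blocks <- rep(1:3, each = 50)
  K <- outer(blocks, blocks, "==") * 1.0
  dimnames(K) <- list(sprintf("s%03d", 1:n), sprintf("s%03d", 1:n))
  g <- rnorm(3)[blocks] * 2
  y <- g + rnorm(n, sd = 0.5)
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(rownames(K), paste0("x", 1:10)))
  fit <- suppressWarnings(
    fit_mixed_random_forest(X, y, K, config = list(n_trees = 100, seed = 2)))
  expect_gte(fit$sigma2_g / (fit$sigma2_g + fit$sigma2_e), 0.5)
})

test_that("mixed RF degenerates gracefully on a constant response", {
  X <- matrix(rnorm(200), 20, 10, dimnames = list(paste0("s", 1:20), paste0("x", 1:10)))
  K <- diag(20); dimnames(K) <- list(rownames(X), rownames(X))
  fit <- fit_mixed_random_forest(X, rep(1, 20), K, config = list(n_trees = 10))
  expect_equal(fit$sigma2_g, 0)
  expect_equal(fit$sigma2_e, 0)
  expect_true(all(abs(predict(fit, X, K_cross = K) - 1) < 1e-8))
})

test_that("GBLUP limits: huge shrinkage gives the mean, zero shrinkage interpolates", {
  set.seed(3)
  Z <- matrix(rnorm(40 * 60), 40, 60)
  y <- rnorm(40)
  big <- fit_blup(Z, y, delta = 1e8)
  expect_true(all(abs(big$fitted - mean(y)) < 1e-4))
  # delta = 0 with an invertible K interpolates the training response
  # (unstandardized: column-centering would make K exactly singular)
  zero <- fit_blup(Z, y, delta = 0, standardize = FALSE)
  expect_true(all(abs(zero$fitted - y) < 1e-6))
})

test_that("GBLUP equals ridge regression on standardized genotypes (penalty m*delta)", {
  for (seed in 1:5) {
    set.seed(seed)
    Z <- matrix(rnorm(30 * 50), 30, 50)
    y <- rnorm(30)
    delta <- runif(1, 0.1, 2)
    fit <- fit_blup(Z, y, delta = delta)
    # independent closed-form ridge oracle
    Zs <- scale(Z)
    m <- ncol(Zs)
    beta <- solve(crossprod(Zs) + diag(m * delta, m), crossprod(Zs, y - mean(y)))
    expect_lt(max(abs(fit$fitted - (mean(y) + Zs %*% beta))), 1e-6)
    Znew <- matrix(rnorm(10 * 50), 10, 50)
    Znew_s <- sweep(sweep(Znew, 2, attr(Zs, "scaled:center")), 2,
                    attr(Zs, "scaled:scale"), "/")
    expect_lt(max(abs(predict(fit, Znew) - (mean(y) + Znew_s %*% beta))), 1e-6)
  }
})

test_that("REML recovers variance fractions and the noiseless limit", {
  set.seed(14)
  n <- 200
  Z <- matrix(rbinom(n * 400, 1, 0.3), n, 400)
  rownames(Z) <- sprintf("s%03d", 1:n)
  K <- additive_grm(Z)$matrix
  g <- as.numeric(t(chol(K + diag(1e-6, n))) %*% rnorm(n))
  vc1 <- ontotyper:::reml_fit(g + rnorm(n), list(K))
  h2 <- vc1$sigma2 / (vc1$sigma2 + vc1$sigma2_e)
  expect_gt(h2, 0.3); expect_lt(h2, 0.7)
  vc0 <- ontotyper:::reml_fit(rnorm(n), list(K))
  expect_lte(vc0$sigma2 / (vc0$sigma2 + vc0$sigma2_e), 0.1)
  vc2 <- ontotyper:::reml_fit(g, list(K))
  expect_gte(vc2$sigma2 / (vc2$sigma2 + vc2$sigma2_e), 0.95)
})

test_that("the MLP backend learns a simple linear signal", {
  set.seed(6)
  n <- 150
  X <- matrix(rnorm(n * 5), n, 5)
  y <- 2 * X[, 1] - X[, 2] + rnorm(n, sd = 0.2)
  fit <- fit_mlp(X, y, config = list(layers = c(16, 8, 4), epochs = 400,
                                     learning_rate = 0.01, seed = 1))
  expect_gt(cor(predict(fit, X), y), 0.8)
})

test_that("lasso and blup run through the shared cross-validation harness", {
  d <- sim_xy(n = 100, p = 15, seed = 4, noise = 0.2)
  lasso <- cross_validate(d$X, d$pheno, backend = "lasso", seed = 2)
  expect_gt(lasso$mean_r2, 0.5)
  blup <- cross_validate(d$X, d$pheno, backend = "blup", seed = 2)
  expect_gt(blup$mean_r2, 0.3)
  expect_s3_class(glance(lasso), "tbl_df")
  expect_equal(nrow(tidy(lasso)), 5)
})
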