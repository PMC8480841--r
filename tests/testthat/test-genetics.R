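gene_mat <- function(vals) ontotyper:::new_gene_matrix(vals)

# 9 strains engineered to fall in burden bins 0/1/2 of a two-gene system,
# with phenotypes {1,2,3}, {2,3,4}, {7,8,9} per bin
three_group_fixture <- function() {
  vals <- matrix(0L, 9, 3, dimnames = list(paste0("s", 1:9), c("gA", "gB", "gC")))
  vals[4:6, "gA"] <- 1L
  vals[7:9, c("gA", "gB")] <- 1L
  vals[, "gC"] <- rep(c(0L, 1L, 0L), 3)   # irrelevant background gene
  y <- setNames(c(1, 2, 3, 2, 3, 4, 7, 8, 9), rownames(vals))
  list(genes = gene_mat(vals), y = y)
}

test_that("burden ANOVA reproduces the hand-computed three-group F statistic", {
  fx <- three_group_fixture()
  res <- burden_test(fx$genes, c("gA", "gB"), fx$y, n_random = 0,
                     min_group_size = 2)
  # hand computation: group means 2, 3, 8; grand mean 13/3;
  # SSB = 3*(49/9 + 16/9 + 121/9) = 62, MSB = 31; SSW = 6, MSW = 1 -> F = 31
  expect_equal(res$anova_F, 31.0, tolerance = 1e-10)
  expect_equal(res$anova_df, c(2, 6))
  # cross-check against stats::aov on the same strata
  oracle <- anova(aov(fx$y ~ factor(c(0, 0, 0, 1, 1, 1, 2, 2, 2))))
  expect_equal(res$anova_F, oracle$`F value`[1], tolerance = 1e-12)
  expect_equal(res$anova_p, oracle$`Pr(>F)`[1], tolerance = 1e-12)
  expect_equal(res$groups$mean, c(2, 3, 8))
})

test_that("burden ANOVA matches the textbook formula on random 3-group data", {
  set.seed(31)
  for (rep in 1:5) {
    g <- rep(0:2, each = 6)
    y <- rnorm(18, mean = g)
    vals <- matrix(0L, 18, 2, dimnames = list(paste0("s", 1:18), c("g1", "g2")))
    vals[g >= 1, "g1"] <- 1L; vals[g == 2, "g2"] <- 1L
    res <- burden_test(gene_mat(vals), c("g1", "g2"),
                       setNames(y, rownames(vals)), n_random = 0)
    means <- tapply(y, g, mean)
    ssb <- sum(6 * (means - mean(y))^2)
    ssw <- sum((y - means[as.character(g)])^2)
    expect_equal(res$anova_F, (ssb / 2) / (ssw / 15), tolerance = 1e-10)
  }
})

test_that("a planted negative burden effect is detected by ANOVA and Tukey", {
  set.seed(12)
  n <- 300
  vals <- matrix(rbinom(n * 10, 1, 0.35), n, 10,
                 dimnames = list(sprintf("s%03d", 1:n), paste0("g", 1:10)))
  sys <- c("g1", "g2")
  burden <- rowSums(vals[, sys])
  y <- setNames(-1.0 * burden + rnorm(n, sd = 0.1), rownames(vals))
  res <- burden_test(gene_mat(vals), sys, y, n_random = 50, seed = 5)
  expect_lt(res$anova_p, 1e-6)
  top_vs_zero <- grepl("^(>=)?2-0$|^0-(>=)?2$", res$tukey$comparison)
  expect_true(any(res$tukey$p_adjusted[top_vs_zero] < 1e-6))
  # random gene sets outside the system show no such gradient:
  # bin-mean spread of the real system exceeds the null median spread
  spread <- function(df) max(df$mean) - min(df$mean)
  null_spread <- res$random_null |> dplyr::group_by(draw) |>
    dplyr::summarise(s = spread(dplyr::pick(dplyr::everything())))
  expect_gt(spread(res$groups), median(null_spread$s))
})

test_that("thin burden bins merge downward and degenerate systems error", {
  fx <- three_group_fixture()
  res <- burden_test(fx$genes, c("gA", "gB"), fx$y, n_random = 0,
                     min_group_size = 4)
  expect_equal(nrow(res$groups), 2)   # 3+3+3 merged to 2 usable strata
  # monomorphic system gene column: single bin -> hard error
  vals <- matrix(0L, 12, 2, dimnames = list(paste0("s", 1:12), c("g1", "g2")))
  y <- setNames(rnorm(12), rownames(vals))
  expect_error(burden_test(gene_mat(vals), "g1", y), "non-informative")
})

test_that("additive GRM: duplicates, diagonal scaling, and the per-entry oracle", {
  set.seed(2)
  Z <- matrix(rbinom(5 * 8, 1, 0.4), 5, 8,
              dimnames = list(paste0("s", 1:5), paste0("v", 1:8)))
  Z[2, ] <- Z[1, ]                      # duplicate strains
  Z[, 8] <- 0L                          # monomorphic -> dropped
  K <- suppressMessages(additive_grm(Z))
  expect_s3_class(K, "kinship")
  expect_equal(K$m, 7)
  expect_equal(K$matrix["s1", "s2"], K$matrix["s1", "s1"])
  expect_equal(K$matrix["s1", "s2"], K$matrix["s2", "s2"])
  # brute-force (1/m) sum_j z_sj z_tj on the standardized columns
  Zs <- scale(Z[, 1:7])
  for (s in 1:5) for (t in 1:5)
    expect_equal(K$matrix[s, t], sum(Zs[s, ] * Zs[t, ]) / 7, tolerance = 1e-12)
  # large m: mean diagonal ~ 1
  Zbig <- matrix(rbinom(40 * 600, 1, 0.3), 40, 600,
                 dimnames = list(paste0("s", 1:40), NULL))
  Kbig <- suppressMessages(additive_grm(Zbig))
  expect_lt(abs(mean(diag(Kbig$matrix)) - 1), 0.1)
  expect_error(additive_grm(matrix(1L, 4, 3)), "monomorphic")
})

test_that("epistatic GRM is the Hadamard square and stays PSD", {
  K <- diag(4); K[1, 2] <- K[2, 1] <- 0.5
  dimnames(K) <- list(paste0("s", 1:4), paste0("s", 1:4))
  E <- epistatic_grm(ontotyper:::new_kinship(K, kind = "additive"))
  expect_equal(E$matrix[1, 2], 0.25)
  expect_equal(E$kind, "epistatic")
  expect_equal(epistatic_grm(diag(5))$matrix, diag(5))
  set.seed(5)
  for (rep in 1:100) {
    A <- matrix(rnorm(36), 6, 6); P <- crossprod(A) / 6
    ev <- eigen((P * P), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * max(abs(P)))
  }
})

test_that("h2 estimates are invariant to affine rescaling of the phenotype", {
  set.seed(77)
  n <- 120; m <- 300
  Z <- matrix(rbinom(n * m, 1, 0.3), n, m, dimnames = list(sprintf("s%03d", 1:n), NULL))
  K <- additive_grm(Z)
  g <- as.numeric(t(chol(K$matrix + diag(1e-8, n))) %*% rnorm(n))
  y <- setNames(g + rnorm(n), rownames(Z))
  h1 <- estimate_variance_components(y, K)
  h2 <- estimate_variance_components(3.7 * y - 11, K)
  expect_equal(h1$h2, h2$h2, tolerance = 1e-3)
  expect_gte(h1$h2, 0); expect_lte(h1$h2, 1)
  expect_equal(h1$h2, h1$sigma2_a / (h1$sigma2_a + h1$sigma2_i + h1$sigma2_e))
})

test_that("variance explained: algebraic identities and nested monotonicity", {
  set.seed(8)
  n <- 60
  vals <- matrix(rbinom(n * 6, 1, 0.5), n, 6,
                 dimnames = list(paste0("s", 1:n), paste0("g", 1:6)))
  gm <- gene_mat(vals)
  # single indicator matching the response pattern exactly -> r2 = 1
  y1 <- setNames(2 * vals[, "g1"] + 5, rownames(vals))
  expect_equal(variance_explained(gm, "g1", y1)$r2, 1, tolerance = 1e-10)
  # single-predictor r2 equals squared Pearson correlation
  y2 <- setNames(rnorm(n), rownames(vals))
  expect_equal(variance_explained(gm, "g3", y2)$r2,
               cor(vals[, "g3"], y2)^2, tolerance = 1e-10)
  # monotone non-decreasing in the gene set (nested OLS)
  r2s <- vapply(1:6, function(k)
    variance_explained(gm, paste0("g", 1:k), y2)$r2, numeric(1))
  expect_true(all(diff(r2s) >= -1e-12))
  expect_error(variance_explained(gm, character(), y2), "empty")
  small <- gene_mat(vals[1:4, ])
  expect_error(variance_explained(small, paste0("g", 1:6),
                                  y2[1:4]), "more genes")
})

test_that("an unrelated gene set explains almost nothing at large n", {
  set.seed(9)
  n <- 1000
  vals <- matrix(rbinom(n * 8, 1, 0.3), n, 8,
                 dimnames = list(sprintf("s%04d", 1:n), paste0("g", 1:8)))
  y <- setNames(rnorm(n), rownames(vals))
  expect_lte(variance_explained(gene_mat(vals), paste0("g", 1:8), y)$r2, 0.02)
})
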