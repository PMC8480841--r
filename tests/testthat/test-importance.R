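fake_fold <- function(p_values, importances = seq_along(p_values),
                      features = paste0("f", seq_along(p_values))) {
  structure(list(table = tibble::tibble(feature = features,
                                        importance = importances,
                                        p_value = p_values),
                 n_perm = 100),
            class = "importance_fold")
}

test_that("a dominant feature hits the empirical P floor 1/(n_perm+1)", {
  set.seed(1)
  n <- 120
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("x", 1:8)))
  y <- 3 * X[, 1] + rnorm(n, sd = 0.1)
  res <- permutation_importance(X, y, n_perm = 50, seed = 4,
                                config = list(n_trees = 60))
  tab <- res$table
  expect_equal(tab$p_value[tab$feature == "x1"], 1 / 51)
  expect_true(all(tab$p_value >= 1 / 51 & tab$p_value <= 1))
  # determinism of the whole null ensemble
  res2 <- permutation_importance(X, y, n_perm = 50, seed = 4,
                                 config = list(n_trees = 60))
  expect_identical(res$table, res2$table)
  expect_identical(res$null, res2$null)
})

test_that("the add-one empirical P formula matches direct counting on the null matrix", {
  set.seed(2)
  n <- 80
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- rnorm(n)
  res <- permutation_importance(X, y, n_perm = 30, seed = 9,
                                config = list(n_trees = 40))
  for (j in seq_len(5)) {
    obs <- res$table$importance[j]
    expect_equal(res$table$p_value[j],
                 (1 + sum(res$null[, j] >= obs)) / (1 + 30))
  }
})

test_that("consensus selection requires P < alpha in every fold", {
  f_all <- fake_fold(c(0.005, 0.005, 0.5))
  f_one <- fake_fold(c(0.005, 0.02, 0.5))
  expect_equal(consensus_features(list(f_all, f_all, f_all, f_all, f_all)),
               c("f2", "f1"))   # ordered by mean importance desc
  expect_equal(consensus_features(list(f_all, f_all, f_all, f_all, f_one)),
               "f1")
  # brute-force all-folds filter on random P tables
  set.seed(3)
  for (rep in 1:10) {
    folds <- lapply(1:5, function(i)
      fake_fold(stats::runif(20), importances = stats::runif(20)))
    got <- consensus_features(folds, alpha = 0.7)
    pmat <- sapply(folds, function(f) f$table$p_value)
    idx <- which(apply(pmat < 0.7, 1, all))
    expect_setequal(got, if (length(idx)) paste0("f", idx) else character())
  }
  expect_error(consensus_features(list(f_all, fake_fold(c(0.1, 0.1)))),
               "universes")
})

test_that("consensus sets shrink monotonically as alpha decreases", {
  set.seed(8)
  folds <- lapply(1:5, function(i) fake_fold(stats::runif(30)))
  sets <- lapply(c(0.5, 0.2, 0.05, 0.01), function(a)
    consensus_features(folds, alpha = a))
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("empirical P values stabilize as n_perm grows (binomial Monte-Carlo error)", {
  set.seed(5)
  n <- 100
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- X[, 2] + rnorm(n)
  cfg <- list(n_trees = 40)
  p100 <- permutation_importance(X, y, n_perm = 100, seed = 1, config = cfg)$table$p_value
  p400 <- permutation_importance(X, y, n_perm = 400, seed = 1, config = cfg)$table$p_value
  se <- sqrt(pmax(p400 * (1 - p400), 0.25 / 400) / 100)
  expect_true(all(abs(p100 - p400) <= 3 * se + 1 / 101))
})

test_that("FDR ratio handles degenerate counts per the stated rules", {
  expect_equal(ontotyper:::fdr_value(10, 0), 0)
  expect_equal(ontotyper:::fdr_value(100, 1), 0.01)
  expect_equal(ontotyper:::fdr_value(0, 0), 0)
  expect_warning(v <- ontotyper:::fdr_value(0, 3), "capped")
  expect_equal(v, 1)
})

test_that("column scrambling preserves marginals and breaks the phenotype link", {
  set.seed(6)
  X <- matrix(rbinom(200 * 10, 3, 0.3), 200, 10,
              dimnames = list(paste0("s", 1:200), paste0("t", 1:10)))
  Xs <- scramble_matrix(X, seed = 3)
  expect_equal(dimnames(Xs), dimnames(X))
  for (j in 1:10) expect_equal(unname(sort(Xs[, j])), unname(sort(X[, j])))
  expect_false(all(Xs == X))
  expect_identical(scramble_matrix(X, seed = 3), Xs)   # seeded streams
  # row scrambling permutes whole strain rows, preserving them as a multiset
  Xr <- scramble_matrix(X, seed = 3, how = "rows")
  expect_setequal(unname(apply(Xr, 1, paste, collapse = ",")),
                  unname(apply(X, 1, paste, collapse = ",")))
  expect_false(all(Xr == X))
})

test_that("hypergeometric enrichment is exact: 5-of-5 pick is 1/C(10,5)", {
  ont <- new_ontology(data.frame(child = c("A", "B"), parent = "root"),
                      list(A = paste0("g", 1:5), B = paste0("g", 1:10)))
  universe <- paste0("g", 1:10)
  res <- enrich_features(paste0("g", 1:5), ont, universe)
  expect_equal(res$p_raw[res$term == "A"], 1 / choose(10, 5))
  # a term holding the whole universe can never be enriched
  expect_equal(res$p_raw[res$term == "B"], 1)
  expect_equal(res$p_raw[res$term == "root"], 1)
  expect_error(enrich_features(character(), ont, universe), "empty")
  expect_error(enrich_features("gX", ont, universe), "subset")
})

test_that("enrichment matches exhaustive tail enumeration on small universes", {
  # oracle: enumerate all C(N, n) selections, tail probability of overlap >= k
  exact_tail <- function(N, K, n, k) {
    sets <- utils::combn(N, n)
    mean(apply(sets, 2, function(s) sum(s <= K)) >= k)
  }
  set.seed(7)
  for (rep in 1:12) {
    N <- sample(6:12, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    universe <- paste0("g", 1:N)
    ont <- new_ontology(data.frame(child = "T", parent = "root"),
                        list(T = paste0("g", 1:K),
                             root = universe))
    sel <- sample(universe, n)
    res <- enrich_features(sel, ont, universe)
    k <- length(intersect(sel, paste0("g", 1:K)))
    expect_equal(res$p_raw[res$term == "T"], exact_tail(N, K, n, k),
                 tolerance = 1e-12)
  }
})

test_that("top-k overlap: identical lists are wildly enriched, disjoint 3-vs-3 in 6 gives p = 0.1", {
  same <- compare_top_features(paste0("f", 1:5), paste0("f", 1:5),
                               universe_size = 50)
  expect_gt(same$odds_ratio, 100)
  expect_lt(same$fisher_p, 1e-6)
  # exact enumeration oracle for k=5, universe=50, full overlap:
  # P(overlap >= 5) under hypergeometric = C(5,5)C(45,0)/C(50,5)
  expect_equal(same$fisher_p, 1 / choose(50, 5), tolerance = 1e-9)
  disj <- compare_top_features(paste0("f", 1:3), paste0("f", 4:6),
                               universe_size = 6)
  expect_equal(disj$fisher_p, 0.1, tolerance = 1e-9)
  expect_error(compare_top_features(paste0("f", 1:9), paste0("f", 1:9), 5), "universe")
})

test_that("independently drawn top lists have odds ratios centered at 1", {
  set.seed(9)
  ors <- replicate(100, {
    a <- sample(paste0("f", 1:200), 30)
    b <- sample(paste0("f", 1:200), 30)
    compare_top_features(a, b, 200)$odds_ratio
  })
  expect_gt(median(ors), 0.4)
  expect_lt(median(ors), 2.5)
})
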