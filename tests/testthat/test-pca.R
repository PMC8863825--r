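sim_features <- function(n = 30, p = 8, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("S", 1:n), paste0("f", 1:p)))
  x
}

test_that("feature matrix concatenates, imputes and z-scores", {
  n <- 20
  s <- paste0("S", 1:n)
  lc <- matrix(rnorm(30 * n, 5), 30, n,
               dimnames = list(paste0("mir", 1:30), s))
  ph <- data.frame(matrix(abs(rnorm(25 * n, 10)), n,
                          dimnames = list(s, paste0("p", 1:25))))
  ph[3, 1] <- NA
  fm <- build_feature_matrix(lc, ph)
  expect_equal(ncol(fm), 55)
  expect_equal(unname(colMeans(fm)), rep(0, 55), tolerance = 1e-12)
  expect_equal(unname(apply(fm, 2, sd)), rep(1, 55), tolerance = 1e-12)
  # a column that is a constant multiple of another z-scores identically
  ph2 <- data.frame(a = abs(rnorm(n)) + 1)
  ph2$b <- ph2$a * 3
  rownames(ph2) <- s
  fm2 <- build_feature_matrix(NULL, ph2, log_pheno = FALSE)
  expect_equal(unname(fm2[, "a"]), unname(fm2[, "b"]), tolerance = 1e-12)
  # zero-variance columns are dropped with a warning
  ph3 <- data.frame(c = rnorm(n), z = rep(4, n), row.names = s)
  expect_warning(fm3 <- build_feature_matrix(NULL, ph3, log_pheno = FALSE),
                 "zero-variance")
  expect_equal(colnames(fm3), "c")
})

test_that("PCA satisfies its spectral and reconstruction identities", {
  x <- sim_features(40, 10, seed = 3)
  x <- scale(x)
  res <- run_pca(x)
  expect_equal(sum(res$var_frac), 1, tolerance = 1e-12)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  # eigen oracle on the correlation matrix
  ev <- eigen(cor(x), symmetric = TRUE)$values
  expect_equal(unname(res$eigenvalues), ev[seq_along(res$eigenvalues)],
               tolerance = 1e-10)
  # orthonormal loadings and exact reconstruction
  expect_equal(crossprod(res$loadings), diag(ncol(res$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$scores %*% t(res$loadings),
               sweep(x, 2, colMeans(x)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # contributions sum to 100 per component
  expect_equal(unname(colSums(res$contrib)),
               rep(100, ncol(res$contrib)), tolerance = 1e-9)
})

test_that("two perfectly correlated features put all variance on PC1", {
  v <- rnorm(25)
  x <- cbind(a = v, b = 2 * v + 1)
  rownames(x) <- paste0("S", 1:25)
  res <- run_pca(scale(x))
  expect_equal(res$var_frac[1], 1, tolerance = 1e-12)
})

test_that("PCA is invariant to feature order up to the sign convention", {
  x <- scale(sim_features(30, 6, seed = 9))
  r1 <- run_pca(x)
  perm <- c(4, 1, 6, 2, 5, 3)
  r2 <- run_pca(x[, perm])
  expect_equal(r1$eigenvalues, r2$eigenvalues, tolerance = 1e-10)
  expect_equal(r1$loadings[colnames(x)[perm], ], r2$loadings,
               tolerance = 1e-8)
  expect_equal(r1$scores, r2$scores, tolerance = 1e-8)
})

test_that("top contributors match the weighted-contribution formula", {
  x <- scale(sim_features(50, 10, seed = 5))
  res <- run_pca(x)
  tc <- top_contributors(res, k = 10, components = 1:2)
  manual <- (res$contrib[, 1] * res$eigenvalues[1] +
               res$contrib[, 2] * res$eigenvalues[2]) /
    sum(res$eigenvalues[1:2])
  manual <- sort(manual, decreasing = TRUE)
  expect_equal(tc$contrib, unname(manual), tolerance = 1e-12)
  expect_equal(tc$feature, names(manual))
  # k beyond the feature count returns everything
  expect_equal(nrow(top_contributors(res, k = 99)), 10)
})

test_that("a single dominant feature takes ~100% of PC1", {
  set.seed(7)
  n <- 40
  x <- cbind(big = rnorm(n, sd = 1),
             matrix(rnorm(n * 5, sd = 1e-4), n, 5,
                    dimnames = list(NULL, paste0("n", 1:5))))
  rownames(x) <- paste0("S", 1:n)
  res <- run_pca(x)  # unscaled on purpose: dominance is in variance
  tc <- top_contributors(res, k = 1, components = 1)
  expect_equal(tc$feature, "big")
  expect_gt(res$contrib["big", 1], 99.9)
})

test_that("group separation detects planted shifts and stays at chance under the null", {
  set.seed(15)
  n <- 30
  shift <- c(rep(-3, n), rep(0, n), rep(3, n))
  x <- matrix(rnorm(3 * n * 12), 3 * n, 12) + shift
  rownames(x) <- paste0("S", 1:(3 * n))
  colnames(x) <- paste0("f", 1:12)
  grp <- rep(c("lo", "mid", "hi"), each = n)
  res <- run_pca(scale(x))
  gs <- group_separation(res, grp)
  expect_gte(gs$accuracy, 0.95)
  expect_true(gs$intermediate)
  expect_setequal(unname(gs$extremes), c("lo", "hi"))
  # identical groups: accuracy near 1/2
  x0 <- matrix(rnorm(2 * n * 12), 2 * n, 12,
               dimnames = list(paste0("S", 1:(2 * n)), paste0("f", 1:12)))
  gs0 <- group_separation(run_pca(scale(x0)), rep(c("a", "b"), each = n))
  expect_lt(gs0$accuracy, 0.75)
})
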