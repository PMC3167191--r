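# Factor analysis, sampling-adequacy diagnostics, Fisher LDA and its
# diagnostics, cross-checked against independent oracles (closed forms,
# brute-force searches, stats::varimax, MASS::lda, manova).

# compound-symmetry block correlation matrix: two independent blocks
block_corr <- function(sizes, r) {
  p <- sum(sizes)
  R <- diag(p)
  start <- cumsum(c(1, sizes))
  for (b in seq_along(sizes)) {
    idx <- start[b]:(start[b + 1] - 1)
    R[idx, idx] <- r
    diag(R)[idx] <- 1
  }
  R
}

test_that("factor analysis recovers a two-block population structure", {
  R <- block_corr(c(7, 8), 0.8)
  fm <- factor_analysis(R, n_obs = 1000)
  # closed form: top eigenvalues 1 + (m-1) r for each block, rest 1 - r
  expect_equal(sort(fm$eigenvalues, decreasing = TRUE),
               c(1 + 7 * 0.8, 1 + 6 * 0.8), tolerance = 1e-10)
  expect_identical(fm$n_factors, 2L)
  member <- fm$assignment
  expect_length(unique(member[1:7]), 1)
  expect_length(unique(member[8:15]), 1)
  expect_false(member[1] == member[8])
})

test_that("independent columns are flagged structureless", {
  # population identity: no eigenvalue exceeds 1, nothing retained
  fm0 <- suppressWarnings(factor_analysis(diag(15), n_obs = 500))
  expect_identical(fm0$n_factors, 0L)
  expect_true(fm0$structureless)
  # large-n sample of independent columns: eigenvalues hover about 1 within
  # sampling noise and the model is flagged structureless
  set.seed(5)
  X <- matrix(stats::rnorm(60000), 4000, 15)
  expect_warning(fm <- factor_analysis(X), "structureless")
  expect_true(fm$structureless)
  expect_lt(max(fm$all_eigenvalues), 1.2)
})

test_that("the default synthetic cohort yields five block-consistent factors", {
  hits <- 0
  for (seed in 1:10) {
    co <- simulate_amplitude_cohort(cohort_spec(n_subjects = 200, seed = seed))
    H <- t(vapply(co$matrices, function(m) as.vector(t(m$H)), numeric(15)))
    fm <- suppressWarnings(factor_analysis(H))
    if (fm$n_factors == 5L) hits <- hits + 1
  }
  expect_gte(hits, 8)  # >= 80% of seeds
})

test_that("varimax preserves communalities and the reproduced correlation", {
  set.seed(7)
  X <- matrix(stats::rnorm(200 * 6), 200, 6)
  X[, 2] <- X[, 1] + stats::rnorm(200, 0, 0.4)
  X[, 4] <- X[, 3] + stats::rnorm(200, 0, 0.4)
  X[, 6] <- X[, 5] + stats::rnorm(200, 0, 0.4)
  R <- stats::cor(X)
  eg <- eigen(R, symmetric = TRUE)
  keep <- which(eg$values > 1)
  L <- eg$vectors[, keep] %*% diag(sqrt(eg$values[keep]))
  rot <- pulsedx:::varimax_rotate(L)
  expect_equal(rowSums(rot$loadings^2), rowSums(L^2), tolerance = 1e-8)
  expect_equal(rot$loadings %*% t(rot$loadings), L %*% t(L), tolerance = 1e-8)
  # criterion value matches stats::varimax (permutation/sign invariant)
  vcrit <- function(M) {
    Z <- M^2
    sum(apply(Z, 2, function(col) mean(col^2) - mean(col)^2))
  }
  sv <- stats::varimax(L, normalize = TRUE, eps = 1e-10)
  expect_equal(vcrit(rot$loadings / sqrt(rowSums(L^2))),
               vcrit(unclass(sv$loadings) / sqrt(rowSums(L^2))),
               tolerance = 1e-6)
})

test_that("eigenvalues of a correlation-based extraction sum to p", {
  set.seed(11)
  X <- matrix(stats::rnorm(50 * 15), 50, 15)
  fm <- suppressWarnings(factor_analysis(X))
  expect_equal(sum(fm$all_eigenvalues), 15, tolerance = 1e-8)
  ft <- default_features(seed = 2)
  fm2 <- suppressWarnings(factor_analysis(as.matrix(ft[, 2:16])))
  expect_equal(sum(fm2$all_eigenvalues), 15, tolerance = 1e-8)
  expect_lte(sum(fm2$pct_variance), 100 + 1e-9)
  expect_true(all(abs(fm2$loadings) <= 1 + 1e-9))
})

test_that("KMO is exactly 0.5 for any correlated bivariate data", {
  set.seed(3)
  for (r in c(0.2, -0.6, 0.9)) {
    x <- stats::rnorm(100)
    y <- r * x + sqrt(1 - r^2) * stats::rnorm(100)
    expect_equal(suppressWarnings(kmo(cbind(x, y))), 0.5, tolerance = 1e-12)
  }
})

test_that("KMO matches a regression-residual partial-correlation oracle", {
  set.seed(19)
  n <- 120; p <- 4
  X <- matrix(stats::rnorm(n * p), n, p)
  X[, 2] <- X[, 1] + stats::rnorm(n, 0, 0.7)
  X[, 4] <- X[, 3] - 0.5 * X[, 1] + stats::rnorm(n, 0, 0.7)
  R <- stats::cor(X)
  # oracle: partial correlation of (i, j) given the rest via residuals of
  # least-squares regressions, no matrix inversion of R
  partial <- function(i, j) {
    others <- setdiff(seq_len(p), c(i, j))
    ri <- stats::lm.fit(cbind(1, X[, others]), X[, i])$residuals
    rj <- stats::lm.fit(cbind(1, X[, others]), X[, j])$residuals
    stats::cor(ri, rj)
  }
  r2 <- 0; q2 <- 0
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    r2 <- r2 + R[i, j]^2
    q2 <- q2 + partial(i, j)^2
  }
  expect_equal(suppressWarnings(kmo(X)), r2 / (r2 + q2), tolerance = 1e-10)
})

test_that("Bartlett sphericity behaves per its closed form", {
  expect_equal(bartlett_sphericity(diag(6), n_obs = 40)$statistic, 0)
  expect_equal(bartlett_sphericity(diag(6), n_obs = 40)$p_value, 1)
  # strictly increasing in n for fixed R
  R <- block_corr(c(3, 3), 0.5)
  stats <- vapply(c(20, 50, 200), function(n)
    bartlett_sphericity(R, n_obs = n)$statistic, numeric(1))
  expect_true(all(diff(stats) > 0))
  # oracle recomputation through the eigenvalue route
  set.seed(23)
  X <- matrix(stats::rnorm(80 * 5), 80, 5)
  X[, 2] <- X[, 1] + stats::rnorm(80)
  b <- bartlett_sphericity(X)
  lam <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  stat_oracle <- -(80 - 1 - (2 * 5 + 5) / 6) * sum(log(lam))
  expect_equal(b$statistic, stat_oracle, tolerance = 1e-10)
  expect_equal(b$df, 10)
})

test_that("a 1-D discriminant with equal priors is the midpoint rule", {
  set.seed(2)
  x <- c(stats::rnorm(10, 0), stats::rnorm(14, 3))
  y <- rep(c("deficient", "excess"), c(10, 14))
  fit <- fisher_lda(matrix(x, ncol = 1), y, prior = "equal")
  mid <- (mean(x[y == "deficient"]) + mean(x[y == "excess"])) / 2
  pred_mid <- ifelse(x >= mid, "excess", "deficient")
  expect_identical(predict(fit, matrix(x, ncol = 1)), pred_mid)
})

test_that("fisher_lda agrees with MASS::lda classifications", {
  ft <- default_features(seed = 4)
  X <- as.matrix(ft[, c("PP1", "PP2", "PP3")])
  y <- ft$label
  ours <- predict(fisher_lda(X, y), X)
  m <- MASS::lda(X, grouping = factor(y))
  theirs <- as.character(predict(m)$class)
  expect_gte(mean(ours == theirs), 69 / 70)  # allow one boundary tie
})

test_that("fisher_lda recovers a known discriminant direction", {
  set.seed(31)
  n <- 500
  mu_shift <- c(2, 0, 0) / sqrt(1)   # separation only along x1
  y <- rep(c("deficient", "excess"), each = n / 2)
  X <- matrix(stats::rnorm(n * 3), n, 3)
  X[y == "excess", 1] <- X[y == "excess", 1] + 2
  fit <- fisher_lda(X, y)
  w <- fit$raw_coefficients
  cosine <- abs(sum(w * c(1, 0, 0))) / sqrt(sum(w^2))
  expect_gt(cosine, 0.95)
})

test_that("fisher_lda predictions are affine invariant", {
  ft <- default_features(seed = 6)
  X <- as.matrix(ft[, c("PP_avg", "MPA_avg", "PP_max")])
  y <- ft$label
  base <- predict(fisher_lda(X, y), X)
  set.seed(8)
  A <- matrix(stats::rnorm(9), 3, 3) + 3 * diag(3)
  b <- c(5, -2, 11)
  Xt <- sweep(X %*% A, 2, b, "+")
  expect_identical(predict(fisher_lda(Xt, y), Xt), base)
})

test_that("Wilks' Lambda matches manova and is ~1 under the null", {
  ft <- default_features(seed = 9)
  X <- as.matrix(ft[, c("PP1", "PP2", "PP3")])
  y <- ft$label
  wl <- wilks_lambda(X, y)
  mv <- summary(stats::manova(X ~ factor(y)), test = "Wilks")
  expect_equal(wl$lambda, mv$stats[1, "Wilks"], tolerance = 1e-8)
  expect_gt(wl$lambda, 0); expect_lte(wl$lambda, 1)
  # identical class means: lambda ~ 1
  set.seed(12)
  X0 <- matrix(stats::rnorm(200 * 3), 200, 3)
  y0 <- rep(c("deficient", "excess"), 100)
  wl0 <- wilks_lambda(X0, y0)
  expect_gt(wl0$lambda, 0.95)
  expect_gt(wl0$p_value, 0.1)
})

test_that("Box's M matches an independent recomputation and is calibrated", {
  ft <- default_features(seed = 10)
  X <- as.matrix(ft[, c("PP1", "PP2", "PP3")])
  y <- ft$label
  bm <- box_m(X, y)
  # oracle: direct textbook formula from class covariances
  n1 <- sum(y == "deficient"); n2 <- sum(y == "excess"); n <- n1 + n2; p <- 3
  S1 <- stats::cov(X[y == "deficient", ]); S2 <- stats::cov(X[y == "excess", ])
  Sp <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n - 2)
  M <- (n - 2) * log(det(Sp)) - (n1 - 1) * log(det(S1)) - (n2 - 1) * log(det(S2))
  expect_equal(bm$statistic, M, tolerance = 1e-8)
  # equal covariances by construction: p-values not systematically small
  set.seed(14)
  ps <- vapply(1:25, function(i) {
    Xh <- matrix(stats::rnorm(200 * 3), 200, 3)
    yh <- rep(c("deficient", "excess"), c(80, 120))
    box_m(Xh, yh)$p_value
  }, numeric(1))
  expect_gt(stats::median(ps), 0.2)
})

test_that("leave-one-out cross-validation bookkeeping is exact", {
  ft <- default_features(seed = 13, n = 30)
  X <- as.matrix(ft[, c("PP_avg", "PP_max")])
  y <- ft$label
  cv <- loocv(function(X, y) fisher_lda(X, y), X, y)
  expect_equal(sum(cv$table), 30)
  expect_length(cv$per_subject, 30)
  expect_true(all(cv$per_subject %in% c("deficient", "excess")))

  # perfectly separated classes cross-validate perfectly
  Xs <- matrix(c(stats::rnorm(15, 0, .1), stats::rnorm(15, 10, .1)), ncol = 1)
  ys <- rep(c("deficient", "excess"), each = 15)
  cvs <- loocv(function(X, y) fisher_lda(X, y), Xs, ys)
  expect_equal(accuracy(cvs$table), 1)
})

test_that("cross-validated accuracy does not beat training accuracy on average", {
  set.seed(17)
  gaps <- vapply(1:40, function(i) {
    n <- 40
    y <- rep(c("deficient", "excess"), each = n / 2)
    X <- matrix(stats::rnorm(n * 4), n, 4)
    X[y == "excess", 1] <- X[y == "excess", 1] + 1
    fit <- fisher_lda(X, y)
    train <- accuracy(confusion(y, predict(fit, X)))
    cv <- accuracy(loocv(function(X, y) fisher_lda(X, y), X, y)$table)
    train - cv
  }, numeric(1))
  expect_gt(mean(gaps), 0)
})
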