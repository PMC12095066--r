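test_that("the GRM matches a brute-force double loop and its invariants", {
  set.seed(41)
  G <- simulate_genotypes(10, 50, seed = 8)
  K <- compute_grm(G)
  # brute force over line pairs
  p <- colMeans(G$dosages) / 2
  W <- sweep(G$dosages, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  ref <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10)
    ref[i, j] <- sum(W[i, ] * W[j, ]) / denom
  expect_matrix_equal(K$K, ref, 1e-10)
  expect_matrix_equal(K$K, t(K$K), 1e-12)
  expect_lt(abs(mean(diag(K$K)) - 1), 0.2)
  expect_gt(min(eigen(K$K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # marker permutation invariance
  perm <- sample(50)
  K2 <- compute_grm(genotype_matrix(G$dosages[, perm]))
  expect_matrix_equal(K$K, K2$K, 1e-10)
  # duplicated lines are maximally related
  dd <- G$dosages[c(1, 1, 2), ]
  rownames(dd) <- c("d1", "d2", "d3")
  dup <- genotype_matrix(dd)
  Kd <- compute_grm(dup)
  expect_equal(Kd$K[1, 2], Kd$K[1, 1], tolerance = 1e-12)
  expect_error(compute_grm(genotype_matrix(matrix(c(2L, 2L, 2L, 2L), 2))),
               "monomorphic")
})

test_that("GRMs round-trip through CSV with symmetry checked", {
  G <- simulate_genotypes(8, 40, seed = 9)
  K <- compute_grm(G)
  f <- withr::local_tempfile(fileext = ".csv")
  write_grm(K, f)
  K2 <- read_grm(f)
  expect_equal(K2$line_ids, K$line_ids)
  expect_matrix_equal(K2$K, K$K, 1e-12)
})

test_that("REML heritability hits the noise-free limit and is affine-invariant", {
  set.seed(42)
  G <- simulate_genotypes(150, 300, seed = 10)
  K <- compute_grm(G)
  ed <- eigen(K$K, symmetric = TRUE)
  y <- 3 * ed$vectors[, 1]
  fit <- reml_single_component(y, K)
  expect_gte(fit$h2, 0.99)
  # shift and positive scaling leave h2 unchanged
  y2 <- 0.4 + ed$vectors[, 1] + rnorm(150, sd = 0.1 * sd(ed$vectors[, 1]))
  f1 <- reml_single_component(y2, K)
  f2 <- reml_single_component(5 + 2 * y2, K)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-5)
  expect_error(reml_single_component(rep(1, 150), K), "constant")
})

test_that("REML is calibrated against planted heritability", {
  set.seed(43)
  G <- simulate_genotypes(300, 800, seed = 12)
  K <- compute_grm(G)
  ed <- eigen(K$K, symmetric = TRUE)
  Wc <- sweep(G$dosages, 2, colMeans(G$dosages))
  ests <- replicate(15, {
    g <- as.numeric(Wc %*% rnorm(800))
    g <- g / sd(g) * sqrt(0.5)
    y <- g + rnorm(300, sd = sqrt(0.5))
    dynamicGP:::reml_h2_spectral(y, ed)$h2
  })
  expect_lt(abs(mean(ests) - 0.5), 0.07)
  # pure noise: near-zero estimates on average
  nulls <- replicate(15, dynamicGP:::reml_h2_spectral(rnorm(300), ed)$h2)
  expect_lt(mean(nulls), 0.12)
})

test_that("RR-BLUP at fixed lambda equals the closed-form ridge solution", {
  set.seed(44)
  M <- matrix(rbinom(12, 2, 0.4), 4, 3)
  y <- rnorm(4)
  f <- fit_rrblup(y, M, lambda = 1)
  Mc <- sweep(M, 2, colMeans(M))
  ref <- solve(crossprod(Mc) + diag(3), crossprod(Mc, y - f$mu))
  expect_matrix_equal(matrix(f$beta), ref, 1e-10)
  expect_error(fit_rrblup(rep(1, 4), M), "constant")
  expect_error(fit_rrblup(c(1, NA, 2, 3), M), "non-finite")
})

test_that("kernel and primal ridge solutions agree at fixed lambda", {
  set.seed(45)
  # n < m and n > m regimes
  for (dims in list(c(20, 50), c(50, 20))) {
    M <- matrix(rbinom(prod(dims), 2, 0.3), dims[1], dims[2])
    y <- rnorm(dims[1])
    f <- fit_rrblup(y, M, lambda = 2.5)
    Mc <- sweep(M, 2, colMeans(M))
    primal <- solve(crossprod(Mc) + 2.5 * diag(dims[2]),
                    crossprod(Mc, y - f$mu))
    expect_matrix_equal(matrix(f$beta), primal, 1e-8)
  }
})

test_that("REML lambda matches a fine grid search on simulated data", {
  set.seed(46)
  G <- simulate_genotypes(60, 80, seed = 13)
  Wc <- sweep(G$dosages, 2, colMeans(G$dosages))
  g <- as.numeric(Wc %*% rnorm(80)); g <- g / sd(g) * sqrt(0.6)
  y <- g + rnorm(60, sd = sqrt(0.4))
  f <- fit_rrblup(y, G$dosages)
  # independent dense REML over a 1000-point log-lambda grid
  Mc <- Wc
  n <- 60
  ones <- rep(1, n)
  Gm <- tcrossprod(Mc)
  rl <- function(lam) {
    V <- Gm + lam * diag(n)
    Vi <- solve(V)
    xx <- as.numeric(t(ones) %*% Vi %*% ones)
    mu <- as.numeric(t(ones) %*% Vi %*% y) / xx
    r <- y - mu
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - 1)
    -0.5 * ((n - 1) * log(s2) + determinant(V)$modulus + log(xx) + (n - 1))
  }
  grid <- seq(-10, 10, length.out = 1000)
  vals <- vapply(grid, function(l) rl(exp(l)), numeric(1))
  best <- grid[which.max(vals)]
  expect_lt(abs(log(f$lambda) - best), diff(grid[1:2]) + 1e-6)
})

test_that("prediction reproduces fitted values and recovers planted signal", {
  set.seed(47)
  G <- simulate_genotypes(500, 300, seed = 14)
  Wc <- sweep(G$dosages, 2, colMeans(G$dosages))
  g <- as.numeric(Wc %*% rnorm(300)); g <- g / sd(g) * sqrt(0.8)
  y <- g + rnorm(500, sd = sqrt(0.2))
  fit <- fit_rrblup(y[1:400], G$dosages[1:400, ])
  # training rows predict their own fitted values
  self <- predict_rrblup(fit, G$dosages[1:400, ])
  Mc <- sweep(G$dosages[1:400, ], 2, fit$marker_centering)
  expect_equal(self, as.numeric(fit$mu + Mc %*% fit$beta), tolerance = 1e-12)
  # held-out accuracy comfortably positive (ceiling sqrt(0.8) ~ 0.89)
  pred <- predict_rrblup(fit, G$dosages[401:500, ])
  expect_gt(cor(pred, y[401:500]), 0.5)
  # null effects predict the intercept everywhere
  fit0 <- fit
  fit0$beta <- rep(0, length(fit$beta))
  expect_equal(unique(round(predict_rrblup(fit0, G$dosages[401:500, ]), 12)),
               round(fit$mu, 12))
  expect_error(predict_rrblup(fit, G$dosages[, 1:10]), "marker")
})
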