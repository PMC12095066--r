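test_that("snapshot pairs respect block boundaries", {
  A <- diag(0.9, 3)
  tt <- make_planted_tensor(A, list(c(1, 2, 3), c(2, 1, 4)))
  s <- build_snapshot_pair(tt, "L1")
  expect_equal(ncol(s$X1), 20L)          # 5 blocks of 5 -> 4 pairs each
  expect_equal(dim(s$X1), dim(s$X2))
  # every pair spans one calendar day and stays inside a block
  expect_true(all(tt$time_axis[s$pair_index$target] -
                  tt$time_axis[s$pair_index$source] == 1))
  # single block: T - 1 pairs
  tt2 <- make_planted_tensor(A, list(c(1, 2, 3)), days = 1:25)
  expect_equal(ncol(build_snapshot_pair(tt2, "L1")$X1), 24L)
  # a one-day block contributes nothing and warns
  tt3 <- make_planted_tensor(A, list(c(1, 2, 3)), days = c(15, 16, 20))
  expect_warning(s3 <- build_snapshot_pair(tt3, "L1"), "single timepoint")
  expect_equal(ncol(s3$X1), 1L)
  expect_error(suppressWarnings(build_snapshot_pair(
    make_planted_tensor(A, list(c(1, 2, 3)), days = c(15, 18, 21)), "L1")),
    "no usable")
})

test_that("classical DMD solves the least-squares operator problem", {
  # constant traits: fixed point
  X <- matrix(rep(c(1, 2), 5), 2)
  s <- structure(list(X1 = X, X2 = X,
                      pair_index = tibble::tibble(source = 1:5, target = 2:6)),
                 class = "snapshot_pair")
  f <- fit_classical_dmd(s)
  expect_matrix_equal(f$A %*% X, X)
  # hand-computed rank-1 pseudoinverse: X1 = X2 = (1,2)'
  s1 <- structure(list(X1 = matrix(c(1, 2)), X2 = matrix(c(1, 2)),
                       pair_index = tibble::tibble(source = 1, target = 2)),
                  class = "snapshot_pair")
  A1 <- fit_classical_dmd(s1)$A
  expect_matrix_equal(A1, matrix(c(0.2, 0.4, 0.4, 0.8), 2))
  # exact recovery from a known operator
  set.seed(31)
  A3 <- matrix(rnorm(9, sd = 0.3), 3) + diag(0.5, 3)
  tt <- make_planted_tensor(A3, list(rnorm(3), rnorm(3), rnorm(3)), days = 1:6)
  sp <- build_snapshot_pair(tt, "L1")
  fit <- fit_classical_dmd(sp)
  expect_lt(norm(fit$A %*% sp$X1 - sp$X2, "F"), 1e-10)
})

test_that("no perturbed operator beats the DMD least-squares fit", {
  set.seed(32)
  X1 <- matrix(rnorm(4 * 9), 4)
  X2 <- matrix(rnorm(4 * 9), 4)
  s <- structure(list(X1 = X1, X2 = X2,
                      pair_index = tibble::tibble(source = 1:9, target = 2:10)),
                 class = "snapshot_pair")
  A <- fit_classical_dmd(s)$A
  base <- norm(A %*% X1 - X2, "F")
  for (i in 1:100) {
    P <- A + matrix(rnorm(16, sd = 0.05), 4)
    expect_gte(norm(P %*% X1 - X2, "F"), base - 1e-12)
  }
})

test_that("Schur-based DMD satisfies its factor identities", {
  set.seed(33)
  Ad <- diag(c(0.9, 0.5))
  tt <- make_planted_tensor(Ad, list(c(1, 1)), days = 1:12)
  m <- fit_schur_dmd(build_snapshot_pair(tt, "L1"), r = 2)
  ev <- sort(Re(eigen(m$A_tilde, only.values = TRUE)$values), decreasing = TRUE)
  expect_equal(ev, c(0.9, 0.5), tolerance = 1e-8)
  # identities on noisy data
  truth <- simulate_operator_family(simulate_genotypes(30, 40, seed = 2),
                                    p = 6, r_true = 2, entry_h2 = 0.5, seed = 3)
  tens <- simulate_trajectories(truth, noise_sd = 0.02, seed = 4)
  for (ln in tens$line_ids[1:5]) {
    m <- fit_schur_dmd(build_snapshot_pair(tens, ln), r = 2)
    Z <- t(m$Q)
    expect_matrix_equal(crossprod(Z), diag(2), 1e-10)
    expect_matrix_equal(m$A_tilde, t(m$Q) %*% m$R %*% m$Q, 1e-10)
    expect_matrix_equal(m$A_r, reconstruct_operator(m$Phi, m$R), 1e-10)
    # nonzero spectrum of A_r equals the spectrum of A_tilde
    e_at <- sort(Mod(eigen(m$A_tilde, only.values = TRUE)$values))
    e_ar <- sort(Mod(eigen(m$A_r, only.values = TRUE)$values),
                 decreasing = TRUE)[2:1]
    expect_equal(e_at, sort(e_ar), tolerance = 1e-8)
    # blocks ordered by descending eigenvalue modulus
    expect_gte(abs(m$R[1, 1]), abs(m$R[2, 2]) - 1e-10)
  }
  # on noise-free rank-2 data the retained spectrum matches classical DMD
  tt2 <- make_planted_tensor(truth$true_operators[[1]],
                             list(as.numeric(truth$mode_basis %*% rnorm(2)),
                                  as.numeric(truth$mode_basis %*% rnorm(2))),
                             days = 1:10)
  sp <- build_snapshot_pair(tt2, "L1")
  mA <- fit_classical_dmd(sp)$A
  mS <- fit_schur_dmd(sp, r = 2)
  eA <- sort(Mod(eigen(mA, only.values = TRUE)$values), decreasing = TRUE)[1:2]
  eS <- sort(Mod(eigen(mS$A_tilde, only.values = TRUE)$values), decreasing = TRUE)
  expect_equal(eA, eS, tolerance = 1e-8)
  expect_error(fit_schur_dmd(sp, r = 0), "r must")
})

test_that("canonicalization is idempotent, sign-symmetric and spectrum-preserving", {
  set.seed(34)
  truth <- simulate_operator_family(simulate_genotypes(20, 30, seed = 5),
                                    p = 5, r_true = 3, entry_h2 = 0, seed = 6)
  tens <- simulate_trajectories(truth, noise_sd = 0.02,
                                x1_spec = list(center = 1, line_sd = 0.2,
                                               genetic_sd = 0), seed = 7)
  m <- fit_schur_dmd(build_snapshot_pair(tens, tens$line_ids[1]), r = 3)
  # idempotence
  m2 <- canonicalize_factors(m)
  expect_identical(m2$R, m$R)
  expect_identical(m2$U_r, m$U_r)
  expect_identical(m2$Phi, m$Phi)
  # negating singular-vector pairs is undone by canonicalization
  m3 <- m
  m3$U_r <- -m3$U_r; m3$V_r <- -m3$V_r
  # A_tilde is invariant under the joint flip of all U and V columns
  m3 <- canonicalize_factors(m3)
  expect_matrix_equal(m3$U_r, m$U_r, 1e-12)
  expect_matrix_equal(m3$V_r, m$V_r, 1e-12)
  # A_r never moves
  expect_matrix_equal(m3$A_r, m$A_r, 1e-10)
})

test_that("reordering a random Schur form preserves the operator", {
  set.seed(35)
  for (i in 1:20) {
    At <- matrix(rnorm(9), 3)
    sc <- Matrix::Schur(At)
    m <- structure(
      list(r = 3, U_r = rbind(diag(3), matrix(0, 2, 3)), Sigma_r = c(3, 2, 1),
           V_r = diag(3), A_tilde = At, Q = t(sc$Q), R = sc$T,
           Phi = matrix(rnorm(15), 5) %*% sc$Q, A_r = NULL),
      class = "schur_dmd")
    m$A_r <- reconstruct_operator(m$Phi, m$R)
    cm <- canonicalize_factors(m)
    expect_matrix_equal(cm$A_r, m$A_r, 1e-9)
    expect_matrix_equal(t(cm$Q) %*% cm$R %*% cm$Q, cm$A_tilde, 1e-9)
    # diagonal blocks ordered by descending eigenvalue modulus
    blocks <- list(); i <- 1
    while (i <= 3) {
      sz <- if (i < 3 && abs(cm$R[i + 1, i]) > 1e-10) 2 else 1
      blocks[[length(blocks) + 1]] <- i:(i + sz - 1)
      i <- i + sz
    }
    mods <- vapply(blocks, function(b)
      max(Mod(eigen(cm$R[b, b, drop = FALSE], only.values = TRUE)$values)),
      numeric(1))
    expect_true(all(diff(mods) <= 1e-8))
  }
})

test_that("operator reconstruction matches the normal-equations formula", {
  # rank-1: lambda * u u'
  u <- c(3, 4) / 5
  expect_matrix_equal(reconstruct_operator(matrix(u), matrix(2)),
                      2 * tcrossprod(u))
  set.seed(36)
  Phi <- matrix(rnorm(10), 5, 2)
  R <- matrix(rnorm(4), 2, 2)
  ref <- Phi %*% R %*% solve(t(Phi) %*% Phi) %*% t(Phi)
  expect_matrix_equal(reconstruct_operator(Phi, R), ref, 1e-10)
  expect_error(reconstruct_operator(Phi, matrix(0, 3, 3)), "dimension")
  # rank-deficient Phi falls back to the pseudoinverse with a warning
  Phi2 <- cbind(u, u)
  expect_warning(A0 <- reconstruct_operator(Phi2, diag(0, 2)), "rank-deficient")
  expect_matrix_equal(A0, matrix(0, 2, 2))
})

test_that("iterative forecasts step from measured states with gap handling", {
  A <- diag(2)
  tt <- make_planted_tensor(diag(0.8, 2), list(c(1, 2), c(2, 1)))
  f <- forecast_iterative(A, tt, "L1")
  expect_true(all(is.na(f[, 1])))
  for (s in 2:ncol(f))
    expect_equal(unname(f[, s]), unname(tt$values[1, , s - 1]))
  f2 <- forecast_iterative(2 * diag(2), tt, "L1")
  expect_equal(unname(f2[, 2]), unname(2 * tt$values[1, , 1]))
  # power policy recovers noise-free dynamics exactly across gaps,
  # unit_step misses exactly at post-gap timepoints
  A0 <- diag(c(0.9, 0.7))
  tt3 <- make_planted_tensor(A0, list(c(1, 1)))
  fp <- forecast_iterative(A0, tt3, "L1", gap_policy = "power")
  expect_matrix_equal(fp[, -1], matrix(tt3$values[1, , -1], nrow = 2), 1e-8)
  fu <- forecast_iterative(A0, tt3, "L1", gap_policy = "unit_step")
  post_gap <- vapply(tt3$blocks[-1], `[`, integer(1), 1)
  within <- setdiff(2:25, post_gap)
  expect_matrix_equal(fu[, within], matrix(tt3$values[1, , within], 2), 1e-8)
  expect_gt(max(abs(fu[, post_gap] - matrix(tt3$values[1, , post_gap], 2))), 1e-3)
})

test_that("recursive forecasts unroll the operator", {
  expect_equal(unname(forecast_recursive(diag(2), c(1, 2), 4)),
               matrix(c(1, 2), 2, 4))
  expect_equal(unname(forecast_recursive(matrix(2), 1, 3)),
               matrix(c(2, 4, 8), 1))
  set.seed(37)
  A <- matrix(rnorm(9, sd = 0.3), 3)
  x <- rnorm(3)
  f <- forecast_recursive(A, x, 24)
  ref <- matrix(NA_real_, 3, 24)
  xx <- x
  for (i in 1:24) { xx <- A %*% xx; ref[, i] <- xx }
  expect_matrix_equal(f, ref, 1e-12)
  expect_error(forecast_recursive(diag(10, 2), c(1e300, 1), 10), "non-finite")
})

test_that("Schur models serialise and round-trip exactly", {
  set.seed(38)
  tt <- make_planted_tensor(diag(c(0.95, 0.6)), list(c(1, 2)), days = 1:10)
  m <- fit_schur_dmd(build_snapshot_pair(tt, "L1"), r = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_schur_model(m, f)
  m2 <- read_schur_model(f)
  for (fld in c("U_r", "Sigma_r", "V_r", "A_tilde", "Q", "R", "Phi", "A_r"))
    expect_equal(unname(as.matrix(m2[[fld]])), unname(as.matrix(m[[fld]])),
                 tolerance = 0)
})
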