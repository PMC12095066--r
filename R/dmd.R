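#' Moore-Penrose pseudoinverse with relative singular-value cutoff
#'
#' @param X numeric matrix.
#' @param rcond singular values below `rcond * max(singular value)` are
#'   truncated. Defaults to `max(dim(X)) * .Machine$double.eps`.
#' @return The pseudoinverse of `X`.
#' @export
pinv <- function(X, rcond = NULL) {
  if (is.null(rcond)) rcond <- max(dim(X)) * .Machine$double.eps
  s <- svd(X)
  keep <- s$d > rcond * s$d[1]
  if (!any(keep)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Build gap-aware snapshot matrices for one line
#'
#' Extracts the p x T trajectory of one line and forms the pair of
#' matrices `X1` (all within-block timepoints except each block's last)
#' and `X2` (all except each block's first), so that column j of `X2` is
#' measured exactly one day after column j of `X1`. Pairs never span a
#' measurement gap; blocks with a single timepoint contribute no pairs and
#' are skipped with a warning.
#'
#' @param t a [trait_tensor()].
#' @param line a line identifier present in `t`.
#' @return An object of class `snapshot_pair` with fields `X1`, `X2`
#'   (p x n_pairs) and `pair_index` (tibble of source/target timepoint
#'   indices).
#' @export
build_snapshot_pair <- function(t, line) {
  stopifnot(inherits(t, "trait_tensor"))
  i <- match(line, t$line_ids)
  if (is.na(i)) abort(sprintf("line '%s' not found", line))
  X <- matrix(t$values[i, , ], nrow = length(t$trait_ids),
              dimnames = list(t$trait_ids, t$time_axis))
  src <- integer(0); tgt <- integer(0)
  for (b in t$blocks) {
    if (length(b) < 2) {
      warn(sprintf("block at day %d has a single timepoint; skipped",
                   t$time_axis[b[1]]))
      next
    }
    src <- c(src, b[-length(b)])
    tgt <- c(tgt, b[-1])
  }
  if (length(src) < 1) abort("no usable snapshot pairs; operator unidentifiable")
  structure(
    list(X1 = X[, src, drop = FALSE], X2 = X[, tgt, drop = FALSE],
         pair_index = tibble(source = src, target = tgt)),
    class = "snapshot_pair")
}

#' Classical dynamic mode decomposition
#'
#' Estimates the best-fit linear operator `A` advancing the trait vector
#' one day, `A = X2 X1^+`, the least-squares minimiser of
#' `||A X1 - X2||_F` over all p x p matrices.
#'
#' @param s a [build_snapshot_pair()] result.
#' @param rcond pseudoinverse cutoff passed to [pinv()].
#' @return An object of class `classical_dmd` with fields `A` and
#'   `rcond_used`.
#' @export
fit_classical_dmd <- function(s, rcond = NULL) {
  stopifnot(inherits(s, "snapshot_pair"))
  if (!all(is.finite(s$X1)) || !all(is.finite(s$X2)))
    abort("snapshot matrices contain non-finite values")
  if (is.null(rcond)) rcond <- max(dim(s$X1)) * .Machine$double.eps
  A <- s$X2 %*% pinv(s$X1, rcond)
  dimnames(A) <- list(rownames(s$X1), rownames(s$X1))
  structure(list(A = A, rcond_used = rcond), class = "classical_dmd")
}

#' Schur-based dynamic mode decomposition
#'
#' Projects the one-day operator onto the `r` leading POD modes of `X1`
#' (left singular vectors), takes the real Schur decomposition of the
#' projected operator, and lifts it back through the projected DMD modes:
#' \deqn{X_1 = U \Sigma V^T, \quad
#'       \tilde A = U_r^T X_2 V_r \Sigma_r^{-1}, \quad
#'       \tilde A = Q^T R Q, \quad
#'       \Phi = X_2 V_r \Sigma_r^{-1} Q^T, \quad
#'       A_r = \Phi R \Phi^+.}
#' `R` is real quasi-upper-triangular (2 x 2 blocks for complex-conjugate
#' eigenvalue pairs). The returned factors are canonicalized (see
#' [canonicalize_factors()]) so that matrix entries are comparable across
#' genotypes: singular-vector signs fixed, Schur blocks ordered by
#' descending eigenvalue modulus, mode signs fixed.
#'
#' @param s a [build_snapshot_pair()] result.
#' @param r number of retained singular vectors; the default 2 keeps the
#'   two dominant modes, which is where factor entries remain heritable in
#'   practice.
#' @return An object of class `schur_dmd` with fields `r`, `U_r`,
#'   `Sigma_r`, `V_r`, `A_tilde`, `Q`, `R`, `Phi`, `A_r`.
#' @export
fit_schur_dmd <- function(s, r = 2) {
  stopifnot(inherits(s, "snapshot_pair"))
  p <- nrow(s$X1); n <- ncol(s$X1)
  if (r < 1 || r > min(p, n)) abort("r must satisfy 1 <= r <= min(p, n_pairs)")
  sv <- svd(s$X1)
  if (sv$d[r] <= .Machine$double.eps * sv$d[1] * max(p, n))
    abort(sprintf("singular value %d of X1 is numerically zero; use a smaller r", r))
  U <- sv$u[, seq_len(r), drop = FALSE]
  V <- sv$v[, seq_len(r), drop = FALSE]
  d <- sv$d[seq_len(r)]
  P <- s$X2 %*% V %*% diag(1 / d, r)      # X2 V_r Sigma_r^{-1}
  At <- crossprod(U, P)                   # r x r projected operator
  sc <- if (r == 1) list(Q = matrix(1), T = At)
        else Matrix::Schur(At)            # At = Z T Z^T
  m <- structure(
    list(r = r, U_r = U, Sigma_r = d, V_r = V, A_tilde = At,
         Q = t(sc$Q), R = sc$T,
         Phi = P %*% sc$Q, A_r = NULL),
    class = "schur_dmd")
  m <- canonicalize_factors(m)
  m$A_r <- reconstruct_operator(m$Phi, m$R)
  dimnames(m$A_r) <- list(rownames(s$X1), rownames(s$X1))
  m
}

# ---- real Schur block utilities ------------------------------------------

schur_block_starts <- function(Tm, tol = 1e-12) {
  n <- nrow(Tm); starts <- integer(0); i <- 1
  while (i <= n) {
    starts <- c(starts, i)
    two <- i < n &&
      abs(Tm[i + 1, i]) > tol * (abs(Tm[i, i]) + abs(Tm[i + 1, i + 1]) + 1)
    i <- i + if (two) 2 else 1
  }
  starts
}

schur_block_modulus <- function(Tm, s, size) {
  blk <- Tm[s:(s + size - 1), s:(s + size - 1), drop = FALSE]
  max(Mod(eigen(blk, only.values = TRUE)$values))
}

# swap adjacent diagonal blocks of a real Schur form by an orthogonal
# similarity (Sylvester solve + QR), preserving A = Z T Z^T
schur_swap_adjacent <- function(Tm, Z, s, p1, p2) {
  idx <- s:(s + p1 + p2 - 1)
  A11 <- Tm[s:(s + p1 - 1), s:(s + p1 - 1), drop = FALSE]
  A22 <- Tm[(s + p1):(s + p1 + p2 - 1), (s + p1):(s + p1 + p2 - 1), drop = FALSE]
  A12 <- Tm[s:(s + p1 - 1), (s + p1):(s + p1 + p2 - 1), drop = FALSE]
  K <- kronecker(diag(p2), A11) - kronecker(t(A22), diag(p1))
  X <- matrix(solve(K, as.vector(A12)), p1, p2)
  G <- qr.Q(qr(rbind(-X, diag(p2))), complete = TRUE)
  Tm[, idx] <- Tm[, idx] %*% G
  Tm[idx, ] <- crossprod(G, Tm[idx, ])
  Z[, idx] <- Z[, idx] %*% G
  Tm[(s + p2):(s + p1 + p2 - 1), s:(s + p2 - 1)] <- 0
  list(T = Tm, Z = Z)
}

# bubble-sort diagonal blocks by descending eigenvalue modulus
schur_order_desc <- function(Tm, Z) {
  repeat {
    st <- schur_block_starts(Tm)
    sz <- diff(c(st, nrow(Tm) + 1))
    mods <- mapply(function(s, z) schur_block_modulus(Tm, s, z), st, sz)
    swapped <- FALSE
    for (b in seq_len(length(st) - 1)) {
      if (mods[b] < mods[b + 1] - 1e-12) {
        r <- schur_swap_adjacent(Tm, Z, st[b], sz[b], sz[b + 1])
        Tm <- r$T; Z <- r$Z; swapped <- TRUE
        break
      }
    }
    if (!swapped) return(list(T = Tm, Z = Z))
  }
}

# sign of the largest-magnitude element of each column (first on ties)
column_canonical_signs <- function(M) {
  apply(M, 2, function(col) {
    j <- which.max(abs(col))
    s <- sign(col[j])
    if (s == 0) 1 else s
  })
}

#' Canonicalize Schur-DMD factors for cross-genotype comparability
#'
#' The SVD and the real Schur form are unique only up to column signs and
#' block order; left uncontrolled, those indeterminacies randomise factor
#' entries across genotypes and destroy their heritability. This applies a
#' fixed convention: (i) the diagonal blocks of `R` are reordered by
#' descending eigenvalue modulus through an orthogonal similarity;
#' (ii) each Schur-vector column of `Z = Q^T` (with its mode column of
#' `Phi`) is flipped so the sum of the mode's elements is nonnegative;
#' (iii) each singular-vector pair `(u_j, v_j)` is flipped so the
#' projection of mode j onto POD direction j, `(A_tilde Z)[j, j]`, is
#' nonnegative. The sign rules are anchored in smooth aggregate
#' quantities of the stable mode directions rather than in single
#' elements or temporal coefficients, so genotypes with nearly identical
#' dynamics receive identical conventions. `A_tilde`, `Q`, `R` and `Phi`
#' are transformed consistently; the reconstructed operator `A_r` is
#' unchanged.
#'
#' @param m a `schur_dmd` model.
#' @return The model in canonical form; idempotent.
#' @export
canonicalize_factors <- function(m) {
  stopifnot(inherits(m, "schur_dmd"))
  r <- m$r
  # (i) order Schur blocks by descending eigenvalue modulus
  Z <- t(m$Q)
  o <- schur_order_desc(m$R, diag(r))   # R = G Rnew G^T with G orthogonal
  G <- o$Z
  m$R <- o$T
  Z <- Z %*% G
  m$Phi <- m$Phi %*% G
  # (ii) Schur-vector/mode signs, anchored on the modes themselves (a
  # diagonal sign similarity keeps R quasi-triangular and its diagonal
  # blocks intact)
  s_phi <- ifelse(colSums(m$Phi) < 0, -1, 1)
  if (any(s_phi < 0)) {
    S2 <- diag(s_phi, r)
    m$R <- S2 %*% m$R %*% S2
    Z <- Z %*% S2
    m$Phi <- m$Phi %*% S2
  }
  # (iii) singular-vector signs, slaved to the sign-fixed modes through
  # <u_j, phi_j>; flipping u_j (with v_j) conjugates A_tilde and flips
  # row j of Z, leaving Phi and R untouched
  s_u <- ifelse(diag(crossprod(m$U_r, m$Phi)) < 0, -1, 1)
  if (any(s_u < 0)) {
    S <- diag(s_u, r)
    m$U_r <- m$U_r %*% S
    m$V_r <- m$V_r %*% S
    m$A_tilde <- S %*% m$A_tilde %*% S
    Z <- S %*% Z
  }
  m$Q <- t(Z)
  if (!is.null(m$A_r)) m$A_r <- reconstruct_operator(m$Phi, m$R)
  m
}

#' Reconstruct the trait-space operator from modes and a reduced operator
#'
#' Returns `Phi R Phi^+`. For full-column-rank `Phi` the pseudoinverse is
#' computed from the normal equations; otherwise [pinv()] is used with a
#' warning.
#'
#' @param Phi p x r mode matrix.
#' @param R r x r reduced operator.
#' @return The p x p operator.
#' @export
reconstruct_operator <- function(Phi, R) {
  Phi <- as.matrix(Phi); R <- as.matrix(R)
  if (ncol(Phi) != nrow(R) || nrow(R) != ncol(R))
    abort("dimension mismatch between Phi and R")
  G <- crossprod(Phi)
  rk <- qr(Phi)$rank
  if (rk < ncol(Phi)) {
    warn("Phi is rank-deficient; using the pseudoinverse")
    return(Phi %*% R %*% pinv(Phi))
  }
  Phi %*% R %*% solve(G, t(Phi))
}

matrix_power <- function(A, k) {
  stopifnot(k >= 0)
  out <- diag(nrow(A))
  P <- A
  while (k > 0) {
    if (k %% 2 == 1) out <- out %*% P
    k <- k %/% 2
    if (k > 0) P <- P %*% P
  }
  out
}

#' One-step-ahead forecasts from measured states
#'
#' Predicts every timepoint after the first from the measured trait vector
#' at the preceding timepoint: `x_{t+1} = A x_t`. Across a measurement gap
#' of `g` missing days, `gap_policy = "unit_step"` applies `A` once while
#' `"power"` applies `A^(g+1)`, i.e. once per elapsed calendar day.
#'
#' @param A p x p operator.
#' @param t a [trait_tensor()].
#' @param line line identifier.
#' @param gap_policy `"unit_step"` or `"power"`.
#' @return A p x T matrix; column 1 is `NA` (no prediction), columns 2..T
#'   hold the forecasts.
#' @export
forecast_iterative <- function(A, t, line, gap_policy = c("unit_step", "power")) {
  gap_policy <- match.arg(gap_policy)
  i <- match(line, t$line_ids)
  if (is.na(i)) abort(sprintf("line '%s' not found", line))
  X <- matrix(t$values[i, , ], nrow = length(t$trait_ids))
  Tn <- length(t$time_axis)
  out <- matrix(NA_real_, nrow(X), Tn,
                dimnames = list(t$trait_ids, t$time_axis))
  for (tt in 2:Tn) {
    g <- t$time_axis[tt] - t$time_axis[tt - 1]
    Op <- if (gap_policy == "power" && g > 1) matrix_power(A, g) else A
    out[, tt] <- Op %*% X[, tt - 1]
  }
  out
}

#' Recursive forecasts from a single starting state
#'
#' Unrolls the operator from `x_start`: the first step uses the measured
#' state, every later step feeds the previous prediction back in. Step
#' `i` spans `day_gaps[i]` calendar days; `gap_policy = "unit_step"`
#' applies `A` once per step regardless, `"power"` applies `A^day_gaps[i]`.
#'
#' @param A p x p operator.
#' @param x_start measured trait vector at the starting timepoint.
#' @param steps number of forecast steps (>= 1).
#' @param gap_policy `"unit_step"` or `"power"`.
#' @param day_gaps integer vector of calendar-day spans per step; defaults
#'   to all ones.
#' @return A p x steps matrix of predictions.
#' @export
forecast_recursive <- function(A, x_start, steps,
                               gap_policy = c("unit_step", "power"),
                               day_gaps = rep(1L, steps)) {
  gap_policy <- match.arg(gap_policy)
  if (steps < 1) abort("steps must be >= 1")
  if (length(day_gaps) != steps) abort("day_gaps must have one entry per step")
  x <- as.numeric(x_start)
  out <- matrix(NA_real_, length(x), steps)
  for (i in seq_len(steps)) {
    Op <- if (gap_policy == "power" && day_gaps[i] > 1)
      matrix_power(A, day_gaps[i]) else A
    x <- as.numeric(Op %*% x)
    if (!all(is.finite(x))) {
      abort(sprintf("forecast diverged to non-finite values at step %d", i))
    }
    out[, i] <- x
  }
  rownames(out) <- rownames(A)
  out
}

#' @export
print.schur_dmd <- function(x, ...) {
  ev <- eigen(x$A_tilde, only.values = TRUE)$values
  cat(sprintf("<schur_dmd> p = %d, r = %d; |eigenvalues| = %s\n",
              nrow(x$U_r), x$r,
              paste(sprintf("%.3f", Mod(ev)), collapse = ", ")))
  invisible(x)
}

#' Mode-level summary of a Schur-DMD model
#'
#' @param x a `schur_dmd` model.
#' @param ... unused.
#' @return A tibble with one row per reduced dimension: the singular value
#'   of `X1` and the modulus of the matching operator eigenvalue.
#' @method tidy schur_dmd
#' @export
tidy.schur_dmd <- function(x, ...) {
  ev <- eigen(x$A_tilde, only.values = TRUE)$values
  ev <- ev[order(-Mod(ev))]
  tibble(mode = seq_len(x$r),
         singular_value = x$Sigma_r,
         eigenvalue_modulus = Mod(ev))
}

#' Serialize a Schur-DMD model to a JSON file
#'
#' All factors are written at full double precision so a round trip
#' reproduces the model exactly.
#'
#' @param m a `schur_dmd` model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_schur_model <- function(m, path) {
  stopifnot(inherits(m, "schur_dmd"))
  payload <- list(
    r = m$r, U_r = m$U_r, Sigma_r = m$Sigma_r, V_r = m$V_r,
    A_tilde = m$A_tilde, Q = m$Q, R = m$R, Phi = m$Phi, A_r = m$A_r)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a Schur-DMD model written by [write_schur_model()]
#'
#' @param path input file.
#' @return A `schur_dmd` model.
#' @export
read_schur_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- list(
    r = as.integer(x$r), U_r = as.matrix(x$U_r), Sigma_r = as.numeric(x$Sigma_r),
    V_r = as.matrix(x$V_r), A_tilde = as.matrix(x$A_tilde),
    Q = as.matrix(x$Q), R = as.matrix(x$R), Phi = as.matrix(x$Phi),
    A_r = as.matrix(x$A_r))
  class(m) <- "schur_dmd"
  m
}
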