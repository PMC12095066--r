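# Restricted log-likelihood of y* = mu x* + e, var(e_i) = sigma2_p * lam_i,
# with sigma2_p profiled out. y*, x* live in the eigenbasis of the
# covariance structure, so everything is O(k) per evaluation.
reml_profile_loglik <- function(lam, ystar, xstar) {
  n <- length(ystar)
  w <- 1 / lam
  xx <- sum(xstar^2 * w)
  mu <- sum(xstar * ystar * w) / xx
  r <- ystar - mu * xstar
  S <- sum(r^2 * w)
  s2 <- S / (n - 1)
  list(loglik = -0.5 * ((n - 1) * log(s2) + sum(log(lam)) + log(xx) + (n - 1)),
       mu = mu, sigma2_p = s2)
}

#' Single-component REML heritability (GREML)
#'
#' Fits `y = mu 1 + g + e` with `g ~ N(0, sigma2_g K)` and
#' `e ~ N(0, sigma2_e I)` by restricted maximum likelihood. The GRM is
#' eigendecomposed once and the restricted likelihood is maximised over
#' `h2 = sigma2_g / (sigma2_g + sigma2_e)` on `[0, 1]` by Brent-type
#' bounded search (tolerance 1e-8); boundary optima are reported with a
#' flag. Estimates are clipped to `[1e-6, 1 - 1e-6]` unless the boundary
#' is the optimum.
#'
#' @param y phenotype vector, one value per line.
#' @param K a `grm` from [compute_grm()], or a symmetric PSD matrix.
#' @return A tibble with one row: `sigma2_g`, `sigma2_e`, `h2`, `loglik`,
#'   `boundary`.
#' @export
reml_single_component <- function(y, K) {
  Km <- if (inherits(K, "grm")) K$K else as.matrix(K)
  y <- as.numeric(y)
  if (length(y) != nrow(Km)) abort("length of y must match the GRM")
  if (!all(is.finite(y))) abort("y contains non-finite values")
  if (var(y) == 0) abort("y is constant; heritability undefined")
  ed <- eigen(Km, symmetric = TRUE)
  if (min(ed$values) < -1e-8 * max(abs(ed$values), 1))
    abort("K is not positive semidefinite")
  reml_h2_spectral(y, ed)
}

# shared worker: eigen(K) is reusable across many phenotypes
reml_h2_spectral <- function(y, ed, tol = 1e-8) {
  d <- pmax(ed$values, 0)
  ystar <- as.numeric(crossprod(ed$vectors, y))
  xstar <- as.numeric(crossprod(ed$vectors, rep(1, length(y))))
  obj <- function(h2) {
    reml_profile_loglik(h2 * d + (1 - h2), ystar, xstar)$loglik
  }
  opt <- optimize(obj, c(0, 1), maximum = TRUE, tol = tol)
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, obj(0), obj(1))
  h2 <- cand[which.max(ll)]
  boundary <- h2 %in% c(0, 1)
  if (!boundary) h2 <- min(max(h2, 1e-6), 1 - 1e-6)
  fit <- reml_profile_loglik(h2 * d + (1 - h2), ystar, xstar)
  tibble(sigma2_g = h2 * fit$sigma2_p,
         sigma2_e = (1 - h2) * fit$sigma2_p,
         h2 = h2,
         loglik = max(ll),
         boundary = boundary)
}
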