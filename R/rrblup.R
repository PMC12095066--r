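#' Ridge-regression BLUP of marker effects
#'
#' Fits `y = mu 1 + M beta + e` with i.i.d. normal marker effects
#' (`beta ~ N(0, sigma2_u I)`), equivalent to ridge regression with
#' penalty `lambda = sigma2_e / sigma2_u`. The variance ratio is estimated
#' by REML through the spectral decomposition of the marker kernel
#' `M M^T`, maximising over `log(lambda)` on `[-10, 10]`; a fixed
#' `lambda` can be supplied instead. Markers are centred internally (not
#' scaled) and the centring is stored for prediction.
#'
#' @param y response vector (one value per line).
#' @param M n x m dosage matrix (uncentered is fine).
#' @param lambda optional fixed ridge ratio; `NULL` estimates it by REML.
#' @return An object of class `rrblup_fit` with fields `mu`, `beta`,
#'   `lambda`, `sigma2_u`, `sigma2_e`, `marker_centering`, `loglik`.
#' @export
fit_rrblup <- function(y, M, lambda = NULL) {
  y <- as.numeric(y)
  M <- as.matrix(M)
  if (length(y) != nrow(M)) abort("length of y must match rows of M")
  if (!all(is.finite(y)) || !all(is.finite(M))) abort("non-finite inputs")
  if (nrow(M) < 3) abort("need at least 3 observations")
  if (var(y) == 0) abort("y is constant; marker variance undefined")
  centering <- colMeans(M)
  Mc <- sweep(M, 2, centering)
  ed <- eigen(tcrossprod(Mc), symmetric = TRUE)
  fit <- rrblup_spectral(y, ed, Mc, lambda)
  fit$marker_centering <- centering
  fit$marker_ids <- colnames(M)
  fit
}

# worker reusing a precomputed eigen decomposition of tcrossprod(Mc);
# this is what makes per-entry CV over many responses cheap
rrblup_spectral <- function(y, ed, Mc, lambda = NULL, tol = 1e-8) {
  d <- pmax(ed$values, 0)
  U <- ed$vectors
  ystar <- as.numeric(crossprod(U, y))
  xstar <- as.numeric(crossprod(U, rep(1, length(y))))
  obj <- function(loglam) {
    reml_profile_loglik(d + exp(loglam), ystar, xstar)$loglik
  }
  if (is.null(lambda)) {
    opt <- optimize(obj, c(-10, 10), maximum = TRUE, tol = tol)
    lambda <- exp(opt$maximum)
    loglik <- opt$objective
  } else {
    loglik <- obj(log(lambda))
  }
  prof <- reml_profile_loglik(d + lambda, ystar, xstar)
  # alpha = (M M^T + lambda I)^{-1} (y - mu 1); beta = M^T alpha
  resid_star <- ystar - prof$mu * xstar
  alpha <- U %*% (resid_star / (d + lambda))
  beta <- as.numeric(crossprod(Mc, alpha))
  structure(
    list(mu = prof$mu, beta = beta, lambda = lambda,
         sigma2_u = prof$sigma2_p, sigma2_e = prof$sigma2_p * lambda,
         loglik = loglik, marker_centering = NULL, marker_ids = NULL),
    class = "rrblup_fit")
}

#' @export
print.rrblup_fit <- function(x, ...) {
  cat(sprintf("<rrblup_fit> %d markers; lambda = %.4g, h2(equiv) = %.3f\n",
              length(x$beta), x$lambda, 1 / (1 + x$lambda / length(x$beta))))
  invisible(x)
}

#' One-row model summary of an RR-BLUP fit
#'
#' @param x an `rrblup_fit`.
#' @param ... unused.
#' @return A tibble with `mu`, `lambda`, `sigma2_u`, `sigma2_e`, `loglik`,
#'   `n_markers`.
#' @method glance rrblup_fit
#' @export
glance.rrblup_fit <- function(x, ...) {
  tibble(mu = x$mu, lambda = x$lambda, sigma2_u = x$sigma2_u,
         sigma2_e = x$sigma2_e, loglik = x$loglik,
         n_markers = length(x$beta))
}

#' Marker-effect table of an RR-BLUP fit
#'
#' @param x an `rrblup_fit`.
#' @param ... unused.
#' @return A tibble with `marker` and `effect`.
#' @method tidy rrblup_fit
#' @export
tidy.rrblup_fit <- function(x, ...) {
  tibble(marker = x$marker_ids %||% paste0("m", seq_along(x$beta)),
         effect = x$beta)
}

#' Predict phenotypes for new lines from an RR-BLUP fit
#'
#' @param fit an `rrblup_fit` (from [fit_rrblup()], so that the training
#'   marker centring is stored).
#' @param M_new n' x m dosage matrix over the same markers, in the same
#'   order.
#' @return Numeric vector of predictions `mu + (M_new - centring) beta`.
#' @export
predict_rrblup <- function(fit, M_new) {
  stopifnot(inherits(fit, "rrblup_fit"))
  M_new <- as.matrix(M_new)
  if (ncol(M_new) != length(fit$beta))
    abort("marker set of M_new does not match the fit")
  if (!is.null(fit$marker_ids) && !is.null(colnames(M_new)) &&
      !identical(colnames(M_new), fit$marker_ids))
    abort("marker ids/order of M_new do not match the fit")
  Mc <- sweep(M_new, 2, fit$marker_centering)
  as.numeric(fit$mu + Mc %*% fit$beta)
}
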