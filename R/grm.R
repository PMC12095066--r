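#' VanRaden genomic relationship matrix
#'
#' Centres each marker by twice its allele frequency and scales the
#' cross-product by `2 * sum(p_j (1 - p_j))` (VanRaden method 1), the
#' centred analogue of the kinship produced by common GP toolchains.
#'
#' @param G a [genotype_matrix()].
#' @param method only `"centered"` is implemented.
#' @return An object of class `grm` with fields `line_ids` and `K`
#'   (k x k symmetric matrix, diagonal averaging about 1).
#' @export
compute_grm <- function(G, method = c("centered")) {
  method <- match.arg(method)
  stopifnot(inherits(G, "genotype_matrix"))
  p <- colMeans(G$dosages) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) abort("all markers are monomorphic; GRM undefined")
  W <- sweep(G$dosages[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  K <- tcrossprod(W) / denom
  K <- (K + t(K)) / 2
  dimnames(K) <- list(G$line_ids, G$line_ids)
  structure(list(line_ids = G$line_ids, K = K), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d lines; mean diagonal %.3f\n",
              length(x$line_ids), mean(diag(x$K))))
  invisible(x)
}

#' Write a GRM as a square CSV with line ids
#'
#' @param x a `grm`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grm <- function(x, path) {
  stopifnot(inherits(x, "grm"))
  df <- as.data.frame(x$K)
  df <- cbind(line = x$line_ids, df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a GRM written by [write_grm()]
#'
#' @param path input file.
#' @param tol maximum allowed asymmetry.
#' @return A `grm`.
#' @export
read_grm <- function(path, tol = 1e-8) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(df[[1]])
  K <- as.matrix(df[, -1, drop = FALSE])
  dimnames(K) <- list(ids, ids)
  if (max(abs(K - t(K))) > tol) abort("GRM on disk is not symmetric")
  K <- (K + t(K)) / 2
  structure(list(line_ids = ids, K = K), class = "grm")
}
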