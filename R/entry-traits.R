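#' Collect factor-matrix entries across lines as quantitative traits
#'
#' Given canonical Schur-DMD models for a set of lines that share the same
#' trait panel and rank, builds a lines x entries table in which every
#' selected matrix entry (e.g. `Phi[3,1]`, `R[1,2]`) is one column. These
#' entry traits are the response variables of the genomic prediction step;
#' the default selection `{Phi, R}` is exactly what the operator
#' reconstruction `A = Phi R Phi^+` needs, while the full selection adds
#' the remaining factors for heritability screens.
#'
#' @param models named list (by line id) of `schur_dmd` models.
#' @param which subset of `c("Phi", "R", "U", "Sigma", "V", "A_tilde",
#'   "Q")`.
#' @return An object of class `entry_trait_table` with fields `line_ids`,
#'   `entry_info` (tibble: `label`, `matrix`, `row`, `col`) and `values`
#'   (k x q matrix with labelled columns).
#' @export
extract_entry_traits <- function(models, which = c("Phi", "R")) {
  allowed <- c("Phi", "R", "U", "Sigma", "V", "A_tilde", "Q")
  if (!all(which %in% allowed))
    abort(sprintf("unknown matrix selection; use %s", paste(allowed, collapse = ", ")))
  stopifnot(length(models) >= 1, all(vapply(models, inherits, TRUE, "schur_dmd")))
  rs <- vapply(models, function(m) m$r, numeric(1))
  if (length(unique(rs)) != 1) abort("models have mixed ranks")
  field_of <- c(Phi = "Phi", R = "R", U = "U_r", Sigma = "Sigma_r",
                V = "V_r", A_tilde = "A_tilde", Q = "Q")
  info <- purrr::map_dfr(which, function(w) {
    x <- models[[1]][[field_of[[w]]]]
    if (is.matrix(x)) {
      idx <- expand.grid(row = seq_len(nrow(x)), col = seq_len(ncol(x)))
      tibble(label = sprintf("%s[%d,%d]", w, idx$row, idx$col),
             matrix = w, row = idx$row, col = idx$col)
    } else {
      tibble(label = sprintf("%s[%d]", w, seq_along(x)),
             matrix = w, row = seq_along(x), col = NA_integer_)
    }
  })
  vals <- t(vapply(models, function(m) {
    unlist(lapply(which, function(w) as.numeric(m[[field_of[[w]]]])))
  }, numeric(nrow(info))))
  dimnames(vals) <- list(names(models), info$label)
  cv <- apply(vals, 2, var)
  if (any(cv == 0))
    inform(sprintf("%d entry column(s) are constant across lines", sum(cv == 0)))
  structure(
    list(line_ids = names(models), entry_info = info, values = vals),
    class = "entry_trait_table")
}

#' @export
print.entry_trait_table <- function(x, ...) {
  cat(sprintf("<entry_trait_table> %d lines x %d entries (%s)\n",
              length(x$line_ids), nrow(x$entry_info),
              paste(unique(x$entry_info$matrix), collapse = ", ")))
  invisible(x)
}

#' @method as_tibble entry_trait_table
#' @export
as_tibble.entry_trait_table <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$values))
  dplyr::bind_cols(tibble(line = x$line_ids), out)
}

#' SNP heritability of every factor-matrix entry
#'
#' Runs single-GRM REML per entry column, reusing one eigendecomposition
#' of the GRM. Constant columns are reported with `NA`.
#'
#' @param table an [extract_entry_traits()] result.
#' @param K a `grm` over the same lines, in the same order.
#' @return A tibble with columns `label`, `matrix`, `row`, `col`, `h2`,
#'   `boundary`.
#' @export
assess_entry_heritability <- function(table, K) {
  stopifnot(inherits(table, "entry_trait_table"), inherits(K, "grm"))
  if (!identical(table$line_ids, K$line_ids))
    abort("lines of the entry table and GRM must match")
  ed <- eigen(K$K, symmetric = TRUE)
  res <- purrr::map_dfr(seq_len(ncol(table$values)), function(q) {
    y <- table$values[, q]
    if (var(y) == 0) return(tibble(h2 = NA_real_, boundary = NA))
    fit <- reml_h2_spectral(y, ed)
    tibble(h2 = fit$h2, boundary = fit$boundary)
  })
  dplyr::bind_cols(table$entry_info, res)
}

#' Cross-validated genomic predictability of factor-matrix entries
#'
#' For every entry column, RR-BLUP models are trained on the training
#' folds and correlated with the held-out truth; the per-entry accuracy is
#' the mean Pearson correlation over all iteration x fold test sets. The
#' marker kernel of each training fold is eigendecomposed once and shared
#' across entries.
#'
#' @param table an [extract_entry_traits()] result.
#' @param G a [genotype_matrix()] over the same lines.
#' @param plan a [cv_plan()] with `validation_fraction = 0`.
#' @return A tibble with columns `label`, `matrix`, `row`, `col`,
#'   `accuracy`, `accuracy_sd`, `n_folds`.
#' @export
cross_validate_entry_prediction <- function(table, G, plan) {
  stopifnot(inherits(table, "entry_trait_table"),
            inherits(G, "genotype_matrix"), inherits(plan, "cv_plan"))
  if (plan$validation_fraction != 0)
    abort("entry CV expects a plain k-fold plan (validation_fraction = 0)")
  if (!identical(table$line_ids, plan$line_ids) ||
      !identical(table$line_ids, G$line_ids))
    abort("lines of the entry table, genotypes and plan must match")
  q <- ncol(table$values)
  cors <- vector("list", plan$n_iterations * plan$n_folds)
  slot <- 1
  for (it in seq_len(plan$n_iterations)) {
    fold_of <- plan$assignments[, it]
    for (f in seq_len(plan$n_folds)) {
      tr <- which(fold_of != f & fold_of > 0)
      te <- which(fold_of == f)
      M <- G$dosages[tr, , drop = FALSE]
      centering <- colMeans(M)
      Mc <- sweep(M, 2, centering)
      Mc_te <- sweep(G$dosages[te, , drop = FALSE], 2, centering)
      ed <- eigen(tcrossprod(Mc), symmetric = TRUE)
      r_f <- rep(NA_real_, q)
      for (j in seq_len(q)) {
        ytr <- table$values[tr, j]
        if (var(ytr) == 0) next  # constant training fold: skipped
        fit <- rrblup_spectral(ytr, ed, Mc)
        pred <- fit$mu + as.numeric(Mc_te %*% fit$beta)
        ytruth <- table$values[te, j]
        if (sd(ytruth) > 0 && sd(pred) > 0) r_f[j] <- cor(ytruth, pred)
      }
      cors[[slot]] <- r_f
      slot <- slot + 1
    }
  }
  cm <- do.call(rbind, cors)
  dplyr::bind_cols(
    table$entry_info,
    tibble(accuracy = colMeans(cm, na.rm = TRUE),
           accuracy_sd = apply(cm, 2, sd, na.rm = TRUE),
           n_folds = colSums(!is.na(cm))))
}
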