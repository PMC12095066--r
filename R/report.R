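#' Write a prediction result to a report directory
#'
#' Emits `accuracy.csv` and `mse.csv` (one row per trait, one column per
#' timepoint), `per_fold.csv` (long per-fold records) and `metadata.txt`
#' (key = value lines: mode, scenario, rank, seed and CV plan when
#' given). Values are written with shortest round-tripping formatting, so
#' reading the tables back reproduces them exactly.
#'
#' @param result a `prediction_result`.
#' @param path output directory (created if needed).
#' @param plan optional [cv_plan()] recorded in the metadata.
#' @param r optional rank recorded in the metadata.
#' @return `path`, invisibly.
#' @export
write_prediction_report <- function(result, path, plan = NULL, r = NULL) {
  stopifnot(inherits(result, "prediction_result"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) abort(sprintf("cannot create directory '%s'", path))
  mat_to_df <- function(M) {
    # 17 significant digits: doubles survive the text round trip exactly
    df <- as.data.frame(M, check.names = FALSE)
    df[] <- lapply(df, function(x)
      ifelse(is.na(x), NA_character_, sprintf("%.17g", x)))
    cbind(data.frame(trait = rownames(M)), df)
  }
  readr::write_csv(mat_to_df(result$accuracy), file.path(path, "accuracy.csv"))
  readr::write_csv(mat_to_df(result$mse), file.path(path, "mse.csv"))
  readr::write_csv(result$per_fold, file.path(path, "per_fold.csv"))
  meta <- c(
    sprintf("mode = %s", result$mode),
    sprintf("scenario = %s", result$scenario),
    if (!is.null(r)) sprintf("rank = %d", r),
    if (!is.null(plan)) c(
      sprintf("seed = %d", plan$seed),
      sprintf("n_iterations = %d", plan$n_iterations),
      sprintf("n_folds = %d", plan$n_folds),
      sprintf("validation_fraction = %g", plan$validation_fraction)))
  writeLines(meta, file.path(path, "metadata.txt"))
  invisible(path)
}

#' Read back a report written by [write_prediction_report()]
#'
#' @param path report directory.
#' @return A list with `accuracy` and `mse` matrices, the `per_fold`
#'   tibble and a named `metadata` character vector.
#' @export
read_prediction_report <- function(path) {
  read_mat <- function(f) {
    # parse as text and convert through strtod for correctly rounded doubles
    d <- readr::read_csv(file.path(path, f), show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = "c"))
    M <- apply(as.matrix(d[, -1, drop = FALSE]), 2, as.numeric)
    rownames(M) <- d[[1]]
    M
  }
  meta_lines <- readLines(file.path(path, "metadata.txt"))
  kv <- strsplit(meta_lines, " = ", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  list(accuracy = read_mat("accuracy.csv"), mse = read_mat("mse.csv"),
       per_fold = readr::read_csv(file.path(path, "per_fold.csv"),
                                  show_col_types = FALSE, progress = FALSE),
       metadata = meta)
}

#' Write a trait tensor as a long CSV
#'
#' @param t a [trait_tensor()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trait_tensor <- function(t, path) {
  readr::write_csv(as_tibble(t), path)
  invisible(path)
}

#' Write a genotype matrix as a dosage table
#'
#' @param G a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(G, path) {
  df <- cbind(data.frame(line = G$line_ids),
              as.data.frame(G$dosages, check.names = FALSE))
  readr::write_csv(df, path)
  invisible(path)
}

#' Heritability screen plot for factor-matrix entries
#'
#' @param h2_table output of [assess_entry_heritability()].
#' @return A ggplot: per-matrix distribution of entry heritabilities.
#' @export
plot_entry_heritability <- function(h2_table) {
  d <- dplyr::filter(h2_table, is.finite(.data$h2))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$matrix, y = .data$h2)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = expression(h^2),
                  title = "SNP heritability of operator building blocks") +
    ggplot2::theme_minimal()
}

#' @method autoplot h2_consistency
#' @export
autoplot.h2_consistency <- function(object, ...) {
  ggplot2::ggplot(object$per_trait,
                  ggplot2::aes(x = .data$cv_h2, y = .data$mean_accuracy)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "CV of heritability across time",
                  y = "mean forecast accuracy",
                  subtitle = sprintf("Pearson r = %.2f (p = %.2g)",
                                     object$estimate, object$p_value)) +
    ggplot2::theme_minimal()
}
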