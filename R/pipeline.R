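#' Reproducible cross-validation plan over lines
#'
#' Draws fold assignments for every iteration from a seed, optionally
#' holding out a fixed validation slice of lines that takes part in
#' neither training nor testing (it is reserved for pre-training screens
#' such as rank selection). Identical seeds give identical assignments.
#'
#' @param line_ids character vector of lines.
#' @param n_iterations number of CV repetitions.
#' @param n_folds folds per iteration.
#' @param seed RNG seed for the assignments.
#' @param validation_fraction fraction of lines (drawn once) set aside as
#'   the validation slice; 0 gives a plain repeated k-fold plan.
#' @return An object of class `cv_plan`; `assignments` is a k x
#'   n_iterations integer matrix with fold ids and 0 marking validation
#'   lines.
#' @export
cv_plan <- function(line_ids, n_iterations = 20, n_folds = 5, seed = 1,
                    validation_fraction = 0) {
  k <- length(line_ids)
  if (n_folds < 2 || k < n_folds) abort("need at least n_folds lines")
  set.seed(seed)
  val <- integer(0)
  if (validation_fraction > 0) {
    n_val <- round(validation_fraction * k)
    val <- sort(sample.int(k, n_val))
  }
  avail <- setdiff(seq_len(k), val)
  assignments <- matrix(0L, k, n_iterations,
                        dimnames = list(line_ids, NULL))
  for (it in seq_len(n_iterations)) {
    shuffled <- sample(avail)
    folds <- rep_len(seq_len(n_folds), length(avail))
    assignments[shuffled, it] <- folds
  }
  structure(
    list(line_ids = line_ids, n_iterations = n_iterations,
         n_folds = n_folds, seed = seed,
         validation_fraction = validation_fraction,
         validation_lines = line_ids[val], assignments = assignments),
    class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %d iterations x %d folds over %d lines (seed %d%s)\n",
              x$n_iterations, x$n_folds, length(x$line_ids), x$seed,
              if (length(x$validation_lines))
                sprintf(", %d validation lines", length(x$validation_lines))
              else ""))
  invisible(x)
}

# fit canonical Schur-DMD models for a set of lines, dropping failures
fit_line_models <- function(t, lines, r) {
  models <- list()
  dropped <- character(0)
  for (ln in lines) {
    m <- tryCatch(
      fit_schur_dmd(build_snapshot_pair(t, ln), r = r),
      error = function(e) NULL)
    if (is.null(m)) dropped <- c(dropped, ln) else models[[ln]] <- m
  }
  if (length(dropped)) {
    inform(sprintf("dropped %d line(s) with unidentifiable dynamics: %s",
                   length(dropped), paste(head(dropped, 5), collapse = ", ")))
    if (length(dropped) > 0.2 * length(lines))
      abort("more than 20% of lines have unidentifiable dynamics")
  }
  models
}

#' Choose the number of retained singular vectors by a heritability and
#' predictability screen
#'
#' For each candidate rank, Schur-DMD factors are fitted on the
#' training-testing lines (the plan's validation slice is excluded), the
#' heritability of every factor entry is estimated, and the genomic
#' predictability of the reduced-operator entries is cross-validated. The
#' chosen rank is the largest candidate whose mean reduced-operator entry
#' predictability exceeds `floor`; when none qualifies the smallest
#' candidate is returned with a no-signal flag.
#'
#' @param t a [trait_tensor()].
#' @param G a [genotype_matrix()] over the same lines.
#' @param candidates candidate ranks, conventionally `2:6`.
#' @param plan a [cv_plan()]; its validation slice is excluded from the
#'   screen.
#' @param floor minimum mean predictability of reduced-operator entries
#'   (default 0.1).
#' @return An object of class `rank_selection` with fields `chosen`,
#'   `no_signal` and `report` (tibble: `r`, `matrix`, `mean_h2`,
#'   `mean_accuracy`).
#' @export
select_rank <- function(t, G, candidates = 2:6, plan, floor = 0.1) {
  stopifnot(inherits(t, "trait_tensor"), inherits(G, "genotype_matrix"))
  if (any(candidates < 2)) abort("candidate ranks must be >= 2")
  tt_lines <- setdiff(t$line_ids, plan$validation_lines)
  Gtt <- genotype_matrix(G$dosages[tt_lines, , drop = FALSE])
  K <- compute_grm(Gtt)
  sub_plan <- cv_plan(tt_lines, plan$n_iterations, plan$n_folds,
                      seed = plan$seed, validation_fraction = 0)
  report <- list()
  mean_acc_atilde <- rep(NA_real_, length(candidates))
  t_tt <- trait_tensor(t$values[tt_lines, , , drop = FALSE], tt_lines,
                       t$trait_ids, t$time_axis, t$blocks)
  for (ci in seq_along(candidates)) {
    r <- candidates[ci]
    # a candidate whose r-th singular value vanishes is infeasible and
    # simply drops out of the screen
    res_r <- tryCatch({
      models <- fit_line_models(t_tt, tt_lines, r)
      tab_all <- extract_entry_traits(
        models, which = c("Phi", "R", "U", "Sigma", "V", "A_tilde", "Q"))
      h2 <- assess_entry_heritability(tab_all, K)
      tab_at <- extract_entry_traits(models, which = "A_tilde")
      acc <- cross_validate_entry_prediction(tab_at, Gtt, sub_plan)
      list(h2 = h2, macc = mean(acc$accuracy, na.rm = TRUE))
    }, error = function(e) NULL)
    if (is.null(res_r)) {
      inform(sprintf("rank %d is infeasible on these data; skipped", r))
      next
    }
    mean_acc_atilde[ci] <- res_r$macc
    report[[ci]] <- res_r$h2 |>
      dplyr::group_by(.data$matrix) |>
      dplyr::summarise(mean_h2 = mean(.data$h2, na.rm = TRUE)) |>
      dplyr::mutate(r = r,
                    mean_accuracy = ifelse(.data$matrix == "A_tilde",
                                           res_r$macc, NA_real_))
  }
  feasible <- which(is.finite(mean_acc_atilde))
  if (!length(feasible)) abort("no candidate rank is feasible on these data")
  ok <- feasible[mean_acc_atilde[feasible] > floor]
  no_signal <- length(ok) == 0
  chosen <- if (no_signal) min(candidates[feasible]) else max(candidates[ok])
  if (no_signal)
    inform("no candidate rank shows predictable reduced-operator entries; falling back to the smallest")
  structure(
    list(chosen = chosen, no_signal = no_signal, floor = floor,
         report = dplyr::bind_rows(report) |>
           dplyr::select("r", "matrix", "mean_h2", "mean_accuracy")),
    class = "rank_selection")
}

#' @export
print.rank_selection <- function(x, ...) {
  cat(sprintf("<rank_selection> chosen r = %d%s\n", x$chosen,
              if (x$no_signal) " (no-signal fallback)" else ""))
  invisible(x)
}

# fit one genomic model per entry column; constant columns get a
# constant-value model so predicted factors stay well formed
fit_entry_models <- function(values, M) {
  centering <- colMeans(M)
  Mc <- sweep(M, 2, centering)
  ed <- eigen(tcrossprod(Mc), symmetric = TRUE)
  fits <- lapply(seq_len(ncol(values)), function(j) {
    y <- values[, j]
    if (var(y) == 0) {
      list(type = "constant", value = y[1])
    } else {
      f <- rrblup_spectral(y, ed, Mc)
      list(type = "rrblup", mu = f$mu, beta = f$beta, lambda = f$lambda)
    }
  })
  names(fits) <- colnames(values)
  list(fits = fits, centering = centering)
}

predict_entries <- function(entry_models, M_new) {
  Mc <- sweep(M_new, 2, entry_models$centering)
  out <- lapply(entry_models$fits, function(f) {
    if (f$type == "constant") rep(f$value, nrow(Mc))
    else f$mu + as.numeric(Mc %*% f$beta)
  })
  matrix(unlist(out), nrow = nrow(M_new),
         dimnames = list(NULL, names(entry_models$fits)))
}

#' Train genomic models for the operator building blocks
#'
#' Fits a canonical Schur-DMD model per line, extracts the `Phi` and `R`
#' entries and trains one RR-BLUP model per entry. The returned bundle is
#' all that is needed to predict the dynamics operator of an unseen
#' genotype.
#'
#' @param t a [trait_tensor()] (on the modelling scale).
#' @param G a [genotype_matrix()]; lines are intersected with the tensor.
#' @param r retained rank (see [select_rank()]).
#' @return An object of class `dynamicgp_bundle`.
#' @export
train_dynamicgp <- function(t, G, r = 2) {
  stopifnot(inherits(t, "trait_tensor"), inherits(G, "genotype_matrix"))
  lines <- intersect(t$line_ids, G$line_ids)
  if (length(setdiff(t$line_ids, lines)) || length(setdiff(G$line_ids, lines)))
    inform(sprintf("using the %d lines common to phenotypes and genotypes",
                   length(lines)))
  models <- fit_line_models(t, lines, r)
  table <- extract_entry_traits(models, which = c("Phi", "R"))
  em <- fit_entry_models(table$values, G$dosages[names(models), , drop = FALSE])
  structure(
    list(r = r, p = length(t$trait_ids), trait_ids = t$trait_ids,
         marker_ids = G$marker_ids, entry_info = table$entry_info,
         entry_models = em, n_lines = length(models)),
    class = "dynamicgp_bundle")
}

#' @export
print.dynamicgp_bundle <- function(x, ...) {
  cat(sprintf("<dynamicgp_bundle> p = %d traits, r = %d; %d entry models over %d markers (%d training lines)\n",
              x$p, x$r, nrow(x$entry_info), length(x$marker_ids), x$n_lines))
  invisible(x)
}

#' Predict the dynamics operator of an unseen line from its markers
#'
#' Every `Phi` and `R` entry is predicted by its genomic model, the
#' predictions are placed back at their matrix positions, and the
#' trait-space operator is reconstructed as
#' `A_P = Phi_P R_P Phi_P^+`.
#'
#' @param bundle a [train_dynamicgp()] result.
#' @param g_new dosage vector (length m) or 1 x m matrix for the new
#'   line, over the bundle's marker set.
#' @return An object of class `predicted_operator` with fields `Phi_P`,
#'   `R_P`, `A_P`.
#' @export
predict_operator_for_line <- function(bundle, g_new) {
  stopifnot(inherits(bundle, "dynamicgp_bundle"))
  M <- matrix(as.numeric(g_new), nrow = 1)
  if (ncol(M) != length(bundle$marker_ids))
    abort("marker set of the new line does not match the bundle")
  ent <- predict_entries(bundle$entry_models, M)[1, ]
  Phi_P <- matrix(0, bundle$p, bundle$r)
  R_P <- matrix(0, bundle$r, bundle$r)
  info <- bundle$entry_info
  for (q in seq_len(nrow(info))) {
    if (info$matrix[q] == "Phi") Phi_P[info$row[q], info$col[q]] <- ent[q]
    else R_P[info$row[q], info$col[q]] <- ent[q]
  }
  A_P <- reconstruct_operator(Phi_P, R_P)
  structure(list(Phi_P = Phi_P, R_P = R_P, A_P = A_P),
            class = "predicted_operator")
}

# --- prediction results ----------------------------------------------------

new_prediction_result <- function(per_fold, trait_ids, time_axis, mode,
                                  scenario) {
  summ <- per_fold |>
    dplyr::group_by(.data$trait, .data$day) |>
    dplyr::summarise(
      acc = mean(.data$accuracy[is.finite(.data$accuracy)]),
      acc_sd = sd(.data$accuracy[is.finite(.data$accuracy)]),
      mse_m = mean(.data$mse[is.finite(.data$mse)]),
      .groups = "drop")
  shape <- function(col) {
    M <- matrix(NA_real_, length(trait_ids), length(time_axis),
                dimnames = list(trait_ids, time_axis))
    M[cbind(match(summ$trait, trait_ids), match(summ$day, time_axis))] <-
      summ[[col]]
    M
  }
  structure(
    list(accuracy = shape("acc"), accuracy_sd = shape("acc_sd"),
         mse = shape("mse_m"), mode = mode, scenario = scenario,
         per_fold = per_fold),
    class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s / %s: mean accuracy %.3f over %d traits x %d timepoints\n",
              x$mode, x$scenario, mean(x$accuracy, na.rm = TRUE),
              nrow(x$accuracy), sum(colSums(!is.na(x$accuracy)) > 0)))
  invisible(x)
}

#' Long-format accuracy and error surfaces
#'
#' @param x a `prediction_result`.
#' @param ... unused.
#' @return A tibble with columns `trait`, `day`, `accuracy`,
#'   `accuracy_sd`, `mse`.
#' @method tidy prediction_result
#' @export
tidy.prediction_result <- function(x, ...) {
  traits <- rownames(x$accuracy)
  days <- as.integer(colnames(x$accuracy))
  tibble(trait = rep(traits, times = length(days)),
         day = rep(days, each = length(traits)),
         accuracy = as.vector(x$accuracy),
         accuracy_sd = as.vector(x$accuracy_sd),
         mse = as.vector(x$mse))
}

#' One-row summary of a prediction result
#'
#' @param x a `prediction_result`.
#' @param ... unused.
#' @return A tibble with the mode, scenario, mean/min/max accuracy and
#'   mean MSE over all evaluated trait-timepoint cells.
#' @method glance prediction_result
#' @export
glance.prediction_result <- function(x, ...) {
  tibble(mode = x$mode, scenario = x$scenario,
         mean_accuracy = mean(x$accuracy, na.rm = TRUE),
         min_accuracy = min(x$accuracy, na.rm = TRUE),
         max_accuracy = max(x$accuracy, na.rm = TRUE),
         mean_mse = mean(x$mse, na.rm = TRUE))
}

#' Accuracy-over-time plot for a prediction result
#'
#' @param object a `prediction_result`.
#' @param ... unused.
#' @return A ggplot: per-trait accuracy trajectories over days, with the
#'   across-trait mean highlighted.
#' @method autoplot prediction_result
#' @export
autoplot.prediction_result <- function(object, ...) {
  d <- tidy(object) |> dplyr::filter(is.finite(.data$accuracy))
  m <- d |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$accuracy)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$trait), alpha = 0.25) +
    ggplot2::geom_line(data = m, colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "day after sowing", y = "Pearson accuracy",
                  title = sprintf("%s forecasts (%s)", object$mode,
                                  object$scenario)) +
    ggplot2::theme_minimal()
}

# forecast one test line with a predicted operator; returns p x T matrix
forecast_test_line <- function(A_P, t, line, mode, start_index, gap_policy) {
  Tn <- length(t$time_axis)
  if (mode == "iterative") {
    out <- forecast_iterative(A_P, t, line, gap_policy)
    if (start_index > 1) out[, seq_len(start_index)] <- NA_real_
    out
  } else {
    i <- match(line, t$line_ids)
    x0 <- t$values[i, , start_index]
    steps <- Tn - start_index
    gaps <- diff(t$time_axis)[start_index:(Tn - 1)]
    out <- matrix(NA_real_, length(t$trait_ids), Tn)
    out[, (start_index + 1):Tn] <-
      forecast_recursive(A_P, x0, steps, gap_policy, gaps)
    out
  }
}

#' Cross-validated evaluation of genomic trajectory forecasting
#'
#' The full method under cross-validation: per fold, the operator entry
#' models are trained on the training lines, operators are predicted for
#' the held-out lines from markers alone, trajectories are forecast
#' (one-step-ahead from measured states, or recursively from the starting
#' state) and compared with the measured values. Accuracy at each trait
#' and timepoint is the Pearson correlation across the fold's test lines,
#' averaged over folds and iterations; MSE likewise.
#'
#' In `scenario = "holdout_tail"` the entry models see only the first
#' `n_train_timepoints` timepoints and forecasting starts either at the
#' first timepoint or at the last trained one.
#'
#' @param t a [trait_tensor()].
#' @param G a [genotype_matrix()] over the same lines.
#' @param plan a [cv_plan()].
#' @param mode `"iterative"` or `"recursive"`.
#' @param scenario `"full_series"` or `"holdout_tail"`.
#' @param r retained rank.
#' @param gap_policy how forecasts cross measurement gaps (see
#'   [forecast_iterative()]).
#' @param n_train_timepoints,start holdout-tail controls.
#' @return A `prediction_result`.
#' @export
run_dynamicgp_cv <- function(t, G, plan,
                             mode = c("iterative", "recursive"),
                             scenario = c("full_series", "holdout_tail"),
                             r = 2,
                             gap_policy = c("unit_step", "power"),
                             n_train_timepoints = NULL,
                             start = c("first", "last_trained")) {
  mode <- match.arg(mode)
  scenario <- match.arg(scenario)
  gap_policy <- match.arg(gap_policy)
  start <- match.arg(start)
  stopifnot(inherits(t, "trait_tensor"), inherits(G, "genotype_matrix"),
            inherits(plan, "cv_plan"))
  if (!identical(t$line_ids, G$line_ids) ||
      !identical(t$line_ids, plan$line_ids))
    abort("tensor, genotypes and plan must cover the same lines in order")
  Tn <- length(t$time_axis)
  if (scenario == "holdout_tail") {
    if (is.null(n_train_timepoints) || n_train_timepoints >= Tn)
      abort("holdout_tail needs n_train_timepoints < T")
    keep <- seq_len(n_train_timepoints)
    t_train <- trait_tensor(t$values[, , keep, drop = FALSE], t$line_ids,
                            t$trait_ids, t$time_axis[keep])
    start_index <- if (start == "first") 1L else n_train_timepoints
  } else {
    t_train <- t
    start_index <- 1L
  }
  # per-line factor models depend only on that line's own data, so they
  # are computed once and subset per fold
  models <- fit_line_models(t_train, t$line_ids, r)
  usable <- names(models)
  table <- extract_entry_traits(models, which = c("Phi", "R"))
  info <- table$entry_info
  per_fold <- list(); slot <- 1
  for (it in seq_len(plan$n_iterations)) {
    fold_of <- plan$assignments[, it]
    for (f in seq_len(plan$n_folds)) {
      tr <- intersect(plan$line_ids[fold_of != f & fold_of > 0], usable)
      te <- intersect(plan$line_ids[fold_of == f], usable)
      if (length(te) < 3) {
        inform(sprintf("fold %d of iteration %d has fewer than 3 usable test lines; skipped", f, it))
        next
      }
      em <- fit_entry_models(table$values[tr, , drop = FALSE],
                             G$dosages[tr, , drop = FALSE])
      ent_pred <- predict_entries(em, G$dosages[te, , drop = FALSE])
      preds <- array(NA_real_, c(length(te), length(t$trait_ids), Tn))
      for (ii in seq_along(te)) {
        Phi_P <- matrix(0, length(t$trait_ids), r)
        R_P <- matrix(0, r, r)
        for (q in seq_len(nrow(info))) {
          if (info$matrix[q] == "Phi") Phi_P[info$row[q], info$col[q]] <- ent_pred[ii, q]
          else R_P[info$row[q], info$col[q]] <- ent_pred[ii, q]
        }
        A_P <- suppressWarnings(reconstruct_operator(Phi_P, R_P))
        preds[ii, , ] <- tryCatch(
          forecast_test_line(A_P, t, te[ii], mode, start_index, gap_policy),
          error = function(e) NA_real_)
      }
      truth <- t$values[te, , , drop = FALSE]
      cells <- expand.grid(j = seq_along(t$trait_ids),
                           tt = (start_index + 1):Tn)
      acc <- purrr::pmap_dfr(cells, function(j, tt) {
        y <- truth[, j, tt]; yh <- preds[, j, tt]
        ok <- is.finite(y) & is.finite(yh)
        a <- if (sum(ok) >= 3 && sd(y[ok]) > 0 && sd(yh[ok]) > 0)
          cor(y[ok], yh[ok]) else NA_real_
        tibble(trait = t$trait_ids[j], day = t$time_axis[tt],
               accuracy = a, mse = mean((y[ok] - yh[ok])^2))
      })
      acc$iteration <- it; acc$fold <- f
      per_fold[[slot]] <- acc; slot <- slot + 1
    }
  }
  new_prediction_result(dplyr::bind_rows(per_fold), t$trait_ids,
                        t$time_axis, mode, scenario)
}

#' Single-timepoint RR-BLUP baseline under the same cross-validation
#'
#' The standard genomic prediction baseline: one RR-BLUP model per trait,
#' trained on the values at `train_timepoint`; its (time-constant)
#' prediction for each test line is correlated with the measured values
#' at every timepoint from `train_timepoint` on. Sharing the `plan` with
#' [run_dynamicgp_cv()] makes the comparison fold-for-fold paired.
#'
#' @param t a [trait_tensor()].
#' @param G a [genotype_matrix()].
#' @param plan a [cv_plan()].
#' @param train_timepoint index of the training timepoint (default 1).
#' @return A `prediction_result` with `mode = "baseline"`.
#' @export
baseline_rrblup_cv <- function(t, G, plan, train_timepoint = 1) {
  stopifnot(inherits(t, "trait_tensor"), inherits(G, "genotype_matrix"),
            inherits(plan, "cv_plan"))
  if (!identical(t$line_ids, G$line_ids) ||
      !identical(t$line_ids, plan$line_ids))
    abort("tensor, genotypes and plan must cover the same lines in order")
  Tn <- length(t$time_axis)
  if (train_timepoint < 1 || train_timepoint > Tn)
    abort("train_timepoint out of range")
  per_fold <- list(); slot <- 1
  for (it in seq_len(plan$n_iterations)) {
    fold_of <- plan$assignments[, it]
    for (f in seq_len(plan$n_folds)) {
      tr <- which(fold_of != f & fold_of > 0)
      te <- which(fold_of == f)
      if (length(te) < 3) next
      M <- G$dosages[tr, , drop = FALSE]
      centering <- colMeans(M)
      Mc <- sweep(M, 2, centering)
      Mc_te <- sweep(G$dosages[te, , drop = FALSE], 2, centering)
      ed <- eigen(tcrossprod(Mc), symmetric = TRUE)
      acc_list <- list()
      for (j in seq_along(t$trait_ids)) {
        ytr <- t$values[tr, j, train_timepoint]
        pred <- if (var(ytr) == 0) rep(mean(ytr), length(te)) else {
          fit <- rrblup_spectral(ytr, ed, Mc)
          fit$mu + as.numeric(Mc_te %*% fit$beta)
        }
        for (tt in train_timepoint:Tn) {
          y <- t$values[te, j, tt]
          a <- if (length(te) >= 3 && sd(y) > 0 && sd(pred) > 0)
            cor(y, pred) else NA_real_
          acc_list[[length(acc_list) + 1]] <-
            tibble(trait = t$trait_ids[j], day = t$time_axis[tt],
                   accuracy = a, mse = mean((y - pred)^2))
        }
      }
      acc <- dplyr::bind_rows(acc_list)
      acc$iteration <- it; acc$fold <- f
      per_fold[[slot]] <- acc; slot <- slot + 1
    }
  }
  new_prediction_result(dplyr::bind_rows(per_fold), t$trait_ids,
                        t$time_axis, "baseline", "full_series")
}

#' Relate forecasting accuracy to the temporal stability of heritability
#'
#' Traits whose SNP heritability is stable over development tend to be
#' forecast better. For each trait the coefficient of variation (sd/mean)
#' of its time-resolved heritability is compared with its mean forecast
#' accuracy; the association is summarised by a Pearson correlation with
#' a two-sided t-test p-value.
#'
#' @param h2_table tibble with columns `trait`, `day`, `h2` (from
#'   [trait_heritability()]).
#' @param result a `prediction_result`.
#' @return An object of class `h2_consistency` with a per-trait tibble
#'   (`trait`, `cv_h2`, `mean_accuracy`), the correlation `estimate` and
#'   `p_value`.
#' @export
heritability_consistency_analysis <- function(h2_table, result) {
  stopifnot(inherits(result, "prediction_result"))
  per_trait <- h2_table |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(mean_h2 = mean(.data$h2, na.rm = TRUE),
                     sd_h2 = sd(.data$h2, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(cv_h2 = ifelse(.data$mean_h2 > 0,
                                 .data$sd_h2 / .data$mean_h2, NA_real_))
  excluded <- per_trait$trait[!is.finite(per_trait$cv_h2)]
  if (length(excluded))
    inform(sprintf("excluding trait(s) with undefined heritability CV: %s",
                   paste(excluded, collapse = ", ")))
  macc <- tibble(trait = rownames(result$accuracy),
                 mean_accuracy = rowMeans(result$accuracy, na.rm = TRUE))
  d <- dplyr::inner_join(per_trait, macc, by = "trait") |>
    dplyr::filter(is.finite(.data$cv_h2), is.finite(.data$mean_accuracy))
  if (nrow(d) < 3) abort("need at least 3 traits with defined CV and accuracy")
  ct <- cor.test(d$cv_h2, d$mean_accuracy)
  structure(
    list(per_trait = dplyr::select(d, "trait", "cv_h2", "mean_accuracy"),
         estimate = unname(ct$estimate), p_value = ct$p.value),
    class = "h2_consistency")
}

#' @export
print.h2_consistency <- function(x, ...) {
  cat(sprintf("<h2_consistency> r = %.3f (p = %.3g) over %d traits\n",
              x$estimate, x$p_value, nrow(x$per_trait)))
  invisible(x)
}

#' @method tidy h2_consistency
#' @export
tidy.h2_consistency <- function(x, ...) x$per_trait

#' @method glance h2_consistency
#' @export
glance.h2_consistency <- function(x, ...) {
  tibble(estimate = x$estimate, p_value = x$p_value,
         n_traits = nrow(x$per_trait))
}

#' Serialize a trained bundle to JSON
#'
#' @param bundle a [train_dynamicgp()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "dynamicgp_bundle"))
  payload <- list(
    r = bundle$r, p = bundle$p, trait_ids = bundle$trait_ids,
    marker_ids = bundle$marker_ids, n_lines = bundle$n_lines,
    entry_info = as.data.frame(bundle$entry_info),
    centering = bundle$entry_models$centering,
    fits = bundle$entry_models$fits)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param path input file.
#' @return A `dynamicgp_bundle`.
#' @export
read_bundle <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fits <- lapply(seq_len(nrow(x$entry_info)), function(i) {
    f <- lapply(x$fits[[i]], identity)
    if (f$type == "constant") list(type = "constant", value = as.numeric(f$value))
    else list(type = "rrblup", mu = as.numeric(f$mu),
              beta = as.numeric(f$beta), lambda = as.numeric(f$lambda))
  })
  names(fits) <- x$entry_info$label
  structure(
    list(r = as.integer(x$r), p = as.integer(x$p),
         trait_ids = as.character(x$trait_ids),
         marker_ids = as.character(x$marker_ids),
         entry_info = as_tibble(x$entry_info),
         entry_models = list(fits = fits,
                             centering = setNames(as.numeric(x$centering),
                                                  x$marker_ids)),
         n_lines = as.integer(x$n_lines)),
    class = "dynamicgp_bundle")
}
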