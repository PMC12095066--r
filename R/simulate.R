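# centre x and rescale to an exact sample standard deviation
scale_exact <- function(x, target_sd) {
  x <- x - mean(x)
  s <- sd(x)
  if (s == 0) {
    if (target_sd > 0) abort("cannot scale a constant vector to nonzero sd")
    return(x)
  }
  x * (target_sd / s)
}

#' Simulate unlinked biallelic genotypes
#'
#' Allele frequencies are drawn uniformly on `maf_range` and dosages are
#' binomial(2, freq) independently per line (Hardy-Weinberg, no linkage).
#' Markers whose realised minor allele frequency falls below 0.01 are
#' redrawn so every marker is usable in a GRM.
#'
#' @param k number of lines (>= 2).
#' @param m number of markers.
#' @param maf_range interval within (0, 0.5] for the allele frequency.
#' @param seed RNG seed; identical seeds reproduce the matrix exactly.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(k, m, maf_range = c(0.1, 0.5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (k < 2 || m < 1) abort("need k >= 2 lines and m >= 1 markers")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    abort("maf_range must be an interval within (0, 0.5]")
  draw <- function(n) {
    f <- runif(n, maf_range[1], maf_range[2])
    d <- matrix(rbinom(k * n, 2, rep(f, each = k)), k, n)
    list(f = f, d = d)
  }
  g <- draw(m)
  for (iter in 1:100) {
    maf <- pmin(colMeans(g$d) / 2, 1 - colMeans(g$d) / 2)
    bad <- which(maf < 0.01)
    if (!length(bad)) break
    redo <- draw(length(bad))
    g$d[, bad] <- redo$d
  }
  if (any(pmin(colMeans(g$d) / 2, 1 - colMeans(g$d) / 2) < 0.01))
    abort("could not realise maf >= 0.01; widen maf_range or increase k")
  dimnames(g$d) <- list(sprintf("line%03d", seq_len(k)),
                        sprintf("snp%05d", seq_len(m)))
  genotype_matrix(g$d)
}

# sparse marker architecture for one scalar trait: effects on n_causal
# markers, genetic values returned centred and scaled to sd_g exactly
genetic_component <- function(Wc, n_causal, sd_g) {
  m <- ncol(Wc)
  idx <- sample.int(m, min(n_causal, m))
  beta <- rnorm(length(idx))
  g <- as.numeric(Wc[, idx, drop = FALSE] %*% beta)
  if (sd(g) == 0) {            # pathological draw; retry once
    beta <- rnorm(length(idx))
    g <- as.numeric(Wc[, idx, drop = FALSE] %*% beta)
  }
  list(values = scale_exact(g, sd_g), causal = idx, beta = beta)
}

#' Simulate a family of genotype-dependent low-rank operators
#'
#' Each line's trait dynamics are governed by a p x p operator
#' `A(g) = Phi0 R(g) Phi0^T`: a mode basis `Phi0` (orthonormal, shared
#' across lines by default) and a line-specific r x r upper-triangular
#' reduced operator `R(g)`. Every upper-triangle entry of `R(g)` is
#' `base + genetic + residual`, the genetic part a sparse linear function
#' of centred dosages; the two parts are rescaled to exact sample
#' variances so the realised entry heritability equals `entry_h2`.
#' Diagonal bases sit at the 0.7 and 0.3 quantiles of
#' `spectral_interval`; any line whose spectral radius leaves the interval
#' is rescaled back to the nearest bound.
#'
#' @param G a [genotype_matrix()].
#' @param p number of observed traits.
#' @param r_true rank of the latent dynamics.
#' @param entry_h2 target heritability of operator entries in `[0, 1]`.
#' @param spectral_interval allowed range for eigenvalue moduli; the upper
#'   bound may not exceed 1.1 (trajectory stability over gap days).
#' @param entry_sd total (genetic + residual) sd of each entry across
#'   lines.
#' @param n_causal causal markers per entry (oligogenic architecture).
#' @param rotation_sd sd of a small line-specific perturbation of the mode
#'   basis; 0 keeps the basis shared, the regime in which operator entries
#'   are comparable across genotypes.
#' @param seed RNG seed.
#' @return An object of class `synthetic_truth` holding the genotypes,
#'   the mode basis, per-line reduced and full operators, the causal
#'   effects per entry and the simulation parameters.
#' @export
simulate_operator_family <- function(G, p = 20, r_true = 2, entry_h2 = 0.5,
                                     spectral_interval = c(0.7, 1.08),
                                     entry_sd = 0.05, n_causal = 20,
                                     rotation_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(G, "genotype_matrix"))
  if (r_true > p) abort("r_true must not exceed p")
  if (entry_h2 < 0 || entry_h2 > 1) abort("entry_h2 must lie in [0, 1]")
  if (spectral_interval[2] > 1.1)
    abort("spectral_interval upper bound above 1.1 risks divergent trajectories")
  k <- length(G$line_ids)
  if (entry_h2 > 0 && k < 3) abort("need at least 3 lines for heritable entries")
  Wc <- sweep(G$dosages, 2, colMeans(G$dosages))
  # shared orthonormal mode basis, sign-canonicalized
  Phi0 <- qr.Q(qr(matrix(rnorm(p * r_true), p, r_true)))
  Phi0 <- Phi0 %*% diag(column_canonical_signs(Phi0), r_true)
  a <- spectral_interval[1]; b <- spectral_interval[2]
  diag_base <- a + (b - a) * seq(0.7, 0.3, length.out = r_true)
  base_R <- diag(diag_base, r_true)
  if (r_true > 1) base_R[upper.tri(base_R)] <- 0.1
  ut <- which(upper.tri(base_R, diag = TRUE), arr.ind = TRUE)
  entries <- matrix(0, k, nrow(ut))
  effects <- vector("list", nrow(ut))
  sd_g <- entry_sd * sqrt(entry_h2)
  sd_e <- entry_sd * sqrt(1 - entry_h2)
  for (q in seq_len(nrow(ut))) {
    gpart <- if (sd_g > 0) genetic_component(Wc, n_causal, sd_g)
             else list(values = rep(0, k), causal = integer(0), beta = numeric(0))
    epart <- if (sd_e > 0) scale_exact(rnorm(k), sd_e) else rep(0, k)
    entries[, q] <- base_R[ut[q, 1], ut[q, 2]] + gpart$values + epart
    effects[[q]] <- list(row = ut[q, 1], col = ut[q, 2],
                         causal = gpart$causal, beta = gpart$beta)
  }
  R_line <- array(0, dim = c(r_true, r_true, k))
  operators <- vector("list", k)
  bases <- vector("list", k)
  rescaled <- logical(k)
  for (i in seq_len(k)) {
    R <- matrix(0, r_true, r_true)
    R[ut] <- entries[i, ]
    rad <- max(Mod(eigen(R, only.values = TRUE)$values))
    if (rad > b) { R <- R * (b / rad); rescaled[i] <- TRUE }
    else if (rad < a && rad > 0) { R <- R * (a / rad); rescaled[i] <- TRUE }
    R_line[, , i] <- R
    Phi_i <- Phi0
    if (rotation_sd > 0) {
      Phi_i <- qr.Q(qr(Phi0 + rotation_sd * matrix(rnorm(p * r_true), p, r_true)))
      Phi_i <- Phi_i %*% diag(column_canonical_signs(Phi_i), r_true)
    }
    bases[[i]] <- Phi_i
    operators[[i]] <- Phi_i %*% R %*% t(Phi_i)
  }
  names(operators) <- G$line_ids
  structure(
    list(genotypes = G, p = p, r_true = r_true, mode_basis = Phi0,
         line_bases = bases, base_R = base_R, reduced_operators = R_line,
         true_operators = operators, true_entry_effects = effects,
         entry_h2 = entry_h2, entry_sd = entry_sd,
         spectral_interval = spectral_interval, rescaled = rescaled,
         rotation_sd = rotation_sd, seed = seed),
    class = "synthetic_truth")
}

#' Default measurement design: weekly blocks of consecutive days
#'
#' @param n_blocks number of blocks.
#' @param block_len measurement days per block.
#' @param gap unmeasured days between blocks.
#' @param start first measurement day (days after sowing).
#' @return A list of integer day vectors, one per block.
#' @export
make_block_days <- function(n_blocks = 5, block_len = 5, gap = 2, start = 15) {
  lapply(seq_len(n_blocks) - 1,
         function(w) start + w * (block_len + gap) + seq_len(block_len) - 1)
}

#' Simulate gap-structured trait trajectories from known operators
#'
#' Latent states start from `x1` on the first measurement day and advance
#' by the line's true operator every calendar day, including the
#' unmeasured gap days; observations are latent values plus i.i.d.
#' Gaussian measurement noise at the measured days only. The starting
#' state is drawn in mode space: a common centre, optional i.i.d. line
#' deviations and an optional genetically shifted component with sparse
#' marker effects.
#'
#' @param truth a `synthetic_truth` from [simulate_operator_family()].
#' @param block_days list of measurement-day vectors (see
#'   [make_block_days()]).
#' @param x1_spec list with `center` (length-r vector or single number),
#'   `line_sd` (non-genetic start variation) and `genetic_sd` (heritable
#'   start variation).
#' @param noise_sd measurement noise sd on the observed (normalised)
#'   trait scale.
#' @param seed RNG seed.
#' @return A [trait_tensor()] of observed values.
#' @export
simulate_trajectories <- function(truth, block_days = make_block_days(),
                                  x1_spec = list(center = 1, line_sd = 0.1,
                                                 genetic_sd = 0),
                                  noise_sd = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(truth, "synthetic_truth"))
  G <- truth$genotypes
  k <- length(G$line_ids); p <- truth$p; r <- truth$r_true
  days <- unlist(block_days)
  if (any(diff(days) <= 0)) abort("block days must be increasing")
  Tn <- length(days)
  center <- rep(x1_spec$center %||% 1, length.out = r)
  Z1 <- matrix(rep(center, each = k), k, r)
  if ((x1_spec$line_sd %||% 0) > 0)
    Z1 <- Z1 + matrix(rnorm(k * r, sd = x1_spec$line_sd), k, r)
  if ((x1_spec$genetic_sd %||% 0) > 0) {
    Wc <- sweep(G$dosages, 2, colMeans(G$dosages))
    for (j in seq_len(r))
      Z1[, j] <- Z1[, j] + genetic_component(Wc, 20, x1_spec$genetic_sd)$values
  }
  vals <- array(NA_real_, dim = c(k, p, Tn))
  all_days <- seq(days[1], days[Tn])
  meas <- match(days, all_days)
  for (i in seq_len(k)) {
    A <- truth$true_operators[[i]]
    x <- as.numeric(truth$line_bases[[i]] %*% Z1[i, ])
    traj <- matrix(NA_real_, p, length(all_days))
    traj[, 1] <- x
    for (dd in seq_along(all_days)[-1]) {
      x <- as.numeric(A %*% x)
      if (!all(is.finite(x)))
        abort(sprintf("trajectory diverged for line '%s'", G$line_ids[i]))
      traj[, dd] <- x
    }
    obs <- traj[, meas, drop = FALSE]
    if (noise_sd > 0) obs <- obs + matrix(rnorm(p * Tn, sd = noise_sd), p, Tn)
    vals[i, , ] <- obs
  }
  trait_tensor(vals, G$line_ids, sprintf("trait%02d", seq_len(p)), days)
}

#' Preset benchmark scenarios with known ground truth
#'
#' Four regimes exercise the whole method:
#' \describe{
#'   \item{perfect}{noise-free dynamics, fully heritable operator entries
#'     and a common starting state: genomic prediction of the operator can
#'     in principle be exact, so recursive forecasts for unseen lines
#'     should approach accuracy 1.}
#'   \item{heritable}{moderate entry heritability (0.5) and measurement
#'     noise (0.05): the realistic regime for ordering comparisons.}
#'   \item{null}{operator entries independent of genotype and a common
#'     latent start: markers carry no information, accuracies should
#'     centre on zero.}
#'   \item{maize_like}{the dimensions of a large field phenomics design
#'     (330 lines, 50 traits, 25 timepoints in 5 blocks).}
#' }
#'
#' @param name one of `"perfect"`, `"heritable"`, `"null"`,
#'   `"maize_like"`.
#' @param seed RNG seed; all components derive from it.
#' @return A list with elements `genotypes`, `tensor`, `truth`.
#' @export
make_benchmark_scenario <- function(name = c("perfect", "heritable", "null",
                                             "maize_like"),
                                    seed = 1) {
  name <- match.arg(name)
  cfg <- switch(name,
    perfect = list(k = 200, m = 100, p = 20, r = 2, h2 = 1, entry_sd = 0.04,
                   noise = 0, line_sd = 0, spec = c(0.7, 1.1)),
    heritable = list(k = 300, m = 1000, p = 20, r = 2, h2 = 0.5,
                     entry_sd = 0.05, noise = 0.05, line_sd = 0.1,
                     spec = c(0.7, 1.08)),
    null = list(k = 300, m = 1000, p = 20, r = 2, h2 = 0, entry_sd = 0.05,
                noise = 0.05, line_sd = 0, spec = c(0.7, 1.08)),
    maize_like = list(k = 330, m = 2000, p = 50, r = 2, h2 = 0.3,
                      entry_sd = 0.05, noise = 0.05, line_sd = 0.1,
                      spec = c(0.7, 1.08)))
  G <- simulate_genotypes(cfg$k, cfg$m, seed = seed)
  truth <- simulate_operator_family(
    G, p = cfg$p, r_true = cfg$r, entry_h2 = cfg$h2,
    spectral_interval = cfg$spec, entry_sd = cfg$entry_sd,
    seed = seed + 1000L)
  gen_sd <- if (name == "heritable" || name == "maize_like") 0.05 else 0
  tensor <- simulate_trajectories(
    truth, make_block_days(),
    x1_spec = list(center = 1, line_sd = cfg$line_sd, genetic_sd = gen_sd),
    noise_sd = cfg$noise, seed = seed + 2000L)
  list(genotypes = G, tensor = tensor, truth = truth)
}
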