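#' Mantel correlation matrix between traits
#'
#' For each trait, lines are compared through the Euclidean distance
#' between their full time profiles, giving one k x k distance matrix per
#' trait; the Mantel correlation between two traits is the Pearson
#' correlation of the strict lower triangles of their distance matrices.
#' `method = "flat"` instead correlates the flattened line x time matrices
#' directly.
#'
#' @param t a [trait_tensor()].
#' @param method `"distance"` (Mantel proper) or `"flat"`.
#' @return A p x p symmetric matrix with unit diagonal; traits whose
#'   profiles have zero variance get `NA` correlations and a warning.
#' @export
mantel_correlation_matrix <- function(t, method = c("distance", "flat")) {
  method <- match.arg(method)
  stopifnot(inherits(t, "trait_tensor"))
  k <- length(t$line_ids); p <- length(t$trait_ids)
  if (method == "distance" && k < 4)
    abort("need at least 4 lines for a Mantel correlation")
  vecs <- lapply(seq_len(p), function(j) {
    prof <- matrix(t$values[, j, ], nrow = k)   # k x T
    if (method == "distance") as.numeric(dist(prof)) else as.numeric(prof)
  })
  sds <- vapply(vecs, sd, numeric(1))
  M <- matrix(NA_real_, p, p, dimnames = list(t$trait_ids, t$trait_ids))
  ok <- sds > 0
  if (any(!ok)) {
    warn(sprintf("trait(s) with zero profile variance: %s",
                 paste(t$trait_ids[!ok], collapse = ", ")))
  }
  if (any(ok)) {
    V <- do.call(cbind, vecs[ok])
    M[ok, ok] <- cor(V)
  }
  diag(M) <- 1
  M
}

#' Threshold a Mantel matrix into an unweighted trait graph
#'
#' @param mantel symmetric p x p correlation matrix.
#' @param threshold edge `(i, j)` is present iff `mantel[i, j] > threshold`
#'   (the conventional screen is 0.96). Must lie in (0, 1).
#' @param absolute compare `|mantel|` instead of the signed value.
#' @return An [igraph::graph] with one node per trait; isolated nodes are
#'   retained.
#' @export
build_trait_graph <- function(mantel, threshold = 0.96, absolute = FALSE) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must lie in (0, 1)")
  vals <- if (absolute) abs(mantel) else mantel
  adj <- !is.na(vals) & vals > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- rownames(mantel) %||% paste0("trait", seq_len(nrow(mantel)))
  g
}

#' Modularity clustering of the trait graph
#'
#' Deterministic greedy (agglomerative) modularity maximisation; isolated
#' nodes become singleton clusters. Cluster labels are integers renumbered
#' in order of each cluster's smallest node index.
#'
#' @param graph an undirected graph from [build_trait_graph()].
#' @return Named integer vector of cluster memberships.
#' @export
detect_modularity_clusters <- function(graph) {
  if (igraph::ecount(graph) == 0) {
    mem <- seq_len(igraph::vcount(graph))
  } else {
    cl <- igraph::cluster_fast_greedy(graph)
    mem <- igraph::membership(cl)
  }
  mem <- as.integer(mem)
  names(mem) <- igraph::V(graph)$name
  # renumber so labels are stable under node order
  first_seen <- match(unique(mem), mem)
  relabel <- order(first_seen)
  out <- match(mem, unique(mem))
  setNames(as.integer(out), names(mem))
}

#' Pick one representative trait per cluster by mean heritability
#'
#' @param memberships named integer vector (trait -> cluster), as returned
#'   by [detect_modularity_clusters()].
#' @param mean_h2 named numeric vector of per-trait mean heritability over
#'   the analysed timepoints.
#' @return Character vector of representative trait ids, one per cluster,
#'   ordered by cluster label. Ties are broken lexicographically by trait
#'   id, with a message.
#' @export
select_representative_traits <- function(memberships, mean_h2) {
  traits <- names(memberships)
  missing_h2 <- setdiff(traits, names(mean_h2))
  if (length(missing_h2))
    abort(sprintf("no heritability for trait(s): %s",
                  paste(missing_h2, collapse = ", ")))
  vapply(sort(unique(memberships)), function(cl) {
    members <- sort(traits[memberships == cl])
    h2 <- mean_h2[members]
    best <- members[h2 == max(h2)]
    if (length(best) > 1)
      inform(sprintf("heritability tie in cluster %d; keeping '%s'", cl, best[1]))
    best[1]
  }, character(1))
}

#' Per-trait, per-timepoint SNP heritability
#'
#' Applies single-GRM REML ([reml_single_component()]) to every trait at
#' every timepoint, reusing one eigendecomposition of the GRM.
#'
#' @param t a [trait_tensor()].
#' @param K a `grm` over the same lines.
#' @return A tibble with columns `trait`, `day`, `h2`, `boundary`;
#'   constant trait-day slices get `NA`.
#' @export
trait_heritability <- function(t, K) {
  stopifnot(inherits(t, "trait_tensor"), inherits(K, "grm"))
  if (!identical(t$line_ids, K$line_ids))
    abort("lines of the tensor and GRM must match")
  ed <- eigen(K$K, symmetric = TRUE)
  grid <- expand.grid(j = seq_along(t$trait_ids), tt = seq_along(t$time_axis))
  res <- purrr::pmap_dfr(grid, function(j, tt) {
    y <- t$values[, j, tt]
    if (var(y) == 0) {
      tibble(trait = t$trait_ids[j], day = t$time_axis[tt],
             h2 = NA_real_, boundary = NA)
    } else {
      fit <- reml_h2_spectral(y, ed)
      tibble(trait = t$trait_ids[j], day = t$time_axis[tt],
             h2 = fit$h2, boundary = fit$boundary)
    }
  })
  as_tibble(res)
}

#' Reduce a correlated trait panel to cluster representatives
#'
#' Convenience wrapper chaining [mantel_correlation_matrix()],
#' [build_trait_graph()], [detect_modularity_clusters()] and
#' [select_representative_traits()].
#'
#' @param t a [trait_tensor()].
#' @param mean_h2 named per-trait mean heritability; computed with
#'   [trait_heritability()] and `K` when omitted.
#' @param K a `grm`, required when `mean_h2` is missing.
#' @param threshold Mantel edge threshold (default 0.96).
#' @param absolute threshold on `|mantel|`.
#' @return An object of class `trait_clustering` with fields `mantel`,
#'   `edge_threshold`, `memberships`, `representatives`, `mean_h2`.
#' @export
cluster_traits <- function(t, mean_h2 = NULL, K = NULL, threshold = 0.96,
                           absolute = FALSE) {
  if (is.null(mean_h2)) {
    if (is.null(K)) abort("provide mean_h2 or a GRM to compute it from")
    h2tab <- trait_heritability(t, K)
    mean_h2 <- h2tab |>
      dplyr::group_by(.data$trait) |>
      dplyr::summarise(h2 = mean(.data$h2, na.rm = TRUE)) |>
      (\(d) setNames(d$h2, d$trait))()
  }
  M <- mantel_correlation_matrix(t)
  g <- build_trait_graph(M, threshold, absolute)
  mem <- detect_modularity_clusters(g)
  reps <- select_representative_traits(mem, mean_h2)
  structure(
    list(trait_ids = t$trait_ids, mantel = M, edge_threshold = threshold,
         memberships = mem, representatives = reps, mean_h2 = mean_h2),
    class = "trait_clustering")
}

#' @export
print.trait_clustering <- function(x, ...) {
  cat(sprintf("<trait_clustering> %d traits -> %d clusters (threshold %.2f)\n",
              length(x$memberships), length(x$representatives),
              x$edge_threshold))
  invisible(x)
}

#' Per-trait cluster report
#'
#' @param x a `trait_clustering`.
#' @param ... unused.
#' @return A tibble with columns `trait`, `cluster`, `mean_h2`,
#'   `is_representative`.
#' @method tidy trait_clustering
#' @export
tidy.trait_clustering <- function(x, ...) {
  traits <- names(x$memberships)
  tibble(trait = traits,
         cluster = as.integer(x$memberships),
         mean_h2 = unname(x$mean_h2[traits]),
         is_representative = traits %in% x$representatives)
}

#' Min-max normalise each trait over all lines and timepoints
#'
#' Maps every trait to `[0, 1]` using its minimum and maximum over lines
#' and timepoints jointly; a constant trait maps to all zeros with a
#' warning. Applying the function twice is a no-op.
#'
#' @param t a [trait_tensor()].
#' @return A normalised [trait_tensor()].
#' @export
minmax_normalize_tensor <- function(t) {
  stopifnot(inherits(t, "trait_tensor"))
  vals <- t$values
  for (j in seq_along(t$trait_ids)) {
    x <- vals[, j, ]
    rng <- range(x)
    if (rng[1] == rng[2]) {
      warn(sprintf("trait '%s' is constant; normalised to zeros", t$trait_ids[j]))
      vals[, j, ] <- 0
    } else {
      vals[, j, ] <- (x - rng[1]) / (rng[2] - rng[1])
    }
  }
  trait_tensor(vals, t$line_ids, t$trait_ids, t$time_axis, t$blocks)
}
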