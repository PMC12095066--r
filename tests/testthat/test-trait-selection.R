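test_that("Mantel correlations match a hand-worked small example", {
  set.seed(51)
  k <- 4; Tn <- 3
  vals <- array(rnorm(k * 2 * Tn), c(k, 2, Tn))
  tt <- trait_tensor(vals, time_axis = 1:3)
  M <- mantel_correlation_matrix(tt)
  # by hand: Euclidean distances over time profiles, Pearson over the
  # 6 lower-triangle entries
  dvec <- function(j) {
    prof <- matrix(vals[, j, ], nrow = k)
    out <- c()
    for (a in 2:k) for (b in 1:(a - 1))
      out <- c(out, sqrt(sum((prof[a, ] - prof[b, ])^2)))
    out
  }
  expect_equal(M[1, 2], cor(dvec(1), dvec(2)), tolerance = 1e-12)
  expect_equal(diag(M), c(trait1 = 1, trait2 = 1))
  expect_equal(M[1, 2], M[2, 1])
})

test_that("Mantel correlation is invariant to positive affine trait transforms", {
  set.seed(52)
  vals <- array(rnorm(6 * 3 * 4), c(6, 3, 4))
  vals[, 2, ] <- 3 * vals[, 1, ] + 5       # exact affine copy of trait 1
  tt <- trait_tensor(vals, time_axis = 1:4)
  M <- mantel_correlation_matrix(tt)
  expect_equal(M[1, 2], 1, tolerance = 1e-12)
  expect_true(all(M >= -1 - 1e-12 & M <= 1 + 1e-12))
  # zero-variance trait flagged as NA with a warning
  vals[, 3, ] <- 2
  expect_warning(M2 <- mantel_correlation_matrix(
    trait_tensor(vals, time_axis = 1:4)), "zero profile variance")
  expect_true(is.na(M2[1, 3]))
  expect_equal(M2[3, 3], 1)
})

test_that("thresholding builds the expected trait graph", {
  M <- diag(6)
  M[1:3, 1:3] <- 0.99
  M[4:6, 4:6] <- 0.99
  M[1:3, 4:6] <- 0.5; M[4:6, 1:3] <- 0.5
  diag(M) <- 1
  rownames(M) <- colnames(M) <- paste0("t", 1:6)
  g <- build_trait_graph(M, 0.96)
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), 6)   # two triangles
  comp <- igraph::components(g)
  expect_equal(comp$no, 2)
  # all-zero correlations: edgeless graph, nodes retained
  M0 <- diag(4); rownames(M0) <- colnames(M0) <- paste0("t", 1:4)
  g0 <- build_trait_graph(M0, 0.96)
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), 4)
  expect_error(build_trait_graph(M, 1.2), "threshold")
})

test_that("greedy modularity clustering matches exhaustive search on two cliques", {
  adj <- matrix(0, 8, 8)
  adj[1:4, 1:4] <- 1; adj[5:8, 5:8] <- 1
  diag(adj) <- 0
  rownames(adj) <- colnames(adj) <- paste0("t", 1:8)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  mem <- detect_modularity_clusters(g)
  # exhaustive search over all set partitions of 8 nodes
  partitions <- function(n) {
    if (n == 1) return(list(list(1L)))
    out <- list()
    for (p in partitions(n - 1)) {
      for (i in seq_along(p)) {
        q <- p; q[[i]] <- c(q[[i]], as.integer(n)); out[[length(out) + 1]] <- q
      }
      out[[length(out) + 1]] <- c(p, list(as.integer(n)))
    }
    out
  }
  best <- -Inf; best_mem <- NULL
  for (p in partitions(8)) {
    mvec <- integer(8)
    for (i in seq_along(p)) mvec[p[[i]]] <- i
    q <- igraph::modularity(g, mvec)
    if (q > best + 1e-12) { best <- q; best_mem <- mvec }
  }
  expect_equal(igraph::modularity(g, mem), best, tolerance = 1e-12)
  expect_equal(unname(mem[1:4]), rep(mem[[1]], 4))
  expect_equal(unname(mem[5:8]), rep(mem[[5]], 4))
  expect_false(mem[[1]] == mem[[5]])
})

test_that("degenerate graphs give singletons and modularity beats one cluster", {
  g0 <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(g0)$name <- paste0("t", 1:5)
  expect_equal(unname(detect_modularity_clusters(g0)), 1:5)
  set.seed(53)
  g1 <- igraph::sample_gnp(12, 0.4)
  igraph::V(g1)$name <- paste0("t", 1:12)
  mem <- detect_modularity_clusters(g1)
  expect_gte(igraph::modularity(g1, mem),
             igraph::modularity(g1, rep(1, 12)))
})

test_that("planted trait groups are recovered exactly", {
  set.seed(54)
  n <- 30; groups <- rep(1:3, each = 10)
  adj <- matrix(0, n, n)
  for (i in 2:n) for (j in 1:(i - 1)) {
    p <- if (groups[i] == groups[j]) 0.9 else 0.05
    adj[i, j] <- adj[j, i] <- rbinom(1, 1, p)
  }
  rownames(adj) <- colnames(adj) <- paste0("t", 1:n)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  mem <- detect_modularity_clusters(g)
  # perfect agreement up to relabelling
  expect_equal(length(unique(mem)), 3)
  for (cl in unique(groups))
    expect_equal(length(unique(mem[groups == cl])), 1)
})

test_that("representatives maximise mean heritability per cluster", {
  mem <- c(a = 1L, b = 1L, c = 2L)
  h2 <- c(a = 0.4, b = 0.6, c = 0.3)
  expect_equal(unname(select_representative_traits(mem, h2)), c("b", "c"))
  # brute-force argmax on random clusters
  set.seed(55)
  mem2 <- setNames(sample(1:10, 40, replace = TRUE), paste0("t", 1:40))
  h22 <- setNames(runif(40), names(mem2))
  reps <- select_representative_traits(mem2, h22)
  labs <- sort(unique(mem2))
  for (cl in labs) {
    members <- names(mem2)[mem2 == cl]
    expect_equal(h22[[reps[match(cl, labs)]]], max(h22[members]))
  }
  expect_error(select_representative_traits(mem, h2[1:2]), "no heritability")
  # ties break lexicographically with a message
  expect_message(
    r <- select_representative_traits(c(x = 1L, w = 1L), c(x = 0.5, w = 0.5)),
    "tie")
  expect_equal(unname(r), "w")
})

test_that("the clustering pipeline is deterministic and reports representatives", {
  set.seed(56)
  G <- simulate_genotypes(40, 60, seed = 15)
  truth <- simulate_operator_family(G, p = 6, r_true = 2, entry_h2 = 0.5,
                                    seed = 16)
  tens <- simulate_trajectories(truth, noise_sd = 0.02, seed = 17)
  K <- compute_grm(G)
  c1 <- cluster_traits(tens, K = K, threshold = 0.9)
  c2 <- cluster_traits(tens, K = K, threshold = 0.9)
  expect_identical(c1$representatives, c2$representatives)
  td <- tidy(c1)
  expect_true(all(c("trait", "cluster", "mean_h2", "is_representative") %in%
                  names(td)))
  expect_equal(sum(td$is_representative), length(unique(td$cluster)))
})
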