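test_that("soft adjacency powers the correlation", {
  withr::with_seed(2, x <- matrix(rnorm(40), 10, 4))
  colnames(x) <- paste0("g", 1:4)
  a <- soft_adjacency(x, soft_power = 2)
  cc <- cor(x)
  expect_equal(a[1, 2], abs(cc[1, 2])^2)
  expect_equal(unname(diag(a)), rep(1, 4))
  expect_equal(abs(-0.5)^2, 0.25)           # unsigned semantics
  expect_equal(0.9^14, 0.228768, tolerance = 1e-6)
  # signed network maps cor -1 to 0
  asg <- soft_adjacency(x, soft_power = 2, signed = TRUE)
  expect_equal(asg[1, 2], ((1 + cc[1, 2]) / 2)^2)
  xc <- cbind(x, const = 1)
  expect_error(soft_adjacency(xc, soft_power = 2), "const")
})

test_that("tom_similarity matches hand cases and the triple-loop oracle", {
  # all adjacencies 1 on 3 genes
  a1 <- matrix(1, 3, 3)
  expect_equal(unname(tom_similarity(a1)), matrix(1, 3, 3))
  # a12 = a13 = 0.5, a23 = 0 -> TOM23 = 1/6
  a2 <- diag(3)
  a2[1, 2] <- a2[2, 1] <- 0.5
  a2[1, 3] <- a2[3, 1] <- 0.5
  t2 <- tom_similarity(a2)
  expect_equal(t2[2, 3], 1 / 6, tolerance = 1e-12)
  # zero adjacency -> zero off-diagonal
  t0 <- tom_similarity(diag(4))
  expect_equal(unname(t0), diag(4))

  withr::with_seed(13, {
    for (i in 1:5) {
      r <- matrix(runif(15 * 15), 15)
      adj <- (r + t(r)) / 2
      diag(adj) <- 1
      tom <- tom_similarity(adj)
      expect_lt(max(abs(tom - oracle_tom(adj))), 1e-10)
      expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
      expect_true(isSymmetric(unname(tom), tol = 1e-12))
    }
  })
})

test_that("module detection recovers planted blocks and respects min size", {
  ms <- simulate_module_expression(
    module_sim_config(n_modules = 2, genes_per_module = 100,
                      n_samples = 300, within_cor = 0.9, seed = 21))
  tom <- tom_similarity(soft_adjacency(ms$expr, soft_power = 6))
  mods <- detect_modules(tom, network_config(min_module_size = 75))
  expect_equal(adjusted_rand_index(mods, ms$modules), 1)

  # a single 50-gene block cannot reach min size 75
  ms2 <- simulate_module_expression(
    module_sim_config(n_modules = 1, genes_per_module = 50,
                      n_samples = 200, within_cor = 0.9, seed = 4))
  tom2 <- tom_similarity(soft_adjacency(ms2$expr, soft_power = 6))
  expect_warning(
    mods2 <- detect_modules(tom2, network_config(min_module_size = 75)),
    "unassigned")
  expect_true(all(mods2 == "unassigned"))
})

test_that("eigengenes are sign-aligned first principal components", {
  withr::with_seed(7, {
    base <- rnorm(40)
    expr <- sapply(1:6, function(i) base + rnorm(40, sd = 1e-8))
  })
  colnames(expr) <- paste0("g", 1:6)
  mods <- setNames(rep("M1", 6), colnames(expr))
  eg <- module_eigengenes(expr, mods)
  expect_equal(abs(cor(eg[, "M1"], scale(base)[, 1])), 1, tolerance = 1e-6)
  expect_gt(mean(cor(eg[, "M1"], expr)), 0)   # sign alignment
  # single-gene module: the standardized profile itself
  one <- module_eigengenes(expr[, 1, drop = FALSE],
                           setNames("M1", "g1"))
  expect_equal(unname(one[, 1]), unname(scale(expr[, 1])[, 1]))
})

test_that("TF-eigengene connectivity counts are sign-flip invariant", {
  ms <- simulate_module_expression(
    module_sim_config(n_modules = 2, genes_per_module = 20,
                      n_samples = 100, within_cor = 0.8, seed = 31))
  mods <- ms$modules
  eg <- module_eigengenes(ms$expr, mods)
  tfs <- setNames(c("zf", "zf", "hd"), colnames(ms$expr)[c(1, 2, 21)])
  n1 <- tf_eigengene_connectivity(ms$expr, eg, tfs, cutoff = 0.01)
  eg_flip <- module_eigengenes(-ms$expr, mods)
  n2 <- tf_eigengene_connectivity(-ms$expr, eg_flip, tfs, cutoff = 0.01)
  expect_equal(n1, n2)
  # a TF identical to an eigengene is counted for that module
  expr2 <- cbind(ms$expr, tf_like = eg[, "M1"])
  n3 <- tf_eigengene_connectivity(expr2, eg,
                                  setNames("special", "tf_like"))
  expect_equal(n3["special", "M1"], 1L)
  expect_error(tf_eigengene_connectivity(ms$expr, eg,
                                         setNames("x", "nope")), "nope")
})

test_that("tom_graph thresholds edges and finds components", {
  tom <- diag(6)
  tom[1, 2] <- tom[2, 1] <- 0.5
  tom[2, 3] <- tom[3, 2] <- 0.2
  tom[4, 5] <- tom[5, 4] <- 0.9
  dimnames(tom) <- list(paste0("g", 1:6), paste0("g", 1:6))
  g <- tom_graph(tom, 0.1)
  expect_equal(nrow(g$edges), 3)
  comp <- g$components
  expect_equal(comp[["g1"]], comp[["g3"]])
  expect_false(comp[["g1"]] == comp[["g4"]])
  expect_equal(sum(table(comp) == 1), 1)   # g6 is a singleton
  # brute-force edge count
  expect_equal(nrow(g$edges), sum(tom[upper.tri(tom)] > 0.1))
  # threshold above the maximum: all singletons
  g2 <- tom_graph(tom, 0.95)
  expect_equal(length(unique(g2$components)), 6)
})

test_that("adjusted Rand index matches oracles and handles edge cases", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(rep(1, 5), rep("z", 5)), 1)
  withr::with_seed(17, {
    for (i in 1:10) {
      x <- sample(1:3, 25, replace = TRUE)
      y <- sample(1:4, 25, replace = TRUE)
      expect_equal(adjusted_rand_index(x, y), oracle_ari(x, y),
                   tolerance = 1e-12)
    }
  })
  # two-block truth vs all singletons, against the pair-counting oracle
  x <- rep(1:2, each = 6)
  y <- seq_along(x)
  expect_equal(adjusted_rand_index(x, y), oracle_ari(x, y),
               tolerance = 1e-12)
  skip_if_not_installed("mclust")
  withr::with_seed(18, {
    x <- sample(1:4, 40, replace = TRUE)
    y <- sample(1:3, 40, replace = TRUE)
  })
  expect_equal(adjusted_rand_index(x, y),
               mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
})

test_that("random labels give near-zero ARI against a real partition", {
  vals <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      truth <- rep(1:4, each = 250)
      rand <- sample(1:4, 1000, replace = TRUE)
      adjusted_rand_index(truth, rand)
    })
  }, numeric(1))
  expect_lt(max(abs(vals)), 0.05)
})

test_that("closeness centrality matches hand-computed values", {
  path_tom <- diag(3)
  path_tom[1, 2] <- path_tom[2, 1] <- 0.5
  path_tom[2, 3] <- path_tom[3, 2] <- 0.5
  dimnames(path_tom) <- list(c("A", "B", "C"), c("A", "B", "C"))
  g <- tom_graph(path_tom, 0.1)
  cc <- tf_centrality(g, c("A", "B"))
  expect_equal(unname(cc[["B"]]), 1.0)
  expect_equal(unname(cc[["A"]]), 2 / 3)

  star <- diag(5)
  star[1, 2:5] <- star[2:5, 1] <- 0.5
  dimnames(star) <- list(paste0("n", 1:5), paste0("n", 1:5))
  gs <- tom_graph(star, 0.1)
  expect_equal(unname(tf_centrality(gs, "n1")[["n1"]]), 1.0)
  # leaves of the star are automorphic: equal closeness
  leaf <- tf_centrality(gs, paste0("n", 2:5))
  expect_equal(length(unique(round(leaf, 12))), 1)
  expect_true(all(leaf >= 0 & leaf <= 1))

  iso <- diag(2)
  dimnames(iso) <- list(c("x", "y"), c("x", "y"))
  expect_equal(unname(tf_centrality(tom_graph(iso, 0.1), "x")[["x"]]), 0)
  expect_error(tf_centrality(g, "nope"), "universe")
})

test_that("cross-module weights follow the stated normalization", {
  tom <- diag(4)
  tom[1, 3] <- tom[3, 1] <- 0.5   # one edge between the modules
  genes <- c("a1", "a2", "b1", "b2")
  dimnames(tom) <- list(genes, genes)
  g <- tom_graph(tom, 0.1)
  mods <- setNames(c("M1", "M1", "M2", "M2"), genes)
  cm <- cross_module_connections(g, mods)
  expect_equal(cm$pairs$weight[cm$pairs$module_a == "M1"], 1 / 2)
  # doubling module M1 with unconnected genes halves the weight
  tom2 <- diag(6)
  tom2[1, 5] <- tom2[5, 1] <- 0.5
  genes2 <- c("a1", "a2", "a3", "a4", "b1", "b2")
  dimnames(tom2) <- list(genes2, genes2)
  mods2 <- setNames(c(rep("M1", 4), "M2", "M2"), genes2)
  cm2 <- cross_module_connections(tom_graph(tom2, 0.1), mods2)
  expect_equal(cm2$pairs$weight[cm2$pairs$module_a == "M1"], 1 / 4)
  # no inter-module edge: zero weights
  tom3 <- diag(4)
  tom3[1, 2] <- tom3[2, 1] <- 0.9
  dimnames(tom3) <- list(genes, genes)
  cm3 <- cross_module_connections(tom_graph(tom3, 0.1), mods)
  expect_true(all(cm3$pairs$weight == 0))
  # unassigned genes are excluded, with a message
  mods4 <- mods
  mods4[["b2"]] <- "unassigned"
  expect_message(cross_module_connections(g, mods4), "unassigned")
})

test_that("the whole network pipeline recovers planted modules", {
  ms <- simulate_module_expression(
    module_sim_config(n_modules = 3, genes_per_module = 80,
                      n_samples = 400, within_cor = 0.9, seed = 99))
  tom <- tom_similarity(soft_adjacency(ms$expr, soft_power = 14))
  mods <- detect_modules(tom, network_config(min_module_size = 60))
  expect_gte(adjusted_rand_index(mods, ms$modules), 0.9)
  g <- tom_graph(tom, 0.01)
  expect_gte(components_vs_modules(g, mods), 0.9)
})
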