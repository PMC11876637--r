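#' Configuration for the weighted co-expression network
#'
#' @param soft_power soft-threshold exponent applied to the correlation
#'   (default 14, a typical choice after a scale-free topology fit on
#'   pseudobulk profiles).
#' @param signed use a signed network (`((1 + cor)/2)^power`) instead of
#'   the unsigned default (`|cor|^power`)?
#' @param tom_graph_threshold keep graph edges with TOM strictly above this
#'   (default 0.01).
#' @param min_module_size smallest gene count for a detected module
#'   (default 75).
#' @param eigengene_connectivity_cutoff Spearman correlation at or above
#'   which a TF counts as connected to a module eigengene (default 0.01).
#' @param seed integer seed (used by stochastic downstream consumers).
#' @return a `network_config` list.
#' @export
network_config <- function(soft_power = 14, signed = FALSE,
                           tom_graph_threshold = 0.01,
                           min_module_size = 75L,
                           eigengene_connectivity_cutoff = 0.01,
                           seed = 1L) {
  check_scalar_num(soft_power, "soft_power", lower = 1)
  check_scalar_num(tom_graph_threshold, "tom_graph_threshold",
                   lower = 0, upper = 1 - 1e-12)
  min_module_size <- check_count(min_module_size, "min_module_size")
  structure(list(soft_power = soft_power, signed = isTRUE(signed),
                 tom_graph_threshold = tom_graph_threshold,
                 min_module_size = min_module_size,
                 eigengene_connectivity_cutoff =
                   eigengene_connectivity_cutoff,
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Soft-threshold adjacency from expression
#'
#' Unsigned: `|cor(i, j)|^power`; signed: `((1 + cor(i, j))/2)^power`.
#' The diagonal is recorded as 1 but excluded from connectivity sums in
#' [tom_similarity()].
#'
#' @param expr sample x gene matrix; at least 3 samples, no constant gene.
#' @param config a [network_config()] (or use `soft_power`/`signed`
#'   directly).
#' @param soft_power,signed overrides for the config values.
#' @return symmetric gene x gene adjacency in [0, 1] with unit diagonal.
#' @export
soft_adjacency <- function(expr, config = network_config(),
                           soft_power = config$soft_power,
                           signed = config$signed) {
  expr <- as_dense(expr)
  if (nrow(expr) < 3L) stopf("need at least 3 samples")
  sdv <- apply(expr, 2, sd)
  if (any(sdv == 0))
    stopf("constant gene '%s'", colnames(expr)[which(sdv == 0)[1]])
  cc <- cor(expr)
  a <- if (signed) ((1 + cc) / 2)^soft_power else abs(cc)^soft_power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_{j != i} a_ij` and the sum over shared
#' neighbours `u != i, j`; `TOM_ii = 1` by convention. Values stay in
#' [0, 1] for adjacency in [0, 1].
#'
#' @param adjacency symmetric gene x gene matrix in [0, 1].
#' @return symmetric gene x gene TOM with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  a <- as_dense(adjacency)
  if (nrow(a) != ncol(a) || !isSymmetric(unname(a), tol = 1e-8))
    stopf("adjacency must be square and symmetric")
  if (any(a < 0 | a > 1)) stopf("adjacency entries must lie in [0, 1]")
  diag(a) <- 0
  shared <- a %*% a               # diag(a)=0 drops the u = i and u = j terms
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`; the tree is cut
#' at the height (scanned over the midpoints between successive merge
#' heights) that maximizes the number of clusters with at least
#' `min_module_size` genes; ties prefer the higher cut, so peripheral
#' genes join their module rather than being stranded. Clusters below the
#' minimum size are labeled `"unassigned"`; modules are named `"M1"`,
#' `"M2"`, ... in decreasing size order.
#'
#' @param tom TOM from [tom_similarity()].
#' @param config a [network_config()]; `min_module_size` is used.
#' @return named character vector: gene -> module label.
#' @export
detect_modules <- function(tom, config = network_config()) {
  min_size <- config$min_module_size
  genes <- colnames(tom) %||% sprintf("g%05d", seq_len(ncol(tom)))
  if (ncol(tom) < min_size) {
    warnf("fewer genes (%d) than min_module_size (%d): all unassigned",
          ncol(tom), min_size)
    return(setNames(rep("unassigned", ncol(tom)), genes))
  }
  hc <- hclust(as.dist(1 - tom), method = "average")
  hts <- sort(unique(hc$height))
  cuts <- c((c(0, hts[-length(hts)]) + hts) / 2, max(hts) + 1e-6)
  best_h <- cuts[1]; best_n <- -1L
  for (h in cuts) {
    grp <- cutree(hc, h = h)
    n_big <- sum(table(grp) >= min_size)
    if (n_big >= best_n) { best_n <- n_big; best_h <- h }
  }
  grp <- cutree(hc, h = best_h)
  sizes <- table(grp)
  big <- names(sizes)[sizes >= min_size]
  big <- big[order(-sizes[big], as.integer(big))]
  lab <- setNames(rep("unassigned", length(grp)), genes)
  for (i in seq_along(big)) lab[grp == as.integer(big[i])] <- paste0("M", i)
  lab
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' module's standardized expression (one score per sample), sign-aligned
#' so its mean correlation with the module's genes is positive. A module
#' of one gene yields that gene's standardized profile.
#'
#' @param expr sample x gene matrix.
#' @param modules gene -> module label vector ("unassigned" is skipped).
#' @return sample x module matrix of eigengene values.
#' @export
module_eigengenes <- function(expr, modules) {
  expr <- as_dense(expr)
  mods <- setdiff(unique(modules), "unassigned")
  if (!length(mods)) stopf("no assigned module")
  eg <- sapply(mods, function(m) {
    g <- names(modules)[modules == m]
    x <- scale(expr[, g, drop = FALSE])
    if (length(g) == 1L) return(drop(x))
    sv <- svd(x, nu = 1, nv = 0)
    e <- drop(sv$u[, 1])
    if (mean(cor(e, x)) < 0) e <- -e
    e
  })
  rownames(eg) <- rownames(expr)
  eg
}

#' TF-class connectivity to module eigengenes
#'
#' For each TF class and module, counts the class's TF genes whose
#' Spearman correlation with the module eigengene is at or above the
#' cutoff.
#'
#' @param expr sample x gene matrix containing the TF genes.
#' @param eigengenes sample x module matrix from [module_eigengenes()].
#' @param tf_classes named character vector: TF gene -> class.
#' @param cutoff Spearman correlation cutoff (default 0.01).
#' @return class x module integer count matrix.
#' @export
tf_eigengene_connectivity <- function(expr, eigengenes, tf_classes,
                                      cutoff = 0.01) {
  expr <- as_dense(expr)
  tfs <- names(tf_classes)
  missing <- setdiff(tfs, colnames(expr))
  if (length(missing))
    stopf("TF gene '%s' not in expression matrix", missing[1])
  sp <- cor(expr[, tfs, drop = FALSE], eigengenes, method = "spearman")
  classes <- sort(unique(tf_classes))
  out <- matrix(0L, length(classes), ncol(eigengenes),
                dimnames = list(classes, colnames(eigengenes)))
  for (cl in classes) {
    rows <- sp[tf_classes == cl, , drop = FALSE]
    out[cl, ] <- colSums(rows >= cutoff)
  }
  out
}

#' Thresholded TOM graph and its connected components
#'
#' Builds the undirected weighted graph with an edge (i, j) whenever
#' `TOM_ij > threshold`, then computes connected components (isolated
#' genes are singleton components).
#'
#' @param tom TOM matrix.
#' @param threshold edge threshold (default 0.01).
#' @return a `tom_graph` list: `edges` (data frame `gene_a`, `gene_b`,
#'   `weight`), `components` (named integer vector gene -> component id),
#'   `graph` (the igraph object), `threshold`.
#' @export
tom_graph <- function(tom, threshold = 0.01) {
  genes <- colnames(tom) %||% sprintf("g%05d", seq_len(ncol(tom)))
  ut <- upper.tri(tom)
  keep <- ut & tom > threshold
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                      weight = tom[keep])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = genes))
  comp <- igraph::components(g)$membership
  structure(list(edges = edges, components = comp[genes], graph = g,
                 threshold = threshold),
            class = "tom_graph")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement under the permutation model,
#' computed from the contingency table of the two labelings. When both
#' partitions are a single cluster (or the index is otherwise degenerate
#' with zero denominator) the agreement is perfect and 1 is returned.
#'
#' @param x,y label vectors over the same items.
#' @return adjusted Rand index in [-1, 1].
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) stopf("labelings must cover the same items")
  tab <- table(x, y)
  n <- length(x)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Agreement between graph components and module membership
#'
#' @param graph a `tom_graph` (or a named component vector).
#' @param modules gene -> module label vector over the same genes.
#' @return adjusted Rand index.
#' @export
components_vs_modules <- function(graph, modules) {
  comp <- if (inherits(graph, "tom_graph")) graph$components else graph
  if (!setequal(names(comp), names(modules)))
    stopf("components and modules must cover the same genes")
  adjusted_rand_index(comp[names(modules)], modules)
}

#' Closeness centrality of TF genes within their components
#'
#' For a TF in a component of size `n_c`, closeness is
#' `(n_c - 1) / sum(shortest-path distances)` on the unweighted graph
#' restricted to that component; an isolated TF has closeness 0. Values
#' lie in [0, 1].
#'
#' @param graph a `tom_graph`.
#' @param tf_genes character vector of TF gene ids (must be graph nodes).
#' @return named numeric vector TF -> closeness.
#' @export
tf_centrality <- function(graph, tf_genes) {
  stopifnot(inherits(graph, "tom_graph"))
  nodes <- names(graph$components)
  missing <- setdiff(tf_genes, nodes)
  if (length(missing))
    stopf("TF gene '%s' not in the gene universe", missing[1])
  out <- setNames(numeric(length(tf_genes)), tf_genes)
  comp <- graph$components
  for (tf in tf_genes) {
    members <- nodes[comp == comp[tf]]
    if (length(members) == 1L) { out[tf] <- 0; next }
    d <- igraph::distances(graph$graph, v = tf, to = members,
                           weights = NA)
    out[tf] <- (length(members) - 1) / sum(d)
  }
  out
}

#' Cross-module connection weights
#'
#' For gene `g` in module `M(g)`, counts its direct neighbours in every
#' module `M'`, normalizes by `|M(g)|`, and sums over the genes of each
#' module: `weight(M, M') = sum_{g in M} n_g(M') / |M|`. The reported
#' inter-module weight is the upper-triangle entry of this aggregated
#' matrix (the diagonal is discarded). Unassigned genes are excluded (a
#' message reports how many).
#'
#' @param graph a `tom_graph`.
#' @param modules gene -> module label vector.
#' @return list: `weights` (module x module aggregated matrix with zero
#'   diagonal), `pairs` (data frame `module_a`, `module_b`, `weight` from
#'   the upper triangle).
#' @export
cross_module_connections <- function(graph, modules) {
  stopifnot(inherits(graph, "tom_graph"))
  unas <- sum(modules == "unassigned")
  if (unas > 0)
    message(sprintf("excluding %d unassigned genes", unas))
  keep <- names(modules)[modules != "unassigned"]
  mods <- sort(unique(modules[keep]))
  sizes <- table(factor(modules[keep], levels = mods))
  W <- matrix(0, length(mods), length(mods),
              dimnames = list(mods, mods))
  adj <- graph$edges
  both <- adj$gene_a %in% keep & adj$gene_b %in% keep
  adj <- adj[both, , drop = FALSE]
  for (i in seq_len(nrow(adj))) {
    ga <- adj$gene_a[i]; gb <- adj$gene_b[i]
    ma <- modules[[ga]]; mb <- modules[[gb]]
    # edge seen from each endpoint: neighbour count normalized by the
    # size of the endpoint's own module
    W[ma, mb] <- W[ma, mb] + 1 / sizes[[ma]]
    W[mb, ma] <- W[mb, ma] + 1 / sizes[[mb]]
  }
  diag(W) <- 0
  idx <- which(upper.tri(W), arr.ind = TRUE)
  pairs <- data.frame(module_a = mods[idx[, 1]], module_b = mods[idx[, 2]],
                      weight = W[upper.tri(W)])
  list(weights = W, pairs = pairs)
}
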