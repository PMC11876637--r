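#' Ensemble configuration for the co-occurrence cell-type tree
#'
#' @param n_iterations number of perturbed clusterings (default 1000).
#' @param downsample_fraction fraction of highly variable genes sampled
#'   (without replacement) in each iteration, in (0, 1] (default 0.85).
#' @param fc_threshold highly-variable-gene fold-change threshold: max
#'   cluster value over mean of the remaining clusters (default 1.5).
#' @param height_range interval from which the tree-cut height is drawn
#'   uniformly each iteration, within [0, 2] for correlation distances
#'   (default c(0.65, 0.95)).
#' @param linkage hierarchical clustering linkage (default "average").
#' @param correlation correlation method (default "pearson").
#' @param log1p correlate on `log1p` of the profiles? Variance
#'   stabilization conventional for correlation trees on normalized
#'   pseudobulk; set `FALSE` for already-transformed input.
#' @param seed integer seed.
#' @return an `ensemble_config` list.
#' @export
ensemble_config <- function(n_iterations = 1000L, downsample_fraction = 0.85,
                            fc_threshold = 1.5,
                            height_range = c(0.65, 0.95),
                            linkage = "average", correlation = "pearson",
                            log1p = TRUE, seed = 1L) {
  n_iterations <- check_count(n_iterations, "n_iterations")
  check_scalar_num(downsample_fraction, "downsample_fraction",
                   lower = 0, upper = 1, strict_lower = TRUE)
  if (length(height_range) != 2L || height_range[1] > height_range[2] ||
      height_range[1] < 0 || height_range[2] > 2)
    stopf("`height_range` must be an increasing pair within [0, 2]")
  structure(list(n_iterations = n_iterations,
                 downsample_fraction = downsample_fraction,
                 fc_threshold = fc_threshold,
                 height_range = height_range, linkage = linkage,
                 correlation = correlation, log1p = isTRUE(log1p),
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Select highly variable genes by top-cluster fold change
#'
#' A gene is kept when its maximum pseudobulk value divided by the mean of
#' the remaining clusters exceeds `fc_threshold`. Genes expressed in
#' exactly one cluster (denominator 0, numerator > 0) are kept; all-zero
#' genes are dropped silently.
#'
#' @param pb a `pseudobulk_matrix` or profile x gene matrix of normalized
#'   values.
#' @param fc_threshold fold-change threshold (default 1.5).
#' @return character vector of kept gene ids.
#' @export
hvg_select <- function(pb, fc_threshold = 1.5) {
  mat <- if (inherits(pb, "pseudobulk_matrix")) pb$normalized else as_dense(pb)
  if (nrow(mat) < 2L) stopf("need at least 2 clusters")
  n <- nrow(mat)
  mx <- apply(mat, 2, max)
  rest_mean <- (colSums(mat) - mx) / (n - 1)
  fc <- ifelse(rest_mean == 0, ifelse(mx > 0, Inf, 0), mx / rest_mean)
  colnames(mat)[fc > fc_threshold]
}

#' Ensemble co-occurrence of cell types
#'
#' Runs `n_iterations` perturbed hierarchical clusterings of the cell-type
#' profiles: each iteration samples `ceil(downsample_fraction * |HVG|)`
#' highly variable genes without replacement, correlates cell types on
#' those genes, clusters on distance `1 - correlation`, cuts the tree at a
#' height drawn uniformly from `height_range`, and counts each pair of
#' cell types falling in the same cut cluster. The co-occurrence matrix is
#' the pair count divided by `n_iterations`.
#'
#' @param pb a `pseudobulk_matrix` or cell-type x gene matrix.
#' @param config an [ensemble_config()].
#' @param genes optional gene set to use; default: [hvg_select()] with the
#'   config's threshold.
#' @return a `cooccurrence_result` list: `cell_types`, `matrix` (symmetric,
#'   unit diagonal, entries in [0, 1]), `config`.
#' @export
ensemble_cooccurrence <- function(pb, config = ensemble_config(),
                                  genes = NULL) {
  mat <- if (inherits(pb, "pseudobulk_matrix")) pb$normalized else as_dense(pb)
  if (nrow(mat) < 3L) stopf("need at least 3 cell types")
  if (is.null(genes)) genes <- hvg_select(mat, config$fc_threshold)
  if (length(genes) < 10L)
    stopf("need at least 10 highly variable genes (got %d)", length(genes))
  mat <- mat[, genes, drop = FALSE]
  if (config$log1p) mat <- log1p(mat)
  csd <- apply(mat, 1, sd)
  if (any(csd == 0))
    stopf("constant profile for cell type '%s'",
          rownames(mat)[which(csd == 0)[1]])
  types <- rownames(mat)
  k <- length(types)
  m <- ceiling(config$downsample_fraction * length(genes))
  cooc <- matrix(0, k, k, dimnames = list(types, types))
  with_seed(config$seed, {
    for (it in seq_len(config$n_iterations)) {
      g <- sample.int(length(genes), m)
      cc <- cor(Matrix::t(mat[, g, drop = FALSE]),
                method = config$correlation)
      hc <- hclust(as.dist(1 - cc), method = config$linkage)
      h <- runif(1, config$height_range[1], config$height_range[2])
      grp <- cutree(hc, h = h)
      same <- outer(grp, grp, "==")
      cooc <- cooc + same
    }
  })
  cooc <- cooc / config$n_iterations
  diag(cooc) <- 1
  structure(list(cell_types = types, matrix = cooc, config = config),
            class = "cooccurrence_result")
}

#' @export
print.cooccurrence_result <- function(x, ...) {
  cat(sprintf("cooccurrence_result: %d cell types, %d iterations\n",
              length(x$cell_types), x$config$n_iterations))
  invisible(x)
}

#' Consensus cell-type tree from a co-occurrence matrix
#'
#' Hierarchically clusters the co-occurrence matrix on distance
#' `1 - co-occurrence` with the ensemble's linkage; branch lengths come
#' from the merge heights.
#'
#' @param result a `cooccurrence_result`.
#' @param newick_file optional path; when given, the tree is also written
#'   in Newick format.
#' @return an `hclust` tree with leaves = cell types.
#' @export
consensus_tree <- function(result, newick_file = NULL) {
  stopifnot(inherits(result, "cooccurrence_result"))
  m <- result$matrix
  if (!isSymmetric(unname(m), tol = 1e-12) || any(m < 0 | m > 1))
    stopf("co-occurrence matrix must be symmetric with entries in [0, 1]")
  hc <- hclust(as.dist(1 - m), method = result$config$linkage)
  if (!is.null(newick_file))
    ape::write.tree(ape::as.phylo(hc), file = newick_file)
  hc
}
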