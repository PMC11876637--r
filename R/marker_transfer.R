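# cross-species marker transfer: subset source-species cluster markers by
# fold change, map them through one-to-one orthologs, and score the
# resulting gene sets per cell in the target species with a binned-control
# gene-set score.

#' Transfer cluster markers through a one-to-one ortholog map
#'
#' Retains marker rows with `fold_change >= fc_min`, maps surviving genes
#' to the target species through the one-to-one ortholog map (markers
#' without an ortholog are dropped; a message reports how many), and
#' deduplicates each cluster's set. Clusters whose set ends up empty are
#' omitted with a warning.
#'
#' @param markers data frame with columns `cluster`, `gene`,
#'   `fold_change`.
#' @param ortholog_map data frame with columns `source`, `target`;
#'   strictly one-to-one (duplicates on either side are an error listing
#'   the offenders).
#' @param fc_min minimum fold change (default 1), applied on whatever
#'   scale the source atlas reports.
#' @return named list: cluster -> character vector of target gene ids.
#' @export
transfer_markers <- function(markers, ortholog_map, fc_min = 1) {
  if (!all(c("cluster", "gene", "fold_change") %in% names(markers)))
    stopf("`markers` needs columns cluster, gene, fold_change")
  if (!all(c("source", "target") %in% names(ortholog_map)))
    stopf("`ortholog_map` needs columns source, target")
  if (any(is.na(markers$fold_change)))
    stopf("fold_change must be present for all rows")
  dup_s <- unique(ortholog_map$source[duplicated(ortholog_map$source)])
  dup_t <- unique(ortholog_map$target[duplicated(ortholog_map$target)])
  if (length(dup_s) || length(dup_t))
    stopf("ortholog map is not one-to-one (duplicated: %s)",
          paste(c(dup_s, dup_t), collapse = ", "))
  kept <- markers[markers$fold_change >= fc_min, , drop = FALSE]
  map <- setNames(ortholog_map$target, ortholog_map$source)
  unmapped <- sum(!kept$gene %in% names(map))
  if (unmapped > 0)
    message(sprintf("dropping %d markers without a one-to-one ortholog",
                    unmapped))
  kept <- kept[kept$gene %in% names(map), , drop = FALSE]
  sets <- lapply(split(kept$gene, kept$cluster),
                 function(g) unique(unname(map[g])))
  empty <- names(sets)[lengths(sets) == 0L]
  for (cl in setdiff(unique(markers$cluster), names(sets)))
    empty <- c(empty, cl)
  if (length(empty))
    warnf("cluster(s) with no surviving markers omitted: %s",
          paste(sort(empty), collapse = ", "))
  sets[lengths(sets) > 0L]
}

#' Log-normalize per-cell counts
#'
#' Scales each cell to a common total count and applies `log1p`; the input
#' the gene-set scorer expects.
#'
#' @param counts cell x gene count matrix (sparse or dense), or a
#'   `labeled_counts` object.
#' @param target_sum per-cell total after scaling; default: median of the
#'   observed cell totals.
#' @return dense cell x gene matrix of `log1p` normalized expression.
#' @export
log_normalize_cells <- function(counts, target_sum = NULL) {
  if (inherits(counts, "labeled_counts")) counts <- counts$counts
  tot <- Matrix::rowSums(counts)
  if (is.null(target_sum)) target_sum <- median(tot[tot > 0])
  tot[tot == 0] <- 1
  norm <- as_dense(counts) / tot * target_sum
  log1p(norm)
}

#' Binned-control gene-set score per cell
#'
#' Genes with nonzero total expression are ranked by their dataset-wide
#' mean expression and split into `n_bins` equal-size bins (all-zero genes
#' take no part in binning, so padding the matrix cannot perturb the
#' control draw); for each set gene, `ctrl_per_gene` control
#' genes are sampled (seeded, without replacement) from its bin, excluding
#' set genes. The score of a cell is its mean expression over the set
#' minus its mean expression over the pooled control genes. If no control
#' gene is available (e.g. the set is the whole matrix) the dataset-wide
#' per-cell mean is used as the reference, so the score is approximately
#' zero.
#'
#' @param expr cell x gene matrix of log-normalized expression (see
#'   [log_normalize_cells()]).
#' @param gene_set character vector; at least one gene must be present in
#'   `expr`.
#' @param n_bins number of expression bins (default 25).
#' @param ctrl_per_gene control genes sampled per set gene (default 50).
#' @param seed integer seed for the control draw.
#' @return named numeric vector: cell -> score.
#' @export
score_cells <- function(expr, gene_set, n_bins = 25L, ctrl_per_gene = 50L,
                        seed = 1L) {
  expr <- as_dense(expr)
  set_genes <- intersect(gene_set, colnames(expr))
  if (!length(set_genes)) stopf("no gene of the set is in the matrix")
  # binning universe: genes with nonzero total expression, so padding a
  # matrix with all-zero genes never changes the control pools
  tot <- colSums(expr)
  universe <- colnames(expr)[tot > 0]
  if (!length(universe)) universe <- colnames(expr)
  mu <- colMeans(expr[, universe, drop = FALSE])
  # equal-size bins over the mean-expression ranking
  rk <- rank(mu, ties.method = "first")
  bin <- ceiling(rk / length(mu) * n_bins)
  names(bin) <- universe
  ctrl <- with_seed(seed, {
    picks <- lapply(set_genes, function(g) {
      if (!g %in% names(bin)) return(character(0))
      pool <- names(bin)[bin == bin[[g]]]
      pool <- setdiff(pool, set_genes)
      if (!length(pool)) return(character(0))
      pool[sample.int(length(pool), min(ctrl_per_gene, length(pool)))]
    })
    unique(unlist(picks))
  })
  set_mean <- rowMeans(expr[, set_genes, drop = FALSE])
  ref_mean <- if (length(ctrl))
    rowMeans(expr[, ctrl, drop = FALSE]) else rowMeans(expr)
  setNames(set_mean - ref_mean, rownames(expr))
}

#' Score several transferred marker sets at once
#'
#' @param expr cell x gene log-normalized matrix.
#' @param gene_sets named list of gene sets (e.g. from
#'   [transfer_markers()]).
#' @param ... passed to [score_cells()].
#' @return cell x set score matrix.
#' @export
score_gene_sets <- function(expr, gene_sets, ...) {
  sapply(gene_sets, function(gs) score_cells(expr, gs, ...))
}

#' Mean gene-set score per cluster
#'
#' @param scores per-cell score vector (or cell x set matrix).
#' @param clusters cluster label per cell, same order as the scores.
#' @return cluster x set matrix (or named vector) of arithmetic means.
#' @export
cluster_score_summary <- function(scores, clusters) {
  if (is.matrix(scores)) {
    if (nrow(scores) != length(clusters))
      stopf("cluster labels must cover all cells")
    agg <- apply(scores, 2, function(s) tapply(s, clusters, mean))
    return(agg)
  }
  if (length(scores) != length(clusters))
    stopf("cluster labels must cover all cells")
  tapply(scores, clusters, mean)
}
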