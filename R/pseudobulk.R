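#' Aggregate single cells into per-label pseudobulk sums
#'
#' Sums raw counts over all cells sharing a label (typically the cell
#' cluster), yielding one profile per label. Labels with zero cells do not
#' appear in the output.
#'
#' @param x a `labeled_counts` object, or a cell x gene matrix.
#' @param by label per cell. For a `labeled_counts` object this may be the
#'   name of a metadata column (default `"cluster"`); for a plain matrix it
#'   must be a vector of length `nrow(x)`.
#' @return label x gene matrix of summed counts (base matrix).
#' @export
aggregate_counts <- function(x, by = "cluster") {
  if (inherits(x, "labeled_counts")) {
    counts <- x$counts
    if (is.character(by) && length(by) == 1L) {
      if (!by %in% names(x$cells))
        stopf("no metadata column '%s'", by)
      by <- x$cells[[by]]
    }
  } else {
    counts <- x
  }
  if (length(by) != nrow(counts))
    stopf("`by` must label every cell (%d labels for %d cells)",
          length(by), nrow(counts))
  miss <- which(is.na(by) | by == "")
  if (length(miss))
    stopf("cell '%s' has no label",
          rownames(counts)[miss[1]] %||% as.character(miss[1]))
  f <- factor(by)
  ind <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f),
                              x = 1, dims = c(length(f), nlevels(f)))
  agg <- as.matrix(Matrix::t(ind) %*% counts)
  rownames(agg) <- levels(f)
  colnames(agg) <- colnames(counts)
  agg
}

#' Median-of-ratios pseudobulk normalization
#'
#' Computes one size factor per pseudobulk profile by the median-of-ratios
#' estimator: for each reference gene (nonzero in every profile), the ratio
#' of its count to its geometric mean across profiles; the size factor is
#' the per-profile median of these ratios, rescaled so the factors have
#' geometric mean 1. Normalized values are the raw sums divided by the
#' factor, optionally rescaled to counts per million.
#'
#' If no gene is nonzero in every profile, falls back to total-count
#' scaling with a warning.
#'
#' @param sums label x gene matrix of summed counts (from
#'   [aggregate_counts()]).
#' @param per_million also rescale each normalized profile to sum
#'   1e6 / size-factor units? Default `FALSE`: plain size-factor division.
#' @return a `pseudobulk_matrix` list: `clusters`, `genes`, `raw_sums`,
#'   `size_factors`, `normalized`.
#' @export
normalize_pseudobulk <- function(sums, per_million = FALSE) {
  sums <- as_dense(sums)
  if (nrow(sums) < 1L) stopf("need at least one profile")
  if (nrow(sums) == 1L) {
    sf <- setNames(1, rownames(sums))
  } else {
    ref <- colSums(sums > 0) == nrow(sums)
    if (!any(ref)) {
      warnf("no gene is nonzero in every profile; falling back to total-count scaling")
      sf <- rowSums(sums)
      sf <- sf / exp(mean(log(sf)))
    } else {
      logref <- log(sums[, ref, drop = FALSE])
      loggeo <- colMeans(logref)
      sf <- apply(sweep(logref, 2, loggeo, "-"), 1, median)
      sf <- exp(sf - mean(sf))        # geometric mean 1
    }
    names(sf) <- rownames(sums)
  }
  normalized <- sweep(sums, 1, sf, "/")
  if (per_million) {
    rs <- rowSums(normalized)
    rs[rs == 0] <- 1
    normalized <- sweep(normalized, 1, rs, "/") * 1e6
  }
  structure(list(clusters = rownames(sums), genes = colnames(sums),
                 raw_sums = sums, size_factors = sf,
                 normalized = normalized),
            class = "pseudobulk_matrix")
}

#' @export
print.pseudobulk_matrix <- function(x, ...) {
  cat(sprintf("pseudobulk_matrix: %d profiles x %d genes\n",
              length(x$clusters), length(x$genes)))
  cat("size factors:", paste(sprintf("%s=%.3f", x$clusters,
                                     x$size_factors), collapse = ", "), "\n")
  invisible(x)
}

#' Coefficient-of-variation gene filter
#'
#' Computes per-gene CV (sample standard deviation over mean) across
#' pseudobulk profiles and keeps genes with CV strictly above the
#' threshold. Genes with mean 0 have no defined CV and are excluded from
#' the ranking.
#'
#' @param pb a `pseudobulk_matrix`, or a profile x gene numeric matrix of
#'   normalized values.
#' @param threshold keep genes with CV > threshold (default 1).
#' @return a `cv_filter_result` list: `kept` (gene ids), `cv` (named CV
#'   vector over genes with defined CV), `threshold`.
#' @export
cv_filter <- function(pb, threshold = 1) {
  mat <- if (inherits(pb, "pseudobulk_matrix")) pb$normalized else as_dense(pb)
  if (nrow(mat) < 2L) stopf("CV undefined with fewer than 2 profiles")
  mu <- colMeans(mat)
  sdv <- apply(mat, 2, sd)
  ok <- mu > 0
  cv <- sdv[ok] / mu[ok]
  names(cv) <- colnames(mat)[ok]
  structure(list(kept = names(cv)[cv > threshold], cv = cv,
                 threshold = threshold),
            class = "cv_filter_result")
}
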