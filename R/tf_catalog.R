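# transcription-factor evidence pooling and class-level statistics

TF_SOURCES <- c("domain_scan_pfam", "domain_scan_panther",
                "domain_scan_superfamily", "rbh_swissprot",
                "orthogroup_model_organisms")
# priority tiers for tie-breaking: domain scans > reciprocal best hit >
# orthogroup co-membership
TF_SOURCE_PRIORITY <- c(domain_scan_pfam = 1, domain_scan_panther = 1,
                        domain_scan_superfamily = 1, rbh_swissprot = 2,
                        orthogroup_model_organisms = 3)

#' Pool transcription-factor evidence across annotation sources
#'
#' Keeps genes supported by at least `min_sources` distinct evidence
#' sources and assigns each a TF class by majority vote over its sources;
#' ties are broken by source priority (domain scans over reciprocal best
#' hits over orthogroups), and a tie at equal priority yields class
#' `"ambiguous"` (with a message).
#'
#' @param evidence data frame with columns `gene`, `source` (one of
#'   `domain_scan_pfam`, `domain_scan_panther`, `domain_scan_superfamily`,
#'   `rbh_swissprot`, `orthogroup_model_organisms`) and `class`;
#'   (gene, source) pairs must be unique.
#' @param min_sources minimum distinct sources (default 2).
#' @return data frame `gene`, `class`, `n_sources`, sorted by gene.
#' @export
pool_tf_evidence <- function(evidence, min_sources = 2L) {
  if (!all(c("gene", "source", "class") %in% names(evidence)))
    stopf("`evidence` needs columns gene, source, class")
  bad <- setdiff(unique(evidence$source), TF_SOURCES)
  if (length(bad)) stopf("unknown evidence source '%s'", bad[1])
  if (anyDuplicated(evidence[, c("gene", "source")]))
    stopf("(gene, source) pairs must be unique")
  if (any(!nzchar(evidence$class))) stopf("class labels must be nonempty")
  evidence <- evidence[order(evidence$gene, evidence$source), ]
  keep_rows <- lapply(split(evidence, evidence$gene), function(df) {
    if (length(unique(df$source)) < min_sources) return(NULL)
    votes <- table(df$class)
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) cls <- top
    else {
      prio <- sapply(top, function(cl)
        min(TF_SOURCE_PRIORITY[df$source[df$class == cl]]))
      best <- top[prio == min(prio)]
      if (length(best) == 1L) cls <- best
      else {
        message(sprintf("gene %s: class tie at equal priority -> ambiguous",
                        df$gene[1]))
        cls <- "ambiguous"
      }
    }
    data.frame(gene = df$gene[1], class = cls,
               n_sources = length(unique(df$source)))
  })
  keep_rows <- keep_rows[!vapply(keep_rows, is.null, logical(1))]
  if (!length(keep_rows))
    return(data.frame(gene = character(), class = character(),
                      n_sources = integer()))
  out <- do.call(rbind, keep_rows)
  rownames(out) <- NULL
  out[order(out$gene), ]
}

#' TF class prominence across cell clusters
#'
#' For each TF class and cluster: sum of the class's gene values in the
#' cluster divided by the number of class genes expressed (value > 0)
#' there; 0 when no class gene is expressed. With `normalize = TRUE`
#' (default) each class row is divided by its maximum, mapping it to
#' [0, 1] for display.
#'
#' @param expr cluster x gene matrix of normalized expression.
#' @param tf_classes named character vector: TF gene -> class. Every TF
#'   gene must be a column of `expr`.
#' @param normalize row-normalize by the class maximum?
#' @return class x cluster matrix; with `normalize = TRUE` the raw matrix
#'   is attached as attribute `"raw"`.
#' @export
class_prominence <- function(expr, tf_classes, normalize = TRUE) {
  expr <- as_dense(expr)
  missing <- setdiff(names(tf_classes), colnames(expr))
  if (length(missing)) stopf("TF gene '%s' not in expression", missing[1])
  classes <- sort(unique(tf_classes))
  out <- matrix(0, length(classes), nrow(expr),
                dimnames = list(classes, rownames(expr)))
  for (cl in classes) {
    g <- names(tf_classes)[tf_classes == cl]
    if (!length(g)) { warnf("class '%s' is empty; dropped", cl); next }
    sub <- expr[, g, drop = FALSE]
    tot <- rowSums(sub)
    n_expr <- rowSums(sub > 0)
    out[cl, ] <- ifelse(n_expr > 0, tot / n_expr, 0)
  }
  if (normalize) {
    raw <- out
    mx <- apply(out, 1, max)
    mx[mx == 0] <- 1
    out <- sweep(out, 1, mx, "/")
    attr(out, "raw") <- raw
  }
  out
}

#' TF class variability statistics
#'
#' Per class: the per-gene coefficient of variation across clusters
#' (sample standard deviation over mean, as in [cv_filter()]), summarized
#' as median and mean over the class's genes; plus the gene count and
#' cumulative expression of the class. Genes with mean 0 have no defined
#' CV; a class whose genes are all zero is flagged (`all_zero = TRUE`,
#' CV statistics `NA`).
#'
#' @param expr cluster x gene matrix of normalized expression (at least
#'   2 clusters).
#' @param tf_classes named character vector: TF gene -> class.
#' @return data frame `class`, `n_genes`, `total_counts`, `median_cv`,
#'   `mean_cv`, `all_zero`.
#' @export
class_cv_stats <- function(expr, tf_classes) {
  expr <- as_dense(expr)
  if (nrow(expr) < 2L) stopf("CV undefined with fewer than 2 clusters")
  missing <- setdiff(names(tf_classes), colnames(expr))
  if (length(missing)) stopf("TF gene '%s' not in expression", missing[1])
  classes <- sort(unique(tf_classes))
  rows <- lapply(classes, function(cl) {
    g <- names(tf_classes)[tf_classes == cl]
    sub <- expr[, g, drop = FALSE]
    mu <- colMeans(sub)
    sdv <- apply(sub, 2, sd)
    cv <- sdv[mu > 0] / mu[mu > 0]
    data.frame(class = cl, n_genes = length(g),
               total_counts = sum(sub),
               median_cv = if (length(cv)) median(cv) else NA_real_,
               mean_cv = if (length(cv)) mean(cv) else NA_real_,
               all_zero = length(cv) == 0L)
  })
  do.call(rbind, rows)
}
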