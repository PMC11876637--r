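#' Cross-tabulate cells by cluster and colony part
#'
#' @param cells data frame with `cluster` and `part` columns, or a
#'   `labeled_counts` object.
#' @param parts optional character vector restricting/validating the part
#'   labels; an unknown part label in `cells` raises an error.
#' @return a `composition_table`: integer cluster x part matrix.
#' @export
count_table <- function(cells, parts = NULL) {
  if (inherits(cells, "labeled_counts")) cells <- cells$cells
  if (!all(c("cluster", "part") %in% names(cells)))
    stopf("`cells` needs columns cluster and part")
  if (!is.null(parts)) {
    bad <- setdiff(unique(cells$part), parts)
    if (length(bad)) stopf("unknown part label: %s",
                           paste(bad, collapse = ", "))
    cells$part <- factor(cells$part, levels = parts)
  }
  tab <- table(cluster = cells$cluster, part = cells$part)
  out <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  class(out) <- c("composition_table", class(out))
  out
}

#' Log2 odds ratio of a cluster between two parts, with pseudocounts
#'
#' Forms the 2x2 table a = cluster in `part_a`, b = other clusters in
#' `part_a`, c = cluster in `part_b`, d = other clusters in `part_b`, and
#' returns `log2(((a+e)(d+e)) / ((b+e)(c+e)))` with pseudocount `e`
#' (Haldane-Anscombe, default 0.5). With `epsilon = 0` and a zero margin
#' the result is +/-Inf with a warning.
#'
#' @param table a `composition_table` (see [count_table()]).
#' @param cluster focal cluster label.
#' @param part_a,part_b distinct part labels.
#' @param epsilon pseudocount, >= 0.
#' @return log2 odds ratio (scalar).
#' @export
log_odds <- function(table, cluster, part_a, part_b, epsilon = 0.5) {
  cells <- composition_2x2(table, cluster, part_a, part_b)
  check_scalar_num(epsilon, "epsilon", lower = 0)
  a <- cells[["a"]]; b <- cells[["b"]]; c <- cells[["c"]]; d <- cells[["d"]]
  if (epsilon == 0 && any(cells == 0))
    warnf("zero cell with epsilon = 0: infinite log odds ratio")
  log2(((a + epsilon) * (d + epsilon)) / ((b + epsilon) * (c + epsilon)))
}

composition_2x2 <- function(table, cluster, part_a, part_b) {
  if (part_a == part_b) stopf("parts must be distinct")
  for (p in c(part_a, part_b))
    if (!p %in% colnames(table)) stopf("unknown part '%s'", p)
  if (!cluster %in% rownames(table)) stopf("unknown cluster '%s'", cluster)
  a <- table[cluster, part_a]
  b <- sum(table[, part_a]) - a
  c <- table[cluster, part_b]
  d <- sum(table[, part_b]) - c
  c(a = a, b = b, c = c, d = d)
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Exact conditional test on the table \code{rbind(c(a, b), c(c, d))}: with
#' margins fixed, the first cell is hypergeometric; the two-sided p-value
#' sums the probabilities of all outcomes no more probable than the
#' observed one (with the customary 1 + 1e-7 relative tolerance for
#' floating-point ties, as in \code{stats::fisher.test}).
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return two-sided p-value.
#' @export
fisher_p <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != floor(c(a, b, c, d))))
    stopf("cell counts must be nonnegative integers")
  m <- a + b            # row 1 total
  n <- c + d            # row 2 total
  k <- a + c            # column 1 total
  if (k == 0 || k == m + n || m == 0 || n == 0) return(1)
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, n, k)
  dobs <- dens[support == a]
  sum(dens[dens <= dobs * (1 + 1e-7)])
}

#' Per-cluster compositional enrichment between two colony parts
#'
#' For every cluster, builds the cluster-vs-rest by part_a-vs-part_b 2x2
#' table, computes the two-sided Fisher exact p on the raw counts, the
#' pseudocounted log2 odds ratio, Benjamini-Hochberg q-values across
#' clusters within this comparison, and a significance tier:
#' `"***"` for q <= 0.0005, `"**"` for q <= 0.005, `"*"` for q <= 0.05,
#' `""` otherwise. The pseudocount affects only the odds ratio, never the
#' exact test.
#'
#' @param table a `composition_table`.
#' @param part_a,part_b distinct part labels, both with at least one cell.
#' @param epsilon pseudocount for the odds ratio (default 0.5).
#' @return data frame of class `enrichment_result`: `cluster`, `part_a`,
#'   `part_b`, `a`, `b`, `c`, `d`, `epsilon`, `log2_or`, `p_value`,
#'   `q_value`, `tier`. Positive `log2_or` means enriched in `part_a`.
#' @export
fisher_enrichment <- function(table, part_a, part_b, epsilon = 0.5) {
  if (part_a == part_b) stopf("parts must be distinct")
  for (p in c(part_a, part_b)) {
    if (!p %in% colnames(table)) stopf("unknown part '%s'", p)
    if (sum(table[, p]) == 0) stopf("part '%s' has zero cells", p)
  }
  clusters <- rownames(table)
  rows <- lapply(clusters, function(cl) {
    x <- composition_2x2(table, cl, part_a, part_b)
    data.frame(cluster = cl, part_a = part_a, part_b = part_b,
               a = x[["a"]], b = x[["b"]], c = x[["c"]], d = x[["d"]],
               epsilon = epsilon,
               log2_or = log_odds(table, cl, part_a, part_b, epsilon),
               p_value = fisher_p(x[["a"]], x[["b"]], x[["c"]], x[["d"]]))
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$tier <- significance_tier(out$q_value)
  class(out) <- c("enrichment_result", class(out))
  out
}

significance_tier <- function(q) {
  ifelse(q <= 0.0005, "***",
         ifelse(q <= 0.005, "**",
                ifelse(q <= 0.05, "*", "")))
}
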