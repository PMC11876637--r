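#' Configuration for the synthetic colony atlas generator
#'
#' Describes a multi-part colony atlas: each colony part contributes
#' `cells_per_part` cells drawn from a multinomial over cell clusters, and
#' each cell's gene counts follow a gamma-Poisson (negative binomial) model
#' with cluster-specific marker genes shifted up by `marker_log_fc`.
#'
#' Part-specific composition is induced by `enrichment_map`: the baseline
#' cluster proportions are multiplied by the given factors and renormalized
#' within each part, so every part remains a proper multinomial.
#'
#' @param n_clusters number of cell clusters.
#' @param n_parts number of colony parts. Three parts are named
#'   `feeding`, `sexual`, `stolon` (the canonical colony parts of a
#'   hydractiniid colony); other counts get `part1`, `part2`, ...
#' @param cells_per_part cells sampled from each part.
#' @param n_genes number of genes.
#' @param baseline_props per-cluster baseline proportions, summing to 1.
#'   Default: uniform.
#' @param enrichment_map data frame with columns `cluster`, `part`,
#'   `factor` giving multiplicative proportion factors (all > 0). Default:
#'   empty (no planted composition effect).
#' @param marker_genes_per_cluster dedicated marker genes per cluster.
#' @param marker_log_fc natural-log fold change of a marker gene in its own
#'   cluster.
#' @param nb_dispersion negative binomial dispersion (1/size); > 0.
#' @param mean_log,sd_log log-normal parameters for baseline per-cell gene
#'   means; the defaults emulate shallow combinatorial-barcoding libraries
#'   (most genes well below one count per cell).
#' @param seed integer seed; identical seeds give bit-identical atlases.
#' @return an `atlas_sim_config` list.
#' @export
atlas_sim_config <- function(n_clusters = 20L, n_parts = 3L,
                             cells_per_part = 5000L, n_genes = 1000L,
                             baseline_props = NULL, enrichment_map = NULL,
                             marker_genes_per_cluster = 10L,
                             marker_log_fc = 1, nb_dispersion = 1,
                             mean_log = -2, sd_log = 1, seed = 1L) {
  n_clusters <- check_count(n_clusters, "n_clusters")
  n_parts <- check_count(n_parts, "n_parts")
  cells_per_part <- check_count(cells_per_part, "cells_per_part")
  n_genes <- check_count(n_genes, "n_genes")
  marker_genes_per_cluster <- check_count(marker_genes_per_cluster,
                                          "marker_genes_per_cluster",
                                          lower = 0L)
  check_scalar_num(marker_log_fc, "marker_log_fc", lower = 0)
  check_scalar_num(nb_dispersion, "nb_dispersion", lower = 0,
                   strict_lower = TRUE)
  if (is.null(baseline_props)) baseline_props <- rep(1 / n_clusters, n_clusters)
  if (length(baseline_props) != n_clusters)
    stopf("`baseline_props` must have length n_clusters (%d)", n_clusters)
  if (abs(sum(baseline_props) - 1) > 1e-9)
    stopf("`baseline_props` must sum to 1 (got %.12f)", sum(baseline_props))
  if (any(baseline_props < 0)) stopf("`baseline_props` must be nonnegative")
  if (is.null(enrichment_map))
    enrichment_map <- data.frame(cluster = character(), part = character(),
                                 factor = numeric())
  if (!all(c("cluster", "part", "factor") %in% names(enrichment_map)))
    stopf("`enrichment_map` needs columns cluster, part, factor")
  if (nrow(enrichment_map) && any(enrichment_map$factor <= 0))
    stopf("enrichment factors must be > 0")
  if (marker_genes_per_cluster * n_clusters > n_genes)
    stopf("not enough genes for %d markers per cluster",
          marker_genes_per_cluster)
  structure(list(n_clusters = n_clusters, n_parts = n_parts,
                 cells_per_part = cells_per_part, n_genes = n_genes,
                 baseline_props = baseline_props,
                 enrichment_map = enrichment_map,
                 marker_genes_per_cluster = marker_genes_per_cluster,
                 marker_log_fc = marker_log_fc,
                 nb_dispersion = nb_dispersion,
                 mean_log = mean_log, sd_log = sd_log,
                 seed = as.integer(seed)),
            class = "atlas_sim_config")
}

part_names <- function(n_parts) {
  if (n_parts == 3L) c("feeding", "sexual", "stolon")
  else paste0("part", seq_len(n_parts))
}

cluster_names <- function(n_clusters) {
  sprintf("C%02d", seq_len(n_clusters))
}

#' Per-part cluster proportions implied by an atlas configuration
#'
#' Applies the enrichment factors to the baseline proportions and
#' renormalizes within each part.
#'
#' @param config an [atlas_sim_config()].
#' @return cluster x part matrix of proportions; columns sum to 1.
#' @export
expected_part_props <- function(config) {
  stopifnot(inherits(config, "atlas_sim_config"))
  parts <- part_names(config$n_parts)
  clusters <- cluster_names(config$n_clusters)
  props <- matrix(config$baseline_props, nrow = config$n_clusters,
                  ncol = config$n_parts,
                  dimnames = list(clusters, parts))
  em <- config$enrichment_map
  for (i in seq_len(nrow(em))) {
    cl <- as.character(em$cluster[i]); pt <- as.character(em$part[i])
    if (!cl %in% clusters) stopf("enrichment_map cluster '%s' unknown", cl)
    if (!pt %in% parts) stopf("enrichment_map part '%s' unknown", pt)
    props[cl, pt] <- props[cl, pt] * em$factor[i]
  }
  props <- sweep(props, 2, colSums(props), "/")
  if (any(rowSums(props) == 0))
    stopf("cluster with zero probability in every part")
  props
}

#' Simulate a labeled colony cell atlas
#'
#' Draws cells per colony part from the renormalized multinomial over
#' clusters, then gene counts from a gamma-Poisson mixture with planted
#' cluster markers. The returned object carries the ground truth used to
#' generate it, so downstream modules can be checked against it.
#'
#' @param config an [atlas_sim_config()].
#' @return a `labeled_counts` list with elements
#'   \describe{
#'     \item{counts}{sparse cell x gene count matrix (`dgCMatrix`).}
#'     \item{cells}{data frame `cell_id`, `cluster`, `part`, `library`
#'       (one library per part).}
#'     \item{genes}{gene identifiers.}
#'     \item{truth}{list: `part_props` (cluster x part proportions),
#'       `marker_genes` (gene, cluster), `base_means`.}
#'   }
#' @export
simulate_atlas <- function(config) {
  stopifnot(inherits(config, "atlas_sim_config"))
  props <- expected_part_props(config)
  parts <- colnames(props)
  clusters <- rownames(props)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  with_seed(config$seed, {
    base_means <- exp(rnorm(config$n_genes, config$mean_log, config$sd_log))
    names(base_means) <- genes
    # dedicated marker genes, disjoint across clusters
    marker <- data.frame(gene = character(), cluster = character())
    if (config$marker_genes_per_cluster > 0L) {
      idx <- seq_len(config$marker_genes_per_cluster * config$n_clusters)
      marker <- data.frame(
        gene = genes[idx],
        cluster = rep(clusters, each = config$marker_genes_per_cluster))
    }
    cell_cluster <- character(0)
    cell_part <- character(0)
    for (p in parts) {
      draw <- sample(clusters, config$cells_per_part, replace = TRUE,
                     prob = props[, p])
      cell_cluster <- c(cell_cluster, draw)
      cell_part <- c(cell_part, rep(p, config$cells_per_part))
    }
    n_cells <- length(cell_cluster)
    cells <- data.frame(
      cell_id = sprintf("cell%06d", seq_len(n_cells)),
      cluster = cell_cluster, part = cell_part,
      library = paste0("lib_", cell_part))
    # per-cluster mean vectors: marker genes up-shifted in their own cluster
    mu_by_cluster <- matrix(rep(base_means, config$n_clusters),
                            nrow = config$n_clusters, byrow = TRUE,
                            dimnames = list(clusters, genes))
    for (i in seq_len(nrow(marker)))
      mu_by_cluster[marker$cluster[i], marker$gene[i]] <-
        mu_by_cluster[marker$cluster[i], marker$gene[i]] *
        exp(config$marker_log_fc)
    size <- 1 / config$nb_dispersion
    counts <- matrix(0L, nrow = n_cells, ncol = config$n_genes)
    for (k in clusters) {
      rows <- which(cell_cluster == k)
      if (!length(rows)) next
      counts[rows, ] <- matrix(
        rnbinom(length(rows) * config$n_genes,
                mu = rep(mu_by_cluster[k, ], each = length(rows)),
                size = size),
        nrow = length(rows))
    }
    dimnames(counts) <- list(cells$cell_id, genes)
    structure(list(counts = methods::as(methods::as(Matrix::Matrix(counts,
                                                                   sparse = TRUE),
                                                    "generalMatrix"),
                                        "CsparseMatrix"),
                   cells = cells, genes = genes,
                   truth = list(part_props = props, marker_genes = marker,
                                base_means = base_means),
                   config = config),
              class = "labeled_counts")
  })
}

#' @export
print.labeled_counts <- function(x, ...) {
  cat(sprintf("labeled_counts: %d cells x %d genes, %d clusters, %d parts\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cells$cluster)),
              length(unique(x$cells$part))))
  invisible(x)
}

#' Configuration for the correlated gene-module generator
#'
#' Genes in a module share a latent factor so that every within-module gene
#' pair has correlation `within_cor`; background genes are independent
#' noise. This emulates the block structure that co-expression module
#' detection assumes.
#'
#' @param n_modules number of planted modules.
#' @param genes_per_module genes per module.
#' @param n_samples number of samples (rows).
#' @param within_cor target pairwise correlation within a module, in [0, 1).
#' @param noise_sd marginal standard deviation of every gene.
#' @param n_background_genes independent genes with no module structure.
#' @param seed integer seed.
#' @return a `module_sim_config` list.
#' @export
module_sim_config <- function(n_modules = 4L, genes_per_module = 100L,
                              n_samples = 500L, within_cor = 0.9,
                              noise_sd = 1, n_background_genes = 0L,
                              seed = 1L) {
  n_modules <- check_count(n_modules, "n_modules")
  genes_per_module <- check_count(genes_per_module, "genes_per_module")
  n_samples <- check_count(n_samples, "n_samples", lower = 2L)
  n_background_genes <- check_count(n_background_genes, "n_background_genes",
                                    lower = 0L)
  check_scalar_num(within_cor, "within_cor", lower = 0)
  if (within_cor >= 1) stopf("`within_cor` must be < 1")
  check_scalar_num(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  structure(list(n_modules = n_modules, genes_per_module = genes_per_module,
                 n_samples = n_samples, within_cor = within_cor,
                 noise_sd = noise_sd,
                 n_background_genes = n_background_genes,
                 seed = as.integer(seed)),
            class = "module_sim_config")
}

#' Simulate expression with planted co-expression modules
#'
#' Latent-factor construction: gene j in module m is
#' `sqrt(r) * z_m + sqrt(1 - r) * e_j` scaled to `noise_sd`, with `z_m` a
#' module-specific standard normal factor, giving pairwise correlation `r`
#' within the module and 0 between modules in expectation.
#'
#' @param config a [module_sim_config()].
#' @return list with `expr` (sample x gene matrix) and `modules`
#'   (character vector per gene: `"M1"`, ..., or `"background"`), class
#'   `module_sim`.
#' @export
simulate_module_expression <- function(config) {
  stopifnot(inherits(config, "module_sim_config"))
  n_genes <- config$n_modules * config$genes_per_module +
    config$n_background_genes
  genes <- sprintf("g%05d", seq_len(n_genes))
  mods <- c(rep(paste0("M", seq_len(config$n_modules)),
                each = config$genes_per_module),
            rep("background", config$n_background_genes))
  r <- config$within_cor
  with_seed(config$seed, {
    expr <- matrix(rnorm(config$n_samples * n_genes),
                   nrow = config$n_samples)
    for (m in paste0("M", seq_len(config$n_modules))) {
      j <- which(mods == m)
      z <- rnorm(config$n_samples)
      expr[, j] <- sqrt(r) * z + sqrt(1 - r) * expr[, j]
    }
    expr <- expr * config$noise_sd
    dimnames(expr) <- list(sprintf("s%04d", seq_len(config$n_samples)), genes)
    structure(list(expr = expr, modules = setNames(mods, genes),
                   config = config),
              class = "module_sim")
  })
}

#' Simulate a species pair sharing one homologous cell type
#'
#' Builds the inputs of a cross-species marker transfer: a target-species
#' atlas (via [simulate_atlas()]), a source-species marker table whose
#' clusters mirror the target's, and a one-to-one ortholog map. The
#' homologous cluster's source markers map onto the target's planted
#' markers for that cluster; markers of the other source clusters map onto
#' random non-marker target genes, so only the homologous set carries
#' signal. A few source markers fall below the fold-change cut or lack an
#' ortholog, as in real reciprocal-best-hit maps.
#'
#' @param seed integer seed.
#' @param homolog_cluster target cluster shared between the species
#'   (default `"C03"`).
#' @param config target-species [atlas_sim_config()]; the default is a
#'   small one-part atlas sized for repeated simulation.
#' @return list: `target` (labeled_counts), `markers` (source-species
#'   marker table: `cluster`, `gene`, `fold_change`), `ortholog_map`
#'   (`source`, `target`), `homolog_cluster`.
#' @export
simulate_species_pair <- function(seed = 1L, homolog_cluster = "C03",
                                  config = NULL) {
  if (is.null(config))
    config <- atlas_sim_config(n_clusters = 5L, n_parts = 1L,
                               cells_per_part = 500L, n_genes = 300L,
                               marker_genes_per_cluster = 10L,
                               marker_log_fc = 1, seed = seed)
  target <- simulate_atlas(config)
  clusters <- cluster_names(config$n_clusters)
  if (!homolog_cluster %in% clusters)
    stopf("unknown homolog cluster '%s'", homolog_cluster)
  mk <- target$truth$marker_genes
  with_seed(seed + 1L, {
    rows <- list(); maps <- list()
    free <- setdiff(target$genes, mk$gene)   # non-marker target genes
    for (cl in clusters) {
      tgt_genes <- if (cl == homolog_cluster)
        mk$gene[mk$cluster == cl]
      else {
        pick <- sample(free, config$marker_genes_per_cluster)
        free <- setdiff(free, pick)
        pick
      }
      src <- sprintf("src_%s_%02d", cl, seq_along(tgt_genes))
      rows[[cl]] <- data.frame(cluster = cl, gene = src,
                               fold_change = runif(length(src), 1.2, 3))
      maps[[cl]] <- data.frame(source = src, target = tgt_genes)
    }
    markers <- do.call(rbind, rows)
    map <- do.call(rbind, maps)
    # realistic nuisance rows: sub-threshold markers and orphan markers
    markers <- rbind(markers,
                     data.frame(cluster = homolog_cluster,
                                gene = c("src_low", "src_orphan"),
                                fold_change = c(0.5, 2)))
    markers <- markers[sample(nrow(markers)), ]
    rownames(markers) <- rownames(map) <- NULL
    list(target = target, markers = markers, ortholog_map = map,
         homolog_cluster = homolog_cluster)
  })
}

REPEAT_CLASS_NAMES <- c(`1` = "singlet", `2` = "duplet",
                        `3` = "triplet", `4` = "quadruplet")

#' Configuration for the repeat-bearing protein generator
#'
#' @param n_proteins number of proteins.
#' @param length_range integer pair, min and max protein length.
#' @param repeat_classes named numeric vector mapping glycine-run length n
#'   (names "1".."4") to the expected (Poisson) number of planted XGnX
#'   repeats per protein.
#' @param signal_fraction fraction of proteins carrying an N/H/C signal
#'   peptide annotation.
#' @param seed integer seed.
#' @return a `protein_sim_config` list.
#' @export
protein_sim_config <- function(n_proteins = 30L, length_range = c(120L, 300L),
                               repeat_classes = c(`1` = 2, `2` = 3,
                                                  `3` = 1, `4` = 0.5),
                               signal_fraction = 0.5, seed = 1L) {
  n_proteins <- check_count(n_proteins, "n_proteins")
  if (length(length_range) != 2L || any(length_range < 1) ||
      length_range[1] > length_range[2])
    stopf("`length_range` must be an increasing positive integer pair")
  if (!length(repeat_classes) || is.null(names(repeat_classes)) ||
      !all(names(repeat_classes) %in% c("1", "2", "3", "4")))
    stopf("`repeat_classes` must be named with n in 1..4")
  if (any(repeat_classes < 0)) stopf("expected repeat counts must be >= 0")
  check_scalar_num(signal_fraction, "signal_fraction", lower = 0, upper = 1)
  structure(list(n_proteins = n_proteins,
                 length_range = as.integer(length_range),
                 repeat_classes = repeat_classes,
                 signal_fraction = signal_fraction,
                 seed = as.integer(seed)),
            class = "protein_sim_config")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
FLANKS <- c("I", "L", "V", "Y")

#' Simulate proteins with planted XGnX glycine repeats
#'
#' Plants non-overlapping X G^n X repeats (X in I/L/V/Y) into random
#' protein sequences. Filler residues immediately adjacent to a planted
#' flank are never glycine, so a planted repeat can never be silently
#' extended and the truth table is exact; elsewhere the filler uses the
#' full 20-letter alphabet, so additional chance repeats may occur (a
#' scanner must recover at least the planted spans).
#'
#' @param config a [protein_sim_config()].
#' @return list of class `protein_sim` with
#'   \describe{
#'     \item{sequences}{named character vector of protein sequences.}
#'     \item{repeats}{truth table: `protein`, `start`, `end` (0-based
#'       half-open), `n`, `class`.}
#'     \item{signals}{truth table: `protein`, `region` (N/H/C), `start`,
#'       `end` (0-based half-open).}
#'   }
#' @export
simulate_proteins <- function(config) {
  stopifnot(inherits(config, "protein_sim_config"))
  with_seed(config$seed, {
    seqs <- character(config$n_proteins)
    ids <- sprintf("prot%03d", seq_len(config$n_proteins))
    rep_rows <- list()
    sig_rows <- list()
    for (i in seq_len(config$n_proteins)) {
      L <- sample(seq(config$length_range[1], config$length_range[2]), 1L)
      ns <- integer(0)
      for (cls in names(config$repeat_classes)) {
        k <- stats::rpois(1, config$repeat_classes[[cls]])
        ns <- c(ns, rep(as.integer(cls), k))
      }
      ns <- ns[sample.int(length(ns))]      # shuffle placement order
      span_len <- ns + 2L
      k <- length(ns)
      total_gap <- L - sum(span_len)
      if (total_gap < k - 1L)
        stopf("planted repeats (total %d residues) do not fit protein of length %d",
              sum(span_len) + max(0L, k - 1L), L)
      res <- sample(AA20, L, replace = TRUE)
      starts <- integer(0)
      if (k > 0L) {
        # interior gaps >= 1 keep planted spans disjoint (flanks unshared)
        extra <- as.vector(rmultinom(1, total_gap - (k - 1L), rep(1, k + 1L)))
        gaps <- extra
        if (k > 1L) gaps[2:k] <- gaps[2:k] + 1L
        pos <- gaps[1]
        for (j in seq_len(k)) {
          starts[j] <- pos
          span <- c(sample(FLANKS, 1), rep("G", ns[j]), sample(FLANKS, 1))
          res[(pos + 1):(pos + span_len[j])] <- span
          pos <- pos + span_len[j] + gaps[j + 1]
        }
        # de-glycinate filler residues touching planted flanks
        for (j in seq_len(k)) {
          for (adj in c(starts[j], starts[j] + span_len[j] + 1L)) {
            if (adj >= 1L && adj <= L && res[adj] == "G")
              res[adj] <- sample(setdiff(AA20, "G"), 1)
          }
        }
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          protein = ids[i], start = starts, end = starts + span_len,
          n = ns, class = unname(REPEAT_CLASS_NAMES[as.character(ns)]))
      }
      if (runif(1) < config$signal_fraction) {
        n_len <- sample(2:6, 1); h_len <- sample(7:12, 1)
        c_len <- sample(3:6, 1)
        sig_rows[[length(sig_rows) + 1L]] <- data.frame(
          protein = ids[i], region = c("N", "H", "C"),
          start = c(0L, n_len, n_len + h_len),
          end = c(n_len, n_len + h_len, n_len + h_len + c_len))
      }
      seqs[i] <- paste(res, collapse = "")
    }
    names(seqs) <- ids
    empty_rep <- data.frame(protein = character(), start = integer(),
                            end = integer(), n = integer(),
                            class = character())
    empty_sig <- data.frame(protein = character(), region = character(),
                            start = integer(), end = integer())
    structure(list(sequences = seqs,
                   repeats = if (length(rep_rows))
                     do.call(rbind, rep_rows) else empty_rep,
                   signals = if (length(sig_rows))
                     do.call(rbind, sig_rows) else empty_sig,
                   config = config),
              class = "protein_sim")
  })
}
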