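test_that("atlas composition follows the configured proportions", {
  # no planted effect: every part converges to the baseline proportions
  cfg <- atlas_sim_config(n_clusters = 5, n_parts = 2,
                          cells_per_part = 10000, n_genes = 5,
                          marker_genes_per_cluster = 0, seed = 42)
  at <- simulate_atlas(cfg)
  tab <- count_table(at)
  props <- sweep(tab, 2, colSums(tab), "/")
  expect_true(all(abs(props - 0.2) < 0.02))

  # planted 4x enrichment of a 0.05-baseline cluster renormalizes
  # analytically to 0.2 / 1.15
  em <- data.frame(cluster = "C03", part = "stolon", factor = 4)
  cfg2 <- atlas_sim_config(n_clusters = 20, n_parts = 3,
                           cells_per_part = 10000, n_genes = 5,
                           marker_genes_per_cluster = 0,
                           enrichment_map = em, seed = 42)
  pp <- expected_part_props(cfg2)
  expect_equal(pp["C03", "stolon"], 0.2 / 1.15)
  expect_equal(pp["C03", "feeding"], 0.05)
  expect_equal(unname(colSums(pp)), rep(1, 3))
  at2 <- simulate_atlas(cfg2)
  tab2 <- count_table(at2)
  expect_lt(abs(tab2["C03", "stolon"] / 10000 - 0.2 / 1.15), 0.02)
})

test_that("atlas generation is seed-deterministic and validates configs", {
  cfg <- atlas_sim_config(n_clusters = 3, n_parts = 2, cells_per_part = 50,
                          n_genes = 30, seed = 7)
  a1 <- simulate_atlas(cfg)
  a2 <- simulate_atlas(cfg)
  expect_identical(as.matrix(a1$counts), as.matrix(a2$counts))
  expect_identical(a1$cells, a2$cells)

  # a cluster with zero probability in every part is rejected
  bad <- atlas_sim_config(n_clusters = 3, n_parts = 2, cells_per_part = 10,
                          n_genes = 10, baseline_props = c(0.5, 0.5, 0),
                          marker_genes_per_cluster = 0, seed = 1)
  expect_error(simulate_atlas(bad), "zero probability")
  expect_error(atlas_sim_config(baseline_props = rep(0.1, 20)), "sum to 1")
  expect_error(
    atlas_sim_config(enrichment_map = data.frame(cluster = "C01",
                                                 part = "stolon",
                                                 factor = 0)),
    "factors")
})

test_that("planted marker genes are up in their own cluster", {
  up <- c()
  for (s in 1:20) {
    cfg <- atlas_sim_config(n_clusters = 4, n_parts = 2,
                            cells_per_part = 150, n_genes = 60,
                            marker_genes_per_cluster = 3, marker_log_fc = 1,
                            seed = s)
    at <- simulate_atlas(cfg)
    pb <- aggregate_counts(at, "cluster")
    means <- sweep(pb, 1, table(at$cells$cluster)[rownames(pb)], "/")
    mk <- at$truth$marker_genes
    up <- c(up, vapply(seq_len(nrow(mk)), function(i) {
      v <- means[, mk$gene[i]]
      v[mk$cluster[i]] > max(v[setdiff(names(v), mk$cluster[i])])
    }, logical(1)))
  }
  expect_gte(mean(up), 0.95)
})

test_that("module simulation hits the target within-module correlation", {
  cfg <- module_sim_config(n_modules = 2, genes_per_module = 30,
                           n_samples = 500, within_cor = 0.9,
                           n_background_genes = 20, seed = 5)
  ms <- simulate_module_expression(cfg)
  cc <- cor(ms$expr)
  within <- function(m) {
    i <- which(ms$modules == m)
    mean(cc[i, i][upper.tri(cc[i, i])])
  }
  expect_gt(within("M1"), 0.85)
  expect_lt(within("M1"), 0.95)
  i1 <- which(ms$modules == "M1"); i2 <- which(ms$modules == "M2")
  expect_lt(mean(abs(cc[i1, i2])), 0.1)
  bg <- which(ms$modules == "background")
  expect_lt(mean(abs(cc[bg, bg][upper.tri(cc[bg, bg])])), 0.1)

  # within_cor 0: no correlation structure at all
  ms0 <- simulate_module_expression(
    module_sim_config(n_modules = 2, genes_per_module = 20,
                      n_samples = 400, within_cor = 0, seed = 5))
  cc0 <- cor(ms0$expr)
  expect_lt(mean(abs(cc0[upper.tri(cc0)])), 0.1)

  expect_error(module_sim_config(within_cor = 1), "< 1")
  expect_identical(simulate_module_expression(cfg)$expr, ms$expr)
})

test_that("protein simulation plants recoverable repeats", {
  cfg <- protein_sim_config(n_proteins = 25, signal_fraction = 1, seed = 9)
  ps <- simulate_proteins(cfg)
  expect_identical(simulate_proteins(cfg)$sequences, ps$sequences)

  # every planted span must be found verbatim by the scanner
  found <- scan_repeats_all(ps$sequences)
  key <- function(df) paste(df$protein, df$start, df$end)
  expect_true(all(key(ps$repeats) %in% key(found)))
  # planted truth agrees with its own class labels and coordinates
  expect_true(all(ps$repeats$end - ps$repeats$start == ps$repeats$n + 2))

  # signal_fraction 1: every protein annotated with N, H and C
  sig <- split(ps$signals, ps$signals$protein)
  expect_setequal(names(sig), names(ps$sequences))
  expect_true(all(vapply(sig, function(d)
    setequal(d$region, c("N", "H", "C")), logical(1))))

  # duplets only
  ps2 <- simulate_proteins(protein_sim_config(
    n_proteins = 10, repeat_classes = c(`2` = 3), seed = 2))
  expect_true(all(ps2$repeats$class == "duplet"))

  # repeats that cannot fit are rejected
  expect_error(
    simulate_proteins(protein_sim_config(
      n_proteins = 5, length_range = c(6, 6),
      repeat_classes = c(`4` = 5), seed = 1)),
    "do not fit")
})
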