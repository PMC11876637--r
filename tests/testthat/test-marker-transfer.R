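marker_fixture <- function() {
  markers <- data.frame(
    cluster = c("n1", "n1", "n1", "n1", "n2", "n2"),
    gene = c("sA", "sB", "sC", "sE", "sD", "sD"),
    fold_change = c(2.0, 1.5, 1.5, 0.8, 1.2, 1.2))
  # sB passes the fold-change cut but has no ortholog; sE has an ortholog
  # but fails the cut
  map <- data.frame(source = c("sA", "sC", "sD", "sE"),
                    target = c("tA", "tC", "tD", "tE"))
  list(markers = markers, map = map)
}

test_that("marker transfer filters by fold change and ortholog presence", {
  fx <- marker_fixture()
  expect_message(sets <- transfer_markers(fx$markers, fx$map, fc_min = 1),
                 "without a one-to-one ortholog")
  expect_equal(sets$n1, c("tA", "tC"))      # sB unmapped, sE below FC 1
  expect_equal(sets$n2, "tD")               # deduplicated
  # idempotent and order-independent
  perm <- fx$markers[rev(seq_len(nrow(fx$markers))), ]
  sets2 <- suppressMessages(transfer_markers(perm, fx$map, fc_min = 1))
  expect_true(setequal(sets2$n1, sets$n1))

  # empty surviving set: cluster omitted with a warning
  low <- data.frame(cluster = "n3", gene = "sA", fold_change = 0.1)
  expect_warning(
    s3 <- suppressMessages(transfer_markers(rbind(fx$markers, low),
                                            fx$map)),
    "n3")
  expect_false("n3" %in% names(s3))

  bad <- rbind(fx$map, data.frame(source = "sZ", target = "tA"))
  expect_error(transfer_markers(fx$markers, bad), "tA")
  na_fc <- fx$markers
  na_fc$fold_change[1] <- NA
  expect_error(transfer_markers(na_fc, fx$map), "fold_change")
})

test_that("gene-set scores are centred and robust to degenerate input", {
  # constant matrix scores exactly zero
  const <- matrix(3, 20, 40,
                  dimnames = list(paste0("c", 1:20), paste0("g", 1:40)))
  sc <- score_cells(const, c("g1", "g2"), seed = 1)
  expect_equal(unname(sc), rep(0, 20))

  withr::with_seed(8, {
    expr <- matrix(abs(rnorm(50 * 200)), 50, 200,
                   dimnames = list(paste0("c", 1:50), paste0("g", 1:200)))
  })
  # set = all genes: control empty, dataset-mean fallback, score ~ 0
  sc_all <- score_cells(expr, colnames(expr), seed = 2)
  expect_equal(unname(sc_all), rep(0, 50), tolerance = 1e-12)

  # zero-expression padding genes never change scores
  sc1 <- score_cells(expr, c("g1", "g5"), seed = 3)
  pad <- cbind(expr, matrix(0, 50, 5,
                            dimnames = list(rownames(expr),
                                            paste0("z", 1:5))))
  sc2 <- score_cells(pad, c("g1", "g5"), seed = 3)
  expect_equal(unname(sc2), unname(sc1), tolerance = 1e-10)

  # determinism of the control draw
  expect_identical(score_cells(expr, c("g1", "g5"), seed = 3), sc1)
  expect_error(score_cells(expr, "absent"), "no gene")
})

test_that("random gene sets have mean score near zero", {
  withr::with_seed(12, {
    expr <- matrix(abs(rnorm(60 * 300)), 60, 300,
                   dimnames = list(paste0("c", 1:60), paste0("g", 1:300)))
  })
  means <- vapply(1:100, function(s) {
    gs <- withr::with_seed(s, sample(colnames(expr), 10))
    mean(score_cells(expr, gs, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.05)
})

test_that("a planted expression shift is recovered by the score", {
  hits <- 0L
  for (s in 1:50) {
    withr::with_seed(s, {
      expr <- matrix(abs(rnorm(120 * 150)), 120, 150,
                     dimnames = list(paste0("c", 1:120),
                                     paste0("g", 1:150)))
      clusters <- rep(paste0("k", 1:4), each = 30)
      set <- sample(colnames(expr), 8)
      expr[clusters == "k2", set] <- expr[clusters == "k2", set] + 2
    })
    sc <- score_cells(expr, set, seed = s)
    mu <- cluster_score_summary(sc, clusters)
    hits <- hits + (names(which.max(mu)) == "k2")
  }
  expect_gte(hits, 48L)
})

test_that("cluster summaries are means, invariant to cell order", {
  sc <- c(a = 1, b = 3, c = 10)
  cl <- c("x", "x", "y")
  mu <- cluster_score_summary(sc, cl)
  expect_equal(unname(mu[["x"]]), 2)
  expect_equal(unname(mu[["y"]]), 10)        # single cell: its own score
  perm <- c(3, 1, 2)
  expect_equal(cluster_score_summary(sc[perm], cl[perm]), mu)
  # matrix input: one column per gene set
  m <- cbind(s1 = sc, s2 = sc * 2)
  mm <- cluster_score_summary(m, cl)
  expect_equal(mm["x", "s2"], 4)
  expect_error(cluster_score_summary(sc, c("x", "y")), "cover")
})
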