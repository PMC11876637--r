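# Independent oracles used to validate the implementations. Each is a
# deliberately naive route: explicit enumeration, triple loops, substring
# matching, pair counting.

# Two-sided Fisher p by enumerating all tables with the observed margins,
# computing each table's probability from binomial coefficients (lchoose),
# and summing those no more probable than the observed table (same 1+1e-7
# relative tie tolerance as the classical implementations).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p <- exp(logp)
  pobs <- p[xs == a]
  sum(p[p <= pobs * (1 + 1e-7)])
}

# TOM by explicit triple loop over shared neighbours.
oracle_tom <- function(adj) {
  a <- adj; diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(adj)
  tom
}

# XGnX spans by testing every substring of length 3..6 against the literal
# pattern: flank, 1-4 glycines, flank. Returns 0-based half-open spans.
oracle_scan <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  flanks <- c("I", "L", "V", "Y")
  out <- list()
  for (i in seq_len(L)) {
    for (n in 1:4) {
      j <- i + n + 1L
      if (j > L) break
      if (chars[i] %in% flanks && chars[j] %in% flanks &&
          all(chars[(i + 1):(j - 1)] == "G")) {
        out[[length(out) + 1L]] <- c(start = i - 1L, end = j, n = n)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), n = integer()))
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$start, df$end), , drop = FALSE]
}

# Adjusted Rand index by looping over all item pairs.
oracle_ari <- function(x, y) {
  n <- length(x)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- x[i] == x[j]; sy <- y[i] == y[j]
    if (sx && sy) a <- a + 1
    else if (sx && !sy) b <- b + 1
    else if (!sx && sy) c_ <- c_ + 1
    else d <- d + 1
  }
  tot <- a + b + c_ + d
  exp_idx <- (a + b) * (a + c_) / tot
  max_idx <- ((a + b) + (a + c_)) / 2
  if (max_idx == exp_idx) return(1)
  (a - exp_idx) / (max_idx - exp_idx)
}

# random G-enriched protein sequences for scanner stress tests
random_g_sequence <- function(max_len = 200) {
  alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                rep("G", 8), rep(c("I", "L", "V", "Y"), 3), "X", "B", "Z")
  paste(sample(alphabet, sample.int(max_len, 1), replace = TRUE),
        collapse = "")
}

# cell-type profiles in two correlated blocks (for co-occurrence tests)
block_profiles <- function(n_per_block = 4, n_genes = 300, within = 0.95,
                           seed = 1) {
  withr::with_seed(seed, {
    types <- paste0("ct", seq_len(2 * n_per_block))
    prof <- matrix(rnorm(length(types) * n_genes), length(types), n_genes,
                   dimnames = list(types, paste0("g", seq_len(n_genes))))
    for (b in 1:2) {
      idx <- ((b - 1) * n_per_block + 1):(b * n_per_block)
      z <- rnorm(n_genes)
      prof[idx, ] <- sqrt(within) *
        matrix(rep(z, length(idx)), nrow = length(idx), byrow = TRUE) +
        sqrt(1 - within) * prof[idx, ]
    }
    prof
  })
}
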