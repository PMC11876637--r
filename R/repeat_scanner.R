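# XGnX glycine-repeat scanner: glycine runs of length 1-4 flanked on both
# sides by one of I, L, V, Y, the architecture characteristic of
# shematrin/prisilkin-type shell-matrix proteins. Coordinates are 0-based
# half-open throughout.

#' Scan a protein for XGnX glycine repeats
#'
#' Finds every maximal glycine run of length n in 1..4 whose immediate
#' left and right neighbours are both in {I, L, V, Y}. Runs longer than 4
#' yield no span (they are not decomposed). Adjacent spans may share a
#' flank residue (e.g. `"IGLGGY"` yields a singlet and a duplet sharing
#' the L). Ambiguity codes (B, J, O, U, X, Z) never match glycine or a
#' flank.
#'
#' @param sequence protein string (possibly empty).
#' @param protein optional protein id attached to the result.
#' @return data frame of class `repeat_spans`: `protein`, `start`, `end`
#'   (0-based half-open, spanning both flanks so `end - start = n + 2`),
#'   `n`, `class` (singlet/duplet/triplet/quadruplet), `flank_left`,
#'   `flank_right`, ordered left to right.
#' @export
scan_repeats <- function(sequence, protein = NA_character_) {
  empty <- data.frame(protein = character(), start = integer(),
                      end = integer(), n = integer(), class = character(),
                      flank_left = character(), flank_right = character())
  class(empty) <- c("repeat_spans", class(empty))
  if (is.na(sequence) || nchar(sequence) == 0L) return(empty)
  runs <- gregexpr("G+", sequence)[[1]]
  if (runs[1] == -1L) return(empty)
  starts1 <- as.integer(runs)                       # 1-based run starts
  lens <- attr(runs, "match.length")
  chars <- strsplit(sequence, "")[[1]]
  rows <- list()
  for (i in seq_along(starts1)) {
    n <- lens[i]
    if (n < 1L || n > 4L) next
    left <- starts1[i] - 1L
    right <- starts1[i] + n
    if (left < 1L || right > length(chars)) next
    if (!(chars[left] %in% FLANKS) || !(chars[right] %in% FLANKS)) next
    rows[[length(rows) + 1L]] <- data.frame(
      protein = protein, start = left - 1L, end = right,
      n = n, class = unname(REPEAT_CLASS_NAMES[as.character(n)]),
      flank_left = chars[left], flank_right = chars[right])
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  class(out) <- c("repeat_spans", class(out))
  out
}

#' Scan many proteins for XGnX repeats
#'
#' @param sequences named character vector (e.g. from
#'   [read_protein_fasta()]).
#' @return one `repeat_spans` data frame over all proteins.
#' @export
scan_repeats_all <- function(sequences) {
  if (is.null(names(sequences))) stopf("`sequences` must be named")
  res <- lapply(names(sequences), function(id)
    scan_repeats(sequences[[id]], protein = id))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarize the repeat architecture of one protein
#'
#' @param protein protein id.
#' @param sequence the protein sequence the spans were scanned from.
#' @param spans `repeat_spans` for this protein (from [scan_repeats()]).
#' @param signal_regions optional data frame `region` (N/H/C), `start`,
#'   `end` in 0-based half-open coordinates (see
#'   [load_signal_regions()]); must lie within the sequence.
#' @return an `architecture_record` list: `protein`, `length`, `spans`,
#'   `counts` (named singlet/duplet/triplet/quadruplet),
#'   `majority_class` (ties broken lexicographically; `"none"` without
#'   spans), `repeat_coverage` (union of span intervals over length),
#'   `signal_regions`, `has_signal`.
#' @export
summarize_architecture <- function(protein, sequence, spans,
                                   signal_regions = NULL) {
  len <- nchar(sequence)
  counts <- setNames(integer(4), unname(REPEAT_CLASS_NAMES))
  cov <- 0
  if (nrow(spans)) {
    tab <- table(spans$class)
    counts[names(tab)] <- as.integer(tab)
    covered <- logical(len)
    for (i in seq_len(nrow(spans)))
      covered[(spans$start[i] + 1):spans$end[i]] <- TRUE
    cov <- sum(covered) / len
  }
  majority <- if (sum(counts) == 0L) "none" else {
    top <- names(counts)[counts == max(counts)]
    sort(top)[1]
  }
  if (!is.null(signal_regions) && nrow(signal_regions)) {
    if (any(signal_regions$start < 0 | signal_regions$end > len))
      stopf("signal region outside sequence bounds for '%s'", protein)
  }
  structure(list(protein = protein, length = len, spans = spans,
                 counts = counts, majority_class = majority,
                 repeat_coverage = cov,
                 signal_regions = signal_regions,
                 has_signal = !is.null(signal_regions) &&
                   nrow(signal_regions) > 0L),
            class = "architecture_record")
}

#' @export
print.architecture_record <- function(x, ...) {
  cat(sprintf("%s (%d aa): %d spans, majority %s, coverage %.2f%s\n",
              x$protein, x$length, sum(x$counts), x$majority_class,
              x$repeat_coverage,
              if (x$has_signal) ", signal peptide" else ""))
  invisible(x)
}

#' Load signal-peptide regions from a predictor-style TSV
#'
#' Reads a table with columns `protein`, `region` (N, H or C), `start`,
#' `end` in 1-based inclusive coordinates and converts to the package's
#' 0-based half-open convention. Regions of a protein are ordered N, H, C
#' regardless of file order; overlapping regions of the same protein are
#' an error.
#'
#' @param path TSV path (or a data frame already in that layout).
#' @return named list: protein -> data frame `region`, `start`, `end`
#'   (0-based half-open).
#' @export
load_signal_regions <- function(path) {
  df <- if (is.data.frame(path)) path else read_tsv(path)
  if (!all(c("protein", "region", "start", "end") %in% names(df)))
    stopf("signal table needs columns protein, region, start, end")
  if (!all(df$region %in% c("N", "H", "C")))
    stopf("region labels must be N, H or C")
  df$start <- df$start - 1L        # to 0-based half-open
  out <- lapply(split(df, df$protein), function(d) {
    d <- d[order(match(d$region, c("N", "H", "C"))), , drop = FALSE]
    if (nrow(d) > 1L) {
      o <- order(d$start)
      s <- d$start[o]; e <- d$end[o]
      if (any(s[-1] < e[-length(e)]))
        stopf("overlapping signal regions for '%s'", d$protein[1])
    }
    rownames(d) <- NULL
    d[, c("region", "start", "end")]
  })
  out
}

#' Architecture records for a whole protein set
#'
#' Convenience wrapper: scans every sequence and attaches signal regions
#' where available (`has_signal` is `FALSE` for proteins absent from the
#' signal table).
#'
#' @param sequences named character vector of protein sequences.
#' @param signal_regions optional result of [load_signal_regions()].
#' @return named list of `architecture_record`s.
#' @export
architecture_records <- function(sequences, signal_regions = NULL) {
  if (is.null(names(sequences))) stopf("`sequences` must be named")
  lapply(setNames(names(sequences), names(sequences)), function(id) {
    spans <- scan_repeats(sequences[[id]], protein = id)
    sig <- signal_regions[[id]]
    summarize_architecture(id, sequences[[id]], spans, sig)
  })
}

#' Write repeat spans as BED
#'
#' One line per span with the protein id as the contig, 0-based half-open
#' coordinates, and the repeat class as the name column.
#'
#' @param spans a `repeat_spans` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeat_bed <- function(spans, path) {
  bed <- data.frame(chrom = spans$protein, start = spans$start,
                    end = spans$end, name = spans$class)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
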