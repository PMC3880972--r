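# Deduplication, redundancy, and summary statistics of contig sets.

# Containment-based duplicate marking shared by contigs and peptides.
# A sequence is dropped iff it is an exact substring of a longer retained
# sequence, or an exact duplicate of an earlier one. Returns a logical
# keep-vector aligned with `seqs`.
dedup_keep <- function(seqs, mode = c("substring", "exact")) {
  mode <- match.arg(mode)
  n <- length(seqs)
  keep <- !duplicated(seqs)          # equal-length ties: keep first in input
  if (mode == "exact" || n == 0L) return(keep)
  idx <- which(keep)
  # longest first; equal lengths cannot contain each other unless identical
  ord <- idx[order(-nchar(seqs[idx]), idx)]
  retained <- character(0)
  for (i in ord) {
    s <- seqs[i]
    if (length(retained) && any(grepl(s, retained, fixed = TRUE))) {
      keep[i] <- FALSE
    } else {
      retained <- c(retained, s)
    }
  }
  keep
}

#' Remove redundant contigs by 100%-identity clustering
#'
#' Emulates clustering at the 100% identity threshold: a contig is removed
#' iff its sequence is an exact, full-length substring of a longer (or an
#' exact duplicate of an earlier-retained equal-length) contig. Redundancy
#' is `(n_before - n_after) / n_before`.
#'
#' @param contigs data.frame with columns `id`, `seq`.
#' @param mode `"substring"` (default; full containment clustering) or
#'   `"exact"` (exact-duplicate removal only).
#' @return A list with `contigs` (retained rows, input order), `redundancy`,
#'   `n_before`, `n_after`.
#' @examples
#' x <- data.frame(id = c("a", "b", "c"),
#'                 seq = c("ATGC", "ATGC", "GATGCA"))
#' dedup_contigs(x)$redundancy   # 2/3
#' @export
dedup_contigs <- function(contigs, mode = c("substring", "exact")) {
  mode <- match.arg(mode)
  n <- nrow(contigs)
  if (n == 0L)
    return(list(contigs = contigs, redundancy = 0, n_before = 0L,
                n_after = 0L))
  keep <- dedup_keep(contigs$seq, mode)
  out <- contigs[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(contigs = out, redundancy = (n - sum(keep)) / n,
       n_before = n, n_after = sum(keep))
}

#' N50 of a length multiset
#'
#' The largest length L such that sequences of length >= L together contain
#' at least half of all bases (weighted-median definition).
#'
#' @param lengths Positive integer vector.
#' @return The N50 as an integer; an element of `lengths`.
#' @export
calc_n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length set")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  as.integer(s[which(cumsum(s) >= sum(s) / 2)[1L]])
}

#' Summary statistics of a (deduplicated) contig set
#'
#' Contigs shorter than `min_len` are discarded, then count, total bases,
#' max/min/mean length and N50 are computed — the layout of the standard
#' per-assembly comparison table. The caller is expected to deduplicate
#' first ([dedup_contigs()]); the CLI chains the two.
#'
#' @param contigs data.frame with columns `id`, `seq`.
#' @param min_len Minimum retained length (default 200, the conventional
#'   nucleotide cutoff; use 50 for amino-acid sets).
#' @param redundancy Optional redundancy fraction to carry into the row.
#' @return One-row data.frame: `n_contigs`, `total_bases`, `max_len`,
#'   `min_len`, `mean_len`, `n50`, `redundancy`.
#' @export
assembly_summary <- function(contigs, min_len = 200, redundancy = NA_real_) {
  lens <- nchar(contigs$seq)
  lens <- lens[lens >= min_len]
  if (length(lens) == 0L) stop("empty assembly after length filter")
  data.frame(n_contigs = length(lens),
             total_bases = sum(lens),
             max_len = max(lens),
             min_len = min(lens),
             mean_len = mean(lens),
             n50 = calc_n50(lens),
             redundancy = redundancy)
}

#' Histogram of lengths over explicit bin edges
#'
#' Bins are half-open `[e_i, e_{i+1})`; the last bin is closed. Items
#' outside `[first_edge, last_edge]` are ignored.
#'
#' @param lengths Numeric vector.
#' @param bin_edges Strictly increasing numeric vector (>= 2 edges).
#' @return data.frame with `bin_start`, `bin_end`, `count`.
#' @export
length_histogram <- function(lengths, bin_edges) {
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing")
  nb <- length(bin_edges) - 1L
  idx <- findInterval(lengths, bin_edges, rightmost.closed = TRUE)
  idx <- idx[idx >= 1L & idx <= nb]
  data.frame(bin_start = bin_edges[-length(bin_edges)],
             bin_end = bin_edges[-1L],
             count = tabulate(idx, nbins = nb))
}
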