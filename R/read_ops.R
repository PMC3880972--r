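# Read preprocessing, seeded pair subsampling for the sequencing-depth
# saturation analysis, and the two library-QC fractions (rRNA content and
# unique-start-site complexity).

# longest homopolymer run of `base`, vectorised
longest_run <- function(seqs, base) {
  hits <- gregexpr(paste0(base, "+"), seqs)
  vapply(hits, function(m) {
    if (m[1L] == -1L) 0L else max(attr(m, "match.length"))
  }, integer(1))
}

#' Filter read pairs by length and poly-A content
#'
#' A pair is discarded when either mate is shorter than `min_len`, or when
#' either mate's poly-adenosine content exceeds `max_polya_frac` of its
#' length. Poly-A content is measured, by default, as the longest A (or T,
#' to catch reverse-complemented tails) homopolymer run — measuring *total*
#' A content against a 6% cap would discard essentially every read;
#' `polya_mode = "total"` provides that literal reading for comparison.
#'
#' @param pairs Read-pair data.frame ([read_fastq_pairs()]).
#' @param min_len Minimum mate length (default 50 nt).
#' @param max_polya_frac Maximum tolerated poly-A fraction, exclusive
#'   (default 0.06: a run *longer* than 6% of the mate is discarded).
#' @param polya_mode `"run"` (longest homopolymer run; default) or
#'   `"total"` (total A or T base content).
#' @return A list: `pairs` (retained rows), `report` (data.frame
#'   `reason`/`n` with rows `short`, `polyA`, `retained`). Retained read
#'   content is never altered, only membership.
#' @export
filter_reads <- function(pairs, min_len = 50, max_polya_frac = 0.06,
                         polya_mode = c("run", "total")) {
  polya_mode <- match.arg(polya_mode)
  len1 <- nchar(pairs$seq1); len2 <- nchar(pairs$seq2)
  short <- len1 < min_len | len2 < min_len
  polya_frac <- function(seqs, lens) {
    if (polya_mode == "run") {
      pmax(longest_run(seqs, "A"), longest_run(seqs, "T")) / lens
    } else {
      up <- toupper(seqs)
      pmax(nchar(gsub("[^A]", "", up)), nchar(gsub("[^T]", "", up))) / lens
    }
  }
  polya <- polya_frac(pairs$seq1, len1) > max_polya_frac |
    polya_frac(pairs$seq2, len2) > max_polya_frac
  drop_short <- short
  drop_polya <- polya & !short            # first matching reason wins
  keep <- !(drop_short | drop_polya)
  list(pairs = {
    out <- pairs[keep, , drop = FALSE]; rownames(out) <- NULL; out
  },
  report = data.frame(reason = c("short", "polyA", "retained"),
                      n = c(sum(drop_short), sum(drop_polya), sum(keep)),
                      stringsAsFactors = FALSE))
}

#' Subsample size for a proportion of n pairs
#'
#' `k = round-half-up(proportion * n)`, clamped to `[1, n]`.
#'
#' @param n Number of pairs.
#' @param proportion Fraction in (0, 1].
#' @return Integer k.
#' @export
subsample_size <- function(n, proportion) {
  if (proportion <= 0 || proportion > 1)
    stop("proportion must lie in (0, 1]")
  k <- floor(proportion * n + 0.5)
  as.integer(min(max(k, 1), n))
}

#' Seeded uniform subsampling of read pairs
#'
#' Draws `subsample_size(n, proportion)` pairs uniformly without
#' replacement. Mates are never separated; output preserves input relative
#' order; identical (input, proportion, seed) yields identical output.
#'
#' @param pairs Read-pair data.frame; any data.frame works (rows are the
#'   sampling unit).
#' @param proportion Fraction in (0, 1].
#' @param seed Integer seed; all randomness flows from it.
#' @return The selected rows.
#' @export
subsample_pairs <- function(pairs, proportion, seed) {
  n <- nrow(pairs)
  if (n == 0L) stop("no pairs to subsample")
  k <- subsample_size(n, proportion)
  idx <- sort(with_seed(seed, sample.int(n, k)))
  out <- pairs[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate replicate metric values per proportion
#'
#' @param values data.frame with columns `proportion` and `value` (one row
#'   per replicate).
#' @return data.frame `proportion`, `mean`, `sd` (sample sd; 0 when n = 1),
#'   `n`, sorted by proportion — the rows of a saturation curve.
#' @export
saturation_table <- function(values) {
  if (nrow(values) == 0L) stop("no metric values to aggregate")
  props <- sort(unique(values$proportion))
  out <- do.call(rbind, lapply(props, function(p) {
    v <- values$value[values$proportion == p]
    data.frame(proportion = p, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               n = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of reads identified as ribosomal RNA
#'
#' @param n_rrna Number of reads mapped to rRNA references.
#' @param n_total Total number of reads (> 0).
#' @return `n_rrna / n_total`.
#' @export
rrna_fraction <- function(n_rrna, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_rrna < 0 || n_rrna > n_total)
    stop("n_rrna must lie in [0, n_total]")
  n_rrna / n_total
}

#' Unique-start-site fraction (library complexity)
#'
#' The proportion of read pairs with distinct mapped fragment coordinates,
#' using the paired-end duplicate-marking identity (reference, both mate
#' start positions, first-mate strand).
#'
#' @param keys data.frame with columns `ref_id`, `start1`, `strand1`,
#'   `start2` — one row per mapped pair.
#' @return Fraction of distinct keys.
#' @export
unique_start_fraction <- function(keys) {
  if (nrow(keys) == 0L) stop("empty key list")
  k <- paste(keys$ref_id, keys$start1, keys$strand1, keys$start2,
             sep = "\r")
  length(unique(k)) / length(k)
}

#' Saturation analysis over exact read placements
#'
#' For each proportion and replicate, subsamples the placed read pairs
#' (replicate seeds derive deterministically from `seed` via
#' [derive_seed()]; the 100% proportion runs once) and scores each
#' reference by the union of its retained read placements — the exact
#' error-free analogue of mapping the subsample back to the reference set.
#' Completeness at `threshold` and percent-hits are reported per run.
#'
#' @param placements data.frame with columns `ref_id`, `start1`, `end1`,
#'   `start2`, `end2` (0-based half-open mate intervals on the reference),
#'   one row per pair; produced by [sim_read_pairs()] or any mapper.
#' @param ref_lens Named integer vector of reference lengths (nt).
#' @param proportions Fractions in (0, 1], e.g. `c(0.05, 0.1, ..., 1)`.
#' @param replicates Replicates per proportion except 1.0 (default 3).
#' @param threshold Coverage threshold for completeness (default 0.8).
#' @param seed Base seed.
#' @return data.frame with one row per run: `proportion`, `replicate`,
#'   `n_pairs`, `completeness`, `pct_hits`.
#' @export
saturation_analysis <- function(placements, ref_lens, proportions,
                                replicates = 3L, threshold = 0.8,
                                seed = 1L) {
  if (any(proportions <= 0 | proportions > 1))
    stop("proportions must lie in (0, 1]")
  proportions <- sort(unique(proportions))
  n <- nrow(placements)
  if (n == 0L) stop("no placements")
  n_refs <- length(ref_lens)
  score_subset <- function(rows) {
    p <- placements[rows, , drop = FALSE]
    ref <- rep(p$ref_id, 2L)
    s <- c(p$start1, p$start2)
    e <- c(p$end1, p$end2)
    covered <- vapply(split(seq_along(ref), ref), function(ix)
      covered_length(s[ix], e[ix]), numeric(1))
    frac <- covered / ref_lens[names(covered)]
    c(completeness = sum(frac >= threshold - 1e-12) / n_refs,
      pct_hits = length(frac) / n_refs)
  }
  out <- list()
  for (i in seq_along(proportions)) {
    p <- proportions[i]
    reps <- if (p >= 1) 1L else as.integer(replicates)
    for (j in seq_len(reps)) {
      k <- subsample_size(n, p)
      rows <- if (p >= 1) seq_len(n) else
        sort(with_seed(derive_seed(seed, i, j), sample.int(n, k)))
      sc <- score_subset(rows)
      out[[length(out) + 1L]] <-
        data.frame(proportion = p, replicate = j, n_pairs = k,
                   completeness = unname(sc["completeness"]),
                   pct_hits = unname(sc["pct_hits"]))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
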