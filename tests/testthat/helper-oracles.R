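# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own interval/statistics code paths: coverage is per-
# position bitmasking, N50 is an explicit sort-and-cumulate walk, dedup is
# an all-pairs scan, translation cross-checks go through seqinr.

# per-position bitmask coverage oracle over a hit table (subject intervals
# 0-based half-open); returns records shaped like reference_coverage()
oracle_coverage <- function(hits, ref_lens) {
  refs <- intersect(names(ref_lens), unique(hits$sid))
  out <- lapply(refs, function(r) {
    h <- hits[hits$sid == r, , drop = FALSE]
    rlen <- ref_lens[[r]]
    mask <- function(hh) {
      m <- rep(FALSE, rlen)
      for (i in seq_len(nrow(hh))) {
        lo <- hh$s_start[i] + 1L
        hi <- hh$s_end[i]
        m[lo:hi] <- TRUE
      }
      m
    }
    per_contig <- vapply(unique(h$qid), function(q)
      sum(mask(h[h$qid == q, , drop = FALSE])), numeric(1))
    data.frame(ref_id = r,
               best_single_frac = max(per_contig) / rlen,
               union_frac = sum(mask(h)) / rlen,
               n_contigs_hitting = length(unique(h$qid)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# explicit sort-descending cumulative-sum N50 walk
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  acc <- 0
  for (l in s) {
    acc <- acc + l
    if (acc >= total / 2) return(l)
  }
}

# all-pairs substring-containment dedup; returns the kept logical vector
oracle_dedup_keep <- function(seqs) {
  n <- length(seqs)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !keep[i]) next
      li <- nchar(seqs[i]); lj <- nchar(seqs[j])
      contained <- grepl(seqs[i], seqs[j], fixed = TRUE)
      if (contained && (lj > li || (lj == li && j < i && keep[j])))
        keep[i] <- FALSE
    }
  }
  keep
}

# longest homopolymer run via rle
oracle_longest_run <- function(seq, base) {
  r <- rle(strsplit(toupper(seq), "")[[1]])
  runs <- r$lengths[r$values == base]
  if (length(runs)) max(runs) else 0L
}

# frame translation through seqinr (independent of Biostrings)
oracle_translate <- function(seq, frame) {
  s <- toupper(seq)
  if (frame < 0) {
    comp <- chartr("ACGTN", "TGCAN", s)
    s <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }
  chars <- strsplit(s, "")[[1]]
  off <- abs(frame) - 1
  chars <- chars[seq_len(length(chars) - off) + off]
  n_codon <- length(chars) %/% 3
  if (n_codon == 0) return("")
  chars <- chars[seq_len(3 * n_codon)]
  paste(seqinr::translate(chars, ambiguous = FALSE, NAstring = "X"),
        collapse = "")
}

random_contig_set <- function(n, len_range = c(10, 60)) {
  data.frame(
    id = sprintf("c%03d", seq_len(n)),
    seq = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"),
                   sample(len_range[1]:len_range[2], 1),
                   replace = TRUE), collapse = ""), ""),
    stringsAsFactors = FALSE)
}
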