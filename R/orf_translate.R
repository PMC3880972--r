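# Alignment-anchored translation: translate the aligned region of a contig
# in its reading frame, then extend codon-by-codon in both directions until
# a stop codon (excluded) or the end of the last complete codon. No start
# codon is required — a peptide may begin mid-ORF — and a codon containing N
# translates to 'X' without stopping the extension (ambiguity is not
# evidence of a stop).

#' Translate a nucleotide sequence in a given reading frame
#'
#' Standard nuclear genetic code. Negative frames operate on the reverse
#' complement; the leading offset is `|frame| - 1` and any trailing partial
#' codon is dropped. Codons containing N render `X`; stop codons render `*`.
#'
#' @param seq Nucleotide string (A/C/G/T/N, case-insensitive).
#' @param frame Integer in `{-3,-2,-1,+1,+2,+3}`.
#' @return The peptide as a character string (possibly empty).
#' @examples
#' translate_frame("ATGGCC", 1)    # "MA"
#' translate_frame("GGCCAT", -1)   # "MA"
#' @export
translate_frame <- function(seq, frame) {
  if (length(frame) != 1L || !frame %in% c(-3:-1, 1:3))
    stop("frame must be one of -3..-1, +1..+3")
  s <- toupper(seq)
  if (frame < 0) s <- revcomp(s)
  off <- abs(frame) - 1L
  s <- substr(s, off + 1L, nchar(s))
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0L) return("")
  s <- substr(s, 1L, 3L * n_codon)
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

# translate complete in-frame codons of oriented sequence S over [from, to)
.trans_region <- function(S, from, to) {
  if (to <= from) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(S, from + 1L, to)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

#' Translate an aligned anchor and extend to the flanking stop codons
#'
#' The anchor (the contig region aligned to a reference protein, with its
#' reading frame) is snapped outward to the codon boundaries of the frame
#' phase, translated, and then extended codon-by-codon upstream and
#' downstream until a stop codon is met (the stop is excluded) or fewer
#' than 3 nt remain.
#'
#' @param contig_seq Contig nucleotide string.
#' @param q_start,q_end Anchor interval, 0-based half-open on the forward
#'   strand of the contig.
#' @param qframe Reading frame in `{-3..-1, +1..+3}` (required; this is the
#'   `qframe` column of a translated-search hit).
#' @param strict If `TRUE`, error when the anchor is not codon-aligned to
#'   the frame phase or contains an in-frame stop; otherwise the anchor is
#'   snapped / truncated at the first in-anchor stop with a message.
#' @return A list: `peptide` (no internal `*`), `frame`, and
#'   `q_start_nt`/`q_end_nt`, the forward-strand nucleotide interval that
#'   back-translates to the peptide
#'   (`q_end_nt - q_start_nt == 3 * nchar(peptide)`).
#' @examples
#' # anchor [8,14) in frame +3: upstream ATG kept, TAA/TGA stops excluded
#' anchor_translate_extend("GGTAAATGGCTGCTTGAGG", 8, 14, 3)$peptide  # "MAA"
#' @export
anchor_translate_extend <- function(contig_seq, q_start, q_end, qframe,
                                    strict = FALSE) {
  if (is.na(qframe)) stop("frame required")
  if (!qframe %in% c(-3:-1, 1:3)) stop("frame must be one of -3..-1, +1..+3")
  L <- nchar(contig_seq)
  if (q_start < 0 || q_end > L || q_start >= q_end)
    stop("anchor interval outside contig")
  S <- toupper(contig_seq)
  if (qframe < 0) S <- revcomp(S)
  # anchor in frame-oriented coordinates
  if (qframe < 0) { a <- L - q_end; b <- L - q_start } else {
    a <- q_start; b <- q_end
  }
  off <- abs(qframe) - 1L
  n_codon <- (L - off) %/% 3L
  last <- off + 3L * n_codon              # end of last complete codon
  if (strict && ((a - off) %% 3L != 0L || (b - off) %% 3L != 0L))
    stop("anchor not codon-aligned with frame phase")
  # snap outward to codon boundaries, clamped to complete codons
  a2 <- off + 3L * ((a - off) %/% 3L)
  a2 <- max(a2, off)
  b2 <- off + 3L * as.integer(ceiling((b - off) / 3))
  b2 <- min(b2, last)
  if (b2 <= a2)
    stop("anchor contains no complete codon in frame ", qframe)
  # translate the whole frame once; extension is then a window expansion
  # over the codon characters, stopping at '*' on either side
  chars <- strsplit(.trans_region(S, off, last), "")[[1L]]
  ca <- (a2 - off) %/% 3L + 1L            # 1-based anchor codon range
  cb <- (b2 - off) %/% 3L
  in_anchor_stop <- which(chars[ca:cb] == "*")
  hit_stop <- length(in_anchor_stop) > 0L
  if (hit_stop) {
    if (strict) stop("stop codon inside anchor")
    message("asmqc: in-anchor stop codon; anchor truncated")
    cb <- ca + in_anchor_stop[1L] - 2L    # last codon before the stop
  }
  ce <- cb
  if (!hit_stop)
    while (ce + 1L <= n_codon && chars[ce + 1L] != "*") ce <- ce + 1L
  cs <- ca
  while (cs - 1L >= 1L && chars[cs - 1L] != "*") cs <- cs - 1L
  peptide <- if (ce >= cs) paste(chars[cs:ce], collapse = "") else ""
  s0 <- off + 3L * (cs - 1L)
  e <- max(off + 3L * ce, s0)
  if (qframe < 0) { q0 <- L - e; q1 <- L - s0 } else { q0 <- s0; q1 <- e }
  list(peptide = peptide, frame = as.integer(qframe),
       q_start_nt = as.integer(q0), q_end_nt = as.integer(q1))
}

#' Translate an assembly from its anchored hits
#'
#' One peptide per contig: the best hit (highest bitscore, ties by lowest
#' evalue then file order) provides the anchor and frame. Peptides are then
#' deduplicated at 100% identity (substring containment, as for contigs),
#' filtered at `min_aa`, and summarised with the translated-contig metrics
#' (count, total aa, max, mean, N50).
#'
#' @param contigs data.frame with columns `id`, `seq`.
#' @param hits Hit data.frame with `qframe` present for every row used.
#' @param min_aa Minimum peptide length retained (default 50 aa).
#' @param strict Passed to [anchor_translate_extend()].
#' @return A list: `peptides` (data.frame `contig_id`, `frame`, `peptide`,
#'   `q_start_nt`, `q_end_nt`, retained rows only), `redundancy`, and
#'   `summary` (one-row data.frame as [assembly_summary()], lengths in aa).
#' @export
translate_assembly <- function(contigs, hits, min_aa = 50, strict = FALSE) {
  if (nrow(hits) == 0L) stop("no hits to anchor translation")
  if (any(is.na(hits$qframe))) stop("frame required")
  missing <- setdiff(unique(hits$qid), contigs$id)
  if (length(missing))
    stop("contig referenced by a hit but absent from the contig set: ",
         missing[1L])
  ord <- order(hits$qid, -hits$bitscore, hits$evalue, seq_len(nrow(hits)))
  best <- hits[ord, , drop = FALSE]
  best <- best[!duplicated(best$qid), , drop = FALSE]
  best <- best[order(match(best$qid, contigs$id)), , drop = FALSE]
  seqs <- stats::setNames(contigs$seq, contigs$id)
  tr <- lapply(seq_len(nrow(best)), function(i) {
    h <- best[i, ]
    t <- anchor_translate_extend(seqs[[h$qid]], h$q_start, h$q_end,
                                 h$qframe, strict = strict)
    data.frame(contig_id = h$qid, frame = t$frame, peptide = t$peptide,
               q_start_nt = t$q_start_nt, q_end_nt = t$q_end_nt,
               stringsAsFactors = FALSE)
  })
  pep <- do.call(rbind, tr)
  pep <- pep[nzchar(pep$peptide), , drop = FALSE]
  n_before <- nrow(pep)
  keep <- dedup_keep(pep$peptide, "substring")
  redundancy <- if (n_before > 0) (n_before - sum(keep)) / n_before else 0
  pep <- pep[keep, , drop = FALSE]
  pep <- pep[nchar(pep$peptide) >= min_aa, , drop = FALSE]
  rownames(pep) <- NULL
  summary <- assembly_summary(
    data.frame(id = pep$contig_id, seq = pep$peptide,
               stringsAsFactors = FALSE),
    min_len = 0, redundancy = redundancy)
  list(peptides = pep, redundancy = redundancy, summary = summary)
}
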