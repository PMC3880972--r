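# Organelle-targeted gene census: PPR motif counting and classification,
# reciprocal-best-hit orthologs, pairwise identity, and coding-sequence
# intactness.
#
# PPR classification: a transcript with more than one PPR motif (of any
# class) is a PPR gene. Class assignment follows standard PPR nomenclature
# priority: any DYW motif -> PLS-DYW; else any E/E+ motif -> PLS-E; else P.

#' Classify sequences by their PPR motif content
#'
#' Motif rows sharing a `seq_id` form one annotation. Fewer than two motifs
#' of any class means not a PPR gene.
#'
#' @param annotations Motif data.frame ([read_motif_table()]): `seq_id`,
#'   `motif_class`, `start`, `end`, `score`.
#' @return data.frame with one row per sequence: `seq_id`, `n_motifs`,
#'   `class_label` in `{P, PLS-E, PLS-DYW, not-PPR}`.
#' @export
classify_ppr <- function(annotations) {
  if (nrow(annotations) == 0L)
    return(data.frame(seq_id = character(), n_motifs = integer(),
                      class_label = character(), stringsAsFactors = FALSE))
  ids <- unique(annotations$seq_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    cls <- annotations$motif_class[annotations$seq_id == id]
    n <- length(cls)
    label <- if (n < 2L) "not-PPR"
    else if (any(cls == "DYW")) "PLS-DYW"
    else if (any(cls %in% c("E", "E+"))) "PLS-E"
    else "P"
    data.frame(seq_id = id, n_motifs = n, class_label = label,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' PPR census over a motif-annotated transcript set
#'
#' @param annotations Motif data.frame as for [classify_ppr()].
#' @return data.frame `class`/`n` with rows `PPR` (total),
#'   `P`, `PLS-E`, `PLS-DYW`, `not-PPR`; the PPR total equals
#'   P + PLS-E + PLS-DYW.
#' @export
ppr_census <- function(annotations) {
  calls <- classify_ppr(annotations)
  n_of <- function(lbl) sum(calls$class_label == lbl)
  data.frame(
    class = c("PPR", "P", "PLS-E", "PLS-DYW", "not-PPR"),
    n = c(n_of("P") + n_of("PLS-E") + n_of("PLS-DYW"),
          n_of("P"), n_of("PLS-E"), n_of("PLS-DYW"), n_of("not-PPR")),
    stringsAsFactors = FALSE)
}

# best hit per query: max bitscore, ties by min evalue, then smallest sid
best_per_query <- function(hits) {
  ord <- order(hits$qid, -hits$bitscore, hits$evalue, hits$sid)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$qid), , drop = FALSE]
}

#' Reciprocal best hits between two sequence sets
#'
#' The best hit per query is the maximum-bitscore row (ties: lowest evalue,
#' then lexicographically smallest subject id). A pair (a, b) is reported
#' iff a's best hit in A->B is b and b's best hit in B->A is a.
#'
#' @param hits_ab,hits_ba Hit data.frames for the two search directions.
#' @return data.frame sorted by `id_a`: `id_a`, `id_b`, `bitscore_ab`,
#'   `bitscore_ba`. No id appears twice on either side.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  if (nrow(hits_ab) == 0L || nrow(hits_ba) == 0L)
    return(data.frame(id_a = character(), id_b = character(),
                      bitscore_ab = numeric(), bitscore_ba = numeric(),
                      stringsAsFactors = FALSE))
  ab <- best_per_query(hits_ab)
  ba <- best_per_query(hits_ba)
  back <- stats::setNames(ba$sid, ba$qid)
  ok <- !is.na(back[ab$sid]) & back[ab$sid] == ab$qid
  out <- data.frame(id_a = ab$qid[ok], id_b = ab$sid[ok],
                    bitscore_ab = ab$bitscore[ok],
                    bitscore_ba = stats::setNames(ba$bitscore,
                                                  ba$qid)[ab$sid[ok]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$id_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise identity of an aligned sequence pair
#'
#' A column matches iff both characters are equal (case-insensitive) and
#' neither is the gap character `-`.
#'
#' @param aln_a,aln_b Equal-length aligned strings (gaps as `-`).
#' @param denominator `"alignment"` (default; all columns, so gapped
#'   columns count against identity) or `"ungapped"` (columns with a gap in
#'   either sequence are excluded).
#' @return Identity as a fraction in \[0,1\].
#' @export
pairwise_identity <- function(aln_a, aln_b,
                              denominator = c("alignment", "ungapped")) {
  denominator <- match.arg(denominator)
  if (nchar(aln_a) != nchar(aln_b))
    stop("aligned sequences differ in length")
  if (nchar(aln_a) == 0L) stop("empty alignment")
  a <- strsplit(toupper(aln_a), "")[[1L]]
  b <- strsplit(toupper(aln_b), "")[[1L]]
  ungapped <- a != "-" & b != "-"
  matches <- sum(a == b & ungapped)
  denom <- if (denominator == "alignment") length(a) else sum(ungapped)
  if (denom == 0L) return(0)
  matches / denom
}

#' Intactness of a coding sequence or peptide
#'
#' Nucleotide input is translated in frame +1 and must be a codon multiple.
#' Classification: `internal-stop` when a stop occurs before the final
#' position; `no-terminus` when nucleotide input lacks a leading ATG or a
#' trailing stop codon; else `intact`. Peptide input is used as-is and can
#' only be screened for internal stops.
#'
#' @param x Sequence string.
#' @param type `"auto"` (nucleotide iff only A/C/G/T/N), `"nt"` or `"aa"`.
#' @return One of `"intact"`, `"internal-stop"`, `"no-terminus"`.
#' @export
intactness_check <- function(x, type = c("auto", "nt", "aa")) {
  type <- match.arg(type)
  up <- toupper(x)
  if (type == "auto")
    type <- if (grepl("^[ACGTN]+$", up)) "nt" else "aa"
  if (type == "nt") {
    if (nchar(up) %% 3L != 0L)
      stop("nucleotide length not divisible by 3")
    pep <- translate_frame(up, 1L)
    body <- substr(pep, 1L, nchar(pep) - 1L)
    if (grepl("*", body, fixed = TRUE)) return("internal-stop")
    has_start <- startsWith(up, "ATG")
    has_stop <- substr(pep, nchar(pep), nchar(pep)) == "*"
    if (!has_start || !has_stop) return("no-terminus")
    "intact"
  } else {
    body <- substr(up, 1L, nchar(up) - 1L)
    if (grepl("*", body, fixed = TRUE)) "internal-stop" else "intact"
  }
}
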