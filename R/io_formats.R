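# Readers and writers for the external formats the toolkit touches.
# Downstream modules operate only on the plain data.frame shapes produced
# here. Parsers are strict: a malformed row aborts with its line number,
# because silently dropped rows would silently change evaluation metrics.

#' Read a FASTA file into a contig table
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` (default) validates sequences over A/C/G/T/N,
#'   case-insensitive; `"aa"` accepts amino-acid letters plus `*`.
#' @return A data.frame with columns `id` (first whitespace-delimited header
#'   token) and `seq` (uppercased), in file order.
#' @details Duplicate ids, empty sequences and non-alphabet characters are
#'   errors.
#' @export
read_fasta <- function(path, alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  if (any(!nzchar(ids))) stop("malformed header: empty id")
  if (anyDuplicated(ids))
    stop("duplicate id: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    stop("empty sequence record: ", ids[!nzchar(seqs)][1L])
  pattern <- if (alphabet == "dna") "^[ACGTN]+$" else "^[A-Z*]+$"
  bad <- !grepl(pattern, seqs)
  if (any(bad))
    stop("sequence with characters outside the ", alphabet,
         " alphabet: ", ids[bad][1L])
  data.frame(id = unname(ids), seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a contig table as FASTA
#'
#' @param contigs data.frame with columns `id`, `seq`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  set <- Biostrings::BStringSet(contigs$seq)
  names(set) <- contigs$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read paired FASTQ files into a read-pair table
#'
#' Records are paired positionally; ids come from the first file with mate
#' suffixes (`/1`, `/2`, Casava `" 1:..."`) stripped.
#'
#' @param path1,path2 The two mate FASTQ files (4-line records).
#' @return data.frame with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  read_fq <- function(p) withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(p),
    warning = function(w) {
      # qualities live in a parallel slot; dropping mcols is expected
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  r1 <- read_fq(path1)
  r2 <- read_fq(path2)
  if (length(r1) != length(r2))
    stop("mate count mismatch: ", length(r1), " vs ", length(r2), " records")
  q1 <- as.character(Biostrings::quality(r1))
  q2 <- as.character(Biostrings::quality(r2))
  s1 <- as.character(r1)
  s2 <- as.character(r2)
  if (any(nchar(q1) != nchar(s1)) || any(nchar(q2) != nchar(s2)))
    stop("quality/sequence length mismatch")
  ids <- sub(" [12]:.*$", "", names(r1))        # Casava tail
  ids <- vapply(strsplit(ids, "[ \t]"), `[`, "", 1L)
  ids <- sub("/[12]$", "", ids)                 # classic /1, /2
  data.frame(id = unname(ids),
             seq1 = unname(toupper(s1)), qual1 = unname(q1),
             seq2 = unname(toupper(s2)), qual2 = unname(q2),
             stringsAsFactors = FALSE)
}

#' Write a read-pair table as two FASTQ files
#'
#' @param pairs data.frame as returned by [read_fastq_pairs()].
#' @param path1,path2 Output FASTQ paths; mate ids get `/1` and `/2`.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  write_one <- function(seqs, quals, ids, suffix, path) {
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- paste0(ids, suffix)
    Biostrings::writeXStringSet(dna, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  write_one(pairs$seq1, pairs$qual1, pairs$id, "/1", path1)
  write_one(pairs$seq2, pairs$qual2, pairs$id, "/2", path2)
  invisible(c(path1, path2))
}

#' Read a BLAST-style 12-column tabular hit file
#'
#' Parses the standard tabular dialect (`qid sid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`) plus declared extra
#' columns, normalising all coordinates to 0-based half-open intervals on
#' the forward strand.
#'
#' @param path Path to the tab-separated hit file.
#' @param extra_cols Character vector of extra columns appended after the 12
#'   standard ones, in file order; any of `"qframe"`, `"qlen"`, `"slen"`.
#' @return A data.frame of hits with columns `qid`, `sid`, `pident`
#'   (fraction in \[0,1\]), `aln_len`, `mismatch`, `gapopen`, `q_start`,
#'   `q_end`, `s_start`, `s_end` (0-based half-open), `evalue`, `bitscore`,
#'   `qframe` (NA when absent), `qlen`, `slen` (NA when absent), and
#'   `q_rev` (`TRUE` when the input had `qstart > qend`, i.e. a
#'   negative-orientation query; when `qframe` is absent this is the only
#'   record of the orientation).
#' @export
read_tabular_hits <- function(path, extra_cols = character()) {
  allowed <- c("qframe", "qlen", "slen")
  if (!all(extra_cols %in% allowed))
    stop("unknown extra column(s): ",
         paste(setdiff(extra_cols, allowed), collapse = ", "))
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  n_expected <- 12L + length(extra_cols)
  if (length(lines) == 0L) {
    out <- empty_hits()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens != n_expected)) {
    i <- which(lens != n_expected)[1L]
    stop("expected ", n_expected, " columns, got ", lens[i],
         " at line ", lineno[i])
  }
  m <- matrix(unlist(parts), ncol = n_expected, byrow = TRUE)
  num_cols <- c(3:12, if (length(extra_cols)) 12L + seq_along(extra_cols))
  num <- suppressWarnings(apply(m[, num_cols, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = length(num_cols))
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1L]
    stop("non-numeric field at line ", lineno[bad])
  }
  colnames(num) <- c("pident", "aln_len", "mismatch", "gapopen", "qstart",
                     "qend", "sstart", "send", "evalue", "bitscore",
                     extra_cols)
  qstart <- num[, "qstart"]; qend <- num[, "qend"]
  sstart <- num[, "sstart"]; send <- num[, "send"]
  q_rev <- qstart > qend
  s_rev <- sstart > send
  hits <- data.frame(
    qid = m[, 1L], sid = m[, 2L],
    pident = num[, "pident"] / 100,
    aln_len = as.integer(num[, "aln_len"]),
    mismatch = as.integer(num[, "mismatch"]),
    gapopen = as.integer(num[, "gapopen"]),
    q_start = as.integer(pmin(qstart, qend)) - 1L,
    q_end = as.integer(pmax(qstart, qend)),
    s_start = as.integer(pmin(sstart, send)) - 1L,
    s_end = as.integer(pmax(sstart, send)),
    evalue = num[, "evalue"],
    bitscore = num[, "bitscore"],
    qframe = if ("qframe" %in% extra_cols)
      as.integer(num[, "qframe"]) else NA_integer_,
    qlen = if ("qlen" %in% extra_cols)
      as.integer(num[, "qlen"]) else NA_integer_,
    slen = if ("slen" %in% extra_cols)
      as.integer(num[, "slen"]) else NA_integer_,
    q_rev = q_rev, s_rev = s_rev,
    stringsAsFactors = FALSE)
  if (any(hits$pident < 0 | hits$pident > 1))
    stop("pident outside [0, 100]")
  if (any(!is.na(hits$qframe) & !hits$qframe %in% c(-3:-1, 1:3)))
    stop("qframe outside {-3..-1, 1..3}")
  ok_q <- is.na(hits$qlen) | hits$q_end <= hits$qlen
  ok_s <- is.na(hits$slen) | hits$s_end <= hits$slen
  if (any(!ok_q)) stop("query interval exceeds qlen at line ",
                       lineno[which(!ok_q)[1L]])
  if (any(!ok_s)) stop("subject interval exceeds slen at line ",
                       lineno[which(!ok_s)[1L]])
  hits
}

empty_hits <- function() {
  data.frame(qid = character(), sid = character(), pident = numeric(),
             aln_len = integer(), mismatch = integer(), gapopen = integer(),
             q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), evalue = numeric(), bitscore = numeric(),
             qframe = integer(), qlen = integer(), slen = integer(),
             q_rev = logical(), s_rev = logical(), stringsAsFactors = FALSE)
}

#' Write a hit table in the 12-column tabular dialect
#'
#' Inverse of [read_tabular_hits()]: coordinates go back to 1-based
#' inclusive, `pident` back to percent; negative-orientation query
#' coordinates are written reversed (`qstart > qend`) as aligners do.
#'
#' @param hits Hit data.frame (see [read_tabular_hits()]).
#' @param path Output path.
#' @param extra_cols Extra columns to append (subset of
#'   `c("qframe","qlen","slen")`).
#' @return The path, invisibly.
#' @export
write_tabular_hits <- function(hits, path,
                               extra_cols = c("qframe", "qlen", "slen")) {
  neg <- !is.na(hits$qframe) & hits$qframe < 0 | hits$q_rev
  out <- data.frame(
    qid = hits$qid, sid = hits$sid,
    pident = sprintf("%.2f", hits$pident * 100),
    aln_len = hits$aln_len, mismatch = hits$mismatch,
    gapopen = hits$gapopen,
    qstart = ifelse(neg, hits$q_end, hits$q_start + 1L),
    qend = ifelse(neg, hits$q_start + 1L, hits$q_end),
    sstart = hits$s_start + 1L, send = hits$s_end,
    evalue = format(hits$evalue, digits = 3, scientific = TRUE),
    bitscore = hits$bitscore, stringsAsFactors = FALSE)
  for (col in extra_cols) out[[col]] <- hits[[col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a motif-hit table (digest of a profile-HMM search)
#'
#' @param path Tab-separated file with columns `seq_id`, `motif_class`,
#'   `start`, `end`, `score` (a `#` header line is allowed). Coordinates are
#'   0-based half-open.
#' @return data.frame grouped by `seq_id` (first-appearance order), motifs
#'   sorted by `start` within each sequence. Motif classes follow PPR
#'   nomenclature: P, L, S, E, E+, DYW.
#' @export
read_motif_table <- function(path) {
  allowed <- c("P", "L", "S", "E", "E+", "DYW")
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(data.frame(seq_id = character(), motif_class = character(),
                      start = integer(), end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens != 5L)) {
    i <- which(lens != 5L)[1L]
    stop("expected 5 columns, got ", lens[i], " at line ", lineno[i])
  }
  m <- matrix(unlist(parts), ncol = 5L, byrow = TRUE)
  bad <- !m[, 2L] %in% allowed
  if (any(bad))
    stop("unknown motif class '", m[bad, 2L][1L], "'; allowed classes: ",
         paste(allowed, collapse = ", "))
  num <- suppressWarnings(apply(m[, 3:5, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 3L)
  if (anyNA(num))
    stop("non-numeric field at line ", lineno[which(rowSums(is.na(num)) > 0)[1L]])
  df <- data.frame(seq_id = m[, 1L], motif_class = m[, 2L],
                   start = as.integer(num[, 1L]), end = as.integer(num[, 2L]),
                   score = num[, 3L], stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("motif interval with start >= end")
  df[order(match(df$seq_id, unique(df$seq_id)), df$start), , drop = FALSE]
}

#' Read an aligned sequence pair (aligned FASTA)
#'
#' @param path FASTA file holding exactly two equal-length aligned records
#'   over the residue alphabet plus the gap character `-`.
#' @return A list with `id_a`, `id_b`, `aln_a`, `aln_b`.
#' @export
read_aligned_pair <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 2L)
    stop("expected exactly 2 aligned records, got ", length(set))
  a <- toupper(as.character(set[[1L]])); b <- toupper(as.character(set[[2L]]))
  if (nchar(a) != nchar(b))
    stop("aligned sequences differ in length: ", nchar(a), " vs ", nchar(b))
  if (nchar(a) == 0L) stop("empty alignment")
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  if (any(ca == "-" & cb == "-"))
    stop("alignment column with gaps in both sequences")
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  list(id_a = ids[1L], id_b = ids[2L], aln_a = a, aln_b = b)
}

#' Read a reference length table
#'
#' @param path Two-column TSV (`id`, `length`); `#` header allowed.
#' @return Named integer vector of lengths.
#' @export
read_ref_lengths <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("expected 2 tab-separated columns")
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  lens <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(lens) || any(lens <= 0L)) stop("lengths must be positive integers")
  if (anyDuplicated(m[, 1L])) stop("duplicate reference id")
  stats::setNames(lens, m[, 1L])
}
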