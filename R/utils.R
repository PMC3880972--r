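# Internal helpers shared across modules.
#
# Coordinate convention: every interval inside the package is 0-based,
# half-open, on the forward strand. Conversion from 1-based inclusive input
# happens exactly once, at parse time (see read_tabular_hits).

#' Merge intervals into a disjoint sorted set
#'
#' Merges overlapping and touching half-open intervals. Total covered length
#' is preserved; adjacent intervals (`end_i == start_j`) coalesce.
#'
#' @param start,end Integer vectors of equal length; 0-based half-open
#'   intervals with `start < end`.
#' @return A data.frame with columns `start`, `end`: disjoint, sorted
#'   intervals.
#' @examples
#' merge_intervals(c(0L, 5L), c(5L, 10L))   # one interval [0, 10)
#' @export
merge_intervals <- function(start, end) {
  if (length(start) != length(end))
    stop("start and end must have equal length")
  if (length(start) == 0L)
    return(data.frame(start = integer(), end = integer()))
  if (any(is.na(start)) || any(is.na(end)))
    stop("intervals must not contain NA")
  if (any(start >= end))
    stop("invalid interval: start >= end")
  ir <- IRanges::reduce(IRanges::IRanges(start = as.integer(start) + 1L,
                                         end = as.integer(end)))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Total number of positions covered by a set of half-open intervals.
covered_length <- function(start, end) {
  m <- merge_intervals(start, end)
  sum(m$end - m$start)
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           sample.kind = "Rejection")
  expr
}

#' Derive a reproducible child seed
#'
#' Deterministically maps a base seed plus indices (e.g. proportion index,
#' replicate index) to a new seed below 2^31, so a whole replicated
#' experiment flows from one user-supplied seed.
#'
#' @param base Integer base seed.
#' @param i,j Non-negative integer indices.
#' @return A single integer seed.
#' @export
derive_seed <- function(base, i = 0L, j = 0L) {
  # doubles are exact here: |value| < 2^53
  v <- (as.numeric(base) * 48271 + as.numeric(i) * 2654435 +
          as.numeric(j) * 97 + 1) %% 2147483647
  as.integer(v)
}

# reverse complement, vectorised over character sequences
revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

# ---- TSV plumbing: all tool outputs are TSV with one '#'-prefixed header ----

write_tsv_hash <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_tsv_hash <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "#"))
    stop("expected a '#'-prefixed header line in ", path)
  header <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    df <- as.data.frame(matrix(character(), ncol = length(header),
                               nrow = 0L), stringsAsFactors = FALSE)
    names(df) <- header
    return(df)
  }
  df <- utils::read.table(text = body, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, col.names = header,
                          comment.char = "")
  df
}

stop_usage <- function(...) {
  cond <- structure(class = c("asmqc_usage_error", "error", "condition"),
                    list(message = paste0(...), call = NULL))
  stop(cond)
}
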