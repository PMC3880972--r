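# Per-reference coverage by assembled contigs and the derived evaluation
# metrics: contiguity (best single contig), completeness (union of contigs)
# and percent-hits, swept across coverage thresholds.
#
# Definitions: a reference counts towards contiguity at threshold tau when
# the single best contig alone covers >= tau of its length; towards
# completeness when the union of all aligned contigs does; percent-hits is
# the fraction of references with any hit at all. "Best single contig" is
# the contig achieving maximal coverage of that reference with its own HSPs
# merged (ties: longer qlen, then lexicographically smaller qid).

# threshold comparisons use a tiny slack so fractions assembled through
# different arithmetic routes cannot straddle a sweep value
.tau_eps <- 1e-12

#' Default coverage-threshold sweep
#'
#' 0 plus 0.05 steps up to 1.00 — the conventional "range of thresholds up
#' to 100%" sweep.
#' @return Numeric vector of thresholds.
#' @export
default_threshold_sweep <- function() c(0, seq_len(20L) * 5 / 100)

#' Per-reference coverage records from a hit table
#'
#' For every reference with at least one hit, computes the union coverage
#' fraction over all hits, the best-single-contig coverage fraction (that
#' contig's own HSPs merged), and the number of distinct contigs hitting.
#' Multiple HSPs between one contig and one reference are merged before any
#' fraction is computed, so coverage can never exceed 1.
#'
#' @param hits Hit data.frame (see [read_tabular_hits()]); `s_start`/`s_end`
#'   are 0-based half-open subject (reference) coordinates.
#' @param ref_lens Named integer vector: reference id -> length (residues).
#' @param max_evalue Optional convenience filter; hits with a larger evalue
#'   are dropped before computing coverage. Default `NULL` (off): hit files
#'   normally encode the search-time filter already.
#' @param best_hsp_only If `TRUE`, only the best-bitscore HSP per
#'   contig-reference pair is used instead of merging all HSPs.
#' @return data.frame with one row per reference that has hits, in
#'   `ref_lens` order: `ref_id`, `ref_len`, `best_contig_id`,
#'   `best_single_frac`, `union_frac`, `n_contigs_hitting`.
#' @export
reference_coverage <- function(hits, ref_lens, max_evalue = NULL,
                               best_hsp_only = FALSE) {
  if (is.null(names(ref_lens)))
    stop("ref_lens must be a named vector")
  if (!is.null(max_evalue))
    hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(ref_id = character(), ref_len = integer(),
                      best_contig_id = character(),
                      best_single_frac = numeric(), union_frac = numeric(),
                      n_contigs_hitting = integer(),
                      stringsAsFactors = FALSE))
  unknown <- setdiff(unique(hits$sid), names(ref_lens))
  if (length(unknown))
    stop("hit to unknown reference: ", unknown[1L])
  if (any(hits$s_end > ref_lens[hits$sid]))
    stop("subject interval exceeds reference length for ",
         hits$sid[which(hits$s_end > ref_lens[hits$sid])[1L]])
  if (best_hsp_only) {
    ord <- order(hits$sid, hits$qid, -hits$bitscore, hits$evalue)
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(hits[c("sid", "qid")]), , drop = FALSE]
  }
  recs <- lapply(split(hits, hits$sid), function(h) {
    rlen <- ref_lens[[h$sid[1L]]]
    union_cov <- covered_length(h$s_start, h$s_end)
    per_contig <- vapply(split(h, h$qid), function(hc)
      covered_length(hc$s_start, hc$s_end), numeric(1))
    qlen_by_contig <- vapply(split(h, h$qid), function(hc) {
      ql <- hc$qlen[!is.na(hc$qlen)]
      if (length(ql)) as.numeric(ql[1L]) else -1
    }, numeric(1))
    qids <- names(per_contig)
    ord <- order(-per_contig, -qlen_by_contig, qids)
    best <- ord[1L]
    data.frame(ref_id = h$sid[1L], ref_len = rlen,
               best_contig_id = qids[best],
               best_single_frac = per_contig[best] / rlen,
               union_frac = union_cov / rlen,
               n_contigs_hitting = length(qids),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out <- out[order(match(out$ref_id, names(ref_lens))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contiguity, completeness and percent-hits across thresholds
#'
#' @param records Coverage records from [reference_coverage()].
#' @param n_refs Total size of the reference set (the denominator; includes
#'   references without hits).
#' @param thresholds Coverage thresholds in \[0,1\]; default
#'   [default_threshold_sweep()]. Comparison is closed (`>=`).
#' @param among_hits If `TRUE`, renormalise all three metrics by the number
#'   of references with hits instead of `n_refs` (percent-hits then equals
#'   1 at every threshold).
#' @return data.frame with one row per threshold: `threshold`,
#'   `contiguity`, `completeness`, `pct_hits`, all fractions.
#' @export
evaluate_coverage <- function(records, n_refs,
                              thresholds = default_threshold_sweep(),
                              among_hits = FALSE) {
  if (n_refs == 0L) stop("n_refs must be positive")
  if (n_refs < nrow(records))
    stop("n_refs smaller than the number of coverage records")
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]")
  denom <- if (among_hits) max(nrow(records), 1L) else n_refs
  rows <- lapply(thresholds, function(tau) {
    data.frame(threshold = tau,
               contiguity =
                 sum(records$best_single_frac >= tau - .tau_eps) / denom,
               completeness =
                 sum(records$union_frac >= tau - .tau_eps) / denom,
               pct_hits = nrow(records) / denom)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Number of references reaching a contiguity threshold
#'
#' The count (not fraction) of references whose best single contig covers at
#' least `tau` of their length.
#'
#' @param records Coverage records from [reference_coverage()].
#' @param tau Threshold in \[0,1\].
#' @return Integer count.
#' @export
contiguity_count_at <- function(records, tau) {
  if (length(tau) != 1L || is.na(tau) || tau < 0 || tau > 1)
    stop("tau must be a single value in [0, 1]")
  sum(records$best_single_frac >= tau - .tau_eps)
}
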