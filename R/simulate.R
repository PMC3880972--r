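# Synthetic-data generation with exact ground truth: reference proteins and
# CDS with planted flanking stop codons, fragmented "assemblies" with known
# per-reference coverage, error-free read pairs with known placements, and
# motif tables with a known census. Everything is a deterministic function
# of (parameters, seed), so the whole evaluation stack runs end-to-end with
# no external data and no aligner: hit tables are emitted directly from
# placement truth.

.stop_codons <- c("TAA", "TAG", "TGA")

# amino acid -> synonymous codons, standard nuclear code
.aa2codons <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

# uniform integer from [lo, hi], immune to R's sample(length-1) surprise
.sample_int_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  sample(seq(as.integer(lo), as.integer(hi)), 1L)
}

.sample_codons <- function(residues) {
  vapply(.aa2codons[residues], function(cs)
    if (length(cs) == 1L) cs else sample(cs, 1L), "")
}

.random_bases <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a reference gene set with planted ORFs
#'
#' Each gene is a random stop-free peptide whose CDS is a random synonymous
#' back-translation, flanked by an in-frame stop codon immediately 5' and
#' 3' of the ORF plus random UTR padding. Translating the CDS in the
#' planted frame therefore yields the peptide flanked by `*` on both sides.
#'
#' @param n_genes Number of genes (>= 1).
#' @param aa_len Length-2 vector: uniform range of peptide lengths (aa).
#' @param utr_len Length-2 vector: uniform range of UTR pad lengths (nt) on
#'   each side (excluding the planted stops).
#' @param seed Integer seed.
#' @return A list of class `asmqc_truth`: `genes` (data.frame `id`, `cds`,
#'   `orf_start`, `orf_end` — the 0-based half-open nt interval of the
#'   peptide codons — `frame`, `aa_len`), `proteins` (named character), and
#'   `protein_len` (named integer).
#' @export
sim_reference <- function(n_genes, aa_len = c(100, 400),
                          utr_len = c(0, 60), seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (aa_len[1L] < 1L || aa_len[2L] < aa_len[1L] ||
      utr_len[1L] < 0L || utr_len[2L] < utr_len[1L])
    stop("degenerate length parameters")
  aas <- setdiff(names(.aa2codons), "*")
  with_seed(seed, {
    genes <- lapply(seq_len(n_genes), function(i) {
      alen <- .sample_int_range(aa_len[1L], aa_len[2L])
      pep <- paste(sample(aas, alen, replace = TRUE), collapse = "")
      orf <- paste(.sample_codons(strsplit(pep, "")[[1L]]), collapse = "")
      u5 <- .sample_int_range(utr_len[1L], utr_len[2L])
      u3 <- .sample_int_range(utr_len[1L], utr_len[2L])
      cds <- paste0(.random_bases(u5), sample(.stop_codons, 1L), orf,
                    sample(.stop_codons, 1L), .random_bases(u3))
      orf_start <- u5 + 3L
      list(id = sprintf("g%04d", i), cds = cds, pep = pep,
           orf_start = orf_start, orf_end = orf_start + 3L * alen,
           frame = (orf_start %% 3L) + 1L, aa_len = alen)
    })
    out <- list(
      genes = data.frame(
        id = vapply(genes, `[[`, "", "id"),
        cds = vapply(genes, `[[`, "", "cds"),
        orf_start = vapply(genes, `[[`, 0L, "orf_start"),
        orf_end = vapply(genes, `[[`, 0L, "orf_end"),
        frame = vapply(genes, `[[`, 0L, "frame"),
        aa_len = vapply(genes, `[[`, 0L, "aa_len"),
        stringsAsFactors = FALSE),
      proteins = stats::setNames(vapply(genes, `[[`, "", "pep"),
                                 vapply(genes, `[[`, "", "id")))
    out$protein_len <- stats::setNames(nchar(out$proteins),
                                       names(out$proteins))
    class(out) <- "asmqc_truth"
    out
  })
}

#' Fragment a simulated reference into an assembly with known coverage
#'
#' Contigs are random substrings of the CDS (some reverse-complemented,
#' recorded in the frame sign). A perfect hit table is emitted directly
#' from the placements: the subject interval of each hit spans the protein
#' residues whose codons lie *completely* inside the fragment, so hit
#' coordinates, true coverage and anchored translation agree exactly.
#' True per-reference coverage is computed here by a per-position bitmask
#' over those intervals.
#'
#' @param truth An `asmqc_truth` from [sim_reference()].
#' @param fragments_per_gene Fragments per gene; either a single count or a
#'   length-2 range sampled uniformly per gene.
#' @param len_frac Length-2 vector: fragment length as a uniform fraction
#'   of the CDS length.
#' @param revcomp_prob Probability a fragment is reverse-complemented.
#' @param seed Integer seed.
#' @return A list: `contigs` (data.frame `id`, `seq`), `fragments`
#'   (placements: `contig_id`, `ref_id`, `f_start`, `f_end`, `rev`,
#'   `frame`), `hits` (hit data.frame as [read_tabular_hits()], protein
#'   subject coordinates, `qframe` set), `true_coverage` (data.frame
#'   `ref_id`, `best_single_frac`, `union_frac`, `n_contigs_hitting`, only
#'   references with hits), `ref_lens` (named protein lengths, all genes),
#'   and `truth` (the input).
#' @export
sim_fragment_assembly <- function(truth, fragments_per_gene = 2L,
                                  len_frac = c(0.3, 0.9),
                                  revcomp_prob = 0.3, seed = 1L) {
  g <- truth$genes
  if (length(fragments_per_gene) == 1L)
    fragments_per_gene <- rep(fragments_per_gene, 2L)
  with_seed(seed, {
    contigs <- list(); frags <- list(); hits <- list()
    for (i in seq_len(nrow(g))) {
      Lg <- nchar(g$cds[i])
      nf <- .sample_int_range(fragments_per_gene[1L], fragments_per_gene[2L])
      for (k in seq_len(nf)) {
        flen <- max(3L, min(Lg, as.integer(round(
          stats::runif(1, len_frac[1L], len_frac[2L]) * Lg))))
        f1 <- sample.int(Lg - flen + 1L, 1L) - 1L
        f2 <- f1 + flen
        rev <- stats::runif(1) < revcomp_prob
        cid <- sprintf("%s_c%02d", g$id[i], k)
        fwd <- substr(g$cds[i], f1 + 1L, f2)
        contigs[[length(contigs) + 1L]] <- data.frame(
          id = cid, seq = if (rev) revcomp(fwd) else fwd,
          stringsAsFactors = FALSE)
        off <- (g$orf_start[i] - f1) %% 3L
        frame <- if (rev) -(off + 1L) else off + 1L
        frags[[length(frags) + 1L]] <- data.frame(
          contig_id = cid, ref_id = g$id[i], f_start = f1, f_end = f2,
          rev = rev, frame = frame, stringsAsFactors = FALSE)
        # protein residues with complete codons inside the fragment
        o1 <- max(f1, g$orf_start[i]); o2 <- min(f2, g$orf_end[i])
        if (o2 > o1) {
          c1 <- as.integer(ceiling((o1 - g$orf_start[i]) / 3))
          c2 <- (o2 - g$orf_start[i]) %/% 3L
          if (c2 > c1) {
            qa <- g$orf_start[i] + 3L * c1 - f1
            qb <- g$orf_start[i] + 3L * c2 - f1
            if (rev) { tmp <- qa; qa <- flen - qb; qb <- flen - tmp }
            hits[[length(hits) + 1L]] <- data.frame(
              qid = cid, sid = g$id[i], pident = 1,
              aln_len = c2 - c1, mismatch = 0L, gapopen = 0L,
              q_start = qa, q_end = qb, s_start = c1, s_end = c2,
              evalue = 0, bitscore = 2 * (c2 - c1),
              qframe = frame, qlen = flen,
              slen = unname(truth$protein_len[g$id[i]]),
              q_rev = rev, s_rev = FALSE, stringsAsFactors = FALSE)
          }
        }
      }
    }
    hits <- if (length(hits)) do.call(rbind, hits) else empty_hits()
    true_coverage <- .bitmask_coverage(hits, truth$protein_len)
    list(contigs = do.call(rbind, contigs),
         fragments = do.call(rbind, frags),
         hits = hits, true_coverage = true_coverage,
         ref_lens = truth$protein_len, truth = truth)
  })
}

# per-position bitmask coverage over subject intervals: the stored truth is
# computed by direct position marking, not by interval arithmetic
.bitmask_coverage <- function(hits, ref_lens) {
  if (nrow(hits) == 0L)
    return(data.frame(ref_id = character(), best_single_frac = numeric(),
                      union_frac = numeric(), n_contigs_hitting = integer(),
                      stringsAsFactors = FALSE))
  out <- lapply(split(hits, hits$sid), function(h) {
    rlen <- ref_lens[[h$sid[1L]]]
    mask_of <- function(hh) {
      m <- logical(rlen)
      for (r in seq_len(nrow(hh)))
        m[(hh$s_start[r] + 1L):hh$s_end[r]] <- TRUE
      m
    }
    union_frac <- sum(mask_of(h)) / rlen
    per_contig <- vapply(split(h, h$qid), function(hh)
      sum(mask_of(hh)) / rlen, numeric(1))
    data.frame(ref_id = h$sid[1L],
               best_single_frac = max(per_contig),
               union_frac = union_frac,
               n_contigs_hitting = length(unique(h$qid)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$ref_id, names(ref_lens))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate error-free paired reads from a reference
#'
#' Fragments are drawn FR-oriented from random CDS positions: mate 1 is the
#' forward prefix of the fragment, mate 2 the reverse complement of its
#' suffix. Insert sizes are normal, rounded and clamped to
#' `[read_len, cds_len]`. Per-gene abundances are uniform unless `weights`
#' is given.
#'
#' @param truth An `asmqc_truth` from [sim_reference()].
#' @param n_pairs Number of pairs (>= 1).
#' @param read_len Read length (must not exceed the shortest CDS).
#' @param insert_mean,insert_sd Insert-size distribution (nt).
#' @param weights Optional per-gene abundance weights (length `n_genes`).
#' @param seed Integer seed.
#' @return A list: `pairs` (read-pair data.frame with all-`I` qualities),
#'   `placements` (data.frame `id`, `ref_id`, `start1`, `end1`, `start2`,
#'   `end2`, `strand1` — 0-based half-open mate intervals on the CDS), and
#'   `per_gene_counts` (named integer over all genes; sums to `n_pairs`).
#' @export
sim_read_pairs <- function(truth, n_pairs, read_len = 101L,
                           insert_mean = 200, insert_sd = 20,
                           weights = NULL, seed = 1L) {
  if (n_pairs < 1L) stop("n_pairs must be >= 1")
  g <- truth$genes
  cds_len <- nchar(g$cds)
  if (read_len > min(cds_len))
    stop("read_len exceeds the shortest CDS (", min(cds_len), " nt)")
  if (!is.null(weights) && length(weights) != nrow(g))
    stop("weights must have one value per gene")
  with_seed(seed, {
    gi <- sample.int(nrow(g), n_pairs, replace = TRUE, prob = weights)
    len_i <- cds_len[gi]
    ins <- pmin(pmax(round(stats::rnorm(n_pairs, insert_mean, insert_sd)),
                     read_len), len_i)
    start <- floor(stats::runif(n_pairs) * (len_i - ins + 1))
    s1 <- as.integer(start); e1 <- s1 + as.integer(read_len)
    e2 <- as.integer(start + ins); s2 <- e2 - as.integer(read_len)
    r1 <- substring(g$cds[gi], s1 + 1L, e1)
    r2 <- revcomp(substring(g$cds[gi], s2 + 1L, e2))
    qual <- strrep("I", read_len)
    ids <- sprintf("rp%07d", seq_len(n_pairs))
    counts <- tabulate(gi, nbins = nrow(g))
    list(pairs = data.frame(id = ids, seq1 = r1, qual1 = qual,
                            seq2 = r2, qual2 = qual,
                            stringsAsFactors = FALSE),
         placements = data.frame(id = ids, ref_id = g$id[gi],
                                 start1 = s1, end1 = e1,
                                 start2 = s2, end2 = e2,
                                 strand1 = "+", stringsAsFactors = FALSE),
         per_gene_counts = stats::setNames(counts, g$id))
  })
}

#' Convert read placements to duplicate-marking fragment keys
#'
#' @param placements Placement data.frame from [sim_read_pairs()] or a
#'   mapper.
#' @return data.frame `ref_id`, `start1`, `strand1`, `start2` for
#'   [unique_start_fraction()].
#' @export
placements_to_keys <- function(placements) {
  data.frame(ref_id = placements$ref_id, start1 = placements$start1,
             strand1 = placements$strand1, start2 = placements$start2,
             stringsAsFactors = FALSE)
}

#' Simulate a motif table with a known PPR census
#'
#' Plants exactly the requested numbers of P-class genes (only P motifs),
#' PLS-E genes (P/L/S motifs plus at least one E or E+), PLS-DYW genes
#' (P/L/S motifs, optionally E, plus a DYW motif), and single-motif decoys.
#'
#' @param n_p,n_pls_e,n_pls_dyw,n_decoys Counts (>= 0).
#' @param seed Integer seed.
#' @return A list: `motifs` (data.frame as [read_motif_table()]) and
#'   `census` (the true class counts, shaped as [ppr_census()]).
#' @export
sim_motif_table <- function(n_p = 5L, n_pls_e = 3L, n_pls_dyw = 2L,
                            n_decoys = 4L, seed = 1L) {
  if (any(c(n_p, n_pls_e, n_pls_dyw, n_decoys) < 0L))
    stop("counts must be >= 0")
  with_seed(seed, {
    rows <- list()
    gene_i <- 0L
    add_gene <- function(classes) {
      gene_i <<- gene_i + 1L
      id <- sprintf("t%04d", gene_i)
      k <- seq_along(classes)
      rows[[length(rows) + 1L]] <<- data.frame(
        seq_id = id, motif_class = classes,
        start = (k - 1L) * 35L, end = k * 35L,
        score = round(stats::runif(length(k), 10, 50), 1),
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_p))
      add_gene(rep("P", sample(2:8, 1L)))
    for (i in seq_len(n_pls_e))
      add_gene(c(sample(c("P", "L", "S"), sample(2:6, 1L), replace = TRUE),
                 sample(c("E", "E+"), 1L)))
    for (i in seq_len(n_pls_dyw))
      add_gene(c(sample(c("P", "L", "S"), sample(2:6, 1L), replace = TRUE),
                 if (stats::runif(1) < 0.5) "E", "DYW"))
    for (i in seq_len(n_decoys))
      add_gene(sample(c("P", "L", "S", "E", "E+", "DYW"), 1L))
    motifs <- if (length(rows)) do.call(rbind, rows) else
      data.frame(seq_id = character(), motif_class = character(),
                 start = integer(), end = integer(), score = numeric(),
                 stringsAsFactors = FALSE)
    list(motifs = motifs,
         census = data.frame(
           class = c("PPR", "P", "PLS-E", "PLS-DYW", "not-PPR"),
           n = c(n_p + n_pls_e + n_pls_dyw, n_p, n_pls_e, n_pls_dyw,
                 n_decoys),
           stringsAsFactors = FALSE))
  })
}
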