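test_that("frame translation follows the standard code in all six frames", {
  expect_equal(translate_frame("ATGGCC", 1), "MA")
  expect_equal(translate_frame("GGCCAT", -1), "MA")
  expect_equal(translate_frame("TATGGCC", 2), "MA")
  expect_equal(translate_frame("ATGNAA", 1), "MX")   # N codon -> X
  expect_equal(translate_frame("AT", 1), "")          # < one codon
  expect_error(translate_frame("ATG", 4), "frame")

  # cross-check against an independent translation route
  withr::local_seed(13)
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(3:60, 1),
                      replace = TRUE), collapse = "")
    fr <- sample(c(-3:-1, 1:3), 1)
    expect_equal(translate_frame(s, fr), oracle_translate(s, fr),
                 info = paste(s, fr))
  }
})

test_that("anchored translation extends to but excludes flanking stops", {
  # frame +3 codons of GGTAAATGGCTGCTTGAGG: TAA ATG GCT GCT TGA
  r <- anchor_translate_extend("GGTAAATGGCTGCTTGAGG", 8, 14, 3)
  expect_equal(r$peptide, "MAA")
  expect_equal(c(r$q_start_nt, r$q_end_nt), c(5L, 14L))

  # anchor spanning everything: no extension possible
  r2 <- anchor_translate_extend("ATGGCTGCT", 0, 9, 1)
  expect_equal(r2$peptide, translate_frame("ATGGCTGCT", 1))

  # no in-frame stop on either side: extends to outermost complete codons
  r3 <- anchor_translate_extend("CATGGCTGCTCA", 4, 7, 2)
  expect_equal(r3$peptide, translate_frame("CATGGCTGCTCA", 2))

  expect_error(anchor_translate_extend("ATGGCT", 0, 6, NA), "frame required")
})

test_that("anchors are snapped outward to codon boundaries", {
  # off-phase anchor [9,13) in frame +3 snaps out to [8,14): same MAA window
  r <- anchor_translate_extend("GGTAAATGGCTGCTTGAGG", 9, 13, 3)
  expect_equal(r$peptide, "MAA")
  expect_error(
    anchor_translate_extend("GGTAAATGGCTGCTTGAGG", 9, 13, 3, strict = TRUE),
    "codon-aligned")
})

test_that("in-anchor stops error under strict and truncate otherwise", {
  # frame +1: ATG TAA GCC — anchor covers all three codons
  expect_error(
    anchor_translate_extend("ATGTAAGCC", 0, 9, 1, strict = TRUE),
    "stop codon inside anchor")
  expect_message(r <- anchor_translate_extend("ATGTAAGCC", 0, 9, 1),
                 "truncated")
  expect_equal(r$peptide, "M")
})

test_that("every output peptide is a stop-flanked window of its frame", {
  n_checked <- 0
  for (i in 1:60) {
    ref <- sim_reference(3, aa_len = c(20, 60), utr_len = c(0, 30),
                         seed = 5000 + i)
    asm <- sim_fragment_assembly(ref, c(1, 3), len_frac = c(0.2, 1),
                                 revcomp_prob = 0.5, seed = 6000 + i)
    if (nrow(asm$hits) == 0) next
    seqs <- setNames(asm$contigs$seq, asm$contigs$id)
    for (k in seq_len(nrow(asm$hits))) {
      h <- asm$hits[k, ]
      r <- anchor_translate_extend(seqs[[h$qid]], h$q_start, h$q_end,
                                   h$qframe)
      full <- oracle_translate(seqs[[h$qid]], h$qframe)
      expect_false(grepl("*", r$peptide, fixed = TRUE))
      expect_equal(3L * nchar(r$peptide), r$q_end_nt - r$q_start_nt)
      hit_at <- regexpr(r$peptide, full, fixed = TRUE)
      expect_true(hit_at > 0)
      # flanking characters in the full-frame translation, if any, are stops
      windows <- gregexpr(r$peptide, full, fixed = TRUE)[[1]]
      flank_ok <- vapply(windows, function(w) {
        pre <- if (w > 1) substr(full, w - 1, w - 1) else "*"
        post_pos <- w + nchar(r$peptide)
        post <- if (post_pos <= nchar(full))
          substr(full, post_pos, post_pos) else "*"
        pre == "*" && post == "*"
      }, logical(1))
      expect_true(any(flank_ok))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 100)
})

test_that("translate_assembly recovers planted peptides on clean fixtures", {
  ref <- sim_reference(10, aa_len = c(60, 120), utr_len = c(5, 40),
                       seed = 91)
  asm <- sim_fragment_assembly(ref, 1, len_frac = c(1, 1),
                               revcomp_prob = 0.5, seed = 92)
  tr <- translate_assembly(asm$contigs, asm$hits, min_aa = 50)
  expect_equal(nrow(tr$peptides), 10)
  planted <- unname(ref$proteins[
    asm$fragments$ref_id[match(tr$peptides$contig_id,
                               asm$fragments$contig_id)]])
  expect_identical(tr$peptides$peptide, planted)
  expect_equal(tr$summary$n_contigs, 10)
})

test_that("translated peptides are deduplicated and length-filtered", {
  # two contigs encoding the same peptide, one 49-aa peptide
  pep_long <- strrep("MA", 30)                # 60 aa
  pep_short <- paste0("M", strrep("A", 48))   # 49 aa
  to_cds <- function(p) {
    codons <- c(M = "ATG", A = "GCT")
    paste0("TAA", paste(codons[strsplit(p, "")[[1]]], collapse = ""), "TGA")
  }
  contigs <- data.frame(id = c("c1", "c2", "c3"),
                        seq = c(to_cds(pep_long), to_cds(pep_long),
                                to_cds(pep_short)),
                        stringsAsFactors = FALSE)
  hit_for <- function(id, n_aa) {
    data.frame(qid = id, sid = "r", pident = 1, aln_len = n_aa,
               mismatch = 0L, gapopen = 0L, q_start = 3L,
               q_end = 3L + 3L * n_aa, s_start = 0L, s_end = n_aa,
               evalue = 0, bitscore = 2 * n_aa, qframe = 1L,
               qlen = NA_integer_, slen = NA_integer_,
               q_rev = FALSE, s_rev = FALSE, stringsAsFactors = FALSE)
  }
  hits <- rbind(hit_for("c1", 60), hit_for("c2", 60), hit_for("c3", 49))
  tr <- translate_assembly(contigs, hits, min_aa = 50)
  expect_equal(tr$peptides$contig_id, "c1")   # duplicate and 49-mer dropped
  expect_equal(tr$redundancy, 1 / 3)

  expect_error(translate_assembly(contigs[1, ], hits),
               "absent from the contig set")
})

test_that("one peptide per contig comes from the best-bitscore hit", {
  contig <- data.frame(id = "c", seq = "TAAATGGCTGCTTGA",
                       stringsAsFactors = FALSE)
  h <- function(bs, ev, q0, q1) {
    data.frame(qid = "c", sid = "r", pident = 1, aln_len = 2L,
               mismatch = 0L, gapopen = 0L, q_start = q0, q_end = q1,
               s_start = 0L, s_end = 2L, evalue = ev, bitscore = bs,
               qframe = 1L, qlen = NA_integer_, slen = NA_integer_,
               q_rev = FALSE, s_rev = FALSE, stringsAsFactors = FALSE)
  }
  hits <- rbind(h(10, 1e-5, 3, 9), h(80, 1e-20, 6, 12))
  tr <- translate_assembly(contig, hits, min_aa = 1)
  expect_equal(nrow(tr$peptides), 1)
  expect_equal(tr$peptides$peptide, "MAA")
})
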