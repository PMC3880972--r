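make_hit <- function(qid, sid, s_start, s_end, qlen = NA_integer_,
                     bitscore = 50, evalue = 0) {
  data.frame(qid = qid, sid = sid, pident = 1,
             aln_len = s_end - s_start, mismatch = 0L, gapopen = 0L,
             q_start = 0L, q_end = 3L * (s_end - s_start),
             s_start = as.integer(s_start), s_end = as.integer(s_end),
             evalue = evalue, bitscore = bitscore,
             qframe = 1L, qlen = as.integer(qlen), slen = NA_integer_,
             q_rev = FALSE, s_rev = FALSE, stringsAsFactors = FALSE)
}

test_that("interval merging coalesces touching and nested intervals", {
  expect_equal(merge_intervals(c(0, 5), c(5, 10)),
               data.frame(start = 0L, end = 10L))
  expect_equal(merge_intervals(c(0, 2), c(10, 5)),
               data.frame(start = 0L, end = 10L))
  expect_error(merge_intervals(5, 5), "start >= end")

  # covered length equals a per-position bitmask count
  withr::local_seed(3)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    s <- sample(0:80, n, replace = TRUE)
    e <- s + sample(1:30, n, replace = TRUE)
    m <- merge_intervals(s, e)
    mask <- rep(FALSE, 200)
    for (k in seq_len(n)) mask[(s[k] + 1):e[k]] <- TRUE
    expect_equal(sum(m$end - m$start), sum(mask))
    expect_true(all(diff(m$start) > 0))
    expect_true(all(m$end[-nrow(m)] < m$start[-1]))  # disjoint, non-touching
  }
})

test_that("per-reference coverage separates best-single from union", {
  # two contigs spanning [0,50) and [40,100) of a 100-residue reference
  hits <- rbind(make_hit("X", "r", 0, 50), make_hit("Y", "r", 40, 100))
  rec <- reference_coverage(hits, c(r = 100L))
  expect_equal(rec$best_single_frac, 0.60)
  expect_equal(rec$best_contig_id, "Y")
  expect_equal(rec$union_frac, 1.00)
  expect_equal(rec$n_contigs_hitting, 2L)

  # one contig, two overlapping HSPs: merged before the fraction
  hits2 <- rbind(make_hit("X", "r", 0, 30), make_hit("X", "r", 20, 60))
  rec2 <- reference_coverage(hits2, c(r = 100L))
  expect_equal(rec2$best_single_frac, 0.60)
  expect_equal(rec2$union_frac, 0.60)

  # references without hits are omitted
  rec3 <- reference_coverage(hits, c(r = 100L, s = 80L))
  expect_equal(rec3$ref_id, "r")

  expect_error(reference_coverage(make_hit("X", "zz", 0, 10), c(r = 100L)),
               "unknown reference")
  expect_error(reference_coverage(make_hit("X", "r", 0, 120), c(r = 100L)),
               "exceeds reference length")
})

test_that("best-contig ties break by longer qlen then smaller qid", {
  hits <- rbind(make_hit("B", "r", 0, 50, qlen = 200),
                make_hit("A", "r", 50, 100, qlen = 100))
  expect_equal(reference_coverage(hits, c(r = 100L))$best_contig_id, "B")
  hits_eq <- rbind(make_hit("B", "r", 0, 50, qlen = 150),
                   make_hit("A", "r", 50, 100, qlen = 150))
  expect_equal(reference_coverage(hits_eq, c(r = 100L))$best_contig_id, "A")
})

test_that("threshold metrics follow the closed >= convention", {
  records <- data.frame(ref_id = c("r1", "r2"),
                        ref_len = c(100L, 100L),
                        best_contig_id = c("a", "b"),
                        best_single_frac = c(0.9, 0.5),
                        union_frac = c(0.95, 0.85),
                        n_contigs_hitting = c(1L, 2L),
                        stringsAsFactors = FALSE)
  ev <- evaluate_coverage(records, n_refs = 4, thresholds = 0.8)
  expect_equal(ev$contiguity, 0.25)
  expect_equal(ev$completeness, 0.50)
  expect_equal(ev$pct_hits, 0.50)

  # at threshold 0 all three coincide
  ev0 <- evaluate_coverage(records, n_refs = 4, thresholds = 0)
  expect_equal(ev0$contiguity, ev0$pct_hits)
  expect_equal(ev0$completeness, ev0$pct_hits)

  empty <- records[0, ]
  expect_equal(unlist(evaluate_coverage(empty, 4, 0.5)[
    c("contiguity", "completeness", "pct_hits")]),
    c(contiguity = 0, completeness = 0, pct_hits = 0))
  expect_error(evaluate_coverage(records, 0), "n_refs")

  expect_equal(contiguity_count_at(records, 0.8), 1L)
  expect_equal(contiguity_count_at(records, 0), 2L)
  expect_error(contiguity_count_at(records, 1.01), "\\[0, 1\\]")

  # among-hits renormalisation
  evh <- evaluate_coverage(records, n_refs = 4, thresholds = 0.8,
                           among_hits = TRUE)
  expect_equal(evh$completeness, 1.0)
  expect_equal(evh$pct_hits, 1.0)
})

test_that("coverage fractions equal the bitmask oracle on random fixtures", {
  for (i in 1:60) {
    ref <- sim_reference(sample(2:6, 1), aa_len = c(30, 90),
                         utr_len = c(0, 40), seed = 1000 + i)
    asm <- sim_fragment_assembly(ref, c(1, 4), len_frac = c(0.15, 1),
                                 revcomp_prob = 0.4, seed = 2000 + i)
    if (nrow(asm$hits) == 0) next
    rec <- reference_coverage(asm$hits, asm$ref_lens)
    ora <- oracle_coverage(asm$hits, asm$ref_lens)
    expect_equal(rec$ref_id, ora$ref_id)
    expect_identical(rec$best_single_frac, ora$best_single_frac)
    expect_identical(rec$union_frac, ora$union_frac)
    expect_equal(rec$n_contigs_hitting, ora$n_contigs_hitting)
  }
})

test_that("contiguity and completeness are monotone and dominated", {
  taus <- default_threshold_sweep()
  for (i in 1:25) {
    ref <- sim_reference(5, aa_len = c(30, 80), seed = 300 + i)
    asm <- sim_fragment_assembly(ref, c(1, 3), seed = 400 + i)
    rec <- reference_coverage(asm$hits, asm$ref_lens)
    ev <- evaluate_coverage(rec, length(asm$ref_lens), taus)
    expect_true(all(diff(ev$contiguity) <= 0))
    expect_true(all(diff(ev$completeness) <= 0))
    expect_true(all(ev$completeness >= ev$contiguity))
    expect_true(all(ev$pct_hits >= ev$completeness))
    expect_equal(ev$contiguity[ev$threshold == 0], ev$pct_hits[1])

    # adding hits from a new contig never decreases union coverage
    r1 <- rec$ref_id[1]
    extra <- asm$hits[asm$hits$sid == r1, , drop = FALSE][1, ]
    extra$qid <- "novel_contig"
    rec2 <- reference_coverage(rbind(asm$hits, extra), asm$ref_lens)
    expect_true(all(rec2$union_frac >= rec$union_frac))
    ev2 <- evaluate_coverage(rec2, length(asm$ref_lens), taus)
    expect_true(all(ev2$completeness >= ev$completeness))
  }
})

test_that("a reference set evaluated against itself is perfect at tau = 1", {
  ref <- sim_reference(8, aa_len = c(40, 100), seed = 77)
  asm <- sim_fragment_assembly(ref, 1, len_frac = c(1, 1), seed = 78)
  rec <- reference_coverage(asm$hits, asm$ref_lens)
  ev <- evaluate_coverage(rec, length(asm$ref_lens), thresholds = 1)
  expect_equal(ev$contiguity, 1.0)
  expect_equal(ev$completeness, 1.0)
  expect_equal(ev$pct_hits, 1.0)
})

test_that("best-HSP-only mode uses one HSP per contig-reference pair", {
  hits <- rbind(make_hit("X", "r", 0, 30, bitscore = 90),
                make_hit("X", "r", 50, 100, bitscore = 40))
  rec <- reference_coverage(hits, c(r = 100L), best_hsp_only = TRUE)
  expect_equal(rec$union_frac, 0.30)
  rec_all <- reference_coverage(hits, c(r = 100L))
  expect_equal(rec_all$union_frac, 0.80)
})
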