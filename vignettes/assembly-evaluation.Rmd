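---
title: "Evaluating de novo transcriptome assemblies with asmqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating de novo transcriptome assemblies with asmqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmqc)
```

## The evaluation model

A de novo transcriptome assembly of a non-model organism cannot be
validated against a genome. `asmqc` instead scores the assembly against a
panel of conserved reference proteins: contigs are aligned to the panel
with a translated search (the package consumes the tabular hit file; it
does not run the aligner), and every reference transcript is summarised by
two coverage fractions. The *union* fraction is the proportion of its
residues covered by any aligned contig, with the HSPs of each contig
merged first so overlap is never double-counted and no fraction can exceed
one. The *best-single* fraction is the largest coverage achieved by one
contig on its own. Sweeping a coverage threshold τ over [0, 1] yields
three panel-level curves:

* **completeness(τ)** — fraction of the panel with union coverage ≥ τ;
* **contiguity(τ)** — fraction with best-single coverage ≥ τ;
* **percent hits** — fraction with at least one hit (constant in τ).

Completeness measures breadth of gene space recovered; the gap between
completeness and contiguity measures fragmentation — genes present only as
stacks of partial contigs. The threshold comparison is closed (≥),
matching the conventional "≥ 80%" reporting; 0.8 is the package default
and the default sweep is 0 plus 0.05 steps to 1.

Two definitional choices here were genuinely open and are worth stating.
First, "covered by a single longest contig" is implemented as the contig
*achieving maximal coverage* of the reference (its own HSPs merged), not
the contig of maximal sequence length; ties break by longer contig length
(`qlen`) and then lexicographically smaller id, so results are
deterministic. Second, the denominator of all three metrics is the full
panel size, so percent-hits is informative on its own; an `among_hits`
switch renormalises by the number of references with hits when comparing
against tools that report that convention.

## Summary statistics and redundancy

Redundancy emulates clustering at the 100% identity threshold: a contig is
removed iff its sequence is an exact full-length substring of a longer
retained contig (equal-length exact duplicates keep the first in input
order). This is deliberately containment, not mere duplicate removal —
at threshold 1.0 a clustering tool folds contained sequences into their
container — and a `mode = "exact"` flag provides the duplicate-only
variant. Redundancy is `(n_before − n_after) / n_before`. Summary
statistics (count, total bases, max/min/mean, N50) are computed after
clustering and after discarding contigs below a length cutoff: 200 nt for
nucleotide sets, 50 aa for translated sets. N50 uses the weighted-median
definition (largest L such that sequences ≥ L hold half the bases); ties
are resolved by the definition itself.

## Anchored translate-and-extend

Translated contigs are produced from alignment anchors rather than by de
novo ORF scanning: the aligned region of a contig, in the reading frame
reported by the search (`qframe`), is translated and then extended
codon-by-codon in both directions until a stop codon is encountered; the
stop is excluded, and the peptide interval is reported on the forward
strand of the contig. Numerical and edge-case policy:

* the anchor interval is snapped *outward* to the codon boundaries of the
  frame phase (alignment columns need not respect codon boundaries, and
  outward snapping never discards anchored residues), then clamped to
  complete codons;
* no start codon is required — peptides may begin mid-ORF, because
  extension is defined by stops only;
* a codon containing N translates to X and does **not** stop extension
  (ambiguity is not evidence of a stop);
* a stop *inside* the anchor is an error under `strict = TRUE`, otherwise
  the anchor is truncated at the first in-anchor stop with a message;
* one peptide per contig, anchored on its best hit (highest bitscore,
  ties by lowest evalue, then input order) — mirroring single-target
  search output; contigs with HSPs in several frames use only that hit's
  frame.

Every output peptide is therefore a stop-free window of the full-frame
translation whose flanking characters, where they exist, are stops — an
invariant the test suite checks against an independent translation route.
Translated sets are then deduplicated with the same containment rule and
filtered at 50 aa before summarisation.

## Read subsampling and the saturation experiment

The depth question — how many reads does a good assembly need — is
answered by evaluating subsamples at increasing proportions.
`subsample_pairs()` draws `k = round-half-up(p·n)` pairs (clamped to
[1, n]) uniformly without replacement, never separating mates and
preserving input order; each (proportion, replicate) run derives its seed
deterministically from the base seed, so a whole experiment reproduces
from one integer. Each proportion except 100% is replicated (default 3)
and replicate metrics are aggregated as mean ± sample sd.

Assembling each subsample with a real assembler is out of scope, so the
package evaluates subsamples through exact read placements: each retained
pair contributes its two mate intervals to the union coverage of its
source reference. For the error-free simulated reads this placement is
known in closed form and is exactly what exhaustive exact matching would
recover; any real mapper's placement table can be substituted through the
same interface. This preserves the *shape* of the saturation experiment
at desk scale without claiming assembler equivalence.

The packaged study condition is 200 genes (150–500 aa) and 200,000 pairs
(101 nt reads, 200 ± 20 nt inserts) at proportions 5–100% with 3
replicates — sizes chosen so the experiment completes in about a minute on
one CPU while leaving the low-proportion regime unsaturated. Per-gene
abundances follow lognormal weights (sdlog = 1.5): a normalised cDNA
library flattens but does not equalise transcript abundance, and it is the
residual spread that makes coverage saturate gradually rather than
instantly. Under these conditions mean completeness at τ = 0.8 rises
steeply to ~40% of reads and gains only a few points thereafter — the
plateau the acceptance suite asserts.

## Library QC and the gene census

Read filtering drops a pair when either mate is shorter than 50 nt or its
poly-adenosine content exceeds 6%. The poly-A rule is read as the longest
A (or T, catching reverse-complemented tails) homopolymer run as a
fraction of read length: a literal *total* A content above 6% would
discard essentially every read, since A alone averages 25%. Both readings
are implemented (`polya_mode = "run"` / `"total"`), with run the default.
rRNA content is the fraction of reads assigned to rRNA references;
library complexity is the fraction of distinct fragment keys (reference,
both mate starts, strand) among mapped pairs — the paired-end
duplicate-marking identity. Mapping itself is out of scope: both
operations consume counts or key tables from any mapper, or from the
simulator's exact placements.

For the PPR census, a transcript with more than one PPR motif (any class)
counts as a PPR gene; class priority is DYW > E/E+ > P, mirroring
standard PPR nomenclature, so a PLS-pattern transcript without E or DYW
motifs falls to P (no separate PLS row exists in the census). Whether
motifs should be counted per transcript or per reading frame was open;
per transcript is implemented. Reciprocal best hits take the best hit per
query (bitscore, then evalue, then smallest subject id — evalue ties at
0.0 are common, hence bitscore first), truncating to one target per query
before requiring reciprocity. Pairwise identity defaults to matches over
all alignment columns (gapped columns count against identity), with an
ungapped-denominator option since reporting conventions differ.

## The fixture generator, and what passing tests do not show

`sim_reference()` plants random stop-free peptides in synonymous
back-translated CDS with an in-frame stop immediately 5' and 3' of the
ORF plus random UTR padding; `sim_fragment_assembly()` cuts contigs from
the CDS (reverse-complementing some) and emits the corresponding perfect
hit table directly from the placements — no aligner involved. The subject
interval of an emitted hit covers exactly the protein residues whose
codons lie completely inside the fragment (partial codons at fragment
edges are excluded on both sides): a residue is claimed iff its codon is
translatable from the contig, which keeps hit tables, stored coverage
truth and anchored translation mutually exact, and makes the closure
property — evaluation of the emitted hits reproduces stored truth
*exactly* — testable at zero tolerance. Stored truth is computed by
per-position bitmasking, a different route than the interval arithmetic
used by the evaluator.

The generator emulates what the metrics measure, not what real data look
like. It produces no sequencing errors, no polymorphism or paralogy, no
chimeric or misassembled contigs, no spurious alignments, and its
"assembly" is a set of exact substrings. Passing tests therefore
demonstrate that the metrics, translation and subsampling machinery are
computed correctly, and nothing about how any particular assembler
behaves on real reads. Acceptance-style checks on real data still require
real alignments supplied through the hit-file interface.

## Problem sizes and determinism

The test suite checks the coverage engine against a brute-force
per-position oracle on 1000 random fixture assemblies, translation
containment on 500+ anchors, N50 on 1000 random length multisets, and
subsampling uniformity over 2000 seeds; the saturation experiment runs at
the 200-gene/200k-pair condition above. All generators and all sampling
flow from explicit integer seeds through one derivation function, and the
RNG kind is pinned (Mersenne-Twister, rejection sampling), so identical
inputs yield byte-identical outputs across runs and platforms.

## Known limitations

* Containment dedup is exact only; near-duplicates (sequencing-error
  copies) are not clustered, so redundancy is a lower bound on real data.
* Coverage is computed on subject (protein) coordinates only; query-side
  coverage of contigs is not reported.
* The saturation proxy scores read placements, not assemblies; absolute
  completeness values are not comparable with assembler-based curves,
  only the shape is.
* Frameshifted contigs yield a peptide from the best hit's frame only.
* FASTQ parsing targets the plain 4-line dialect; multi-line FASTQ and
  gzip transparency are not supported.
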