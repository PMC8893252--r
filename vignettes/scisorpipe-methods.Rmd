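---
title: "Methods: from barcoded long reads to improved gene models"
author: "scisorpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from barcoded long reads to improved gene models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scisorpipe)
```

## The problem

Draft genome annotations — especially for non-mammalian model organisms —
systematically under-annotate 3'-UTRs and miss splice variants. Because
droplet scRNA-seq chemistries sequence the 3' end of transcripts, reads from
genes with truncated 3'-UTR models fall outside the annotated gene body and
are silently discarded during quantification. Single-cell isoform sequencing
(ScISOr-Seq) — long-read sequencing of 10x-barcoded full-length cDNA — lets
one rebuild gene models from full-length molecules while retaining the cell
barcode and UMI of every read. `scisorpipe` implements that rebuild as a
testable pipeline: read processing, intron-chain collapse, SQANTI-style
structural classification with artifact filters, reference merging, and
quantification of the resulting 5'/3' gene-end improvements.

## Read model and processing

A full-length sense read is assumed to have the 10x 3' GEX v3.1 structure

```
5'-primer | cDNA | polyA tail | rc(UMI) | rc(cell barcode) | rc(3'-primer)
```

with an optional sample barcode flanking either terminus. All elements are
configurable through `read_layout()`; the defaults are the v3.1 NextGem
lengths (16 nt cell barcode, 12 nt UMI) and the library's primer sequences.
Processing proceeds in this order:

1. **Sample-barcode clipping.** Terminal occurrences of the sample barcode
   (either orientation, edit distance ≤ 2) are removed; interior sequence is
   never modified.
2. **Orientation.** Both the read and its reverse complement are scored for
   a 5'-primer hit at the start and a reverse-complemented 3'-primer hit at
   the end (semi-global edit distance ≤ 3 by default, lowest-edit leftmost
   occurrence). The better-supported orientation wins; reads matching fully
   in both orientations are palindromic artifacts and are rejected. Reads
   missing one or both primers are routed to a rejects stream with category
   `MISSING_5P`, `MISSING_3P` or `MISSING_BOTH`.
3. **Barcode extraction.** The 28 nt immediately 5' of the 3'-primer hit
   are read as rc(cell barcode) (proximal 16 nt) and rc(UMI) (distal 12 nt);
   a `umi_proximal` flag swaps the block order for other chemistries. Reads
   whose inter-primer region is shorter than the barcode block are rejected.
4. **polyA trimming.** The maximal 3'-terminal window of the remaining
   insert containing at most `max_non_a = 2` non-A bases is identified and
   shrunk so it starts on an A; if it reaches `min_polya_len = 10` nt it is
   removed as the tail, otherwise the read is categorised `NO_POLYA`.
5. **Deduplication.** One representative is kept per (cell barcode, UMI)
   key — the longest cDNA, ties broken by read id. No whitelist correction
   is applied: duplicate detection operates on raw barcodes, which matches
   a processing script that saves barcodes without correcting them.

Two boundary conditions deserve notice. First, edit-distance primer
matching tolerates indels, so a substitution at the terminal primer base
can shift a detected boundary by one; at 1% uniform substitution error this
and barcode-internal errors leave ≥ 95% of reads with exactly recovered raw
barcodes (the simulator reports both planted and as-sequenced barcodes, and
recovery is measured against the as-sequenced values, since uncorrected
extraction is the defined task). Second, the cDNA/polyA boundary is not
identifiable when the cDNA itself ends in adenines; the simulator therefore
records the *recoverable* cDNA — terminal bases indistinguishable from the
tail are assigned to the tail by an independent reference scan — and exact
recovery is asserted against that, while the trimmer is separately
cross-checked against a brute-force windowed-scan oracle.

## Collapse by intron chain

Splice-aware alignments (SAM with N CIGAR operations) are filtered on query
coverage `c = aligned query bases / full query length ≥ 0.99` and identity
`I = (aligned − edit distance)/aligned ≥ 0.95`, the conventional thresholds
for full-length transcript collapse. Passing multi-exon reads on one
chromosome and strand collapse into a single model when their intron chains
are identical (`junction_tol = 0`; a tolerance knob exists but exact splice
sites are the conservative default). The model's span is the widest member
span — long-read 5' truncation then only shortens support, never fabricates
junctions. Mono-exon reads cluster by single-linkage reciprocal overlap
≥ 0.5. Models are numbered `PB.<locus>.<n>` deterministically, so collapse
is invariant to input order and idempotent.

## Structural classification

Each collapsed isoform is compared with the reference annotation through a
fixed decision list: FSM (intron chain equals a reference transcript's) →
ISM (consecutive sub-chain) → FUSION (exonic overlap with ≥ 2 mutually
disjoint same-strand genes) → NIC (all donors and acceptors known, chain
new) → NNC (≥ 1 novel site; flagged `intron_retention` when a query exon
fully contains a reference intron) → INTERGENIC / GENIC. Same-strand genes
take priority; mono-exon queries are FSM only against a mono-exon reference
transcript at reciprocal overlap ≥ 0.5 (the threshold is a package choice —
"reciprocal overlap" alone does not fix one). FSM isoforms are
sub-categorised by strand-aware end differences with `end_tol = 50` nt:
`reference_match`, `alt_3`, `alt_5`, or `alt_3_and_5`.

Two artifact filters mirror common long-read QC practice:

* **Intra-priming** — the 20 nt genomic window downstream of the 3' end is
  ≥ 60% A on the transcript strand, the signature of oligo-dT priming on
  genomic adenine runs rather than a real tail.
* **RT template switching** — the 8 nt ending at the donor site equal the
  8 nt ending at the acceptor's upstream flank (a direct repeat lets the
  reverse transcriptase jump templates and fabricate a junction).

Flagged isoforms are removed, except that FSM isoforms are exempt from
intra-priming removal by default: an annotated model that happens to sit on
an A-rich stretch is more likely real than artifactual, and removing known
genes wholesale is the costlier error. The exemption is a documented knob
(`fsm_exempt = FALSE` restores unconditional removal).

## Merging and identifier assignment

Retained isoforms are pooled with the reference; genes are re-formed as
connected components of same-strand transcripts sharing ≥ 1 nt of exonic
overlap (span overlap alone would chain neighbouring genes across shared
introns). With `dedup = TRUE`, transcripts with byte-identical exon chains
collapse to one record, keeping the reference copy. Components containing
reference transcripts adopt the reference gene id and name — when two
reference genes land in one component the larger exonic overlap wins and
the conflict is reported — and isoform-only components receive sequential
`NOVELG_%06d` ids in genomic order. Genes on the mitochondrial contig get
an `MT-` name prefix (idempotently), matching the convention expression
pipelines use to compute mitochondrial fractions.

## Quantifying annotation improvement

For every gene id shared by two annotations, `gene_end_shifts()` reports
strand-aware signed end changes: on the plus strand
`delta5 = new.start − old.start`, `delta3 = new.end − old.end`; minus-strand
formulas mirror them so a 3'-UTR extension is positive and an earlier start
negative on either strand. `terminal_exon_read_counts()` counts reads
overlapping the first and last exon (strand-aware, taken from the longest
transcript — the definition is a package choice) by ≥ 1 nt, each read at
most once per exon. Summaries use the lower median for even n, keeping
every reported value an observed integer. Genes present in only one
annotation are excluded from medians and counted separately.

## The simulator and what it does (not) show

`make_genome()`, `make_annotation()`, `truncate_utrs()`,
`simulate_scisoseq_reads()` and `simulate_alignments()` generate a complete
study in code, fully determined by a seed. The defaults describe a compact
vertebrate-like locus structure: 2–8 exons of 100–400 nt, introns of
60–1500 nt, a 100–400 nt 3'-UTR carried by the terminal exon, genes placed
without overlap at ≥ 500 nt spacing on both strands; polyA tails are
uniform 20–60 nt; cell barcodes are drawn at pairwise Hamming distance ≥ 4
so duplicate-removal tests are unambiguous; sequencing noise is uniform
substitution only, which keeps simulated CIGARs exact (an indel mode would
require CIGAR adjustment and is deliberately out of the default model).
Structural categories are planted with exact largest-remainder counts, not
sampled, so category recovery can be asserted exactly.

Simulated alignments encode the *true* exon chains with NM set from the
planted errors — they bypass an aligner by design, so pipeline tests
measure the package's own logic, not minimap2's. Consequently, passing
tests demonstrate correctness of processing, collapse, classification,
merging and comparison under the stated read model; they do not demonstrate
robustness to real PacBio error profiles, alignment ambiguity, ambient RNA,
doublets, or expression-level variation, none of which the simulator
models.

Problem sizes used by the test-suite and the acceptance script — 2,000
reads for recovery checks, 25 transcripts for collapse, a 200-gene
annotation for the classifier self-test, 100 random annotations for format
stability — were chosen as the package's standard verification scale: large
enough that every code path and both strands are exercised many times,
small enough to run comfortably on one CPU.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open, genomic ascending, converted
  exactly once at the I/O layer (GTF 1-based inclusive on disk; BED12
  native). Round trips are byte-stable: records are ordered by
  (chrom, start, gene_id, transcript_id) and GTF attributes are emitted in
  the fixed order gene_id, transcript_id, gene_name.
* Identity computation prefers the NM tag, falls back to parsing MD, and
  errors when both are absent rather than guessing.
* Empty inputs yield empty outputs with zero counts everywhere except
  `summarize_shifts()` and `classification_summary()`, which refuse empty
  input (a median or proportion of nothing is undefined).
* Ties are broken lexicographically everywhere (dedup representatives,
  FSM candidate matches, largest-overlap identifier conflicts), making
  every output order-invariant and rerun-stable.

## Limitations

Fusion detection requires mutually disjoint partner genes and therefore
does not call read-through into overlapping genes; no CDS inference is done
for novel isoforms (reference CDS records pass through unchanged); barcode
correction against a whitelist is intentionally out of scope; and
paper-scale results on real libraries (read-retention gains from
re-annotation, category proportions of a real transcriptome) require real
sequencing data and a quantifier, which this package does not ship.
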