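# shared in-code fixtures

# two genes on chr1 (one per strand), one gene on chr2
tiny_annotation <- function() {
  tx <- data.frame(
    transcript_id = c("t1", "t2", "t3"),
    gene_id = c("g1", "g2", "g3"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    source = "ensembl",
    gene_name = c("alpha", "beta", NA),
    stringsAsFactors = FALSE)
  ex <- data.frame(
    transcript_id = c("t1", "t1", "t2", "t2", "t2", "t3"),
    start = c(100L, 300L, 1000L, 1500L, 2000L, 50L),
    end = c(200L, 400L, 1200L, 1700L, 2300L, 450L),
    stringsAsFactors = FALSE)
  annotation(tx, ex)
}

# a random annotation over a fresh genome; returns both
random_fixture <- function(seed, n_genes = 20L, n_chrom = 2L,
                           chrom_len = 250000L, ...) {
  genome <- make_genome(n_chrom, chrom_len, 0.5, seed = seed)
  ann <- make_annotation(genome, n_genes, seed = seed + 1L, ...)
  list(genome = genome, annotation = ann$annotation, truth = ann$truth)
}

# assemble a full-length read by the library construct
build_read <- function(cdna, cb, umi, layout = read_layout(), tail = 30L,
                       p5 = TRUE, p3 = TRUE, polya = TRUE) {
  paste0(if (p5) layout$p5_primer else "",
         cdna,
         if (polya) strrep("A", tail) else "",
         if (p3) paste0(revcomp(umi), revcomp(cb), revcomp(layout$p3_primer))
         else "")
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# mirror an annotation through coordinate reflection (x -> L - x) with
# strand flip, per contig lengths
reflect_annotation <- function(annot, contig_len) {
  tx <- annot$transcripts
  ex <- annot$exons
  L <- contig_len[tx$chrom[match(ex$transcript_id, tx$transcript_id)]]
  new_start <- L - ex$end
  new_end <- L - ex$start
  ex$start <- as.integer(new_start)
  ex$end <- as.integer(new_end)
  tx$strand <- ifelse(tx$strand == "+", "-", "+")
  annotation(tx, ex)
}

reflect_genome <- function(genome) {
  Biostrings::reverseComplement(genome)
}
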