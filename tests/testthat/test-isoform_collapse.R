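# build a scisor_alignments object directly from read descriptions
make_aln <- function(reads, exons) {
  structure(list(reads = reads, exons = exons,
                 skipped = c(unmapped = 0L, non_primary = 0L)),
            class = "scisor_alignments")
}

aln_from_chains <- function(chains, chrom = "chr1", strand = "+") {
  ids <- names(chains)
  reads <- data.frame(read_id = ids, chrom = chrom, strand = strand,
                      coverage = 1, identity = 1,
                      cell_barcode = NA_character_, umi = NA_character_,
                      stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(ids, function(r) {
    data.frame(read_id = r, start = chains[[r]][, 1], end = chains[[r]][, 2],
               stringsAsFactors = FALSE)
  }))
  make_aln(reads, exons)
}

test_that("coverage and identity follow their definitions", {
  rec <- function(cigar, nm, md = NA_character_) {
    data.frame(read_id = "r", flag = 0L, chrom = "c", pos = 1L, mapq = 60L,
               cigar = cigar, seq = "*", nm = nm, md = md,
               cell_barcode = NA_character_, umi = NA_character_,
               stringsAsFactors = FALSE)
  }
  expect_equal(compute_alignment_metrics(rec("100M", 0L)),
               data.frame(coverage = 1, identity = 1))
  expect_equal(compute_alignment_metrics(rec("10S90M", 0L)),
               data.frame(coverage = 0.9, identity = 1))
  expect_equal(compute_alignment_metrics(rec("100M", 5L)),
               data.frame(coverage = 1, identity = 0.95))
  # N never counts against identity
  expect_equal(compute_alignment_metrics(rec("50M5000N50M", 0L))$identity, 1)
  # MD fallback: 2 mismatches + 1 inserted base
  md <- compute_alignment_metrics(rec("50M1I49M", NA, "30A10C58"))
  expect_equal(md$identity, (100 - 3) / 100)
  expect_error(compute_alignment_metrics(rec("100M", NA)), "NM nor MD")
})

test_that("alignment filtering uses inclusive thresholds", {
  reads <- data.frame(read_id = paste0("r", 1:3), chrom = "chr1",
                      strand = "+", coverage = c(0.99, 0.98, 1.0),
                      identity = c(0.95, 1.0, 0.949),
                      cell_barcode = NA_character_, umi = NA_character_,
                      stringsAsFactors = FALSE)
  exons <- data.frame(read_id = paste0("r", 1:3), start = 0L, end = 100L,
                      stringsAsFactors = FALSE)
  fl <- filter_alignments(make_aln(reads, exons))
  expect_equal(fl$passed$reads$read_id, "r1")   # boundary passes, others fail
  expect_equal(fl$n_rejected, 2L)

  set.seed(5)
  reads2 <- data.frame(read_id = paste0("r", 1:200), chrom = "chr1",
                       strand = "+",
                       coverage = round(runif(200, 0.95, 1), 3),
                       identity = round(runif(200, 0.90, 1), 3),
                       cell_barcode = NA_character_, umi = NA_character_,
                       stringsAsFactors = FALSE)
  exons2 <- data.frame(read_id = reads2$read_id, start = 0L, end = 100L,
                       stringsAsFactors = FALSE)
  fl2 <- filter_alignments(make_aln(reads2, exons2))
  brute <- sum(reads2$coverage >= 0.99 & reads2$identity >= 0.95)
  expect_equal(nrow(fl2$passed$reads), brute)
})

test_that("identical intron chains collapse into one widest-span model", {
  chains <- list(
    r1 = cbind(c(100, 300, 500), c(200, 400, 600)),
    r2 = cbind(c(120, 300, 500), c(200, 400, 600)))   # 20 nt shorter 5' start
  cc <- collapse_isoforms(aln_from_chains(chains))
  expect_equal(nrow(cc$annotation$transcripts), 1L)
  ch <- exon_chain(cc$annotation, cc$annotation$transcripts$transcript_id[1])
  expect_equal(unname(ch[, "start"]), c(100, 300, 500))
  expect_equal(unname(ch[, "end"]), c(200, 400, 600))
  expect_equal(sort(cc$support$read_id), c("r1", "r2"))

  # one junction shifted by 5 nt at tolerance 0 -> two models
  chains$r2 <- cbind(c(120, 305, 500), c(200, 400, 600))
  cc2 <- collapse_isoforms(aln_from_chains(chains))
  expect_equal(nrow(cc2$annotation$transcripts), 2L)
  # ... but one model at tolerance 5
  cc3 <- collapse_isoforms(aln_from_chains(chains), junction_tol = 5L)
  expect_equal(nrow(cc3$annotation$transcripts), 1L)
})

test_that("mono-exon reads cluster by reciprocal overlap", {
  chains <- list(r1 = cbind(100, 300), r2 = cbind(150, 350),
                 r3 = cbind(5000, 5200))
  cc <- collapse_isoforms(aln_from_chains(chains))
  expect_equal(nrow(cc$annotation$transcripts), 2L)
  sup <- split(cc$support$read_id, cc$support$transcript_id)
  expect_true(any(vapply(sup, function(s) setequal(s, c("r1", "r2")), TRUE)))
})

test_that("error-free reads from known transcripts are recovered exactly", {
  fx <- random_fixture(61, n_genes = 25L, n_chrom = 2L, chrom_len = 400000L)
  sim <- simulate_scisoseq_reads(fx$annotation, fx$genome, read_layout(),
                                 n_cells = 10, reads_per_cell = 25,
                                 error_rate = 0, seed = 62)
  # every transcript must be hit at least once for exact recovery
  expect_setequal(unique(sim$truth$transcript_id),
                  fx$annotation$transcripts$transcript_id)
  sam <- simulate_alignments(sim$truth, fx$annotation, fx$genome)
  aln <- parse_sam_alignments(sam)
  cc <- collapse_isoforms(filter_alignments(aln)$passed)
  expect_equal(nrow(cc$annotation$transcripts), 25L)
  truth_keys <- vapply(fx$annotation$transcripts$transcript_id, function(t) {
    i <- match(t, fx$annotation$transcripts$transcript_id)
    scisorpipe:::exon_key(fx$annotation$transcripts$chrom[i],
                          fx$annotation$transcripts$strand[i],
                          exon_chain(fx$annotation, t))
  }, "")
  got_keys <- vapply(cc$annotation$transcripts$transcript_id, function(t) {
    i <- match(t, cc$annotation$transcripts$transcript_id)
    scisorpipe:::exon_key(cc$annotation$transcripts$chrom[i],
                          cc$annotation$transcripts$strand[i],
                          exon_chain(cc$annotation, t))
  }, "")
  expect_setequal(unname(got_keys), unname(truth_keys))
})

test_that("collapse partition equals the brute-force grouping oracle", {
  set.seed(63)
  for (rep in 1:5) {
    base_chains <- list(
      cbind(c(100, 400), c(200, 600)),
      cbind(c(100, 400, 800), c(200, 600, 900)),
      cbind(150, 450),
      cbind(c(2000, 2500), c(2100, 2700)))
    chains <- list()
    for (i in 1:30) {
      b <- base_chains[[sample(4, 1)]]
      jitter5 <- sample(0:30, 1)
      b[1, 1] <- b[1, 1] + if (nrow(b) > 1) min(jitter5, b[1, 2] - b[1, 1] - 1) else 0
      chains[[sprintf("r%02d", i)]] <- b
    }
    aln <- aln_from_chains(chains)
    cc <- collapse_isoforms(aln)
    got <- unname(lapply(split(cc$support$read_id, cc$support$transcript_id),
                         sort))
    want <- unname(lapply(oracle_collapse_partition(aln$reads,
      lapply(split(aln$exons[c("start", "end")], aln$exons$read_id),
             function(d) cbind(d$start[order(d$start)], d$end[order(d$start)]))),
      sort))
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
  }
})

test_that("collapse conserves support, is idempotent and order-invariant", {
  fx <- random_fixture(71, n_genes = 12L)
  sim <- simulate_scisoseq_reads(fx$annotation, fx$genome, read_layout(),
                                 n_cells = 6, reads_per_cell = 15,
                                 error_rate = 0, seed = 72)
  aln <- parse_sam_alignments(simulate_alignments(sim$truth, fx$annotation,
                                                  fx$genome))
  cc <- collapse_isoforms(aln)
  expect_equal(nrow(cc$support), nrow(aln$reads))

  # idempotence: collapse the models as pseudo-reads
  ann <- cc$annotation
  pseudo <- aln_from_chains(
    stats::setNames(lapply(ann$transcripts$transcript_id,
                           function(t) exon_chain(ann, t)),
                    ann$transcripts$transcript_id),
    chrom = ann$transcripts$chrom, strand = ann$transcripts$strand)
  cc2 <- collapse_isoforms(pseudo)
  expect_equal(nrow(cc2$annotation$transcripts), nrow(ann$transcripts))
  expect_true(annotations_equal(cc2$annotation, ann))

  # permutation invariance
  perm <- sample(nrow(aln$reads))
  aln_p <- structure(list(reads = aln$reads[perm, ],
                          exons = aln$exons[sample(nrow(aln$exons)), ],
                          skipped = aln$skipped),
                     class = "scisor_alignments")
  cc3 <- collapse_isoforms(aln_p)
  expect_true(annotations_equal(cc3$annotation, cc$annotation))
  expect_equal(sort(paste(cc3$support$transcript_id, cc3$support$read_id)),
               sort(paste(cc$support$transcript_id, cc$support$read_id)))
})
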