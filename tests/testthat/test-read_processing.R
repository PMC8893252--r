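layout <- read_layout()

test_that("locate_primer finds the lowest-edit occurrence", {
  p <- layout$p5_primer
  hit <- locate_primer(p, p, 2)
  expect_equal(hit[c("start", "end", "edits")],
               list(start = 0L, end = nchar(p), edits = 0L))
  # one substitution
  p1 <- paste0(substr(p, 1, 9), "A" , substr(p, 11, nchar(p)))
  if (p1 == p) p1 <- paste0(substr(p, 1, 9), "C", substr(p, 11, nchar(p)))
  hit <- locate_primer(paste0("GGGG", p1, "GGGG"), p, 2)
  expect_equal(hit$edits, 1L)
  expect_error(locate_primer("ACGTACGT", "ACGTACG", 1), "at least 10 nt")
})

test_that("locate_primer agrees with a brute-force edit-distance scan", {
  set.seed(42)
  p <- layout$p3_primer
  for (i in 1:40) {
    seq <- random_seq(200)
    plant <- i %% 2 == 0
    if (plant) {
      mut <- strsplit(p, "")[[1]]
      k <- sample(0:2, 1)
      if (k > 0) {
        at <- sample(nchar(p), k)
        mut[at] <- vapply(mut[at], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
      }
      pos <- sample(150, 1)
      seq <- paste0(substr(seq, 1, pos), paste(mut, collapse = ""),
                    substr(seq, pos + 1, 200))
    }
    truth <- oracle_min_edits(p, seq)
    hit <- locate_primer(seq, p, 2)
    if (truth > 2) {
      expect_null(hit)
    } else {
      expect_equal(hit$edits, truth)
    }
  }
})

test_that("sample barcode clipping removes terminal occurrences only", {
  body <- random_seq(120)
  bc <- layout$sample_barcode
  expect_equal(clip_sample_barcode(paste0(bc, body), layout), body)
  expect_equal(clip_sample_barcode(paste0(body, revcomp(bc)), layout), body)
  expect_equal(clip_sample_barcode(body, layout), body)
  # interior occurrence untouched
  inner <- paste0(substr(body, 1, 60), bc, substr(body, 61, 120))
  expect_equal(clip_sample_barcode(inner, layout), inner)
})

test_that("orientation detection is strand-symmetric and categorises structure", {
  set.seed(7)
  # a cDNA ending in non-A keeps the polyA boundary unambiguous
  cdna <- paste0(random_seq(396), "CCGG")
  cb <- paste0(strrep("A", 8), strrep("C", 8))
  umi <- paste0(strrep("G", 6), strrep("T", 6))
  read <- build_read(cdna, cb, umi, layout)
  o <- orient_and_classify(read, layout)
  expect_equal(o$category, "FULL_LENGTH")
  expect_equal(o$raw_orientation, "sense")
  bx <- extract_barcodes(o, layout)
  expect_equal(bx$cell_barcode, cb)
  expect_equal(bx$umi, umi)
  expect_equal(bx$cdna, cdna)
  expect_equal(bx$polya_len, 30L)

  o2 <- orient_and_classify(revcomp(read), layout)
  expect_equal(o2$raw_orientation, "antisense")
  bx2 <- extract_barcodes(o2, layout)
  expect_equal(bx2[c("cell_barcode", "umi", "cdna")],
               bx[c("cell_barcode", "umi", "cdna")])

  no5 <- build_read(cdna, cb, umi, layout, p5 = FALSE)
  expect_equal(orient_and_classify(no5, layout)$category, "MISSING_5P")
  no3 <- build_read(cdna, cb, umi, layout, p3 = FALSE)
  expect_equal(orient_and_classify(no3, layout)$category, "MISSING_3P")
  expect_equal(orient_and_classify(random_seq(300), layout)$category,
               "MISSING_BOTH")
})

test_that("polyA trimming matches its definition and brute-force oracle", {
  expect_equal(trim_polya(paste0("ACGT", strrep("A", 30))),
               list(sequence = "ACGT", tail_length = 30L))
  # 1 non-A inside a 30 nt tail is tolerated at max_non_a = 2
  tail <- paste0(strrep("A", 5), "G", strrep("A", 24))
  tr <- trim_polya(paste0("CCGT", tail), 10, 2)
  expect_equal(tr$tail_length, 30L)
  expect_equal(tr$sequence, "CCGT")
  expect_equal(trim_polya("ACGTACGT"), list(sequence = "ACGTACGT",
                                            tail_length = 0L))
  set.seed(33)
  for (i in 1:60) {
    s <- paste0(random_seq(sample(5:40, 1)),
                if (i %% 2) strrep("A", sample(0:35, 1)) else "")
    expect_equal(trim_polya(s, 10, 2), oracle_trim_polya(s, 10, 2), info = s)
  }
})

test_that("reads with a truncated barcode block are rejected", {
  set.seed(8)
  cb <- random_seq(16); umi <- random_seq(12)
  # only 20 nt of block between tail and primer: inter-primer region too short
  short <- paste0(layout$p5_primer, random_seq(20),
                  revcomp(layout$p3_primer))
  o <- orient_and_classify(short, layout)
  expect_equal(o$category, "FULL_LENGTH")   # both primers present
  expect_equal(extract_barcodes(o, layout)$category, "MISSING_3P")
  p <- process_reads(data.frame(read_id = "r1", sequence = short), layout)
  expect_equal(unname(p$summary["MISSING_3P"]), 1L)
})

test_that("deduplication keeps one representative per cell barcode + UMI", {
  df <- data.frame(
    read_id = c("b", "a", "c", "d", "e"),
    cell_barcode = c("CB1", "CB1", "CB1", "CB2", "CB1"),
    umi = c("U1", "U1", "U1", "U1", "U2"),
    cdna = c("ACGTACGT", "ACGTACGTAC", "ACGTACGTAC", "AC", "A"),
    stringsAsFactors = FALSE)
  dd <- deduplicate_reads(df)
  expect_equal(dd$n_duplicates, 2L)
  # longest cdna wins; ties by smallest read_id (a beats c)
  expect_setequal(dd$unique$read_id, c("a", "d", "e"))
  # same umi, different cell barcode: all retained
  expect_true(all(c("d", "e") %in% dd$unique$read_id))
})

test_that("planted duplicates are removed exactly", {
  fx <- random_fixture(21, n_genes = 10L)
  sim <- simulate_scisoseq_reads(fx$annotation, fx$genome, layout,
                                 n_cells = 10, reads_per_cell = 40,
                                 error_rate = 0, n_duplicates = 100,
                                 seed = 22)
  expect_equal(nrow(sim$reads), 500L)
  p <- process_reads(sim$reads, layout)
  expect_equal(nrow(p$full_length), 400L)
  expect_equal(unname(p$summary["duplicates"]), 100L)
})

test_that("process_reads conserves reads across output streams", {
  fx <- random_fixture(31, n_genes = 10L)
  sim <- simulate_scisoseq_reads(
    fx$annotation, fx$genome, layout, n_cells = 8, reads_per_cell = 10,
    error_rate = 0.01,
    category_mix = c(full_length = 0.7, missing_5p = 0.1, missing_3p = 0.1,
                     no_polya = 0.1), seed = 32)
  p <- process_reads(sim$reads, layout, dedup = FALSE)
  cats <- c("FULL_LENGTH", "MISSING_5P", "MISSING_3P", "MISSING_BOTH",
            "NO_POLYA")
  expect_equal(sum(p$summary[cats]), nrow(sim$reads))
  expect_equal(nrow(p$full_length) + nrow(p$rejects), nrow(sim$reads))
  expect_length(intersect(p$full_length$read_id, p$rejects$read_id), 0L)
  # empty input
  p0 <- process_reads(data.frame(read_id = character(),
                                 sequence = character()), layout)
  expect_equal(nrow(p0$full_length), 0L)
  expect_equal(unname(p0$summary["input"]), 0L)
})

test_that("processing is strand-symmetric on whole batches", {
  fx <- random_fixture(41, n_genes = 8L)
  sim <- simulate_scisoseq_reads(fx$annotation, fx$genome, layout,
                                 n_cells = 5, reads_per_cell = 10,
                                 error_rate = 0, seed = 42)
  p1 <- process_reads(sim$reads, layout, dedup = FALSE)
  flipped <- sim$reads
  flipped$sequence <- revcomp(flipped$sequence)
  p2 <- process_reads(flipped, layout, dedup = FALSE)
  m <- merge(p1$full_length, p2$full_length, by = "read_id")
  expect_equal(nrow(m), nrow(p1$full_length))
  expect_equal(m$cell_barcode.x, m$cell_barcode.y)
  expect_equal(m$umi.x, m$umi.y)
  expect_equal(m$cdna.x, m$cdna.y)
  expect_true(all(m$raw_orientation.x != m$raw_orientation.y))
})

test_that("full-length cDNA never contains an exact full primer", {
  fx <- random_fixture(51, n_genes = 8L)
  sim <- simulate_scisoseq_reads(fx$annotation, fx$genome, layout,
                                 n_cells = 6, reads_per_cell = 10,
                                 error_rate = 0, seed = 52)
  p <- process_reads(sim$reads, layout)
  expect_false(any(grepl(layout$p5_primer, p$full_length$cdna, fixed = TRUE)))
  expect_false(any(grepl(layout$p3_primer, p$full_length$cdna, fixed = TRUE)))
})

test_that("processed FASTA round-trips barcode tags", {
  df <- data.frame(read_id = c("r1", "r2"),
                   cell_barcode = c("ACGTACGTACGTACGT", "TGCATGCATGCATGCA"),
                   umi = c("ACGTACGTACGT", "TTTTACGTACGT"),
                   cdna = c("ACGTACGT", "GGGGCCCC"),
                   raw_orientation = "sense", polya_len = 30L,
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_processed_fasta(df, f)
  back <- read_processed_fasta(f)
  expect_equal(back$read_id, df$read_id)
  expect_equal(back$cell_barcode, df$cell_barcode)
  expect_equal(back$umi, df$umi)
  expect_equal(back$cdna, df$cdna)
})
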