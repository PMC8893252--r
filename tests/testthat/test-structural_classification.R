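# reference with two well-separated genes plus one mono-exon gene
ref_fixture <- function() {
  tx <- data.frame(
    transcript_id = c("rt1", "rt2", "rt3"),
    gene_id = c("rg1", "rg1", "rg2"),
    chrom = "chr1", strand = c("+", "+", "+"),
    source = "ensembl", gene_name = NA_character_,
    stringsAsFactors = FALSE)
  ex <- data.frame(
    transcript_id = c(rep("rt1", 4), rep("rt2", 2), "rt3"),
    start = c(1000L, 2000L, 3000L, 4000L, 1000L, 3000L, 20000L),
    end =   c(1200L, 2200L, 3200L, 4400L, 1200L, 3200L, 20500L),
    stringsAsFactors = FALSE)
  annotation(tx, ex)
}

q_annot <- function(exons, strand = "+", chrom = "chr1", id = "q1") {
  annotation(
    data.frame(transcript_id = id, gene_id = paste0(id, "g"), chrom = chrom,
               strand = strand, source = "isoseq",
               gene_name = NA_character_, stringsAsFactors = FALSE),
    data.frame(transcript_id = id, start = exons[, 1], end = exons[, 2],
               stringsAsFactors = FALSE))
}

test_that("verbatim reference copies are FSM reference_match with zero diffs", {
  ref <- ref_fixture()
  q <- q_annot(cbind(c(1000, 2000, 3000, 4000), c(1200, 2200, 3200, 4400)))
  call <- classify_isoforms(q, ref)
  expect_equal(call$category, "FSM")
  expect_equal(call$fsm_subcategory, "reference_match")
  expect_equal(call$matched_ref_transcript, "rt1")
  expect_equal(call$diff_to_tss, 0L)
  expect_equal(call$diff_to_tts, 0L)
})

test_that("a consecutive terminal sub-chain is ISM", {
  ref <- ref_fixture()
  q <- q_annot(cbind(c(3050, 4000), c(3200, 4300)))  # last 2 exons of rt1
  expect_equal(classify_isoforms(q, ref)$category, "ISM")
  # non-consecutive sub-chain (exon skipping) is NIC, not ISM
  q2 <- q_annot(cbind(c(1000, 3000, 4000), c(1200, 3200, 4400)))
  expect_equal(classify_isoforms(q2, ref)$category, "NIC")
})

test_that("spanning two separate genes is FUSION", {
  ref <- ref_fixture()
  q <- q_annot(cbind(c(4000, 20000), c(4400, 20200)))
  call <- classify_isoforms(q, ref)
  expect_equal(call$category, "FUSION")
  expect_setequal(strsplit(call$assigned_gene_ids, ",")[[1]], c("rg1", "rg2"))
})

test_that("novel donors/acceptors give NNC, with intron retention flagged", {
  ref <- ref_fixture()
  # novel acceptor inside intron 1
  q <- q_annot(cbind(c(1000, 2500), c(1200, 2700)))
  call <- classify_isoforms(q, ref)
  expect_equal(call$category, "NNC")
  expect_equal(call$nnc_subcategory, "novel_donor_or_acceptor")
  # novel junction, and an exon spanning exon2 + intron2 + exon3 retains
  # the intron
  q2 <- q_annot(cbind(c(1000, 1500), c(1100, 3200)))
  call2 <- classify_isoforms(q2, ref)
  expect_equal(call2$category, "NNC")
  expect_equal(call2$nnc_subcategory, "intron_retention")
})

test_that("mono-exon and non-overlapping queries fall to GENIC/INTERGENIC", {
  ref <- ref_fixture()
  # mono-exon inside rg1, no mono-exon reference partner
  expect_equal(classify_isoforms(q_annot(cbind(2000, 2200)), ref)$category,
               "GENIC")
  # mono-exon reciprocally overlapping the mono-exon reference rt3
  call <- classify_isoforms(q_annot(cbind(20000, 20400)), ref)
  expect_equal(call$category, "FSM")
  expect_equal(call$matched_ref_transcript, "rt3")
  # far away
  expect_equal(classify_isoforms(q_annot(cbind(50000, 50500)), ref)$category,
               "INTERGENIC")
  # overlap only on the opposite strand
  expect_equal(classify_isoforms(q_annot(cbind(c(1000, 2000), c(1200, 2200)),
                                         strand = "-"), ref)$category,
               "GENIC")
})

test_that("intron retention detection equals brute-force containment", {
  set.seed(91)
  for (i in 1:40) {
    ri <- cbind(start = cumsum(sample(100:300, 3)),
                end = cumsum(sample(100:300, 3)) + sample(50:150, 3))
    ri <- cbind(start = pmin(ri[, 1], ri[, 2]), end = pmax(ri[, 1], ri[, 2]))
    qe <- cbind(start = sample(0:800, 2), end = 0L)
    qe[, 2] <- qe[, 1] + sample(100:600, 2)
    got <- detect_intron_retention(qe, ri)
    want <- FALSE
    for (x in seq_len(nrow(qe))) for (y in seq_len(nrow(ri))) {
      if (qe[x, 1] < ri[y, 1] && qe[x, 2] > ri[y, 2]) want <- TRUE
    }
    expect_equal(got, want)
  }
})

test_that("FSM end subcategories are strand-aware", {
  expect_equal(subclassify_fsm(0, 0), "reference_match")
  expect_equal(subclassify_fsm(120, 500), "alt_3_and_5")
  expect_equal(subclassify_fsm(0, 300), "alt_3")
  expect_equal(subclassify_fsm(-300, 10), "alt_5")
  # minus-strand gene: a 300 nt lower genomic start with equal 5' ends is a
  # 3' extension
  ref <- annotation(
    data.frame(transcript_id = "mt1", gene_id = "mg1", chrom = "chr1",
               strand = "-", source = "ensembl", gene_name = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(transcript_id = "mt1", start = c(5000L, 6000L),
               end = c(5300L, 6400L), stringsAsFactors = FALSE))
  q <- q_annot(cbind(c(4700, 6000), c(5300, 6400)), strand = "-")
  call <- classify_isoforms(q, ref)
  expect_equal(call$category, "FSM")
  expect_equal(call$diff_to_tss, 0L)
  expect_equal(call$diff_to_tts, 300L)
  expect_equal(call$fsm_subcategory, "alt_3")
  # symmetric plus-strand case
  refp <- ref_fixture()
  qp <- q_annot(cbind(c(1000, 2000, 3000, 4000), c(1200, 2200, 3200, 4700)))
  callp <- classify_isoforms(qp, refp)
  expect_equal(callp$diff_to_tts, 300L)
  expect_equal(callp$fsm_subcategory, "alt_3")
})

test_that("intra-priming is detected on genomic A-stretches, strand-aware", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 100), strrep("A", 20), strrep("C", 60),
    strrep("T", 20), strrep("G", 100))))
  # + strand tx ending at 100: downstream 20 nt are all A
  expect_true(intra_priming_flag("chr1", "+", 40L, 100L, genome))
  # + strand tx ending at 150: downstream mixed C/A
  expect_false(intra_priming_flag("chr1", "+", 100L, 170L, genome))
  # - strand tx starting at 200: upstream (genomic) 20 nt are T = A on tx strand
  expect_true(intra_priming_flag("chr1", "-", 200L, 280L, genome))
  set.seed(93)
  for (i in 1:20) {
    w <- random_seq(20)
    genome2 <- Biostrings::DNAStringSet(c(chr1 = paste0(random_seq(50), w)))
    got <- intra_priming_flag("chr1", "+", 10L, 50L, genome2)
    want <- mean(strsplit(w, "")[[1]] == "A") >= 0.6
    expect_equal(got, want)
  }
})

test_that("RT switching requires a direct repeat across the junction", {
  rep8 <- "ACGTACGT"
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 92), rep8, strrep("G", 400), rep8, strrep("C", 100))))
  # intron (100, 500): both flanks end with rep8
  expect_true(rt_switching_flag("chr1", 100L, 508L, genome))
  expect_false(rt_switching_flag("chr1", 100L, 400L, genome))
  expect_error(rt_switching_flag("chr1", 100L, 508L, genome, repeat_len = 0L),
               ">= 4")
  set.seed(94)
  g <- random_seq(2000)
  genome3 <- Biostrings::DNAStringSet(c(chr1 = g))
  for (i in 1:30) {
    s <- sample(100:800, 1); e <- sample(1000:1900, 1)
    got <- rt_switching_flag("chr1", s, e, genome3)
    want <- substr(g, s - 7, s) == substr(g, e - 7, e)
    expect_equal(got, want)
  }
})

test_that("artifact filtering removes flagged isoforms with FSM exemption", {
  fx <- random_fixture(95, n_genes = 10L)
  ann <- fx$annotation
  ids <- ann$transcripts$transcript_id
  calls <- data.frame(transcript_id = ids,
                      category = c("FSM", rep("NNC", length(ids) - 1)),
                      stringsAsFactors = FALSE)
  flags <- data.frame(transcript_id = ids,
                      intra_priming = c(TRUE, TRUE, TRUE, TRUE,
                                        rep(FALSE, length(ids) - 4)),
                      rt_switching = FALSE, stringsAsFactors = FALSE)
  flags$retained <- !(flags$intra_priming | flags$rt_switching)
  fi <- filter_isoforms(ann, calls, flags)
  # 3 non-FSM flagged removed; the flagged FSM is exempt
  expect_equal(nrow(fi$report), 3L)
  expect_equal(nrow(fi$retained$transcripts), length(ids) - 3L)
  expect_true(ids[1] %in% fi$retained$transcripts$transcript_id)
  fi2 <- filter_isoforms(ann, calls, flags, fsm_exempt = FALSE)
  expect_equal(nrow(fi2$report), 4L)
  # no flags -> identity
  flags0 <- flags; flags0$intra_priming <- FALSE; flags0$retained <- TRUE
  fi0 <- filter_isoforms(ann, calls, flags0)
  expect_true(annotations_equal(fi0$retained, ann))
})

test_that("classification proportions sum to one per level", {
  calls <- data.frame(
    transcript_id = paste0("t", 1:4),
    category = c("FSM", "FSM", "NNC", "NNC"),
    fsm_subcategory = c("reference_match", "alt_3", NA, NA),
    nnc_subcategory = c(NA, NA, "intron_retention", "novel_donor_or_acceptor"),
    stringsAsFactors = FALSE)
  s <- classification_summary(calls)
  expect_equal(s$category$proportion, c(0.5, 0.5))
  expect_equal(sum(s$fsm_subcategory$proportion), 1)
  all_fsm <- classification_summary(data.frame(
    transcript_id = "t", category = "FSM", fsm_subcategory = "alt_3",
    nnc_subcategory = NA_character_, stringsAsFactors = FALSE))
  expect_equal(all_fsm$category$proportion, 1)
  expect_error(classification_summary(calls[0, ]), "no classification")
})

test_that("classifying a reference against itself gives all FSM/reference_match", {
  fx <- random_fixture(97, n_genes = 30L)
  calls <- classify_isoforms(fx$annotation, fx$annotation)
  expect_true(all(calls$category == "FSM"))
  expect_true(all(calls$fsm_subcategory == "reference_match"))
  expect_true(all(calls$diff_to_tss == 0L & calls$diff_to_tts == 0L))
})

test_that("classification is invariant under coordinate reflection", {
  fx <- random_fixture(98, n_genes = 12L)
  ref <- fx$annotation
  # queries: a mix of copies, truncations and perturbed chains
  qs <- list(
    q_annot(exon_chain(ref, ref$transcripts$transcript_id[1]),
            strand = ref$transcripts$strand[1],
            chrom = ref$transcripts$chrom[1]),
    q_annot(cbind(1000, 1400)),
    q_annot(cbind(c(3000, 9000), c(3500, 9400))))
  contig_len <- stats::setNames(Biostrings::width(fx$genome),
                                names(fx$genome))
  mref <- reflect_annotation(ref, contig_len)
  for (q in qs) {
    c1 <- classify_isoforms(q, ref)
    c2 <- classify_isoforms(reflect_annotation(q, contig_len), mref)
    expect_equal(c2$category, c1$category)
    expect_equal(c2$fsm_subcategory, c1$fsm_subcategory)
    expect_equal(c2$diff_to_tss, c1$diff_to_tss)
    expect_equal(c2$diff_to_tts, c1$diff_to_tts)
  }
})

test_that("verdicts equal the brute-force decision-list oracle", {
  ref <- ref_fixture()
  set.seed(99)
  for (i in 1:40) {
    n_ex <- sample(1:3, 1)
    starts <- sort(sample(seq(500, 21000, by = 50), n_ex))
    ends <- starts + sample(100:900, n_ex, replace = TRUE)
    if (n_ex > 1) ends[-n_ex] <- pmin(ends[-n_ex], starts[-1] - 10)
    ok <- all(ends > starts)
    if (!ok) next
    q <- q_annot(cbind(starts, ends))
    got <- classify_isoforms(q, ref)$category
    want <- oracle_classify("chr1", "+", cbind(starts, ends), ref)
    expect_equal(got, want, info = paste(starts, ends, collapse = " "))
  }
  # plus spec-style curated cases through the oracle too
  curated <- list(
    cbind(c(1000, 2000, 3000, 4000), c(1200, 2200, 3200, 4400)),  # FSM
    cbind(c(3000, 4000), c(3200, 4300)),                          # ISM
    cbind(c(4000, 20000), c(4400, 20200)),                        # FUSION
    cbind(c(1000, 3000, 4000), c(1200, 3200, 4400)),              # NIC
    cbind(c(1000, 2500), c(1200, 2700)))                          # NNC
  for (qe in curated) {
    expect_equal(classify_isoforms(q_annot(qe), ref)$category,
                 oracle_classify("chr1", "+", qe, ref))
  }
})
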