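#' Generate a random genome
#'
#' Seeded, reproducible contigs over ACGT with a given GC content.
#'
#' @param n_chrom number of contigs
#' @param length length of each contig in nt (recycled)
#' @param gc GC fraction in \[0, 1\]
#' @param seed integer seed; `NULL` leaves the RNG state alone
#' @return named `DNAStringSet` (contigs `chr1`, `chr2`, ...)
#' @export
make_genome <- function(n_chrom = 1L, length = 100000L, gc = 0.5,
                        seed = NULL) {
  stopifnot(all(length >= 1000L), gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  length <- rep_len(as.integer(length), n_chrom)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_chrom), function(i) {
    paste(sample(names(p), length[i], replace = TRUE, prob = p), collapse = "")
  }, "")
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  Biostrings::DNAStringSet(seqs)
}

#' Generate a random annotation on a genome
#'
#' Places non-overlapping genes (one transcript each) on both strands by
#' rejection sampling. Each gene's 3'-terminal exon carries an extra
#' 3'-UTR stretch of recorded length, so truncation experiments have a known
#' ground truth.
#'
#' @param genome named `DNAStringSet` from [make_genome()]
#' @param n_genes number of genes to place
#' @param exons_per_gene integer range (min, max) of exons per gene
#' @param exon_len integer range of internal exon lengths in nt
#' @param intron_len integer range of intron lengths in nt
#' @param utr3_len integer range of the extra 3'-UTR length appended to the
#'   terminal exon
#' @param min_gene_gap minimum nt between neighbouring genes
#' @param seed integer seed
#' @return list with `annotation` and `truth` (data.frame: gene_id,
#'   transcript_id, chrom, strand, utr3_len, terminal_exon_len)
#' @export
make_annotation <- function(genome, n_genes, exons_per_gene = c(2L, 8L),
                            exon_len = c(100L, 400L),
                            intron_len = c(60L, 1500L),
                            utr3_len = c(100L, 400L),
                            min_gene_gap = 500L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_genes == 0L) {
    return(list(annotation = empty_annotation(),
                truth = data.frame(gene_id = character(),
                                   transcript_id = character(),
                                   chrom = character(), strand = character(),
                                   utr3_len = integer(),
                                   terminal_exon_len = integer(),
                                   stringsAsFactors = FALSE)))
  }
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  occupied <- lapply(names(genome), function(x) cbind(start = integer(),
                                                      end = integer()))
  names(occupied) <- names(genome)
  runif_int <- function(rng) sample(seq(rng[1L], rng[2L]), 1L)
  tx_rows <- list(); ex_rows <- list(); truth_rows <- list()
  for (g in seq_len(n_genes)) {
    placed <- FALSE
    for (attempt in 1:200) {
      chrom <- sample(names(genome), 1L)
      strand <- sample(c("+", "-"), 1L)
      n_ex <- runif_int(exons_per_gene)
      elens <- vapply(seq_len(n_ex), function(i) runif_int(exon_len), 0L)
      ilens <- if (n_ex > 1L) {
        vapply(seq_len(n_ex - 1L), function(i) runif_int(intron_len), 0L)
      } else integer()
      u3 <- runif_int(utr3_len)
      # the 3'-terminal exon (strand-aware) carries the UTR extension
      if (strand == "+") elens[n_ex] <- elens[n_ex] + u3
      else elens[1L] <- elens[1L] + u3
      span <- sum(elens) + sum(ilens)
      if (span + 2L * min_gene_gap >= clen[chrom]) next
      s0 <- sample.int(clen[chrom] - span - 2L * min_gene_gap, 1L) +
        min_gene_gap
      occ <- occupied[[chrom]]
      if (nrow(occ) > 0L &&
          any(s0 - min_gene_gap < occ[, "end"] &
              s0 + span + min_gene_gap > occ[, "start"])) next
      occupied[[chrom]] <- rbind(occ, cbind(start = s0, end = s0 + span))
      gid <- sprintf("G%05d", g)
      tid <- paste0(gid, ".t1")
      starts <- s0 + c(0L, cumsum(elens[-n_ex] + ilens))
      ex_rows[[g]] <- data.frame(transcript_id = tid, start = starts,
                                 end = starts + elens,
                                 stringsAsFactors = FALSE)
      tx_rows[[g]] <- data.frame(transcript_id = tid, gene_id = gid,
                                 chrom = chrom, strand = strand,
                                 source = "ensembl",
                                 gene_name = paste0("gene", g),
                                 stringsAsFactors = FALSE)
      truth_rows[[g]] <- data.frame(
        gene_id = gid, transcript_id = tid, chrom = chrom, strand = strand,
        utr3_len = u3,
        terminal_exon_len = if (strand == "+") elens[n_ex] else elens[1L],
        stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place gene ", g, " after 200 attempts; ",
           "reduce n_genes or enlarge the genome")
    }
  }
  list(annotation = annotation(do.call(rbind, tx_rows),
                               do.call(rbind, ex_rows)),
       truth = do.call(rbind, truth_rows))
}

#' Truncate 3'-UTRs of an annotation by known amounts
#'
#' Shortens each gene's 3'-terminal exon strand-aware, emulating a reference
#' annotation with poorly annotated 3'-UTRs. Amounts that would consume the
#' whole terminal exon are clamped to (exon length - 1) and recorded.
#'
#' @param annot annotation object (one or more transcripts per gene; every
#'   transcript's terminal exon is shortened by its gene's amount)
#' @param amounts either a single amount applied to every gene, a named
#'   vector (gene_id -> amount), or a function `(n) -> integer vector` used
#'   as a sampler
#' @param seed integer seed (used when `amounts` is a sampler)
#' @return list with `annotation` (truncated) and `truth` (data.frame:
#'   gene_id, requested, applied)
#' @export
truncate_utrs <- function(annot, amounts = 200L, seed = NULL) {
  stopifnot(is_annotation(annot))
  if (!is.null(seed)) set.seed(seed)
  genes <- gene_spans(annot)
  req <- if (is.function(amounts)) {
    as.integer(amounts(nrow(genes)))
  } else if (!is.null(names(amounts))) {
    as.integer(amounts[genes$gene_id])
  } else {
    rep_len(as.integer(amounts), nrow(genes))
  }
  names(req) <- genes$gene_id
  ex <- annot$exons
  tx <- annot$transcripts
  applied <- stats::setNames(rep(0L, nrow(genes)), genes$gene_id)
  for (t in tx$transcript_id) {
    gid <- tx$gene_id[tx$transcript_id == t]
    strand <- tx$strand[tx$transcript_id == t]
    idx <- which(ex$transcript_id == t)
    idx <- idx[order(ex$start[idx])]
    term <- if (strand == "+") idx[length(idx)] else idx[1L]
    elen <- ex$end[term] - ex$start[term]
    amt <- min(req[[gid]], elen - 1L)
    if (strand == "+") ex$end[term] <- ex$end[term] - amt
    else ex$start[term] <- ex$start[term] + amt
    applied[[gid]] <- max(applied[[gid]], amt)
  }
  list(annotation = annotation(tx, ex),
       truth = data.frame(gene_id = genes$gene_id,
                          requested = unname(req[genes$gene_id]),
                          applied = unname(applied[genes$gene_id]),
                          stringsAsFactors = FALSE))
}

# n random cb_len-mers at pairwise Hamming distance >= min_dist
sample_cell_barcodes <- function(n, cb_len = 16L, min_dist = 4L) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 200L * n) stop("cannot draw ", n, " distant cell barcodes")
    cand <- paste(sample(c("A", "C", "G", "T"), cb_len, replace = TRUE),
                  collapse = "")
    if (length(out) == 0L ||
        all(vapply(out, function(b) {
          sum(strsplit(b, "")[[1L]] != strsplit(cand, "")[[1L]]) >= min_dist
        }, FALSE))) {
      out <- c(out, cand)
    }
  }
  out
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# spliced transcript sequence in transcription direction
spliced_sequence <- function(genome, chrom, strand, exmat) {
  gseq <- genome_sequence(genome, chrom)
  parts <- vapply(seq_len(nrow(exmat)), function(i) {
    substr(gseq, exmat[i, "start"] + 1L, exmat[i, "end"])
  }, "")
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp(s) else s
}

# reference definition of the polyA boundary, written as a plain scan so it
# stays independent of the vectorised trimmer it cross-checks: the tail is
# the longest suffix with at most max_non_a non-A bases, shrunk so it starts
# on an A. The cDNA/tail boundary inside an A-run is not identifiable from
# sequence, so the recoverable cDNA ends at this boundary by definition.
split_polya <- function(seq, min_polya_len = 10L, max_non_a = 2L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  count <- 0L
  L <- 0L
  for (i in rev(seq_len(n))) {
    if (ch[i] != "A") count <- count + 1L
    if (count > max_non_a) break
    L <- n - i + 1L
  }
  while (L > 0L && ch[n - L + 1L] != "A") L <- L - 1L
  if (L < min_polya_len) L <- 0L
  list(cdna = substr(seq, 1L, n - L), tail_len = L)
}

apply_substitutions <- function(seq, positions) {
  if (length(positions) == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Simulate barcoded full-length single-cell isoform reads
#'
#' Emits circular-consensus-like reads assembled per the library layout:
#' 5' primer, cDNA (spliced from the genome), polyA tail (uniform 20-60 nt),
#' reverse-complemented UMI, reverse-complemented cell barcode,
#' reverse-complemented 3' primer. Structural categories are planted with
#' exact counts (largest-remainder allocation of `category_mix`), read
#' orientation is 50/50, and uniform substitution errors are applied at
#' `error_rate`. Cell barcodes are drawn at pairwise Hamming distance >= 4.
#' `n_duplicates` reads re-use the (cell barcode, UMI, transcript) of an
#' earlier full-length read, planting PCR duplicates with known ground
#' truth.
#'
#' @param annot annotation supplying transcripts
#' @param genome named `DNAStringSet`
#' @param layout [read_layout()] object
#' @param n_cells number of cells
#' @param reads_per_cell reads per cell
#' @param error_rate per-base substitution probability
#' @param category_mix named numeric, proportions summing to 1 over
#'   `full_length`, `missing_5p`, `missing_3p`, `no_polya`
#' @param n_duplicates number of planted PCR duplicates (added on top of
#'   `n_cells * reads_per_cell` base reads)
#' @param seed integer seed
#' @return list with `reads` (data.frame read_id, sequence) and `truth`
#'   (one row per read: read_id, transcript_id, gene_id, cell_barcode, umi,
#'   orientation, category, polya_len, cdna (biological), cell_barcode_seq,
#'   umi_seq, cdna_seq (as-sequenced and recoverable: errors applied,
#'   tail-ambiguous terminal bases assigned to the tail), cdna_full_seq
#'   (as-sequenced full cDNA), n_errors, n_errors_cdna, duplicate_of)
#' @export
simulate_scisoseq_reads <- function(annot, genome, layout = read_layout(),
                                    n_cells = 10L, reads_per_cell = 20L,
                                    error_rate = 0,
                                    category_mix = c(full_length = 1,
                                                     missing_5p = 0,
                                                     missing_3p = 0,
                                                     no_polya = 0),
                                    n_duplicates = 0L, seed = NULL) {
  stopifnot(is_annotation(annot), nrow(annot$transcripts) > 0L)
  if (abs(sum(category_mix) - 1) > 1e-8) {
    stop("category_mix proportions must sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)
  n_base <- n_cells * reads_per_cell
  cats <- c("full_length", "missing_5p", "missing_3p", "no_polya")
  mix <- stats::setNames(rep(0, 4L), cats)
  mix[names(category_mix)] <- category_mix
  # exact largest-remainder allocation
  raw <- mix * n_base
  counts <- floor(raw)
  rem <- n_base - sum(counts)
  if (rem > 0L) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  category <- sample(rep(cats, counts))
  cells <- sample_cell_barcodes(n_cells, layout$cb_len)
  tx <- transcript_spans(annot)
  chains <- exon_chain_list(annot)
  p3rc <- revcomp(layout$p3_primer)

  used_keys <- new.env(hash = TRUE)
  rows <- vector("list", n_base + n_duplicates)
  make_read <- function(i, cb, umi, t, cat, dup_of) {
    tj <- match(t, tx$transcript_id)
    cdna <- spliced_sequence(genome, tx$chrom[tj], tx$strand[tj],
                             chains[[t]])
    tail_len <- sample(20:60, 1L)
    tail <- strrep("A", tail_len)
    body <- switch(cat,
      full_length = paste0(layout$p5_primer, cdna, tail, revcomp(umi),
                           revcomp(cb), p3rc),
      missing_5p = paste0(cdna, tail, revcomp(umi), revcomp(cb), p3rc),
      missing_3p = paste0(layout$p5_primer, cdna, tail),
      no_polya = paste0(layout$p5_primer, cdna, revcomp(umi), revcomp(cb),
                        p3rc))
    # error positions in sense coordinates; cdna span for NM accounting
    cdna_off <- if (cat == "missing_5p") 0L else nchar(layout$p5_primer)
    n <- nchar(body)
    err <- which(stats::runif(n) < error_rate)
    body_err <- apply_substitutions(body, err)
    in_cdna <- err[err > cdna_off & err <= cdna_off + nchar(cdna)]
    cdna_seq <- substr(body_err, cdna_off + 1L, cdna_off + nchar(cdna))
    # recoverable cDNA: terminal bases indistinguishable from the tail are
    # assigned to the tail (see split_polya)
    if (cat == "no_polya") {
      cdna_rec <- cdna_seq
    } else {
      tail_err <- substr(body_err, cdna_off + nchar(cdna) + 1L,
                         cdna_off + nchar(cdna) + tail_len)
      sp <- split_polya(paste0(cdna_seq, tail_err), layout$min_polya_len,
                        layout$max_non_a)
      cdna_rec <- sp$cdna
    }
    cb_seq <- cb; umi_seq <- umi
    if (cat %in% c("full_length", "no_polya")) {
      bstart <- n - nchar(p3rc) - layout$cb_len - layout$umi_len
      umi_seq <- revcomp(substr(body_err, bstart + 1L,
                                bstart + layout$umi_len))
      cb_seq <- revcomp(substr(body_err, bstart + layout$umi_len + 1L,
                               bstart + layout$umi_len + layout$cb_len))
    }
    orientation <- sample(c("sense", "antisense"), 1L)
    final <- if (orientation == "antisense") revcomp(body_err) else body_err
    list(read_id = sprintf("read%06d", i), sequence = final,
         transcript_id = t, gene_id = tx$gene_id[tj], cell_barcode = cb,
         umi = umi, orientation = orientation,
         category = toupper(cat),
         polya_len = if (cat == "no_polya") 0L else tail_len,
         cdna = cdna, cell_barcode_seq = cb_seq, umi_seq = umi_seq,
         cdna_seq = cdna_rec, cdna_full_seq = cdna_seq,
         n_errors = length(err),
         n_errors_cdna = length(in_cdna), duplicate_of = dup_of)
  }
  for (i in seq_len(n_base)) {
    cb <- cells[((i - 1L) %% n_cells) + 1L]
    repeat {
      umi <- random_dna(layout$umi_len)
      if (!exists(paste(cb, umi), envir = used_keys)) break
    }
    assign(paste(cb, umi), TRUE, envir = used_keys)
    t <- sample(tx$transcript_id, 1L)
    rows[[i]] <- make_read(i, cb, umi, t, category[i], NA_character_)
  }
  if (n_duplicates > 0L) {
    fl <- which(category == "full_length")
    if (length(fl) == 0L) stop("cannot plant duplicates without full-length reads")
    src <- sample(fl, n_duplicates, replace = TRUE)
    for (k in seq_len(n_duplicates)) {
      s <- rows[[src[k]]]
      rows[[n_base + k]] <- make_read(n_base + k, s$cell_barcode, s$umi,
                                      s$transcript_id, "full_length",
                                      s$read_id)
    }
  }
  truth <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  list(reads = truth[c("read_id", "sequence")],
       truth = truth[setdiff(names(truth), "sequence")])
}

#' Simulate splice-aware alignments for simulated reads
#'
#' Bypasses an external aligner: emits one primary SAM record per
#' full-length read whose CIGAR encodes the true exon chain (M blocks split
#' by N introns), with NM set from the planted cDNA substitutions and CB/UB
#' tags carrying the as-sequenced cell barcode and UMI.
#'
#' @param truth truth table from [simulate_scisoseq_reads()] (subset the
#'   rows to control which reads are aligned)
#' @param annot the generating annotation
#' @param genome named `DNAStringSet` (contig lengths for the header)
#' @return data.frame of SAM records as produced by [read_sam()], with a
#'   `"header"` attribute
#' @export
simulate_alignments <- function(truth, annot, genome) {
  stopifnot(is_annotation(annot))
  tr <- truth[truth$category == "FULL_LENGTH", , drop = FALSE]
  tx <- transcript_spans(annot)
  chains <- exon_chain_list(annot)
  recs <- lapply(seq_len(nrow(tr)), function(i) {
    t <- tr$transcript_id[i]
    tj <- match(t, tx$transcript_id)
    m <- chains[[t]]
    widths <- m[, "end"] - m[, "start"]
    gaps <- if (nrow(m) > 1L) m[-1L, "start"] - m[-nrow(m), "end"] else integer()
    cig <- paste0(widths[1L], "M")
    for (k in seq_along(gaps)) {
      cig <- paste0(cig, gaps[k], "N", widths[k + 1L], "M")
    }
    minus <- tx$strand[tj] == "-"
    seq_plus <- if (minus) revcomp(tr$cdna_full_seq[i]) else tr$cdna_full_seq[i]
    data.frame(read_id = tr$read_id[i], flag = if (minus) 16L else 0L,
               chrom = tx$chrom[tj], pos = m[1L, "start"] + 1L, mapq = 60L,
               cigar = cig, seq = seq_plus, nm = tr$n_errors_cdna[i],
               md = NA_character_, cell_barcode = tr$cell_barcode_seq[i],
               umi = tr$umi_seq[i], stringsAsFactors = FALSE)
  })
  out <- if (length(recs) > 0L) do.call(rbind, recs) else
    data.frame(read_id = character(), flag = integer(), chrom = character(),
               pos = integer(), mapq = integer(), cigar = character(),
               seq = character(), nm = integer(), md = character(),
               cell_barcode = character(), umi = character(),
               stringsAsFactors = FALSE)
  attr(out, "header") <- c("@HD\tVN:1.6\tSO:unsorted",
                           paste0("@SQ\tSN:", names(genome), "\tLN:",
                                  Biostrings::width(genome)))
  out
}

#' Write SAM records to a text SAM file
#'
#' @param records data.frame of SAM records (the shape produced by
#'   [read_sam()] / [simulate_alignments()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sam <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- attr(records, "header")
  if (!is.null(hdr)) writeLines(hdr, con)
  if (nrow(records) > 0L) {
    tags <- paste0("NM:i:", records$nm)
    tags <- ifelse(is.na(records$cell_barcode), tags,
                   paste0(tags, "\tCB:Z:", records$cell_barcode))
    tags <- ifelse(is.na(records$umi), tags,
                   paste0(tags, "\tUB:Z:", records$umi))
    writeLines(paste(records$read_id, records$flag, records$chrom,
                     records$pos, records$mapq, records$cigar, "*", 0, 0,
                     records$seq, "*", tags, sep = "\t"), con)
  }
  invisible(path)
}
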