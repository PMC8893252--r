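#' Read layout of a barcoded full-length cDNA library
#'
#' Describes the expected structure of a circular-consensus read from a 10x
#' 3' gene-expression library sequenced full-length: on the sense strand,
#' 5' primer, cDNA, polyA tail, reverse-complemented UMI, reverse-complemented
#' cell barcode, reverse-complemented 3' primer. An optional sample barcode
#' may flank either end. Defaults are the v3.1 NextGem chemistry lengths
#' (16 nt cell barcode, 12 nt UMI) and the library's primer sequences.
#'
#' @param p5_primer 5' primer sequence (sense strand)
#' @param p3_primer 3' primer sequence (as sequenced; appears
#'   reverse-complemented at the 3' end of a sense read)
#' @param sample_barcode optional sample-specific barcode clipped from the
#'   read ends before primer detection; `NA` disables clipping
#' @param cb_len cell-barcode length in nt
#' @param umi_len UMI length in nt
#' @param min_polya_len minimum polyA tail length in nt
#' @param max_non_a maximum non-A bases tolerated inside the polyA tail
#' @param max_primer_edits maximum edit distance for primer matching
#' @param max_barcode_edits maximum edit distance for sample-barcode matching
#' @param umi_proximal if TRUE the UMI, not the cell barcode, is proximal to
#'   the 3' primer (block-order swap for other chemistries)
#' @return list of class `read_layout`
#' @export
read_layout <- function(p5_primer = "CCCATGTACTCTGCGTTGATACCACTGCTT",
                        p3_primer = "CTACACGACGCTCTTCCGATCT",
                        sample_barcode = "ATATAGCGCGCGTGTG",
                        cb_len = 16L, umi_len = 12L,
                        min_polya_len = 10L, max_non_a = 2L,
                        max_primer_edits = 3L, max_barcode_edits = 2L,
                        umi_proximal = FALSE) {
  stopifnot(grepl("^[ACGT]+$", p5_primer), grepl("^[ACGT]+$", p3_primer),
            cb_len > 0L, umi_len > 0L)
  structure(list(p5_primer = p5_primer, p3_primer = p3_primer,
                 sample_barcode = sample_barcode,
                 cb_len = as.integer(cb_len), umi_len = as.integer(umi_len),
                 min_polya_len = as.integer(min_polya_len),
                 max_non_a = as.integer(max_non_a),
                 max_primer_edits = as.integer(max_primer_edits),
                 max_barcode_edits = as.integer(max_barcode_edits),
                 umi_proximal = isTRUE(umi_proximal)),
            class = "read_layout")
}

#' Reverse-complement a character DNA sequence
#'
#' @param x character vector of DNA sequences (ACGTN alphabet)
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  vapply(chartr("ACGTN", "TGCAN", x), function(s) {
    rawToChar(rev(charToRaw(s)))
  }, "", USE.NAMES = FALSE)
}

# batched semi-global search: for each window, the lowest-edit occurrence of
# the primer (leftmost on ties). Windows are concatenated with an N spacer
# long enough that no acceptable match can cross it, and searched with one
# matchPattern pass per edit level.
batch_locate <- function(windows, primer, max_edits) {
  n <- length(windows)
  out <- data.frame(start = rep(NA_integer_, n), end = rep(NA_integer_, n),
                    edits = rep(NA_integer_, n))
  lens <- nchar(windows)
  valid <- which(lens > 0L)
  if (length(valid) == 0L) return(out)
  sep_len <- nchar(primer) + max_edits + 1L
  offs <- cumsum(c(0L, utils::head(lens[valid] + sep_len, -1L)))
  subj <- tryCatch(
    Biostrings::DNAString(paste(windows[valid],
                                collapse = strrep("N", sep_len))),
    error = function(e) NULL)
  if (is.null(subj)) return(out)
  resolved <- rep(FALSE, length(valid))
  for (k in 0:max_edits) {
    if (all(resolved)) break
    m <- tryCatch(
      Biostrings::matchPattern(primer, subj, max.mismatch = k,
                               with.indels = TRUE),
      error = function(e) NULL)
    if (is.null(m) || length(m) == 0L) next
    ms <- Biostrings::start(m) - 1L          # 0-based in subject
    me <- Biostrings::end(m)
    w <- findInterval(ms, offs)
    ls <- ms - offs[w]
    le <- pmin(me - offs[w], lens[valid][w])
    ok <- ls >= 0L & ls < lens[valid][w] & !resolved[w]
    if (!any(ok)) next
    o <- order(w[ok], ls[ok])
    wo <- w[ok][o]; first <- !duplicated(wo)
    rows <- valid[wo[first]]
    out$start[rows] <- ls[ok][o][first]
    out$end[rows] <- le[ok][o][first]
    out$edits[rows] <- k
    resolved[wo[first]] <- TRUE
  }
  out
}

#' Locate the best approximate occurrence of a primer in a sequence
#'
#' Semi-global search: finds the occurrence with the lowest edit distance
#' (substitutions and indels), breaking ties by the leftmost start. Returns
#' `NULL` when the minimum edit distance exceeds `max_edits`.
#'
#' @param seq subject sequence (character)
#' @param primer pattern sequence, at least 10 nt
#' @param max_edits maximum edit distance accepted
#' @return list with `start` (0-based), `end` (0-based exclusive) and
#'   `edits`, or `NULL` when no acceptable occurrence exists
#' @export
locate_primer <- function(seq, primer, max_edits = 3L) {
  if (nchar(primer) < 10L) stop("primer must be at least 10 nt")
  hit <- batch_locate(seq, primer, max_edits)
  if (is.na(hit$start[1L])) return(NULL)
  list(start = hit$start[1L], end = hit$end[1L], edits = hit$edits[1L])
}

#' Clip a sample-specific barcode from the read termini
#'
#' Removes occurrences of the sample barcode (either orientation) at either
#' end of the read, within `max_barcode_edits` edits; interior sequence is
#' never touched. Vectorised over reads.
#'
#' @param seq read sequence(s) (character vector)
#' @param layout [read_layout()] object
#' @return clipped sequence(s)
#' @export
clip_sample_barcode <- function(seq, layout) {
  bc <- layout$sample_barcode
  if (is.null(bc) || is.na(bc)) return(seq)
  maxe <- layout$max_barcode_edits
  w <- nchar(bc) + maxe
  pick <- function(h1, h2) {                 # lower-edit of two hit tables
    use2 <- !is.na(h2$edits) & (is.na(h1$edits) | h2$edits < h1$edits)
    data.frame(start = ifelse(use2, h2$start, h1$start),
               end = ifelse(use2, h2$end, h1$end))
  }
  n <- nchar(seq)
  pre <- substr(seq, 1L, pmin(w, n))
  h <- pick(batch_locate(pre, bc, maxe), batch_locate(pre, revcomp(bc), maxe))
  got <- !is.na(h$end)
  seq[got] <- substr(seq[got], h$end[got] + 1L, n[got])
  n <- nchar(seq)
  off <- pmax(0L, n - w)
  suf <- substr(seq, off + 1L, n)
  h <- pick(batch_locate(suf, bc, maxe), batch_locate(suf, revcomp(bc), maxe))
  got <- !is.na(h$start)
  seq[got] <- substr(seq[got], 1L, off[got] + h$start[got])
  seq
}

# batched primer evidence for one orientation: p5 within the 5' window,
# reverse-complemented p3 within the 3' window (coordinates in full reads)
primer_evidence_batch <- function(seqs, layout) {
  n <- nchar(seqs)
  maxe <- layout$max_primer_edits
  w5 <- nchar(layout$p5_primer) + maxe
  h5 <- batch_locate(substr(seqs, 1L, pmin(w5, n)), layout$p5_primer, maxe)
  p3rc <- revcomp(layout$p3_primer)
  w3 <- nchar(p3rc) + maxe
  off <- pmax(0L, n - w3)
  h3 <- batch_locate(substr(seqs, off + 1L, n), p3rc, maxe)
  h3$start <- h3$start + off
  h3$end <- h3$end + off
  found <- (!is.na(h5$edits)) + (!is.na(h3$edits))
  edits <- ifelse(is.na(h5$edits), 0L, h5$edits) +
    ifelse(is.na(h3$edits), 0L, h3$edits)
  list(h5 = h5, h3 = h3, found = found, edits = edits)
}

# single-read evidence in the list form used by orient_and_classify()
primer_evidence <- function(seq, layout) {
  ev <- primer_evidence_batch(seq, layout)
  tolist <- function(h) {
    if (is.na(h$start[1L])) NULL else
      list(start = h$start[1L], end = h$end[1L], edits = h$edits[1L])
  }
  list(h5 = tolist(ev$h5), h3 = tolist(ev$h3), found = ev$found[1L],
       edits = ev$edits[1L])
}

#' Orient a read and classify its primer structure
#'
#' A read is in sense orientation when it begins with the 5' primer and ends
#' with the reverse complement of the 3' primer. If the antisense pattern
#' matches better, the read is reverse-complemented and `raw_orientation` is
#' `"antisense"`. Reads matching fully in both orientations are palindromic
#' artifacts and are classified `MISSING_BOTH`.
#'
#' @param seq read sequence, sample barcode already clipped
#' @param layout [read_layout()] object
#' @return list with `sequence` (oriented sense), `hit5`, `hit3` (primer hit
#'   coordinates in the oriented sequence, 0-based half-open, or NULL),
#'   `raw_orientation` and `category` (`FULL_LENGTH` provisional on polyA,
#'   else `MISSING_5P` / `MISSING_3P` / `MISSING_BOTH`)
#' @export
orient_and_classify <- function(seq, layout) {
  sense <- primer_evidence(seq, layout)
  rcseq <- revcomp(seq)
  anti <- primer_evidence(rcseq, layout)
  if (sense$found == 2L && anti$found == 2L) {
    return(list(sequence = seq, hit5 = NULL, hit3 = NULL,
                raw_orientation = "sense", category = "MISSING_BOTH"))
  }
  take_anti <- anti$found > sense$found ||
    (anti$found == sense$found && anti$edits < sense$edits)
  ev <- if (take_anti) anti else sense
  oriented <- if (take_anti) rcseq else seq
  category <- if (!is.null(ev$h5) && !is.null(ev$h3)) "FULL_LENGTH"
  else if (is.null(ev$h5) && is.null(ev$h3)) "MISSING_BOTH"
  else if (is.null(ev$h5)) "MISSING_5P"
  else "MISSING_3P"
  list(sequence = oriented, hit5 = ev$h5, hit3 = ev$h3,
       raw_orientation = if (take_anti) "antisense" else "sense",
       category = category)
}

#' Trim a polyA tail from the 3' end of a sense sequence
#'
#' Finds the maximal 3'-terminal window containing at most `max_non_a` non-A
#' bases, shrinks it so the tail starts on an A (leading non-A bases belong
#' to the cDNA), and removes it when its length reaches `min_polya_len`.
#'
#' @param seq sense-oriented sequence with the 3' primer/barcode block
#'   already removed
#' @param min_polya_len minimum qualifying tail length in nt
#' @param max_non_a maximum non-A bases tolerated inside the tail
#' @return list with `sequence` (tail removed) and `tail_length` (0 when no
#'   qualifying tail is present)
#' @export
trim_polya <- function(seq, min_polya_len = 10L, max_non_a = 2L) {
  n <- nchar(seq)
  if (n == 0L) return(list(sequence = seq, tail_length = 0L))
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  non_a <- cumsum(rev(ch) != "A")
  L <- if (non_a[1L] > max_non_a && ch[n] != "A") 0L else
    max(which(non_a <= max_non_a), 0L)
  if (L > 0L) {
    tail_chars <- ch[(n - L + 1L):n]
    lead <- which(tail_chars == "A")
    L <- if (length(lead) == 0L) 0L else L - (lead[1L] - 1L)
  }
  if (L < min_polya_len) return(list(sequence = seq, tail_length = 0L))
  list(sequence = substr(seq, 1L, n - L), tail_length = L)
}

#' Extract cell barcode, UMI and cDNA from an oriented full-length read
#'
#' On the sense strand the block immediately 5' of the reverse-complemented
#' 3' primer is the reverse complement of the cell barcode (`cb_len` nt),
#' preceded by the reverse complement of the UMI (`umi_len` nt); everything
#' between the 5' primer and the UMI block is cDNA plus polyA tail, which is
#' trimmed by [trim_polya()].
#'
#' @param oriented result of [orient_and_classify()] with category
#'   `FULL_LENGTH`
#' @param layout [read_layout()] object
#' @return list with `cell_barcode`, `umi`, `cdna`, `polya_len` and
#'   `category` (`FULL_LENGTH`, or `MISSING_3P` when the barcode block is
#'   shorter than cb_len + umi_len, or `NO_POLYA` when no qualifying tail)
#' @export
extract_barcodes <- function(oriented, layout) {
  stopifnot(identical(oriented$category, "FULL_LENGTH"))
  p <- oriented$hit3$start            # 0-based start of rc(p3) block
  blk <- layout$cb_len + layout$umi_len
  h5_end <- oriented$hit5$end         # 0-based end (exclusive) of p5 block
  if (p - h5_end < blk) {
    return(list(cell_barcode = NA_character_, umi = NA_character_,
                cdna = NA_character_, polya_len = 0L, category = "MISSING_3P"))
  }
  s <- oriented$sequence
  if (layout$umi_proximal) {
    umi <- revcomp(substr(s, p - layout$umi_len + 1L, p))
    cb <- revcomp(substr(s, p - blk + 1L, p - layout$umi_len))
  } else {
    cb <- revcomp(substr(s, p - layout$cb_len + 1L, p))
    umi <- revcomp(substr(s, p - blk + 1L, p - layout$cb_len))
  }
  upstream <- substr(s, h5_end + 1L, p - blk)
  tr <- trim_polya(upstream, layout$min_polya_len, layout$max_non_a)
  if (tr$tail_length == 0L) {
    return(list(cell_barcode = cb, umi = umi, cdna = tr$sequence,
                polya_len = 0L, category = "NO_POLYA"))
  }
  list(cell_barcode = cb, umi = umi, cdna = tr$sequence,
       polya_len = tr$tail_length, category = "FULL_LENGTH")
}

#' Remove PCR/optical duplicates among full-length reads
#'
#' One representative is kept per (cell barcode, UMI) key: the read with the
#' longest cDNA, ties broken by the lexicographically smallest read id.
#'
#' @param processed data.frame of full-length processed reads (columns
#'   read_id, cell_barcode, umi, cdna, ...)
#' @return list with `unique` (representatives, input column set preserved)
#'   and `n_duplicates` (count of removed reads)
#' @export
deduplicate_reads <- function(processed) {
  if (nrow(processed) == 0L) {
    return(list(unique = processed, n_duplicates = 0L))
  }
  key <- paste(processed$cell_barcode, processed$umi, sep = "|")
  o <- order(key, -nchar(processed$cdna), processed$read_id)
  d <- processed[o, , drop = FALSE]
  keep <- !duplicated(key[o])
  uniq <- d[keep, , drop = FALSE]
  uniq <- uniq[order(match(uniq$read_id, processed$read_id)), , drop = FALSE]
  rownames(uniq) <- NULL
  list(unique = uniq, n_duplicates = sum(!keep))
}

#' Process a batch of CCS reads into barcoded full-length cDNA
#'
#' Composition of sample-barcode clipping, primer orientation, cell-barcode
#' and UMI extraction, polyA trimming and duplicate removal. Every input read
#' is routed to exactly one output stream: `full_length` (post-dedup
#' representatives), or `rejects` with its failure category; duplicate
#' full-length reads are reported in the summary.
#'
#' @param reads data.frame with columns `read_id` and `sequence`
#' @param layout [read_layout()] object
#' @param dedup remove (cell barcode, UMI) duplicates among full-length reads
#' @return list of class `scisor_processed` with `full_length` (data.frame:
#'   read_id, cell_barcode, umi, cdna, raw_orientation, polya_len),
#'   `rejects` (data.frame: read_id, sequence, category) and `summary`
#'   (named integer vector: per-category counts over all input reads, plus
#'   `duplicates` and `input`)
#' @export
process_reads <- function(reads, layout = read_layout(), dedup = TRUE) {
  stopifnot(is.data.frame(reads))
  cats <- c("FULL_LENGTH", "MISSING_5P", "MISSING_3P", "MISSING_BOTH",
            "NO_POLYA")
  n <- nrow(reads)
  seqs <- clip_sample_barcode(reads$sequence, layout)
  rcs <- revcomp(seqs)
  evS <- primer_evidence_batch(seqs, layout)
  evA <- primer_evidence_batch(rcs, layout)
  palindromic <- evS$found == 2L & evA$found == 2L
  take_anti <- !palindromic &
    (evA$found > evS$found | (evA$found == evS$found & evA$edits < evS$edits))
  oriented <- ifelse(take_anti, rcs, seqs)
  h5s <- ifelse(take_anti, evA$h5$start, evS$h5$start)
  h5e <- ifelse(take_anti, evA$h5$end, evS$h5$end)
  h3s <- ifelse(take_anti, evA$h3$start, evS$h3$start)
  has5 <- !is.na(h5s); has3 <- !is.na(h3s)
  category <- rep("MISSING_BOTH", n)
  category[!palindromic & has5 & has3] <- "FULL_LENGTH"
  category[!palindromic & has5 & !has3] <- "MISSING_3P"
  category[!palindromic & !has5 & has3] <- "MISSING_5P"
  raw_orientation <- ifelse(take_anti, "antisense", "sense")

  cb <- umi <- cdna <- rep(NA_character_, n)
  polya <- rep(0L, n)
  blk <- layout$cb_len + layout$umi_len
  fl <- which(category == "FULL_LENGTH")
  short <- fl[h3s[fl] - h5e[fl] < blk]
  category[short] <- "MISSING_3P"
  fl <- setdiff(fl, short)
  if (length(fl) > 0L) {
    p <- h3s[fl]
    if (layout$umi_proximal) {
      umi[fl] <- revcomp(substr(oriented[fl], p - layout$umi_len + 1L, p))
      cb[fl] <- revcomp(substr(oriented[fl], p - blk + 1L, p - layout$umi_len))
    } else {
      cb[fl] <- revcomp(substr(oriented[fl], p - layout$cb_len + 1L, p))
      umi[fl] <- revcomp(substr(oriented[fl], p - blk + 1L, p - layout$cb_len))
    }
    upstream <- substr(oriented[fl], h5e[fl] + 1L, p - blk)
    for (j in seq_along(fl)) {
      tr <- trim_polya(upstream[j], layout$min_polya_len, layout$max_non_a)
      cdna[fl[j]] <- tr$sequence
      polya[fl[j]] <- tr$tail_length
    }
    category[fl[polya[fl] == 0L]] <- "NO_POLYA"
  }

  is_fl <- category == "FULL_LENGTH"
  full <- data.frame(read_id = reads$read_id[is_fl],
                     cell_barcode = cb[is_fl], umi = umi[is_fl],
                     cdna = cdna[is_fl],
                     raw_orientation = raw_orientation[is_fl],
                     polya_len = polya[is_fl], stringsAsFactors = FALSE)
  rownames(full) <- NULL
  rejects <- data.frame(read_id = reads$read_id[!is_fl],
                        sequence = seqs[!is_fl], category = category[!is_fl],
                        stringsAsFactors = FALSE)
  rownames(rejects) <- NULL
  n_dup <- 0L
  if (dedup && nrow(full) > 0L) {
    dd <- deduplicate_reads(full)
    full <- dd$unique
    n_dup <- dd$n_duplicates
  }
  counts <- vapply(cats, function(ct) sum(category == ct), 0L)
  summary <- c(counts, duplicates = n_dup, input = n)
  structure(list(full_length = full, rejects = rejects, summary = summary),
            class = "scisor_processed")
}

#' @export
print.scisor_processed <- function(x, ...) {
  cat("scisor_processed:\n")
  print(x$summary)
  invisible(x)
}

#' Read CCS reads from FASTA/FASTQ
#'
#' @param path FASTA or FASTQ file; format inferred from the extension
#'   (`.fq`/`.fastq` = FASTQ, otherwise FASTA)
#' @return data.frame with columns read_id and sequence
#' @export
read_ccs <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", path)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  ids <- vapply(strsplit(names(ss), "[ \t]"), `[[`, "", 1L)
  data.frame(read_id = ids, sequence = as.character(ss),
             stringsAsFactors = FALSE)
}

#' Write processed full-length reads as FASTA with barcode header tags
#'
#' Headers carry `cb=` and `umi=` key=value tags so downstream alignment can
#' propagate cell and molecule identity.
#'
#' @param full data.frame of full-length reads from [process_reads()]
#' @param path output FASTA path
#' @return `path`, invisibly
#' @export
write_processed_fasta <- function(full, path) {
  ss <- Biostrings::DNAStringSet(full$cdna)
  names(ss) <- paste0(full$read_id, " cb=", full$cell_barcode,
                      " umi=", full$umi)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read processed full-length reads written by [write_processed_fasta()]
#'
#' @param path FASTA path
#' @return data.frame with read_id, cell_barcode, umi, cdna
#' @export
read_processed_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(ss), " ", fixed = TRUE)
  grab <- function(p, key) {
    hit <- grep(paste0("^", key, "="), p, value = TRUE)
    if (length(hit) == 0L) NA_character_ else sub("^[a-z]+=", "", hit[1L])
  }
  data.frame(read_id = vapply(parts, `[[`, "", 1L),
             cell_barcode = vapply(parts, grab, "", "cb"),
             umi = vapply(parts, grab, "", "umi"),
             cdna = as.character(ss), stringsAsFactors = FALSE)
}
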