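#' Convert an annotation to BED12 records (TAMA dialect)
#'
#' One BED12 record per transcript. The name field is
#' `"<gene_id>;<transcript_id>"`, the dialect used when preparing files for
#' TAMA-style merging. BED12 is natively 0-based half-open, matching the
#' package's internal convention, so no coordinate shift occurs. Score is
#' written as 40 and thickStart/thickEnd as chromStart/chromEnd (no-CDS
#' defaults of TAMA-consuming tools).
#'
#' @param annot annotation object
#' @return data.frame with the 12 standard BED columns
#' @export
annotation_to_bed12 <- function(annot) {
  stopifnot(is_annotation(annot))
  annot <- sort_annotation(annot)
  chains <- exon_chain_list(annot)
  tx <- annot$transcripts
  if (nrow(tx) == 0L) {
    return(data.frame(chrom = character(), chromStart = integer(),
                      chromEnd = integer(), name = character(),
                      score = integer(), strand = character(),
                      thickStart = integer(), thickEnd = integer(),
                      itemRgb = character(), blockCount = integer(),
                      blockSizes = character(), blockStarts = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(tx)), function(i) {
    exm <- chains[[tx$transcript_id[i]]]
    s <- min(exm[, "start"]); e <- max(exm[, "end"])
    data.frame(
      chrom = tx$chrom[i], chromStart = s, chromEnd = e,
      name = paste0(tx$gene_id[i], ";", tx$transcript_id[i]),
      score = 40L, strand = tx$strand[i],
      thickStart = s, thickEnd = e, itemRgb = "0,0,0",
      blockCount = nrow(exm),
      blockSizes = paste(exm[, "end"] - exm[, "start"], collapse = ","),
      blockStarts = paste(exm[, "start"] - s, collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert BED12 records back to an annotation
#'
#' Inverse of [annotation_to_bed12()]: the name field must contain exactly
#' one semicolon separating gene_id from transcript_id, and blockSizes /
#' blockStarts reconstruct the exon chain exactly.
#'
#' @param bed data.frame of BED12 records (12+ columns; extra columns ignored)
#' @param source source tag for the reconstructed transcripts
#' @return an [annotation()] object
#' @export
bed12_to_annotation <- function(bed, source = "ensembl") {
  bed <- as.data.frame(bed, stringsAsFactors = FALSE)
  if (nrow(bed) == 0L) return(empty_annotation())
  if (ncol(bed) < 12L) stop("BED12 requires 12 columns, got ", ncol(bed))
  names(bed)[1:12] <- c("chrom", "chromStart", "chromEnd", "name", "score",
                        "strand", "thickStart", "thickEnd", "itemRgb",
                        "blockCount", "blockSizes", "blockStarts")
  parts <- strsplit(bed$name, ";", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop("BED12 record ", bad[1L], ": name field '", bed$name[bad[1L]],
         "' does not contain exactly one semicolon (expected gene_id;transcript_id)")
  }
  gene_id <- vapply(parts, `[[`, "", 1L)
  tx_id <- vapply(parts, `[[`, "", 2L)
  num_list <- function(x) lapply(strsplit(sub(",$", "", x), ",", fixed = TRUE),
                                 as.integer)
  sizes <- num_list(bed$blockSizes)
  starts <- num_list(bed$blockStarts)
  ex <- do.call(rbind, lapply(seq_len(nrow(bed)), function(i) {
    if (length(sizes[[i]]) != bed$blockCount[i] ||
        length(starts[[i]]) != bed$blockCount[i]) {
      stop("BED12 record ", i, ": blockCount inconsistent with block lists")
    }
    s <- as.integer(bed$chromStart[i]) + starts[[i]]
    data.frame(transcript_id = tx_id[i], start = s, end = s + sizes[[i]],
               stringsAsFactors = FALSE)
  }))
  tx <- data.frame(transcript_id = tx_id, gene_id = gene_id,
                   chrom = bed$chrom, strand = bed$strand,
                   source = source, gene_name = NA_character_,
                   stringsAsFactors = FALSE)
  annotation(tx, ex)
}

#' Read / write BED12 files
#'
#' Plain tab-separated serialisation of the records produced by
#' [annotation_to_bed12()]; no headers, deterministic record order.
#'
#' @param path file path
#' @param bed data.frame of BED12 records
#' @return `read_bed12`: a data.frame; `write_bed12`: `path`, invisibly.
#' @export
read_bed12 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  n1 <- length(readLines(path, n = 1L))
  if (n1 == 0L) {
    return(annotation_to_bed12(empty_annotation()))
  }
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 12L) stop("BED12 requires 12 columns, got ", ncol(bed))
  names(bed)[1:12] <- c("chrom", "chromStart", "chromEnd", "name", "score",
                        "strand", "thickStart", "thickEnd", "itemRgb",
                        "blockCount", "blockSizes", "blockStarts")
  for (cc in c("chromStart", "chromEnd", "score", "thickStart", "thickEnd",
               "blockCount")) bed[[cc]] <- as.integer(bed[[cc]])
  bed
}

#' @rdname read_bed12
#' @export
write_bed12 <- function(bed, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(bed) > 0L) {
    writeLines(do.call(paste, c(unname(as.list(bed[, 1:12])), sep = "\t")), con)
  }
  invisible(path)
}
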