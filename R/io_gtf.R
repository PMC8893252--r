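#' Read an Ensembl-dialect GTF file into an annotation
#'
#' Only `exon` features are used to build transcript models; `gene`,
#' `transcript` and CDS records are tolerated and skipped (CDS carry-through
#' happens at the merge layer). Coordinates are converted from GTF's 1-based
#' inclusive convention to the package's 0-based half-open convention at this
#' single site.
#'
#' @param path GTF file path
#' @param source source tag to assign to all transcripts (`"ensembl"` or
#'   `"isoseq"`); defaults to `"ensembl"`, the dialect read here.
#' @return an [annotation()] object
#' @export
read_gtf <- function(path, source = "ensembl") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lnos <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_annotation())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) {
    stop("GTF line ", lnos[which(nf < 8L)[1L]], ": fewer than 8 tab fields")
  }
  feat <- vapply(fields, `[[`, "", 3L)
  exon_i <- which(feat == "exon")
  if (length(exon_i) == 0L) return(empty_annotation())

  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0('(^|; ?)', key, ' "([^"]*)"'), attrs))
    vapply(m, function(x) if (length(x) == 3L) x[[3L]] else NA_character_, "")
  }
  attrs <- vapply(fields[exon_i], function(f) if (length(f) >= 9L) f[[9L]] else "", "")
  gene_id <- get_attr(attrs, "gene_id")
  tx_id <- get_attr(attrs, "transcript_id")
  gene_name <- get_attr(attrs, "gene_name")
  bad <- which(is.na(gene_id) | is.na(tx_id))
  if (length(bad) > 0L) {
    stop("GTF line ", lnos[exon_i[bad[1L]]],
         ": exon feature lacks gene_id or transcript_id attribute")
  }
  chrom <- vapply(fields[exon_i], `[[`, "", 1L)
  start1 <- suppressWarnings(as.integer(vapply(fields[exon_i], `[[`, "", 4L)))
  end1 <- suppressWarnings(as.integer(vapply(fields[exon_i], `[[`, "", 5L)))
  strand <- vapply(fields[exon_i], `[[`, "", 7L)
  if (anyNA(start1) || anyNA(end1)) {
    stop("GTF line ", lnos[exon_i[which(is.na(start1) | is.na(end1))[1L]]],
         ": non-integer coordinate")
  }
  if (any(end1 < start1)) {
    stop("GTF line ", lnos[exon_i[which(end1 < start1)[1L]]],
         ": exon end < start")
  }
  ex <- data.frame(transcript_id = tx_id, start = start1 - 1L, end = end1,
                   stringsAsFactors = FALSE)
  tx <- unique(data.frame(transcript_id = tx_id, gene_id = gene_id,
                          chrom = chrom, strand = strand,
                          source = source, gene_name = gene_name,
                          stringsAsFactors = FALSE))
  if (anyDuplicated(tx$transcript_id)) {
    stop("transcript_id ", tx$transcript_id[duplicated(tx$transcript_id)][1L],
         " has inconsistent gene_id/chrom/strand across exon lines")
  }
  annotation(tx, ex)
}

#' Write an annotation as an Ensembl-dialect GTF file
#'
#' Emits one `exon` line per exon, 1-based inclusive coordinates, attributes
#' in the fixed order gene_id, transcript_id, gene_name (gene_name omitted
#' when absent). Record order is deterministic — (chrom, span start, gene_id,
#' transcript_id, exon start) — so two writes of the same annotation are
#' byte-identical.
#'
#' @param annot annotation object
#' @param path output file path
#' @param source_label value for GTF column 2
#' @return `path`, invisibly
#' @export
write_gtf <- function(annot, path, source_label = "scisorpipe") {
  stopifnot(is_annotation(annot))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(annot$transcripts) == 0L) return(invisible(path))
  annot <- sort_annotation(annot)
  tx <- annot$transcripts
  ex <- annot$exons
  i <- match(ex$transcript_id, tx$transcript_id)
  attr_str <- paste0('gene_id "', tx$gene_id[i], '"; transcript_id "',
                     ex$transcript_id, '";',
                     ifelse(is.na(tx$gene_name[i]), "",
                            paste0(' gene_name "', tx$gene_name[i], '";')))
  out <- paste(tx$chrom[i], source_label, "exon", ex$start + 1L, ex$end, ".",
               tx$strand[i], ".", attr_str, sep = "\t")
  writeLines(out, con)
  invisible(path)
}
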