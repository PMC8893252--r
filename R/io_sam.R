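#' Read alignment records from a SAM (or BAM) file
#'
#' Text SAM is parsed directly; a `.bam` path is read through
#' \pkg{Rsamtools}. Only the fields the pipeline consumes are retained:
#' read id, flag, chromosome, 1-based position, CIGAR, sequence, the NM
#' (edit distance) and MD tags, and the 10x-style CB/UB cell-barcode and
#' UMI tags when present.
#'
#' @param path SAM or BAM file path
#' @return data.frame of alignment records with attribute `"header"` holding
#'   the header lines (SAM input only)
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    return(read_bam_records(path))
  }
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0L) {
    out <- data.frame(read_id = character(), flag = integer(),
                      chrom = character(), pos = integer(), mapq = integer(),
                      cigar = character(), seq = character(), nm = integer(),
                      md = character(), cell_barcode = character(),
                      umi = character(), stringsAsFactors = FALSE)
    attr(out, "header") <- hdr
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11L)) {
    stop("SAM record ", which(lengths(fields) < 11L)[1L],
         ": fewer than 11 fields")
  }
  tag_val <- function(f, tag) {
    if (length(f) < 12L) return(NA_character_)
    hit <- grep(paste0("^", tag, ":"), f[12:length(f)], value = TRUE)
    if (length(hit) == 0L) NA_character_ else sub("^..:.:", "", hit[1L])
  }
  out <- data.frame(
    read_id = vapply(fields, `[[`, "", 1L),
    flag = as.integer(vapply(fields, `[[`, "", 2L)),
    chrom = vapply(fields, `[[`, "", 3L),
    pos = as.integer(vapply(fields, `[[`, "", 4L)),
    mapq = as.integer(vapply(fields, `[[`, "", 5L)),
    cigar = vapply(fields, `[[`, "", 6L),
    seq = vapply(fields, `[[`, "", 10L),
    nm = suppressWarnings(as.integer(vapply(fields, tag_val, "", "NM"))),
    md = vapply(fields, tag_val, "", "MD"),
    cell_barcode = vapply(fields, tag_val, "", "CB"),
    umi = vapply(fields, tag_val, "", "UB"),
    stringsAsFactors = FALSE)
  attr(out, "header") <- hdr
  out
}

read_bam_records <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("BAM input requires the Rsamtools package; convert to SAM text or install it")
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = c("NM", "MD", "CB", "UB"))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  data.frame(
    read_id = b$qname, flag = b$flag, chrom = as.character(b$rname),
    pos = b$pos, mapq = b$mapq, cigar = b$cigar,
    seq = as.character(b$seq),
    nm = if (is.null(b$tag$NM)) NA_integer_ else as.integer(b$tag$NM),
    md = if (is.null(b$tag$MD)) NA_character_ else as.character(b$tag$MD),
    cell_barcode = if (is.null(b$tag$CB)) NA_character_ else b$tag$CB,
    umi = if (is.null(b$tag$UB)) NA_character_ else b$tag$UB,
    stringsAsFactors = FALSE)
}

# NM-equivalent edit distance from an MD tag plus the CIGAR's insertions:
# mismatched reference bases (single letters) + deleted bases (after ^) from
# MD, + inserted query bases from CIGAR I operations.
nm_from_md <- function(md, cigar) {
  toks <- regmatches(md, gregexpr("\\^[A-Za-z]+|[A-Za-z]|[0-9]+", md))[[1L]]
  mism <- sum(grepl("^[A-Za-z]$", toks))
  dels <- sum(nchar(sub("^\\^", "", toks[startsWith(toks, "^")])))
  ins <- cigar_op_total(cigar, "I")
  mism + dels + ins
}

cigar_op_total <- function(cigar, ops) {
  opl <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  opc <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  sum(opl[opc %in% ops])
}

#' Build exon-chain alignments from SAM records
#'
#' Keeps mapped primary alignments only (secondary and supplementary records
#' are dropped; unmapped records are skipped and counted). Each retained
#' record yields an aligned read whose exon chain is the reference footprint
#' split at N (intron) CIGAR operations, with coverage and identity computed
#' by [compute_alignment_metrics()].
#'
#' @param records data.frame from [read_sam()]
#' @return list of class `scisor_alignments` with elements `reads` (data.frame:
#'   read_id, chrom, strand, coverage, identity, cell_barcode, umi),
#'   `exons` (data.frame: read_id, start, end; 0-based half-open) and
#'   `skipped` (named counts of unmapped / non-primary records)
#' @export
parse_sam_alignments <- function(records) {
  stopifnot(is.data.frame(records))
  unmapped <- bitwAnd(records$flag, 4L) != 0L | records$cigar == "*"
  nonprimary <- bitwAnd(records$flag, 256L) != 0L |
    bitwAnd(records$flag, 2048L) != 0L
  keep <- !unmapped & !nonprimary
  rec <- records[keep, , drop = FALSE]
  skipped <- c(unmapped = sum(unmapped), non_primary = sum(!unmapped & nonprimary))
  if (nrow(rec) == 0L) {
    return(structure(list(
      reads = data.frame(read_id = character(), chrom = character(),
                         strand = character(), coverage = numeric(),
                         identity = numeric(), cell_barcode = character(),
                         umi = character(), stringsAsFactors = FALSE),
      exons = data.frame(read_id = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE),
      skipped = skipped), class = "scisor_alignments"))
  }
  # seq-length consistency check (seq may be "*")
  has_seq <- rec$seq != "*"
  if (any(has_seq)) {
    qw <- GenomicAlignments::cigarWidthAlongQuerySpace(rec$cigar[has_seq])
    sl <- nchar(rec$seq[has_seq])
    if (any(qw != sl)) {
      bad <- which(qw != sl)[1L]
      stop("SAM record ", rec$read_id[has_seq][bad],
           ": CIGAR query width (", qw[bad],
           ") does not match sequence length (", sl[bad], ")")
    }
  }
  blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
    rec$cigar, pos = rec$pos, drop.D.ranges = FALSE)
  nb <- lengths(blocks)
  fl <- unlist(blocks, use.names = FALSE)
  exons <- data.frame(read_id = rep(rec$read_id, nb),
                      start = IRanges::start(fl) - 1L,
                      end = IRanges::end(fl),
                      stringsAsFactors = FALSE)
  met <- compute_alignment_metrics(rec)
  reads <- data.frame(
    read_id = rec$read_id, chrom = rec$chrom,
    strand = ifelse(bitwAnd(rec$flag, 16L) != 0L, "-", "+"),
    coverage = met$coverage, identity = met$identity,
    cell_barcode = rec$cell_barcode, umi = rec$umi,
    stringsAsFactors = FALSE)
  structure(list(reads = reads, exons = exons, skipped = skipped),
            class = "scisor_alignments")
}

#' @export
print.scisor_alignments <- function(x, ...) {
  cat("scisor_alignments: ", nrow(x$reads), " reads (skipped: ",
      paste(names(x$skipped), x$skipped, sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}
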