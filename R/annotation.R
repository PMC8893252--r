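#' Construct an annotation object
#'
#' An annotation is the package's in-memory representation of a set of gene
#' models: transcripts grouped into genes, each transcript an ordered chain of
#' exons. All coordinates held in memory are 0-based half-open on the genomic
#' (ascending) axis regardless of strand; strand is interpreted only where the
#' semantics require it (5'/3' ends, intron chains read in transcription
#' order). On-disk conventions (GTF 1-based inclusive, BED12 0-based
#' half-open) are converted at the single I/O layer.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand` (one of `"+"`, `"-"`), and optionally `source`
#'   (`"ensembl"` or `"isoseq"`) and `gene_name`.
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open). Exons of one transcript must be disjoint.
#'
#' @return An object of class `scisor_annotation`: a list with normalised
#'   `transcripts` and `exons` data.frames. Exons are stored sorted by
#'   ascending genomic start within each transcript.
#' @export
annotation <- function(transcripts, exons) {
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  if (nrow(transcripts) == 0L) {
    return(empty_annotation())
  }
  need <- c("transcript_id", "gene_id", "chrom", "strand")
  missing_cols <- setdiff(need, names(transcripts))
  if (length(missing_cols) > 0L) {
    stop("transcripts is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"source" %in% names(transcripts)) transcripts$source <- "ensembl"
  if (!"gene_name" %in% names(transcripts)) transcripts$gene_name <- NA_character_
  transcripts <- transcripts[c("transcript_id", "gene_id", "chrom", "strand",
                               "source", "gene_name")]
  if (anyDuplicated(transcripts$transcript_id)) {
    stop("duplicate transcript_id in annotation: ",
         transcripts$transcript_id[duplicated(transcripts$transcript_id)][1L])
  }
  if (!all(transcripts$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (!all(c("transcript_id", "start", "end") %in% names(exons))) {
    stop("exons must have columns transcript_id, start, end")
  }
  exons <- exons[c("transcript_id", "start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$end <= exons$start)) {
    bad <- which(exons$end <= exons$start)[1L]
    stop("exon with end <= start for transcript ", exons$transcript_id[bad])
  }
  if (!all(exons$transcript_id %in% transcripts$transcript_id)) {
    stop("exons reference unknown transcript_id")
  }
  if (!all(transcripts$transcript_id %in% exons$transcript_id)) {
    stop("transcript without exons: ",
         setdiff(transcripts$transcript_id, exons$transcript_id)[1L])
  }
  # canonical order: exons ascending within transcript, transcripts by locus
  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                       exons$start), , drop = FALSE]
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    s <- exons$start[idx]; e <- exons$end[idx]
    if (length(idx) > 1L && any(s[-1L] < e[-length(e)] + 1L)) {
      stop("overlapping or abutting-with-negative-intron exons in transcript ",
           exons$transcript_id[idx[1L]])
    }
  }
  # per-gene consistency: one chrom and strand per gene
  g <- unique(transcripts[c("gene_id", "chrom", "strand")])
  if (anyDuplicated(g$gene_id)) {
    stop("gene ", g$gene_id[duplicated(g$gene_id)][1L],
         " spans multiple chromosomes or strands")
  }
  obj <- structure(list(transcripts = transcripts, exons = exons),
                   class = "scisor_annotation")
  sort_annotation(obj)
}

#' @rdname annotation
#' @export
empty_annotation <- function() {
  structure(list(
    transcripts = data.frame(transcript_id = character(), gene_id = character(),
                             chrom = character(), strand = character(),
                             source = character(), gene_name = character(),
                             stringsAsFactors = FALSE),
    exons = data.frame(transcript_id = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)),
    class = "scisor_annotation")
}

#' @export
print.scisor_annotation <- function(x, ...) {
  cat("scisor_annotation: ", length(unique(x$transcripts$gene_id)), " genes, ",
      nrow(x$transcripts), " transcripts, ", nrow(x$exons), " exons\n", sep = "")
  invisible(x)
}

is_annotation <- function(x) inherits(x, "scisor_annotation")

#' Per-transcript span table
#'
#' @param annot annotation object
#' @return data.frame with transcript_id, gene_id, chrom, strand, source,
#'   gene_name, start, end (0-based half-open span) and n_exons.
#' @export
transcript_spans <- function(annot) {
  stopifnot(is_annotation(annot))
  tx <- annot$transcripts
  if (nrow(tx) == 0L) {
    return(cbind(tx, data.frame(start = integer(), end = integer(),
                                n_exons = integer())))
  }
  s <- vapply(split(annot$exons$start, annot$exons$transcript_id), min, 0L)
  e <- vapply(split(annot$exons$end, annot$exons$transcript_id), max, 0L)
  n <- lengths(split(annot$exons$start, annot$exons$transcript_id))
  tx$start <- as.integer(s[tx$transcript_id])
  tx$end <- as.integer(e[tx$transcript_id])
  tx$n_exons <- as.integer(n[tx$transcript_id])
  tx
}

#' Per-gene span table
#'
#' @param annot annotation object
#' @return data.frame with gene_id, gene_name, chrom, strand, start, end;
#'   span is (min start, max end) over the gene's transcripts.
#' @export
gene_spans <- function(annot) {
  tx <- transcript_spans(annot)
  if (nrow(tx) == 0L) {
    return(data.frame(gene_id = character(), gene_name = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  sp <- do.call(rbind, lapply(split(tx, tx$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1L], gene_name = d$gene_name[1L],
               chrom = d$chrom[1L], strand = d$strand[1L],
               start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp[order(sp$chrom, sp$start, sp$gene_id), , drop = FALSE]
}

#' Exon chain of one transcript
#'
#' @param annot annotation object
#' @param transcript_id transcript identifier
#' @return integer matrix with columns start, end (ascending genomic order)
#' @export
exon_chain <- function(annot, transcript_id) {
  ex <- annot$exons[annot$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(ex) == 0L) stop("unknown transcript_id: ", transcript_id)
  cbind(start = ex$start, end = ex$end)
}

# intron chain of an exon matrix: gaps between consecutive exons, ascending.
# returns a 0-row matrix for mono-exon chains.
introns_of <- function(exmat) {
  n <- nrow(exmat)
  if (n < 2L) return(cbind(start = integer(), end = integer()))
  cbind(start = exmat[-n, "end"], end = exmat[-1L, "start"])
}

# string key identifying an intron chain on its chrom/strand; the identity
# used for collapse, FSM matching and dedup-by-chain.
chain_key <- function(chrom, strand, exmat) {
  ic <- introns_of(exmat)
  paste(chrom, strand, paste(ic[, "start"], ic[, "end"], sep = "-",
                             collapse = ","), sep = "|")
}

# full exon-chain key (exact exon coordinates), used by merge's dedup
exon_key <- function(chrom, strand, exmat) {
  paste(chrom, strand, paste(exmat[, "start"], exmat[, "end"], sep = "-",
                             collapse = ","), sep = "|")
}

# split exons into a named list of matrices, one per transcript
exon_chain_list <- function(annot) {
  ex <- annot$exons
  if (nrow(ex) == 0L) return(list())
  lapply(split(ex[c("start", "end")], ex$transcript_id),
         function(d) cbind(start = d$start, end = d$end))
}

#' Deterministically order an annotation
#'
#' Transcripts are ordered by (chrom, span start, gene_id, transcript_id) and
#' exons ascending within transcript, so that two structurally equal
#' annotations have identical internal layout and identical serialised output.
#'
#' @param annot annotation object
#' @return the same annotation, canonically ordered
#' @export
sort_annotation <- function(annot) {
  stopifnot(is_annotation(annot))
  if (nrow(annot$transcripts) == 0L) return(annot)
  ex <- annot$exons
  tx_start <- vapply(split(ex$start, ex$transcript_id), min, 0L)
  tx <- annot$transcripts
  o <- order(tx$chrom, tx_start[tx$transcript_id], tx$gene_id, tx$transcript_id)
  tx <- tx[o, , drop = FALSE]
  rownames(tx) <- NULL
  ex <- ex[order(match(ex$transcript_id, tx$transcript_id), ex$start), ,
           drop = FALSE]
  rownames(ex) <- NULL
  structure(list(transcripts = tx, exons = ex), class = "scisor_annotation")
}

#' Structural equality of two annotations
#'
#' Compares gene/transcript membership, strands, sources, names and exact exon
#' chains, ignoring row order.
#'
#' @param a,b annotation objects
#' @return TRUE or FALSE
#' @export
annotations_equal <- function(a, b) {
  a <- sort_annotation(a); b <- sort_annotation(b)
  ta <- a$transcripts; tb <- b$transcripts
  na <- function(x) ifelse(is.na(x), "<NA>", x)
  ta$gene_name <- na(ta$gene_name); tb$gene_name <- na(tb$gene_name)
  isTRUE(all.equal(ta, tb, check.attributes = FALSE)) &&
    isTRUE(all.equal(a$exons, b$exons, check.attributes = FALSE))
}

#' Subset an annotation to a set of transcripts
#'
#' @param annot annotation object
#' @param transcript_ids character vector of transcript ids to keep
#' @return annotation containing only those transcripts (genes with no
#'   remaining transcript are dropped)
#' @export
subset_transcripts <- function(annot, transcript_ids) {
  keep <- annot$transcripts$transcript_id %in% transcript_ids
  tx <- annot$transcripts[keep, , drop = FALSE]
  ex <- annot$exons[annot$exons$transcript_id %in% tx$transcript_id, ,
                    drop = FALSE]
  if (nrow(tx) == 0L) return(empty_annotation())
  annotation(tx, ex)
}
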