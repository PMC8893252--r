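#' Strand-aware gene end shifts between two annotations
#'
#' For each gene id present in both annotations, computes the signed change
#' of the 5' and 3' gene ends in transcription direction. On the plus strand
#' `delta5 = new.start - old.start` and `delta3 = new.end - old.end`; on the
#' minus strand `delta5 = old.end - new.end` and `delta3 = old.start -
#' new.start`. A 3'-UTR extension is therefore positive on either strand and
#' an earlier (upstream) start is negative.
#'
#' @param old annotation (e.g. the existing reference)
#' @param new annotation (e.g. the isoform-sequencing improved models)
#' @return list with `records` (data.frame: gene_id, strand, delta5, delta3)
#'   and `excluded` (named counts of genes present in only one annotation)
#' @export
gene_end_shifts <- function(old, new) {
  stopifnot(is_annotation(old), is_annotation(new))
  so <- gene_spans(old)
  sn <- gene_spans(new)
  shared <- intersect(so$gene_id, sn$gene_id)
  io <- match(shared, so$gene_id)
  im <- match(shared, sn$gene_id)
  strand <- so$strand[io]
  plus <- strand == "+"
  delta5 <- ifelse(plus, sn$start[im] - so$start[io], so$end[io] - sn$end[im])
  delta3 <- ifelse(plus, sn$end[im] - so$end[io], so$start[io] - sn$start[im])
  records <- data.frame(gene_id = shared, strand = strand,
                        delta5 = as.integer(delta5),
                        delta3 = as.integer(delta3), stringsAsFactors = FALSE)
  list(records = records,
       excluded = c(old_only = length(setdiff(so$gene_id, sn$gene_id)),
                    new_only = length(setdiff(sn$gene_id, so$gene_id))))
}

#' Count reads overlapping each gene's first and last exon
#'
#' First and last exons are defined strand-aware on each gene's longest
#' transcript (most exonic nucleotides; ties broken by transcript id). A
#' read is counted in an exon iff any of its aligned blocks overlaps that
#' exon by at least 1 nt, and at most once per exon.
#'
#' @param annot annotation object
#' @param aln `scisor_alignments` object (see [parse_sam_alignments()])
#' @return data.frame: gene_id, first_exon_count, last_exon_count
#' @export
terminal_exon_read_counts <- function(annot, aln) {
  stopifnot(is_annotation(annot), inherits(aln, "scisor_alignments"))
  tx <- transcript_spans(annot)
  chains <- exon_chain_list(annot)
  exlen <- vapply(tx$transcript_id, function(t) {
    m <- chains[[t]]; sum(m[, "end"] - m[, "start"])
  }, 0L)
  genes <- gene_spans(annot)
  term <- do.call(rbind, lapply(genes$gene_id, function(g) {
    cand <- tx[tx$gene_id == g, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    best <- cand$transcript_id[order(-exlen[cand$transcript_id],
                                     cand$transcript_id)][1L]
    m <- chains[[best]]
    strand <- cand$strand[1L]
    first <- if (strand == "+") m[1L, ] else m[nrow(m), ]
    last <- if (strand == "+") m[nrow(m), ] else m[1L, ]
    data.frame(gene_id = g, chrom = cand$chrom[1L],
               first_start = first[["start"]], first_end = first[["end"]],
               last_start = last[["start"]], last_end = last[["end"]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(term)) {
    return(data.frame(gene_id = character(), first_exon_count = integer(),
                      last_exon_count = integer(), stringsAsFactors = FALSE))
  }
  blocks <- aln$exons
  bchrom <- aln$reads$chrom[match(blocks$read_id, aln$reads$read_id)]
  count_in <- function(chrom, s, e) {
    hit <- bchrom == chrom & blocks$start < e & blocks$end > s
    length(unique(blocks$read_id[hit]))
  }
  data.frame(
    gene_id = term$gene_id,
    first_exon_count = vapply(seq_len(nrow(term)), function(i) {
      count_in(term$chrom[i], term$first_start[i], term$first_end[i])
    }, 0L),
    last_exon_count = vapply(seq_len(nrow(term)), function(i) {
      count_in(term$chrom[i], term$last_start[i], term$last_end[i])
    }, 0L),
    stringsAsFactors = FALSE)
}

# lower median: for even n the smaller of the two central order statistics
lower_median <- function(x) {
  n <- length(x)
  if (n == 0L) stop("lower_median of empty vector")
  sort(x)[ceiling(n / 2)]
}

#' Summarise end-shift records and terminal-exon count changes
#'
#' Medians use the lower median for even n, keeping every summary value an
#' observed integer. Count differences are (new - old) per gene and are
#' included when both count tables are supplied.
#'
#' @param records end-shift records from [gene_end_shifts()]
#' @param counts_old,counts_new optional data.frames from
#'   [terminal_exon_read_counts()] on the old / new annotation
#' @return list of class `scisor_comparison_summary` with median_delta5,
#'   median_delta3, median_first_exon_count_diff,
#'   median_last_exon_count_diff (NA when counts not supplied) and n_genes
#' @export
summarize_shifts <- function(records, counts_old = NULL, counts_new = NULL) {
  if (nrow(records) == 0L) stop("no shared genes to summarise")
  md5 <- lower_median(records$delta5)
  md3 <- lower_median(records$delta3)
  mfirst <- mlast <- NA_integer_
  if (!is.null(counts_old) && !is.null(counts_new)) {
    shared <- intersect(counts_old$gene_id, counts_new$gene_id)
    io <- match(shared, counts_old$gene_id)
    im <- match(shared, counts_new$gene_id)
    mfirst <- lower_median(counts_new$first_exon_count[im] -
                             counts_old$first_exon_count[io])
    mlast <- lower_median(counts_new$last_exon_count[im] -
                            counts_old$last_exon_count[io])
  }
  structure(list(median_delta5 = md5, median_delta3 = md3,
                 median_first_exon_count_diff = mfirst,
                 median_last_exon_count_diff = mlast,
                 n_genes = nrow(records)),
            class = "scisor_comparison_summary")
}

#' @export
print.scisor_comparison_summary <- function(x, ...) {
  cat("gene-end shift summary over", x$n_genes, "shared genes\n",
      "  median delta5 (5' start shift):", x$median_delta5, "nt\n",
      "  median delta3 (3' end shift):  ", x$median_delta3, "nt\n",
      "  median first-exon read gain:   ", x$median_first_exon_count_diff, "\n",
      "  median last-exon read gain:    ", x$median_last_exon_count_diff, "\n")
  invisible(x)
}
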