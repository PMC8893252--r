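#' Classify isoforms against a reference annotation
#'
#' SQANTI-style structural classification. Each query transcript receives
#' exactly one category, decided in this order:
#' \enumerate{
#'   \item FSM — the query intron chain exactly equals a reference
#'     transcript's intron chain (multi-exon), or a mono-exon reference
#'     transcript reciprocally overlaps a mono-exon query by >= 0.5;
#'   \item ISM — the query intron chain is a consecutive sub-chain of a
#'     reference transcript's;
#'   \item FUSION — query exons overlap the exonic spans of two or more
#'     distinct, mutually non-overlapping same-strand reference genes;
#'   \item NIC — all query donors and acceptors exist in one overlapping
#'     gene's reference splice sites but the chain is new;
#'   \item NNC — at least one donor or acceptor is absent from the gene's
#'     reference sites (subcategorised as intron retention when a query exon
#'     fully contains a reference intron);
#'   \item INTERGENIC — no reference gene overlap;
#'   \item GENIC — overlap without matching junction structure (including
#'     mono-exon queries inside a gene).
#' }
#' Same-strand genes take priority in assignment; a query overlapping genes
#' only on the opposite strand is GENIC. TSS/TTS differences are computed
#' strand-aware against the matched reference transcript (FSM/ISM):
#' positive diff_to_tts means the query 3' end extends downstream of the
#' reference in transcription direction.
#'
#' @param query annotation of isoforms to classify
#' @param ref reference annotation
#' @param end_tol tolerance in nt for the FSM `reference_match` subcategory
#' @return data.frame with one row per query transcript: transcript_id,
#'   category, fsm_subcategory, nnc_subcategory, assigned_gene_ids
#'   (comma-separated), matched_ref_transcript, diff_to_tss, diff_to_tts
#' @export
classify_isoforms <- function(query, ref, end_tol = 50L) {
  stopifnot(is_annotation(query), is_annotation(ref))
  ridx <- build_ref_index(ref)
  qtx <- transcript_spans(query)
  qchains <- exon_chain_list(query)
  rows <- lapply(seq_len(nrow(qtx)), function(i) {
    classify_one(qtx[i, ], qchains[[qtx$transcript_id[i]]], ridx, end_tol)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(), category = character(),
                      fsm_subcategory = character(),
                      nnc_subcategory = character(),
                      assigned_gene_ids = character(),
                      matched_ref_transcript = character(),
                      diff_to_tss = integer(), diff_to_tts = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# reference lookup structures shared by all queries
build_ref_index <- function(ref) {
  tx <- transcript_spans(ref)
  chains <- exon_chain_list(ref)
  ckey <- vapply(seq_len(nrow(tx)), function(i) {
    chain_key(tx$chrom[i], tx$strand[i], chains[[tx$transcript_id[i]]])
  }, "")
  genes <- gene_spans(ref)
  ex <- ref$exons
  gid_of_tx <- stats::setNames(tx$gene_id, tx$transcript_id)
  exon_gr <- GenomicRanges::GRanges(
    tx$chrom[match(ex$transcript_id, tx$transcript_id)],
    IRanges::IRanges(ex$start + 1L, ex$end),
    strand = tx$strand[match(ex$transcript_id, tx$transcript_id)])
  S4Vectors::mcols(exon_gr)$gene_id <- unname(gid_of_tx[ex$transcript_id])
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L, genes$end),
                                    strand = genes$strand)
  S4Vectors::mcols(gene_gr)$gene_id <- genes$gene_id
  # per-gene splice-site and intron tables
  gene_sites <- lapply(split(tx$transcript_id, tx$gene_id), function(tids) {
    ints <- do.call(rbind, lapply(tids, function(t) introns_of(chains[[t]])))
    list(starts = unique(ints[, "start"]), ends = unique(ints[, "end"]),
         introns = unique(ints))
  })
  list(tx = tx, chains = chains, ckey = ckey, genes = genes,
       exon_gr = exon_gr, gene_gr = gene_gr, gene_sites = gene_sites)
}

# strand-aware end differences of a query span vs a reference span
end_diffs <- function(strand, qs, qe, rs, re) {
  if (strand == "+") c(tss = qs - rs, tts = qe - re)
  else c(tss = re - qe, tts = rs - qs)
}

classify_one <- function(q, qexm, ridx, end_tol) {
  res <- data.frame(transcript_id = q$transcript_id, category = NA_character_,
                    fsm_subcategory = NA_character_,
                    nnc_subcategory = NA_character_,
                    assigned_gene_ids = "", matched_ref_transcript = NA_character_,
                    diff_to_tss = NA_integer_, diff_to_tts = NA_integer_,
                    stringsAsFactors = FALSE)
  multi <- nrow(qexm) > 1L
  rtx <- ridx$tx

  pick_match <- function(cand) {    # best end-agreement among candidate ref tx
    d <- vapply(cand, function(j) {
      dd <- end_diffs(q$strand, q$start, q$end, rtx$start[j], rtx$end[j])
      abs(dd["tss"]) + abs(dd["tts"])
    }, 0)
    cand[order(d, rtx$transcript_id[cand])][1L]
  }
  finish_match <- function(j, category) {
    dd <- end_diffs(q$strand, q$start, q$end, rtx$start[j], rtx$end[j])
    res$category <- category
    res$matched_ref_transcript <- rtx$transcript_id[j]
    res$assigned_gene_ids <- rtx$gene_id[j]
    res$diff_to_tss <- as.integer(dd["tss"])
    res$diff_to_tts <- as.integer(dd["tts"])
    if (category == "FSM") {
      res$fsm_subcategory <- subclassify_fsm(dd["tss"], dd["tts"], end_tol)
    }
    res
  }

  if (multi) {
    # (1) FSM: exact intron-chain equality
    qk <- chain_key(q$chrom, q$strand, qexm)
    cand <- which(ridx$ckey == qk & rtx$n_exons > 1L)
    if (length(cand) > 0L) return(finish_match(pick_match(cand), "FSM"))
    # (2) ISM: consecutive sub-chain
    qint <- introns_of(qexm)
    cand <- which(rtx$chrom == q$chrom & rtx$strand == q$strand &
                    rtx$n_exons > nrow(qexm))
    ism <- cand[vapply(cand, function(j) {
      is_consecutive_subchain(qint, introns_of(ridx$chains[[rtx$transcript_id[j]]]))
    }, FALSE)]
    if (length(ism) > 0L) return(finish_match(pick_match(ism), "ISM"))
  } else {
    # mono-exon FSM: reciprocal overlap >= 0.5 with a mono-exon reference tx
    cand <- which(rtx$chrom == q$chrom & rtx$strand == q$strand &
                    rtx$n_exons == 1L)
    ro <- vapply(cand, function(j) {
      ov <- min(q$end, rtx$end[j]) - max(q$start, rtx$start[j])
      if (ov <= 0) 0 else min(ov / (q$end - q$start), ov / (rtx$end[j] - rtx$start[j]))
    }, 0)
    hit <- cand[ro >= 0.5]
    if (length(hit) > 0L) return(finish_match(pick_match(hit), "FSM"))
  }

  # overlapping genes by exonic overlap
  qgr <- GenomicRanges::GRanges(q$chrom,
                                IRanges::IRanges(qexm[, "start"] + 1L, qexm[, "end"]),
                                strand = q$strand)
  hits_same <- GenomicRanges::findOverlaps(qgr, ridx$exon_gr,
                                           ignore.strand = FALSE)
  genes_same <- unique(S4Vectors::mcols(ridx$exon_gr)$gene_id[
    S4Vectors::subjectHits(hits_same)])

  # (3) FUSION: >= 2 distinct non-overlapping same-strand genes
  if (multi && length(genes_same) >= 2L) {
    gs <- ridx$genes[ridx$genes$gene_id %in% genes_same, , drop = FALSE]
    gs <- gs[order(gs$start), , drop = FALSE]
    disjoint <- nrow(gs) >= 2L && all(gs$start[-1L] >= gs$end[-nrow(gs)])
    if (disjoint) {
      res$category <- "FUSION"
      res$assigned_gene_ids <- paste(gs$gene_id, collapse = ",")
      return(res)
    }
  }

  if (multi && length(genes_same) >= 1L) {
    # assign the same-strand gene with the most exonic overlap
    ovl <- vapply(genes_same, function(g) {
      ge <- ridx$exon_gr[S4Vectors::mcols(ridx$exon_gr)$gene_id == g]
      sum(IRanges::width(IRanges::intersect(
        IRanges::reduce(IRanges::ranges(qgr)),
        IRanges::reduce(IRanges::ranges(ge)))))
    }, 0)
    g <- genes_same[order(-ovl, genes_same)][1L]
    sites <- ridx$gene_sites[[g]]
    qint <- introns_of(qexm)
    known <- all(qint[, "start"] %in% sites$starts) &&
      all(qint[, "end"] %in% sites$ends)
    res$assigned_gene_ids <- g
    if (known) {
      res$category <- "NIC"                               # (4)
    } else {
      res$category <- "NNC"                               # (5)
      res$nnc_subcategory <- if (detect_intron_retention(qexm, sites$introns))
        "intron_retention" else "novel_donor_or_acceptor"
    }
    return(res)
  }

  # (6) INTERGENIC / (7) GENIC — any-strand gene-span overlap decides
  hits_any <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(q$chrom, IRanges::IRanges(q$start + 1L, q$end)),
    ridx$gene_gr, ignore.strand = TRUE)
  genes_any <- unique(S4Vectors::mcols(ridx$gene_gr)$gene_id[
    S4Vectors::subjectHits(hits_any)])
  if (length(genes_any) == 0L) {
    res$category <- "INTERGENIC"
  } else {
    res$category <- "GENIC"
    res$assigned_gene_ids <- paste(sort(genes_any), collapse = ",")
  }
  res
}

# qint is a consecutive run of rint (both ascending intron matrices)
is_consecutive_subchain <- function(qint, rint) {
  nq <- nrow(qint); nr <- nrow(rint)
  if (nq == 0L || nq >= nr) return(FALSE)
  for (off in 0:(nr - nq)) {
    if (all(qint == rint[(off + 1L):(off + nq), , drop = FALSE])) return(TRUE)
  }
  FALSE
}

#' Subcategorise a full splice match by its end agreement
#'
#' @param diff_tss,diff_tts signed strand-aware end differences in nt
#' @param end_tol tolerance in nt
#' @return one of `"reference_match"`, `"alt_3"`, `"alt_5"`, `"alt_3_and_5"`
#' @export
subclassify_fsm <- function(diff_tss, diff_tts, end_tol = 50L) {
  ok5 <- abs(diff_tss) <= end_tol
  ok3 <- abs(diff_tts) <= end_tol
  if (ok5 && ok3) "reference_match"
  else if (ok5) "alt_3"
  else if (ok3) "alt_5"
  else "alt_3_and_5"
}

#' Detect intron retention of a query chain over reference introns
#'
#' TRUE iff some query exon fully contains a reference intron (so both
#' flanking reference exons are overlapped by that same query exon).
#'
#' @param qexm query exon matrix (columns start, end)
#' @param ref_introns reference intron matrix (columns start, end)
#' @return logical
#' @export
detect_intron_retention <- function(qexm, ref_introns) {
  if (nrow(ref_introns) == 0L) return(FALSE)
  for (i in seq_len(nrow(qexm))) {
    if (any(qexm[i, "start"] < ref_introns[, "start"] &
            qexm[i, "end"] > ref_introns[, "end"])) return(TRUE)
  }
  FALSE
}

#' Flag likely intra-priming artifacts
#'
#' TRUE iff the genomic window immediately downstream (strand-aware) of the
#' transcript 3' end is A-rich on the transcript strand — the signature of
#' oligo-dT priming on genomic A stretches instead of a real polyA tail.
#' Windows truncated by a contig end use the available bases.
#'
#' @param chrom,strand,start,end transcript span (0-based half-open)
#' @param genome named `DNAStringSet` (or named character vector)
#' @param window window length in nt downstream of the 3' end
#' @param a_frac A-fraction threshold on the transcript strand
#' @return logical
#' @export
intra_priming_flag <- function(chrom, strand, start, end, genome,
                               window = 20L, a_frac = 0.6) {
  gseq <- genome_sequence(genome, chrom)
  glen <- nchar(gseq)
  if (strand == "+") {
    from <- end + 1L; to <- min(end + window, glen)
    if (from > to) return(FALSE)
    w <- substr(gseq, from, to)
    base <- "A"
  } else {
    from <- max(1L, start - window + 1L); to <- start
    if (from > to) return(FALSE)
    w <- substr(gseq, from, to)
    base <- "T"                       # A on the transcript (minus) strand
  }
  ch <- strsplit(w, "", fixed = TRUE)[[1L]]
  mean(ch == base) >= a_frac
}

#' Flag likely RT template-switching junctions
#'
#' TRUE iff the `repeat_len` nt of genome ending at the donor site equal the
#' `repeat_len` nt ending at the acceptor's upstream flank — the direct
#' repeat that lets the reverse transcriptase jump templates and fabricate a
#' junction.
#'
#' @param chrom chromosome name
#' @param intron_start,intron_end intron coordinates (0-based half-open)
#' @param genome named `DNAStringSet` (or named character vector)
#' @param repeat_len direct-repeat length in nt (minimum 4)
#' @return logical
#' @export
rt_switching_flag <- function(chrom, intron_start, intron_end, genome,
                              repeat_len = 8L) {
  if (repeat_len < 4L) stop("repeat_len must be >= 4")
  gseq <- genome_sequence(genome, chrom)
  if (intron_start - repeat_len < 0L || intron_end > nchar(gseq)) return(FALSE)
  donor_flank <- substr(gseq, intron_start - repeat_len + 1L, intron_start)
  acceptor_flank <- substr(gseq, intron_end - repeat_len + 1L, intron_end)
  donor_flank == acceptor_flank
}

genome_sequence <- function(genome, chrom) {
  if (inherits(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) stop("unknown contig: ", chrom)
    as.character(genome[[chrom]])
  } else {
    if (!chrom %in% names(genome)) stop("unknown contig: ", chrom)
    genome[[chrom]]
  }
}

#' Compute artifact filter flags for every transcript
#'
#' @param annot annotation of transcripts to screen
#' @param genome named `DNAStringSet` (or named character vector)
#' @param window,a_frac intra-priming parameters (see [intra_priming_flag()])
#' @param repeat_len RT-switch direct-repeat length
#' @return data.frame: transcript_id, intra_priming, rt_switching, retained
#'   (`retained` under the default rule, before any FSM exemption)
#' @export
compute_filter_flags <- function(annot, genome, window = 20L, a_frac = 0.6,
                                 repeat_len = 8L) {
  tx <- transcript_spans(annot)
  chains <- exon_chain_list(annot)
  ip <- vapply(seq_len(nrow(tx)), function(i) {
    intra_priming_flag(tx$chrom[i], tx$strand[i], tx$start[i], tx$end[i],
                       genome, window, a_frac)
  }, FALSE)
  rt <- vapply(seq_len(nrow(tx)), function(i) {
    ints <- introns_of(chains[[tx$transcript_id[i]]])
    any(vapply(seq_len(nrow(ints)), function(j) {
      rt_switching_flag(tx$chrom[i], ints[j, "start"], ints[j, "end"],
                        genome, repeat_len)
    }, FALSE))
  }, FALSE)
  data.frame(transcript_id = tx$transcript_id, intra_priming = ip,
             rt_switching = rt, retained = !(ip | rt),
             stringsAsFactors = FALSE)
}

#' Remove artifact-flagged isoforms
#'
#' Default rule: drop any transcript flagged for intra-priming or RT
#' switching. FSM transcripts are exempt from intra-priming removal (they
#' match known models); the exemption can be disabled.
#'
#' @param annot annotation of transcripts
#' @param calls classification data.frame from [classify_isoforms()]
#' @param flags flag data.frame from [compute_filter_flags()]
#' @param fsm_exempt exempt FSM transcripts from intra-priming removal
#' @return list with `retained` (filtered annotation) and `report`
#'   (data.frame of removals: transcript_id, category, reason)
#' @export
filter_isoforms <- function(annot, calls, flags, fsm_exempt = TRUE) {
  stopifnot(is_annotation(annot))
  m <- merge(calls[c("transcript_id", "category")], flags,
             by = "transcript_id")
  ip_remove <- m$intra_priming & !(fsm_exempt & m$category == "FSM")
  remove <- ip_remove | m$rt_switching
  reason <- ifelse(ip_remove & m$rt_switching, "intra_priming+rt_switching",
                   ifelse(ip_remove, "intra_priming", "rt_switching"))
  report <- data.frame(transcript_id = m$transcript_id[remove],
                       category = m$category[remove],
                       reason = reason[remove], stringsAsFactors = FALSE)
  keep <- setdiff(annot$transcripts$transcript_id, report$transcript_id)
  list(retained = subset_transcripts(annot, keep), report = report)
}

#' Tabulate structural category and subcategory proportions
#'
#' @param calls classification data.frame from [classify_isoforms()]
#' @return list of data.frames `category`, `fsm_subcategory`,
#'   `nnc_subcategory`, each with columns level, n, proportion (proportions
#'   sum to 1 within each table)
#' @export
classification_summary <- function(calls) {
  if (nrow(calls) == 0L) stop("no classification calls to summarise")
  tab <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) {
      return(data.frame(level = character(), n = integer(),
                        proportion = numeric(), stringsAsFactors = FALSE))
    }
    t <- sort(table(x), decreasing = TRUE)
    data.frame(level = names(t), n = as.integer(t),
               proportion = as.numeric(t) / length(x),
               stringsAsFactors = FALSE)
  }
  list(category = tab(calls$category),
       fsm_subcategory = tab(calls$fsm_subcategory),
       nnc_subcategory = tab(calls$nnc_subcategory))
}
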