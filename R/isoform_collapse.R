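#' Alignment coverage and identity
#'
#' Coverage (c) is the fraction of the full query consumed by the alignment:
#' aligned query bases (M/=/X plus insertions) divided by the full query
#' length including soft and hard clips. Identity (I) is
#' (aligned query bases - edit distance) / aligned query bases; N (intron)
#' operations never contribute to the edit distance. The NM tag is preferred;
#' when absent the MD tag is parsed; when both are absent this is an error.
#'
#' @param records data.frame of SAM records (see [read_sam()])
#' @return data.frame with columns coverage and identity, one row per record
#' @export
compute_alignment_metrics <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 0L)
  if (nrow(records) == 0L) {
    return(data.frame(coverage = numeric(), identity = numeric()))
  }
  cig <- records$cigar
  aligned <- vapply(cig, cigar_op_total, 0, ops = c("M", "=", "X", "I"),
                    USE.NAMES = FALSE)
  clips <- vapply(cig, cigar_op_total, 0, ops = c("S", "H"), USE.NAMES = FALSE)
  qlen <- aligned + clips
  nm <- records$nm
  need_md <- is.na(nm)
  if (any(need_md)) {
    md <- records$md[need_md]
    if (anyNA(md)) {
      stop("record ", records$read_id[need_md][which(is.na(md))[1L]],
           ": neither NM nor MD tag present; identity cannot be computed")
    }
    nm[need_md] <- mapply(nm_from_md, md, cig[need_md])
  }
  data.frame(coverage = aligned / qlen,
             identity = (aligned - nm) / aligned)
}

#' Filter aligned reads on coverage and identity
#'
#' A read passes iff coverage >= `c_min` and identity >= `i_min` (inclusive
#' bounds). Defaults are the thresholds used for full-length transcript
#' collapse, c = 0.99 and I = 0.95.
#'
#' @param aln `scisor_alignments` object from [parse_sam_alignments()]
#' @param c_min minimum query coverage, fraction in \[0, 1\]
#' @param i_min minimum alignment identity, fraction in \[0, 1\]
#' @return list with `passed` (a `scisor_alignments` subset) and
#'   `n_rejected` (count of reads removed)
#' @export
filter_alignments <- function(aln, c_min = 0.99, i_min = 0.95) {
  stopifnot(inherits(aln, "scisor_alignments"))
  keep <- aln$reads$coverage >= c_min & aln$reads$identity >= i_min
  passed <- structure(list(
    reads = aln$reads[keep, , drop = FALSE],
    exons = aln$exons[aln$exons$read_id %in% aln$reads$read_id[keep], ,
                      drop = FALSE],
    skipped = aln$skipped), class = "scisor_alignments")
  rownames(passed$reads) <- NULL; rownames(passed$exons) <- NULL
  list(passed = passed, n_rejected = sum(!keep))
}

#' Collapse aligned reads into unique transcript models
#'
#' Multi-exon reads on the same chromosome and strand with identical intron
#' chains (junction coordinates equal within `junction_tol`) form one
#' transcript model whose span runs from the minimum start to the maximum end
#' of its members and whose internal structure is the shared intron chain.
#' Mono-exon reads are clustered by single-linkage reciprocal overlap of at
#' least `mono_exon_min_overlap`. Models are numbered deterministically,
#' `PB.<locus>.<n>`, loci being span-overlap groups ordered along the genome.
#'
#' @param aln `scisor_alignments` object (already filtered)
#' @param junction_tol junction coordinate tolerance in nt (default 0 = exact
#'   splice sites)
#' @param mono_exon_min_overlap reciprocal-overlap fraction linking mono-exon
#'   reads into one model
#' @return list with `annotation` (collapsed models, source `"isoseq"`,
#'   gene ids = locus ids) and `support` (data.frame transcript_id, read_id,
#'   cell_barcode, umi)
#' @export
collapse_isoforms <- function(aln, junction_tol = 0L,
                              mono_exon_min_overlap = 0.5) {
  stopifnot(inherits(aln, "scisor_alignments"))
  reads <- aln$reads
  if (nrow(reads) == 0L) {
    return(list(annotation = empty_annotation(),
                support = data.frame(transcript_id = character(),
                                     read_id = character(),
                                     cell_barcode = character(),
                                     umi = character(),
                                     stringsAsFactors = FALSE)))
  }
  exl <- split(aln$exons[c("start", "end")], aln$exons$read_id)
  exl <- lapply(exl, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    cbind(start = as.integer(d$start), end = as.integer(d$end))
  })
  chains <- exl[reads$read_id]
  nex <- vapply(chains, nrow, 0L)

  # --- multi-exon: group by intron chain ----------------------------------
  multi <- which(nex > 1L)
  groups <- list()
  if (length(multi) > 0L) {
    if (junction_tol == 0L) {
      key <- vapply(multi, function(i) {
        chain_key(reads$chrom[i], reads$strand[i], chains[[i]])
      }, "")
      groups <- split(multi, key)
    } else {
      groups <- fuzzy_junction_groups(reads, chains, multi, junction_tol)
    }
  }

  # --- mono-exon: single-linkage reciprocal overlap ------------------------
  mono <- which(nex == 1L)
  if (length(mono) > 0L) {
    ms <- vapply(mono, function(i) chains[[i]][1L, "start"], 0L)
    me <- vapply(mono, function(i) chains[[i]][1L, "end"], 0L)
    key <- paste(reads$chrom[mono], reads$strand[mono])
    for (k in unique(key)) {
      idx <- which(key == k)
      adj <- outer(idx, idx, function(a, b) {
        ov <- pmin(me[a], me[b]) - pmax(ms[a], ms[b])
        ov >= mono_exon_min_overlap * (me[a] - ms[a]) &
          ov >= mono_exon_min_overlap * (me[b] - ms[b])
      })
      comp <- connected_components(adj)
      for (cc in split(seq_along(idx), comp)) {
        groups[[length(groups) + 1L]] <- mono[idx[cc]]
      }
    }
  }

  # --- build models --------------------------------------------------------
  models <- lapply(groups, function(idx) {
    idx <- idx[order(reads$read_id[idx])]   # order-independent representative
    first <- chains[[idx[1L]]]
    span_s <- min(vapply(idx, function(i) chains[[i]][1L, "start"], 0L))
    span_e <- max(vapply(idx, function(i) {
      m <- chains[[i]]; m[nrow(m), "end"]
    }, 0L))
    exm <- first
    exm[1L, "start"] <- span_s
    exm[nrow(exm), "end"] <- span_e
    list(chrom = reads$chrom[idx[1L]], strand = reads$strand[idx[1L]],
         exons = exm, members = reads$read_id[idx],
         cb = reads$cell_barcode[idx], umi = reads$umi[idx],
         start = span_s, end = span_e)
  })
  # deterministic order then locus numbering by span overlap per chrom/strand
  o <- order(vapply(models, `[[`, "", "chrom"),
             vapply(models, `[[`, 0L, "start"),
             vapply(models, `[[`, 0L, "end"),
             vapply(models, `[[`, "", "strand"),
             vapply(models, function(m) m$members[1L], ""))
  models <- models[o]
  locus <- assign_loci(models)
  per_locus <- stats::ave(seq_along(models), locus, FUN = seq_along)
  tid <- sprintf("PB.%d.%d", locus, per_locus)
  tx <- data.frame(transcript_id = tid,
                   gene_id = sprintf("PB.%d", locus),
                   chrom = vapply(models, `[[`, "", "chrom"),
                   strand = vapply(models, `[[`, "", "strand"),
                   source = "isoseq", gene_name = NA_character_,
                   stringsAsFactors = FALSE)
  ex <- do.call(rbind, lapply(seq_along(models), function(i) {
    data.frame(transcript_id = tid[i],
               start = models[[i]]$exons[, "start"],
               end = models[[i]]$exons[, "end"], stringsAsFactors = FALSE)
  }))
  support <- do.call(rbind, lapply(seq_along(models), function(i) {
    data.frame(transcript_id = tid[i], read_id = models[[i]]$members,
               cell_barcode = models[[i]]$cb, umi = models[[i]]$umi,
               stringsAsFactors = FALSE)
  }))
  rownames(support) <- NULL
  list(annotation = annotation(tx, ex), support = support)
}

# single-linkage groups of multi-exon reads whose junction vectors agree
# within tol at every coordinate (same junction count required)
fuzzy_junction_groups <- function(reads, chains, multi, tol) {
  key <- paste(reads$chrom[multi], reads$strand[multi],
               vapply(multi, function(i) nrow(chains[[i]]), 0L))
  out <- list()
  for (k in unique(key)) {
    idx <- multi[key == k]
    jx <- lapply(idx, function(i) as.vector(t(introns_of(chains[[i]]))))
    adj <- outer(seq_along(idx), seq_along(idx), Vectorize(function(a, b) {
      all(abs(jx[[a]] - jx[[b]]) <= tol)
    }))
    comp <- connected_components(adj)
    for (cc in split(seq_along(idx), comp)) {
      out[[length(out) + 1L]] <- idx[cc]
    }
  }
  out
}

# connected components of a logical adjacency matrix (single linkage)
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# locus numbers: connected components of span overlap on same chrom+strand,
# numbered in (chrom, start) order of their first member
assign_loci <- function(models) {
  n <- length(models)
  if (n == 0L) return(integer())
  chrom <- vapply(models, `[[`, "", "chrom")
  strand <- vapply(models, `[[`, "", "strand")
  s <- vapply(models, `[[`, 0L, "start")
  e <- vapply(models, `[[`, 0L, "end")
  locus <- integer(n)
  cur <- 0L
  for (k in unique(paste(chrom, strand))) {
    idx <- which(paste(chrom, strand) == k)
    idx <- idx[order(s[idx], e[idx])]
    grp_end <- -1L
    for (i in idx) {
      if (s[i] >= grp_end) {          # no overlap with open locus -> new locus
        cur <- cur + 1L
        grp_end <- e[i]
      } else {
        grp_end <- max(grp_end, e[i])
      }
      locus[i] <- cur
    }
  }
  # renumber in order of first appearance along the sorted model list
  match(locus, unique(locus[order(seq_along(locus))]))
}
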