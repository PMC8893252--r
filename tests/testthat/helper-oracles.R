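# Independent brute-force oracles. These deliberately re-derive results by
# the most literal method available (string scans, all-pairs grouping,
# union-find, double loops) so they share no code path with the package
# implementations they cross-check.

# minimal edit distance of pattern against any substring of text
oracle_min_edits <- function(pattern, text) {
  as.integer(utils::adist(pattern, text, partial = TRUE))
}

# polyA trimming per the boundary definition: try every suffix length,
# keep the longest with <= max_non_a non-A bases, then drop leading non-A
oracle_trim_polya <- function(seq, min_len, max_non_a) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  best <- 0L
  for (L in seq_len(n)) {
    if (sum(ch[(n - L + 1L):n] != "A") <= max_non_a) best <- L
  }
  while (best > 0L && ch[n - best + 1L] != "A") best <- best - 1L
  if (best < min_len) best <- 0L
  list(sequence = substr(seq, 1L, n - best), tail_length = best)
}

# all-pairs single-linkage partition of reads under the collapse keys
oracle_collapse_partition <- function(reads, chains) {
  n <- nrow(reads)
  same <- function(i, j) {
    if (reads$chrom[i] != reads$chrom[j] ||
        reads$strand[i] != reads$strand[j]) return(FALSE)
    a <- chains[[reads$read_id[i]]]; b <- chains[[reads$read_id[j]]]
    if (nrow(a) > 1L && nrow(b) > 1L) {
      ia <- cbind(a[-nrow(a), 2], a[-1, 1]); ib <- cbind(b[-nrow(b), 2], b[-1, 1])
      return(nrow(ia) == nrow(ib) && all(ia == ib))
    }
    if (nrow(a) == 1L && nrow(b) == 1L) {
      ov <- min(a[1, 2], b[1, 2]) - max(a[1, 1], b[1, 1])
      return(ov >= 0.5 * (a[1, 2] - a[1, 1]) && ov >= 0.5 * (b[1, 2] - b[1, 1]))
    }
    FALSE
  }
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (grp[i] != grp[j] && same(i, j)) {
        grp[grp == grp[j]] <- grp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(reads$read_id, grp)
}

# union-find partition of transcripts by >=1 nt same-strand exonic overlap
oracle_gene_partition <- function(annot) {
  tx <- annot$transcripts
  ex <- annot$exons
  n <- nrow(tx)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  overlap <- function(i, j) {
    if (tx$chrom[i] != tx$chrom[j] || tx$strand[i] != tx$strand[j]) return(FALSE)
    a <- ex[ex$transcript_id == tx$transcript_id[i], ]
    b <- ex[ex$transcript_id == tx$transcript_id[j], ]
    for (x in seq_len(nrow(a))) for (y in seq_len(nrow(b))) {
      if (a$start[x] < b$end[y] && b$start[y] < a$end[x]) return(TRUE)
    }
    FALSE
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && overlap(i, j)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  unname(lapply(split(tx$transcript_id, comp), sort))
}

# literal decision-list classifier over plain data structures
oracle_classify <- function(q_chrom, q_strand, q_exons, ref) {
  tx <- transcript_spans(ref)
  chains <- exon_chain_list(ref)
  introns <- function(m) {
    if (nrow(m) < 2L) return(matrix(0L, 0, 2)) else
      cbind(m[-nrow(m), 2], m[-1, 1])
  }
  qint <- introns(q_exons)
  qs <- min(q_exons[, 1]); qe <- max(q_exons[, 2])
  multi <- nrow(q_exons) > 1L
  # FSM
  for (i in seq_len(nrow(tx))) {
    if (tx$chrom[i] != q_chrom || tx$strand[i] != q_strand) next
    m <- chains[[tx$transcript_id[i]]]
    if (multi && nrow(m) > 1L) {
      ri <- introns(m)
      if (nrow(ri) == nrow(qint) && all(ri == qint)) return("FSM")
    }
    if (!multi && nrow(m) == 1L) {
      ov <- min(qe, m[1, 2]) - max(qs, m[1, 1])
      if (ov >= 0.5 * (qe - qs) && ov >= 0.5 * (m[1, 2] - m[1, 1])) return("FSM")
    }
  }
  # ISM
  if (multi) {
    for (i in seq_len(nrow(tx))) {
      if (tx$chrom[i] != q_chrom || tx$strand[i] != q_strand) next
      ri <- introns(chains[[tx$transcript_id[i]]])
      if (nrow(ri) <= nrow(qint)) next
      for (off in 0:(nrow(ri) - nrow(qint))) {
        if (all(ri[(off + 1):(off + nrow(qint)), , drop = FALSE] == qint)) {
          return("ISM")
        }
      }
    }
  }
  # genes with same-strand exonic overlap
  hit_genes <- character(0)
  for (i in seq_len(nrow(tx))) {
    if (tx$chrom[i] != q_chrom || tx$strand[i] != q_strand) next
    m <- chains[[tx$transcript_id[i]]]
    for (x in seq_len(nrow(q_exons))) for (y in seq_len(nrow(m))) {
      if (q_exons[x, 1] < m[y, 2] && m[y, 1] < q_exons[x, 2]) {
        hit_genes <- union(hit_genes, tx$gene_id[i])
      }
    }
  }
  gsp <- gene_spans(ref)
  if (multi && length(hit_genes) >= 2L) {
    gs <- gsp[gsp$gene_id %in% hit_genes, ]
    gs <- gs[order(gs$start), ]
    if (all(gs$start[-1] >= gs$end[-nrow(gs)])) return("FUSION")
  }
  if (multi && length(hit_genes) >= 1L) {
    # most-overlap gene
    ov <- vapply(hit_genes, function(g) {
      tot <- 0
      for (t in tx$transcript_id[tx$gene_id == g]) {
        m <- chains[[t]]
        for (x in seq_len(nrow(q_exons))) for (y in seq_len(nrow(m))) {
          tot <- tot + max(0, min(q_exons[x, 2], m[y, 2]) -
                             max(q_exons[x, 1], m[y, 1]))
        }
      }
      tot
    }, 0)
    g <- hit_genes[order(-ov, hit_genes)][1L]
    sts <- integer(0); ens <- integer(0)
    for (t in tx$transcript_id[tx$gene_id == g]) {
      ri <- introns(chains[[t]])
      sts <- union(sts, ri[, 1]); ens <- union(ens, ri[, 2])
    }
    if (all(qint[, 1] %in% sts) && all(qint[, 2] %in% ens)) return("NIC")
    return("NNC")
  }
  any_overlap <- any(gsp$chrom == q_chrom & gsp$start < qe & gsp$end > qs)
  if (any_overlap) "GENIC" else "INTERGENIC"
}

# double-loop terminal-exon read counting
oracle_terminal_counts <- function(annot, aln) {
  tx <- transcript_spans(annot)
  chains <- exon_chain_list(annot)
  out <- list()
  for (g in unique(tx$gene_id)) {
    cand <- tx[tx$gene_id == g, ]
    len <- vapply(cand$transcript_id, function(t) {
      m <- chains[[t]]; sum(m[, 2] - m[, 1])
    }, 0L)
    best <- cand$transcript_id[order(-len, cand$transcript_id)][1L]
    m <- chains[[best]]
    strand <- cand$strand[1L]
    fe <- if (strand == "+") m[1L, ] else m[nrow(m), ]
    le <- if (strand == "+") m[nrow(m), ] else m[1L, ]
    cnt <- function(ex) {
      hit <- character(0)
      for (r in unique(aln$exons$read_id)) {
        if (aln$reads$chrom[aln$reads$read_id == r] != cand$chrom[1L]) next
        b <- aln$exons[aln$exons$read_id == r, ]
        if (any(b$start < ex[2] & b$end > ex[1])) hit <- c(hit, r)
      }
      length(hit)
    }
    out[[g]] <- data.frame(gene_id = g, first_exon_count = cnt(fe),
                           last_exon_count = cnt(le))
  }
  do.call(rbind, unname(out))
}
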