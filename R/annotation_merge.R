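#' Merge two annotations into unified gene models
#'
#' Pools the transcripts of a reference (`ensembl`-source) annotation and an
#' isoform-sequencing (`isoseq`-source) annotation, then re-forms genes as
#' connected components of same-strand transcripts linked by at least 1 nt
#' of exonic overlap. With `dedup = TRUE`, transcripts with identical exon
#' chains collapse to a single copy, keeping the ensembl-source record when
#' sources differ. Merged genes receive interim ids `MERGEG_%06d` in
#' (chrom, start) order; [assign_gene_identifiers()] maps them to reference
#' ids or novel ids.
#'
#' @param a annotation, conventionally the reference (source `"ensembl"`)
#' @param b annotation, conventionally the new models (source `"isoseq"`)
#' @param dedup collapse identical exon chains
#' @return list with `annotation` (merged), `dedup_report` (data.frame:
#'   removed transcript_id, kept transcript_id)
#' @export
merge_annotations <- function(a, b, dedup = TRUE) {
  stopifnot(is_annotation(a), is_annotation(b))
  btx <- b$transcripts
  bex <- b$exons
  clash <- btx$transcript_id %in% a$transcripts$transcript_id
  if (any(clash)) {                 # e.g. merge(A, A): disambiguate then dedup
    newid <- paste0(btx$transcript_id, ".b")
    map <- stats::setNames(newid, btx$transcript_id)
    bex$transcript_id <- unname(map[bex$transcript_id])
    btx$transcript_id <- newid
  }
  tx <- rbind(a$transcripts, btx)
  ex <- rbind(a$exons, bex)
  dedup_report <- data.frame(removed = character(), kept = character(),
                             stringsAsFactors = FALSE)
  if (dedup && nrow(tx) > 0L) {
    chains <- lapply(split(ex[c("start", "end")], ex$transcript_id),
                     function(d) cbind(start = d$start[order(d$start)],
                                       end = d$end[order(d$start)]))
    key <- vapply(seq_len(nrow(tx)), function(i) {
      exon_key(tx$chrom[i], tx$strand[i], chains[[tx$transcript_id[i]]])
    }, "")
    # keep the ensembl copy on chain ties, then the lexicographically first id
    o <- order(key, tx$source != "ensembl", tx$transcript_id)
    keep <- !duplicated(key[o])
    kept_of <- stats::setNames(tx$transcript_id[o][
      match(key[o], key[o][keep])], tx$transcript_id[o])
    removed <- tx$transcript_id[o][!keep]
    dedup_report <- data.frame(removed = removed,
                               kept = unname(kept_of[removed]),
                               stringsAsFactors = FALSE)
    tx <- tx[tx$transcript_id %in% tx$transcript_id[o][keep], , drop = FALSE]
    ex <- ex[ex$transcript_id %in% tx$transcript_id, , drop = FALSE]
  }
  if (nrow(tx) == 0L) {
    return(list(annotation = empty_annotation(), dedup_report = dedup_report))
  }
  comp <- exonic_overlap_components(tx, ex)
  # interim gene ids in (chrom, component start) order
  tx_start <- vapply(split(ex$start, ex$transcript_id), min, 0L)[tx$transcript_id]
  comp_ids <- sort(unique(comp))
  comp_chrom <- vapply(comp_ids, function(cc) tx$chrom[comp == cc][1L], "")
  comp_start <- vapply(comp_ids, function(cc) min(tx_start[comp == cc]), 0L)
  ranked <- comp_ids[order(comp_chrom, comp_start)]
  tx$gene_id <- sprintf("MERGEG_%06d", match(comp, ranked))
  tx$gene_name <- NA_character_
  list(annotation = annotation(tx, ex), dedup_report = dedup_report)
}

# connected components (integer labels, in tx row order) of transcripts
# linked by >= 1 nt exonic overlap on the same chrom and strand
exonic_overlap_components <- function(tx, ex) {
  i <- match(ex$transcript_id, tx$transcript_id)
  gr <- GenomicRanges::GRanges(tx$chrom[i],
                               IRanges::IRanges(ex$start + 1L, ex$end),
                               strand = tx$strand[i])
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = FALSE)
  from <- i[S4Vectors::queryHits(hits)]
  to <- i[S4Vectors::subjectHits(hits)]
  # union-find over transcript indices
  parent <- seq_len(nrow(tx))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(from)) {
    ra <- find(from[k]); rb <- find(to[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(nrow(tx)), find, 0L)
}

#' Map merged gene components to reference identifiers
#'
#' A merged gene containing at least one ensembl-source transcript adopts
#' that transcript's reference gene id and gene name; when transcripts from
#' two or more distinct reference genes ended up in one component, the gene
#' contributing the most exonic overlap wins and the others are listed in
#' the conflict report. Components with only isoseq transcripts receive
#' sequential novel ids (`NOVELG_000001`, ...) in (chrom, start) order.
#'
#' @param merged annotation from [merge_annotations()]
#' @param ensembl the original reference annotation (provides gene ids/names)
#' @return list with `annotation` (ids and names assigned) and `conflicts`
#'   (data.frame: merged_gene_id, adopted, rejected, adopted_overlap,
#'   rejected_overlap)
#' @export
assign_gene_identifiers <- function(merged, ensembl) {
  stopifnot(is_annotation(merged), is_annotation(ensembl))
  tx <- merged$transcripts
  ex <- merged$exons
  ens_tx <- ensembl$transcripts
  ens_gene_of_tx <- stats::setNames(ens_tx$gene_id, ens_tx$transcript_id)
  ens_name_of_gene <- stats::setNames(
    ens_tx$gene_name[!duplicated(ens_tx$gene_id)],
    ens_tx$gene_id[!duplicated(ens_tx$gene_id)])
  conflicts <- list()
  new_gid <- tx$gene_id
  new_gname <- tx$gene_name
  # novel ids assigned in (chrom, start) order over isoseq-only components
  sp <- gene_spans(merged)
  comp_order <- sp$gene_id[order(sp$chrom, sp$start)]
  novel_counter <- 0L
  for (g in comp_order) {
    rows <- which(tx$gene_id == g)
    member_ens <- tx$transcript_id[rows][tx$source[rows] == "ensembl"]
    # transcripts renamed during merge keep their origin by the ".b" suffix
    origin <- sub("\\.b$", "", member_ens)
    ens_ids <- unique(unname(ens_gene_of_tx[origin]))
    ens_ids <- ens_ids[!is.na(ens_ids)]
    if (length(ens_ids) == 0L) {
      novel_counter <- novel_counter + 1L
      new_gid[rows] <- sprintf("NOVELG_%06d", novel_counter)
      new_gname[rows] <- NA_character_
    } else if (length(ens_ids) == 1L) {
      new_gid[rows] <- ens_ids
      new_gname[rows] <- unname(ens_name_of_gene[ens_ids])
    } else {
      ov <- vapply(ens_ids, function(eg) {
        etids <- ens_tx$transcript_id[ens_tx$gene_id == eg]
        ee <- ensembl$exons[ensembl$exons$transcript_id %in% etids, ,
                            drop = FALSE]
        me <- ex[ex$transcript_id %in% tx$transcript_id[rows], , drop = FALSE]
        sum(IRanges::width(IRanges::intersect(
          IRanges::reduce(IRanges::IRanges(ee$start + 1L, ee$end)),
          IRanges::reduce(IRanges::IRanges(me$start + 1L, me$end)))))
      }, 0)
      win <- ens_ids[order(-ov, ens_ids)][1L]
      new_gid[rows] <- win
      new_gname[rows] <- unname(ens_name_of_gene[win])
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        merged_gene_id = g, adopted = win,
        rejected = paste(setdiff(ens_ids, win), collapse = ","),
        adopted_overlap = max(ov),
        rejected_overlap = paste(ov[order(-ov)][-1L], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  tx$gene_id <- new_gid
  tx$gene_name <- new_gname
  conflicts <- if (length(conflicts) > 0L) do.call(rbind, conflicts) else
    data.frame(merged_gene_id = character(), adopted = character(),
               rejected = character(), adopted_overlap = numeric(),
               rejected_overlap = character(), stringsAsFactors = FALSE)
  list(annotation = annotation(tx, ex), conflicts = conflicts)
}

#' Prefix mitochondrial gene names with "MT-"
#'
#' Every gene on the mitochondrial contig has its gene name prefixed with
#' `MT-` (genes without a name use their gene id as the base). Already
#' prefixed names are left untouched, so the operation is idempotent.
#'
#' @param annot annotation object
#' @param mito_chrom name of the mitochondrial contig
#' @param known_chroms optional character vector of valid contig names; when
#'   supplied, an unknown `mito_chrom` is an error
#' @return annotation with renamed mitochondrial genes
#' @export
apply_mito_prefix <- function(annot, mito_chrom, known_chroms = NULL) {
  stopifnot(is_annotation(annot))
  if (!is.null(known_chroms) && !mito_chrom %in% known_chroms) {
    stop("unknown contig: ", mito_chrom)
  }
  tx <- annot$transcripts
  on_mt <- tx$chrom == mito_chrom
  base <- ifelse(is.na(tx$gene_name), tx$gene_id, tx$gene_name)
  needs <- on_mt & !startsWith(base, "MT-")
  tx$gene_name[needs] <- paste0("MT-", base[needs])
  tx$gene_name[on_mt & !needs] <- base[on_mt & !needs]
  annotation(tx, annot$exons)
}
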