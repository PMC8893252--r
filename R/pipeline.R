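#' Pipeline configuration
#'
#' Collects the paths and tunable parameters of the end-to-end driver in one
#' validated list. The collapse thresholds default to the full-length
#' filtering values c = 0.99 (query coverage) and I = 0.95 (alignment
#' identity); classification and artifact-filter defaults follow the
#' package's SQANTI-style conventions.
#'
#' @param reads path to CCS reads (FASTA/FASTQ)
#' @param alignments path to splice-aware alignments (SAM, or BAM with
#'   \pkg{Rsamtools})
#' @param reference_gtf path to the reference annotation (Ensembl-dialect GTF)
#' @param genome path to the genome FASTA
#' @param out_dir output directory (created if needed)
#' @param c_min,i_min collapse coverage/identity thresholds
#' @param junction_tol junction tolerance in nt for collapse
#' @param end_tol FSM end tolerance in nt
#' @param window,a_frac intra-priming window (nt) and A-fraction threshold
#' @param repeat_len RT-switch direct-repeat length in nt
#' @param dedup collapse duplicate chains during merge
#' @param mito_chrom mitochondrial contig name (NA disables MT- renaming)
#' @param seed integer seed recorded in the manifest
#' @param layout [read_layout()] object
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(reads = NULL, alignments = NULL,
                            reference_gtf = NULL, genome = NULL,
                            out_dir = "scisor_run",
                            c_min = 0.99, i_min = 0.95, junction_tol = 0L,
                            end_tol = 50L, window = 20L, a_frac = 0.6,
                            repeat_len = 8L, dedup = TRUE,
                            mito_chrom = NA_character_, seed = 1L,
                            layout = read_layout()) {
  stopifnot(c_min >= 0, c_min <= 1, i_min >= 0, i_min <= 1,
            junction_tol >= 0, end_tol >= 0, window > 0,
            a_frac >= 0, a_frac <= 1, repeat_len >= 4)
  structure(list(reads = reads, alignments = alignments,
                 reference_gtf = reference_gtf, genome = genome,
                 out_dir = out_dir, c_min = c_min, i_min = i_min,
                 junction_tol = as.integer(junction_tol),
                 end_tol = as.integer(end_tol), window = as.integer(window),
                 a_frac = a_frac, repeat_len = as.integer(repeat_len),
                 dedup = isTRUE(dedup), mito_chrom = mito_chrom,
                 seed = as.integer(seed), layout = layout),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration file (YAML)
#'
#' The file round-trips losslessly: `read_pipeline_config(write_pipeline_config(x))`
#' reproduces `x`.
#'
#' @param path config file path
#' @param config `pipeline_config` object
#' @return `read_pipeline_config`: a `pipeline_config`;
#'   `write_pipeline_config`: `path`, invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  layout_fields <- raw[["layout"]]
  raw$layout <- NULL
  raw <- raw[!vapply(raw, is.null, FALSE)]
  cfg <- do.call(pipeline_config, raw)
  if (!is.null(layout_fields)) {
    layout_fields$sample_barcode <-
      if (is.null(layout_fields$sample_barcode)) NA_character_ else
        layout_fields$sample_barcode
    cfg$layout <- do.call(read_layout, layout_fields)
  }
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$layout <- unclass(x$layout)
  if (is.na(x$layout$sample_barcode)) x$layout$sample_barcode <- NULL
  if (is.na(x$mito_chrom)) x$mito_chrom <- NULL
  x <- x[!vapply(x, function(v) is.null(v) || (length(v) == 1L && is.na(v)),
                 FALSE) | names(x) == "layout"]
  yaml::write_yaml(x, path)
  invisible(path)
}

stage_summary <- function(out_dir, stage, values) {
  path <- file.path(out_dir, paste0(stage, "_summary.json"))
  obj <- c(list(stage = stage), values)
  validate_stage_summary(obj)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Validate a stage summary object
#'
#' Checks a stage summary against the bundled schema
#' (`inst/schema/stage_summary.json`): `stage` must be a string and every
#' other entry a scalar number, string or logical.
#'
#' @param obj named list
#' @return TRUE, invisibly; errors otherwise
#' @export
validate_stage_summary <- function(obj) {
  if (!is.list(obj) || is.null(obj$stage) || !is.character(obj$stage)) {
    stop("stage summary must be a named list with a string 'stage' field")
  }
  ok <- vapply(obj, function(v) {
    length(v) == 1L && (is.numeric(v) || is.character(v) || is.logical(v))
  }, FALSE)
  if (!all(ok)) {
    stop("stage summary fields must be scalars: ",
         paste(names(obj)[!ok], collapse = ", "))
  }
  invisible(TRUE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full annotation pipeline
#'
#' Executes the stages in order — read processing, alignment ingestion and
#' collapse, structural classification and artifact filtering, annotation
#' merge, and annotation comparison — writing each stage's outputs and a
#' machine-readable JSON summary under `config$out_dir`. Alignment itself is
#' an external step: point `config$alignments` at a splice-aware SAM/BAM of
#' the processed full-length reads (e.g. minimap2 with `-ax splice -uf`).
#' Rerunning with identical inputs and config reproduces identical outputs.
#'
#' @param config `pipeline_config` object or path to a YAML config file
#' @return invisibly, a list with the per-stage results and the manifest
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, files = character())
  note <- function(p) manifest$files <<- c(manifest$files, p)

  # --- process -------------------------------------------------------------
  proc <- run_stage("process", {
    if (is.null(config$reads)) stop("config$reads is not set (--reads)")
    reads <- read_ccs(config$reads)
    p <- process_reads(reads, config$layout)
    note(write_processed_fasta(p$full_length,
                               file.path(out, "full_length.fasta")))
    rej <- Biostrings::DNAStringSet(p$rejects$sequence)
    names(rej) <- sprintf("%s category=%s", p$rejects$read_id,
                          p$rejects$category)
    Biostrings::writeXStringSet(rej, file.path(out, "rejects.fasta"))
    note(file.path(out, "rejects.fasta"))
    utils::write.table(data.frame(metric = names(p$summary),
                                  count = as.integer(p$summary)),
                       file.path(out, "process_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    note(stage_summary(out, "process", as.list(p$summary)))
    p
  })

  # --- collapse ------------------------------------------------------------
  collapsed <- run_stage("collapse", {
    if (is.null(config$alignments)) {
      stop("config$alignments is not set (--alignments); align the ",
           "full-length reads with a splice-aware aligner first ",
           "(e.g. minimap2 -ax splice -uf)")
    }
    aln <- parse_sam_alignments(read_sam(config$alignments))
    filt <- filter_alignments(aln, config$c_min, config$i_min)
    cc <- collapse_isoforms(filt$passed, config$junction_tol)
    note(write_gtf(cc$annotation, file.path(out, "collapsed.gtf")))
    utils::write.table(cc$support, file.path(out, "collapsed_support.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    note(file.path(out, "collapsed_support.tsv"))
    note(stage_summary(out, "collapse", list(
      n_alignments = nrow(aln$reads), n_filtered_out = filt$n_rejected,
      n_models = nrow(cc$annotation$transcripts))))
    list(collapse = cc, alignments = filt$passed)
  })

  # --- classify / filter ---------------------------------------------------
  classified <- run_stage("classify", {
    if (is.null(config$reference_gtf)) stop("config$reference_gtf is not set")
    if (is.null(config$genome)) stop("config$genome is not set")
    ref <- read_gtf(config$reference_gtf)
    genome <- Biostrings::readDNAStringSet(config$genome)
    names(genome) <- vapply(strsplit(names(genome), "[ \t]"), `[[`, "", 1L)
    calls <- classify_isoforms(collapsed$collapse$annotation, ref,
                               config$end_tol)
    flags <- compute_filter_flags(collapsed$collapse$annotation, genome,
                                  config$window, config$a_frac,
                                  config$repeat_len)
    fi <- filter_isoforms(collapsed$collapse$annotation, calls, flags)
    tab <- merge(calls, flags, by = "transcript_id")
    utils::write.table(tab, file.path(out, "classification.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    note(file.path(out, "classification.tsv"))
    note(write_gtf(fi$retained, file.path(out, "filtered.gtf")))
    cs <- classification_summary(calls)
    props <- stats::setNames(as.list(cs$category$proportion),
                             paste0("prop_", cs$category$level))
    note(stage_summary(out, "classify", c(list(
      n_input = nrow(calls), n_removed = nrow(fi$report),
      n_retained = nrow(fi$retained$transcripts)), props)))
    list(ref = ref, genome = genome, calls = calls, flags = flags,
         retained = fi$retained, report = fi$report)
  })

  # --- merge ---------------------------------------------------------------
  merged <- run_stage("merge", {
    mg <- merge_annotations(classified$ref, classified$retained,
                            dedup = config$dedup)
    asg <- assign_gene_identifiers(mg$annotation, classified$ref)
    final <- asg$annotation
    if (!is.na(config$mito_chrom)) {
      final <- apply_mito_prefix(final, config$mito_chrom,
                                 known_chroms = names(classified$genome))
    }
    note(write_gtf(final, file.path(out, "merged.gtf")))
    note(write_bed12(annotation_to_bed12(final), file.path(out, "merged.bed")))
    utils::write.table(mg$dedup_report, file.path(out, "merge_dedup.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(asg$conflicts, file.path(out, "merge_conflicts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    note(stage_summary(out, "merge", list(
      n_genes = length(unique(final$transcripts$gene_id)),
      n_transcripts = nrow(final$transcripts),
      n_dedup_removed = nrow(mg$dedup_report),
      n_conflicts = nrow(asg$conflicts))))
    final
  })

  # --- compare -------------------------------------------------------------
  comparison <- run_stage("compare", {
    sh <- gene_end_shifts(classified$ref, merged)
    co <- terminal_exon_read_counts(classified$ref, collapsed$alignments)
    cn <- terminal_exon_read_counts(merged, collapsed$alignments)
    sm <- summarize_shifts(sh$records, co, cn)
    utils::write.table(sh$records, file.path(out, "end_shifts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    note(file.path(out, "end_shifts.tsv"))
    note(stage_summary(out, "compare", list(
      n_genes = sm$n_genes, median_delta5 = sm$median_delta5,
      median_delta3 = sm$median_delta3,
      median_first_exon_count_diff = sm$median_first_exon_count_diff,
      median_last_exon_count_diff = sm$median_last_exon_count_diff)))
    sm
  })

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(process = proc, collapse = collapsed$collapse,
                 classify = classified[c("calls", "flags", "report")],
                 merged = merged, comparison = comparison,
                 manifest = manifest))
}
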