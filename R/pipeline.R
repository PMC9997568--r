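# Per-sample orchestration: extract -> filter -> cluster (threshold scan) ->
# consensus + specificity screen -> annotate, with a machine-readable report.

#' Pipeline run configuration
#'
#' Defaults are the pipeline's published operating point: smallest amplicon
#' strictly over 1,000 bp, a 1,200-2,400 bp size window with mean quality
#' strictly over Q14 (plus the optional Q7 read prefilter), an identity
#' threshold grid 0.84-0.91 in 0.01 steps with the >10% supported-cluster
#' rule, and the 99.45% consensus-identity overclustering limit.
#'
#' @param min_amplicon strict lower bound for target-amplicon extraction.
#' @param primer_indels allow indels inside primer sites during extraction
#'   (default `FALSE`; substitution-only matching).
#' @param min_len,max_len inclusive amplicon size window.
#' @param min_q strict amplicon mean-quality floor.
#' @param prefilter_q strict read-level quality floor (`NULL` to skip; the
#'   stage is redundant when input reads already passed basecaller filtering).
#' @param c_grid identity-threshold grid.
#' @param support supported-cluster fraction.
#' @param overcluster_limit consensus identity limit for overclustering.
#' @param nonspecific_min_identity specificity floor against the references.
#' @param assign_min_identity,assign_min_margin paralog assignment rules.
#' @param consensus_rounds,max_members consensus-polishing controls.
#' @param snap_window splice-boundary snapping window (bp).
#' @param expected_cys expected conserved cysteine count.
#' @return a list of class `paraseek_config`.
#' @export
paraseek_config <- function(min_amplicon = 1000L,
                            primer_indels = FALSE,
                            min_len = 1200L, max_len = 2400L, min_q = 14,
                            prefilter_q = 7,
                            c_grid = seq(0.84, 0.91, by = 0.01),
                            support = 0.10,
                            overcluster_limit = 0.9945,
                            nonspecific_min_identity = 0.80,
                            assign_min_identity = 0.97,
                            assign_min_margin = 0.005,
                            consensus_rounds = 2L,
                            max_members = 100L,
                            snap_window = 6L,
                            expected_cys = 4L) {
  structure(as.list(environment()), class = "paraseek_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys are [paraseek_config()] arguments; unknown
#' keys are rejected, unstated keys keep their defaults.
#'
#' @param path YAML file path.
#' @return a [paraseek_config()].
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(paraseek_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  }
  do.call(paraseek_config, vals)
}

#' Run the full pipeline on one sample
#'
#' Executes amplicon extraction, size/quality filtering, the identity
#' threshold scan with overclustering control, consensus polishing, the
#' nonspecific screen, and (when a reference gene model is supplied)
#' annotation with homopolymer frameshift repair, hallmark validation and
#' paralog assignment. Samples are processed in isolation; the threshold is
#' selected per sample.
#'
#' @param reads reads tibble (see [read_fastq()]) or a FASTQ path.
#' @param primers a [primer_pair()] or primer-table row for this sample.
#' @param references named character vector (or `name`/`bases` tibble) of
#'   reference gene sequences for the nonspecific screen.
#' @param ref_model optional [gene_model()] for annotation transfer.
#' @param named_refs optional named paralog reference sequences for
#'   [assign_paralog()].
#' @param profile optional [conserved_profile()] for hallmark validation.
#' @param config a [paraseek_config()].
#' @param sample_id sample label (default: from the reads).
#' @return an object of class `paraseek_report`; see [tidy.paraseek_report()].
#' @export
run_sample <- function(reads, primers, references,
                       ref_model = NULL, named_refs = NULL, profile = NULL,
                       config = paraseek_config(), sample_id = NULL) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  sample_id <- sample_id %||%
    (if (nrow(reads)) reads$sample_id[1] else "sample")
  primers <- sample_primers(primers, sample_id)
  warnings <- character(0)

  n_in <- nrow(reads)
  if (!is.null(config$prefilter_q)) reads <- prefilter_reads(reads, config$prefilter_q)
  n_prefiltered <- nrow(reads)

  amplicons <- extract_amplicons(reads, primers, config$min_amplicon,
                                 with_indels = config$primer_indels)
  n_extracted <- nrow(amplicons)
  amplicons <- filter_amplicons(amplicons, config$min_len, config$max_len, config$min_q)
  n_filtered <- nrow(amplicons)

  counts <- tibble::tibble(
    n_reads_in = n_in, n_reads_prefiltered = n_prefiltered,
    n_amplicons_extracted = n_extracted, n_amplicons_filtered = n_filtered
  )
  if (n_filtered == 0L) {
    warnings <- c(warnings, "no amplicons passed extraction and filtering")
    return(new_report(sample_id, counts, scan = NULL, consensus = tibble::tibble(),
                      genes = list(), warnings = warnings, config = config))
  }

  scan <- run_cluster_stage(
    amplicons, grid = config$c_grid, support = config$support,
    overcluster_limit = config$overcluster_limit,
    consensus_rounds = config$consensus_rounds, max_members = config$max_members
  )
  consensus <- scan$consensus
  if (nrow(consensus) == 0L) {
    warnings <- c(warnings, "no supported clusters at the chosen threshold")
    return(new_report(sample_id, counts, scan, consensus, list(), warnings, config))
  }
  consensus$cluster_id <- paste0(sample_id, ".cluster", consensus$cluster)
  consensus <- screen_nonspecific(consensus, references,
                                  config$nonspecific_min_identity)
  if (any(!consensus$specific)) {
    warnings <- c(warnings,
                  paste0(sum(!consensus$specific), " nonspecific consensus(es) removed"))
  }

  genes <- list()
  specific <- consensus[consensus$specific, , drop = FALSE]
  for (i in seq_len(nrow(specific))) {
    if (is.null(ref_model)) break
    g <- tryCatch(
      map_gene_model(specific$bases[i], ref_model,
                     consensus_id = specific$cluster_id[i],
                     snap_window = config$snap_window),
      error = function(e) {
        warnings <<- c(warnings, paste0(specific$cluster_id[i], ": ",
                                        conditionMessage(e)))
        NULL
      }
    )
    if (is.null(g)) next
    g <- fix_homopolymer_frameshifts(g, ref_model)
    g <- validate_hallmarks(g, profile, config$expected_cys)
    if (!is.null(named_refs)) {
      g$paralog_label <- assign_paralog(g$bases, named_refs,
                                        config$assign_min_identity,
                                        config$assign_min_margin)
    }
    if (!g$in_frame) {
      warnings <- c(warnings, paste0(g$consensus_id, ": frame not restored"))
    }
    genes[[g$consensus_id]] <- g
  }
  new_report(sample_id, counts, scan, consensus, genes, warnings, config)
}

new_report <- function(sample_id, counts, scan, consensus, genes, warnings, config) {
  structure(
    list(sample_id = sample_id, counts = counts, scan = scan,
         chosen_c = if (!is.null(scan)) scan$chosen_c else NA_real_,
         discarded_cs = if (!is.null(scan)) scan$discarded_cs else numeric(0),
         n_supported = if (!is.null(scan)) scan$chosen$n_supported else 0L,
         consensus = consensus, genes = genes,
         warnings = warnings, config = config),
    class = "paraseek_report"
  )
}

#' @export
print.paraseek_report <- function(x, ...) {
  cat("<paraseek_report> sample ", x$sample_id, "\n", sep = "")
  cat("  reads in: ", x$counts$n_reads_in,
      "; amplicons extracted: ", x$counts$n_amplicons_extracted,
      "; after size/quality filter: ", x$counts$n_amplicons_filtered, "\n", sep = "")
  if (!is.null(x$scan)) {
    cat("  chosen c = ", format(x$chosen_c), " (", x$n_supported, " supported clusters",
        if (length(x$discarded_cs)) paste0("; discarded c: ",
                                           paste(format(x$discarded_cs), collapse = ", ")),
        ")\n", sep = "")
  }
  if (nrow(x$consensus) && "specific" %in% names(x$consensus)) {
    cat("  specific consensuses: ", sum(x$consensus$specific), "/",
        nrow(x$consensus), "\n", sep = "")
  }
  cat("  genes: ", length(x$genes), "\n", sep = "")
  for (g in x$genes) print(g)
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

gene_summary_row <- function(g) {
  hm <- g$hallmarks
  tibble::tibble(
    gene_id = g$consensus_id,
    length_start_stop = g$gene_span[2] - g$gene_span[1],
    paralog_label = g$paralog_label,
    n_cds = nrow(g$cds_exons),
    in_frame = g$in_frame,
    partial = g$partial,
    n_repairs = nrow(g$repaired),
    has_start = if (!is.null(hm)) hm$has_start else NA,
    has_stop = if (!is.null(hm)) hm$has_stop else NA,
    all_splice_canonical = if (!is.null(hm)) hm$all_splice_canonical else NA,
    n_conserved_cys = if (!is.null(hm)) hm$n_conserved_cys else NA_integer_,
    conserved_pro = if (!is.null(hm)) hm$conserved_pro else NA,
    protein_length = if (!is.null(hm)) hm$protein_length else NA_integer_,
    complete = if (!is.null(hm)) hm$complete else NA
  )
}

#' Write a sample report to disk
#'
#' Emits a nested JSON report plus flat TSVs (gene summary, per-threshold
#' scan table, consensus table) and FASTA/GFF3 for the annotated genes.
#'
#' @param report a [run_sample()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- tidy(report)
  readr::write_tsv(genes, file.path(dir, "genes.tsv"))
  if (!is.null(report$scan)) {
    readr::write_tsv(report$scan$grid, file.path(dir, "threshold_scan.tsv"))
  }
  if (nrow(report$consensus)) {
    readr::write_tsv(
      dplyr::select(report$consensus, -dplyr::any_of("quals")),
      file.path(dir, "consensus.tsv")
    )
    write_fasta(stats::setNames(report$consensus$bases, report$consensus$cluster_id),
                file.path(dir, "consensus.fasta"))
  }
  for (g in report$genes) {
    write_gene_gff3(g, file.path(dir, paste0(g$consensus_id, ".gff3")))
  }
  payload <- list(
    sample_id = report$sample_id,
    counts = as.list(report$counts),
    chosen_c = report$chosen_c,
    discarded_cs = report$discarded_cs,
    n_supported = report$n_supported,
    genes = genes,
    warnings = report$warnings
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
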