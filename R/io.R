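# Readers/writers for the pipeline's external formats. Parsing is delegated
# to Biostrings (FASTQ/FASTA), rtracklayer (GFF3) and readr (TSV); these
# wrappers convert to/from the package's tabular containers and add the
# validation the pipeline relies on.

#' Read a FASTQ file into a reads tibble
#'
#' Qualities are decoded from Phred+33 (the ONT output standard); gzipped
#' files are read transparently.
#'
#' @param path path to a FASTQ file (plain or gzip).
#' @param sample_id sample label attached to every read (default: file stem).
#' @return a tibble with columns `read_id`, `sample_id`, `bases` and `quals`
#'   (list-column of integer Phred scores, one per base).
#' @export
read_fastq <- function(path, sample_id = NULL) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  sample_id <- sample_id %||% sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  fastq_diagnose(path)  # structural validation (4-line records, seq/qual lengths)
  qs <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) abort(paste0("failed to parse FASTQ ", path, ": ",
                                     conditionMessage(e)))
  )
  if (length(qs) == 0L) {
    return(tibble::tibble(
      read_id = character(), sample_id = character(),
      bases = character(), quals = list()
    ))
  }
  quals <- suppressWarnings(
    lapply(as(Biostrings::quality(qs), "IntegerList"), as.integer)
  )
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(qs)),
    sample_id = sample_id,
    bases = unname(toupper(as.character(qs))),
    quals = unname(quals)
  )
}

# structural scan: 4-line records, '@'/'+' markers, matching seq/qual
# lengths; errors name the offending record, silent when clean
fastq_diagnose <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n_rec <- length(lines) %/% 4L
  if (length(lines) %% 4L != 0L) {
    abort(paste0("malformed FASTQ: truncated record ", n_rec + 1L, " in ", path))
  }
  for (k in seq_len(n_rec)) {
    block <- lines[(4L * (k - 1L) + 1L):(4L * k)]
    if (!startsWith(block[1], "@") || !startsWith(block[3], "+")) {
      abort(paste0("malformed FASTQ record ", k, " in ", path))
    }
    if (nchar(block[2]) != nchar(block[4])) {
      abort(paste0(
        "FASTQ record ", k, " (", sub("^@", "", sub("\\s.*$", "", block[1])),
        "): sequence length ", nchar(block[2]),
        " != quality length ", nchar(block[4])
      ))
    }
  }
  invisible(TRUE)
}

#' Write a reads tibble to FASTQ (Phred+33)
#'
#' @param reads tibble with `read_id`, `bases`, `quals` columns.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "bases", "quals") %in% names(reads)))
  bad <- which(nchar(reads$bases) != lengths(reads$quals))
  if (length(bad)) {
    abort(paste0("read ", reads$read_id[bad[1]], ": bases/quals length mismatch"))
  }
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$read_id
  q <- Biostrings::PhredQuality(IRanges::IntegerList(reads$quals))
  qs <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(x, q))
  Biostrings::writeQualityScaledXStringSet(qs, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read / write FASTA
#'
#' @param path file path.
#' @return `read_fasta()`: a tibble with columns `name` and `bases`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(name = sub("\\s.*$", "", names(x)),
                 bases = unname(toupper(as.character(x))))
}

#' @param seqs named character vector of sequences, or a tibble with
#'   `name` and `bases` columns.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- stats::setNames(seqs$bases, seqs$name)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Construct a primer pair
#'
#' The reverse primer is stored as the oligo sequence, 5'->3' on the opposite
#' strand (the way wet-lab primer tables are written); matching code
#' reverse-complements it.
#'
#' @param fwd,rev IUPAC DNA strings, length >= 10.
#' @param name primer set label.
#' @param max_mismatches substitution budget per primer site.
#' @return a one-row tibble with class `paraseek_primers`.
#' @export
primer_pair <- function(fwd, rev, name = "primer", max_mismatches = 3L) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  for (p in c(fwd = fwd, rev = rev)) {
    if (nchar(p) < 10L) abort("primers must be at least 10 bp")
    if (!is_iupac(p)) abort(paste0("non-IUPAC character in primer: ", p))
  }
  out <- tibble::tibble(
    name = name, fwd = fwd, rev = rev,
    max_mismatches = as.integer(max_mismatches)
  )
  class(out) <- c("paraseek_primers", class(out))
  out
}

#' Load a per-sample primer table
#'
#' Expects a TSV with header columns `sample_id`, `primer_name`, `fwd`,
#' `rev`, `max_mismatches`.
#'
#' @param path TSV file path.
#' @return tibble keyed by `sample_id`, one validated primer pair per sample.
#' @export
load_primer_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    primer_name = readr::col_character(),
    fwd = readr::col_character(),
    rev = readr::col_character(),
    max_mismatches = readr::col_integer()
  ))
  need <- c("sample_id", "primer_name", "fwd", "rev", "max_mismatches")
  if (!all(need %in% names(tbl))) {
    abort(paste0("primer table must have columns: ", paste(need, collapse = ", ")))
  }
  dup <- tbl$sample_id[duplicated(tbl$sample_id)]
  if (length(dup)) abort(paste0("duplicate sample_id in primer table: ", dup[1]))
  tbl$fwd <- toupper(tbl$fwd); tbl$rev <- toupper(tbl$rev)
  for (i in seq_len(nrow(tbl))) {
    pr <- primer_pair(tbl$fwd[i], tbl$rev[i], tbl$primer_name[i], tbl$max_mismatches[i])
    tbl$fwd[i] <- pr$fwd; tbl$rev[i] <- pr$rev
  }
  tbl
}

#' Fetch one sample's primer pair from a primer table
#'
#' Passes a [primer_pair()] through unchanged; selects the matching row of a
#' [load_primer_table()] result otherwise (the first row when `sample_id` is
#' `NULL`).
#'
#' @param primers a [primer_pair()] or primer table.
#' @param sample_id sample to select.
#' @return a [primer_pair()].
#' @export
sample_primers <- function(primers, sample_id = NULL) {
  if (inherits(primers, "paraseek_primers")) return(primers)
  if (!is.null(sample_id) && "sample_id" %in% names(primers)) {
    row <- primers[primers$sample_id == sample_id, , drop = FALSE]
    if (nrow(row) == 0L) abort(paste0("no primers for sample ", sample_id))
    return(primer_pair(row$fwd, row$rev, row$primer_name, row$max_mismatches))
  }
  primer_pair(primers$fwd[1], primers$rev[1],
              primers$primer_name[1] %||% "primer",
              primers$max_mismatches[1] %||% 3L)
}

#' Construct a gene model
#'
#' A gene model is a genomic sequence plus an ordered set of CDS exon
#' intervals in 0-based half-open coordinates on the forward strand. A model
#' whose concatenated CDS length is not divisible by 3 is flagged
#' (`in_frame = FALSE`) with a warning rather than rejected, since truncated
#' reference models occur in practice.
#'
#' @param gene_id gene identifier.
#' @param genomic_seq DNA string.
#' @param cds_exons tibble/data.frame with integer columns `start`, `end`
#'   (0-based, half-open), non-overlapping.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, genomic_seq, cds_exons) {
  genomic_seq <- toupper(genomic_seq)
  stopifnot(is.character(genomic_seq), length(genomic_seq) == 1L)
  cds_exons <- tibble::as_tibble(cds_exons[, c("start", "end")])
  cds_exons$start <- as.integer(cds_exons$start)
  cds_exons$end <- as.integer(cds_exons$end)
  cds_exons <- dplyr::arrange(cds_exons, .data$start)
  if (any(cds_exons$end <= cds_exons$start)) abort("empty or inverted CDS exon")
  if (nrow(cds_exons) > 1L &&
      any(cds_exons$start[-1L] < cds_exons$end[-nrow(cds_exons)])) {
    abort("overlapping CDS exons")
  }
  if (max(cds_exons$end) > nchar(genomic_seq)) abort("CDS exon beyond sequence end")
  cds_len <- sum(cds_exons$end - cds_exons$start)
  in_frame <- cds_len %% 3L == 0L
  if (!in_frame) {
    warn(paste0("gene ", gene_id, ": CDS length ", cds_len, " not divisible by 3"))
  }
  structure(
    list(gene_id = gene_id, genomic_seq = genomic_seq,
         cds_exons = cds_exons, in_frame = in_frame),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, ": ", nchar(x$genomic_seq), " bp, ",
      nrow(x$cds_exons), " CDS exons (",
      sum(x$cds_exons$end - x$cds_exons$start), " bp coding",
      if (!x$in_frame) ", OUT OF FRAME" else "", ")\n", sep = "")
  invisible(x)
}

# concatenated CDS of a gene model
model_cds <- function(model) {
  paste(substring(model$genomic_seq, model$cds_exons$start + 1L, model$cds_exons$end),
        collapse = "")
}

#' Load a gene model from FASTA + GFF3
#'
#' GFF3 coordinates (1-based, inclusive) are converted to the internal
#' 0-based half-open convention at this boundary. CDS features are matched to
#' `gene_id` through their `ID`, `Parent`, `gene_id` or `Name` attribute.
#'
#' @param fasta FASTA with the genomic sequence.
#' @param gff3 GFF3 with CDS features for `gene_id`.
#' @param gene_id gene to extract.
#' @return a [gene_model()].
#' @export
load_gene_model <- function(fasta, gff3, gene_id) {
  gr <- rtracklayer::import(gff3)
  md <- S4Vectors::mcols(gr)
  match_attr <- function(col) {
    if (!col %in% names(md)) return(rep(FALSE, length(gr)))
    v <- md[[col]]
    if (methods::is(v, "List")) {
      vapply(as.list(v), function(z) any(!is.na(z) & z == gene_id), logical(1))
    } else {
      !is.na(v) & v == gene_id
    }
  }
  hit <- match_attr("ID") | match_attr("Parent") | match_attr("gene_id") | match_attr("Name")
  cds <- gr[hit & !is.na(md$type) & md$type == "CDS"]
  if (length(cds) == 0L) abort(paste0("gene ", gene_id, " not found in ", gff3))
  fa <- read_fasta(fasta)
  seqid <- as.character(GenomicRanges::seqnames(cds))[1]
  seq_row <- fa[fa$name == seqid, , drop = FALSE]
  if (nrow(seq_row) == 0L) seq_row <- fa[1, , drop = FALSE]
  exons <- tibble::tibble(
    start = GenomicRanges::start(cds) - 1L,  # GFF3 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(cds)
  )
  gene_model(gene_id, seq_row$bases, exons)
}

#' Write a gene model (or annotated gene) as GFF3
#'
#' Internal 0-based half-open intervals are converted back to the GFF3
#' 1-based inclusive convention.
#'
#' @param model a [gene_model()] or `paraseek_gene`.
#' @param path output GFF3 path.
#' @param seqid sequence name for column 1 (default: the gene/consensus id).
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(model, path, seqid = NULL) {
  if (inherits(model, "paraseek_gene")) {
    gid <- model$consensus_id
    exons <- model$cds_exons
    span <- model$gene_span
  } else {
    gid <- model$gene_id
    exons <- model$cds_exons
    span <- c(min(exons$start), max(exons$end))
  }
  seqid <- seqid %||% gid
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(
      start = c(span[1], exons$start) + 1L,
      end = c(span[2], exons$end)
    ),
    strand = "+"
  )
  cds_len <- exons$end - exons$start
  phase <- (3L - c(0L, cumsum(cds_len)[-length(cds_len)]) %% 3L) %% 3L
  S4Vectors::mcols(gr)$source <- "paraseek"
  S4Vectors::mcols(gr)$type <- c("gene", rep("CDS", nrow(exons)))
  S4Vectors::mcols(gr)$ID <- c(gid, paste0(gid, ".cds", seq_len(nrow(exons))))
  S4Vectors::mcols(gr)$Parent <- c(NA_character_, rep(gid, nrow(exons)))
  S4Vectors::mcols(gr)$phase <- c(NA_integer_, phase)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
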