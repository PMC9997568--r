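# In-silico amplicon extraction: locate every primer-delimited amplicon on
# both strands of each read, keep the smallest amplicon above a length floor,
# and apply NanoFilt-style length/quality filters.

#' Mean read quality (NanoFilt convention)
#'
#' The mean quality of a read is defined on the error-probability scale:
#' \eqn{-10 \log_{10}(\mathrm{mean}_i\, 10^{-Q_i/10})}, not the arithmetic
#' mean of the Phred scores.
#'
#' @param quals integer vector of Phred scores.
#' @return mean quality (numeric scalar).
#' @export
mean_quality <- function(quals) {
  if (length(quals) == 0L) abort("mean_quality: empty quality vector")
  -10 * log10(mean(10^(-quals / 10)))
}

# all matches of an IUPAC primer on a read via Biostrings (primer degenerate,
# read literal). Substitution-only by default; with_indels allows indels in
# the primer site (edit budget = max_mismatches, mismatch counts then NA).
primer_matches <- function(primer, read_seq, max_mismatches, with_indels = FALSE) {
  subj <- Biostrings::DNAString(read_seq)
  pat <- Biostrings::DNAString(primer)
  m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatches,
                                with.indels = with_indels, fixed = "subject")
  if (length(m) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(), mismatches = integer()))
  }
  starts <- BiocGenerics::start(m)
  mm <- if (with_indels) {
    rep(NA_integer_, length(m))
  } else {
    as.integer(Biostrings::neditStartingAt(pat, subj, starting.at = starts,
                                           with.indels = FALSE, fixed = "subject"))
  }
  # 0-based half-open on the read
  tibble::tibble(start = starts - 1L, end = as.integer(BiocGenerics::end(m)),
                 mismatches = mm)
}

# hits on one oriented read sequence: every fwd match paired with every
# downstream (non-overlapping) reverse-complemented rev match
oriented_hits <- function(oriented_seq, primers, with_indels = FALSE) {
  fm <- primer_matches(primers$fwd, oriented_seq, primers$max_mismatches, with_indels)
  if (nrow(fm) == 0L) return(NULL)
  rm_ <- primer_matches(revcomp(primers$rev), oriented_seq,
                        primers$max_mismatches, with_indels)
  if (nrow(rm_) == 0L) return(NULL)
  pairs <- tidyr::expand_grid(f = seq_len(nrow(fm)), r = seq_len(nrow(rm_)))
  keep <- rm_$start[pairs$r] >= fm$end[pairs$f]
  if (!any(keep)) return(NULL)
  tibble::tibble(
    start = fm$start[pairs$f][keep],
    end = rm_$end[pairs$r][keep],  # inclusive of both primer sites
    fwd_mismatches = fm$mismatches[pairs$f][keep],
    rev_mismatches = rm_$mismatches[pairs$r][keep]
  )
}

#' Find all primer-delimited amplicons in reads
#'
#' Scans both strands with substitution-only IUPAC-degenerate primer matching
#' (per-primer mismatch budget, no indels inside a primer site). Every
#' forward-primer match paired with a downstream reverse-primer match is
#' reported; coordinates are 0-based half-open on the oriented read (the read
#' as given for `+` hits, its reverse complement for `-` hits) and the
#' amplicon span includes both primer sites.
#'
#' @param reads tibble of reads (see [read_fastq()]), or a one-row tibble.
#' @param primers a [primer_pair()] (or a primer-table row).
#' @param with_indels allow indels inside primer sites (edit budget =
#'   `max_mismatches`); off by default, matching substitution-only in-silico
#'   PCR behaviour.
#' @return tibble of hits: `read_id`, `strand`, `start`, `end`, `length`,
#'   `fwd_mismatches`, `rev_mismatches`, sorted by ascending length within
#'   each read.
#' @export
find_amplicons <- function(reads, primers, with_indels = FALSE) {
  primers <- sample_primers(primers)
  min_len <- nchar(primers$fwd) + nchar(primers$rev)
  out <- purrr::map(seq_len(nrow(reads)), function(i) {
    seq_i <- reads$bases[i]
    if (nchar(seq_i) < min_len) return(NULL)
    res <- list()
    plus <- oriented_hits(seq_i, primers, with_indels)
    if (!is.null(plus)) res$p <- dplyr::mutate(plus, strand = "+")
    minus <- oriented_hits(revcomp(seq_i), primers, with_indels)
    if (!is.null(minus)) res$m <- dplyr::mutate(minus, strand = "-")
    if (length(res) == 0L) return(NULL)
    hits <- dplyr::bind_rows(res)
    hits$read_id <- reads$read_id[i]
    hits$length <- hits$end - hits$start
    dplyr::arrange(hits, .data$length, .data$strand == "-", .data$start)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      read_id = character(), strand = character(), start = integer(),
      end = integer(), length = integer(),
      fwd_mismatches = integer(), rev_mismatches = integer()
    ))
  }
  dplyr::select(out, "read_id", "strand", "start", "end", "length",
                "fwd_mismatches", "rev_mismatches")
}

#' Extract the target amplicon of each read
#'
#' Among a read's amplicon hits strictly longer than `min_len`, the smallest
#' is extracted (the smallest-qualifying rule suppresses concatemer and
#' chimera-spanning hits). Ties are broken toward the `+` orientation, then
#' the leftmost start. Bases and qualities are oriented so the forward primer
#' is at the 5' end.
#'
#' @param hits tibble from [find_amplicons()].
#' @param reads the reads tibble the hits were computed from.
#' @param min_len strict lower length bound (default 1000).
#' @return amplicons tibble: `read_id`, `bases`, `quals`, `length`, `mean_q`,
#'   `strand`; zero rows when no read has a qualifying hit.
#' @export
extract_target_amplicon <- function(hits, reads, min_len = 1000L) {
  qual <- hits[hits$length > min_len, , drop = FALSE]
  if (nrow(qual) == 0L) return(empty_amplicons())
  pick <- qual |>
    dplyr::group_by(.data$read_id) |>
    dplyr::arrange(.data$length, .data$strand == "-", .data$start, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  idx <- match(pick$read_id, reads$read_id)
  if (anyNA(idx)) abort("hits refer to read_ids absent from `reads`")
  rows <- purrr::map(seq_len(nrow(pick)), function(k) {
    i <- idx[k]
    n <- nchar(reads$bases[i])
    q <- reads$quals[[i]]
    if (pick$strand[k] == "+") {
      b <- substr(reads$bases[i], pick$start[k] + 1L, pick$end[k])
      qq <- q[(pick$start[k] + 1L):pick$end[k]]
    } else {
      # coordinates live on the reverse-complemented read
      b <- substr(revcomp(reads$bases[i]), pick$start[k] + 1L, pick$end[k])
      qq <- rev(q)[(pick$start[k] + 1L):pick$end[k]]
    }
    tibble::tibble(
      read_id = pick$read_id[k], bases = b, quals = list(as.integer(qq)),
      length = nchar(b), mean_q = mean_quality(qq), strand = pick$strand[k]
    )
  })
  # preserve input read order
  out <- dplyr::bind_rows(rows)
  out[order(match(out$read_id, reads$read_id)), , drop = FALSE]
}

empty_amplicons <- function() {
  tibble::tibble(
    read_id = character(), bases = character(), quals = list(),
    length = integer(), mean_q = numeric(), strand = character()
  )
}

#' Extract amplicons from reads in one step
#'
#' Convenience wrapper: [find_amplicons()] then [extract_target_amplicon()].
#'
#' @inheritParams find_amplicons
#' @inheritParams extract_target_amplicon
#' @export
extract_amplicons <- function(reads, primers, min_len = 1000L, with_indels = FALSE) {
  extract_target_amplicon(find_amplicons(reads, primers, with_indels), reads, min_len)
}

#' Length and quality filtering of extracted amplicons
#'
#' Keeps amplicons with `min_len <= length <= max_len` (inclusive range) and
#' mean quality strictly greater than `min_q`; input order is preserved.
#'
#' @param amplicons amplicons tibble.
#' @param min_len,max_len inclusive size window (defaults 1200-2400 bp).
#' @param min_q strict mean-quality floor (default 14).
#' @export
filter_amplicons <- function(amplicons, min_len = 1200L, max_len = 2400L, min_q = 14) {
  amplicons[amplicons$length >= min_len & amplicons$length <= max_len &
              amplicons$mean_q > min_q, , drop = FALSE]
}

#' Mean-quality prefilter on whole reads
#'
#' Keeps reads with mean quality strictly greater than `min_q` (the
#' basecaller-level pass filter; optional when input reads are already
#' filtered upstream).
#'
#' @param reads reads tibble.
#' @param min_q strict floor (default 7).
#' @export
prefilter_reads <- function(reads, min_q = 7) {
  if (nrow(reads) == 0L) return(reads)
  keep <- vapply(reads$quals, function(q) mean_quality(q) > min_q, logical(1))
  reads[keep, , drop = FALSE]
}
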