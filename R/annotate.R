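# Reference-guided annotation: project a reference gene model onto each
# specific consensus through a global alignment, repair homopolymer-induced
# frameshifts inside CDS exons, translate, and validate gene hallmarks.

# per-reference-position map onto consensus coordinates.
# Returns list(cpos = integer vector, one entry per ref position (0-based
# consensus index of the aligned base, NA where the consensus has a gap),
# identity = alignment identity).
alignment_map <- function(ref_seq, consensus) {
  al <- cpp_align_strings(ref_seq, consensus)
  ra <- strsplit(al[1], "", fixed = TRUE)[[1]]
  ca <- strsplit(al[2], "", fixed = TRUE)[[1]]
  rpos <- cumsum(ra != "-")
  cpos <- cumsum(ca != "-")
  keep <- ra != "-"
  m <- sum(keep)
  out <- rep(NA_integer_, m)
  aligned <- keep & ca != "-"
  out[rpos[aligned]] <- cpos[aligned] - 1L
  matches <- sum(ra == ca & keep & ca != "-")
  list(cpos = out, identity = min(1, matches / min(length(out), sum(ca != "-"))))
}

# project a 0-based half-open reference interval onto the consensus;
# returns c(start, end, n_aligned) or NULL when nothing aligns
project_interval <- function(map, s, e) {
  idx <- (s + 1L):e
  hit <- map$cpos[idx]
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0L) return(NULL)
  c(min(hit), max(hit) + 1L, length(hit))
}

# snap a projected exon boundary to the nearest canonical splice dinucleotide
# within +/- window bp; kind is "donor" (GT after exon end) or "acceptor"
# (AG before exon start). Returns the (possibly unchanged) boundary.
snap_boundary <- function(consensus, pos, kind, window = 6L) {
  n <- nchar(consensus)
  motif_ok <- function(p) {
    if (kind == "donor") {
      p + 2L <= n && substr(consensus, p + 1L, p + 2L) == "GT"
    } else {
      p - 2L >= 0L && substr(consensus, p - 1L, p) == "AG"
    }
  }
  if (motif_ok(pos)) return(pos)
  offsets <- setdiff(seq(-window, window), 0L)
  offsets <- offsets[order(abs(offsets), offsets)]
  for (d in offsets) {
    p <- pos + d
    if (p >= 1L && p <= n - 1L && motif_ok(p)) return(p)
  }
  pos
}

#' Project a reference gene model onto a consensus sequence
#'
#' Globally aligns the consensus to the reference genomic sequence and lifts
#' each reference CDS exon through the alignment onto consensus coordinates.
#' Projected exon boundaries that break the canonical GT..AG intron motif are
#' snapped to the nearest canonical dinucleotide within `snap_window` bp.
#' The gene is flagged `partial` when some (but at least `min(4, n)`) of the
#' reference exons project.
#'
#' @param consensus consensus DNA string, or a one-row consensus tibble.
#' @param ref a [gene_model()].
#' @param consensus_id label for the annotated gene.
#' @param min_map_identity alignment identity below which the reference is
#'   rejected as too distant (default 0.5).
#' @param snap_window splice-snapping window in bp (default 6).
#' @return an object of class `paraseek_gene` (unrepaired; see
#'   [fix_homopolymer_frameshifts()]).
#' @export
map_gene_model <- function(consensus, ref, consensus_id = NULL,
                           min_map_identity = 0.5, snap_window = 6L) {
  if (is.data.frame(consensus)) {
    consensus_id <- consensus_id %||% consensus$cluster_id[1]
    consensus <- consensus$bases[1]
  }
  consensus_id <- consensus_id %||% "consensus"
  map <- alignment_map(ref$genomic_seq, consensus)
  if (map$identity < min_map_identity) {
    abort(paste0("reference too distant (identity ",
                 format(round(map$identity, 3)), " < ", min_map_identity,
                 ") for ", consensus_id))
  }
  n_ref <- nrow(ref$cds_exons)
  proj <- purrr::map(seq_len(n_ref), function(k) {
    project_interval(map, ref$cds_exons$start[k], ref$cds_exons$end[k])
  })
  # an exon counts as mapped when at least half its reference bases align
  ref_len <- ref$cds_exons$end - ref$cds_exons$start
  mapped <- vapply(seq_len(n_ref), function(k) {
    !is.null(proj[[k]]) && proj[[k]][3] >= 0.5 * ref_len[k]
  }, logical(1))
  if (sum(mapped) < min(4L, n_ref)) {
    abort(paste0("only ", sum(mapped), "/", n_ref, " CDS exons of ",
                 ref$gene_id, " project onto ", consensus_id))
  }
  exons <- tibble::tibble(
    start = vapply(proj[mapped], `[`, integer(1), 1L),
    end = vapply(proj[mapped], `[`, integer(1), 2L)
  )
  n_ex <- nrow(exons)
  if (n_ex > 1L) {
    for (k in seq_len(n_ex - 1L)) {
      exons$end[k] <- snap_boundary(consensus, exons$end[k], "donor", snap_window)
      exons$start[k + 1L] <- snap_boundary(consensus, exons$start[k + 1L],
                                           "acceptor", snap_window)
    }
  }
  new_paraseek_gene(consensus_id, consensus, exons,
                    partial = !all(mapped), ref = ref,
                    map_identity = map$identity)
}

new_paraseek_gene <- function(consensus_id, bases, cds_exons, partial, ref,
                              map_identity, repaired = NULL) {
  cds <- paste(substring(bases, cds_exons$start + 1L, cds_exons$end), collapse = "")
  protein <- translate_dna(cds)
  structure(
    list(
      consensus_id = consensus_id,
      bases = bases,
      gene_span = c(min(cds_exons$start), max(cds_exons$end)),
      cds_exons = cds_exons,
      repaired = repaired %||% tibble::tibble(
        position = integer(), base = character(),
        from_len = integer(), to_len = integer()
      ),
      protein = protein,
      in_frame = (nchar(cds) %% 3L == 0L) && !has_internal_stop(protein),
      partial = partial,
      ref_gene_id = ref$gene_id,
      map_identity = map_identity,
      hallmarks = NULL,
      paralog_label = "unassigned"
    ),
    class = "paraseek_gene"
  )
}

#' @export
print.paraseek_gene <- function(x, ...) {
  cat("<paraseek_gene> ", x$consensus_id, ": span ",
      x$gene_span[2] - x$gene_span[1], " bp, ", nrow(x$cds_exons), " CDS exons, ",
      "protein ", nchar(sub("\\*$", "", x$protein)), " aa",
      if (!x$in_frame) " [FRAME BROKEN]",
      if (x$partial) " [partial]",
      if (nrow(x$repaired)) paste0(" [", nrow(x$repaired), " homopolymer repairs]"),
      "; paralog: ", x$paralog_label, "\n", sep = "")
  invisible(x)
}

# homopolymer runs (length >= min_len) in the reference lying fully inside a
# reference CDS exon
ref_cds_runs <- function(ref, min_len = 3L) {
  chars <- strsplit(ref$genomic_seq, "", fixed = TRUE)[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$lengths >= min_len
  runs <- tibble::tibble(start = starts[keep], end = ends[keep],
                         base = r$values[keep], len = r$lengths[keep])
  inside <- vapply(seq_len(nrow(runs)), function(i) {
    any(runs$start[i] >= ref$cds_exons$start & runs$end[i] <= ref$cds_exons$end)
  }, logical(1))
  runs[inside, , drop = FALSE]
}

# apply run-length edits (right-to-left) to a consensus + exon set
apply_run_edits <- function(bases, exons, edits) {
  edits <- edits[order(-edits$pos), , drop = FALSE]
  for (i in seq_len(nrow(edits))) {
    ps <- edits$pos[i]; pe <- ps + edits$from_len[i]
    delta <- edits$to_len[i] - edits$from_len[i]
    bases <- paste0(
      substr(bases, 1L, ps),
      strrep(edits$base[i], edits$to_len[i]),
      substr(bases, pe + 1L, nchar(bases))
    )
    shift <- function(x) {
      ifelse(x >= pe, x + delta,
             ifelse(x > ps, ps + pmin(x - ps, edits$to_len[i]), x))
    }
    exons$start <- shift(exons$start)
    exons$end <- shift(exons$end)
  }
  list(bases = bases, exons = exons)
}

#' Repair homopolymer-induced frameshifts in CDS exons
#'
#' When the concatenated CDS length is not a multiple of 3 or the translation
#' hits a premature stop, homopolymer runs (length >= 3 in the reference)
#' inside CDS exons where the consensus run length differs from the reference
#' are candidate repair sites. The minimal set of run-length restorations
#' (consensus run reset to the reference run length) that restores the frame
#' and removes the premature stop is applied and recorded; if no combination
#' succeeds the gene is left unrepaired and flagged. In-frame genes are
#' returned unchanged — a run-length difference that does not break the frame
#' is treated as a genuine difference, not an error.
#'
#' @param gene a `paraseek_gene` from [map_gene_model()].
#' @param ref the [gene_model()] used for mapping.
#' @param max_combo largest number of simultaneous run edits tried (default 4).
#' @return the (possibly repaired) `paraseek_gene`; repairs are listed in
#'   `$repaired` and `$in_frame` reports the outcome.
#' @export
fix_homopolymer_frameshifts <- function(gene, ref, max_combo = 4L) {
  if (gene$in_frame) return(gene)
  runs <- ref_cds_runs(ref)
  if (nrow(runs) == 0L) return(gene)
  map <- alignment_map(ref$genomic_seq, gene$bases)
  n <- nchar(gene$bases)
  chars <- strsplit(gene$bases, "", fixed = TRUE)[[1]]

  cand <- purrr::map(seq_len(nrow(runs)), function(i) {
    pr <- project_interval(map, runs$start[i], runs$end[i])
    if (is.null(pr)) pr <- c(NA_integer_, NA_integer_)
    wlo <- max(0L, (if (is.na(pr[1])) runs$start[i] else pr[1]) - 1L)
    whi <- min(n, (if (is.na(pr[2])) runs$end[i] else pr[2]) + 1L)
    if (whi <= wlo) return(NULL)
    win <- chars[(wlo + 1L):whi]
    rw <- rle(win)
    we <- cumsum(rw$lengths); ws <- we - rw$lengths
    hit <- which(rw$values == runs$base[i])
    if (length(hit) == 0L) {
      # run absent from consensus: insert at the projected start
      pos <- if (is.na(pr[1])) wlo else pr[1]
      return(tibble::tibble(pos = pos, base = runs$base[i],
                            from_len = 0L, to_len = runs$len[i]))
    }
    hit <- hit[which.max(rw$lengths[hit])]
    from_len <- rw$lengths[hit]
    if (from_len == runs$len[i]) return(NULL)
    tibble::tibble(pos = wlo + ws[hit], base = runs$base[i],
                   from_len = from_len, to_len = runs$len[i])
  })
  cand <- dplyr::bind_rows(cand)
  if (nrow(cand) == 0L) return(gene)
  cand <- dplyr::distinct(dplyr::arrange(cand, .data$pos))

  ok <- function(bases, exons) {
    cds <- paste(substring(bases, exons$start + 1L, exons$end), collapse = "")
    nchar(cds) %% 3L == 0L && !has_internal_stop(translate_dna(cds))
  }
  for (size in seq_len(min(nrow(cand), max_combo))) {
    combos <- utils::combn(nrow(cand), size, simplify = FALSE)
    for (sel in combos) {
      edited <- apply_run_edits(gene$bases, gene$cds_exons, cand[sel, , drop = FALSE])
      if (ok(edited$bases, edited$exons)) {
        return(new_paraseek_gene(
          gene$consensus_id, edited$bases, edited$exons,
          partial = gene$partial,
          ref = list(gene_id = gene$ref_gene_id),
          map_identity = gene$map_identity,
          repaired = cand[sel, , drop = FALSE]
        ))
      }
    }
  }
  gene # no combination restores the frame; flagged via in_frame = FALSE
}

#' Build a conserved-site profile from a reference gene model
#'
#' Conserved residues (the cysteines and proline diagnostic of the ependymin
#' family) are defined positionally on the reference protein and checked in
#' annotated genes through a protein-level alignment.
#'
#' @param ref a [gene_model()].
#' @param cys_positions 1-based positions of the conserved cysteines on the
#'   reference protein.
#' @param pro_position 1-based position of the conserved proline.
#' @return a profile list used by [validate_hallmarks()].
#' @export
conserved_profile <- function(ref, cys_positions, pro_position) {
  protein <- translate_dna(model_cds(ref))
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  if (!all(aa[cys_positions] == "C")) {
    abort("reference protein lacks C at a stated conserved cysteine position")
  }
  if (aa[pro_position] != "P") {
    abort("reference protein lacks P at the stated conserved proline position")
  }
  list(ref_protein = protein, cys_positions = as.integer(cys_positions),
       pro_position = as.integer(pro_position))
}

#' Validate gene hallmarks of an annotated consensus
#'
#' Checks the structural evidence that a consensus encodes a functional gene:
#' ATG at the gene start, a stop codon at the gene end, canonical GT..AG
#' dinucleotides at every intron, the expected conserved cysteines and
#' proline (at reference-aligned positions from a [conserved_profile()]),
#' and the protein length.
#'
#' @param gene a `paraseek_gene` (repaired or flagged).
#' @param profile optional [conserved_profile()]; without it the conserved
#'   residue checks are `NA`.
#' @param expected_cys number of conserved cysteines expected (default 4).
#' @return the gene, with `$hallmarks` set to a one-row tibble: `has_start`,
#'   `has_stop`, `n_cds`, `splice_canonical` (list-column, one flag per
#'   intron), `all_splice_canonical`, `n_conserved_cys`, `conserved_pro`,
#'   `protein_length`, `complete`.
#' @export
validate_hallmarks <- function(gene, profile = NULL, expected_cys = 4L) {
  b <- gene$bases
  s <- gene$gene_span[1]; e <- gene$gene_span[2]
  has_start <- substr(b, s + 1L, s + 3L) == "ATG"
  has_stop <- substr(b, e - 2L, e) %in% STOP_CODONS
  ex <- gene$cds_exons
  n_intron <- nrow(ex) - 1L
  splice <- logical(0)
  if (n_intron > 0L) {
    splice <- vapply(seq_len(n_intron), function(k) {
      substr(b, ex$end[k] + 1L, ex$end[k] + 2L) == "GT" &&
        substr(b, ex$start[k + 1L] - 1L, ex$start[k + 1L]) == "AG"
    }, logical(1))
  }
  prot <- sub("\\*$", "", gene$protein)
  n_cys <- NA_integer_; pro <- NA
  if (!is.null(profile)) {
    pal <- cpp_align_strings(sub("\\*$", "", profile$ref_protein), prot)
    ra <- strsplit(pal[1], "", fixed = TRUE)[[1]]
    ga <- strsplit(pal[2], "", fixed = TRUE)[[1]]
    rpos <- cumsum(ra != "-")
    residue_at <- function(p) {
      k <- which(rpos == p & ra != "-")
      if (length(k) == 0L) return(NA_character_)
      ga[k[1]]
    }
    n_cys <- sum(vapply(profile$cys_positions, residue_at, character(1)) == "C",
                 na.rm = TRUE)
    pro <- identical(residue_at(profile$pro_position), "P")
  }
  gene$hallmarks <- tibble::tibble(
    has_start = has_start, has_stop = has_stop, n_cds = nrow(ex),
    splice_canonical = list(splice),
    all_splice_canonical = all(splice),
    n_conserved_cys = n_cys, conserved_pro = pro,
    protein_length = nchar(prot),
    complete = has_start && has_stop && all(splice) && gene$in_frame &&
      (is.na(n_cys) || n_cys == expected_cys) && (is.na(pro) || pro)
  )
  gene
}

#' Assign a consensus to a named paralog
#'
#' Best-identity assignment with a margin rule: the argmax reference label is
#' returned when the best identity reaches `min_identity` and exceeds the
#' runner-up by at least `min_margin`; otherwise `"unassigned"` (identity
#' floor failed) or `"ambiguous"` (margin failed).
#'
#' @param consensus consensus DNA string (or one-row consensus tibble).
#' @param named_refs named character vector of paralog reference sequences.
#' @param min_identity assignment floor (default 0.97).
#' @param min_margin required lead over the second-best reference (default 0.005).
#' @return the paralog label, `"unassigned"`, or `"ambiguous"`.
#' @export
assign_paralog <- function(consensus, named_refs, min_identity = 0.97,
                           min_margin = 0.005) {
  if (is.data.frame(consensus)) consensus <- consensus$bases[1]
  if (is.data.frame(named_refs)) {
    named_refs <- stats::setNames(named_refs$bases, named_refs$name)
  }
  if (length(named_refs) == 0L) abort("assign_paralog: empty reference list")
  ids <- vapply(named_refs, function(r) pairwise_identity(consensus, r), numeric(1))
  ord <- order(-ids)
  best <- ids[ord[1]]
  if (best < min_identity) return("unassigned")
  if (length(ids) > 1L && best - ids[ord[2]] < min_margin) return("ambiguous")
  names(named_refs)[ord[1]]
}
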