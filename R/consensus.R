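# Per-cluster consensus polishing: members are aligned to a template (the
# longest member, then the evolving consensus) and voted per column, which
# replaces a neural polisher with a transparent, deterministic majority rule.

#' Build a polished consensus from cluster members
#'
#' Round 1 star-aligns every member against the longest member and takes the
#' per-column majority base (gap-majority columns are deleted; insertions
#' supported by more than half of the members are added); later rounds
#' realign members to the previous consensus and re-vote. Ties are broken
#' toward the current template (the representative in round 1). The result is
#' deterministic given the member order.
#'
#' @param members amplicons tibble (needs `bases`) or character vector.
#' @param rounds voting/realignment rounds (default 2).
#' @param seed accepted for interface stability; the procedure is
#'   deterministic and draws no random numbers.
#' @param max_members at most this many members, longest first, feed the
#'   consensus (default 100; bounds runtime on very deep clusters).
#' @param cluster_id label carried into the output.
#' @return a one-row tibble: `cluster_id`, `bases`, `n_support`,
#'   `mean_member_identity`, `specific`, `closest_reference`,
#'   `closest_identity`.
#' @export
build_consensus <- function(members, rounds = 2L, seed = 1L,
                            max_members = 100L, cluster_id = "cluster") {
  seqs <- if (is.character(members)) members else members$bases
  if (length(seqs) == 0L) abort("build_consensus: no members")
  ord <- order(-nchar(seqs))
  used <- seqs[ord][seq_len(min(length(seqs), max_members))]
  template <- used[1]
  if (length(used) > 1L) {
    for (r in seq_len(rounds)) {
      template <- vote_consensus(template, used)
    }
  }
  mmi <- mean(vapply(used, function(s) pairwise_identity(s, template), numeric(1)))
  tibble::tibble(
    cluster_id = cluster_id, bases = template,
    n_support = length(seqs), mean_member_identity = mmi,
    specific = NA, closest_reference = NA_character_,
    closest_identity = NA_real_
  )
}

# one round of star alignment against `template` + per-column majority vote
vote_consensus <- function(template, members) {
  tchars <- strsplit(template, "", fixed = TRUE)[[1]]
  L <- length(tchars)
  nm <- length(members)
  votes <- matrix("-", nrow = L, ncol = nm)
  ins <- vector("list", nm)
  for (m in seq_len(nm)) {
    al <- cpp_align_strings(template, members[m])
    ta <- strsplit(al[1], "", fixed = TRUE)[[1]]
    ma <- strsplit(al[2], "", fixed = TRUE)[[1]]
    tgap <- ta == "-"
    tpos <- cumsum(!tgap)
    votes[tpos[!tgap], m] <- ma[!tgap]
    if (any(tgap)) {
      r <- rle(tgap)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      gi <- which(r$values)
      ins[[m]] <- tibble::tibble(
        pos = ifelse(starts[gi] == 1L, 0L, tpos[starts[gi] - 1L]),
        str = vapply(gi, function(g) paste(ma[starts[g]:ends[g]], collapse = ""),
                     character(1))
      )
    }
  }

  # column majority; ties keep the template base
  alphabet <- c("A", "C", "G", "T", "N", "-")
  counts <- vapply(alphabet, function(ch) rowSums(votes == ch), numeric(L))
  if (L == 1L) counts <- matrix(counts, nrow = 1L, dimnames = list(NULL, alphabet))
  best <- apply(counts, 1L, max)
  winner <- character(L)
  for (i in seq_len(L)) {
    w <- alphabet[counts[i, ] == best[i]]
    winner[i] <- if (tchars[i] %in% w) tchars[i] else w[1]
  }

  # insertions supported by a strict majority of members
  ins_tbl <- dplyr::bind_rows(ins)
  ins_at <- rep("", L + 1L) # slot p = insertion after template position p
  if (!is.null(ins_tbl) && nrow(ins_tbl)) {
    by_pos <- split(ins_tbl$str, ins_tbl$pos)
    for (p in names(by_pos)) {
      strs <- by_pos[[p]]
      if (length(strs) > nm / 2) {
        tab <- sort(table(strs), decreasing = TRUE)
        top <- names(tab)[tab == tab[1]]
        ins_at[as.integer(p) + 1L] <- sort(top)[1]
      }
    }
  }

  keep <- winner != "-"
  pieces <- character(2L * L + 1L)
  pieces[seq(1L, 2L * L + 1L, by = 2L)] <- ins_at
  pieces[seq(2L, 2L * L, by = 2L)] <- ifelse(keep, winner, "")
  paste(pieces, collapse = "")
}

#' Screen consensuses against reference genes
#'
#' Operationalizes the manual curation step that removes nonspecific
#' amplicons: a consensus is specific when its best identity to any reference
#' gene sequence reaches `min_identity` (inclusive). Nonspecific consensuses
#' are retained in reports but excluded from annotation.
#'
#' @param consensus consensus tibble from [build_consensus()] (one or more rows).
#' @param references named character vector of reference gene sequences, or a
#'   tibble with `name` and `bases`.
#' @param min_identity specificity floor (default 0.80, inclusive).
#' @return the consensus tibble with `specific`, `closest_reference` and
#'   `closest_identity` filled in.
#' @export
screen_nonspecific <- function(consensus, references, min_identity = 0.80) {
  if (is.data.frame(references)) {
    references <- stats::setNames(references$bases, references$name)
  }
  if (length(references) == 0L) abort("screen_nonspecific: empty reference set")
  if (is.null(names(references))) {
    names(references) <- paste0("ref", seq_along(references))
  }
  ids <- vapply(consensus$bases, function(b) {
    vapply(references, function(r) pairwise_identity(b, r), numeric(1))
  }, numeric(length(references)))
  ids <- matrix(ids, nrow = length(references))
  best <- apply(ids, 2L, which.max)
  consensus$closest_reference <- names(references)[best]
  consensus$closest_identity <- ids[cbind(best, seq_len(ncol(ids)))]
  consensus$specific <- consensus$closest_identity >= min_identity
  consensus
}
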