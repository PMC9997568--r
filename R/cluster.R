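# Greedy identity-threshold clustering of amplicons and the automatic
# selection of the identity threshold c, including the overclustering guard
# that collapses clusters whose consensuses are nearly identical.

#' Pairwise sequence identity (cd-hit convention)
#'
#' Identity is the number of matched columns of a global minimum-edit
#' alignment (unit costs; ties resolved toward more matches) divided by the
#' length of the shorter sequence, capped at 1. This is the definition behind
#' cd-hit's identity threshold, computed exactly by alignment rather than by
#' the word heuristic.
#'
#' @param a,b DNA strings (any non-empty character strings are accepted).
#' @return identity in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) abort("pairwise_identity: empty sequence")
  st <- cpp_align_stats(a, b, -1L)
  min(1, st[2] / min(nchar(a), nchar(b)))
}

# banded threshold test: exact identity when >= c, NA when provably < c.
# If identity >= c the optimal alignment has at most 2m(1-c) + |na-nb| edits
# and therefore never leaves that diagonal band, so the banded DP is exact;
# band overflow proves identity < c.
identity_at_least <- function(a, b, c) {
  na <- nchar(a); nb <- nchar(b); m <- min(na, nb)
  band <- as.integer(ceiling(2 * m * (1 - c)) + abs(na - nb) + 2L)
  if (band >= max(na, nb)) band <- -1L
  st <- cpp_align_stats(a, b, band)
  if (st[1] < 0L) return(NA_real_)
  id <- min(1, st[2] / m)
  if (id >= c) id else NA_real_
}

#' Count supported cluster sizes
#'
#' A cluster is supported when it contains strictly more than 10% (the
#' `support` fraction) of the sample's amplicons.
#'
#' @param sizes integer vector of cluster sizes.
#' @param total total amplicon count (`sum(sizes)`).
#' @param support support fraction (default 0.10).
#' @return number of supported clusters.
#' @export
supported_count <- function(sizes, total, support = 0.10) {
  if (total == 0L) return(0L)
  stopifnot(sum(sizes) == total)
  sum(sizes > total * support)
}

#' Greedy incremental clustering at an identity threshold
#'
#' Amplicons are sorted by length, longest first (ties keep input order);
#' the first seeds a cluster, and each subsequent amplicon joins the first
#' existing cluster whose representative (its longest member, i.e. the seed)
#' has identity `>= c`, otherwise seeds a new cluster — the greedy scheme of
#' cd-hit, with the identity computed exactly.
#'
#' @param amplicons amplicons tibble (needs a `bases` column), or a character
#'   vector of sequences.
#' @param c identity threshold in `(0, 1]`.
#' @param support supported-cluster fraction (default 0.10).
#' @return an object of class `paraseek_clustering`: threshold `c`, a
#'   `clusters` tibble (`cluster`, `representative`, `size`, `supported`,
#'   `members` list of input indices), `n_supported`, `n_classified`,
#'   `n_total`.
#' @export
greedy_cluster <- function(amplicons, c, support = 0.10) {
  stopifnot(c > 0, c <= 1)
  seqs <- if (is.character(amplicons)) amplicons else amplicons$bases
  n <- length(seqs)
  if (n == 0L) {
    return(new_clustering(c, tibble::tibble(
      cluster = integer(), representative = integer(), size = integer(),
      supported = logical(), members = list()
    ), 0L, support))
  }
  ord <- order(-nchar(seqs))  # stable: ties keep input order
  rep_idx <- integer(0)
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(rep_idx)) {
      if (!is.na(identity_at_least(seqs[i], seqs[rep_idx[k]], c))) {
        members[[k]] <- c(members[[k]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      members[[length(rep_idx)]] <- i
    }
  }
  clusters <- tibble::tibble(
    cluster = seq_along(rep_idx),
    representative = rep_idx,
    size = lengths(members),
    members = members
  )
  new_clustering(c, clusters, n, support)
}

new_clustering <- function(c, clusters, n_total, support) {
  clusters$supported <- clusters$size > n_total * support
  n_supported <- sum(clusters$supported)
  structure(
    list(c = c, clusters = clusters,
         n_supported = as.integer(n_supported),
         n_classified = as.integer(sum(clusters$size[clusters$supported])),
         n_total = as.integer(n_total), support = support),
    class = "paraseek_clustering"
  )
}

#' @export
print.paraseek_clustering <- function(x, ...) {
  cat("<paraseek_clustering> c = ", format(x$c), ": ", nrow(x$clusters),
      " clusters over ", x$n_total, " amplicons; ", x$n_supported,
      " supported (", x$n_classified, " amplicons classified)\n", sep = "")
  invisible(x)
}

#' Select the identity threshold from a grid of clusterings
#'
#' Applies the three-tier rule: (1) the largest number of supported clusters;
#' (2) among ties, the largest number of amplicons classified into supported
#' clusters; (3) among remaining ties, the largest `c`.
#'
#' @param results list of `paraseek_clustering` objects, or a data frame with
#'   columns `c`, `n_supported`, `n_classified`.
#' @return the chosen `c` value.
#' @export
select_threshold <- function(results) {
  tbl <- scan_table(results)
  if (nrow(tbl) == 0L) abort("select_threshold: no results")
  best <- tbl[tbl$n_supported == max(tbl$n_supported), , drop = FALSE]
  best <- best[best$n_classified == max(best$n_classified), , drop = FALSE]
  max(best$c)
}

scan_table <- function(results) {
  if (is.data.frame(results)) return(tibble::as_tibble(results))
  dplyr::bind_rows(lapply(results, function(r) {
    tibble::tibble(c = r$c, n_supported = r$n_supported,
                   n_classified = r$n_classified,
                   n_clusters = nrow(r$clusters))
  }))
}

#' Detect overclustering among cluster consensuses
#'
#' Flags every unordered pair of consensus sequences whose pairwise identity
#' is strictly greater than `limit` — the signature of one gene's amplicons
#' split across clusters.
#'
#' @param consensuses character vector of consensus sequences.
#' @param limit identity limit (default 0.9945, strict).
#' @return tibble of offending pairs (`i`, `j`, `identity`).
#' @export
detect_overclustering <- function(consensuses, limit = 0.9945) {
  out <- tibble::tibble(i = integer(), j = integer(), identity = numeric())
  n <- length(consensuses)
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      id <- pairwise_identity(consensuses[i], consensuses[j])
      if (id > limit) out <- dplyr::bind_rows(out, tibble::tibble(i = i, j = j, identity = id))
    }
  }
  out
}

#' Cluster amplicons over a threshold grid and pick the best threshold
#'
#' Runs [greedy_cluster()] at every grid value, picks a threshold with
#' [select_threshold()], builds consensuses for its supported clusters, and
#' applies the overclustering guard: if any two consensuses exceed the
#' overclustering identity limit, that threshold is discarded, the candidate
#' set is restricted to thresholds with strictly fewer supported clusters
#' than the discarded one, and selection is reapplied until a clean threshold
#' is found. If restriction exhausts the candidates, the never-flagged grid
#' values (if any) are re-selected over as a fallback; if every value was
#' flagged the scan fails.
#'
#' @param amplicons amplicons tibble (or character vector of sequences).
#' @param grid identity-threshold grid (default `seq(0.84, 0.91, 0.01)`).
#' @param support supported-cluster fraction (default 0.10).
#' @param overcluster_limit consensus identity limit (default 0.9945).
#' @param consensus_rounds,max_members passed to [build_consensus()].
#' @return an object of class `paraseek_scan`: `grid` tibble (per-c counts),
#'   `results` (clusterings, one per grid value), `chosen_c`, `chosen`
#'   (its clustering), `discarded_cs`, `consensus` tibble for the chosen
#'   threshold's supported clusters, `flagged_pairs`.
#' @export
run_cluster_stage <- function(amplicons,
                              grid = seq(0.84, 0.91, by = 0.01),
                              support = 0.10,
                              overcluster_limit = 0.9945,
                              consensus_rounds = 2L,
                              max_members = 100L) {
  seqs <- if (is.character(amplicons)) amplicons else amplicons$bases
  if (length(seqs) == 0L) abort("run_cluster_stage: no amplicons")
  results <- lapply(grid, function(cc) greedy_cluster(amplicons, cc, support))
  tbl <- scan_table(results)

  consensus_for <- function(res) {
    sup <- res$clusters[res$clusters$supported, , drop = FALSE]
    purrr::map(sup$members, function(idx) {
      build_consensus(subset_amplicons(amplicons, idx),
                      rounds = consensus_rounds, max_members = max_members)
    })
  }

  candidates <- seq_along(grid)
  flagged <- logical(length(grid))
  discarded <- numeric(0)
  chosen_idx <- NA_integer_
  chosen_cons <- NULL
  flagged_pairs <- NULL
  repeat {
    if (length(candidates) == 0L) {
      never <- which(!flagged)
      if (length(never) == 0L) {
        abort("unresolvable overclustering: every candidate threshold was flagged")
      }
      warn("overclustering reselection exhausted; falling back to never-flagged thresholds")
      candidates <- never
    }
    cc <- select_threshold(tbl[candidates, , drop = FALSE])
    idx <- which(abs(grid - cc) < 1e-9)[1]
    cons <- consensus_for(results[[idx]])
    pairs <- detect_overclustering(
      vapply(cons, function(x) x$bases, character(1)), overcluster_limit
    )
    if (nrow(pairs) == 0L) {
      chosen_idx <- idx
      chosen_cons <- cons
      break
    }
    flagged[idx] <- TRUE
    discarded <- c(discarded, grid[idx])
    flagged_pairs <- dplyr::bind_rows(flagged_pairs, dplyr::mutate(pairs, c = grid[idx]))
    ns <- results[[idx]]$n_supported
    candidates <- setdiff(
      which(vapply(results, function(r) r$n_supported < ns, logical(1))),
      which(flagged)
    )
  }

  chosen <- results[[chosen_idx]]
  sup <- chosen$clusters[chosen$clusters$supported, , drop = FALSE]
  cons_tbl <- if (length(chosen_cons)) {
    dplyr::bind_rows(purrr::imap(chosen_cons, function(cg, k) {
      dplyr::mutate(cg, cluster = sup$cluster[k], .before = 1L)
    }))
  } else {
    tibble::tibble()
  }
  structure(
    list(grid = tbl, results = results,
         chosen_c = grid[chosen_idx], chosen = chosen,
         discarded_cs = discarded,
         consensus = cons_tbl,
         flagged_pairs = flagged_pairs %||%
           tibble::tibble(i = integer(), j = integer(), identity = numeric(), c = numeric())),
    class = "paraseek_scan"
  )
}

subset_amplicons <- function(amplicons, idx) {
  if (is.character(amplicons)) {
    tibble::tibble(read_id = paste0("seq", idx), bases = amplicons[idx])
  } else {
    amplicons[idx, , drop = FALSE]
  }
}

#' @export
print.paraseek_scan <- function(x, ...) {
  cat("<paraseek_scan> chosen c = ", format(x$chosen_c),
      " (", x$chosen$n_supported, " supported clusters)",
      if (length(x$discarded_cs)) paste0("; discarded: ",
                                         paste(format(x$discarded_cs), collapse = ", ")),
      "\n", sep = "")
  print(x$grid)
  invisible(x)
}
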