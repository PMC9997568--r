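# Shared fixtures: all built in code, no files.

# a 3-exon toy gene: CDS = ATG GCT TGT CCG | AAA AAG GGG TGA -> "MACPKKG*",
# one GT..AG intron, an AAAAA homopolymer inside CDS2
toy_ref <- function() {
  suppressWarnings(gene_model(
    "toy",
    paste0("ATGGCTTGTCCG", "GTAAACCCAG", "AAAAAGGGGTGA"),
    tibble::tibble(start = c(0L, 22L), end = c(12L, 34L))
  ))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# substitute k bases of `seq` at distinct positions (never to the same base)
mutate_subs <- function(seq, k, positions = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- positions %||% sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

make_reads <- function(bases, q = 30L, ids = NULL) {
  ids <- ids %||% paste0("r", seq_along(bases))
  tibble::tibble(
    read_id = ids, sample_id = "test", bases = bases,
    quals = lapply(nchar(bases), function(n) rep(as.integer(q), n))
  )
}

make_amplicons <- function(bases, q = 30) {
  tibble::tibble(
    read_id = paste0("a", seq_along(bases)), bases = bases,
    quals = lapply(nchar(bases), function(n) rep(30L, n)),
    length = nchar(bases), mean_q = q, strand = "+"
  )
}

test_primers <- function() {
  primer_pair("ACGGTCAGTCTGAACGCTTAGC", "TGCAGGTCACTAGCTTGACCAG", "test")
}

`%||%` <- rlang::`%||%`

# pure-R lexicographic edit-distance DP (min edits, then max matches):
# the independent oracle for the identity metric
r_identity_dp <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(A); n <- length(B); K <- 100000
  prev <- (0:n) * K
  for (i in seq_len(m)) {
    cur <- numeric(n + 1)
    cur[1] <- i * K
    for (j in seq_len(n)) {
      cur[j + 1] <- min(prev[j] + (if (A[i] == B[j]) -1 else K),
                        prev[j + 1] + K, cur[j] + K)
    }
    prev <- cur
  }
  v <- prev[n + 1]
  e <- (v + K - 1) %/% K
  min(1, (e * K - v) / min(m, n))
}

# independent greedy-clustering re-implementation over a full identity matrix
oracle_greedy <- function(seqs, c) {
  n <- length(seqs)
  idm <- diag(1, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      idm[i, j] <- idm[j, i] <- pairwise_identity(seqs[i], seqs[j])
    }
  }
  ord <- order(-nchar(seqs))
  reps <- integer(0); mem <- list()
  for (i in ord) {
    hit <- 0L
    for (k in seq_along(reps)) {
      if (idm[i, reps[k]] >= c) { hit <- k; break }
    }
    if (hit > 0L) mem[[hit]] <- c(mem[[hit]], i)
    else { reps <- c(reps, i); mem[[length(reps)]] <- i }
  }
  list(reps = reps, members = mem)
}

# independent enumeration of the three-tier threshold-selection criteria
brute_select <- function(tbl) {
  best <- tbl[1, ]
  for (i in seq_len(nrow(tbl))[-1]) {
    cand <- tbl[i, ]
    better <- cand$n_supported > best$n_supported ||
      (cand$n_supported == best$n_supported &&
         cand$n_classified > best$n_classified) ||
      (cand$n_supported == best$n_supported &&
         cand$n_classified == best$n_classified && cand$c > best$c)
    if (better) best <- cand
  }
  best$c
}
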