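# Ground-truthed simulator: a multi-exon gene duplicated into paralogs at a
# controlled pairwise divergence, amplified between UTR-anchored primers and
# read with Nanopore-like substitution/indel noise (elevated indel rates in
# homopolymer runs), plus nonspecific and chimeric amplicons.

#' Simulation configuration
#'
#' Defaults emulate the data regime the pipeline is designed for: a ~1.5 kb
#' six-exon gene duplicated into three paralogs at ~5% pairwise divergence,
#' ~100 amplicon reads per paralog with a 2%/1%/1% substitution /
#' insertion / deletion noise floor, indel rates tripled inside homopolymer
#' runs of four or more bases, and small fractions of nonspecific and
#' chimeric amplicons.
#'
#' @param seed integer; the single source of randomness for the whole
#'   simulation (reads use a sub-stream derived from it).
#' @param n_paralogs number of paralogs (>= 1).
#' @param gene_length start-to-stop gene length in bp, introns included.
#' @param n_exons number of CDS exons.
#' @param pairwise_divergence target substitution fraction between paralogs.
#' @param sub_rate,ins_rate,del_rate per-base read error rates.
#' @param homopolymer_indel_boost indel-rate multiplier inside runs >= 4 bp.
#' @param reads_per_paralog amplicon reads emitted per paralog.
#' @param frac_nonspecific,frac_chimeric extra nonspecific / chimeric reads,
#'   as fractions of the paralog read count.
#' @param qual_mean,qual_sd per-base Phred quality model (error-derived bases
#'   are drawn 8 Phred lower).
#' @param utr_length length of the UTR spacer between each primer site and
#'   the gene.
#' @param margin_max maximal random non-amplicon margin on each side of a read.
#' @param intron2_deletion if `TRUE`, the first paralog loses 130 bp from the
#'   middle of intron 2 (a paralog-diagnostic structural difference).
#' @param fwd_primer,rev_primer primer oligos (reverse as ordered on the
#'   opposite strand).
#' @param protein_length protein length in amino acids (stop codon added).
#' @param cys_positions,pro_position conserved-residue positions (1-based, on
#'   the protein) the simulator fixes and divergence never touches.
#' @return a validated list of class `paraseek_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_paralogs = 3L,
                       gene_length = 1500L,
                       n_exons = 6L,
                       pairwise_divergence = 0.05,
                       sub_rate = 0.02, ins_rate = 0.01, del_rate = 0.01,
                       homopolymer_indel_boost = 3,
                       reads_per_paralog = 100L,
                       frac_nonspecific = 0.05,
                       frac_chimeric = 0.02,
                       qual_mean = 18, qual_sd = 4,
                       utr_length = 130L,
                       margin_max = 150L,
                       intron2_deletion = FALSE,
                       fwd_primer = "ACGGTCAGTCTGAACGCTTAGC",
                       rev_primer = "TGCAGGTCACTAGCTTGACCAG",
                       protein_length = 214L,
                       cys_positions = c(45L, 80L, 140L, 180L),
                       pro_position = 110L) {
  cfg <- as.list(environment())
  rates <- c(pairwise_divergence, sub_rate, ins_rate, del_rate,
             frac_nonspecific, frac_chimeric)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (n_paralogs < 1L) abort("n_paralogs must be >= 1")
  cds_total <- 3L * (protein_length + 1L)
  if (n_exons < 1L || cds_total < 30L * n_exons) abort("too many exons for the coding length")
  if (n_exons > 1L && gene_length < cds_total + 60L * (n_exons - 1L)) {
    abort("gene_length too short for the requested exon structure")
  }
  if (gene_length <= nchar(fwd_primer) + nchar(rev_primer) + 1200L) {
    abort("gene_length must exceed the primers plus 1200 bp")
  }
  if (max(cys_positions, pro_position) > protein_length) {
    abort("conserved positions beyond protein length")
  }
  structure(cfg, class = "paraseek_sim_config")
}

# split `total` into `k` parts, each >= minimum, with moderate random spread
random_partition <- function(total, k, minimum) {
  if (k == 1L) return(total)
  w <- runif(k, 0.7, 1.3)
  part <- pmax(minimum, floor(total * w / sum(w)))
  part[k] <- total - sum(part[-k])
  stopifnot(part[k] >= minimum)
  part
}

random_codons <- function(aa_spec) {
  code <- Biostrings::GENETIC_CODE
  sense <- setdiff(names(code), STOP_CODONS)
  vapply(aa_spec, function(a) {
    if (is.na(a)) sample(sense, 1L)
    else sample(names(code)[code == a], 1L)
  }, character(1))
}

#' Simulate a paralog family with ground truth
#'
#' Draws an ancestral multi-exon gene (ATG start, stop codon, GT..AG introns,
#' conserved cysteines and proline at fixed protein positions), then derives
#' each paralog by placing substitutions to reach the target pairwise
#' divergence. Substitutions in CDS exons are restricted to synonymous
#' third-codon-position changes (so divergence never destroys the hallmark
#' residues), and primer sites and splice dinucleotides are never touched.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `paraseek_truth`: `paralog_seqs` (named, full
#'   amplicon region including primer sites), `gene_models` (one
#'   [gene_model()] per paralog, on amplicon coordinates), `primers`,
#'   `profile` (conserved-site profile), `ancestor`, `cfg`.
#' @export
simulate_paralog_family <- function(cfg) {
  stopifnot(inherits(cfg, "paraseek_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  cds_total <- 3L * (cfg$protein_length + 1L)
  exon_len <- random_partition(cds_total, cfg$n_exons, 30L)
  n_intron <- cfg$n_exons - 1L
  intron_len <- if (n_intron > 0L) {
    random_partition(cfg$gene_length - cds_total, n_intron, 60L)
  } else integer(0)

  aa_spec <- rep(NA_character_, cfg$protein_length)
  aa_spec[1L] <- "M"
  aa_spec[cfg$cys_positions] <- "C"
  aa_spec[cfg$pro_position] <- "P"
  cds <- paste(c(random_codons(aa_spec), sample(STOP_CODONS, 1L)), collapse = "")

  # lay CDS across exons with GT..AG introns between
  gene <- character(0)
  exon_starts <- integer(cfg$n_exons)
  pos <- 0L
  cds_off <- cumsum(c(0L, exon_len))
  for (k in seq_len(cfg$n_exons)) {
    exon_starts[k] <- pos
    gene <- c(gene, substr(cds, cds_off[k] + 1L, cds_off[k + 1L]))
    pos <- pos + exon_len[k]
    if (k <= n_intron) {
      gene <- c(gene, paste0("GT", random_dna(intron_len[k] - 4L), "AG"))
      pos <- pos + intron_len[k]
    }
  }
  gene <- paste(gene, collapse = "")

  utr5 <- random_dna(cfg$utr_length)
  utr3 <- random_dna(cfg$utr_length)
  ancestor <- paste0(cfg$fwd_primer, utr5, gene, utr3, revcomp(cfg$rev_primer))
  gene_off <- nchar(cfg$fwd_primer) + cfg$utr_length
  exons <- tibble::tibble(start = exon_starts + gene_off,
                          end = exon_starts + exon_len + gene_off)

  mut <- mutable_sites(ancestor, exons, cfg)
  k_mut <- if (cfg$n_paralogs > 1L) {
    round(cfg$pairwise_divergence / 2 * nchar(ancestor))
  } else 0L
  if (k_mut > nrow(mut)) {
    abort(paste0("requested divergence needs ", k_mut, " substitutions but only ",
                 nrow(mut), " sites can change without destroying gene hallmarks"))
  }

  paralogs <- character(cfg$n_paralogs)
  models <- vector("list", cfg$n_paralogs)
  for (p in seq_len(cfg$n_paralogs)) {
    seq_p <- ancestor
    exons_p <- exons
    if (k_mut > 0L) {
      sites <- mut[sample.int(nrow(mut), k_mut), , drop = FALSE]
      ch <- strsplit(seq_p, "", fixed = TRUE)[[1]]
      for (i in seq_len(nrow(sites))) {
        ch[sites$pos[i] + 1L] <- sample(strsplit(sites$alts[i], "", fixed = TRUE)[[1]], 1L)
      }
      seq_p <- paste(ch, collapse = "")
    }
    if (cfg$intron2_deletion && p == 1L && cfg$n_exons >= 3L) {
      i2s <- exons_p$end[2L]; i2e <- exons_p$start[3L]
      if (i2e - i2s >= 170L) {
        mid <- i2s + (i2e - i2s) %/% 2L
        dstart <- mid - 65L
        seq_p <- paste0(substr(seq_p, 1L, dstart), substr(seq_p, dstart + 131L, nchar(seq_p)))
        after <- exons_p$start >= dstart + 130L
        exons_p$start[after] <- exons_p$start[after] - 130L
        exons_p$end[after] <- exons_p$end[after] - 130L
      }
    }
    paralogs[p] <- seq_p
    models[[p]] <- gene_model(paste0("paralog_", p), seq_p, exons_p)
  }
  names(paralogs) <- paste0("paralog_", seq_len(cfg$n_paralogs))

  profile <- list(
    ref_protein = translate_dna(cds),
    cys_positions = cfg$cys_positions,
    pro_position = cfg$pro_position
  )
  structure(
    list(paralog_seqs = paralogs, gene_models = models,
         primers = primer_pair(cfg$fwd_primer, cfg$rev_primer, "sim"),
         profile = profile, ancestor = ancestor, cfg = cfg),
    class = "paraseek_truth"
  )
}

# sites free to substitute without touching hallmarks: synonymous third codon
# positions outside the start/stop/conserved codons, intron interiors, UTRs
mutable_sites <- function(ancestor, exons, cfg) {
  code <- Biostrings::GENETIC_CODE
  gene_off <- nchar(cfg$fwd_primer) + cfg$utr_length
  gene_end <- nchar(ancestor) - nchar(cfg$rev_primer) - cfg$utr_length
  ch <- strsplit(ancestor, "", fixed = TRUE)[[1]]

  sites <- list()
  # UTRs (primer sites excluded)
  utr <- c(seq(nchar(cfg$fwd_primer), gene_off - 1L),
           seq(gene_end, nchar(ancestor) - nchar(cfg$rev_primer) - 1L))
  sites$utr <- tibble::tibble(
    pos = as.integer(utr),
    alts = vapply(utr, function(p) paste(setdiff(c("A", "C", "G", "T"), ch[p + 1L]),
                                         collapse = ""), character(1))
  )
  # intron interiors (GT..AG preserved)
  if (nrow(exons) > 1L) {
    intr <- unlist(lapply(seq_len(nrow(exons) - 1L), function(k) {
      s <- exons$end[k] + 2L; e <- exons$start[k + 1L] - 2L
      if (e > s) seq(s, e - 1L) else integer(0)
    }))
    sites$intron <- tibble::tibble(
      pos = as.integer(intr),
      alts = vapply(intr, function(p) paste(setdiff(c("A", "C", "G", "T"), ch[p + 1L]),
                                            collapse = ""), character(1))
    )
  }
  # synonymous third positions in CDS
  cds_pos <- unlist(lapply(seq_len(nrow(exons)),
                           function(k) seq(exons$start[k], exons$end[k] - 1L)))
  protected <- c(1L, cfg$cys_positions, cfg$pro_position, cfg$protein_length + 1L)
  syn <- list()
  for (ci in seq_len(length(cds_pos) %/% 3L)) {
    if (ci %in% protected) next
    p3 <- cds_pos[3L * ci]  # genomic position of the codon's 3rd base (0-based)
    codon <- paste0(ch[cds_pos[3L * ci - 2L] + 1L], ch[cds_pos[3L * ci - 1L] + 1L],
                    ch[p3 + 1L])
    aa <- code[[codon]]
    alts <- c("A", "C", "G", "T")
    alts <- alts[alts != substr(codon, 3L, 3L)]
    alts <- alts[vapply(alts, function(b) {
      code[[paste0(substr(codon, 1L, 2L), b)]] == aa
    }, logical(1))]
    if (length(alts)) {
      syn[[length(syn) + 1L]] <- tibble::tibble(pos = p3, alts = paste(alts, collapse = ""))
    }
  }
  sites$cds <- dplyr::bind_rows(syn)
  dplyr::bind_rows(sites)
}

# save/restore the global RNG state so simulation seeds never leak
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# apply per-base substitution/indel noise; indel rates are boosted inside
# homopolymer runs >= 4. Returns bases plus a flag per emitted base marking
# error-derived positions (used to draw lower quality scores).
add_read_noise <- function(seq, cfg) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  r <- rle(ch)
  runlen <- rep(r$lengths, r$lengths)
  boost <- ifelse(runlen >= 4L, cfg$homopolymer_indel_boost, 1)
  del <- runif(n) < cfg$del_rate * boost
  sub <- !del & runif(n) < cfg$sub_rate
  ins <- runif(n) < cfg$ins_rate * boost
  base_out <- ch
  if (any(sub)) {
    base_out[sub] <- vapply(ch[sub], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  }
  # homopolymer insertions duplicate the run base; elsewhere a random base
  ins_base <- character(n)
  if (any(ins)) {
    ins_base[ins] <- ifelse(runlen[ins] >= 4L, ch[ins],
                            sample(c("A", "C", "G", "T"), sum(ins), replace = TRUE))
  }
  emit <- rbind(!del, ins)                       # column-major: base, then insertion
  chars <- rbind(base_out, ins_base)
  errs <- rbind(sub, rep(TRUE, n))
  list(bases = paste(chars[emit], collapse = ""), err = errs[emit])
}

#' Simulate amplicon reads from a paralog family
#'
#' Each read carries a full amplicon (primer sites included) flanked by
#' random non-amplicon margins, with substitution/insertion/deletion noise
#' (homopolymer-boosted indels) and per-base qualities drawn from the quality
#' model (error-derived bases lower); half the reads are reverse-complemented.
#' Nonspecific reads (random inserts between intact primer sites) and
#' chimeras (5' of one paralog joined to the 3' of another) are injected at
#' the configured fractions of the paralog read count. Deterministic given
#' the configuration seed.
#'
#' @param truth a [simulate_paralog_family()] result.
#' @param cfg the simulation configuration (default: `truth$cfg`).
#' @return a list with `reads` (tibble as from [read_fastq()]) and `origins`
#'   (tibble `read_id`, `origin`: `"paralog_<i>"`, `"nonspecific"` or
#'   `"chimeric"`).
#' @export
simulate_reads <- function(truth, cfg = truth$cfg) {
  stopifnot(inherits(truth, "paraseek_truth"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, 1L))

  n_main <- cfg$n_paralogs * cfg$reads_per_paralog
  n_nonspec <- round(cfg$frac_nonspecific * n_main)
  n_chim <- if (cfg$n_paralogs > 1L) round(cfg$frac_chimeric * n_main) else 0L
  origin <- c(rep(names(truth$paralog_seqs), each = cfg$reads_per_paralog),
              rep("nonspecific", n_nonspec), rep("chimeric", n_chim))
  origin <- origin[sample.int(length(origin))]

  L <- nchar(truth$paralog_seqs[1])
  rc_rev <- revcomp(cfg$rev_primer)
  template_for <- function(o) {
    if (o == "nonspecific") {
      paste0(cfg$fwd_primer,
             random_dna(round(runif(1, 0.8, 1.1) * (L - nchar(cfg$fwd_primer) - nchar(rc_rev)))),
             rc_rev)
    } else if (o == "chimeric") {
      ij <- sample.int(cfg$n_paralogs, 2L)
      bp <- round(runif(1, 0.3, 0.7) * L)
      paste0(substr(truth$paralog_seqs[ij[1]], 1L, bp),
             substr(truth$paralog_seqs[ij[2]], bp + 1L,
                    nchar(truth$paralog_seqs[ij[2]])))
    } else {
      truth$paralog_seqs[[o]]
    }
  }

  rows <- vector("list", length(origin))
  for (i in seq_along(origin)) {
    tmpl <- template_for(origin[i])
    full <- paste0(random_dna(sample.int(cfg$margin_max + 1L, 1L) - 1L), tmpl,
                   random_dna(sample.int(cfg$margin_max + 1L, 1L) - 1L))
    noisy <- add_read_noise(full, cfg)
    nb <- nchar(noisy$bases)
    q <- round(rnorm(nb, cfg$qual_mean, cfg$qual_sd))
    if (any(noisy$err)) {
      q[noisy$err] <- round(rnorm(sum(noisy$err), cfg$qual_mean - 8, cfg$qual_sd))
    }
    q <- as.integer(pmin(41L, pmax(2L, q)))
    b <- noisy$bases
    if (rbinom(1L, 1L, 0.5) == 1L) {
      b <- revcomp(b)
      q <- rev(q)
    }
    rows[[i]] <- tibble::tibble(
      read_id = sprintf("read_%05d", i), sample_id = "sim",
      bases = b, quals = list(q)
    )
  }
  list(
    reads = dplyr::bind_rows(rows),
    origins = tibble::tibble(read_id = sprintf("read_%05d", seq_along(origin)),
                             origin = origin)
  )
}
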