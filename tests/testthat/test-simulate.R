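test_that("a single-paralog family is the ancestor itself", {
  cfg <- sim_config(seed = 51, n_paralogs = 1)
  tr <- simulate_paralog_family(cfg)
  expect_length(tr$paralog_seqs, 1L)
  expect_identical(unname(tr$paralog_seqs[1]), tr$ancestor)
})

test_that("paralogs reach the target pairwise divergence", {
  cfg <- sim_config(seed = 52, n_paralogs = 3, pairwise_divergence = 0.05)
  tr <- simulate_paralog_family(cfg)
  for (i in 1:2) for (j in (i + 1):3) {
    id <- pairwise_identity(tr$paralog_seqs[i], tr$paralog_seqs[j])
    expect_gte(id, 0.94)
    expect_lte(id, 0.96)
  }
})

test_that("simulation is deterministic per seed and leaves the RNG untouched", {
  cfg <- sim_config(seed = 53, n_paralogs = 2, reads_per_paralog = 10)
  set.seed(999); before <- runif(3)
  t1 <- simulate_paralog_family(cfg)
  t2 <- simulate_paralog_family(cfg)
  expect_identical(t1$paralog_seqs, t2$paralog_seqs)
  r1 <- simulate_reads(t1)
  r2 <- simulate_reads(t2)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$origins, r2$origins)
  set.seed(999)
  expect_identical(runif(3), before)
})

test_that("every paralog keeps its gene hallmarks despite divergence", {
  cfg <- sim_config(seed = 54, n_paralogs = 4, pairwise_divergence = 0.08)
  tr <- simulate_paralog_family(cfg)
  profile <- list(ref_protein = tr$profile$ref_protein,
                  cys_positions = tr$profile$cys_positions,
                  pro_position = tr$profile$pro_position)
  for (gm in tr$gene_models) {
    g <- map_gene_model(gm$genomic_seq, gm)
    g <- validate_hallmarks(g, profile)
    expect_true(g$hallmarks$complete)
    expect_equal(g$hallmarks$n_cds, 6L)
    expect_equal(g$hallmarks$n_conserved_cys, 4L)
  }
})

test_that("impossible divergence requests fail loudly", {
  # an almost intron-free gene leaves too few hallmark-safe sites
  cfg <- sim_config(seed = 55, n_paralogs = 2, pairwise_divergence = 1,
                    protein_length = 450L, gene_length = 1660L)
  expect_error(simulate_paralog_family(cfg), "hallmarks")
})

test_that("noise-free reads extract to their exact source paralog", {
  cfg <- sim_config(seed = 56, n_paralogs = 2, reads_per_paralog = 5,
                    sub_rate = 0, ins_rate = 0, del_rate = 0,
                    frac_nonspecific = 0, frac_chimeric = 0)
  tr <- simulate_paralog_family(cfg)
  sim <- simulate_reads(tr)
  amps <- extract_amplicons(sim$reads, tr$primers)
  expect_equal(nrow(amps), nrow(sim$reads))
  origin <- sim$origins$origin[match(amps$read_id, sim$origins$read_id)]
  expect_identical(unname(amps$bases), unname(tr$paralog_seqs[origin]))
})

test_that("nonspecific and chimeric reads appear at the configured fractions", {
  cfg <- sim_config(seed = 57, n_paralogs = 2, reads_per_paralog = 50,
                    frac_nonspecific = 0.1, frac_chimeric = 0.05)
  tr <- simulate_paralog_family(cfg)
  sim <- simulate_reads(tr)
  tab <- table(sim$origins$origin)
  expect_equal(unname(tab["nonspecific"]), 10L)
  expect_equal(unname(tab["chimeric"]), 5L)
  expect_equal(nrow(sim$reads), 115L)
  # every read is labelled
  expect_setequal(sim$reads$read_id, sim$origins$read_id)
})

test_that("realized per-base error matches the configured rates within 20%", {
  cfg <- sim_config(seed = 58, n_paralogs = 1, reads_per_paralog = 30,
                    margin_max = 0, frac_nonspecific = 0, frac_chimeric = 0)
  tr <- simulate_paralog_family(cfg)
  sim <- simulate_reads(tr)
  tmpl <- tr$paralog_seqs[[1]]
  edits <- vapply(seq_len(nrow(sim$reads)), function(i) {
    b <- sim$reads$bases[i]
    st <- paraseek:::cpp_align_stats(tmpl, b, -1L)
    st2 <- paraseek:::cpp_align_stats(tmpl, revcomp(b), -1L)
    min(st[1], st2[1])
  }, numeric(1))
  realized <- mean(edits) / nchar(tmpl)
  configured <- cfg$sub_rate + cfg$ins_rate + cfg$del_rate
  # homopolymer boost raises the indel share slightly above the floor
  expect_gte(realized, configured * 0.8)
  expect_lte(realized, configured * 1.2)
})

test_that("the quality model tracks errors: error-derived bases score lower", {
  cfg <- sim_config(seed = 59, n_paralogs = 1, reads_per_paralog = 20,
                    frac_nonspecific = 0, frac_chimeric = 0)
  tr <- simulate_paralog_family(cfg)
  sim <- simulate_reads(tr)
  mq <- vapply(sim$reads$quals, mean_quality, numeric(1))
  expect_true(all(mq > 10))
  expect_true(all(mq < 30))
})
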