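test_that("pairwise identity matches hand-computed and oracle values", {
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTACGTAT"), 0.9)
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTACGTAC"), 1.0)
  # 8 matches / shorter length 8, despite the length difference
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGTAC"), 1.0)
  expect_error(pairwise_identity("", "ACGT"), "empty")
})

test_that("identity agrees with a pure-R alignment DP on random pairs", {
  withr::local_seed(11)
  for (i in 1:60) {
    a <- rand_dna(sample(10:60, 1))
    b <- if (i %% 3 == 0) rand_dna(sample(10:60, 1)) else
      mutate_subs(a, sample(0:6, 1))
    expect_equal(pairwise_identity(a, b), r_identity_dp(a, b),
                 info = paste(a, b))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("banded threshold testing agrees with the full computation", {
  withr::local_seed(12)
  for (i in 1:40) {
    a <- rand_dna(sample(100:400, 1))
    b <- mutate_subs(a, sample(0:80, 1))
    full <- pairwise_identity(a, b)
    for (cc in c(0.84, 0.91, 0.97)) {
      banded <- paraseek:::identity_at_least(a, b, cc)
      if (full >= cc) expect_equal(banded, full)
      else expect_true(is.na(banded))
    }
  }
})

test_that("supported-cluster counting is strictly greater than 10%", {
  expect_equal(supported_count(c(50, 30, 11, 9), 100), 3L)
  expect_equal(supported_count(c(100), 100), 1L)
  expect_equal(supported_count(rep(10, 10), 100), 0L)
  expect_equal(supported_count(integer(0), 0), 0L)
})

test_that("greedy clustering separates and lumps according to c", {
  withr::local_seed(13)
  A <- rand_dna(500)
  A2 <- mutate_subs(A, 5)     # 99% to A
  B <- mutate_subs(A, 75)     # ~85% to A
  res_hi <- greedy_cluster(c(A, A2, B), c = 0.90)
  expect_equal(nrow(res_hi$clusters), 2L)
  expect_equal(sort(lengths(res_hi$clusters$members)), c(1L, 2L))
  res_lo <- greedy_cluster(c(A, A2, B), c = 0.84)
  expect_equal(nrow(res_lo$clusters), 1L)

  one <- greedy_cluster(c(A), c = 0.9)
  expect_equal(nrow(one$clusters), 1L)
  expect_true(one$clusters$supported)
  expect_equal(one$clusters$representative, 1L)
})

test_that("greedy clustering matches the brute-force oracle on fuzzed inputs", {
  withr::local_seed(14)
  for (case in 1:120) {
    n_proto <- sample(1:3, 1)
    protos <- vapply(seq_len(n_proto), function(i) rand_dna(sample(40:80, 1)), "")
    n <- sample(2:12, 1)
    seqs <- vapply(seq_len(n), function(i) {
      p <- protos[sample(n_proto, 1)]
      mutate_subs(p, sample(0:8, 1))
    }, "")
    cc <- sample(seq(0.70, 0.95, 0.05), 1)
    got <- greedy_cluster(seqs, cc)
    want <- oracle_greedy(seqs, cc)
    expect_equal(got$clusters$representative, want$reps)
    expect_equal(lapply(got$clusters$members, sort),
                 lapply(want$members, sort))
    # partition property
    expect_setequal(unlist(got$clusters$members), seq_len(n))
    expect_equal(sum(got$clusters$size), n)
  }
})

test_that("cluster count is non-decreasing in c on simulated amplicons", {
  cfg <- sim_config(seed = 21, n_paralogs = 2, reads_per_paralog = 15,
                    frac_nonspecific = 0, frac_chimeric = 0)
  tr <- simulate_paralog_family(cfg)
  sim <- simulate_reads(tr)
  amps <- extract_amplicons(sim$reads, tr$primers)
  ns <- vapply(seq(0.84, 0.91, 0.01),
               function(cc) nrow(greedy_cluster(amps, cc)$clusters), numeric(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("threshold selection applies the three-tier rule", {
  tbl <- tibble::tibble(
    c = c(0.84, 0.85, 0.86, 0.87, 0.88),
    n_supported = c(2, 3, 3, 3, 2),
    n_classified = c(90, 85, 88, 88, 95)
  )
  expect_equal(select_threshold(tbl), 0.87)
  flat <- tibble::tibble(c = seq(0.84, 0.91, 0.01),
                         n_supported = 1, n_classified = 100)
  expect_equal(select_threshold(flat), 0.91)
  expect_equal(select_threshold(tbl[3, ]), 0.86)
  # permutation invariance
  perm <- tbl[sample(nrow(tbl)), ]
  expect_equal(select_threshold(perm), 0.87)
})

test_that("threshold selection matches exhaustive enumeration of the criteria", {
  grid_c <- c(0.84, 0.87, 0.91)
  vals_sup <- 0:2
  vals_cls <- c(0, 50, 100)
  combos <- expand.grid(s1 = vals_sup, s2 = vals_sup, s3 = vals_sup,
                        k1 = vals_cls, k2 = vals_cls, k3 = vals_cls)
  for (i in seq_len(nrow(combos))) {
    tbl <- tibble::tibble(
      c = grid_c,
      n_supported = as.numeric(combos[i, 1:3]),
      n_classified = as.numeric(combos[i, 4:6])
    )
    expect_equal(select_threshold(tbl), brute_select(tbl), info = paste(i))
  }
})

test_that("overclustering detection uses a strict identity limit", {
  withr::local_seed(15)
  base <- rand_dna(2000)
  # 10 substitutions in 2000 bp: identity 0.995 > 0.9945 -> flagged
  near <- mutate_subs(base, 10)
  expect_equal(nrow(detect_overclustering(c(base, near))), 1L)
  # 11 substitutions: identity 0.9945 exactly -> not flagged (strict >)
  at_limit <- mutate_subs(base, 11)
  expect_equal(pairwise_identity(base, at_limit), 0.9945)
  expect_equal(nrow(detect_overclustering(c(base, at_limit))), 0L)
  far <- mutate_subs(base, 40)
  expect_equal(nrow(detect_overclustering(c(base, far))), 0L)
  expect_equal(nrow(detect_overclustering(base)), 0L)
})

test_that("overclustering discards the threshold and reselects with fewer supported clusters", {
  withr::local_seed(16)
  X <- rand_dna(1000)
  Y <- mutate_subs(X, 1)  # identity 0.999
  amps <- c(rep(X, 5), rep(Y, 5))
  scan <- run_cluster_stage(amps, grid = c(0.995, 0.9995))
  # at c = 0.9995 the two variants split into two supported clusters whose
  # consensuses are 99.9% identical -> flagged; reselection must fall back
  expect_equal(scan$discarded_cs, 0.9995)
  expect_equal(scan$chosen_c, 0.995)
  expect_equal(scan$chosen$n_supported, 1L)
  expect_equal(nrow(scan$consensus), 1L)

  expect_error(run_cluster_stage(amps, grid = 0.9995),
               "unresolvable overclustering")
})

test_that("threshold scans are deterministic", {
  cfg <- sim_config(seed = 22, n_paralogs = 2, reads_per_paralog = 12,
                    frac_nonspecific = 0, frac_chimeric = 0)
  tr <- simulate_paralog_family(cfg)
  sim <- simulate_reads(tr)
  amps <- extract_amplicons(sim$reads, tr$primers)
  s1 <- run_cluster_stage(amps, grid = c(0.84, 0.88, 0.91))
  s2 <- run_cluster_stage(amps, grid = c(0.84, 0.88, 0.91))
  expect_identical(tidy(s1), tidy(s2))
  expect_identical(s1$consensus$bases, s2$consensus$bases)
})
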