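test_that("mean quality follows the error-probability convention", {
  expect_equal(mean_quality(c(20, 20, 20)), 20)
  # closed form: mean error (0.1 + 0.01) / 2 = 0.055
  expect_equal(mean_quality(c(10, 20)), -10 * log10(0.055), tolerance = 1e-10)
  expect_equal(mean_quality(c(10, 20)), 12.59, tolerance = 0.01)
  expect_equal(mean_quality(0L), 0)
  expect_error(mean_quality(integer(0)), "empty")
})

test_that("a constructed amplicon is found once, on the plus strand", {
  withr::local_seed(1)
  pr <- test_primers()
  filler <- rand_dna(1500)
  read <- make_reads(paste0(pr$fwd, filler, revcomp(pr$rev)))
  hits <- find_amplicons(read, pr)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$length, 1500L + nchar(pr$fwd) + nchar(pr$rev))
  expect_equal(hits$fwd_mismatches, 0L)
})

test_that("strand symmetry: the reverse-complemented read yields the same amplicon", {
  withr::local_seed(2)
  pr <- test_primers()
  amp <- paste0(pr$fwd, rand_dna(1500), revcomp(pr$rev))
  fwd_read <- make_reads(paste0(rand_dna(40), amp, rand_dna(60)), ids = "f")
  rev_read <- make_reads(revcomp(fwd_read$bases), ids = "r")
  a_f <- extract_amplicons(fwd_read, pr)
  a_r <- extract_amplicons(rev_read, pr)
  expect_equal(nrow(a_f), 1L)
  expect_equal(a_r$strand, "-")
  expect_identical(a_f$bases, a_r$bases)
  expect_identical(a_f$bases, amp)
  expect_identical(a_r$quals, a_f$quals)
})

test_that("multiple amplicons in one read are all reported, sorted by length", {
  withr::local_seed(3)
  pr <- test_primers()
  read <- make_reads(paste0(pr$fwd, rand_dna(1400), revcomp(pr$rev),
                            rand_dna(25),
                            pr$fwd, rand_dna(1100), revcomp(pr$rev)))
  hits <- find_amplicons(read, pr)
  # brute force: 2 fwd x 2 rev downstream pairings = 3 valid spans
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$length, sort(hits$length))
  expect_equal(min(hits$length), 1100L + 44L)
})

test_that("IUPAC-degenerate primer bases match their sets within the budget", {
  withr::local_seed(4)
  pr <- primer_pair("ACGGTCAGTCTRAACGCTTAGC", "TGCAGGTCACTAGCTTGACCAG",
                    max_mismatches = 0L)
  core <- rand_dna(1200)
  for (b in c("A", "G")) {
    site <- sub("R", b, pr$fwd)
    hits <- find_amplicons(make_reads(paste0(site, core, revcomp(pr$rev))), pr)
    expect_equal(nrow(hits), 1L)
  }
  site_bad <- sub("R", "C", pr$fwd)
  hits <- find_amplicons(make_reads(paste0(site_bad, core, revcomp(pr$rev))), pr)
  expect_equal(nrow(hits), 0L)
})

test_that("the smallest amplicon strictly over the floor is extracted", {
  withr::local_seed(5)
  read <- make_reads(rand_dna(2000))
  hit <- function(len) tibble::tibble(
    read_id = "r1", strand = "+", start = 0L, end = as.integer(len),
    length = as.integer(len), fwd_mismatches = 0L, rev_mismatches = 0L
  )
  hits <- dplyr::bind_rows(hit(950), hit(1300), hit(1800))
  out <- extract_target_amplicon(hits, read, min_len = 1000L)
  expect_equal(out$length, 1300L)

  expect_equal(nrow(extract_target_amplicon(
    dplyr::bind_rows(hit(800), hit(1000)), read, 1000L)), 0L)

  out <- extract_target_amplicon(hit(1001), read, 1000L)
  expect_equal(out$length, 1001L)
  expect_identical(out$bases, substr(read$bases, 1, 1001))
})

test_that("extracted amplicons are always substrings of the (oriented) read", {
  withr::local_seed(6)
  pr <- test_primers()
  for (i in 1:10) {
    amp <- paste0(pr$fwd, rand_dna(sample(1100:1600, 1)), revcomp(pr$rev))
    raw <- paste0(rand_dna(sample(0:80, 1)), amp, rand_dna(sample(0:80, 1)))
    if (i %% 2 == 0) raw <- revcomp(raw)
    out <- extract_amplicons(make_reads(raw), pr)
    expect_equal(nrow(out), 1L)
    expect_true(grepl(out$bases, raw, fixed = TRUE) ||
                  grepl(out$bases, revcomp(raw), fixed = TRUE))
  }
})

test_that("size window is inclusive and quality floors are strict", {
  amp <- function(len, q) make_amplicons(strrep("A", len), q = q)
  expect_equal(nrow(filter_amplicons(amp(1250, 15))), 1L)   # kept
  expect_equal(nrow(filter_amplicons(amp(1200, 15))), 1L)   # inclusive low edge
  expect_equal(nrow(filter_amplicons(amp(2400, 15))), 1L)   # inclusive high edge
  expect_equal(nrow(filter_amplicons(amp(1150, 30))), 0L)   # below 1,200
  expect_equal(nrow(filter_amplicons(amp(2401, 30))), 0L)   # above 2,400
  expect_equal(nrow(filter_amplicons(amp(1300, 14))), 0L)   # Q = 14 is not > 14
  expect_equal(nrow(filter_amplicons(amp(1300, 14.01))), 1L)
})

test_that("read prefilter keeps Q > 7 strictly", {
  reads <- make_reads(c(strrep("A", 100), strrep("C", 100)), q = 8L)
  reads$quals[[2]] <- rep(7L, 100)
  kept <- prefilter_reads(reads, 7)
  expect_equal(kept$read_id, "r1")
  expect_equal(nrow(prefilter_reads(reads[0, ], 7)), 0L)
})

test_that("indel-tolerant primer matching recovers sites broken by an indel", {
  withr::local_seed(9)
  pr <- test_primers()
  fwd_del <- paste0(substr(pr$fwd, 1, 10), substr(pr$fwd, 12, nchar(pr$fwd)))
  read <- make_reads(paste0(fwd_del, rand_dna(1300), revcomp(pr$rev)))
  expect_equal(nrow(find_amplicons(read, pr)), 0L)
  hits <- find_amplicons(read, pr, with_indels = TRUE)
  expect_equal(nrow(hits), 1L)
})
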