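test_that("mapping a reference onto itself returns its own intervals", {
  ref <- toy_ref()
  g <- map_gene_model(ref$genomic_seq, ref, consensus_id = "self")
  expect_equal(g$cds_exons, ref$cds_exons)
  expect_equal(g$gene_span, c(0L, 34L))
  expect_true(g$in_frame)
  expect_false(g$partial)
  expect_equal(g$protein, "MACPKKG*")
})

test_that("an insertion in the intron shifts downstream CDS intervals", {
  ref <- toy_ref()
  # 10 bp inserted mid-intron (after position 16)
  cons <- paste0(substr(ref$genomic_seq, 1, 16), "CATCATCATC",
                 substr(ref$genomic_seq, 17, nchar(ref$genomic_seq)))
  g <- map_gene_model(cons, ref)
  expect_equal(g$cds_exons$start, c(0L, 32L))
  expect_equal(g$cds_exons$end, c(12L, 44L))
  expect_equal(g$protein, "MACPKKG*")
})

test_that("too-distant references and unmappable exons are rejected", {
  ref <- toy_ref()
  withr::local_seed(41)
  expect_error(map_gene_model(strrep("T", 60), ref), "too distant")
  truncated <- substr(ref$genomic_seq, 1, 14)   # only exon 1 projects
  expect_error(map_gene_model(truncated, ref), "project")
})

test_that("a homopolymer deletion breaking the frame is repaired to the reference protein", {
  ref <- toy_ref()
  # delete one A from the AAAAA run in CDS2 (positions 22..26)
  cons <- paste0(substr(ref$genomic_seq, 1, 22),
                 substr(ref$genomic_seq, 24, nchar(ref$genomic_seq)))
  g <- map_gene_model(cons, ref)
  expect_false(g$in_frame)
  rep <- fix_homopolymer_frameshifts(g, ref)
  expect_true(rep$in_frame)
  expect_equal(nrow(rep$repaired), 1L)
  expect_equal(rep$repaired$base, "A")
  expect_equal(rep$repaired$from_len, 4L)
  expect_equal(rep$repaired$to_len, 5L)
  expect_equal(rep$protein, "MACPKKG*")
  # repair soundness: frame restored, single terminal stop
  cds <- with(rep, paste(substring(bases, cds_exons$start + 1, cds_exons$end),
                         collapse = ""))
  expect_equal(nchar(cds) %% 3, 0)
  expect_equal(as.integer(gregexpr("\\*", rep$protein)[[1]]), nchar(rep$protein))
})

test_that("a homopolymer insertion breaking the frame is repaired", {
  ref <- toy_ref()
  cons <- paste0(substr(ref$genomic_seq, 1, 24), "A",
                 substr(ref$genomic_seq, 25, nchar(ref$genomic_seq)))
  g <- map_gene_model(cons, ref)
  expect_false(g$in_frame)
  rep <- fix_homopolymer_frameshifts(g, ref)
  expect_true(rep$in_frame)
  expect_equal(rep$repaired$from_len, 6L)
  expect_equal(rep$repaired$to_len, 5L)
  expect_equal(rep$protein, "MACPKKG*")
})

test_that("in-frame genes are returned untouched", {
  ref <- toy_ref()
  g <- map_gene_model(ref$genomic_seq, ref)
  out <- fix_homopolymer_frameshifts(g, ref)
  expect_identical(out$bases, ref$genomic_seq)
  expect_equal(nrow(out$repaired), 0L)
  # a full-codon (3 bp) deletion keeps the frame: repair must not trigger
  cons3 <- paste0(substr(ref$genomic_seq, 1, 24),
                  substr(ref$genomic_seq, 28, nchar(ref$genomic_seq)))
  g3 <- map_gene_model(cons3, ref)
  expect_true(g3$in_frame)
  out3 <- fix_homopolymer_frameshifts(g3, ref)
  expect_identical(out3$bases, cons3)
  expect_equal(nrow(out3$repaired), 0L)
})

test_that("irreparable frameshifts are flagged, not repaired", {
  ref <- toy_ref()
  # 1 bp deletion in CDS1 outside any homopolymer run (position 5, "C")
  cons <- paste0(substr(ref$genomic_seq, 1, 4),
                 substr(ref$genomic_seq, 6, nchar(ref$genomic_seq)))
  g <- map_gene_model(cons, ref)
  expect_false(g$in_frame)
  out <- fix_homopolymer_frameshifts(g, ref)
  expect_false(out$in_frame)
  expect_identical(out$bases, cons)
})

test_that("hallmark validation checks start, stop, splice sites and conserved residues", {
  ref <- toy_ref()
  profile <- conserved_profile(ref, cys_positions = 3L, pro_position = 4L)
  g <- map_gene_model(ref$genomic_seq, ref)
  g <- validate_hallmarks(g, profile, expected_cys = 1L)
  hm <- g$hallmarks
  expect_true(hm$has_start)
  expect_true(hm$has_stop)
  expect_equal(hm$n_cds, 2L)
  expect_true(hm$all_splice_canonical)
  expect_equal(hm$n_conserved_cys, 1L)
  expect_true(hm$conserved_pro)
  expect_equal(hm$protein_length, 7L)
  expect_true(hm$complete)

  # break the donor site: GT -> GC
  broken <- ref$genomic_seq
  substr(broken, 14, 14) <- "C"
  gb <- validate_hallmarks(map_gene_model(broken, ref, snap_window = 0L), profile, 1L)
  expect_false(gb$hallmarks$all_splice_canonical)
  expect_false(gb$hallmarks$complete)

  # substitute the conserved cysteine (TGT at bases 7-9 -> GGT, Gly)
  nocys <- ref$genomic_seq
  substr(nocys, 7, 7) <- "G"
  gc <- validate_hallmarks(map_gene_model(nocys, ref), profile, 1L)
  expect_equal(gc$hallmarks$n_conserved_cys, 0L)
})

test_that("conserved profiles reject wrong reference residues", {
  ref <- toy_ref()
  expect_error(conserved_profile(ref, cys_positions = 2L, pro_position = 4L),
               "cysteine")
  expect_error(conserved_profile(ref, cys_positions = 3L, pro_position = 5L),
               "proline")
})

test_that("paralog assignment applies floor and margin rules", {
  withr::local_seed(42)
  base <- rand_dna(1000)
  refs <- c(p1 = base, p2 = mutate_subs(base, 60))       # 94% apart
  expect_equal(assign_paralog(mutate_subs(base, 10), refs), "p1")  # 99% vs ~94%
  expect_equal(assign_paralog(rand_dna(1000), refs), "unassigned") # ~55%
  # best below the 0.97 floor
  expect_equal(assign_paralog(mutate_subs(base, 40), refs), "unassigned")
  # margin failure: two references 2 subs apart
  close_refs <- c(a = base, b = mutate_subs(base, 2))
  expect_equal(assign_paralog(base, close_refs), "ambiguous")
  expect_error(assign_paralog(base, character(0)), "empty")
})

test_that("annotated genes round-trip through GFF3 with correct conversion", {
  td <- withr::local_tempdir()
  ref <- toy_ref()
  g <- map_gene_model(ref$genomic_seq, ref, consensus_id = "cons1")
  path <- file.path(td, "g.gff3")
  write_gene_gff3(g, path)
  lines <- grep("\tCDS\t", readLines(path), value = TRUE)
  f <- strsplit(lines, "\t")
  # internal [0,12) and [22,34) -> GFF3 1..12 and 23..34
  expect_equal(as.integer(vapply(f, `[`, "", 4)), c(1L, 23L))
  expect_equal(as.integer(vapply(f, `[`, "", 5)), c(12L, 34L))
})
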