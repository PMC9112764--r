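test_that("a single passing read produces one column per aligned base", {
  refs <- c(r1 = "ACGTACGT")
  pu <- build_pileup(aln_row("f1", "r1", 1, "ACGT"), refs)
  expect_equal(pu$pos, 1:4)
  expect_equal(pu$base, c("A", "C", "G", "T"))
  cnt <- pileup_counts(pu)
  expect_true(all(cnt$n == 1L))
})

test_that("the alignment filter excludes low mapq and flagged records", {
  expect_true(alignment_passes(flag = 0L, mapq = 20L))
  expect_false(alignment_passes(flag = 0L, mapq = 19L))
  # each excluded flag bit on its own, at high mapq
  for (bit in c(0x4L, 0x100L, 0x200L, 0x400L, 0x800L)) {
    expect_false(alignment_passes(flag = bit, mapq = 60L))
  }
  # paired/proper/reverse/mate bits are not exclusion reasons
  expect_true(alignment_passes(flag = 99L, mapq = 20L))

  refs <- c(r1 = "ACGTACGT")
  aln <- dplyr::bind_rows(
    aln_row("pass", "r1", 1, "ACGT", mapq = 30),
    aln_row("fail", "r1", 1, "GGGG", mapq = 10)
  )
  cnt <- pileup_counts(build_pileup(aln, refs))
  expect_true(all(cnt$base == c("A", "C", "G", "T")))
  expect_true(all(cnt$n == 1L))
})

test_that("a paired fragment contributes at most one base per column", {
  refs <- c(r1 = strrep("A", 20))
  # mates overlap on positions 5..8; same base there -> counted once
  aln <- dplyr::bind_rows(
    aln_row("frag", "r1", 1, "CCCCCCCC", flag = 99),
    aln_row("frag", "r1", 5, "CCCCCCCC", flag = 147)
  )
  cnt <- pileup_counts(build_pileup(aln, refs))
  expect_equal(nrow(cnt), 12L)
  expect_true(all(cnt$n == 1L))

  # disagreeing mates: the fragment contributes nothing at those columns
  aln2 <- dplyr::bind_rows(
    aln_row("frag", "r1", 1, "CCCC", flag = 99),
    aln_row("frag", "r1", 3, "GGGG", flag = 147)
  )
  pu2 <- build_pileup(aln2, refs)
  expect_equal(pu2$pos, c(1L, 2L, 5L, 6L))
  expect_equal(pu2$base, c("C", "C", "G", "G"))
})

test_that("deletions, N calls, soft clips and insertions never enter the pileup", {
  refs <- c(r1 = "ACGTACGTAC")
  sam <- withr::local_tempfile(fileext = ".sam")
  write_raw_sam(sam, refs, c(
    # 2M1D2M at pos 1: covers 1,2 then deletion at 3, then 4,5
    "del_read\t0\tr1\t1\t60\t2M1D2M\t*\t0\t0\tACTA\tIIII",
    # soft clip + insertion: aligned part is only 4M at pos 3
    "clip_read\t0\tr1\t3\t60\t2S4M2I1M\t*\t0\t0\tGGGTACTTA\tIIIIIIIII",
    # N base inside the read
    "n_read\t0\tr1\t6\t60\t3M\t*\t0\t0\tCNT\tIII"
  ))
  aln <- read_alignments(sam)
  pu <- build_pileup(aln, refs)
  del <- pu[pu$fragment_id == "del_read", ]
  expect_equal(del$pos, c(1L, 2L, 4L, 5L))
  clip <- pu[pu$fragment_id == "clip_read", ]
  expect_equal(clip$pos, 3:7)
  expect_equal(clip$base, c("G", "T", "A", "C", "A"))
  nr <- pu[pu$fragment_id == "n_read", ]
  expect_equal(nr$pos, c(6L, 8L))
})

test_that("counts equal distinct contributing fragments and are monotone under read removal", {
  sim <- simulate_community(sim_config(
    seed = 11, ref_length = 1200, n_strains = 2, snv_rate = 0.01,
    depth = 10, error_rate = 0.01
  ))
  aln <- as_alignments(simulate_alignments(sim))
  pu <- build_pileup(aln, sim$refs)
  per_col <- dplyr::summarise(
    dplyr::group_by(pu, ref_id, pos),
    n_calls = dplyr::n(), n_frags = dplyr::n_distinct(fragment_id),
    .groups = "drop"
  )
  expect_true(all(per_col$n_calls == per_col$n_frags))

  drop_frag <- unique(aln$fragment_id)[1]
  cnt_all <- pileup_counts(pu)
  cnt_sub <- pileup_counts(build_pileup(
    aln[aln$fragment_id != drop_frag, ], sim$refs
  ))
  joined <- dplyr::left_join(
    cnt_sub, cnt_all,
    by = c("ref_id", "pos", "base"), suffix = c("_sub", "_all")
  )
  expect_true(all(joined$n_sub <= joined$n_all))
})

test_that("error-free single-strain reads pile up as the reference base everywhere", {
  sim <- simulate_community(sim_config(
    seed = 12, ref_length = 1500, n_strains = 1, snv_rate = 0,
    depth = 15, error_rate = 0
  ))
  pu <- build_pileup(as_alignments(simulate_alignments(sim)), sim$refs)
  per_col <- dplyr::summarise(
    dplyr::group_by(pu, pos), n_alleles = dplyr::n_distinct(base),
    base = base[1], .groups = "drop"
  )
  expect_true(all(per_col$n_alleles == 1L))
  ref_chars <- strsplit(sim$refs[["ref_1"]], "")[[1]]
  expect_true(all(per_col$base == ref_chars[per_col$pos]))
})

test_that("unknown references and unsorted input are fatal", {
  refs <- c(r1 = "ACGT")
  expect_error(build_pileup(aln_row("f", "rX", 1, "AC"), refs), "rX")
  unsorted <- dplyr::bind_rows(
    aln_row("a", "r1", 3, "T"),
    aln_row("b", "r1", 1, "AC")
  )
  expect_error(build_pileup(unsorted, refs), "sorted")
})
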