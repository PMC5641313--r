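test_that("block profiles lay out single-type runs exactly", {
  p <- make_block_profile(4, list(c(0, 2, 0), c(2, 4, 1)))
  expect_equal(p$abundance, rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L)))
  expect_equal(p$n_beads, 4L)
  expect_equal(p$n_types, 2L)

  fig3 <- fig3_profile()
  expect_equal(fig3$n_types, 2L)
  expect_equal(unname(rowSums(fig3$abundance)), c(20, 20))
  expect_equal(fig3$abundance[1, 1:10], rep(1L, 10))
  expect_equal(fig3$abundance[2, 11:20], rep(1L, 10))

  empty <- make_block_profile(12, list())
  expect_true(all(empty$abundance == 0))
})

test_that("conflicting block overlaps are rejected with the interval named", {
  expect_error(make_block_profile(10, list(c(0, 6, 0), c(4, 8, 1))),
               "\\[4, 8\\)")
  expect_error(make_block_profile(10, list(c(3, 3, 0))), "start < end")
  expect_error(make_block_profile(10, list(c(0, 11, 0))), "start < end|n_beads")
  # same-type overlap is harmless
  expect_silent(make_block_profile(10, list(c(0, 6, 0), c(4, 8, 0))))
})

test_that("random profiles are seeded, cover every type, and match the locus scales", {
  p7q <- make_random_profile(160, 15, mean_domain_len = 6, seed = 3)
  expect_equal(dim(p7q$abundance), c(15L, 160L))
  expect_true(all(rowSums(p7q$abundance) > 0))

  bmp7 <- make_random_profile(78, 11, mean_domain_len = 5, seed = 4,
                              bin_size_bp = 30000L)
  expect_equal(dim(bmp7$abundance), c(11L, 78L))
  expect_true(all(rowSums(bmp7$abundance) > 0))

  expect_identical(make_random_profile(60, 5, seed = 11)$abundance,
                   make_random_profile(60, 5, seed = 11)$abundance)
  expect_false(identical(make_random_profile(60, 5, seed = 11)$abundance,
                         make_random_profile(60, 5, seed = 12)$abundance))
  expect_error(make_random_profile(4, 9, seed = 1), "exceed")
})

test_that("profiles serialize to TSV and back losslessly", {
  p <- make_random_profile(30, 4, seed = 8, bin_size_bp = 50000L,
                           genomic_start = 129500000L, chrom = "chr5")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(p, path, header = c("tool x", "seed 1"))
  q <- read_profile_tsv(path)
  expect_identical(unname(q$abundance), unname(p$abundance))
  expect_equal(q$bin_size_bp, p$bin_size_bp)
  expect_equal(q$genomic_start, p$genomic_start)
  expect_equal(q$chrom, p$chrom)
  expect_match(readLines(path, n = 1), "^# tool x")

  bins <- profile_bins(p)
  expect_equal(bins$start[1], 129500000L)
  expect_equal(bins$end[30], 129500000L + 30 * 50000L)
})
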