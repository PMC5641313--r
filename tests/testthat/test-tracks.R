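test_that("track binning is a coverage-weighted mean with missing-as-NA", {
  prof <- make_block_profile(4, list(), bin_size_bp = 100L, chrom = "chrT")
  # uniform value across the region
  uni <- track(data.frame(chrom = "chrT", start = 0, end = 400, value = 5))
  expect_equal(bin_track(uni, prof), rep(5, 4))
  # one interval covering exactly half of bin 2, everything else uncovered
  half <- track(data.frame(chrom = "chrT", start = 100, end = 150, value = 10))
  expect_equal(bin_track(half, prof), c(NA, 10, NA, NA))
  # two intervals with different values inside one bin: weighted by bases
  two <- track(data.frame(chrom = "chrT", start = c(0, 75), end = c(75, 100),
                          value = c(4, 8)))
  expect_equal(bin_track(two, prof)[1], (75 * 4 + 25 * 8) / 100)
  # empty track: all missing
  empty <- track(data.frame(chrom = character(), start = numeric(),
                            end = numeric(), value = numeric()))
  expect_true(all(is.na(bin_track(empty, prof))))
  # wrong chromosome is an error
  wrong <- track(data.frame(chrom = "chrX", start = 0, end = 400, value = 1))
  expect_error(bin_track(wrong, prof), "chrT|chrX")
})

test_that("profile-track correlations match an independent Pearson oracle", {
  prof <- make_random_profile(40, 3, seed = 5, bin_size_bp = 1000L)
  bins <- profile_bins(prof)
  vals <- local_seed(77, runif(40) * 3)
  tr <- track(data.frame(chrom = bins$chrom, start = bins$start,
                         end = bins$end, value = vals), name = "rand")
  cr <- correlate_profile_tracks(prof, tr)
  for (t in 1:3)
    expect_equal(unname(cr$r[t, 1]),
                 cor(as.numeric(prof$abundance[t, ]), vals),
                 tolerance = 1e-12)
  expect_equal(unname(cr$n_bins[, 1]), rep(40L, 3))
})

test_that("correlations are invariant under positive affine track transforms", {
  prof <- make_random_profile(30, 2, seed = 9, bin_size_bp = 500L)
  bins <- profile_bins(prof)
  vals <- local_seed(5, runif(30))
  base <- track(data.frame(chrom = bins$chrom, start = bins$start,
                           end = bins$end, value = vals))
  aff <- track(data.frame(chrom = bins$chrom, start = bins$start,
                          end = bins$end, value = 3.7 * vals + 11))
  expect_equal(correlate_profile_tracks(prof, base)$r,
               correlate_profile_tracks(prof, aff)$r, tolerance = 1e-12)
})

test_that("sparse tracks flag cells as missing instead of failing", {
  prof <- make_block_profile(10, list(c(0, 5, 0), c(5, 10, 1)),
                             bin_size_bp = 100L, chrom = "chrT")
  # covers only 3 bins < min_bins
  sparse <- track(data.frame(chrom = "chrT", start = c(0, 100, 200),
                             end = c(100, 200, 300), value = c(1, 2, 3)))
  cr <- correlate_profile_tracks(prof, sparse)
  expect_true(all(is.na(cr$r)))
  expect_equal(unname(cr$n_bins[1, 1]), 3L)
})

test_that("negated signals correlate at -1", {
  prof <- make_block_profile(8, list(c(0, 4, 0)), bin_size_bp = 100L)
  bins <- profile_bins(prof)
  neg <- track(data.frame(chrom = bins$chrom, start = bins$start,
                          end = bins$end,
                          value = 1 - as.numeric(prof$abundance[1, ])))
  cr <- correlate_profile_tracks(prof, neg)
  expect_equal(unname(cr$r[1, 1]), -1)
})

test_that("bedGraph round-trips through rtracklayer", {
  skip_if_not_installed("rtracklayer")
  prof <- make_block_profile(6, list(c(0, 3, 0)), bin_size_bp = 200L,
                             chrom = "chrT")
  tr <- synth_track(prof, 0, noise_sd = 0.5, seed = 2)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_track(tr, path)
  back <- read_track(path)
  expect_equal(back$intervals$start, tr$intervals$start)
  expect_equal(back$intervals$value, tr$intervals$value, tolerance = 1e-6)
})
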