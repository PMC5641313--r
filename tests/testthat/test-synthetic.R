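test_that("noiseless synthetic maps reproduce the forward model exactly", {
  prof <- fig3_profile()
  expect_identical(synth_contact_map(prof, noise_cv = 0)$matrix,
                   forward_contact_model(prof)$matrix)
})

test_that("a site-free profile yields the pure backbone decay", {
  prof <- make_block_profile(12, list())
  m <- synth_contact_map(prof, decay_exponent = 1.2, noise_cv = 0)$matrix
  s <- abs(outer(1:12, 1:12, "-"))
  expected <- ifelse(s > 0, s^-1.2, 1)
  expect_equal(m, expected, tolerance = 1e-12)
})

test_that("multiplicative noise has the requested coefficient of variation", {
  prof <- make_random_profile(100, 3, seed = 2)
  m0 <- synth_contact_map(prof, noise_cv = 0)$matrix
  m5 <- synth_contact_map(prof, noise_cv = 0.05, seed = 9)$matrix
  ratio <- m5[upper.tri(m5)] / m0[upper.tri(m0)]
  cv <- sd(ratio) / mean(ratio)
  expect_gt(cv, 0.04)
  expect_lt(cv, 0.06)
  # seeded purity and exact symmetry
  m5b <- synth_contact_map(prof, noise_cv = 0.05, seed = 9)$matrix
  expect_identical(m5, m5b)
  expect_identical(m5, t(m5))
  expect_error(synth_contact_map(prof, enrichment = -1), "positive")
  expect_error(synth_contact_map(prof, noise_cv = -0.1), "noise_cv")
})

test_that("planted tracks carry their type's signal", {
  prof <- fig3_profile()
  t0 <- synth_track(prof, 0, noise_sd = 0)
  expect_equal(t0$intervals$value, as.numeric(prof$abundance[1, ]))
  cr <- correlate_profile_tracks(prof, t0)
  expect_equal(unname(cr$r[1, 1]), 1)
  # heavy noise drowns the planted signal
  tn <- synth_track(prof, 0, noise_sd = 10, seed = 3)
  crn <- correlate_profile_tracks(prof, tn)
  expect_lt(abs(crn$r[1, 1]), 0.5)
  expect_error(synth_track(prof, 5, 0), "type_index")
})
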