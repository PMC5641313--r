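test_that("pure curves behave like their phases", {
  pure <- pure_curves_48()
  cc <- pure$curves$coil
  # strict decay of the coil curve on average
  expect_gt(cc[2], cc[8])
  expect_gt(cc[8], cc[32])
  # compact states keep long-range contacts the coil has lost
  long_s <- 13:47
  expect_gt(mean(pure$curves$disordered_globule[long_s] / pmax(cc[long_s], 1e-6)), 1)
  expect_gt(mean(pure$curves$ordered_globule[long_s] / pmax(cc[long_s], 1e-6)), 1)
})

test_that("a pure coil observation fits as pure coil", {
  pure <- pure_curves_48()
  obs <- structure(list(s = pure$s, p = pure$curves$coil, n_beads = 48),
                   class = "contact_curve")
  fit <- fit_mixture(obs, pure)
  expect_equal(unname(fit$fractions),
               c(1, 0, 0), tolerance = 0.01)
  expect_lt(fit$chi_squared, 1e-6)
})

test_that("constructed mixtures are recovered and scale drops out", {
  pure <- pure_curves_48()
  mix <- 0.5 * pure$curves$coil + 0.3 * pure$curves$disordered_globule +
    0.2 * pure$curves$ordered_globule
  obs <- structure(list(s = pure$s, p = mix, n_beads = 48),
                   class = "contact_curve")
  fit <- fit_mixture(obs, pure)
  expect_equal(unname(fit$fractions), c(0.5, 0.3, 0.2), tolerance = 0.02)
  # simplex constraint holds exactly
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-9)
  expect_true(all(fit$fractions >= 0))
  # overall positive scale is profiled out
  obs10 <- obs; obs10$p <- 10 * obs$p
  expect_equal(fit_mixture(obs10, pure)$fractions, fit$fractions,
               tolerance = 1e-6)
})

test_that("degenerate fit windows are refused", {
  pure <- pure_curves_48()
  obs <- structure(list(s = pure$s, p = pure$curves$coil, n_beads = 48),
                   class = "contact_curve")
  expect_error(fit_mixture(obs, pure, fit_range = c(2, 3)), "4 usable|4 separation")
})

test_that("pure-curve caches round-trip through disk", {
  cache <- withr::local_tempdir()
  # build a tiny entry by hand through the write path: reuse session curves
  pure <- pure_curves_48()
  tab <- data.frame(s = pure$s, coil = pure$curves$coil,
                    disordered_globule = pure$curves$disordered_globule,
                    ordered_globule = pure$curves$ordered_globule)
  key <- sprintf("pure_N%d_seeds%s_th%g_sc%g", 48,
                 paste(1:8, collapse = "-"), 3.5, 1)
  write.table(tab, file.path(cache, paste0(key, ".tsv")), sep = "\t",
              row.names = FALSE, quote = FALSE)
  cached <- estimate_pure_curves(48, seeds = 1:8, cache_dir = cache)
  expect_true(cached$provenance$cached)
  expect_equal(cached$curves$coil, pure$curves$coil, tolerance = 1e-10)
})
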