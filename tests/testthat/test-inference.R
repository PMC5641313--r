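test_that("forward model matches the closed-form expression", {
  # site-free: pure backbone
  empty <- make_block_profile(8, list())
  m <- forward_contact_model(empty, forward_params(1.5, 1, 10))$matrix
  s <- abs(outer(1:8, 1:8, "-"))
  expect_equal(m, ifelse(s > 0, s^-1.5, 1), tolerance = 1e-15)

  # one shared type doubles the backbone below saturation
  two <- make_block_profile(6, list(c(0, 1, 0), c(5, 6, 0)))
  m2 <- forward_contact_model(two, forward_params(1, 1, 10))$matrix
  expect_equal(m2[1, 6], 2 * 5^-1)

  # 4-bead block profile, every pair hand-evaluated
  p4 <- make_block_profile(4, list(c(0, 2, 0), c(2, 4, 1)))
  m4 <- forward_contact_model(p4, forward_params(1, 1, 10))$matrix
  expected <- rbind(
    c(1,   2,   1/2, 1/3),
    c(2,   1,   1,   1/2),
    c(1/2, 1,   1,   2),
    c(1/3, 1/2, 2,   1))
  expect_equal(m4, expected, tolerance = 1e-15)
  # saturation caps entries
  msat <- forward_contact_model(p4, forward_params(1, 10, 3))$matrix
  expect_equal(msat[1, 2], 3)
})

test_that("inference cost equals its definition", {
  prof <- fig3_profile()
  m <- forward_contact_model(prof)
  expect_equal(inference_cost(m, m, prof, 0), 0)
  expect_equal(inference_cost(m, m, prof, 0.1), 0.1 * 40 / 40)

  a <- random_sym_map(12, 21); b <- random_sym_map(12, 22)
  off <- row(a) != col(a)
  oracle <- mean(abs(a[off] / mean(a[off]) - b[off] / mean(b[off]))) +
    0.05 * sum(prof$abundance) / prof$n_beads
  expect_equal(inference_cost(contact_map(a), contact_map(b), prof, 0.05),
               oracle, tolerance = 1e-15)
  expect_error(inference_cost(matrix(1, 3, 3), matrix(1, 4, 4), prof, 0),
               "mismatch")
})

test_that("map Pearson agrees with the covariance formula", {
  a <- random_sym_map(20, 31)
  expect_equal(map_pearson(a, a), 1)
  expect_equal(map_pearson(a, 5 - a), -1)
  b <- random_sym_map(20, 32)
  ua <- a[upper.tri(a)]; ub <- b[upper.tri(b)]
  oracle <- mean((ua - mean(ua)) * (ub - mean(ub))) /
    (sqrt(mean((ua - mean(ua))^2)) * sqrt(mean((ub - mean(ub))^2)))
  expect_equal(map_pearson(a, b), oracle, tolerance = 1e-12)
  expect_error(map_pearson(a, matrix(1, 20, 20)), "variance")
})

test_that("annealer recovers a single uniform block and keeps its trace monotone", {
  # saturation below the enriched level imprints a shape the backbone alone
  # cannot mimic, making the uniform block identifiable under the
  # scale-invariant cost
  all1 <- make_block_profile(12, list(c(0, 12, 0)))
  fw <- forward_params(saturation = 1.5)
  dmap <- forward_contact_model(all1, fw)
  inf <- infer_binding_profile(dmap, 1, fw,
                               anneal = anneal_params(n_sweeps = 80, seed = 2))
  expect_equal(unname(inf$profile$abundance[1, ]), rep(1L, 12))
  expect_true(all(diff(inf$cost_trace) <= 0))
  expect_equal(inf$pearson_r, 1, tolerance = 1e-12)
  expect_error(infer_binding_profile(dmap, 0), "n_types")
  expect_error(infer_binding_profile(matrix(0, 5, 5), 2), "zero")
})

test_that("type labels are gauge freedom: permuted profiles score identically", {
  prof <- fig3_profile()
  perm <- binding_profile(prof$abundance[c(2, 1), ])
  expect_equal(forward_contact_model(prof)$matrix,
               forward_contact_model(perm)$matrix)
  expect_equal(match_types(perm, prof), c(2L, 1L))
  expect_equal(profile_jaccard(perm, prof), c(1, 1))
  # matching is by best overlap, not by index, for larger type sets
  p5 <- make_random_profile(50, 5, seed = 13)
  shuffled <- binding_profile(p5$abundance[c(3, 5, 1, 2, 4), ])
  expect_equal(profile_jaccard(shuffled, p5), rep(1, 5))
})

test_that("the reported final cost is consistent with inference_cost", {
  prof <- fig3_profile()
  dmap <- synth_contact_map(prof, noise_cv = 0.05, seed = 4)
  an <- anneal_params(n_sweeps = 120, lambda_reg = 0.02, seed = 6)
  inf <- infer_binding_profile(dmap, 2, forward_params(), an)
  recomputed <- inference_cost(forward_contact_model(inf$profile), dmap,
                               inf$profile, 0.02)
  expect_equal(inf$final_cost, recomputed, tolerance = 1e-10)
  # determinism
  inf2 <- infer_binding_profile(dmap, 2, forward_params(), an)
  expect_identical(inf$profile$abundance, inf2$profile$abundance)
})
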