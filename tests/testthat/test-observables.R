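test_that("gyration radius matches closed forms", {
  expect_equal(gyration_radius(matrix(c(5, 5, 5), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_equal(gyration_radius(two), 1.5)
  three <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(gyration_radius(three), sqrt(2 / 3))
})

test_that("contact maps count exactly what a brute-force loop counts", {
  # three collinear beads at unit spacing: contacts (1,2),(2,3) only
  prof3 <- make_block_profile(3, list())
  p <- sim_params(n_steps = 0, save_stride = 1)
  tr <- simulate_trajectory(build_initial_saw(prof3, seed = 1), prof3, NULL, p)
  tr$frames[[1]]$bead_positions <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  cm <- contact_map_from_ensemble(tr, threshold = 1.1, discard_fraction = 0)
  expect_equal(cm$matrix,
               rbind(c(1, 1, 0), c(1, 1, 1), c(0, 1, 1)))
  # saturation at huge threshold
  cm_inf <- contact_map_from_ensemble(tr, threshold = 1e6, discard_fraction = 0)
  expect_true(all(cm_inf$matrix == 1))

  # seeded 20-bead frames vs an O(n^2) double loop, exact equality
  prof <- make_block_profile(20, list())
  p2 <- sim_params(n_steps = 2000, save_stride = 250)
  ens <- run_ensemble(prof, NULL, p2, 2, c(3, 4))
  got <- contact_map_from_ensemble(ens, threshold = 2.5, discard_fraction = 0.5)
  acc <- matrix(0, 20, 20); nf <- 0
  for (tr in ens) {
    frames <- tr$frames[(floor(0.5 * length(tr$frames)) + 1):length(tr$frames)]
    for (fr in frames) {
      for (i in 1:20) for (j in 1:20) {
        d <- fr$bead_positions[i, ] - fr$bead_positions[j, ]
        d <- d - tr$box_side * round(d / tr$box_side)
        if (sum(d^2) < 2.5^2) acc[i, j] <- acc[i, j] + 1
      }
      nf <- nf + 1
    }
  }
  expect_equal(got$matrix, acc / nf, tolerance = 1e-15)
  expect_error(contact_map_from_ensemble(ens, threshold = -1), "threshold")
  expect_error(contact_map_from_ensemble(ens, discard_fraction = 1), "discard")
})

test_that("P(s) equals per-antidiagonal means", {
  all1 <- contact_map(matrix(1, 6, 6))
  expect_equal(contact_curve(all1)$p, rep(1, 5))
  ident <- contact_map(diag(6))
  expect_equal(contact_curve(ident)$p, rep(0, 5))
  m <- random_sym_map(15, seed = 6)
  cc <- contact_curve(contact_map(m))
  oracle <- sapply(1:14, function(s) {
    v <- c()
    for (i in 1:(15 - s)) v <- c(v, m[i, i + s])
    mean(v)
  })
  expect_equal(cc$p, oracle, tolerance = 1e-15)
})

test_that("scaling exponent recovery on exact power laws", {
  n <- c(16, 32, 64, 128)
  fit <- estimate_scaling_exponent(n, 0.45 * n^0.588)
  expect_equal(fit$nu, 0.588, tolerance = 1e-10)
  expect_equal(fit$amplitude, 0.45, tolerance = 1e-10)
})

test_that("a mid-collapse quench is refused as non-equilibrated", {
  prof <- make_block_profile(64, list(c(0, 64, 0)))
  binders <- binder_spec(64, 4)
  p <- sim_params(n_steps = 20000, timestep = 0.008, save_stride = 200,
                  box_side = 20)
  ens <- run_ensemble(prof, binders, p, 2, c(1, 2), start = "saw")
  expect_error(classify_phase(ens, binders), "plateau|more steps")
})
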