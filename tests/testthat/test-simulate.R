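test_that("initial self-avoiding walks respect bond length and excluded volume", {
  prof <- make_block_profile(50, list())
  c1 <- build_initial_saw(prof, seed = 3)
  expect_equal(nrow(c1$bead_positions), 50)
  # unit bonds
  bl <- sqrt(rowSums(diff(c1$bead_positions)^2))
  expect_equal(bl, rep(1, 49), tolerance = 1e-12)
  # brute-force pairwise check on non-consecutive beads (minimum image)
  box <- c1$box_side
  mind <- Inf
  for (i in 1:48) for (j in (i + 2):50) {
    d <- c1$bead_positions[i, ] - c1$bead_positions[j, ]
    d <- d - box * round(d / box)
    mind <- min(mind, sqrt(sum(d^2)))
  }
  expect_gte(mind, 0.8)
  # determinism
  c2 <- build_initial_saw(prof, seed = 3)
  expect_identical(c1$bead_positions, c2$bead_positions)
  # single bead at the origin
  expect_equal(build_initial_saw(make_block_profile(1, list()))$bead_positions,
               matrix(0, 1, 3))
})

test_that("an impossible box is reported with its side", {
  prof <- make_block_profile(300, list())
  expect_error(build_initial_saw(prof, box_side = 4, seed = 1),
               "box_side|4\\.00")
})

test_that("binders are placed without overlaps", {
  prof <- make_block_profile(20, list(c(0, 20, 0)))
  binders <- binder_spec(30, 1)
  conf <- build_initial_saw(prof, binders, box_side = 8, seed = 2)
  expect_equal(nrow(conf$binder_positions), 30)
  all_pos <- rbind(conf$bead_positions, conf$binder_positions)
  n <- nrow(all_pos)
  mind <- Inf
  for (i in 21:n) for (j in 1:(i - 1)) {
    d <- all_pos[i, ] - all_pos[j, ]
    d <- d - 8 * round(d / 8)
    mind <- min(mind, sqrt(sum(d^2)))
  }
  expect_gte(mind, 0.8)
})

test_that("trajectories are bitwise reproducible for a fixed seed", {
  prof <- fig3_profile()
  binders <- binder_spec(c(10, 10), c(2, 2))
  conf <- build_initial_saw(prof, binders, box_side = 12, seed = 5)
  p <- sim_params(n_steps = 2000, save_stride = 500, seed = 9, box_side = 12)
  t1 <- simulate_trajectory(conf, prof, binders, p)
  t2 <- simulate_trajectory(conf, prof, binders, p)
  expect_identical(t1$frames[[length(t1$frames)]]$bead_positions,
                   t2$frames[[length(t2$frames)]]$bead_positions)
  p2 <- p; p2$seed <- 10L
  t3 <- simulate_trajectory(conf, prof, binders, p2)
  expect_false(identical(t1$frames[[5]]$bead_positions,
                         t3$frames[[5]]$bead_positions))
})

test_that("zero-temperature dynamics is deterministic damped relaxation to the bond minimum", {
  prof <- make_block_profile(20, list())
  conf <- build_initial_saw(prof, seed = 1)
  p <- sim_params(n_steps = 3000, temperature = 0, save_stride = 1000)
  t1 <- simulate_trajectory(conf, prof, NULL, p)
  t2 <- simulate_trajectory(conf, prof, NULL, p)
  final1 <- t1$frames[[length(t1$frames)]]$bead_positions
  expect_identical(final1, t2$frames[[length(t2$frames)]]$bead_positions)
  # bonds relax to the FENE+WCA force balance near 0.961 sigma
  bl <- sqrt(rowSums(diff(final1)^2))
  r_star <- uniroot(function(r) -30 * r / (1 - r^2 / 2.25) +
                      24 * (2 * r^-13 - r^-7), c(0.9, 1.1))$root
  expect_equal(mean(bl), r_star, tolerance = 1e-3)
})

test_that("saved frames keep bonds intact and energies finite", {
  prof <- fig3_profile()
  binders <- binder_spec(c(15, 15), c(3, 3))
  p <- sim_params(n_steps = 10000, save_stride = 500)
  tr <- run_ensemble(prof, binders, p, 1, 42)[[1]]
  for (fr in tr$frames) {
    bl <- sqrt(rowSums(diff(fr$bead_positions)^2))
    expect_lt(max(bl), 1.5)
  }
  expect_true(all(is.finite(as.matrix(tr$energies))))
  expect_true(all(diff(tr$times) > 0))
})

test_that("a too-large timestep fails loudly with the step index", {
  prof <- make_block_profile(24, list(c(0, 24, 0)))
  binders <- binder_spec(48, 12)
  conf <- build_initial_saw(prof, binders, box_side = 7, seed = 2)
  p <- sim_params(n_steps = 20000, timestep = 0.05, box_side = 7)
  expect_error(simulate_trajectory(conf, prof, binders, p),
               "step|timestep")
})

test_that("ensembles are replica-independent and seed-order equivariant", {
  prof <- make_block_profile(16, list())
  p <- sim_params(n_steps = 2000, save_stride = 500)
  expect_error(run_ensemble(prof, NULL, p, 2, c(7, 7)), "duplicate")
  e12 <- run_ensemble(prof, NULL, p, 2, c(1, 2))
  e21 <- run_ensemble(prof, NULL, p, 2, c(2, 1))
  last <- function(tr) tr$frames[[length(tr$frames)]]$bead_positions
  expect_identical(last(e12[[1]]), last(e21[[2]]))
  expect_identical(last(e12[[2]]), last(e21[[1]]))
  expect_false(identical(last(e12[[1]]), last(e12[[2]])))
  # single replica reproduces a manual run
  single <- run_ensemble(prof, NULL, p, 1, 5)
  conf <- build_initial_saw(prof, NULL, single[[1]]$box_side, seed = 5)
  p2 <- p; p2$seed <- 5L; p2$box_side <- single[[1]]$box_side
  manual <- simulate_trajectory(conf, prof, NULL, p2)
  expect_identical(last(single[[1]]), last(manual))
})

test_that("zero-affinity binders leave the coil Rg unchanged within error", {
  prof <- make_block_profile(24, list(c(0, 24, 0)))
  p <- sim_params(n_steps = 30000, save_stride = 250, box_side = 16)
  free <- run_ensemble(prof, NULL, p, 10, 1:10)
  inert <- run_ensemble(prof, binder_spec(20, 0), p, 10, 11:20)
  rg_free <- sapply(free, function(tr) equilibrium_rg(tr))
  rg_inert <- sapply(inert, function(tr) equilibrium_rg(tr))
  se <- sqrt(var(rg_free) / 10 + var(rg_inert) / 10)
  expect_lt(abs(mean(rg_free) - mean(rg_inert)), 2.5 * se + 0.05)
})
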