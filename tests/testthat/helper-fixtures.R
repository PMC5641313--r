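# Shared fixtures and a lazy cache so expensive simulations run once per
# test session and are reused by every file that needs them.

.sbs_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sbs_test_cache, inherits = FALSE))
    assign(key, force(expr), envir = .sbs_test_cache)
  get(key, envir = .sbs_test_cache, inherits = FALSE)
}

# the alternating two-type block layout (four blocks of ten beads)
fig3_profile <- function() {
  make_block_profile(40, list(c(0, 10, 0), c(10, 20, 1),
                              c(20, 30, 0), c(30, 40, 1)))
}

# symmetric non-negative random matrix with unit diagonal
random_sym_map <- function(n, seed) {
  r <- local_seed(seed, matrix(runif(n * n), n, n))
  m <- (r + t(r)) / 2
  diag(m) <- 1
  m
}

local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# binder-free coil ensembles per chain length (10 seeds)
coil_ensemble <- function(N) {
  steps <- c(`16` = 60000, `32` = 80000, `64` = 160000, `128` = 300000)
  cached(paste0("coil_", N), {
    prof <- make_block_profile(N, list())
    p <- sim_params(n_steps = steps[[as.character(N)]], save_stride = 250)
    run_ensemble(prof, NULL, p, 10, 1:10)
  })
}

# strong-binding homopolymer globule ensembles (compact start, 10 seeds)
globule_ensemble <- function(N) {
  cached(paste0("glob_", N), {
    prof <- make_block_profile(N, list(c(0, N, 0)))
    binders <- binder_spec(N, 4)
    p <- sim_params(n_steps = max(40000, 600 * N), timestep = 0.008,
                    save_stride = 400)
    run_ensemble(prof, binders, p, 10, 1:10, start = "compact")
  })
}

# high c / high affinity corner (ordered globule)
ordered_ensemble <- function() {
  cached("ordered_64", {
    prof <- make_block_profile(64, list(c(0, 64, 0)))
    binders <- binder_spec(128, 9)
    p <- sim_params(n_steps = 50000, timestep = 0.004, save_stride = 400)
    list(ens = run_ensemble(prof, binders, p, 4, 1:4, start = "compact"),
         binders = binders)
  })
}

pure_curves_48 <- function() {
  cached("pure48",
         estimate_pure_curves(48, seeds = 1:8,
                              cache_dir = file.path(tempdir(), "sbs_pure")))
}
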