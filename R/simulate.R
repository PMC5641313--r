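#' Binder species specification
#'
#' Describes the diffusing binder particles of the SBS system: how many
#' binders of each type are present (the concentration `c`, given the box
#' volume) and their binding affinity `E_X` to cognate beads, in kT units.
#'
#' @param counts integer vector, number of binders per type.
#' @param affinities numeric vector, binding affinity per type (kT); well
#'   depth of the bead-binder attraction, scaled by the bead's site copy
#'   number.
#' @param interaction_range attraction cutoff in bead diameters; must exceed
#'   the hard-core contact distance of 1 diameter.
#' @return An object of class `binder_spec`.
#' @export
binder_spec <- function(counts, affinities, interaction_range = 1.5) {
  if (length(counts) != length(affinities))
    stop("counts and affinities must have one entry per binder type")
  if (any(counts < 0)) stop("binder counts must be non-negative")
  if (any(affinities < 0)) stop("affinities must be >= 0")
  if (interaction_range <= 1) stop("interaction_range must exceed 1 diameter")
  structure(list(counts = as.integer(counts), affinities = as.numeric(affinities),
                 interaction_range = interaction_range, n_types = length(counts)),
            class = "binder_spec")
}

#' Simulation parameters
#'
#' Parameters of the underdamped Langevin (BAOAB) integrator in reduced
#' units: bead diameter sigma = 1, energy kT = 1, time tau = 1, mass 1.
#'
#' @param n_steps number of integration steps.
#' @param timestep integration timestep in tau; 0.01 is safe for the default
#'   force field, use smaller values for deep binding wells.
#' @param friction Langevin friction coefficient (1/tau).
#' @param temperature temperature in kT.
#' @param box_side periodic cubic box side in bead diameters; see
#'   [default_box_side].
#' @param seed integer seed; identical seed and parameters give an identical
#'   trajectory on one platform.
#' @param save_stride store one frame every `save_stride` steps.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_steps, timestep = 0.01, friction = 0.5,
                       temperature = 1, box_side = NULL, seed = 1L,
                       save_stride = 1000L) {
  if (timestep <= 0) stop("timestep must be positive")
  if (n_steps < 0) stop("n_steps must be >= 0")
  if (save_stride < 1) stop("save_stride must be >= 1")
  structure(list(n_steps = as.integer(n_steps), timestep = timestep,
                 friction = friction, temperature = temperature,
                 box_side = box_side, seed = as.integer(seed),
                 save_stride = as.integer(save_stride)),
            class = "sim_params")
}

#' Default periodic box side
#'
#' For systems with binders the box is sized so that the bead plus binder
#' volume fraction is `phi` (default 0.1), which fixes the binder
#' concentration `c = counts / box^3`. For binder-free (or zero-affinity)
#' chains a dilute box is returned, wide enough that a self-avoiding coil
#' does not interact with its periodic images.
#'
#' @param profile a [binding_profile].
#' @param binders a [binder_spec] or `NULL`.
#' @param phi target volume fraction for binder systems.
#' @return box side in bead diameters.
#' @export
default_box_side <- function(profile, binders = NULL, phi = 0.1) {
  n <- profile$n_beads
  dilute <- 3.5 * (0.45 * n^0.588) * 2   # ~3.5 coil diameters
  if (is.null(binders) || sum(binders$counts) == 0 ||
      all(binders$affinities == 0))
    return(max(6, dilute))
  n_tot <- n + sum(binders$counts)
  max(4, (n_tot * pi / 6 / phi)^(1 / 3))
}

new_conformation <- function(bead_positions, binder_positions, time, box_side) {
  structure(list(bead_positions = bead_positions,
                 binder_positions = binder_positions,
                 time = time, box_side = box_side),
            class = "conformation")
}

#' Initial self-avoiding-walk conformation
#'
#' Grows the bead chain as a self-avoiding walk with bond length 1.0 and a
#' hard-core exclusion of 0.95 diameters between non-consecutive beads
#' (minimum-image distances in the periodic box), then scatters the binders
#' uniformly in the box with the same exclusion. The margin above the 0.8
#' contact limit keeps startup core forces mild even under deep binding
#' wells. Growth backtracks on dead ends; a box too small to host the chain
#' raises an error naming the box side.
#'
#' @param profile a [binding_profile].
#' @param binders a [binder_spec] or `NULL` for a binder-free chain.
#' @param box_side periodic box side; defaults to [default_box_side].
#' @param seed integer seed; the conformation is deterministic given it.
#' @return A `conformation` with bead and binder coordinates.
#' @export
build_initial_saw <- function(profile, binders = NULL, box_side = NULL,
                              seed = 1L) {
  n <- profile$n_beads
  if (n < 1) stop("need at least one bead")
  if (is.null(box_side)) box_side <- default_box_side(profile, binders)
  min_d2 <- 0.95^2   # above the 0.8 contract: keeps startup core forces mild
  mi <- function(d) d - box_side * round(d / box_side)
  rng <- local_rng(seed)
  on.exit(rng$restore())

  pos <- matrix(0, nrow = n, ncol = 3)
  i <- 2L
  fails <- integer(n)
  while (i <= n) {
    placed <- FALSE
    for (try in 1:60) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- pos[i - 1L, ] + u
      if (i > 2L) {
        prev <- pos[1:(i - 2L), , drop = FALSE]
        d2 <- rowSums(mi(sweep(prev, 2, cand))^2)
        if (any(d2 < min_d2)) next
      }
      pos[i, ] <- cand
      placed <- TRUE
      break
    }
    if (placed) {
      i <- i + 1L
    } else {
      fails[i] <- fails[i] + 1L
      if (fails[i] > 200)
        stop(sprintf("could not grow a self-avoiding walk of %d beads in a box of side %.2f; increase box_side",
                     n, box_side))
      i <- max(2L, i - 5L)   # backtrack a few beads and regrow
    }
  }

  n_binders <- if (is.null(binders)) 0L else sum(binders$counts)
  bpos <- matrix(numeric(0), nrow = 0, ncol = 3)
  if (n_binders > 0) {
    bpos <- matrix(0, nrow = n_binders, ncol = 3)
    all_pos <- pos
    for (b in seq_len(n_binders)) {
      ok <- FALSE
      for (try in 1:2000) {
        cand <- runif(3, -box_side / 2, box_side / 2)
        d2 <- rowSums(mi(sweep(all_pos, 2, cand))^2)
        if (all(d2 >= min_d2)) { ok <- TRUE; break }
      }
      if (!ok)
        stop(sprintf("could not place binder %d without overlap in a box of side %.2f; increase box_side",
                     b, box_side))
      bpos[b, ] <- cand
      all_pos <- rbind(all_pos, cand)
    }
  }
  new_conformation(pos, bpos, time = 0, box_side = box_side)
}

#' Compact initial conformation for globule-phase sampling
#'
#' Grows the chain as a random walk confined to a sphere of radius
#' `0.85 * n_beads^(1/3)` (bond length 1.0, hard core 0.95), a standard
#' equilibration aid when the equilibrium state is compact: sampling the
#' globule from a pre-collapsed start avoids the slow coarsening dynamics
#' of a coil-to-globule quench. Binders are scattered uniformly in the box.
#'
#' @inheritParams build_initial_saw
#' @return A `conformation`.
#' @export
build_compact_start <- function(profile, binders = NULL, box_side = NULL,
                                seed = 1L) {
  n <- profile$n_beads
  if (n < 1) stop("need at least one bead")
  if (is.null(box_side)) box_side <- default_box_side(profile, binders)
  radius <- max(2, 0.85 * n^(1 / 3) + 0.5)
  min_d2 <- 0.95^2   # above the 0.8 contract: keeps startup core forces mild
  rng <- local_rng(seed)
  on.exit(rng$restore())
  pos <- matrix(0, nrow = n, ncol = 3)
  i <- 2L
  fails <- integer(n)
  while (i <= n) {
    placed <- FALSE
    for (try in 1:120) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- pos[i - 1L, ] + u
      if (sum(cand^2) > radius^2) next
      if (i > 2L) {
        prev <- pos[1:(i - 2L), , drop = FALSE]
        if (any(rowSums(sweep(prev, 2, cand)^2) < min_d2)) next
      }
      pos[i, ] <- cand
      placed <- TRUE
      break
    }
    if (placed) i <- i + 1L
    else {
      fails[i] <- fails[i] + 1L
      if (fails[i] > 400)
        stop(sprintf("could not grow a compact chain of %d beads; box %.2f",
                     n, box_side))
      i <- max(2L, i - 8L)
    }
  }
  n_binders <- if (is.null(binders)) 0L else sum(binders$counts)
  bpos <- matrix(numeric(0), nrow = 0, ncol = 3)
  if (n_binders > 0) {
    mi <- function(d) d - box_side * round(d / box_side)
    bpos <- matrix(0, nrow = n_binders, ncol = 3)
    all_pos <- pos
    for (b in seq_len(n_binders)) {
      ok <- FALSE
      for (try in 1:2000) {
        cand <- runif(3, -box_side / 2, box_side / 2)
        if (all(rowSums(mi(sweep(all_pos, 2, cand))^2) >= min_d2)) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        stop(sprintf("could not place binder %d in a box of side %.2f; increase box_side",
                     b, box_side))
      bpos[b, ] <- cand
      all_pos <- rbind(all_pos, cand)
    }
  }
  new_conformation(pos, bpos, time = 0, box_side = box_side)
}

binder_type_vector <- function(binders) {
  if (is.null(binders) || sum(binders$counts) == 0) return(integer(0))
  rep(seq_along(binders$counts) - 1L, times = binders$counts)
}

#' Run Langevin dynamics of the bead-binder system
#'
#' Integrates the SBS system with the BAOAB Langevin scheme under FENE bonds
#' between consecutive beads, purely repulsive excluded volume between all
#' particle pairs, and a short-range attractive well of depth
#' `affinity * abundance` between binders and their cognate beads, in a
#' periodic cubic box. The same seed and parameters reproduce the
#' trajectory bitwise on one platform.
#'
#' @param start a `conformation` from [build_initial_saw] (or a previous
#'   trajectory's last frame).
#' @param profile a [binding_profile]; sizes must match `start`.
#' @param binders a [binder_spec] or `NULL`; must cover `profile$n_types`
#'   types when binders are present.
#' @param params a [sim_params]. `params$box_side`, when set, must match the
#'   conformation's box.
#' @return An object of class `sbs_trajectory`: `frames` (conformations
#'   sampled every `save_stride` steps, including the start), `times`,
#'   per-frame potential/kinetic `energies`, and `provenance`.
#' @export
simulate_trajectory <- function(start, profile, binders = NULL, params) {
  stopifnot(inherits(start, "conformation"), inherits(params, "sim_params"))
  if (nrow(start$bead_positions) != profile$n_beads)
    stop("start conformation and profile disagree on n_beads")
  n_binders <- if (is.null(binders)) 0L else sum(binders$counts)
  if (nrow(start$binder_positions) != n_binders)
    stop("start conformation and binder_spec disagree on binder count")
  if (!is.null(binders) && binders$n_types < profile$n_types)
    stop("binder_spec must define every binding-site type of the profile")
  box <- if (!is.null(params$box_side)) params$box_side else start$box_side
  if (abs(box - start$box_side) > 1e-12)
    stop("params$box_side disagrees with the start conformation's box")
  affin <- if (is.null(binders)) numeric(profile$n_types) else binders$affinities
  rng_range <- if (is.null(binders)) 1.5 else binders$interaction_range

  res <- cpp_run_langevin(start$bead_positions, start$binder_positions,
                          profile$abundance, binder_type_vector(binders),
                          affin, box, params$timestep, params$friction,
                          params$temperature, params$n_steps,
                          params$save_stride, params$seed, rng_range)
  frames <- lapply(res$frames, function(f)
    new_conformation(f$bead_positions, f$binder_positions, f$time, box))
  energies <- data.frame(time = res$times, bond = res$e_bond,
                         pair = res$e_pair, kinetic = res$e_kinetic)
  structure(list(frames = frames, times = res$times, energies = energies,
                 box_side = box,
                 provenance = list(profile = profile, binders = binders,
                                   params = params, seed = params$seed)),
            class = "sbs_trajectory")
}

#' @export
print.sbs_trajectory <- function(x, ...) {
  nb <- nrow(x$frames[[1]]$bead_positions)
  ns <- nrow(x$frames[[1]]$binder_positions)
  cat(sprintf("sbs_trajectory: %d frames, %d beads + %d binders, t in [%g, %g], box %.2f\n",
              length(x$frames), nb, ns, min(x$times), max(x$times), x$box_side))
  invisible(x)
}

#' Run an ensemble of independent trajectories
#'
#' Each replica grows its own initial self-avoiding walk and integrates with
#' its own seed, so replica `i` depends only on `seed_list[i]`.
#'
#' @inheritParams simulate_trajectory
#' @param n_replicas number of replicas.
#' @param seed_list distinct integer seeds, one per replica.
#' @param start `"saw"` (open self-avoiding walk, the folding-dynamics view)
#'   or `"compact"` (pre-collapsed, see [build_compact_start]) initial
#'   conformation.
#' @return A list of `sbs_trajectory`, in the order of `seed_list`.
#' @export
run_ensemble <- function(profile, binders = NULL, params, n_replicas,
                         seed_list = seq_len(n_replicas),
                         start = c("saw", "compact")) {
  start <- match.arg(start)
  if (length(seed_list) != n_replicas)
    stop("seed_list must have n_replicas entries")
  if (anyDuplicated(seed_list))
    stop("seed_list has duplicate seeds; the ensemble would be degenerate")
  box <- if (!is.null(params$box_side)) params$box_side else
    default_box_side(profile, binders)
  builder <- if (start == "saw") build_initial_saw else build_compact_start
  lapply(seed_list, function(s) {
    p <- params
    p$seed <- as.integer(s)
    p$box_side <- box
    conf <- builder(profile, binders, box, seed = s)
    simulate_trajectory(conf, profile, binders, p)
  })
}
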