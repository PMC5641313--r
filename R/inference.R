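#' Mean-field forward contact model parameters
#'
#' The forward model maps a binding profile to an expected contact map
#' without running dynamics: a power-law backbone decay `s^-decay_exponent`
#' boosted by `1 + enrichment * (shared binding-type product)` and capped at
#' `saturation`. It is the surrogate the annealer optimizes against; the
#' inferred profile can then be handed to [run_ensemble] for a full 3D
#' reconstruction.
#'
#' @param decay_exponent positive backbone decay exponent.
#' @param enrichment positive contact gain per shared-type product.
#' @param saturation positive cap on entries.
#' @return An object of class `forward_params`.
#' @export
forward_params <- function(decay_exponent = 1, enrichment = 1,
                           saturation = 10) {
  if (decay_exponent <= 0 || enrichment <= 0 || saturation <= 0)
    stop("forward-model parameters must all be positive")
  structure(list(decay_exponent = decay_exponent, enrichment = enrichment,
                 saturation = saturation),
            class = "forward_params")
}

#' Forward contact map of a binding profile
#'
#' Entry (i, j), i != j, is
#' `min(saturation, |i-j|^-decay * (1 + enrichment * sum_t a[t,i] a[t,j]))`;
#' the diagonal is 1. Deterministic and symmetric.
#'
#' @param profile a [binding_profile].
#' @param params a [forward_params].
#' @return A [contact_map].
#' @export
forward_contact_model <- function(profile, params = forward_params()) {
  n <- profile$n_beads
  if (n < 2) stop("need at least 2 beads")
  shared <- crossprod(profile$abundance)        # n x n shared-type products
  s <- abs(outer(seq_len(n), seq_len(n), "-"))
  backbone <- matrix(0, n, n)
  backbone[s > 0] <- s[s > 0]^(-params$decay_exponent)
  m <- pmin(backbone * (1 + params$enrichment * shared), params$saturation)
  diag(m) <- 1
  contact_map(m, profile$chrom, profile$genomic_start, profile$bin_size_bp)
}

#' Inference cost between a model and a data contact map
#'
#' Mean absolute difference of the two maps over off-diagonal entries after
#' each map is scaled to unit off-diagonal mean (contact data are
#' count-valued, so only relative structure is compared), plus an L0
#' sparsity penalty `lambda_reg * total_sites / n_beads` that keeps the
#' annealer from painting sites everywhere.
#'
#' @param model_map,data_map [contact_map]s (or matrices) of equal size.
#' @param profile the [binding_profile] whose site count is penalized.
#' @param lambda_reg non-negative sparsity penalty.
#' @return the scalar cost (>= 0).
#' @export
inference_cost <- function(model_map, data_map, profile, lambda_reg = 0) {
  m <- as_contact_matrix(model_map)
  d <- as_contact_matrix(data_map)
  if (!all(dim(m) == dim(d)))
    stop(sprintf("dimension mismatch: model %dx%d vs data %dx%d",
                 nrow(m), ncol(m), nrow(d), ncol(d)))
  off <- row(m) != col(m)
  ms <- m[off] / mean(m[off])
  ds <- d[off] / mean(d[off])
  mean(abs(ms - ds)) + lambda_reg * sum(profile$abundance) / profile$n_beads
}

#' Pearson correlation between two contact maps
#'
#' Computed over upper-triangle off-diagonal entries only, the convention
#' used to score model-vs-experiment agreement of Hi-C matrices.
#'
#' @param map_a,map_b [contact_map]s (or matrices) of equal size.
#' @return Pearson r in `[-1, 1]`.
#' @export
map_pearson <- function(map_a, map_b) {
  a <- as_contact_matrix(map_a)
  b <- as_contact_matrix(map_b)
  if (!all(dim(a) == dim(b))) stop("dimension mismatch between maps")
  up <- upper.tri(a)
  if (sd(a[up]) == 0 || sd(b[up]) == 0)
    stop("zero variance in a map's upper triangle; Pearson undefined")
  cor(a[up], b[up])
}

#' Annealing parameters for profile inference
#'
#' @param n_sweeps sweeps per restart (one sweep = `n_types * n_beads`
#'   proposed single-site flips).
#' @param T_start starting temperature; `NA` auto-calibrates it from 100
#'   probe moves so the initial uphill acceptance is about 50%.
#' @param T_end temperature floor.
#' @param cooling geometric cooling factor per sweep, in (0, 1).
#' @param lambda_reg sparsity penalty (see [inference_cost]).
#' @param n_restarts independent restarts; the best profile is returned.
#' @param seed integer seed; the whole optimization is deterministic given
#'   it.
#' @return An object of class `anneal_params`.
#' @export
anneal_params <- function(n_sweeps = 300, T_start = NA, T_end = 1e-5,
                          cooling = 0.95, lambda_reg = 0.02, n_restarts = 1,
                          seed = 1L) {
  if (!is.na(T_start) && T_start <= T_end)
    stop("need T_start > T_end > 0")
  if (T_end <= 0) stop("T_end must be positive")
  if (cooling <= 0 || cooling >= 1) stop("cooling must be in (0, 1)")
  if (lambda_reg < 0) stop("lambda_reg must be >= 0")
  structure(list(n_sweeps = as.integer(n_sweeps), T_start = T_start,
                 T_end = T_end, cooling = cooling, lambda_reg = lambda_reg,
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed)),
            class = "anneal_params")
}

#' Infer a binding profile from a contact map
#'
#' Simulated-annealing Monte-Carlo over binary site occupancies: each move
#' flips one site of one type at one bead, accepted by the Metropolis rule
#' at the current temperature under the [inference_cost] objective against
#' the mean-field forward model; temperatures cool geometrically and the
#' best profile over all restarts is returned. Equal-cost proposals are
#' accepted, keeping the chain mobile on cost plateaus.
#'
#' @param data_map a symmetric non-negative [contact_map] (or matrix).
#' @param n_types number of binding-site types to infer.
#' @param forward a [forward_params].
#' @param anneal an [anneal_params].
#' @return An object of class `sbs_inference`: `profile` (the inferred
#'   [binding_profile]), `final_cost`, non-increasing best-so-far
#'   `cost_trace` (one entry per sweep), and `pearson_r` between the
#'   profile's forward map and the data.
#' @export
infer_binding_profile <- function(data_map, n_types,
                                  forward = forward_params(),
                                  anneal = anneal_params()) {
  d <- as_contact_matrix(data_map)
  if (n_types < 1) stop("n_types must be >= 1")
  if (nrow(d) < 2 || n_types * nrow(d) == 0) stop("empty inference problem")
  if (any(d < 0)) stop("data map has negative entries")
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(d)))
    stop("data map must be symmetric")
  if (sum(d[row(d) != col(d)]) == 0)
    stop("contact map has zero off-diagonal mass; nothing to fit")
  T_start <- if (is.na(anneal$T_start)) -1 else anneal$T_start
  res <- cpp_anneal(d, as.integer(n_types), forward$decay_exponent,
                    forward$enrichment, forward$saturation,
                    anneal$n_sweeps, T_start, anneal$T_end, anneal$cooling,
                    anneal$lambda_reg, anneal$n_restarts, anneal$seed)
  meta <- if (inherits(data_map, "contact_map")) data_map else
    contact_map(d)
  profile <- binding_profile(res$abundance, meta$bin_size_bp,
                             meta$genomic_start, meta$chrom)
  fwd <- forward_contact_model(profile, forward)
  structure(list(profile = profile, final_cost = res$final_cost,
                 cost_trace = res$cost_trace,
                 pearson_r = map_pearson(fwd, d),
                 forward = forward, anneal = anneal),
            class = "sbs_inference")
}

#' @export
print.sbs_inference <- function(x, ...) {
  cat(sprintf("sbs_inference: %d types x %d beads, final cost %.4f, map Pearson r = %.3f\n",
              x$profile$n_types, x$profile$n_beads, x$final_cost, x$pearson_r))
  invisible(x)
}

#' Optimal type matching between two profiles
#'
#' Binding-site types are only identifiable up to relabelling, so recovered
#' profiles are scored after the assignment of inferred to reference types
#' that maximizes total overlap (maximum-weight bipartite matching).
#'
#' @param inferred,reference [binding_profile]s on the same beads.
#' @return integer vector `m`: inferred type `t` corresponds to reference
#'   type `m[t]` (`NA` for unmatched types).
#' @export
match_types <- function(inferred, reference) {
  A <- inferred$abundance > 0
  B <- reference$abundance > 0
  ti <- nrow(A); tr <- nrow(B)
  overlap <- A %*% t(B)            # ti x tr co-occupancy counts
  dimnames(overlap) <- list(paste0("i", seq_len(ti)), paste0("r", seq_len(tr)))
  g <- igraph::graph_from_biadjacency_matrix(overlap + 1e-9, weighted = TRUE)
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)$matching
  idx <- m[paste0("i", seq_len(ti))]
  out <- rep(NA_integer_, ti)
  matched <- !is.na(idx)
  out[matched] <- as.integer(sub("^r", "", idx[matched]))
  out
}

#' Per-type Jaccard overlap after optimal matching
#'
#' @param inferred,reference [binding_profile]s on the same beads.
#' @return numeric vector of Jaccard indices, one per reference type that
#'   received a match (unmatched reference types score 0).
#' @export
profile_jaccard <- function(inferred, reference) {
  mt <- match_types(inferred, reference)
  out <- numeric(reference$n_types)
  A <- inferred$abundance > 0
  B <- reference$abundance > 0
  for (t in seq_along(mt)) {
    if (is.na(mt[t])) next
    a <- A[t, ]; b <- B[mt[t], ]
    un <- sum(a | b)
    out[mt[t]] <- if (un == 0) 1 else sum(a & b) / un
  }
  out
}
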