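#' Binding-site profiles
#'
#' A `binding_profile` annotates each bead of the polymer (each genomic bin)
#' with the copy number of every binding-site type. It is the central object
#' of the SBS model: simulation reads it to decide which binders attract
#' which beads, and inference produces one from a contact matrix.
#'
#' @param abundance integer matrix, `n_types` rows by `n_beads` columns;
#'   entry `[t, i]` is the number of sites of type `t` on bead `i`.
#' @param bin_size_bp genomic size of one bead, in base pairs.
#' @param genomic_start 0-based start coordinate of the first bin.
#' @param chrom chromosome label.
#' @return An object of class `binding_profile` with fields `abundance`,
#'   `n_beads`, `n_types`, `bin_size_bp`, `genomic_start`, `chrom`.
#' @export
binding_profile <- function(abundance, bin_size_bp = 50000L,
                            genomic_start = 0L, chrom = "chrS") {
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("abundance entries must be non-negative")
  if (any(abundance != round(abundance)))
    stop("abundance entries must be integer copy numbers")
  storage.mode(abundance) <- "integer"
  if (bin_size_bp <= 0) stop("bin_size_bp must be positive")
  if (genomic_start < 0) stop("genomic_start must be non-negative")
  structure(list(abundance = abundance,
                 n_beads = ncol(abundance),
                 n_types = nrow(abundance),
                 bin_size_bp = as.integer(bin_size_bp),
                 genomic_start = as.integer(genomic_start),
                 chrom = chrom),
            class = "binding_profile")
}

#' @export
print.binding_profile <- function(x, ...) {
  cat(sprintf("binding_profile: %d beads x %d types, %s:%d-%d (bin %d bp), %d sites\n",
              x$n_beads, x$n_types, x$chrom, x$genomic_start,
              x$genomic_start + x$n_beads * x$bin_size_bp,
              x$bin_size_bp, sum(x$abundance)))
  invisible(x)
}

#' Build a block binding profile
#'
#' Lays out contiguous blocks of single binding-site types along the chain,
#' the classic block-copolymer toy used to illustrate TAD formation: beads
#' inside a block carry one site of that block's type, all other entries are
#' zero.
#'
#' @param n_beads chain length in beads.
#' @param blocks list of `c(start_bead, end_bead, type_index)` triplets with
#'   0-based, half-open bead ranges `[start, end)` and 0-based type indices.
#' @inheritParams binding_profile
#' @return A [binding_profile]. An empty `blocks` list gives the all-zero
#'   profile (a pure self-avoiding walk with no binding sites).
#' @examples
#' make_block_profile(4, list(c(0, 2, 0), c(2, 4, 1)))
#' @export
make_block_profile <- function(n_beads, blocks, bin_size_bp = 50000L,
                               genomic_start = 0L, chrom = "chrS") {
  n_types <- if (length(blocks) == 0) 1L else
    max(vapply(blocks, function(b) b[[3]], numeric(1))) + 1L
  ab <- matrix(0L, nrow = n_types, ncol = n_beads)
  claimed <- rep(NA_integer_, n_beads)
  for (b in blocks) {
    start <- b[[1]]; end <- b[[2]]; type <- b[[3]]
    if (start < 0 || end > n_beads || start >= end)
      stop(sprintf("invalid block [%d, %d): need 0 <= start < end <= n_beads",
                   start, end))
    if (type < 0 || type >= n_types) stop("type index out of range")
    idx <- (start + 1):end
    clash <- which(!is.na(claimed[idx]) & claimed[idx] != type)
    if (length(clash) > 0)
      stop(sprintf("block [%d, %d) of type %d overlaps beads already assigned type %d",
                   start, end, type, claimed[idx][clash[1]]))
    claimed[idx] <- type
    ab[type + 1L, idx] <- 1L
  }
  binding_profile(ab, bin_size_bp, genomic_start, chrom)
}

#' Draw a random multi-type binding profile
#'
#' Generates a planted binding-domain architecture as consecutive domains of
#' geometrically distributed length, each assigned a uniformly random type —
#' the kind of multi-colour layout inferred for real loci (for example 15
#' types over 160 bins at 50 kb for an 8 Mb region). Profiles in which some
#' type never occurs are resampled so that every type appears at least once.
#'
#' @inheritParams make_block_profile
#' @param n_types number of binding-site types (colours).
#' @param mean_domain_len mean domain length in beads (geometric run lengths).
#' @param seed integer seed; the profile is a pure function of the arguments.
#' @return A [binding_profile] with 0/1 abundance.
#' @export
make_random_profile <- function(n_beads, n_types, mean_domain_len = 6,
                                seed = 1L, bin_size_bp = 50000L,
                                genomic_start = 0L, chrom = "chrS") {
  if (n_types < 1) stop("n_types must be >= 1")
  if (n_types > n_beads) stop("n_types must not exceed n_beads")
  if (mean_domain_len < 1) stop("mean_domain_len must be >= 1")
  ab <- NULL
  rng <- local_rng(seed)
  for (attempt in 1:1000) {
    ab <- matrix(0L, nrow = n_types, ncol = n_beads)
    pos <- 1L
    while (pos <= n_beads) {
      len <- 1L + stats::rgeom(1, prob = 1 / mean_domain_len)
      type <- sample.int(n_types, 1L)
      idx <- pos:min(n_beads, pos + len - 1L)
      ab[type, idx] <- 1L
      pos <- pos + length(idx)
    }
    if (all(rowSums(ab) > 0)) break
    ab <- NULL
  }
  rng$restore()
  if (is.null(ab)) stop("could not place every type; increase n_beads")
  binding_profile(ab, bin_size_bp, genomic_start, chrom)
}

#' Bin coordinates of a profile
#'
#' @param profile a [binding_profile].
#' @return data.frame with `chrom`, `start`, `end` per bin (0-based half-open).
#' @export
profile_bins <- function(profile) {
  i <- seq_len(profile$n_beads) - 1L
  data.frame(chrom = profile$chrom,
             start = profile$genomic_start + i * profile$bin_size_bp,
             end = profile$genomic_start + (i + 1L) * profile$bin_size_bp)
}

# scoped use of R's RNG so generators are pure functions of their seed
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
}
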