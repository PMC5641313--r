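#' Synthetic contact map with a planted binding-domain architecture
#'
#' Pushes a binding profile through the mean-field forward contact model
#' (backbone distance decay times shared-type enrichment, see
#' [forward_contact_model]) and applies multiplicative log-normal noise,
#' emulating a Hi-C matrix of a locus whose folding is driven by the planted
#' domains. Hi-C counts are overdispersed, so ratio (scale-free) noise is
#' used; `noise_cv` is the coefficient of variation of the noise field.
#'
#' @param profile a [binding_profile].
#' @param decay_exponent backbone contact decay exponent (P ~ s^-decay).
#' @param enrichment contact gain per shared binding-type product.
#' @param noise_cv coefficient of variation of the multiplicative noise;
#'   `0` reproduces the forward model exactly.
#' @param seed integer seed for the noise field.
#' @param saturation cap on forward-model entries.
#' @return A [contact_map], symmetric and non-negative.
#' @export
synth_contact_map <- function(profile, decay_exponent = 1, enrichment = 1,
                              noise_cv = 0, seed = 1L, saturation = 10) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  fwd <- forward_contact_model(profile,
                               forward_params(decay_exponent, enrichment,
                                              saturation))
  m <- fwd$matrix
  if (noise_cv > 0) {
    n <- nrow(m)
    sdlog <- sqrt(log(1 + noise_cv^2))
    rng <- local_rng(seed)
    up <- upper.tri(m)
    noise <- matrix(1, n, n)
    noise[up] <- stats::rlnorm(sum(up), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    rng$restore()
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]  # mirror, diag 1
    m <- m * noise
  }
  contact_map(m, profile$chrom, profile$genomic_start, profile$bin_size_bp,
              normalized = FALSE)
}

#' Synthetic epigenomic track correlated with one binding-site type
#'
#' Emulates a chromatin feature (a ChIP-seq style signal) enriched where one
#' binding type is abundant: the per-bin signal is the abundance row of
#' `type_index` plus Gaussian noise, floored at zero.
#'
#' @param profile a [binding_profile].
#' @param type_index 0-based binding-site type to plant the signal on.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed.
#' @param name track name.
#' @return A `track` object (see [track]).
#' @export
synth_track <- function(profile, type_index, noise_sd = 0, seed = 1L,
                        name = sprintf("planted_type_%d", type_index)) {
  if (type_index < 0 || type_index >= profile$n_types)
    stop("type_index out of range")
  signal <- as.numeric(profile$abundance[type_index + 1L, ])
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    signal <- signal + rnorm(length(signal), sd = noise_sd)
    rng$restore()
  }
  signal <- pmax(signal, 0)
  bins <- profile_bins(profile)
  track(data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                   value = signal), name = name)
}
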