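#' Contact maps
#'
#' A `contact_map` is a symmetric, non-negative bin-by-bin contact-frequency
#' matrix with genomic bin metadata, the common currency between Hi-C style
#' input data, the mean-field forward model, and simulated ensembles.
#'
#' @param matrix symmetric numeric matrix of non-negative contact values.
#' @param chrom chromosome label.
#' @param genomic_start 0-based start coordinate of bin 0.
#' @param bin_size_bp bin size in base pairs.
#' @param normalized logical; `TRUE` when entries are contact probabilities
#'   in `[0, 1]` (e.g. from a simulated ensemble) rather than raw counts.
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(matrix, chrom = "chrS", genomic_start = 0L,
                        bin_size_bp = 50000L, normalized = FALSE) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("contact matrix must be square")
  if (any(!is.finite(matrix))) stop("contact matrix has non-finite entries")
  if (any(matrix < 0)) stop("contact matrix has negative entries")
  if (max(abs(matrix - t(matrix))) > 1e-8 * max(1, max(abs(matrix))))
    stop("contact matrix is not symmetric; see read_contact_matrix() for symmetrization")
  dimnames(matrix) <- NULL
  structure(list(matrix = matrix, n_beads = nrow(matrix), chrom = chrom,
                 genomic_start = as.integer(genomic_start),
                 bin_size_bp = as.integer(bin_size_bp),
                 normalized = isTRUE(normalized)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d x %d bins, %s:%d- (bin %d bp), %s\n",
              x$n_beads, x$n_beads, x$chrom, x$genomic_start, x$bin_size_bp,
              if (x$normalized) "contact probabilities" else "raw values"))
  invisible(x)
}

as_contact_matrix <- function(x) {
  if (inherits(x, "contact_map")) x$matrix else as.matrix(x)
}
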