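#' Genomic signal tracks
#'
#' A `track` holds interval signal (bedGraph semantics): 0-based half-open
#' intervals with one numeric value each, e.g. a binned ChIP-seq signal of a
#' chromatin feature.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `value`.
#' @param name track name (used as column label in correlation heatmaps).
#' @return An object of class `track`.
#' @export
track <- function(intervals, name = "track") {
  need <- c("chrom", "start", "end", "value")
  if (!all(need %in% names(intervals)))
    stop("intervals needs columns chrom, start, end, value")
  intervals <- intervals[need]
  if (any(intervals$end <= intervals$start))
    stop("every interval needs end > start")
  intervals <- intervals[order(intervals$chrom, intervals$start), ]
  rownames(intervals) <- NULL
  structure(list(intervals = intervals, name = name), class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("track '%s': %d intervals on %s\n", x$name,
              nrow(x$intervals), paste(unique(x$intervals$chrom), collapse = ",")))
  invisible(x)
}

#' Read a bedGraph / scored BED track
#'
#' Thin wrapper over `rtracklayer::import`; bedGraph and 4-column BED with a
#' score are both accepted.
#'
#' @param path file path.
#' @param format passed to rtracklayer ("bedGraph" or "bed").
#' @param name track name; defaults to the file stem.
#' @return A [track].
#' @export
read_track <- function(path, format = "bedGraph",
                       name = tools::file_path_sans_ext(basename(path))) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading tracks requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  value <- if ("score" %in% names(df)) df$score else df[[ncol(df)]]
  track(data.frame(chrom = as.character(df$seqnames), start = df$start - 1L,
                   end = df$end, value = as.numeric(value)),
        name = name)
}

#' Write a track as bedGraph
#'
#' @param x a [track].
#' @param path output path.
#' @export
write_track <- function(x, path) {
  utils::write.table(x$intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bin a track onto a profile's grid
#'
#' Per-bin value is the coverage-weighted mean of the interval values
#' overlapping the bin; bins with zero covered bases are `NA` (no data is
#' not the same as zero signal).
#'
#' @param x a [track].
#' @param bins a [binding_profile], or a list with `chrom`, `start`
#'   (genomic start), `bin_size_bp`, `n_beads`.
#' @return numeric vector of length `n_beads`, with `NA` for uncovered bins.
#' @export
bin_track <- function(x, bins) {
  if (inherits(bins, "binding_profile"))
    bins <- list(chrom = bins$chrom, start = bins$genomic_start,
                 bin_size_bp = bins$bin_size_bp, n_beads = bins$n_beads)
  iv <- x$intervals
  if (nrow(iv) > 0 && !any(iv$chrom == bins$chrom))
    stop(sprintf("track covers %s but the profile is on %s",
                 paste(unique(iv$chrom), collapse = ","), bins$chrom))
  iv <- iv[iv$chrom == bins$chrom, , drop = FALSE]
  wsum <- numeric(bins$n_beads)
  vsum <- numeric(bins$n_beads)
  bs <- bins$bin_size_bp
  g0 <- bins$start
  for (k in seq_len(nrow(iv))) {
    lo <- max(iv$start[k], g0)
    hi <- min(iv$end[k], g0 + bins$n_beads * bs)
    if (hi <= lo) next
    b_first <- (lo - g0) %/% bs
    b_last <- (hi - 1 - g0) %/% bs
    for (b in b_first:b_last) {
      o_lo <- max(lo, g0 + b * bs)
      o_hi <- min(hi, g0 + (b + 1) * bs)
      w <- o_hi - o_lo
      wsum[b + 1L] <- wsum[b + 1L] + w
      vsum[b + 1L] <- vsum[b + 1L] + w * iv$value[k]
    }
  }
  out <- ifelse(wsum > 0, vsum / wsum, NA_real_)
  as.numeric(out)
}

#' Correlate binding-domain abundance with epigenomic tracks
#'
#' Pearson correlation between each binding-site type's abundance row and
#' each track's binned signal, over bins where both are defined — the
#' "barcode" heatmap linking inferred binding domains to the molecular
#' nature of their binders. No multiple-testing correction is applied; the
#' result is a matrix of raw r values.
#'
#' @param profile a [binding_profile].
#' @param tracks a list of [track]s (a single track is accepted).
#' @param min_bins minimum shared non-missing bins per cell; cells below it
#'   are `NA`.
#' @return An object of class `track_correlation`: matrix `r` (types x
#'   tracks) and matrix `n_bins` of bins used per cell.
#' @export
correlate_profile_tracks <- function(profile, tracks, min_bins = 4) {
  if (inherits(tracks, "track")) tracks <- list(tracks)
  nt <- profile$n_types
  nk <- length(tracks)
  r <- matrix(NA_real_, nt, nk,
              dimnames = list(paste0("type_", seq_len(nt) - 1L),
                              vapply(tracks, function(t) t$name, character(1))))
  nb <- matrix(0L, nt, nk, dimnames = dimnames(r))
  binned <- lapply(tracks, bin_track, bins = profile)
  for (t in seq_len(nt)) {
    ab <- as.numeric(profile$abundance[t, ])
    for (k in seq_len(nk)) {
      y <- binned[[k]]
      ok <- !is.na(y)
      nb[t, k] <- sum(ok)
      if (sum(ok) < min_bins) next
      if (sd(ab[ok]) == 0 || sd(y[ok]) == 0) next   # flagged missing
      r[t, k] <- cor(ab[ok], y[ok])
    }
  }
  structure(list(r = r, n_bins = nb), class = "track_correlation")
}

#' @export
print.track_correlation <- function(x, ...) {
  cat("track_correlation (Pearson r, types x tracks):\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Write a correlation heatmap matrix as TSV
#'
#' Rows are binding-domain types, columns track names.
#'
#' @param x a `track_correlation`.
#' @param path output path.
#' @param header optional comment lines (prefixed with `#`).
#' @export
write_correlation_tsv <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(data.frame(type = rownames(x$r), x$r,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
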