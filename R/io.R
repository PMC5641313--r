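#' Read a contact matrix from dense or triplet TSV
#'
#' Dense files are whitespace/tab-separated square numeric matrices
#' (headerless by default; a leading column of strictly increasing bin start
#' coordinates is auto-detected and used as bin metadata). Triplet files
#' list `bin_i bin_j value` with 0-based indices (1-based input is detected
#' when the smallest index is 1 and shifted). Matrices are symmetrized by
#' averaging with the transpose; both triangle entries of a triplet file are
#' filled. Lines starting with `#` are ignored.
#'
#' @param path input file.
#' @param format "dense", "triplet", or "auto" (square content is read as
#'   dense, 3-column content as triplet).
#' @param chrom,genomic_start,bin_size_bp bin metadata (overridden by an
#'   auto-detected coordinate column).
#' @return A [contact_map].
#' @export
read_contact_matrix <- function(path, format = c("auto", "dense", "triplet"),
                                chrom = "chrS", genomic_start = 0L,
                                bin_size_bp = 50000L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  tab <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (format == "auto")
    format <- if (ncol(tab) == 3 && nrow(tab) != 3) "triplet" else "dense"

  if (format == "dense") {
    m <- as.matrix(tab)
    # leading bin-start column?
    if (ncol(m) == nrow(m) + 1 && nrow(m) > 1) {
      first <- m[, 1]
      d <- diff(first)
      # coordinates: constant positive spacing, starts on the bin grid
      if (all(is.finite(first)) && length(unique(d)) == 1 && d[1] > 0 &&
          all(first %% d[1] == 0)) {
        genomic_start <- as.integer(first[1])
        if (nrow(m) > 1) bin_size_bp <- as.integer(first[2] - first[1])
        m <- m[, -1, drop = FALSE]
      }
    }
    if (nrow(m) != ncol(m))
      stop(sprintf("non-square dense matrix: %d x %d", nrow(m), ncol(m)))
    storage.mode(m) <- "double"
    bad <- which(is.na(m))
    if (length(bad) > 0)
      stop(sprintf("%d NaN/NA entries in matrix; first at (row %d, col %d)",
                   length(bad), (bad[1] - 1) %% nrow(m) + 1,
                   (bad[1] - 1) %/% nrow(m) + 1))
    if (any(m < 0)) stop("negative entries in contact matrix")
    m <- (m + t(m)) / 2
  } else {
    if (ncol(tab) != 3) stop("triplet format needs exactly 3 columns")
    i <- tab[[1]]; j <- tab[[2]]; v <- tab[[3]]
    if (any(is.na(v))) stop("NaN/NA values in triplet file")
    if (any(v < 0)) stop("negative entries in contact matrix")
    if (min(c(i, j)) >= 1) { i <- i - 1; j <- j - 1 }   # 1-based input
    n <- max(c(i, j)) + 1L
    m <- matrix(0, n, n)
    m[cbind(i + 1, j + 1)] <- v
    m[cbind(j + 1, i + 1)] <- v
  }
  contact_map(m, chrom, genomic_start, bin_size_bp)
}

#' Write a contact map as TSV
#'
#' @param map a [contact_map].
#' @param path output path.
#' @param format "dense" (square matrix) or "triplet" (upper triangle,
#'   0-based `i j value` rows, zeros omitted).
#' @param header optional provenance comment lines (prefixed `#`).
#' @export
write_contact_matrix <- function(map, path, format = c("dense", "triplet"),
                                 header = NULL) {
  format <- match.arg(format)
  m <- as_contact_matrix(map)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (format == "dense") {
    utils::write.table(m, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    up <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    utils::write.table(data.frame(i = up[, 1] - 1L, j = up[, 2] - 1L,
                                  value = m[up]),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a binding profile as TSV
#'
#' Columns: `chrom`, `bin_start`, `bin_end`, then one `type_k` abundance
#' column per binding-site type.
#'
#' @param profile a [binding_profile].
#' @param path output path.
#' @param header optional provenance comment lines (prefixed `#`).
#' @export
write_profile_tsv <- function(profile, path, header = NULL) {
  bins <- profile_bins(profile)
  ab <- t(profile$abundance)
  colnames(ab) <- paste0("type_", seq_len(profile$n_types) - 1L)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(data.frame(chrom = bins$chrom, bin_start = bins$start,
                                bin_end = bins$end, ab, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binding profile from TSV
#'
#' @param path a file written by [write_profile_tsv].
#' @return A [binding_profile].
#' @export
read_profile_tsv <- function(path) {
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
  type_cols <- grep("^type_", names(tab))
  if (length(type_cols) == 0) stop("no type_* columns in profile TSV")
  ab <- t(as.matrix(tab[, type_cols, drop = FALSE]))
  bs <- if (nrow(tab) > 1) tab$bin_start[2] - tab$bin_start[1] else
    tab$bin_end[1] - tab$bin_start[1]
  binding_profile(ab, bin_size_bp = bs, genomic_start = tab$bin_start[1],
                  chrom = tab$chrom[1])
}

#' Write a trajectory in XYZ format
#'
#' One block per saved frame: atom count, a comment line carrying the frame
#' time, then bead records (`B<type>`; `B` when a bead carries no site) and
#' binder records (`S<type>`).
#'
#' @param trajectory an `sbs_trajectory`.
#' @param path output path.
#' @export
write_xyz <- function(trajectory, path) {
  prof <- trajectory$provenance$profile
  binders <- trajectory$provenance$binders
  bead_lab <- apply(prof$abundance, 2, function(col) {
    t <- which(col > 0)
    if (length(t) == 0) "B" else paste0("B", t[1] - 1L)
  })
  bind_lab <- paste0("S", binder_type_vector(binders))
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in trajectory$frames) {
    n <- nrow(fr$bead_positions) + nrow(fr$binder_positions)
    writeLines(as.character(n), con)
    writeLines(sprintf("time=%g box=%g", fr$time, trajectory$box_side), con)
    bp <- fr$bead_positions
    writeLines(sprintf("%s %.5f %.5f %.5f", bead_lab, bp[, 1], bp[, 2], bp[, 3]), con)
    sp <- fr$binder_positions
    if (nrow(sp) > 0)
      writeLines(sprintf("%s %.5f %.5f %.5f", bind_lab, sp[, 1], sp[, 2], sp[, 3]), con)
  }
  invisible(path)
}

#' Export a single conformation as PDB
#'
#' Beads become CA atoms of consecutive residues (chain A), binders HETATM
#' spheres (chain B); convenient for molecular viewers. Requires bio3d.
#'
#' @param conformation a `conformation`.
#' @param path output path.
#' @export
write_pdb <- function(conformation, path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("PDB export requires the bio3d package")
  bp <- conformation$bead_positions
  sp <- conformation$binder_positions
  xyz <- rbind(bp, sp)
  n <- nrow(xyz)
  nb <- nrow(bp)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   type = c(rep("ATOM", nb), rep("HETATM", n - nb)),
                   resno = seq_len(n),
                   chain = c(rep("A", nb), rep("B", n - nb)),
                   resid = c(rep("BEA", nb), rep("BIN", n - nb)),
                   elety = rep("CA", n))
  invisible(path)
}

#' Write a contact curve as two-column TSV
#'
#' @param curve a `contact_curve`.
#' @param path output path.
#' @param header optional provenance comment lines (prefixed `#`).
#' @export
write_contact_curve <- function(curve, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(data.frame(s = curve$s, p = curve$p), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
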