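# P-site offset calibration by metagene analysis and triplet-periodicity
# quality control.

#' P-site offset table
#'
#' Maps read length to the 5' end to P-site offset in nt. Two calibration
#' modes mirror the two analysis arms: `fixed` assigns the same offset
#' (default 14 nt) to every length, as used for gene-level counting;
#' `metagene` carries per-length offsets recovered from the initiation
#' peak, as used for pause calling.
#'
#' @param offsets Named numeric vector (names are read lengths), or a
#'   single unnamed value applied to every length.
#' @param mode `"fixed"` or `"metagene"`.
#' @return Object of class `psite_offsets`.
#' @export
psite_offsets <- function(offsets = 14, mode = c("fixed", "metagene")) {
  mode <- match.arg(mode)
  if (length(offsets) > 1 || !is.null(names(offsets))) {
    if (is.null(names(offsets)))
      stop("multi-length offset tables must be named by read length")
    lens <- as.integer(names(offsets))
    if (any(offsets < 0 | offsets >= lens))
      stop("offsets must satisfy 0 <= offset < read_length")
  }
  structure(list(offsets = offsets, mode = mode), class = "psite_offsets")
}

#' @export
print.psite_offsets <- function(x, ...) {
  cat("P-site offsets (", x$mode, " mode)\n", sep = "")
  if (is.null(names(x$offsets))) {
    cat("  all lengths -> ", x$offsets, " nt\n", sep = "")
  } else {
    for (l in names(x$offsets))
      cat("  ", l, " nt -> ", x$offsets[[l]], " nt\n", sep = "")
  }
  invisible(x)
}

# Resolve offsets for a vector of read lengths; errors on a length with no
# entry (a silent default would corrupt P-site assignment).
offset_lookup <- function(offsets, read_lengths) {
  if (inherits(offsets, "psite_offsets")) offsets <- offsets$offsets
  if (length(offsets) == 1 && is.null(names(offsets)))
    return(rep(as.integer(offsets), length(read_lengths)))
  out <- offsets[as.character(read_lengths)]
  if (anyNA(out)) {
    miss <- unique(read_lengths[is.na(out)])
    stop("no P-site offset defined for read length(s): ",
         paste(miss, collapse = ", "))
  }
  as.integer(out)
}

#' Metagene matrix of 5' end positions around the start codon
#'
#' For every alignment, the distance `pos5 - cds_start` of the read 5' end
#' from the start codon is accumulated per read length over a window
#' (default -40..+20 nt). Multi-mapped reads are weighted `1/n_locations`.
#'
#' @param records Alignment data frame.
#' @param models Transcript models.
#' @param window Two integers, inclusive distance window around the start.
#' @return Matrix (read lengths x distances) of class `metagene_matrix`
#'   with attributes `window` and `n_reads`.
#' @export
metagene_matrix <- function(records, models, window = c(-40L, 20L)) {
  stopifnot(window[1] < 0, window[2] > 0)
  cds_start <- models$cds_start[match(records$transcript_id,
                                      models$transcript_id)]
  d <- records$pos5 - cds_start
  keep <- !is.na(d) & d >= window[1] & d <= window[2]
  lens <- sort(unique(records$read_length[keep]))
  dists <- seq(window[1], window[2])
  mat <- matrix(0, nrow = length(lens), ncol = length(dists),
                dimnames = list(as.character(lens), as.character(dists)))
  if (any(keep)) {
    w <- 1 / records$n_locations[keep]
    acc <- tapply(w, list(records$read_length[keep], d[keep]), sum)
    acc[is.na(acc)] <- 0
    mat[rownames(acc), colnames(acc)] <- acc
  }
  structure(mat, class = c("metagene_matrix", "matrix"), window = window,
            n_reads = sum(keep))
}

#' Calibrate P-site offsets
#'
#' In `metagene` mode the offset for each read length is the negated
#' location of the initiation spike: the argmax of 5' end counts over
#' distances in `search` (default -20..-8 nt) upstream of the start codon,
#' so that `cds_start = pos5 + offset` at the peak. Ties are broken toward
#' the smaller offset (the distance closer to zero) with a message. Lengths
#' with fewer than `min_reads` reads fall back to the fixed offset (with a
#' warning) or raise an error when `fallback = FALSE`. `fixed` mode returns
#' the constant offset for every length.
#'
#' @param matrix_ A `metagene_matrix` (ignored in fixed mode when lengths
#'   are supplied).
#' @param mode `"metagene"` or `"fixed"`.
#' @param fixed_offset Offset used in fixed mode and as fallback (nt).
#' @param search Two integers, distance range scanned for the peak.
#' @param min_reads Minimum reads per length for metagene calibration.
#' @param fallback Fall back to `fixed_offset` for under-covered lengths?
#' @param jitter_merge Merge counts at adjacent distances (moving sum of 3)
#'   before the argmax, absorbing +/-1 nt 5' end heterogeneity.
#' @param lengths Read lengths for fixed mode (defaults to matrix rows).
#' @return A [psite_offsets()] table.
#' @export
calibrate_offsets <- function(matrix_ = NULL,
                              mode = c("metagene", "fixed"),
                              fixed_offset = 14, search = c(-20L, -8L),
                              min_reads = 100, fallback = TRUE,
                              jitter_merge = FALSE, lengths = 26:32) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (!is.null(matrix_)) lengths <- as.integer(rownames(matrix_))
    off <- stats::setNames(rep(fixed_offset, length(lengths)),
                           as.character(lengths))
    return(psite_offsets(off, mode = "fixed"))
  }
  stopifnot(inherits(matrix_, "metagene_matrix"))
  dists <- as.integer(colnames(matrix_))
  in_search <- dists >= search[1] & dists <= search[2]
  if (!any(in_search)) stop("search range outside the metagene window")
  out <- numeric(0)
  for (len in rownames(matrix_)) {
    counts <- matrix_[len, ]
    if (sum(counts) < min_reads) {
      if (!fallback)
        stop("read length ", len, " has fewer than ", min_reads,
             " metagene reads and fallback is disabled")
      warning("read length ", len, ": too few metagene reads, ",
              "falling back to fixed offset ", fixed_offset)
      out[len] <- fixed_offset
      next
    }
    scan <- counts
    if (jitter_merge) {
      scan <- stats::filter(counts, rep(1, 3), sides = 2)
      scan[is.na(scan)] <- counts[is.na(scan)]
      scan <- as.numeric(scan)
      names(scan) <- names(counts)
    }
    scan <- scan[in_search]
    d_scan <- dists[in_search]
    peak <- which(scan == max(scan))
    if (length(peak) > 1) {
      message("read length ", len, ": tied metagene peak at distances ",
              paste(d_scan[peak], collapse = ", "),
              "; choosing the smaller offset")
      peak <- peak[which.max(d_scan[peak])]  # distance closest to 0
    }
    out[len] <- -d_scan[peak]
  }
  psite_offsets(out, mode = "metagene")
}

#' Triplet-periodicity frame report
#'
#' Computes the fraction of P-site mass in each reading frame
#' (`(position - cds_start) mod 3`) over the CDS of every transcript.
#'
#' @param profiles A `ribo_coverage` (or named list of coverage vectors).
#' @param models Transcript models.
#' @return List of class `frame_report`: `fractions` (length 3, sums to 1),
#'   `mass` (raw per-frame mass), `total_mass`, and `defined` (`FALSE` when
#'   no CDS mass was observed).
#' @export
frame_periodicity <- function(profiles, models) {
  mass <- c(`0` = 0, `1` = 0, `2` = 0)
  for (i in seq_len(nrow(models))) {
    tx <- models$transcript_id[i]
    v <- profiles[[tx]]
    if (is.null(v)) next
    idx <- seq(models$cds_start[i] + 1L, models$cds_end[i])
    cds <- v[idx]
    frame <- (seq_along(cds) - 1L) %% 3L
    acc <- tapply(cds, frame, sum)
    mass[names(acc)] <- mass[names(acc)] + acc
  }
  total <- sum(mass)
  structure(list(fractions = if (total > 0) mass / total else
                   rep(NA_real_, 3),
                 mass = mass, total_mass = total, defined = total > 0),
            class = "frame_report")
}

#' @export
print.frame_report <- function(x, ...) {
  cat("Triplet periodicity over CDS (P-site mass fractions)\n")
  if (!x$defined) {
    cat("  undefined: no CDS mass\n")
  } else {
    cat(sprintf("  frame %d: %.4f\n", 0:2, x$fractions))
  }
  invisible(x)
}

#' Write an offset table to TSV
#'
#' @param offsets A [psite_offsets()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_offsets <- function(offsets, path) {
  off <- offsets$offsets
  if (is.null(names(off))) off <- stats::setNames(off, "all")
  utils::write.table(data.frame(read_length = names(off),
                                offset = as.numeric(off),
                                mode = offsets$mode),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
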