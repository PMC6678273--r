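#' Construct a coding-potential track
#'
#' Per-position, per-frame posterior probabilities of the coding state, as
#' produced by the posterior decoding of an HMM gene finder. Stored as a
#' genome-length x 6 matrix; columns 1-3 are the forward frames, 4-6 the
#' reverse frames (see [frame_code()]). Positions never reported default to 0.
#'
#' @param mat Numeric matrix, `genome_len` rows, 6 columns, values in [0, 1].
#' @return An object of class `coding_track`.
#' @export
coding_track <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 6L) stop("coding track must have 6 frame columns")
  if (any(is.na(mat)) || any(mat < 0) || any(mat > 1)) {
    stop("coding-potential posteriors must lie in [0, 1]")
  }
  structure(mat, class = c("coding_track", "matrix"))
}

#' Read a coding-potential track from TSV
#'
#' Expected columns: `position` (1-based), `frame` (1-6), `posterior`
#' (in [0, 1]). Unlisted (position, frame) cells default to 0.
#'
#' @param path TSV path with a header row; comment lines start with `#`.
#' @param genome_len Genome length; positions outside 1..genome_len error.
#' @return A [coding_track()].
#' @export
read_coding_track <- function(path, genome_len) {
  df <- utils::read.delim(path, comment.char = "#")
  need <- c("position", "frame", "posterior")
  if (!all(need %in% names(df))) {
    stop("coding track TSV needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) > 0) {
    if (any(df$position < 1 | df$position > genome_len)) {
      stop("track positions fall outside the genome (length ", genome_len, ")")
    }
    if (any(!(df$frame %in% 1:6))) stop("track frame codes must be 1..6")
  }
  mat <- matrix(0, nrow = genome_len, ncol = 6L)
  if (nrow(df) > 0) {
    mat[cbind(as.integer(df$position), as.integer(df$frame))] <- df$posterior
  }
  coding_track(mat)
}

#' Write a coding-potential track to TSV (sparse: zero cells omitted)
#' @param track A [coding_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coding_track <- function(track, path) {
  idx <- which(track != 0, arr.ind = TRUE)
  df <- data.frame(
    position = idx[, 1L], frame = idx[, 2L],
    posterior = track[idx]
  )
  df <- df[order(df$position, df$frame), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# posterior values over an ORF's own frame, 5'->3' along the genome interval
orf_track_values <- function(track, orf, genome_len = nrow(track)) {
  left <- as.integer(orf$left[1L])
  right <- as.integer(orf$right[1L])
  if (left < 1L || right > nrow(track)) {
    stop("track does not cover the ORF (track length ", nrow(track), ")")
  }
  col <- frame_code(orf$strand[1L], left, right, genome_len)
  track[left:right, col]
}

#' Score the coding potential of an ORF (class 0-3)
#'
#' Class 3: posterior is high (`> high_thresh`) somewhere in the ORF's frame
#' and sustained (more than `sustain_frac` of ORF positions above
#' `high_thresh`). Class 2: high but not sustained. Class 1: never high, but
#' low-level signal (`> low_thresh`) is sustained. Class 0: neither.
#'
#' @param track A [coding_track()] covering the genome.
#' @param orf One ORF row (see [find_orfs()]).
#' @param high_thresh Posterior above which signal counts as high (default
#'   0.75).
#' @param sustain_frac Fraction of ORF positions that must exceed a threshold
#'   for the signal to count as sustained (default 0.5).
#' @param low_thresh Posterior above which signal counts as low-but-present
#'   (default 0.25; the dividing line is not standardised, so it is exposed
#'   here).
#' @return Integer class in 0..3.
#' @export
classify_coding_potential <- function(track, orf, high_thresh = 0.75,
                                      sustain_frac = 0.5, low_thresh = 0.25) {
  vals <- orf_track_values(track, orf)
  frac_high <- mean(vals > high_thresh)
  if (max(vals) > high_thresh) {
    if (frac_high > sustain_frac) 3L else 2L
  } else {
    if (mean(vals > low_thresh) > sustain_frac) 1L else 0L
  }
}

#' Locate the coding-potential plateau of an ORF
#'
#' The plateau is the longest contiguous run of positions whose posterior
#' exceeds `high_thresh` in the ORF's own frame; only the plateau counts when
#' judging whether a start codon retains all coding potential, not the sloped
#' flanks. Ties are broken towards the 5' end of the gene.
#'
#' @inheritParams classify_coding_potential
#' @return A list with `left` and `right` genome coordinates, or `NULL` when
#'   no position exceeds the threshold.
#' @export
coding_plateau <- function(track, orf, high_thresh = 0.75) {
  vals <- orf_track_values(track, orf)
  r <- rle(vals > high_thresh)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hi <- which(r$values)
  lens <- r$lengths[hi]
  best <- hi[lens == max(lens)]
  # 5'-most: first run for forward genes, last (rightmost) for reverse
  best <- if (normalize_strand(orf$strand[1L]) == "+") best[1L] else best[length(best)]
  left <- as.integer(orf$left[1L])
  list(left = left + starts[best] - 1L, right = left + ends[best] - 1L)
}

#' Does a candidate start retain all of the gene's coding potential?
#'
#' True when the candidate lies 5' of (or at) the plateau's 5' edge, so the
#' resulting gene contains the whole plateau. With no plateau the criterion is
#' vacuously true for every candidate.
#'
#' @param candidate_coord Start-candidate coordinate (5'-most base).
#' @param plateau Result of [coding_plateau()] (may be `NULL`).
#' @param strand `"+"` or `"-"`.
#' @return Logical.
#' @export
covers_all_coding_potential <- function(candidate_coord, plateau, strand) {
  if (is.null(plateau)) return(rep(TRUE, length(candidate_coord)))
  strand <- normalize_strand(strand)
  if (strand == "+") candidate_coord <= plateau$left else candidate_coord >= plateau$right
}
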