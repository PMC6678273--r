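#' @keywords internal
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Default permitted start codons (standard for phage/bacterial annotation)
#' @keywords internal
DEFAULT_START_CODONS <- c("ATG", "GTG", "TTG")

#' Stop-anchor key for a gene
#'
#' A gene's identity is its 3' end plus strand: gene callers agree on stop
#' codons but frequently disagree on starts, so the stop anchor is the stable
#' key under which evidence from different programs is merged.
#'
#' @param strand `"+"` or `"-"` (vectorised).
#' @param three_prime 1-based coordinate of the 3'-most base of the stop codon
#'   (the `right` end for forward genes, the `left` end for reverse genes).
#' @return Character key, e.g. `"+:9"`.
#' @export
orf_key <- function(strand, three_prime) {
  paste0(strand, ":", as.integer(three_prime))
}

#' Stop-anchor keys for an interval table
#'
#' @param x A data frame with columns `strand`, `left`, `right`.
#' @return Character vector of keys.
#' @export
interval_keys <- function(x) {
  orf_key(x$strand, ifelse(x$strand == "+", x$right, x$left))
}

normalize_strand <- function(strand) {
  s <- as.character(strand)
  s[s %in% c("forward", "f", "F", "1")] <- "+"
  s[s %in% c("reverse", "r", "R", "-1")] <- "-"
  bad <- !(s %in% c("+", "-"))
  if (any(bad)) {
    stop("unknown strand symbol(s): ", paste(unique(strand[bad]), collapse = ", "))
  }
  s
}

# Scan one strand (sequence given 5'->3') for stop-to-stop frame segments.
# Returns local coordinates: one row per stop codon that has at least one
# in-frame start codon upstream (previous stop exclusive).
scan_frames <- function(s, start_codons, min_len_bp) {
  L <- nchar(s)
  out <- vector("list", 3L)
  for (f in 0:2) {
    p <- seq.int(1L + f, L - 2L, by = 3L)
    if (length(p) == 0L) next
    cod <- substring(s, p, p + 2L)
    stop_i <- which(cod %in% STOP_CODONS)
    start_i <- which(cod %in% start_codons)
    if (length(stop_i) == 0L || length(start_i) == 0L) next
    # segment index: the first stop at or after each start
    seg <- findInterval(start_i - 1L, stop_i) + 1L
    ok <- seg <= length(stop_i)
    if (!any(ok)) next
    first_start <- vapply(
      split(start_i[ok], seg[ok]), min, integer(1L)
    )
    segs <- as.integer(names(first_start))
    left <- p[first_start]
    right <- p[stop_i[segs]] + 2L
    keep <- (right - left + 1L) >= min_len_bp
    if (!any(keep)) next
    out[[f + 1L]] <- data.frame(
      left = left[keep], right = right[keep], frame = f + 1L
    )
  }
  do.call(rbind, out)
}

#' Enumerate open reading frames in a genome
#'
#' An ORF is a stop-to-stop frame segment reported from its 5'-most permitted
#' start codon through its stop codon (stop included in the length). One ORF
#' is reported per stop anchor; segments without any permitted start codon are
#' not reported. Coordinates are 1-based and fully inclusive.
#'
#' For circular genomes (`genome$circular`), the doubled sequence is scanned
#' and origin-spanning ORFs are reported with `right > genome_length`
#' (forward) or coordinates in the second copy; duplicates are removed by stop
#' anchor modulo the genome length.
#'
#' @param genome A [genome_sequence()].
#' @param min_len_bp Minimum ORF length in bp, start through stop inclusive.
#'   The default 76 keeps ORFs strictly longer than 75 bp, the conventional
#'   floor for phage proteins (as short as 27 aa have been observed).
#' @param start_codons Permitted start codons.
#' @return A data frame with columns `orf_key`, `strand`, `left`, `right`,
#'   `frame` (1-3 per strand, from the 5' end of that strand), `length_bp`,
#'   sorted by `left` then `strand`.
#' @examples
#' find_orfs(genome_sequence("ATGAAATAA"), min_len_bp = 1)
#' @export
find_orfs <- function(genome, min_len_bp = 76L,
                      start_codons = DEFAULT_START_CODONS) {
  stopifnot(inherits(genome, "genome_sequence"))
  if (min_len_bp < 1L) stop("'min_len_bp' must be >= 1")
  L <- genome_length(genome)
  s <- if (genome$circular) paste0(genome$seq, genome$seq) else genome$seq

  fw <- scan_frames(s, start_codons, min_len_bp)
  rv <- scan_frames(revcomp(s), start_codons, min_len_bp)

  Ls <- nchar(s)
  res <- list()
  if (!is.null(fw)) {
    res$fw <- data.frame(
      strand = "+", left = fw$left, right = fw$right, frame = fw$frame
    )
  }
  if (!is.null(rv)) {
    res$rv <- data.frame(
      strand = "-",
      left = Ls - rv$right + 1L,
      right = Ls - rv$left + 1L,
      frame = rv$frame
    )
  }
  orfs <- do.call(rbind, res)
  if (is.null(orfs) || nrow(orfs) == 0L) {
    return(empty_orf_table())
  }

  if (genome$circular) {
    # keep ORFs anchored in the first copy; wrap and deduplicate by anchor
    three <- ifelse(orfs$strand == "+", orfs$right, orfs$left)
    len <- orfs$right - orfs$left + 1L
    anchor_mod <- ((three - 1L) %% L) + 1L
    keep <- orfs$left <= L & len <= L
    orfs <- orfs[keep, , drop = FALSE]
    anchor_mod <- anchor_mod[keep]
    dedup <- !duplicated(paste0(orfs$strand, ":", anchor_mod))
    orfs <- orfs[dedup, , drop = FALSE]
  }

  orfs$length_bp <- orfs$right - orfs$left + 1L
  orfs$orf_key <- orf_key(
    orfs$strand, ifelse(orfs$strand == "+", orfs$right, orfs$left)
  )
  orfs <- orfs[order(orfs$left, orfs$strand, orfs$frame), ]
  rownames(orfs) <- NULL
  orfs[, c("orf_key", "strand", "left", "right", "frame", "length_bp")]
}

empty_orf_table <- function() {
  data.frame(
    orf_key = character(0), strand = character(0), left = integer(0),
    right = integer(0), frame = integer(0), length_bp = integer(0)
  )
}

#' Enumerate candidate start codons for an ORF
#'
#' All in-frame occurrences of permitted start codons between the previous
#' in-frame stop codon (exclusive) and this ORF's stop codon (exclusive),
#' ordered 5' to 3' so the first candidate yields the longest gene. For
#' reverse-strand ORFs the reported coordinate is the 5'-most (numerically
#' largest) base of the codon, matching GenBank-style coordinates.
#'
#' @param orf One row of the table returned by [find_orfs()] (or a list with
#'   `strand`, `left`, `right`).
#' @param genome The [genome_sequence()] the ORF belongs to.
#' @param start_codons Permitted start codons.
#' @return Data frame with columns `coordinate`, `codon`, `orf_key`; zero rows
#'   if the segment holds no permitted start codon.
#' @export
enumerate_start_candidates <- function(orf, genome,
                                       start_codons = DEFAULT_START_CODONS) {
  stopifnot(inherits(genome, "genome_sequence"))
  strand <- normalize_strand(orf$strand[1L])
  left <- as.integer(orf$left[1L])
  right <- as.integer(orf$right[1L])
  L <- genome_length(genome)
  if (left < 1L || right > L || left >= right) {
    stop("ORF coordinates fall outside the genome")
  }
  if (strand == "+") {
    s <- genome$seq
    q <- right - 2L # local stop codon start
    f <- (left - 1L) %% 3L
  } else {
    s <- revcomp(genome$seq)
    q <- (L - right + 1L) + (right - left + 1L) - 3L
    f <- (L - right) %% 3L
  }
  p <- seq.int(1L + f, nchar(s) - 2L, by = 3L)
  cod <- substring(s, p, p + 2L)
  stops <- p[cod %in% STOP_CODONS]
  if (!(q %in% stops)) stop("ORF does not end in a stop codon in its frame")
  prev <- stops[stops < q]
  prev <- if (length(prev)) max(prev) else -Inf
  cand <- p[cod %in% start_codons & p > prev & p < q]
  codons <- substring(s, cand, cand + 2L)
  coordinate <- if (strand == "+") cand else L - cand + 1L
  key <- orf_key(strand, if (strand == "+") right else left)
  data.frame(
    coordinate = as.integer(coordinate),
    codon = codons,
    orf_key = rep(key, length(cand))
  )
}

#' Reading-frame column index into a six-frame track
#'
#' Frames 1-3 are forward (codon start congruent to 1,2,3 modulo 3); frames
#' 4-6 are the reverse-strand frames counted from the 3' end of the genome,
#' i.e. frame of the reverse complement.
#'
#' @param strand `"+"` or `"-"`.
#' @param left,right ORF coordinates.
#' @param genome_len Genome length.
#' @return Integer in 1..6.
#' @export
frame_code <- function(strand, left, right, genome_len) {
  strand <- normalize_strand(strand)
  ifelse(
    strand == "+",
    ((left - 1L) %% 3L) + 1L,
    3L + ((genome_len - right) %% 3L) + 1L
  )
}
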