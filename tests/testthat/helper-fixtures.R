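# In-code fixtures shared across test files.

# an ORF row as find_orfs() would report it
orf_row <- function(strand, left, right, genome_len = NULL) {
  frame <- if (strand == "+") ((left - 1L) %% 3L) + 1L else {
    stopifnot(!is.null(genome_len))
    ((genome_len - right) %% 3L) + 1L
  }
  data.frame(
    orf_key = orf_key(strand, if (strand == "+") right else left),
    strand = strand, left = as.integer(left), right = as.integer(right),
    frame = frame, length_bp = as.integer(right - left + 1L)
  )
}

# flat track with a constant level over one interval in one frame column
flat_track <- function(genome_len, left, right, col, level) {
  mat <- matrix(0, nrow = genome_len, ncol = 6L)
  mat[left:right, col] <- level
  coding_track(mat)
}

# the worked five-candidate start-selection example (printed evidence rows)
table7_rows <- function() {
  data.frame(
    coordinate = c(442L, 578L, 587L, 605L, 626L),
    covers_coding_potential = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    overlap_or_gap = c(128L, 0L, 0L, 0L, 0L),
    operon = FALSE,
    program_votes = c(0L, 0L, 1L, 2L, 3L),
    similarity_start_matches = c(0L, 1L, 4L, 2L, 1L),
    sd_score = c(-5.9, -5, -6.5, -4.6, -3.8),
    resulting_length_bp = c(500L, 364L, 355L, 337L, 316L)
  )
}

# call table with the given programs all calling one stop anchor
calls_for <- function(programs, left, right, strand) {
  data.frame(program = programs, left = left, right = right, strand = strand)
}
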