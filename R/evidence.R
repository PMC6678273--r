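#' Load gene calls from one or more programs
#'
#' Accepts GFF3 (any dialect rtracklayer understands) or TSV files with
#' columns `program`, `left`, `right`, `strand`. Each file may be tagged with
#' a program label via `names(paths)`; for GFF3 an untagged file falls back to
#' its `source` column, for TSV to its `program` column. Coordinates are
#' normalised to 1-based inclusive `left <= right` regardless of dialect.
#' Duplicate calls by the same program for the same stop anchor are collapsed
#' to the first occurrence.
#'
#' @param paths Character vector of file paths, optionally named with program
#'   labels.
#' @param genome_len Optional genome length for coordinate validation.
#' @return Data frame with columns `program`, `left`, `right`, `strand`.
#' @export
load_program_calls <- function(paths, genome_len = NULL) {
  labels <- names(paths)
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    path <- paths[[i]]
    label <- if (!is.null(labels) && nzchar(labels[i])) labels[i] else NA_character_
    df <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
      read_calls_gff3(path, label)
    } else {
      read_calls_tsv(path, label)
    }
    if (nrow(df) == 0L) warning("no gene calls in '", path, "'")
    out[[i]] <- df
  }
  calls <- do.call(rbind, out)
  if (is.null(calls) || nrow(calls) == 0L) {
    return(data.frame(
      program = character(0), left = integer(0), right = integer(0),
      strand = character(0)
    ))
  }
  calls$strand <- normalize_strand(calls$strand)
  if (any(!nzchar(calls$program) | is.na(calls$program))) {
    stop("every gene call needs a non-empty program label")
  }
  if (any(calls$right <= calls$left)) {
    stop("gene calls must satisfy right > left")
  }
  if (!is.null(genome_len) &&
      any(calls$left < 1L | calls$right > genome_len)) {
    stop("gene call coordinates fall outside the genome (length ", genome_len, ")")
  }
  dup <- duplicated(paste0(calls$program, "|", interval_keys(calls)))
  calls <- calls[!dup, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

read_calls_gff3 <- function(path, label) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) {
    return(data.frame(
      program = character(0), left = integer(0), right = integer(0),
      strand = character(0)
    ))
  }
  src <- as.character(S4Vectors::mcols(gr)$source)
  program <- if (is.na(label)) src else rep(label, length(gr))
  data.frame(
    program = program,
    left = GenomicRanges::start(gr),
    right = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

read_calls_tsv <- function(path, label) {
  df <- utils::read.delim(path, comment.char = "#")
  if (nrow(df) == 0L) {
    return(data.frame(
      program = character(0), left = integer(0), right = integer(0),
      strand = character(0)
    ))
  }
  if (!all(c("left", "right", "strand") %in% names(df))) {
    stop("call TSV '", path, "' needs columns left, right, strand")
  }
  program <- if (!is.na(label)) rep(label, nrow(df)) else df$program
  if (is.null(program)) stop("call TSV '", path, "' has no program label")
  data.frame(
    program = as.character(program),
    left = as.integer(df$left), right = as.integer(df$right),
    strand = as.character(df$strand)
  )
}

#' Count the programs calling a gene
#'
#' Programs are credited per stop anchor: a call counts for an ORF when it
#' shares the ORF's 3' end and strand, whatever start it picked. Each program
#' is counted at most once.
#'
#' @param orf One ORF row.
#' @param calls Call table from [load_program_calls()].
#' @return Integer count in 0..(number of distinct programs).
#' @export
count_program_calls <- function(orf, calls) {
  if (nrow(calls) == 0L) return(0L)
  key <- orf_key(
    normalize_strand(orf$strand[1L]),
    if (normalize_strand(orf$strand[1L]) == "+") orf$right[1L] else orf$left[1L]
  )
  length(unique(calls$program[interval_keys(calls) == key]))
}

#' Number of programs voting for each start candidate of an ORF
#'
#' @param candidates Data frame from [enumerate_start_candidates()].
#' @param orf The ORF row the candidates belong to.
#' @param calls Call table.
#' @return Integer vector parallel to `candidates`.
#' @export
start_program_votes <- function(candidates, orf, calls) {
  if (nrow(calls) == 0L || nrow(candidates) == 0L) {
    return(integer(nrow(candidates)))
  }
  strand <- normalize_strand(orf$strand[1L])
  key <- orf_key(strand, if (strand == "+") orf$right[1L] else orf$left[1L])
  mine <- calls[interval_keys(calls) == key, , drop = FALSE]
  five <- if (strand == "+") mine$left else mine$right
  vapply(
    candidates$coordinate,
    function(cc) length(unique(mine$program[five == cc])),
    integer(1L)
  )
}

#' Score sequence-similarity evidence (class 0-4)
#'
#' Base score from the best (smallest) E-value: 3 below `strong_thresh`
#' (default 1e-50), 2 below `mid_thresh` (default 1e-20), 1 below
#' `sig_thresh` (default 1e-10), else 0. One bonus point when any match that
#' itself passes `sig_thresh` is to a protein of known function (a
#' "hypothetical protein" never earns the bonus), capped at 4. An ORF with no
#' significant match cannot earn the bonus alone.
#'
#' @param e_values Numeric vector of match E-values (may be empty).
#' @param known_function Logical vector parallel to `e_values`.
#' @param sig_thresh,mid_thresh,strong_thresh Significance bin edges.
#' @return Integer in 0..4.
#' @export
score_similarity <- function(e_values, known_function = logical(length(e_values)),
                             sig_thresh = 1e-10, mid_thresh = 1e-20,
                             strong_thresh = 1e-50) {
  if (length(e_values) == 0L) return(0L)
  if (any(is.na(e_values)) || any(e_values < 0)) {
    stop("E-values must be non-negative")
  }
  stopifnot(length(known_function) == length(e_values))
  best <- min(e_values)
  base <- if (best < strong_thresh) 3L else if (best < mid_thresh) 2L else if (best < sig_thresh) 1L else 0L
  bonus <- as.integer(base > 0L && any(known_function & e_values < sig_thresh))
  min(4L, base + bonus)
}

#' Read a similarity-match table
#'
#' TSV columns: `orf_key`, `e_value`, `known_function` (TRUE/FALSE),
#' `subject_start_offset` (signed in-frame nucleotide offset of the
#' alignment-implied gene start relative to the ORF's 5'-most candidate start;
#' may be NA when irrelevant).
#'
#' @param path TSV path.
#' @return Data frame with the four columns above.
#' @export
read_similarity_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#")
  if (nrow(df) == 0L) {
    return(data.frame(
      orf_key = character(0), e_value = numeric(0),
      known_function = logical(0), subject_start_offset = integer(0)
    ))
  }
  need <- c("orf_key", "e_value", "known_function")
  if (!all(need %in% names(df))) {
    stop("similarity TSV needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$subject_start_offset)) df$subject_start_offset <- NA_integer_
  data.frame(
    orf_key = as.character(df$orf_key),
    e_value = as.numeric(df$e_value),
    known_function = as.logical(df$known_function),
    subject_start_offset = as.integer(df$subject_start_offset)
  )
}

#' Similarity matches supporting each start candidate
#'
#' A match supports a candidate when it passes the significance threshold and
#' its implied gene start (the ORF's 5'-most candidate shifted by
#' `subject_start_offset` towards 3') coincides with that candidate.
#'
#' @param candidates Data frame from [enumerate_start_candidates()] (ordered
#'   5' to 3', longest gene first).
#' @param sim Similarity rows for this ORF (see [read_similarity_table()]).
#' @param strand `"+"` or `"-"`.
#' @param sig_thresh Significance threshold (default 1e-10).
#' @return Integer vector parallel to `candidates`.
#' @export
start_similarity_matches <- function(candidates, sim, strand,
                                     sig_thresh = 1e-10) {
  n <- nrow(candidates)
  if (n == 0L || nrow(sim) == 0L) return(integer(n))
  strand <- normalize_strand(strand)
  anchor <- candidates$coordinate[1L] # 5'-most candidate = longest gene
  sim <- sim[!is.na(sim$subject_start_offset) & sim$e_value < sig_thresh, , drop = FALSE]
  if (nrow(sim) == 0L) return(integer(n))
  implied <- if (strand == "+") anchor + sim$subject_start_offset else anchor - sim$subject_start_offset
  vapply(candidates$coordinate, function(cc) sum(implied == cc), integer(1L))
}

#' Read a Shine-Dalgarno score table
#'
#' TSV columns: `start_coordinate`, `sd_score` (negative reals, closer to
#' zero is stronger). SD scores are consumed as input, typically exported
#' from an annotation browser; this package does not compute them.
#'
#' @param path TSV path.
#' @return Data frame with columns `start_coordinate`, `sd_score`.
#' @export
read_sd_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#")
  if (nrow(df) == 0L) {
    return(data.frame(start_coordinate = integer(0), sd_score = numeric(0)))
  }
  if (!all(c("start_coordinate", "sd_score") %in% names(df))) {
    stop("SD TSV needs columns start_coordinate, sd_score")
  }
  data.frame(
    start_coordinate = as.integer(df$start_coordinate),
    sd_score = as.numeric(df$sd_score)
  )
}

#' Assemble per-ORF evidence bundles
#'
#' One row per ORF with the three intrinsic evidence classes; overlap and
#' length are contributed by the scoring stage, which also needs the strong
#' calls.
#'
#' @param orfs ORF table from [find_orfs()].
#' @param calls Call table from [load_program_calls()].
#' @param track A [coding_track()], or `NULL` for "no signal anywhere".
#' @param sim Similarity table, or `NULL`.
#' @param config A [rubric_config()].
#' @return Data frame: `orf_key`, `program_count`, `coding_class`,
#'   `similarity_class`.
#' @export
build_evidence <- function(orfs, calls, track = NULL, sim = NULL,
                           config = rubric_config()) {
  n <- nrow(orfs)
  program_count <- integer(n)
  coding_class <- integer(n)
  similarity_class <- integer(n)
  for (i in seq_len(n)) {
    orf <- orfs[i, ]
    program_count[i] <- count_program_calls(orf, calls)
    coding_class[i] <- if (is.null(track)) 0L else {
      classify_coding_potential(
        track, orf,
        high_thresh = config$coding_high, sustain_frac = config$coding_sustain,
        low_thresh = config$coding_low
      )
    }
    similarity_class[i] <- if (is.null(sim)) 0L else {
      rows <- sim[sim$orf_key == orf$orf_key, , drop = FALSE]
      score_similarity(
        rows$e_value, rows$known_function,
        sig_thresh = config$sim_sig, mid_thresh = config$sim_mid,
        strong_thresh = config$sim_strong
      )
    }
  }
  data.frame(
    orf_key = orfs$orf_key,
    program_count = program_count,
    coding_class = coding_class,
    similarity_class = similarity_class
  )
}
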