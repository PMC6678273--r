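#' Shared bases between two intervals
#'
#' @param a_left,a_right,b_left,b_right 1-based inclusive coordinates
#'   (vectorised).
#' @return Non-negative integer overlap in bp; symmetric in its arguments.
#' @export
overlap_bp <- function(a_left, a_right, b_left, b_right) {
  pmax(0L, as.integer(pmin(a_right, b_right) - pmax(a_left, b_left) + 1L))
}

# penalty magnitude for an overlap (or divergent deficit) of x bp:
# [0,10) -> 0, [10,40) -> 1, [40,70) -> 2, [70,100) -> 3, [100,Inf) -> 4
overlap_penalty <- function(x, bins = c(10, 40, 70, 100)) {
  findInterval(x, bins)
}

#' Overlap context of a candidate gene against the strong calls
#'
#' Computes the worst (maximum) overlap with any strong call, whether the
#' candidate forms an operon junction (its start codon overlapping the stop
#' codon of a same-strand strong call by exactly 1, 4, or 8 bp), and the
#' divergent deficit: for a head-to-head pair (a reverse gene with a forward
#' strong call downstream, or vice versa) the shortfall below the 50 bp the
#' two promoters need between the facing 5' ends.
#'
#' Only strong calls (genes called by both designated anchor programs) are
#' scored against: overlap among putative genes within a coding gap is left
#' unscored because it is not yet known which of them will be kept.
#'
#' @param orf Candidate ORF row.
#' @param strong_calls Data frame of strong-call intervals (`left`, `right`,
#'   `strand`); the candidate itself is excluded by stop anchor.
#' @param config A [rubric_config()].
#' @return List: `worst_overlap_bp`, `operon_overlap`, `divergent_deficit_bp`.
#' @export
overlap_context <- function(orf, strong_calls, config = rubric_config()) {
  ctx <- list(worst_overlap_bp = 0L, operon_overlap = FALSE,
              divergent_deficit_bp = 0L)
  if (is.null(strong_calls) || nrow(strong_calls) == 0L) return(ctx)
  strand <- normalize_strand(orf$strand[1L])
  left <- as.integer(orf$left[1L]); right <- as.integer(orf$right[1L])
  key <- orf_key(strand, if (strand == "+") right else left)
  sc <- strong_calls
  sc$strand <- normalize_strand(sc$strand)
  sc <- sc[interval_keys(sc) != key, , drop = FALSE]
  if (nrow(sc) == 0L) return(ctx)

  ov <- overlap_bp(left, right, sc$left, sc$right)
  ctx$worst_overlap_bp <- max(ov)

  # operon junction: overlap of exactly 1/4/8 bp located at the candidate's
  # 5' end against the neighbour's 3' (stop) end, same strand
  same <- sc$strand == strand
  if (strand == "+") {
    junction <- same & sc$right >= left & sc$left < left
  } else {
    junction <- same & sc$left <= right & sc$right > right
  }
  ctx$operon_overlap <- any(junction & ov %in% config$operon_overlaps)

  # divergent (head-to-head) 5' ends: reverse gene 5' = right, facing the 5'
  # (left) end of a forward neighbour further right, and the mirror case
  if (strand == "-") {
    facing <- sc$strand == "+" & sc$left > right
    gaps <- sc$left[facing] - right - 1L
  } else {
    facing <- sc$strand == "-" & sc$right < left
    gaps <- left - sc$right[facing] - 1L
  }
  if (length(gaps)) {
    ctx$divergent_deficit_bp <- max(0L, config$divergent_gap - min(gaps))
  }
  ctx
}

#' Overlap component of the rubric (-4 .. +1)
#'
#' An operon-forming 1/4/8 bp stop/start overlap with a strong call earns +1
#' (false positives are unlikely to land in an operon). Otherwise the worst
#' overlap with a strong call -- with any divergent promoter deficit binned
#' as if it were overlap -- is penalised 0/-1/-2/-3/-4 at the configured bin
#' edges (default <10 free, then 10/40/70/100).
#'
#' @inheritParams overlap_context
#' @return List with `score` (integer in -4..1) and `context` (the
#'   [overlap_context()]).
#' @export
score_overlap <- function(orf, strong_calls, config = rubric_config()) {
  ctx <- overlap_context(orf, strong_calls, config)
  score <- if (ctx$operon_overlap) 1L else {
    -overlap_penalty(
      max(ctx$worst_overlap_bp, ctx$divergent_deficit_bp),
      config$overlap_bins
    )
  }
  list(score = as.integer(score), context = ctx)
}

#' Length component of the rubric (-4 .. 0)
#'
#' Short ORFs are more often non-coding: >200 bp is free, (150,200] costs 1,
#' (120,150] costs 2, (90,120] costs 3, and 90 bp or shorter costs 4.
#'
#' @param length_bp Positive ORF length (vectorised).
#' @param bins Right edges of the four penalty bins.
#' @return Integer score(s) in -4..0.
#' @export
score_length <- function(length_bp, bins = c(90, 120, 150, 200)) {
  if (any(length_bp <= 0)) stop("'length_bp' must be positive")
  # x > bins[4] -> 0; (bins[3], bins[4]] -> -1; ... ; <= bins[1] -> -4
  -(4L - findInterval(length_bp, bins + 1L))
}

#' Sum the five rubric components into a keep/discard decision
#'
#' The total is the plain sum of program count, coding class, similarity
#' class, overlap score and length score. Totals at or above `keep_thresh`
#' (default 3) are kept, at or below `discard_thresh` (default 0) discarded,
#' and anything between is a borderline case flagged for human review, never
#' auto-resolved. The thresholds guarantee that a gene with no program,
#' coding-potential or similarity support (maximum total 0 + 0 + 0 + 1 + 0 =
#' 1) can never be kept on length/overlap alone.
#'
#' @param program_count Integer 0..N programs.
#' @param coding_class Integer 0..3.
#' @param similarity_class Integer 0..4.
#' @param overlap_score Integer -4..1.
#' @param length_score Integer -4..0.
#' @param config A [rubric_config()].
#' @return List: `components` (named integer vector), `total`, `verdict`
#'   (`"Keep"`, `"Discard"` or `"Borderline"`).
#' @export
total_score <- function(program_count, coding_class, similarity_class,
                        overlap_score, length_score,
                        config = rubric_config()) {
  stopifnot(
    program_count >= 0,
    coding_class %in% 0:3,
    similarity_class %in% 0:4,
    overlap_score >= -4, overlap_score <= 1,
    length_score >= -4, length_score <= 0
  )
  comp <- c(
    programs = as.integer(program_count),
    coding = as.integer(coding_class),
    similarity = as.integer(similarity_class),
    overlap = as.integer(overlap_score),
    length = as.integer(length_score)
  )
  total <- sum(comp)
  verdict <- if (total >= config$keep_thresh) "Keep"
             else if (total <= config$discard_thresh) "Discard"
             else "Borderline"
  list(components = comp, total = total, verdict = verdict)
}

#' Strong gene calls: the consensus of the anchor programs
#'
#' A gene is "strong" when both designated anchor programs called its stop
#' anchor; such genes are unlikely to be false positives and serve as the
#' frame of reference for overlap penalties.
#'
#' @param calls Call table from [load_program_calls()].
#' @param anchor_programs Character vector of exactly two program labels.
#' @return Data frame of intervals (`left`, `right`, `strand`), one per stop
#'   anchor, using the widest extent either anchor program reported.
#' @export
strong_calls <- function(calls, anchor_programs) {
  if (length(anchor_programs) != 2L) {
    stop("exactly two anchor programs are required")
  }
  sub <- calls[calls$program %in% anchor_programs, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(data.frame(left = integer(0), right = integer(0), strand = character(0)))
  }
  sub$strand <- normalize_strand(sub$strand)
  keys <- interval_keys(sub)
  keep_keys <- names(which(vapply(
    split(sub$program, keys), function(p) length(unique(p)) == 2L, logical(1L)
  )))
  sub <- sub[keys %in% keep_keys, , drop = FALSE]
  keys <- interval_keys(sub)
  agg <- lapply(split(seq_len(nrow(sub)), keys), function(i) {
    data.frame(
      left = min(sub$left[i]), right = max(sub$right[i]),
      strand = sub$strand[i[1L]]
    )
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Coding gaps: regions no anchor program covered
#'
#' Maximal intervals of the genome not covered by any anchor-program call;
#' these are searched for genes the anchor callers missed. Candidate putative
#' genes are the ORFs longer than the configured minimum that intersect a
#' gap.
#'
#' @param genome_len Genome length.
#' @param anchor_calls Data frame of intervals (`left`, `right`).
#' @return Data frame of gap intervals (`left`, `right`); one genome-spanning
#'   row when there are no calls, zero rows when calls tile the genome.
#' @export
find_coding_gaps <- function(genome_len, anchor_calls) {
  if (is.null(anchor_calls) || nrow(anchor_calls) == 0L) {
    return(data.frame(left = 1L, right = as.integer(genome_len)))
  }
  o <- order(anchor_calls$left, anchor_calls$right)
  l <- as.integer(anchor_calls$left[o]); r <- as.integer(anchor_calls$right[o])
  gaps <- list()
  cursor <- 1L
  for (i in seq_along(l)) {
    if (l[i] > cursor) {
      gaps[[length(gaps) + 1L]] <- c(cursor, l[i] - 1L)
    }
    cursor <- max(cursor, r[i] + 1L)
  }
  if (cursor <= genome_len) {
    gaps[[length(gaps) + 1L]] <- c(cursor, as.integer(genome_len))
  }
  if (!length(gaps)) {
    return(data.frame(left = integer(0), right = integer(0)))
  }
  m <- do.call(rbind, gaps)
  data.frame(left = m[, 1L], right = m[, 2L])
}

#' ORFs intersecting coding gaps
#' @param orfs ORF table.
#' @param gaps Gap table from [find_coding_gaps()].
#' @return The subset of `orfs` overlapping any gap by at least 1 bp.
#' @export
orfs_in_gaps <- function(orfs, gaps) {
  if (nrow(orfs) == 0L || nrow(gaps) == 0L) return(orfs[0L, , drop = FALSE])
  hit <- vapply(seq_len(nrow(orfs)), function(i) {
    any(overlap_bp(orfs$left[i], orfs$right[i], gaps$left, gaps$right) > 0L)
  }, logical(1L))
  orfs[hit, , drop = FALSE]
}

#' Flag potential false positives among program calls
#'
#' Genes called by exactly one program, or by several programs but with very
#' short ORFs (shorter than `short_len`, default 120 bp), are routed through
#' the full rubric; genes called by two or more programs with ordinary
#' lengths are accepted without review.
#'
#' @param calls Call table.
#' @param orfs Optional ORF universe used to measure each called gene's ORF
#'   length; calls whose stop anchor is absent fall back to the call span.
#' @param short_len Length threshold in bp.
#' @return Character vector of flagged stop-anchor keys.
#' @export
triage_potential_false_positives <- function(calls, orfs = NULL,
                                             short_len = 120L) {
  if (nrow(calls) == 0L) return(character(0))
  calls$strand <- normalize_strand(calls$strand)
  keys <- interval_keys(calls)
  n_prog <- vapply(split(calls$program, keys), function(p) length(unique(p)),
                   integer(1L))
  span <- vapply(split(as.numeric(calls$right - calls$left + 1), keys), max,
                 numeric(1L))
  len <- span
  if (!is.null(orfs) && nrow(orfs) > 0L) {
    m <- match(names(len), orfs$orf_key)
    len[!is.na(m)] <- orfs$length_bp[m[!is.na(m)]]
  }
  flagged <- n_prog == 1L | (n_prog > 1L & len < short_len)
  sort(names(which(flagged)))
}

#' Score a set of putative genes with the full rubric
#'
#' Produces the curation spreadsheet: one row per ORF with the five component
#' scores, the total and the verdict, mirroring the manual workflow's
#' columns (reading frame, 5' end, 3' end, programs, coding potential,
#' sequence similarity, overlap, length, points, result).
#'
#' @param orfs ORF table (the putative genes to evaluate).
#' @param calls Call table.
#' @param track A [coding_track()] or `NULL`.
#' @param sim Similarity table or `NULL`.
#' @param strong Strong-call intervals (see [strong_calls()]), or `NULL`.
#' @param config A [rubric_config()].
#' @return Data frame with one decision row per ORF.
#' @export
score_genes <- function(orfs, calls, track = NULL, sim = NULL, strong = NULL,
                        config = rubric_config()) {
  ev <- build_evidence(orfs, calls, track, sim, config)
  n <- nrow(orfs)
  overlap_score <- integer(n); worst_ov <- integer(n); operon <- logical(n)
  total <- integer(n); verdict <- character(n); length_score <- integer(n)
  for (i in seq_len(n)) {
    ovl <- score_overlap(orfs[i, ], strong, config)
    overlap_score[i] <- ovl$score
    worst_ov[i] <- ovl$context$worst_overlap_bp
    operon[i] <- ovl$context$operon_overlap
    length_score[i] <- score_length(orfs$length_bp[i], config$length_bins)
    dec <- total_score(
      ev$program_count[i], ev$coding_class[i], ev$similarity_class[i],
      overlap_score[i], length_score[i], config
    )
    total[i] <- dec$total
    verdict[i] <- dec$verdict
  }
  data.frame(
    orf_key = orfs$orf_key,
    reading_frame = paste0(ifelse(orfs$strand == "+", "F", "R"), orfs$frame),
    five_prime = ifelse(orfs$strand == "+", orfs$left, orfs$right),
    three_prime = ifelse(orfs$strand == "+", orfs$right, orfs$left),
    programs = ev$program_count,
    coding_potential = ev$coding_class,
    sequence_similarity = ev$similarity_class,
    overlap_bp = worst_ov,
    operon = operon,
    overlap_score = overlap_score,
    length_bp = orfs$length_bp,
    length_score = length_score,
    points = total,
    result = c(Keep = "Add", Discard = "Delete", Borderline = "Review")[verdict],
    verdict = verdict
  )
}
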