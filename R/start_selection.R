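#' Overlap/gap arithmetic between a start candidate and a neighbouring stop
#'
#' For a forward gene the upstream neighbour's stop coordinate minus the
#' candidate start gives the raw difference; for a reverse gene it is the
#' candidate start minus the downstream neighbour's stop. A non-negative raw
#' difference is an overlap and 1 is added (so coordinate-equal start and
#' stop count as a 1 bp overlap); a negative difference is a gap and 1 is
#' subtracted. Positive results are overlaps in bp; negative results are
#' gaps. Note the gap branch is a bookkeeping convention 2 bp larger in
#' magnitude than the plain intergenic base count and is used comparatively;
#' [overlap_context()] reports geometric distances.
#'
#' @param candidate_coord Candidate start coordinate(s), 5'-most base.
#' @param neighbor_stop 3'-end coordinate of the neighbouring gene's stop
#'   codon (upstream gene for forward genes, downstream gene for reverse).
#' @param orientation `"forward"` or `"reverse"` (the candidate gene's
#'   strand).
#' @return Signed integer(s): positive = overlap bp, negative = gap.
#' @examples
#' start_overlap_or_gap(998, 1000, "forward")  # 3 shared bases
#' start_overlap_or_gap(1000, 1000, "forward") # +1: operon candidate
#' @export
start_overlap_or_gap <- function(candidate_coord, neighbor_stop, orientation) {
  orientation <- match.arg(orientation, c("forward", "reverse"))
  r <- if (orientation == "forward") {
    as.integer(neighbor_stop) - as.integer(candidate_coord)
  } else {
    as.integer(candidate_coord) - as.integer(neighbor_stop)
  }
  ifelse(r >= 0L, r + 1L, r - 1L)
}

#' Divergent (head-to-head) promoter-room table
#'
#' For a facing forward/reverse gene pair, every combination of candidate 5'
#' ends is tabulated two ways: the conventional bookkeeping value
#' `(forward_start - reverse_start) + 50`, and the geometric 5'-to-5'
#' intergenic gap. A cell satisfies the promoter rule when the geometric gap
#' is at least `required_gap` (default 50 bp); overlapping 5' ends always
#' violate it.
#'
#' @param forward_starts Candidate 5' coordinates of the forward gene (rows).
#' @param reverse_starts Candidate 5' coordinates of the reverse gene
#'   (columns).
#' @param required_gap Minimum promoter room in bp.
#' @return List of three matrices: `formula` (bookkeeping values), `gap`
#'   (geometric 5'-to-5' gaps) and `ok` (logical).
#' @export
divergent_pair_table <- function(forward_starts, reverse_starts,
                                 required_gap = 50L) {
  f <- as.integer(forward_starts); r <- as.integer(reverse_starts)
  formula <- outer(f, r, function(a, b) (a - b) + 50L)
  gap <- outer(f, r, function(a, b) a - b - 1L)
  dimnames(formula) <- dimnames(gap) <- list(f, r)
  list(formula = formula, gap = gap, ok = gap >= required_gap)
}

#' Assemble the per-candidate evidence rows for one ORF
#'
#' @param orf The ORF row (from [find_orfs()]).
#' @param genome The [genome_sequence()].
#' @param track A [coding_track()] or `NULL`.
#' @param calls Call table or `NULL`.
#' @param sim Similarity table or `NULL`.
#' @param sd SD score table (see [read_sd_table()]) or `NULL`.
#' @param neighbor_stop 3' coordinate of the relevant neighbouring gene's
#'   stop codon (upstream for forward genes, downstream for reverse), or `NA`
#'   when there is none (treated as a very large gap).
#' @param config A [rubric_config()].
#' @return Data frame of `StartEvidenceRow`s ordered 5' to 3' (longest gene
#'   first): `coordinate`, `codon`, `covers_coding_potential`,
#'   `overlap_or_gap`, `operon`, `program_votes`,
#'   `similarity_start_matches`, `sd_score`, `resulting_length_bp`.
#' @export
build_start_rows <- function(orf, genome, track = NULL, calls = NULL,
                             sim = NULL, sd = NULL, neighbor_stop = NA,
                             config = rubric_config()) {
  cand <- enumerate_start_candidates(orf, genome, config$start_codons)
  n <- nrow(cand)
  if (n == 0L) return(cbind(cand, empty_start_cols(0L)))
  strand <- normalize_strand(orf$strand[1L])
  three <- if (strand == "+") orf$right[1L] else orf$left[1L]

  plateau <- if (is.null(track)) NULL else {
    coding_plateau(track, orf, config$coding_high)
  }
  covers <- covers_all_coding_potential(cand$coordinate, plateau, strand)

  ovg <- if (is.na(neighbor_stop)) rep(-.Machine$integer.max, n) else {
    start_overlap_or_gap(
      cand$coordinate, neighbor_stop,
      if (strand == "+") "forward" else "reverse"
    )
  }
  operon <- ovg %in% config$operon_overlaps

  votes <- if (is.null(calls)) integer(n) else {
    start_program_votes(cand, orf, calls)
  }
  sim_rows <- if (is.null(sim)) sim else sim[sim$orf_key == cand$orf_key[1L], , drop = FALSE]
  smatch <- if (is.null(sim_rows)) integer(n) else {
    start_similarity_matches(cand, sim_rows, strand, config$sim_sig)
  }
  sd_score <- rep(NA_real_, n)
  if (!is.null(sd) && nrow(sd) > 0L) {
    m <- match(cand$coordinate, sd$start_coordinate)
    sd_score[!is.na(m)] <- sd$sd_score[m[!is.na(m)]]
  }
  sd_score[operon] <- NA_real_ # SD is irrelevant for operon-forming starts
  cbind(cand, data.frame(
    covers_coding_potential = covers,
    overlap_or_gap = as.integer(ovg),
    operon = operon,
    program_votes = votes,
    similarity_start_matches = smatch,
    sd_score = sd_score,
    resulting_length_bp = abs(as.integer(three) - cand$coordinate) + 1L
  ))
}

empty_start_cols <- function(n) {
  data.frame(
    covers_coding_potential = logical(n), overlap_or_gap = integer(n),
    operon = logical(n), program_votes = integer(n),
    similarity_start_matches = integer(n), sd_score = numeric(n),
    resulting_length_bp = integer(n)
  )
}

#' Choose a start codon by ordered elimination
#'
#' Candidates are eliminated by strictly ordered criteria:
#' \enumerate{
#'   \item starts that fail to retain all coding potential are dropped first
#'     (whenever at least one candidate does retain it);
#'   \item starts with an unusually large overlap (over
#'     `config$large_overlap`, default 100 bp) are dropped while alternatives
#'     remain; if any survivor forms an operon junction (overlap of exactly
#'     1, 4 or 8 bp), the field is restricted to those;
#'   \item the most auto-annotation program votes wins;
#'   \item then the most start-specific similarity matches;
#'   \item then the best Shine-Dalgarno score (negative, closest to zero;
#'     scores within `config$sd_tie_tol` are tied, missing scores compare as
#'     worst; skipped entirely when the survivors are operon-forming starts);
#'   \item finally the longest resulting gene without more than 10 bp of
#'     overlap breaks remaining ties.
#' }
#'
#' @param rows Data frame of candidate evidence rows (see
#'   [build_start_rows()]); row order is irrelevant.
#' @param config A [rubric_config()].
#' @return List: `chosen` (the winning row), `coordinate`, and `audit` (a data
#'   frame mapping every candidate to the criterion that eliminated it,
#'   `"chosen"` for the winner).
#' @export
select_start <- function(rows, config = rubric_config()) {
  n <- nrow(rows)
  if (n == 0L) stop("no start candidates to select from")
  alive <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  eliminate <- function(drop, why) {
    idx <- which(alive & drop)
    reason[idx] <<- why
    alive[idx] <<- FALSE
  }

  # 1. coding-potential coverage
  if (any(rows$covers_coding_potential[alive])) {
    eliminate(!rows$covers_coding_potential, "coding_potential")
  }
  # 2. unusually large overlap, then operon privilege
  small <- rows$overlap_or_gap <= config$large_overlap
  if (any(alive & small)) eliminate(!small, "large_overlap")
  if (any(alive & rows$operon)) eliminate(!rows$operon, "operon")
  # 3. program votes
  eliminate(rows$program_votes < max(rows$program_votes[alive]), "programs")
  # 4. similarity start matches
  eliminate(
    rows$similarity_start_matches < max(rows$similarity_start_matches[alive]),
    "similarity"
  )
  # 5. SD score (irrelevant for operon-forming survivors)
  if (sum(alive) > 1L && !all(rows$operon[alive])) {
    sd <- rows$sd_score
    if (any(alive & !is.na(sd))) {
      best <- max(sd[alive], na.rm = TRUE)
      eliminate(is.na(sd) | sd < best - config$sd_tie_tol, "sd_score")
    }
  }
  # 6. longest gene with tolerable (<= 10 bp) overlap
  if (sum(alive) > 1L) {
    tolerable <- rows$overlap_or_gap <= 10L
    if (any(alive & tolerable)) eliminate(!tolerable, "length")
    eliminate(
      rows$resulting_length_bp < max(rows$resulting_length_bp[alive]),
      "length"
    )
    if (sum(alive) > 1L) {
      # fully tied rows (possible only for synthetic input): break the tie on
      # the coordinate so the result is permutation-invariant
      eliminate(rows$coordinate != min(rows$coordinate[alive]), "length")
    }
  }
  idx <- which(alive)
  reason[idx] <- "chosen"
  list(
    chosen = rows[idx, , drop = FALSE],
    coordinate = rows$coordinate[idx],
    audit = data.frame(
      coordinate = rows$coordinate,
      eliminated_by = reason
    )
  )
}

#' Can the full start analysis be skipped?
#'
#' True when there is a single candidate, or when the candidate producing the
#' longest gene is the start every calling program picked (a shorter start
#' can then never score better on coding potential). A gene no program called
#' never takes the shortcut.
#'
#' @param rows Candidate evidence rows (see [build_start_rows()]).
#' @param n_programs_calling Number of programs that called the gene at all.
#' @return Logical.
#' @export
shortcut_applies <- function(rows, n_programs_calling) {
  if (nrow(rows) == 1L) return(TRUE)
  if (n_programs_calling == 0L) return(FALSE)
  longest <- which.max(rows$resulting_length_bp)
  rows$program_votes[longest] == n_programs_calling
}
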