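#' Run the full curation pipeline on one genome
#'
#' Enumerates the ORF universe, scores every ORF with the five-criterion
#' rubric against the loaded evidence, keeps genes at or above the keep
#' threshold, and selects a start codon for each kept gene by ordered
#' elimination.
#'
#' @param genome A [genome_sequence()].
#' @param calls Call table from [load_program_calls()] (or compatible).
#' @param track A [coding_track()] or `NULL`.
#' @param sim Similarity table or `NULL`.
#' @param sd SD-score table or `NULL`.
#' @param config A [rubric_config()]; `config$anchor_programs` (two labels)
#'   defines the strong calls, otherwise overlap is scored against nothing.
#' @return List: `orfs` (the universe), `decisions` (rubric spreadsheet),
#'   `predicted` (kept genes with chosen starts: `orf_key`, `strand`, `left`,
#'   `right`), `starts` (per-candidate audit rows for kept genes).
#' @export
annotate_genome <- function(genome, calls, track = NULL, sim = NULL,
                            sd = NULL, config = rubric_config()) {
  orfs <- find_orfs(genome, config$min_orf_len, config$start_codons)
  strong <- if (length(config$anchor_programs) == 2L) {
    strong_calls(calls, config$anchor_programs)
  } else NULL
  decisions <- score_genes(orfs, calls, track, sim, strong, config)
  kept <- orfs[decisions$verdict == "Keep", , drop = FALSE]

  three_all <- ifelse(kept$strand == "+", kept$right, kept$left)
  predicted <- kept
  audits <- list()
  for (i in seq_len(nrow(kept))) {
    orf <- kept[i, ]
    mine <- three_all[i]
    # upstream (forward) / downstream (reverse) neighbour: the nearest other
    # kept gene's 3' end on the 5' side of this gene's stop
    neighbor <- if (orf$strand == "+") {
      cand <- three_all[three_all < mine]
      if (length(cand)) max(cand) else NA_integer_
    } else {
      cand <- three_all[three_all > mine]
      if (length(cand)) min(cand) else NA_integer_
    }
    rows <- build_start_rows(orf, genome, track, calls, sim, sd,
                             neighbor_stop = neighbor, config = config)
    sel <- select_start(rows, config)
    if (orf$strand == "+") predicted$left[i] <- sel$coordinate
    else predicted$right[i] <- sel$coordinate
    a <- sel$audit
    a$orf_key <- orf$orf_key
    a$chosen <- a$eliminated_by == "chosen"
    audits[[i]] <- cbind(rows, a[, c("eliminated_by", "chosen")])
  }
  predicted$length_bp <- predicted$right - predicted$left + 1L
  starts <- if (length(audits)) do.call(rbind, audits) else NULL
  list(orfs = orfs, decisions = decisions, predicted = predicted,
       starts = starts)
}

#' Benchmark a prediction against a reference annotation
#'
#' @param predicted Predicted genes (`strand`, `left`, `right`), e.g.
#'   `annotate_genome(...)$predicted`.
#' @param reference Reference annotation (see [read_reference()]).
#' @param orf_universe ORF table from [find_orfs()].
#' @param method Label for the report row.
#' @return One-row data frame mirroring the benchmark tables: confusion
#'   counts, sensitivity/specificity (raw and rounded to the nearest 0.5%),
#'   and start-accuracy columns.
#' @export
evaluate_annotation <- function(predicted, reference, orf_universe,
                                method = "manual") {
  cc <- confusion(predicted, reference, orf_universe)
  sa <- start_accuracy(predicted, reference)
  data.frame(
    method = method,
    positives = cc$TP + cc$FP,
    TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN,
    sensitivity = sensitivity(cc),
    specificity = specificity(cc),
    sensitivity_rounded = round_half_percent(sensitivity(cc)),
    specificity_rounded = round_half_percent(specificity(cc)),
    starts_correct = sa$n_correct,
    starts_long = sa$n_long,
    starts_short = sa$n_short,
    pct_correct_starts = sa$percent_correct,
    pct_correct_starts_rounded = if (is.na(sa$percent_correct)) NA_real_ else
      round_half_percent(sa$percent_correct)
  )
}
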