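#' Confusion counts against a reference annotation
#'
#' Genes are matched by stop anchor, so nested genes with distinct stops are
#' scored independently and start-codon disagreement does not affect gene
#' identification. The negative universe is the set of ORFs (longer than the
#' configured minimum) whose stop anchor is not a reference gene.
#'
#' @param predicted Character vector of predicted stop-anchor keys, or a data
#'   frame with `strand`, `left`, `right` columns.
#' @param reference Reference annotation: data frame with `strand`, `left`,
#'   `right` (see [read_reference()]), or a character vector of keys.
#' @param orf_universe ORF table from [find_orfs()] (or a character vector of
#'   keys): every ORF considered, coding or not.
#' @return List of class `confusion_counts` with integer fields `TP`, `FP`,
#'   `FN`, `TN`. `TP + FN` equals the reference gene count and `FP + TN` the
#'   non-coding universe size.
#' @export
confusion <- function(predicted, reference, orf_universe) {
  as_keys <- function(x) {
    if (is.character(x)) unique(x) else unique(interval_keys(x))
  }
  pred <- as_keys(predicted)
  ref <- as_keys(reference)
  uni <- as_keys(orf_universe)
  missing_ref <- setdiff(ref, uni)
  if (length(missing_ref)) {
    warning(
      length(missing_ref), " reference stop anchor(s) absent from the ORF ",
      "universe (start-codon-set or length-threshold mismatch); they still ",
      "count towards TP/FN"
    )
  }
  tp <- length(intersect(pred, ref))
  fp <- length(setdiff(pred, ref))
  fn <- length(setdiff(ref, pred))
  noncoding <- length(setdiff(uni, ref))
  structure(
    list(TP = tp, FP = fp, FN = fn, TN = noncoding - fp),
    class = "confusion_counts"
  )
}

#' Sensitivity and specificity in percent
#'
#' Sensitivity = 100 * TP / (TP + FN); specificity = 100 * TN / (TN + FP).
#'
#' @param counts A [confusion()] result or any list with `TP`, `FP`, `FN`,
#'   `TN`.
#' @return Percentage (unrounded); errors on an undefined (zero) denominator.
#' @export
sensitivity <- function(counts) {
  d <- counts$TP + counts$FN
  if (d == 0) stop("sensitivity undefined: TP + FN = 0")
  100 * counts$TP / d
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  d <- counts$TN + counts$FP
  if (d == 0) stop("specificity undefined: TN + FP = 0")
  100 * counts$TN / d
}

#' Round a percentage to the nearest 0.5% (half-up)
#'
#' Presentation-layer rounding used in benchmark tables; stored metrics stay
#' unrounded.
#'
#' @param x Percentages (vectorised).
#' @return Multiples of 0.5.
#' @examples
#' round_half_percent(c(89.04, 92.31, 95.23))
#' @export
round_half_percent <- function(x) {
  floor(x * 2 + 0.5) / 2
}

#' Start-codon accuracy over true-positive genes
#'
#' For every gene whose stop anchor is both predicted and in the reference,
#' the predicted 5' end is compared with the reference 5' end: an exact match
#' is correct; otherwise the call is "long" when the predicted gene extends
#' beyond the reference gene and "short" when it is contained in it.
#'
#' @param predicted Data frame with `strand`, `left`, `right` for each
#'   predicted gene (one row per stop anchor).
#' @param reference Reference annotation data frame (same columns).
#' @return List of class `start_accuracy`: `n_correct`, `n_long`, `n_short`,
#'   `TP`, and `percent_correct` (unrounded).
#' @export
start_accuracy <- function(predicted, reference) {
  pk <- interval_keys(predicted)
  rk <- interval_keys(reference)
  common <- intersect(pk, rk)
  tp <- length(common)
  if (tp == 0L) {
    return(structure(
      list(n_correct = 0L, n_long = 0L, n_short = 0L, TP = 0L,
           percent_correct = NA_real_),
      class = "start_accuracy"
    ))
  }
  pi <- match(common, pk); ri <- match(common, rk)
  p5 <- ifelse(predicted$strand[pi] == "+", predicted$left[pi], predicted$right[pi])
  r5 <- ifelse(reference$strand[ri] == "+", reference$left[ri], reference$right[ri])
  plen <- predicted$right[pi] - predicted$left[pi]
  rlen <- reference$right[ri] - reference$left[ri]
  correct <- p5 == r5
  long <- !correct & plen > rlen
  short <- !correct & !long
  structure(
    list(
      n_correct = sum(correct), n_long = sum(long), n_short = sum(short),
      TP = tp, percent_correct = 100 * sum(correct) / tp
    ),
    class = "start_accuracy"
  )
}

#' Read a reference annotation (CDS features only)
#'
#' GFF3 is parsed with rtracklayer; GenBank flat files with a minimal
#' feature-table reader (no R package in scope parses GenBank offline). Only
#' CDS features are kept; `join(...)` compound locations collapse to their
#' outermost coordinates with a warning; tRNA and other features are ignored.
#'
#' @param path File path.
#' @param format `"gff3"` or `"genbank"`; guessed from the extension by
#'   default.
#' @return Data frame with `left`, `right`, `strand`, `orf_key`.
#' @export
read_reference <- function(path, format = c("auto", "gff3", "genbank")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gbk?|gbff|genbank)$", path, ignore.case = TRUE)) {
      "genbank"
    } else "gff3"
  }
  ref <- if (format == "gff3") read_reference_gff3(path) else read_reference_genbank(path)
  if (anyDuplicated(interval_keys(ref))) {
    stop("reference annotation has duplicate stop anchors")
  }
  ref$orf_key <- interval_keys(ref)
  ref
}

read_reference_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  data.frame(
    left = GenomicRanges::start(gr),
    right = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

read_reference_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  feat_start <- grep("^FEATURES", lines)
  if (!length(feat_start)) stop("no FEATURES table in GenBank file '", path, "'")
  end_keys <- grep("^(ORIGIN|CONTIG|//)", lines)
  feat_end <- if (length(end_keys)) min(end_keys[end_keys > feat_start[1L]]) - 1L else length(lines)
  block <- lines[(feat_start[1L] + 1L):feat_end]

  is_key <- grepl("^ {5}\\S", block)
  key <- sub("^ {5}(\\S+).*$", "\\1", block)
  locs <- character(0)
  i <- 1L
  while (i <= length(block)) {
    if (is_key[i] && key[i] == "CDS") {
      loc <- sub("^ {5}\\S+\\s+", "", block[i])
      j <- i + 1L
      # location may continue over lines until a qualifier (/) or new key
      while (j <= length(block) && !is_key[j] &&
             !grepl("^\\s+/", block[j])) {
        loc <- paste0(loc, trimws(block[j]))
        j <- j + 1L
      }
      locs <- c(locs, gsub("\\s", "", loc))
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (!length(locs)) {
    return(data.frame(left = integer(0), right = integer(0), strand = character(0)))
  }
  parse_loc <- function(loc) {
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
      strand <- "-"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    if (grepl("^join\\(", loc)) {
      warning("compound (join) CDS location collapsed to outermost coordinates: ", loc)
      loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    }
    nums <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
    data.frame(left = min(nums), right = max(nums), strand = strand)
  }
  out <- do.call(rbind, lapply(locs, parse_loc))
  rownames(out) <- NULL
  out
}

#' Write gene intervals as GFF3 CDS features
#'
#' @param genes Data frame with `left`, `right`, `strand` (and optionally
#'   `orf_key` used as the ID).
#' @param path Output path.
#' @param seqid Sequence identifier for column 1.
#' @param source Value for the source column.
#' @return `path`, invisibly.
#' @export
write_reference_gff3 <- function(genes, path, seqid = "genome",
                                 source = "phageCurate") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = genes$left, end = genes$right),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$phase <- 0L
  if (!is.null(genes$orf_key)) S4Vectors::mcols(gr)$ID <- genes$orf_key
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d TN=%d\n", x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' @export
print.start_accuracy <- function(x, ...) {
  cat(sprintf(
    "TP=%d correct=%d long=%d short=%d (%.2f%% correct)\n",
    x$TP, x$n_correct, x$n_long, x$n_short, x$percent_correct
  ))
  invisible(x)
}
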