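# Independent brute-force oracles. These deliberately share no code with the
# package internals: the ORF oracle walks codon-by-codon from every candidate
# start, and the start-selection oracle applies the criteria as sequential
# data-frame subsets.

oracle_orfs <- function(seq, min_len = 76L, starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  scan_one <- function(s) {
    L <- nchar(s)
    hits <- list()
    for (i in seq_len(max(0L, L - 2L))) {
      if (!(substr(s, i, i + 2L) %in% starts)) next
      j <- i + 3L
      while (j + 2L <= L) {
        cod <- substr(s, j, j + 2L)
        if (cod %in% stops) {
          hits[[length(hits) + 1L]] <- c(left = i, right = j + 2L)
          break
        }
        j <- j + 3L
      }
    }
    if (!length(hits)) {
      return(data.frame(left = integer(0), right = integer(0)))
    }
    df <- as.data.frame(do.call(rbind, hits))
    # one ORF per stop: the 5'-most start defines it
    df <- df[order(df$right, df$left), ]
    df <- df[!duplicated(df$right), ]
    df[df$right - df$left + 1L >= min_len, , drop = FALSE]
  }
  L <- nchar(seq)
  fw <- scan_one(seq)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  rv <- scan_one(rc)
  out <- rbind(
    if (nrow(fw)) data.frame(strand = "+", left = fw$left, right = fw$right),
    if (nrow(rv)) data.frame(strand = "-", left = L - rv$right + 1L,
                             right = L - rv$left + 1L)
  )
  if (is.null(out)) {
    return(data.frame(strand = character(0), left = integer(0),
                      right = integer(0)))
  }
  out[order(out$left, out$strand), , drop = FALSE]
}

orf_set_string <- function(df) {
  sort(paste(df$strand, df$left, df$right, sep = ":"))
}

oracle_select_start <- function(rows, large_overlap = 100, sd_tol = 0.1) {
  df <- rows
  if (any(df$covers_coding_potential)) {
    df <- df[df$covers_coding_potential, , drop = FALSE]
  }
  if (any(df$overlap_or_gap <= large_overlap)) {
    df <- df[df$overlap_or_gap <= large_overlap, , drop = FALSE]
  }
  if (any(df$operon)) df <- df[df$operon, , drop = FALSE]
  df <- df[df$program_votes == max(df$program_votes), , drop = FALSE]
  df <- df[df$similarity_start_matches == max(df$similarity_start_matches), ,
           drop = FALSE]
  if (nrow(df) > 1L && !all(df$operon) && any(!is.na(df$sd_score))) {
    best <- max(df$sd_score, na.rm = TRUE)
    df <- df[!is.na(df$sd_score) & df$sd_score >= best - sd_tol, ,
             drop = FALSE]
  }
  if (nrow(df) > 1L) {
    if (any(df$overlap_or_gap <= 10L)) {
      df <- df[df$overlap_or_gap <= 10L, , drop = FALSE]
    }
    df <- df[df$resulting_length_bp == max(df$resulting_length_bp), ,
             drop = FALSE]
    df <- df[order(df$coordinate), , drop = FALSE]
  }
  df$coordinate[1L]
}

random_start_rows <- function(n) {
  ovg <- sample(c(-200:150, 1L, 4L, 8L), n, replace = TRUE)
  data.frame(
    coordinate = sample.int(5000L, n),
    covers_coding_potential = sample(c(TRUE, FALSE), n, replace = TRUE),
    overlap_or_gap = ovg,
    operon = ovg %in% c(1L, 4L, 8L) & runif(n) < 0.5,
    program_votes = sample(0:4, n, replace = TRUE),
    similarity_start_matches = sample(0:5, n, replace = TRUE),
    sd_score = ifelse(runif(n) < 0.2, NA_real_,
                      -round(runif(n, 1, 9), 1)),
    resulting_length_bp = sample(seq(90L, 900L, 3L), n, replace = TRUE)
  )
}
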