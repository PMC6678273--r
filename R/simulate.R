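NON_STOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  setdiff(as.vector(outer(outer(b, b, paste0), b, paste0)),
          c("TAA", "TAG", "TGA"))
})

# fixed non-uniform codon weights; `strength` interpolates from uniform (0)
# to fully biased (1). Simple, but enough to give planted genes the
# compositional contrast the rubric consumes.
codon_weights <- function(strength) {
  w0 <- exp(-0.06 * seq(0, length(NON_STOP_CODONS) - 1L))
  w0 <- w0 / sum(w0)
  (1 - strength) / length(NON_STOP_CODONS) + strength * w0
}

sample_codons <- function(n, strength) {
  sample(NON_STOP_CODONS, n, replace = TRUE, prob = codon_weights(strength))
}

# forward-sense gene: ATG + biased codons + stop; tail constraints allow the
# operon-junction stamps below
plant_gene_seq <- function(n_codons, strength, stop_codon = NULL,
                           tail_codons = NULL, head = NULL) {
  stop_codon <- if (is.null(stop_codon)) sample(STOP_CODONS, 1L) else stop_codon
  n_tail <- if (is.null(tail_codons)) 0L else length(tail_codons)
  body <- sample_codons(max(0L, n_codons - n_tail), strength)
  if (is.null(head)) head <- "ATG"
  paste0(head, paste(c(body, tail_codons), collapse = ""), stop_codon)
}

# two same-strand genes overlapping by exactly 1, 4 or 8 bp (stop/start
# junction), built in forward sense; returns list(seq, genes (local coords))
plant_operon_cassette <- function(ov, n_codons_a, n_codons_b, strength) {
  if (ov == 1L) {
    a <- plant_gene_seq(n_codons_a, strength, stop_codon = "TAA")
    b <- plant_gene_seq(n_codons_b, strength)
    seq <- paste0(a, substring(b, 2L))
    b_left <- nchar(a)
  } else if (ov == 4L) {
    a <- plant_gene_seq(n_codons_a, strength, stop_codon = "TGA",
                        tail_codons = "GCA")
    # B's second codon must start with A (shared with A's final stop base)
    b <- plant_gene_seq(
      n_codons_b, strength,
      head = paste0("ATG", "A", paste(sample(c("A", "C", "G", "T"), 2L,
                                             replace = TRUE), collapse = ""))
    )
    stopifnot(substring(b, 1L, 4L) == substring(a, nchar(a) - 3L, nchar(a)))
    seq <- paste0(a, substring(b, 5L))
    b_left <- nchar(a) - 3L
  } else if (ov == 8L) {
    a <- plant_gene_seq(n_codons_a, strength, stop_codon = "TGA",
                        tail_codons = c("CAT", "GCC"))
    b <- plant_gene_seq(
      n_codons_b, strength,
      head = paste0("ATGCCTGA", sample(c("A", "C", "G", "T"), 1L))
    )
    stopifnot(substring(b, 1L, 8L) == substring(a, nchar(a) - 7L, nchar(a)))
    seq <- paste0(a, substring(b, 9L))
    b_left <- nchar(a) - 7L
  } else {
    stop("operon overlap must be 1, 4 or 8 bp")
  }
  list(
    seq = seq,
    genes = data.frame(
      left = c(1L, b_left),
      right = c(nchar(a), nchar(seq)),
      strand = "+"
    )
  )
}

reflect_genes <- function(genes, M) {
  data.frame(
    left = M - genes$right + 1L,
    right = M - genes$left + 1L,
    strand = ifelse(genes$strand == "+", "-", "+")
  )[rev(seq_len(nrow(genes))), , drop = FALSE]
}

#' Plant a synthetic genome with known genes
#'
#' Generates a linear genome in which coding regions are drawn from a biased
#' codon distribution and intergenic regions from uniform random bases, so
#' the truth is known exactly. A configurable fraction of adjacent same-strand
#' gene pairs share 1/4/8 bp stop/start operon junctions, and one
#' head-to-head (divergent) pair with comfortable promoter room is planted
#' when space allows. Fully deterministic per seed.
#'
#' @param n_genes Number of genes to plant.
#' @param length_bp Genome length (intergenic spacers absorb the slack).
#' @param seed Integer seed; all randomness flows from it.
#' @param codon_bias_strength 0 (uniform codons) .. 1 (fully biased).
#' @param operon_fraction Approximate fraction of genes planted as operon
#'   junction pairs.
#' @param divergent_pair Plant one head-to-head pair (needs >= 2 genes).
#' @param gene_codons Range of inner codon counts per gene (gene length is
#'   `3 * (codons + 2)` bp).
#' @return List of class `planted_genome`: `genome` (a [genome_sequence()])
#'   and `truth` (data frame `left`, `right`, `strand`, `orf_key`,
#'   `true_start`, `length_bp`).
#' @export
plant_genome <- function(n_genes = 10L, length_bp = 20000L, seed = 1L,
                         codon_bias_strength = 0.8, operon_fraction = 0.2,
                         divergent_pair = TRUE, gene_codons = c(60L, 200L)) {
  stopifnot(n_genes >= 1L, length_bp >= 200L)
  withr::with_seed(derive_seed(seed, "plant_genome"), {
    strength <- codon_bias_strength
    cassettes <- list()
    remaining <- n_genes
    planted_divergent <- FALSE
    while (remaining > 0L) {
      n_cod <- function() sample(seq(gene_codons[1L], gene_codons[2L]), 1L)
      if (divergent_pair && !planted_divergent && remaining >= 2L) {
        gA <- plant_gene_seq(n_cod(), strength)
        gB <- plant_gene_seq(n_cod(), strength)
        gap <- 60L
        spacer <- paste(sample(c("A", "C", "G", "T"), gap, replace = TRUE),
                        collapse = "")
        seq <- paste0(revcomp(gA), spacer, gB)
        genes <- data.frame(
          left = c(1L, nchar(gA) + gap + 1L),
          right = c(nchar(gA), nchar(seq)),
          strand = c("-", "+")
        )
        cassettes[[length(cassettes) + 1L]] <- list(seq = seq, genes = genes)
        planted_divergent <- TRUE
        remaining <- remaining - 2L
      } else if (remaining >= 2L && stats::runif(1) < operon_fraction) {
        ov <- sample(c(1L, 4L, 8L), 1L)
        cas <- plant_operon_cassette(ov, n_cod(), n_cod(), strength)
        if (stats::runif(1) < 0.5) {
          M <- nchar(cas$seq)
          cas <- list(seq = revcomp(cas$seq), genes = reflect_genes(cas$genes, M))
        }
        cassettes[[length(cassettes) + 1L]] <- cas
        remaining <- remaining - 2L
      } else {
        g <- plant_gene_seq(n_cod(), strength)
        rev <- stats::runif(1) < 0.5
        cassettes[[length(cassettes) + 1L]] <- list(
          seq = if (rev) revcomp(g) else g,
          genes = data.frame(left = 1L, right = nchar(g),
                             strand = if (rev) "-" else "+")
        )
        remaining <- remaining - 1L
      }
    }

    cass_len <- vapply(cassettes, function(c) nchar(c$seq), integer(1L))
    n_sp <- length(cassettes) + 1L
    slack <- length_bp - sum(cass_len)
    if (slack < 40L * n_sp) {
      stop("infeasible packing: ", n_genes, " genes do not fit in ",
           length_bp, " bp with room for spacers")
    }
    w <- stats::runif(n_sp)
    extra <- slack - 40L * n_sp
    sp_len <- 40L + as.integer(floor(extra * w / sum(w)))
    sp_len[n_sp] <- slack - sum(sp_len[-n_sp]) # exact fill

    parts <- character(0)
    truth <- list()
    pos <- 0L
    for (i in seq_along(cassettes)) {
      sp <- paste(sample(c("A", "C", "G", "T"), sp_len[i], replace = TRUE),
                  collapse = "")
      parts <- c(parts, sp)
      pos <- pos + sp_len[i]
      cas <- cassettes[[i]]
      g <- cas$genes
      g$left <- g$left + pos
      g$right <- g$right + pos
      truth[[i]] <- g
      parts <- c(parts, cas$seq)
      pos <- pos + nchar(cas$seq)
    }
    parts <- c(parts, paste(sample(c("A", "C", "G", "T"), sp_len[n_sp],
                                   replace = TRUE), collapse = ""))
    genome <- genome_sequence(
      paste(parts, collapse = ""),
      id = sprintf("planted_seed%d", as.integer(seed))
    )
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$left), , drop = FALSE]
    truth$orf_key <- interval_keys(truth)
    truth$true_start <- ifelse(truth$strand == "+", truth$left, truth$right)
    truth$length_bp <- truth$right - truth$left + 1L
    rownames(truth) <- NULL
    structure(list(genome = genome, truth = truth), class = "planted_genome")
  })
}

#' Mock per-program gene calls
#'
#' Each pseudo-program reproduces the planted truth, independently dropping
#' genes at `fn_rate`, perturbing 5' ends (3'-ward, in frame) at
#' `start_error_rate`, and calling decoy (non-coding) ORFs at `fp_rate`.
#'
#' @param truth Truth table from [plant_genome()].
#' @param n_programs Number of pseudo-programs (`prog1` .. `progN`).
#' @param fn_rate,fp_rate,start_error_rate Per-gene probabilities.
#' @param seed Integer seed.
#' @param decoys Optional table of non-coding ORFs (`left`, `right`,
#'   `strand`) used as the false-positive pool.
#' @return Call table (`program`, `left`, `right`, `strand`).
#' @export
mock_program_calls <- function(truth, n_programs = 4L, fn_rate = 0,
                               fp_rate = 0, start_error_rate = 0, seed = 1L,
                               decoys = NULL) {
  withr::with_seed(derive_seed(seed, "mock_program_calls"), {
    out <- list()
    for (p in seq_len(n_programs)) {
      keep <- stats::runif(nrow(truth)) >= fn_rate
      g <- truth[keep, c("left", "right", "strand"), drop = FALSE]
      if (nrow(g) > 0L && start_error_rate > 0) {
        perturb <- stats::runif(nrow(g)) < start_error_rate
        for (i in which(perturb)) {
          len <- g$right[i] - g$left[i] + 1L
          max_shift <- max(0L, (len - 60L) %/% 3L)
          if (max_shift == 0L) next
          shift <- 3L * sample.int(min(5L, max_shift), 1L)
          if (g$strand[i] == "+") g$left[i] <- g$left[i] + shift
          else g$right[i] <- g$right[i] - shift
        }
      }
      if (!is.null(decoys) && nrow(decoys) > 0L && fp_rate > 0) {
        fp <- decoys[stats::runif(nrow(decoys)) < fp_rate,
                     c("left", "right", "strand"), drop = FALSE]
        g <- rbind(g, fp)
      }
      if (nrow(g) > 0L) {
        g$program <- sprintf("prog%d", p)
        out[[p]] <- g[, c("program", "left", "right", "strand")]
      }
    }
    calls <- do.call(rbind, out)
    if (is.null(calls)) {
      calls <- data.frame(program = character(0), left = integer(0),
                          right = integer(0), strand = character(0))
    }
    rownames(calls) <- NULL
    calls
  })
}

#' Mock coding-potential track
#'
#' Posterior approximately `high_level` inside each planted gene (in its own
#' frame), approximately 0 elsewhere, with Gaussian noise clipped to [0, 1].
#' Per-gene profiles emulate the four qualitative signal classes: `"high"`
#' (sustained plateau), `"spike"` (high but not sustained), `"low"`
#' (sustained at 0.4) and `"none"`.
#'
#' @param truth Truth table from [plant_genome()].
#' @param genome_len Genome length.
#' @param high_level Plateau posterior for `"high"` genes.
#' @param noise_sd Gaussian noise s.d.
#' @param seed Integer seed.
#' @param profiles Character vector (recycled over genes) of per-gene
#'   profiles.
#' @return A [coding_track()].
#' @export
mock_coding_track <- function(truth, genome_len, high_level = 0.9,
                              noise_sd = 0.02, seed = 1L,
                              profiles = "high") {
  withr::with_seed(derive_seed(seed, "mock_coding_track"), {
    mat <- matrix(
      pmin(1, pmax(0, stats::rnorm(genome_len * 6L, 0, noise_sd))),
      nrow = genome_len, ncol = 6L
    )
    profiles <- rep_len(profiles, nrow(truth))
    for (i in seq_len(nrow(truth))) {
      l <- truth$left[i]; r <- truth$right[i]
      col <- frame_code(truth$strand[i], l, r, genome_len)
      n <- r - l + 1L
      level <- switch(
        profiles[i],
        high = rep(high_level, n),
        spike = {
          v <- rep(0.1, n)
          w <- max(1L, n %/% 10L)
          mid <- (n - w) %/% 2L
          v[(mid + 1L):(mid + w)] <- high_level
          v
        },
        low = rep(0.4, n),
        none = rep(0.05, n),
        stop("unknown coding-track profile: ", profiles[i])
      )
      mat[l:r, col] <- pmin(1, pmax(0, level + stats::rnorm(n, 0, noise_sd)))
    }
    coding_track(mat)
  })
}

#' Mock similarity-match table
#'
#' Each planted gene receives matches with probability `hit_rate`; E-values
#' are log-uniform over `10^evalue_log10_range`, the known-function flag is
#' Bernoulli(`known_function_rate`), and `subject_start_offset` is set so the
#' implied start is the true start (when `genome` and `orfs` are supplied to
#' anchor the offsets at each ORF's 5'-most candidate, otherwise 0).
#'
#' @param truth Truth table from [plant_genome()].
#' @param hit_rate Probability a gene has any match.
#' @param known_function_rate Probability a match has known function.
#' @param seed Integer seed.
#' @param evalue_log10_range log10 E-value range, e.g. c(-60, -11).
#' @param n_matches_range Range of match counts per hit gene.
#' @param genome,orfs Optional [genome_sequence()] and ORF table used to
#'   compute start offsets.
#' @param config A [rubric_config()] (start codons for candidate
#'   enumeration).
#' @return Similarity table (`orf_key`, `e_value`, `known_function`,
#'   `subject_start_offset`).
#' @export
mock_similarity <- function(truth, hit_rate = 0.9, known_function_rate = 0.3,
                            seed = 1L, evalue_log10_range = c(-60, -11),
                            n_matches_range = c(1L, 3L), genome = NULL,
                            orfs = NULL, config = rubric_config()) {
  withr::with_seed(derive_seed(seed, "mock_similarity"), {
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      if (stats::runif(1) >= hit_rate) next
      k <- sample(seq(n_matches_range[1L], n_matches_range[2L]), 1L)
      offset <- 0L
      if (!is.null(genome) && !is.null(orfs)) {
        m <- match(truth$orf_key[i], orfs$orf_key)
        if (!is.na(m)) {
          cand <- enumerate_start_candidates(orfs[m, ], genome,
                                             config$start_codons)
          if (nrow(cand) > 0L) {
            offset <- abs(truth$true_start[i] - cand$coordinate[1L])
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        orf_key = truth$orf_key[i],
        e_value = 10^stats::runif(k, evalue_log10_range[1L],
                                  evalue_log10_range[2L]),
        known_function = stats::runif(k) < known_function_rate,
        subject_start_offset = offset
      )
    }
    sim <- do.call(rbind, rows)
    if (is.null(sim)) {
      sim <- data.frame(orf_key = character(0), e_value = numeric(0),
                        known_function = logical(0),
                        subject_start_offset = integer(0))
    }
    rownames(sim) <- NULL
    sim
  })
}

#' Write a call table as per-program TSV files
#' @param calls Call table.
#' @param dir Output directory (created if absent).
#' @return Named character vector of file paths.
#' @export
write_program_calls <- function(calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  progs <- unique(calls$program)
  paths <- file.path(dir, paste0(progs, ".tsv"))
  names(paths) <- progs
  for (p in progs) {
    utils::write.table(
      calls[calls$program == p, ], paths[[p]],
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  paths
}
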