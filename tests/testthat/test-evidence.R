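test_that("program calls load from TSV and GFF3 with normalised coordinates", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "program\tleft\tright\tstrand",
    "glimmer\t100\t300\t+",
    "glimmer\t100\t300\t+",      # exact duplicate collapses
    "glimmer\t120\t300\t+",      # same stop anchor, different start: collapses
    "genemark\t400\t600\t-"
  ), tsv)
  calls <- load_program_calls(tsv, genome_len = 1000)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$left[calls$program == "glimmer"], 100L)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "g\tprodigal\tCDS\t50\t250\t.\t-\t0\tID=p1",
    "g\tprodigal\tCDS\t500\t700\t.\t+\t0\tID=p2"
  ), gff)
  gcalls <- load_program_calls(gff, genome_len = 1000)
  expect_equal(gcalls$program, c("prodigal", "prodigal"))
  # minus-strand rows keep left < right
  expect_equal(gcalls$left[1], 50L)
  expect_equal(gcalls$right[1], 250L)
  expect_equal(gcalls$strand[1], "-")

  # file labels override the embedded program column
  named <- c(progA = tsv)
  expect_setequal(unique(load_program_calls(named)$program), "progA")
})

test_that("program call loading rejects bad strands and coordinates", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("program\tleft\tright\tstrand", "x\t10\t50\t?"), tsv)
  expect_error(load_program_calls(tsv), "strand")
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("program\tleft\tright\tstrand", "x\t10\t5000\t+"), tsv2)
  expect_error(load_program_calls(tsv2, genome_len = 1000), "outside")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("program\tleft\tright\tstrand", empty)
  expect_warning(res <- load_program_calls(empty), "no gene calls")
  expect_equal(nrow(res), 0L)
})

test_that("count_program_calls keys on the stop anchor only", {
  orf <- orf_row("-", 50061, 50159, genome_len = 51000)
  calls <- rbind(
    calls_for(c("glimmer", "genemark", "prodigal", "phanotate"),
              50061, 50159, "-"),
    calls_for("glimmer", 50061, 50159, "-"),   # same program twice: once
    calls_for("genemark_s", 50070, 50159, "-") # different stop anchor (3'=left)
  )
  expect_equal(count_program_calls(orf, calls), 4L)
  # start disagreement does not matter: same 3' end, different 5' still counts
  calls2 <- calls_for(c("a", "b"), c(50061, 50061), c(50159, 50100), "-")
  expect_equal(count_program_calls(orf, calls2), 2L)
  expect_equal(count_program_calls(orf, calls[0, ]), 0L)
  expect_lte(count_program_calls(orf, calls), length(unique(calls$program)))
})

test_that("coding-potential classes follow the high/sustained rules", {
  orf <- orf_row("+", 301, 399)
  L <- 500
  # constant high over the whole ORF -> 3
  expect_equal(classify_coding_potential(flat_track(L, 301, 399, 1, 0.9), orf), 3L)
  # single-position spike -> high but not sustained -> 2
  spike <- flat_track(L, 350, 350, 1, 0.9)
  expect_equal(classify_coding_potential(spike, orf), 2L)
  # constant low -> 1; nothing -> 0
  expect_equal(classify_coding_potential(flat_track(L, 301, 399, 1, 0.4), orf), 1L)
  expect_equal(classify_coding_potential(flat_track(L, 301, 399, 1, 0), orf), 0L)
  # signal in another frame is invisible to this ORF
  expect_equal(classify_coding_potential(flat_track(L, 301, 399, 2, 0.9), orf), 0L)
  # track must cover the ORF
  expect_error(classify_coding_potential(flat_track(200, 1, 10, 1, 0.5), orf),
               "cover")
})

test_that("classify_coding_potential is monotone in the posteriors", {
  orf <- orf_row("+", 1, 90)
  withr::with_seed(5, {
    for (i in 1:25) {
      base <- matrix(0, 120, 6)
      base[1:90, 1] <- runif(90)
      hi <- base
      bump <- sample(90, 30)
      hi[bump, 1] <- pmin(1, hi[bump, 1] + runif(30))
      expect_gte(
        classify_coding_potential(coding_track(hi), orf),
        classify_coding_potential(coding_track(base), orf)
      )
    }
  })
})

test_that("similarity scoring bins E-values and caps the function bonus", {
  expect_equal(score_similarity(numeric(0)), 0L)
  expect_equal(score_similarity(1e-13, FALSE), 1L)          # E-13, hypothetical
  expect_equal(score_similarity(1e-55, FALSE), 3L)          # < E-50
  expect_equal(score_similarity(0.0018, FALSE), 0L)         # insignificant
  expect_equal(score_similarity(1e-60, TRUE), 4L)           # known function
  expect_equal(score_similarity(c(1e-30, 1e-5), c(FALSE, TRUE)), 2L) # bonus match must pass threshold
  expect_equal(score_similarity(1e-4, TRUE), 0L)            # no bonus without base
  expect_error(score_similarity(-1), "non-negative")
})

test_that("score_similarity is monotone under added matches", {
  withr::with_seed(9, {
    for (i in 1:30) {
      e <- 10^runif(sample(1:4, 1), -60, 0)
      kf <- runif(length(e)) < 0.4
      s1 <- score_similarity(e, kf)
      s2 <- score_similarity(c(e, 10^runif(1, -60, 0)), c(kf, runif(1) < 0.4))
      expect_gte(s2, s1)
      expect_true(s1 %in% 0:4 && s2 %in% 0:4)
    }
  })
})

test_that("per-start program votes and similarity matches are counted", {
  g <- genome_sequence("TAAATGATGAAATAA")   # starts at 4 and 7, stop 13..15
  orf <- find_orfs(g, min_len_bp = 1)
  orf <- orf[orf$strand == "+", ][1, ]
  cand <- enumerate_start_candidates(orf, g)
  expect_equal(cand$coordinate, c(4L, 7L))
  calls <- calls_for(c("p1", "p2", "p3"), c(4, 7, 7), 15, "+")
  expect_equal(start_program_votes(cand, orf, calls), c(1L, 2L))

  sim <- data.frame(
    orf_key = orf$orf_key, e_value = c(1e-30, 1e-30, 1e-5),
    known_function = FALSE, subject_start_offset = c(0L, 3L, 3L)
  )
  # anchor is the 5'-most candidate (4); offset 3 implies start 7; the
  # insignificant match does not count
  expect_equal(start_similarity_matches(cand, sim, "+"), c(1L, 1L))
})

test_that("similarity and SD tables round-trip through their TSV readers", {
  sim <- data.frame(
    orf_key = c("+:900", "-:120"), e_value = c(1e-12, 2e-60),
    known_function = c(FALSE, TRUE), subject_start_offset = c(0L, 6L)
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(sim, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_similarity_table(f), sim)

  sd <- data.frame(start_coordinate = c(442L, 605L), sd_score = c(-5.9, -4.6))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(sd, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_sd_table(f2), sd)
})

test_that("coding track TSV round-trips and validates", {
  mat <- matrix(0, 50, 6)
  mat[10:20, 1] <- 0.9
  mat[30:40, 5] <- 0.4
  tr <- coding_track(mat)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_coding_track(tr, f)
  tr2 <- read_coding_track(f, 50)
  expect_equal(unclass(tr2), unclass(tr), ignore_attr = TRUE)
  expect_error(read_coding_track(f, 30), "outside")
  expect_error(coding_track(matrix(2, 5, 6)), "\\[0, 1\\]")
})
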