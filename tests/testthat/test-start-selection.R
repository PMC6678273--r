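test_that("coding_plateau finds the longest high run, ties 5'-most", {
  orf <- orf_row("+", 101, 200)
  L <- 300
  colf <- frame_code("+", 101, 200, L)
  # constant high: plateau is the whole ORF
  p <- coding_plateau(flat_track(L, 101, 200, colf, 0.9), orf)
  expect_equal(p, list(left = 101L, right = 200L))
  # no signal: no plateau
  expect_null(coding_plateau(flat_track(L, 101, 200, colf, 0.2), orf))
  # two runs: the longer wins
  mat <- matrix(0, L, 6)
  mat[111:120, colf] <- 0.9  # 10 bp
  mat[141:170, colf] <- 0.9  # 30 bp
  expect_equal(coding_plateau(coding_track(mat), orf),
               list(left = 141L, right = 170L))
  # equal runs: 5'-most wins (forward = leftmost)
  mat2 <- matrix(0, L, 6)
  mat2[111:120, colf] <- 0.9
  mat2[141:150, colf] <- 0.9
  expect_equal(coding_plateau(coding_track(mat2), orf),
               list(left = 111L, right = 120L))
  # for a reverse gene the 5'-most tie-break is the rightmost run
  orf_r <- orf_row("-", 101, 200, genome_len = L)
  mat3 <- matrix(0, L, 6)
  col <- frame_code("-", 101, 200, L)
  mat3[111:120, col] <- 0.9
  mat3[141:150, col] <- 0.9
  expect_equal(coding_plateau(coding_track(mat3), orf_r),
               list(left = 141L, right = 150L))
})

test_that("coding_plateau matches a brute-force run scan", {
  withr::with_seed(13, {
    for (i in 1:20) {
      L <- 120
      vals <- round(runif(L), 2)
      mat <- matrix(0, L, 6); mat[, 1] <- vals
      orf <- orf_row("+", 1, L)
      p <- coding_plateau(coding_track(mat), orf)
      # oracle: enumerate all maximal runs > 0.75 by scanning
      above <- vals > 0.75
      runs <- list(); start <- NA
      for (j in seq_len(L)) {
        if (above[j] && is.na(start)) start <- j
        if ((!above[j] || j == L) && !is.na(start)) {
          end <- if (above[j]) j else j - 1L
          runs[[length(runs) + 1L]] <- c(start, end)
          start <- NA
        }
      }
      if (!length(runs)) {
        expect_null(p)
      } else {
        lens <- vapply(runs, function(r) r[2] - r[1] + 1L, integer(1))
        best <- runs[[which.max(lens)]]
        expect_equal(c(p$left, p$right), best)
      }
    }
  })
})

test_that("plateau coverage matches the multi-start picture", {
  # forward gene, six starts, only the leftmost is upstream of the plateau
  starts <- c(100L, 130L, 160L, 190L, 220L, 250L)
  plateau <- list(left = 120L, right = 400L)
  expect_equal(covers_all_coding_potential(starts, plateau, "+"),
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  # reverse gene, eight starts, the rightmost three cover
  rstarts <- seq(500L, 850L, by = 50L)
  rplateau <- list(left = 300L, right = 740L)
  expect_equal(sum(covers_all_coding_potential(rstarts, rplateau, "-")), 3L)
  # no plateau: vacuously true
  expect_true(all(covers_all_coding_potential(starts, NULL, "+")))
})

test_that("start overlap/gap arithmetic follows the +1/-1 convention", {
  expect_equal(start_overlap_or_gap(998, 1000, "forward"), 3L)
  expect_equal(start_overlap_or_gap(1000, 1000, "forward"), 1L)
  expect_equal(start_overlap_or_gap(1005, 1000, "forward"), -6L) # 4 bp gap
  # the worked example: candidate 442 against an upstream stop at 569
  expect_equal(start_overlap_or_gap(442, 569, "forward"), 128L)
  # reverse genes subtract the downstream stop from the start
  expect_equal(start_overlap_or_gap(1000, 998, "reverse"), 3L)
  expect_equal(start_overlap_or_gap(990, 998, "reverse"), -9L)
  # positive results agree with overlap_bp on the implied intervals
  withr::with_seed(3, {
    for (i in 1:30) {
      stop3 <- sample(500:600, 1)
      start5 <- stop3 - sample(0:80, 1)
      ovg <- start_overlap_or_gap(start5, stop3, "forward")
      expect_equal(ovg, overlap_bp(start5, 10000, 1, stop3))
    }
  })
})

test_that("divergent pair tables carry the formula and the geometric gap", {
  tab <- divergent_pair_table(1000, 900)
  expect_equal(tab$formula[1, 1], 150L)
  expect_equal(tab$gap[1, 1], 99L)
  expect_true(tab$ok[1, 1])
  # boundary: gap exactly 50 is OK
  tab2 <- divergent_pair_table(951, 900)
  expect_equal(tab2$gap[1, 1], 50L)
  expect_true(tab2$ok[1, 1])
  expect_false(divergent_pair_table(950, 900)$ok[1, 1])
  # overlapping 5' ends always violate
  expect_false(divergent_pair_table(890, 900)$ok[1, 1])
  # matrix shape over candidate sets
  tab3 <- divergent_pair_table(c(1000, 1030), c(900, 910, 920))
  expect_equal(dim(tab3$formula), c(2L, 3L))
})

test_that("select_start reproduces the worked five-candidate example", {
  sel <- select_start(table7_rows())
  expect_equal(sel$coordinate, 605L)
  audit <- sel$audit
  expect_equal(audit$eliminated_by[audit$coordinate == 626], "coding_potential")
  expect_equal(audit$eliminated_by[audit$coordinate == 442], "large_overlap")
  expect_equal(audit$eliminated_by[audit$coordinate == 578], "programs")
  expect_equal(audit$eliminated_by[audit$coordinate == 587], "programs")
  expect_equal(audit$eliminated_by[audit$coordinate == 605], "chosen")
})

test_that("select_start handles degenerate and rule-specific cases", {
  expect_error(select_start(table7_rows()[0, ]), "no start candidates")
  one <- table7_rows()[1, ]
  expect_equal(select_start(one)$coordinate, 442L)
  # operon-forming candidate is privileged and SD is skipped for it
  rows <- data.frame(
    coordinate = c(10L, 40L),
    covers_coding_potential = TRUE,
    overlap_or_gap = c(-10L, 4L),
    operon = c(FALSE, TRUE),
    program_votes = c(3L, 0L),
    similarity_start_matches = c(2L, 0L),
    sd_score = c(-2.0, NA),
    resulting_length_bp = c(300L, 270L)
  )
  sel <- select_start(rows)
  expect_equal(sel$coordinate, 40L)
  expect_equal(sel$audit$eliminated_by[1], "operon")
  # all-equal rows: longest ORF wins via rule 6
  eq <- data.frame(
    coordinate = c(10L, 40L), covers_coding_potential = TRUE,
    overlap_or_gap = 0L, operon = FALSE, program_votes = 1L,
    similarity_start_matches = 1L, sd_score = -3.0,
    resulting_length_bp = c(300L, 270L)
  )
  expect_equal(select_start(eq)$coordinate, 10L)
  # rule 6 prefers tolerable overlap over raw length
  eq$overlap_or_gap <- c(40L, 0L)
  expect_equal(select_start(eq)$coordinate, 40L)
  # missing SD scores compare as worst; close scores tie
  sd <- data.frame(
    coordinate = c(1L, 2L, 3L), covers_coding_potential = TRUE,
    overlap_or_gap = 0L, operon = FALSE, program_votes = 0L,
    similarity_start_matches = 0L, sd_score = c(-3.05, -3.0, NA),
    resulting_length_bp = c(120L, 117L, 114L)
  )
  sel2 <- select_start(sd)
  expect_equal(sel2$coordinate, 1L)  # tied on SD (within 0.1), longer wins
  expect_equal(sel2$audit$eliminated_by[3], "sd_score")
})

test_that("select_start is permutation-invariant and matches the oracle", {
  withr::with_seed(77, {
    for (i in 1:150) {
      rows <- random_start_rows(sample(2:6, 1))
      chosen <- select_start(rows)$coordinate
      expect_equal(chosen, oracle_select_start(rows))
      perm <- rows[sample(nrow(rows)), ]
      expect_equal(select_start(perm)$coordinate, chosen)
      # the chosen start covers the plateau whenever any candidate does
      if (any(rows$covers_coding_potential)) {
        expect_true(rows$covers_coding_potential[rows$coordinate == chosen])
      }
    }
  })
})

test_that("the longest-start shortcut applies only on unanimity", {
  rows <- table7_rows()
  expect_false(shortcut_applies(rows, 3L))
  expect_true(shortcut_applies(rows[3, ], 3L))  # single candidate
  unanimous <- rows
  unanimous$program_votes <- c(8L, 0L, 0L, 0L, 0L)
  expect_true(shortcut_applies(unanimous, 8L))
  expect_false(shortcut_applies(unanimous, 0L))
})

test_that("build_start_rows assembles evidence from all sources", {
  g <- genome_sequence("TAAATGATGAAATAA")
  orf <- find_orfs(g, min_len_bp = 1)
  orf <- orf[orf$strand == "+", ][1, ]
  track <- flat_track(15, 5, 15, frame_code("+", 4, 15, 15), 0.9)
  calls <- calls_for(c("p1", "p2"), c(4, 7), 15, "+")
  sim <- data.frame(orf_key = orf$orf_key, e_value = 1e-30,
                    known_function = FALSE, subject_start_offset = 0L)
  sd <- data.frame(start_coordinate = c(4L, 7L), sd_score = c(-4.1, -2.2))
  rows <- build_start_rows(orf, g, track, calls, sim, sd, neighbor_stop = 3L)
  expect_equal(rows$coordinate, c(4L, 7L))
  expect_equal(rows$covers_coding_potential, c(TRUE, FALSE))
  expect_equal(rows$overlap_or_gap, c(-2L, -5L))
  expect_equal(rows$program_votes, c(1L, 1L))
  expect_equal(rows$similarity_start_matches, c(1L, 0L))
  expect_equal(rows$sd_score, c(-4.1, -2.2))
  expect_equal(rows$resulting_length_bp, c(12L, 9L))
  expect_equal(select_start(rows)$coordinate, 4L)
})
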