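test_that("evolutionary distance matches BLOSUM62 arithmetic and its identities", {
  expect_equal(evolutionary_distance("AR", "AR")$ed, 0)
  expect_equal(evolutionary_distance("A", "R")$ed, 122.22, tolerance = 1e-2)
  expect_equal(evolutionary_distance("AA", "AR")$ed, 64.71, tolerance = 1e-2)
  # gap columns are excluded from all three sums
  expect_equal(evolutionary_distance("A-A", "ARA")$ed,
               evolutionary_distance("AA", "AA")$ed)
  expect_error(evolutionary_distance("A-", "-A"), "no aligned")
  expect_error(evolutionary_distance("AA", "A"), "equal length")
})

test_that("ED is symmetric and zero on gap-free self-comparison for random pairs", {
  set.seed(2)
  for (k in 1:50) {
    p <- random_aligned_pair(25)
    expect_equal(evolutionary_distance(p[1], p[2])$ed,
                 evolutionary_distance(p[2], p[1])$ed)
    s <- gsub("-", "A", p[1])
    expect_equal(evolutionary_distance(s, s)$ed, 0)
  }
})

test_that("ED rank-correlates with the number of substitutions applied", {
  set.seed(3)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- sample(aa, 120, replace = TRUE)
  k_subs <- sample(0:30, 100, replace = TRUE)
  eds <- vapply(k_subs, function(k) {
    mut <- base
    if (k > 0) {
      pos <- sample(120, k)
      for (p in pos) mut[p] <- sample(setdiff(aa, base[p]), 1)
    }
    evolutionary_distance(paste(base, collapse = ""),
                          paste(mut, collapse = ""))$ed
  }, 0)
  expect_gt(cor(k_subs, eds, method = "spearman"), 0.9)
})

test_that("extreme alignments follow the criterion direction with deterministic ties", {
  mk <- function(id_a, id_b, rmsd, tm) {
    structure(list(id_a = id_a, id_b = id_b, rmsd = rmsd, tm_score = tm),
              class = "superposition")
  }
  gp <- list(comparisons = list(mk("A1", "B1", 1.0, 0.8), mk("A2", "B2", 2.0, 0.4),
                                mk("A3", "B3", 0.5, 0.9)))
  ex <- select_extreme_alignments(gp, "rmsd")
  expect_equal(ex$best$rmsd, 0.5)
  expect_equal(ex$worst$rmsd, 2.0)
  ex_tm <- select_extreme_alignments(gp, "tm")
  expect_equal(ex_tm$best$tm_score, 0.9)
  expect_equal(ex_tm$worst$tm_score, 0.4)
  # all equal: best = worst, resolved lexicographically
  gp2 <- list(comparisons = list(mk("A2", "B2", 1, 0.5), mk("A1", "B1", 1, 0.5)))
  ex2 <- select_extreme_alignments(gp2, "rmsd")
  expect_equal(ex2$best$id_a, "A1")
  expect_equal(ex2$worst$id_a, "A1")
})

test_that("gap counting trims unaligned terminal columns then applies the run-length rule", {
  # leading column (-, M) is trimmed away
  g1 <- count_gaps("-AC", "MAC")
  expect_equal(unname(g1$combined), c(0L, 0L))
  # core (A,A)(C,C)(D,-)(-,G)(E,E): two openings, no extensions
  g2 <- count_gaps("ACD-E", "AC-GE")
  expect_equal(unname(g2$combined), c(2L, 0L))
  # one gap run of length 3: 1 opening + 2 extensions
  g3 <- count_gaps("AC---DE", "ACWYVDE")
  expect_equal(unname(g3$combined), c(1L, 2L))
  # row-swap invariance of the combined counts
  expect_equal(count_gaps("AC-GE", "ACD-E")$combined, g2$combined)
  # trimming that consumes everything flags degenerate
  expect_true(count_gaps("--", "AA")$degenerate)
})

test_that("exception analysis classifies ED reversals and censuses quadrants", {
  mk_gp <- function(ga, gb, aln_best, aln_worst) {
    comps <- list(
      structure(list(id_a = "A1", id_b = "B1", rmsd = 0.5, tm_score = 0.9,
                     correspondence = list(aligned = aln_best)),
                class = "superposition"),
      structure(list(id_a = "A2", id_b = "B2", rmsd = 2.0, tm_score = 0.4,
                     correspondence = list(aligned = aln_worst)),
                class = "superposition"))
    structure(list(group_a = ga, group_b = gb, comparisons = comps),
              class = "group_pair")
  }
  # conforming: min-RMSD alignment is identical (ED 0), max-RMSD differs
  gp_ok <- mk_gp("G1", "G2", c("ACDE", "ACDE"), c("ACDE", "ACDW"))
  # exception: min-RMSD alignment has the higher ED and more gaps
  gp_ex <- mk_gp("G3", "G4", c("AC-DEF", "ACW-EW"), c("ACDEF", "ACDEF"))
  rep <- exception_analysis(list(gp_ok, gp_ex), "rmsd")
  expect_equal(rep$records$status, c("conforming", "exception"))
  expect_equal(sum(rep$census), sum(rep$records$status == "exception"))
  # quadrant assignment from signed gap differences
  expect_equal(flexwobble:::.quadrant_label(1, -2), "IV")
  expect_equal(flexwobble:::.quadrant_label(-1, 2), "II")
  expect_equal(flexwobble:::.quadrant_label(0, 0), "origin")
  expect_equal(flexwobble:::.quadrant_label(0, 3), "axis")
})
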