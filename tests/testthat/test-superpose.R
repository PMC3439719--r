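test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(1)
  A <- matrix(rnorm(30), ncol = 3)
  R <- random_rotation()
  B <- A %*% t(R) + matrix(rep(c(3, -1, 2), each = 10), ncol = 3)
  k <- kabsch_superpose(A, B)
  expect_equal(k$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(A, B[1:5, ]), "same size")
  expect_error(kabsch_superpose(A[1:2, ], B[1:2, ]), "at least 3")
})

test_that("Kabsch equals the quaternion brute-force oracle on small random sets", {
  set.seed(42)
  for (rep_i in 1:10) {
    n <- sample(4:8, 1)
    A <- matrix(rnorm(3 * n), ncol = 3)
    B <- matrix(rnorm(3 * n), ncol = 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, brute_force_rmsd(A, B),
                 tolerance = 1e-3)
  }
})

test_that("RMSD and TM-score are invariant under rigid transforms and symmetric", {
  set.seed(7)
  cs1 <- make_dihedral_chain(runif(30, -150, -60), runif(30, -60, 150), "A:A")
  cs2 <- make_dihedral_chain(runif(30, -150, -60), runif(30, -60, 150), "B:A")
  s12 <- structural_align(cs1, cs2)
  # rigid-motion invariance: rotate + translate one input
  R <- random_rotation()
  cs2r <- cs2
  for (a in names(cs2r$atoms)) {
    cs2r$atoms[[a]] <- cs2r$atoms[[a]] %*% t(R) +
      matrix(rep(c(5, 1, -3), each = 30), ncol = 3)
  }
  s12r <- structural_align(cs1, cs2r)
  expect_equal(s12r$rmsd, s12$rmsd, tolerance = 1e-6)
  expect_equal(s12r$tm_score, s12$tm_score, tolerance = 1e-6)
  # symmetry (identical sequences use the 1:1 correspondence both ways)
  s21 <- structural_align(cs2, cs1)
  expect_equal(s21$rmsd, s12$rmsd, tolerance = 1e-6)
  expect_equal(s21$tm_score, s12$tm_score, tolerance = 1e-6)
})

test_that("the TM-score formula and d0 guard match direct arithmetic", {
  expect_equal(compute_tm_score(rep(0, 35), 35), 1)
  expect_equal(tm_d0(35), 1.566, tolerance = 1e-3)
  expect_equal(compute_tm_score(rep(tm_d0(35), 35), 35), 0.5)
  expect_equal(tm_d0(21), 0.5)
  expect_equal(tm_d0(10), 0.5)
  expect_error(compute_tm_score(c(1, -1), 10), "nonnegative")
})

test_that("identical chains give the identity correspondence, zero RMSD, TM-score 1", {
  cs <- make_helix_chain(20)
  s <- structural_align(cs, cs)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)
  expect_equal(s$tm_score, 1, tolerance = 1e-12)
  expect_equal(s$correspondence$pairs[, 1], s$correspondence$pairs[, 2])
  expect_equal(s$n_aligned, 20L)
})

test_that("identical-sequence pairs report the plain Kabsch RMSD over all residues", {
  # two-domain chain vs a hinge-perturbed copy of itself
  set.seed(11)
  phi <- c(rep(-57, 25), -100, rep(-57, 25)); psi <- c(rep(-47, 25), 130, rep(-47, 25))
  phi2 <- phi; phi2[26] <- phi2[26] + 25
  seqs <- paste(sample(strsplit("ACDEFHIKLMNQRSTVWY", "")[[1]], 51,
                       replace = TRUE), collapse = "")
  A <- make_dihedral_chain(phi, psi, "A:A", seqs)
  B <- make_dihedral_chain(phi2, psi, "B:A", seqs)
  s <- structural_align(A, B)
  direct <- kabsch_superpose(A$atoms$CA, B$atoms$CA)
  expect_equal(s$rmsd, direct$rmsd, tolerance = 1e-9)
  expect_gt(s$rmsd, 0.5)
})

test_that("the iterative aligner recovers a shifted register despite sequence disagreement", {
  set.seed(13)
  alpha <- strsplit("ACDEFHIKLMNQRSTVWY", "")[[1]]
  phi <- c(runif(5, -140, -80), rep(-57, 30), runif(5, -140, -80),
           rep(-57, 20))
  psi <- c(runif(5, 100, 160), rep(-47, 30), runif(5, 100, 160),
           rep(-47, 20))
  core_seq <- sample(alpha, 60, replace = TRUE)
  # B carries 3 extra N-terminal residues and an unrelated sequence, so the
  # correspondence must come from structure, not sequence
  phiB <- c(runif(3, -140, -80), phi); psiB <- c(runif(3, 100, 160), psi)
  A <- make_dihedral_chain(phi, psi, "A:A", paste(core_seq, collapse = ""))
  B <- make_dihedral_chain(phiB, psiB, "B:A",
                           paste(sample(alpha, 63, replace = TRUE), collapse = ""))
  s <- structural_align(A, B, identity_threshold = 0.99)
  truth <- cbind(1:60, 4:63)
  hits <- sum(paste(s$correspondence$pairs[, 1], s$correspondence$pairs[, 2]) %in%
                paste(truth[, 1], truth[, 2]))
  expect_gte(hits / 60, 0.95)
  # colinearity invariant
  expect_true(all(diff(s$correspondence$pairs[, 1]) > 0))
  expect_true(all(diff(s$correspondence$pairs[, 2]) > 0))
})

test_that("alignment and matrix exports round-trip through plain text", {
  cs <- make_helix_chain(20)
  sp <- structural_align(cs, cs)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_alignment_fasta(sp, f1)
  lines <- readLines(f1)
  expect_equal(lines[2], cs$sequence)
  expect_equal(lines[4], cs$sequence)
  write_superposition_matrix(sp, f2)
  vals <- do.call(rbind, lapply(strsplit(readLines(f2), " +"), function(x)
    as.numeric(x[nzchar(x)])))
  expect_equal(vals[, 1:3], sp$rotation, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(vals[, 4], sp$translation, tolerance = 1e-7)
})

test_that("the structural DP matches exhaustive enumeration of colinear matchings on toys", {
  set.seed(17)
  for (rep_i in 1:8) {
    n <- sample(4:6, 1); m <- sample(4:6, 1)
    S <- matrix(runif(n * m), n, m)
    pairs <- flexwobble:::dp_align(S, gap = 0.6)
    expect_equal(dp_pairs_score(S, pairs, 0.6),
                 enumerate_best_matching(S, 0.6), tolerance = 1e-9)
  }
})
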