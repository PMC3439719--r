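test_that("the same seed reproduces the dataset exactly", {
  cfg <- generator_config(families = 1, groups_per_family = 2,
                          structures_per_group = 3, seed = 31)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  for (k in seq_along(d1$groups)) {
    m1 <- d1$groups[[k]]$members; m2 <- d2$groups[[k]]$members
    for (i in seq_along(m1)) {
      expect_identical(m1[[i]]$sequence, m2[[i]]$sequence)
      expect_identical(m1[[i]]$atoms, m2[[i]]$atoms)
      expect_identical(m1[[i]]$resolution, m2[[i]]$resolution)
    }
  }
  expect_identical(d1$ground_truth, d2$ground_truth)
})

test_that("with all perturbations off, structures within a group are identical", {
  ds <- generate_dataset(generator_config(
    families = 1, groups_per_family = 1, structures_per_group = 4,
    flexible_prob = 0, hinge_spread = 0, jitter = c(H = 0, E = 0, C = 0),
    mutation_prob = 0, seed = 8))
  g <- ds$groups[[1]]
  sp <- structural_align(g$members[[1]], g$members[[2]])
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(detect_mutation_sites(g$msa), integer(0))
})

test_that("mutation probability zero yields no mutation sites anywhere", {
  ds <- generate_dataset(generator_config(families = 1, groups_per_family = 3,
                                          structures_per_group = 4,
                                          mutation_prob = 0, seed = 12))
  for (g in ds$groups) expect_equal(detect_mutation_sites(g$msa), integer(0))
})

test_that("noise-free backbones carry canonical covalent geometry", {
  ds <- generate_dataset(generator_config(
    families = 1, groups_per_family = 1, structures_per_group = 1,
    jitter = c(H = 0, E = 0, C = 0), seed = 4))
  at <- ds$groups[[1]]$members[[1]]$atoms
  n <- nrow(at$CA)
  bond <- function(X, Y, off = 0) {
    sqrt(rowSums((X[seq_len(n - off), , drop = FALSE] -
                  Y[(1 + off):n, , drop = FALSE])^2))
  }
  expect_true(all(abs(bond(at$N, at$CA) - 1.458) < 0.05))
  expect_true(all(abs(bond(at$CA, at$C) - 1.525) < 0.05))
  expect_true(all(abs(bond(at$C, at$N, off = 1) - 1.329) < 0.05))
})

test_that("a dihedral hinge swings domains apart while keeping each domain rigid", {
  cfg <- generator_config(
    families = 1, groups_per_family = 1, structures_per_group = 6,
    segment_layout = data.frame(state = c("H", "C", "H"),
                                length = c(25, 5, 25)),
    hinge_segments = 2, hinge_spread = 20, wobble_segments = integer(0),
    melt_subset_size = 1,
    flexible_prob = 1, jitter = c(H = 0, E = 0, C = 0),
    mutation_prob = 0, terminal_deletion_max = 0,
    substitutions_between_groups = 0, seed = 14)
  ds <- generate_dataset(cfg)
  g <- ds$groups[[1]]
  rmsds <- vapply(2:6, function(i)
    kabsch_superpose(ca_all <- g$members[[1]]$atoms$CA,
                     g$members[[i]]$atoms$CA)$rmsd, 0)
  expect_gt(max(rmsds), 1)
  dom1 <- 1:25; dom2 <- 31:55
  for (i in 2:6) {
    expect_lt(kabsch_superpose(g$members[[1]]$atoms$CA[dom1, ],
                               g$members[[i]]$atoms$CA[dom1, ])$rmsd, 0.2)
    expect_lt(kabsch_superpose(g$members[[1]]$atoms$CA[dom2, ],
                               g$members[[i]]$atoms$CA[dom2, ])$rmsd, 0.2)
  }
})

test_that("the resolution model is linear in coil content with truncation", {
  set.seed(1)
  expect_equal(assign_resolution(0, c(a = 1.2, b = 1.5, sigma = 0)), 1.2)
  expect_equal(assign_resolution(0.4, c(a = 1.2, b = 1.5, sigma = 0)), 1.8)
  expect_equal(assign_resolution(1, c(a = 3.6, b = 1.5, sigma = 0)), 3.49)
  expect_error(assign_resolution(1.2, c(a = 1, b = 1, sigma = 0)))
})

test_that("written datasets round-trip through the PDB/metadata reader", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(generator_config(families = 1, groups_per_family = 2,
                                          structures_per_group = 2,
                                          mutation_prob = 0, seed = 18))
  write_synthetic_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "metadata.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.tsv")))
  groups <- read_structure_dir(dir, file.path(dir, "metadata.tsv"))
  expect_equal(length(groups), 2L)
  orig <- ds$groups[[1]]$members[[1]]
  back <- NULL
  for (g in groups) {
    for (m in g$members) if (m$structure_id == orig$structure_id) back <- m
  }
  expect_identical(back$sequence, orig$sequence)
  expect_lt(max(abs(back$atoms$CA - orig$atoms$CA)), 1e-3 + 1e-9)
})
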