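# build a structural group with given member sequences and resolutions,
# using an arbitrary backbone (wobble analysis only consumes the alignment,
# states and resolutions)
make_group <- function(seqs, resolutions = NULL, group_id = "G1",
                       family_id = "F1") {
  n <- nchar(seqs[1])
  if (is.null(resolutions)) resolutions <- rep(2.0, length(seqs))
  members <- lapply(seq_along(seqs), function(i) {
    bb <- flexwobble:::build_backbone(rep(-57, n), rep(-47, n))
    cs <- chain_structure(sprintf("%s-S%02d:A", group_id, i), seqs[i], bb)
    cs$resolution <- resolutions[i]
    cs
  })
  structural_group(group_id, members, family_id)
}

test_that("the wobble-site ratio follows Rw = Nw/Na * 100", {
  expect_equal(round(wobble_ratio(72, 412), 2), 17.48)
  expect_equal(wobble_ratio(0, 10), 0)
  expect_error(wobble_ratio(1, 0), "positive")
})

test_that("wobble sites are columns with two or more observed states, typed by state pair", {
  g <- make_group(rep(strrep("A", 6), 3))
  st <- c("HHHCEH", "HCHCEH", "HEHCCH")
  names(st) <- vapply(g$members, function(m) m$structure_id, "")
  wt <- find_wobble_sites(g, st)
  expect_equal(wt$na, 6L)
  expect_equal(which(wt$wobble_flags), c(2L, 5L))
  expect_equal(wt$nw, 2L)
  expect_equal(wt$rw, 100 * 2 / 6)
  # column 2 saw {H, C, E}: all three transition types; column 5 saw {E, C}
  expect_equal(unname(classify_wobble_types(wt)),
               c(2L, 1L, 1L))  # C<=>E, C<=>H, H<=>E
  expect_gte(sum(wt$type_counts), wt$nw)
})

test_that("wobble detection is invariant under member order permutation", {
  seqs <- rep(strrep("A", 5), 3)
  st <- c(S1 = "HHHHH", S2 = "HCHHH", S3 = "HHHCH")
  g1 <- make_group(seqs)
  names(st) <- vapply(g1$members, function(m) m$structure_id, "")
  wt1 <- find_wobble_sites(g1, st)
  wt2 <- find_wobble_sites(g1, st[c(3, 1, 2)])
  expect_equal(wt1$wobble_flags, wt2$wobble_flags)
  expect_equal(wt1$rw, wt2$rw)
})

test_that("wobble single never exceeds wobble total within a group", {
  set.seed(1)
  g <- make_group(rep(strrep("A", 40), 5))
  ids <- vapply(g$members, function(m) m$structure_id, "")
  st <- vapply(ids, function(i)
    paste(sample(c("H", "C", "E"), 40, replace = TRUE, prob = c(.6, .3, .1)),
          collapse = ""), "")
  wt <- find_wobble_sites(g, st)
  ps <- wobble_pair_summaries(g, wt)
  expect_true(all(ps$wobble_single <= wt$rw + 1e-9))
})

test_that("the total-versus-single regression reports slope and intermediate fraction", {
  f <- wobble_total_vs_single(c(10, 20, 30), c(5, 10, 15))
  expect_equal(f$slope, 2)
  expect_equal(f$intermediate_fraction, 0.5)
  f2 <- wobble_total_vs_single(c(10, 20, 30), c(10, 20, 30))
  expect_equal(f2$slope, 1)
  expect_equal(f2$intermediate_fraction, 0)
  # the arithmetic behind the reported intermediate-conformation share
  expect_equal((1.5956 - 1) / 1.5956, 0.3733, tolerance = 1e-4)
  expect_error(wobble_total_vs_single(c(1, 2), c(1, 2)), "3 groups")
})

test_that("mutation-site enrichment builds the right 2x2 table and handles degenerate input", {
  wt <- list(wobble_flags = c(TRUE, FALSE, TRUE, FALSE), nw = 40L, na = 400L)
  ms <- mutation_wobble_stats(wt, c(1, 2, 3, 4))
  expect_true(ms$applicable)
  expect_equal(unname(ms$table["mutation", ]), c(2, 2))
  expect_equal(unname(ms$table["all", ]), c(40, 360))
  # mutation ratio equal to overall ratio -> statistic near zero
  wt2 <- list(wobble_flags = rep(c(TRUE, FALSE), c(10, 90)), nw = 100L, na = 1000L)
  ms2 <- mutation_wobble_stats(wt2, 1:100)
  expect_lt(ms2$chi_square$statistic, 0.05)
  expect_false(mutation_wobble_stats(wt, integer(0))$applicable)
})

test_that("the resolution-coil curve attributes wobble-site states to 0.1 A bins", {
  # two structures, resolutions 1.23 and 2.57 -> bins 1.2 and 2.5;
  # states differ at two sites: each bin receives one C and one H
  g <- make_group(rep(strrep("A", 4), 2), resolutions = c(1.23, 2.57))
  st <- c("HHCC", "HCHC")
  names(st) <- vapply(g$members, function(m) m$structure_id, "")
  wt <- find_wobble_sites(g, st)
  curve <- resolution_coil_curve(list(g), list(wt))
  expect_equal(curve$bins$lower, c(1.2, 2.5))
  expect_equal(curve$bins$n_states, c(2, 2))
  expect_equal(curve$bins$coil_ratio, c(0.5, 0.5))

  # a single differing site: exactly one state lands in each structure's bin
  g2 <- make_group(rep(strrep("A", 4), 2), resolutions = c(1.51, 2.52))
  st2 <- c("CCCH", "CCCC")
  names(st2) <- vapply(g2$members, function(m) m$structure_id, "")
  wt2 <- find_wobble_sites(g2, st2)
  curve2 <- resolution_coil_curve(list(g2), list(wt2))
  expect_equal(sum(curve2$bins$n_states), 2)

  # two bins with different coil ratios -> perfectly linear, |PCC| 1
  mk_states <- function(nC, nH) {
    paste(rep(c("C", "H"), c(nC, nH)), collapse = "")
  }
  # structure pair at bin 1.5: one C vs one H at each differing site
  g3 <- make_group(rep(strrep("A", 10), 2), resolutions = c(1.58, 1.55))
  st3 <- c(mk_states(2, 8), mk_states(8, 2))
  names(st3) <- vapply(g3$members, function(m) m$structure_id, "")
  wt3 <- find_wobble_sites(g3, st3)
  g4 <- make_group(rep(strrep("A", 10), 2), resolutions = c(2.58, 2.55),
                   group_id = "G2")
  # differing sites all {H, E}: zero coil ratio in the 2.5 A bin
  st4 <- c("EEEEHHHHHH", "HHHHEEEEHH")
  names(st4) <- vapply(g4$members, function(m) m$structure_id, "")
  wt4 <- find_wobble_sites(g4, st4)
  curve3 <- resolution_coil_curve(list(g3, g4), list(wt3, wt4))
  expect_equal(nrow(curve3$bins), 2L)
  expect_equal(abs(curve3$pcc$r), 1, tolerance = 1e-9)
})

test_that("the curve recovers a positive resolution-coil relationship from the generator", {
  ds <- generate_dataset(generator_config(families = 1, groups_per_family = 3,
                                          structures_per_group = 8,
                                          flexible_prob = 1, mutation_prob = 0,
                                          terminal_deletion_max = 0, seed = 21))
  wts <- lapply(ds$groups, function(g) {
    st <- vapply(g$members, function(m) assign_secondary_structure(m)$states3, "")
    names(st) <- vapply(g$members, function(m) m$structure_id, "")
    find_wobble_sites(g, st)
  })
  curve <- resolution_coil_curve(ds$groups, wts)
  expect_gt(curve$fit$slope, 0)
  expect_gt(curve$pcc$r, 0.5)
})
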