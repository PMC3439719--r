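# hand-built group pair: two groups of 2 members each, 5-residue proteins,
# with explicitly chosen pairwise alignments
toy_group_pair <- function(alignments, seq_b = "ACDEF") {
  msa_a <- c("A1:A" = "ACDEF", "A2:A" = "ACDEF")
  msa_b <- c("B1:A" = seq_b, "B2:A" = seq_b)
  ids <- expand.grid(a = names(msa_a), b = names(msa_b),
                     stringsAsFactors = FALSE)
  comps <- lapply(seq_len(nrow(ids)), function(k) {
    structure(list(id_a = ids$a[k], id_b = ids$b[k],
                   correspondence = list(aligned = alignments[[k]])),
              class = "superposition")
  })
  structure(list(group_a = "GA", group_b = "GB",
                 msa_a = msa_a, msa_b = msa_b, comparisons = comps),
            class = "group_pair")
}

test_that("sites agreeing in all comparisons are common; the classes partition and sum to 100", {
  # all four comparisons identical and complete
  aln_id <- c("ACDEF", "ACDEF")
  gp <- toy_group_pair(rep(list(aln_id), 4))
  sc <- classify_sites(gp)
  expect_equal(sc$rc, 100)
  expect_equal(sc$rm, 0)
  expect_equal(sc$rg, 0)
  expect_equal(unname(sum(variation_ratios(sc))), 100)

  # one comparison shifts the register of the last two residues:
  # residues joining different partners become multi
  aln_shift <- c("ACDEF-", "ACD-EF")
  gp2 <- toy_group_pair(c(rep(list(aln_id), 3), list(aln_shift)))
  sc2 <- classify_sites(gp2)
  expect_true(all(sc2$class_a[4:5] == "multi"))
  expect_true(all(sc2$class_a[1:3] == "common"))
  expect_equal(unname(sum(variation_ratios(sc2))), 100)

  # a residue aligned to a gap in every comparison is a gap site
  aln_gap <- c("ACDEF", "ACD-F")   # E of A faces a gap everywhere
  gp3 <- toy_group_pair(rep(list(aln_gap), 4), seq_b = "ACDF")
  sc3 <- classify_sites(gp3)
  expect_equal(sc3$class_a[4], "gap")
  expect_true(all(sc3$class_b == "common"))
  expect_equal(sc3$na_avg, 4.5)
  expect_equal(unname(sum(variation_ratios(sc3))), 100)
})

test_that("counts average over the two proteins per the ratio definition", {
  # equal lengths 5; A side: 3 common + 2 multi, B side symmetric
  aln_id <- c("ACDEF", "ACDEF")
  aln_shift <- c("ACDEF-", "ACD-EF")
  gp <- toy_group_pair(c(rep(list(aln_id), 3), list(aln_shift)))
  sc <- classify_sites(gp)
  expect_equal(sc$na_avg, 5)
  expect_equal(sc$nc, (sum(sc$class_a == "common") +
                         sum(sc$class_b == "common")) / 2)
  expect_equal(sc$rc, 100 * sc$nc / 5)
})

test_that("state distribution by class splits wobble-site weight equally among states", {
  aln_id <- c("ACDEF", "ACDEF")
  gp <- toy_group_pair(rep(list(aln_id), 4))
  sc <- classify_sites(gp)

  mk_wt <- function(rows) list(site_states = do.call(rbind, strsplit(rows, "")))
  # group A: site 2 wobbles {C, E}; site 3 sees all three states
  wt_a <- mk_wt(c("HCHEC", "HEEEC", "HCCEC"))
  wt_b <- mk_wt(c("HHCEC", "HHCEC"))
  d <- ss_distribution_by_class(sc, wt_a, wt_b)
  expect_true(all(abs(rowSums(d$fractions)[rowSums(d$weights) > 0] - 1) < 1e-9))
  expect_equal(d$n_three_state, 1L)   # site 3 of group A saw {C, E, H}
  # total weight: one unit per observed site per side
  expect_equal(sum(d$weights), 10)
})

test_that("forced-identical synthetic group pairs have no multi sites", {
  ds <- generate_dataset(generator_config(families = 1, groups_per_family = 2,
                                          structures_per_group = 2,
                                          flexible_prob = 0, hinge_spread = 0,
                                          jitter = c(H = 0, E = 0, C = 0),
                                          mutation_prob = 0,
                                          substitutions_between_groups = 0,
                                          terminal_deletion_max = 0, seed = 9))
  gp <- group_pair(ds$groups[[1]], ds$groups[[2]])
  sc <- classify_sites(gp)
  expect_equal(sc$rm, 0)
  expect_equal(sc$rc, 100)
})
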