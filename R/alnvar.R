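#' All cross-comparisons between two structural groups
#'
#' Runs [structural_align()] for every member pair (one structure from each
#' group) and records the extreme comparisons. A group pair is the unit of
#' the sequence-alignment variation and evolutionary-distance analyses.
#'
#' @param ga,gb [structural_group()] objects from the same family.
#' @param ... passed to [structural_align()].
#' @return object of class `group_pair`: `group_a`, `group_b`,
#'   `comparisons` (list of `superposition`, length `|A| * |B|`),
#'   `rmsd_max`, `rmsd_min`, `tm_max`, `tm_min`.
#' @export
group_pair <- function(ga, gb, ...) {
  comps <- list()
  for (ma in ga$members) {
    for (mb in gb$members) {
      comps[[length(comps) + 1]] <- structural_align(ma, mb, ...)
    }
  }
  rmsds <- vapply(comps, function(s) s$rmsd, 0)
  tms <- vapply(comps, function(s) s$tm_score, 0)
  structure(
    list(group_a = ga$group_id, group_b = gb$group_id,
         msa_a = ga$msa, msa_b = gb$msa,
         comparisons = comps,
         rmsd_max = max(rmsds), rmsd_min = min(rmsds),
         tm_max = max(tms), tm_min = min(tms)),
    class = "group_pair"
  )
}

#' @export
print.group_pair <- function(x, ...) {
  cat(sprintf(
    "<group_pair> %s vs %s: %d comparisons, RMSD [%.3f, %.3f] A, TM [%.4f, %.4f]\n",
    x$group_a, x$group_b, length(x$comparisons),
    x$rmsd_min, x$rmsd_max, x$tm_min, x$tm_max))
  invisible(x)
}

# residue ordinal -> group-MSA column map for one member row
.res_to_col <- function(msa_row) which(strsplit(msa_row, "")[[1]] != "-")

#' Classify alignment sites of a group pair as common, multi or gap
#'
#' Looks at every site (group-alignment column) of each of the two proteins
#' across all structure-pair alignments of the group pair: a site aligned to
#' the same partner site in every comparison is a common site; a site
#' aligned to a gap in every comparison is a gap site; everything else
#' (different partners, or a mix of partners and gaps) is a multi site, so
#' the three classes partition the sites. Counts are averaged over the two
#' proteins (`Nx = (count_A + count_B) / 2`) and expressed as percentages of
#' the average protein length, so `Rc + Rm + Rg = 100`.
#'
#' @param gp a [group_pair()].
#' @return object of class `site_classification`: `class_a`, `class_b`
#'   (character vectors over sites), `nc`, `nm`, `ng`, `na_avg`, `rc`,
#'   `rm`, `rg`, `degenerate` (single comparison).
#' @export
classify_sites <- function(gp) {
  comps <- gp$comparisons
  degenerate <- length(comps) < 2
  colmap_a <- lapply(gp$msa_a, .res_to_col)
  colmap_b <- lapply(gp$msa_b, .res_to_col)
  n_a <- nchar(gp$msa_a[[1]]); n_b <- nchar(gp$msa_b[[1]])

  # partners[[site]] = vector of partner columns (NA = gap) over comparisons
  part_a <- vector("list", n_a)
  part_b <- vector("list", n_b)
  for (cp in comps) {
    map_a <- colmap_a[[cp$id_a]]; map_b <- colmap_b[[cp$id_b]]
    aln <- cp$correspondence$aligned
    c1 <- strsplit(aln[1], "")[[1]]; c2 <- strsplit(aln[2], "")[[1]]
    i <- cumsum(c1 != "-"); j <- cumsum(c2 != "-")
    for (col in seq_along(c1)) {
      if (c1[col] != "-") {
        sa <- map_a[i[col]]
        part_a[[sa]] <- c(part_a[[sa]],
                          if (c2[col] != "-") map_b[j[col]] else NA_integer_)
      }
      if (c2[col] != "-") {
        sb <- map_b[j[col]]
        part_b[[sb]] <- c(part_b[[sb]],
                          if (c1[col] != "-") map_a[i[col]] else NA_integer_)
      }
    }
  }
  classify <- function(partners) {
    vapply(partners, function(p) {
      if (is.null(p) || all(is.na(p))) return("gap")
      if (!anyNA(p) && length(unique(p)) == 1) return("common")
      "multi"
    }, "")
  }
  class_a <- classify(part_a)
  class_b <- classify(part_b)
  cnt <- function(cl, what) sum(cl == what)
  nc <- (cnt(class_a, "common") + cnt(class_b, "common")) / 2
  nm <- (cnt(class_a, "multi") + cnt(class_b, "multi")) / 2
  ng <- (cnt(class_a, "gap") + cnt(class_b, "gap")) / 2
  na_avg <- (n_a + n_b) / 2
  structure(
    list(class_a = class_a, class_b = class_b,
         nc = nc, nm = nm, ng = ng, na_avg = na_avg,
         rc = 100 * nc / na_avg, rm = 100 * nm / na_avg,
         rg = 100 * ng / na_avg, degenerate = degenerate),
    class = "site_classification"
  )
}

#' @export
print.site_classification <- function(x, ...) {
  cat(sprintf(
    "<site_classification> Rc %.2f%%, Rm %.2f%%, Rg %.2f%% (Na = %.1f)%s\n",
    x$rc, x$rm, x$rg, x$na_avg,
    if (x$degenerate) " [degenerate: single comparison]" else ""))
  invisible(x)
}

#' Site-class ratios
#'
#' @param sc a [classify_sites()] result.
#' @return named vector `c(rc, rm, rg)` in percent, summing to 100.
#' @export
variation_ratios <- function(sc) {
  if (sc$na_avg == 0) stop("Na is zero")
  c(rc = sc$rc, rm = sc$rm, rg = sc$rg)
}

#' Secondary-structure state distribution by alignment site class
#'
#' For each site of each protein of a group pair, the site's observed
#' 3-state set across its group's structures contributes a total weight of
#' 1, split equally among the observed states (0.5 each at a two-state
#' wobble site, 1/3 each at a three-state site -- the latter are flagged).
#' Weights are accumulated per site class and normalised to fractions.
#'
#' @param sc a [classify_sites()] result for the group pair.
#' @param wt_a,wt_b the two groups' [find_wobble_sites()] tables.
#' @return object of class `ss_class_distribution`: `fractions` (3x3 matrix
#'   classes x states), `weights`, `n_three_state` (count of three-state
#'   sites encountered).
#' @export
ss_distribution_by_class <- function(sc, wt_a, wt_b) {
  classes <- c("common", "multi", "gap")
  states <- c("C", "H", "E")
  w <- matrix(0, 3, 3, dimnames = list(classes, states))
  n3 <- 0L
  add_side <- function(cl, wt) {
    for (site in seq_along(cl)) {
      obs <- unique(wt$site_states[, site])
      obs <- obs[!is.na(obs)]
      if (length(obs) == 0) next
      if (length(obs) >= 3) n3 <<- n3 + 1L
      for (s in obs) w[cl[site], s] <<- w[cl[site], s] + 1 / length(obs)
    }
  }
  add_side(sc$class_a, wt_a)
  add_side(sc$class_b, wt_b)
  fr <- w / ifelse(rowSums(w) == 0, 1, rowSums(w))
  structure(list(fractions = fr, weights = w, n_three_state = n3),
            class = "ss_class_distribution")
}

#' @export
print.ss_class_distribution <- function(x, ...) {
  cat("<ss_class_distribution> state fractions by site class:\n")
  print(round(x$fractions, 4))
  if (x$n_three_state > 0) {
    cat(sprintf(" note: %d three-state site(s) weighted 1/3 per state\n",
                x$n_three_state))
  }
  invisible(x)
}
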