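# Fixtures and independent oracles shared across the test files. All
# structures are built in code; nothing is read from disk except files the
# tests write themselves.

# ideal poly-ALA alpha helix
make_helix_chain <- function(n = 18, id = "HLX:A") {
  bb <- flexwobble:::build_backbone(rep(-57, n), rep(-47, n))
  chain_structure(id, strrep("A", n), bb)
}

# two-strand antiparallel beta hairpin (strand dihedrals with a tight turn
# whose geometry was fixed once by construction)
make_hairpin_chain <- function(id = "HPN:A") {
  phi <- c(rep(-150, 6), 53, 96, rep(-150, 6))
  psi <- c(rep(128, 6), 56, -20, rep(128, 6))
  chain_structure(id, strrep("A", 14), flexwobble:::build_backbone(phi, psi))
}

# chain from explicit dihedrals with a repeated-letter sequence
make_dihedral_chain <- function(phi, psi, id = "DHC:A", seq = NULL) {
  if (is.null(seq)) seq <- strrep("A", length(phi))
  chain_structure(id, seq, flexwobble:::build_backbone(phi, psi))
}

# minimal 3-residue PDB text fixture (ALA-CYS-ASP, chain A, altloc on CYS CA)
write_toy_pdb <- function(path, resolution_line = TRUE) {
  lines <- c(
    if (resolution_line) "REMARK   2 RESOLUTION.    1.80 ANGSTROMS.",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  N   CYS A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      6  CA ACYS A   2       4.000   2.800   0.100  0.50  0.00           C",
    "ATOM      7  CA BCYS A   2       4.100   2.900   0.200  0.50  0.00           C",
    "ATOM      8  C   CYS A   2       5.300   2.500   0.800  1.00  0.00           C",
    "ATOM      9  O   CYS A   2       5.600   1.400   1.200  1.00  0.00           O",
    "ATOM     10  N   ASP A   3       6.100   3.500   1.000  1.00  0.00           N",
    "ATOM     11  CA  ASP A   3       7.500   3.400   1.400  1.00  0.00           C",
    "ATOM     12  C   ASP A   3       8.300   4.600   0.900  1.00  0.00           C",
    "TER", "END")
  writeLines(lines, path)
  path
}

# classic-format DSSP text for a 4-residue chain A with a chain break row
write_toy_dssp <- function(path) {
  lines <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A A  H  >",
    "    2    2 A C  H  >",
    "    3    3 A D     >",
    "    4      A !      ",
    "    5    4 A E  E  >")
  writeLines(lines, path)
  path
}

# quaternion -> rotation matrix (for the brute-force superposition oracle)
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_rotation <- function() quat_to_rot(stats::rnorm(4))

# brute-force minimal RMSD over rotations: random quaternion sampling
# followed by Nelder-Mead polish; independent of the SVD route
brute_force_rmsd <- function(A, B, n_rot = 2000) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  obj <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((Ac - Bc %*% t(R))^2)))
  }
  qs <- matrix(stats::rnorm(4 * n_rot), ncol = 4)
  vals <- apply(qs, 1, obj)
  best <- qs[which.min(vals), ]
  o <- stats::optim(best, obj, method = "Nelder-Mead",
                    control = list(maxit = 1000, reltol = 1e-14))
  o$value
}

# exhaustive enumeration of colinear matchings for the structural DP:
# score = sum of matched similarities minus gap * skipped residues strictly
# inside the matched span of each chain (free end gaps)
enumerate_best_matching <- function(S, gap = 0.6) {
  n <- nrow(S); m <- ncol(S)
  best <- -Inf
  score_matching <- function(pairs) {
    if (nrow(pairs) == 0) return(0)
    s <- sum(S[pairs])
    span_gap <- function(idx) (max(idx) - min(idx) + 1) - length(idx)
    s - gap * (span_gap(pairs[, 1]) + span_gap(pairs[, 2]))
  }
  recurse <- function(i, j, pairs) {
    best <<- max(best, score_matching(pairs))
    if (i > n || j > m) return()
    for (a in i:n) {
      for (b in j:m) {
        recurse(a + 1, b + 1, rbind(pairs, c(a, b)))
      }
    }
  }
  recurse(1, 1, matrix(0L, 0, 2))
  best
}

# score the pair list returned by the package DP under the same objective
dp_pairs_score <- function(S, pairs, gap = 0.6) {
  if (nrow(pairs) == 0) return(0)
  span_gap <- function(idx) (max(idx) - min(idx) + 1) - length(idx)
  sum(S[pairs]) - gap * (span_gap(pairs[, 1]) + span_gap(pairs[, 2]))
}

# a quick small synthetic configuration for pipeline-level tests
small_config <- function(...) {
  args <- list(families = 1, groups_per_family = 3, structures_per_group = 5,
               mutation_prob = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generator_config, args)
}

# random gapped aligned pair of amino-acid strings
random_aligned_pair <- function(len = 30, gap_prob = 0.1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sx <- sample(aa, len, replace = TRUE)
  sy <- sample(aa, len, replace = TRUE)
  gx <- stats::runif(len) < gap_prob
  gy <- stats::runif(len) < gap_prob & !gx
  sx[gx] <- "-"; sy[gy] <- "-"
  # ensure at least one both-residue column
  sx[1] <- sample(aa, 1); sy[1] <- sample(aa, 1)
  c(paste(sx, collapse = ""), paste(sy, collapse = ""))
}
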