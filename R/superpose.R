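#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping point set `B` onto `A`
#' (`a ~ R b + t`), with the reflection excluded by the usual determinant
#' sign correction, and the RMSD of the superposed sets.
#'
#' @param A,B `n x 3` coordinate matrices with matching rows, `n >= 3`.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` (Angstroms).
#' @export
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("point sets must have the same size")
  if (nrow(A) < 3) stop("need at least 3 points for a unique superposition")
  cA <- colMeans(A); cB <- colMeans(B)
  Ac <- sweep(A, 2, cA); Bc <- sweep(B, 2, cB)
  s <- svd(t(Bc) %*% Ac)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Bfit <- Bc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Ac - Bfit)^2)))
  list(rotation = R, translation = as.vector(cA - R %*% cB), rmsd = rmsd)
}

# apply a superposition to an n x 3 matrix
apply_transform <- function(X, rotation, translation) {
  sweep(as.matrix(X) %*% t(rotation), 2, translation, "+")
}

#' TM-score normalisation distance d0
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, clamped to at least 0.5 A (the clamp is
#' active for `L <= 21`, where the expression turns small or undefined).
#'
#' @param L_norm normalisation length (residues), `>= 1`.
#' @return d0 in Angstroms.
#' @export
tm_d0 <- function(L_norm) {
  if (L_norm < 1) stop("L_norm must be >= 1")
  if (L_norm <= 15) return(0.5)
  max(0.5, 1.24 * (L_norm - 15)^(1 / 3) - 1.8)
}

#' TM-score from aligned-pair distances
#'
#' `TM = (1 / L_norm) * sum 1 / (1 + (d_i / d0)^2)` with [tm_d0()]'s `d0`.
#'
#' @param distances Angstrom distances of aligned residue pairs (>= 0).
#' @param L_norm normalisation length.
#' @return TM-score in `(0, 1]` (0 for an empty distance set).
#' @export
compute_tm_score <- function(distances, L_norm) {
  if (any(distances < 0)) stop("distances must be nonnegative")
  if (L_norm < 1) stop("L_norm must be >= 1")
  d0 <- tm_d0(L_norm)
  sum(1 / (1 + (distances / d0)^2)) / L_norm
}

# Semi-global (free end gap) dynamic-programming alignment on an
# n x m similarity matrix with a linear gap penalty. Returns the colinear
# pair list (i, j), 1-based. Ties prefer the diagonal move for determinism.
dp_align <- function(S, gap = 0.6) {
  n <- nrow(S); m <- ncol(S)
  H <- matrix(0, n + 1, m + 1)
  js <- seq_len(m)
  for (i in seq_len(n)) {
    tmp <- pmax(H[i, js] + S[i, ], H[i, js + 1] - gap)
    H[i + 1, js + 1] <- cummax(tmp + gap * js) - gap * js
  }
  # free trailing gaps: start traceback at the best boundary cell
  last_col <- H[, m + 1]; last_row <- H[n + 1, ]
  if (max(last_row) >= max(last_col)) {
    i <- n; j <- which.max(last_row) - 1L
  } else {
    i <- which.max(last_col) - 1L; j <- m
  }
  pairs <- matrix(0L, 0, 2)
  eps <- 1e-9
  while (i > 0 && j > 0) {
    if (abs(H[i + 1, j + 1] - (H[i, j] + S[i, j])) < eps) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1L; j <- j - 1L
    } else if (abs(H[i + 1, j + 1] - (H[i, j + 1] - gap)) < eps) {
      i <- i - 1L
    } else if (abs(H[i + 1, j + 1] - (H[i + 1, j] - gap)) < eps) {
      j <- j - 1L
    } else {
      break
    }
  }
  pairs
}

# global sequence alignment of two amino-acid strings (BLOSUM62, affine
# gaps via Biostrings); returns the two gapped strings.
nw_align <- function(s1, s2, gap_opening = 10, gap_extension = 1) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s1), Biostrings::AAString(s2),
    substitutionMatrix = blosum62_matrix(), type = "global",
    gapOpening = gap_opening, gapExtension = gap_extension)
  c(as.character(Biostrings::alignedPattern(al)),
    as.character(Biostrings::alignedSubject(al)))
}

# percent identity (matches / alignment length incl. gaps), as a fraction
seq_identity <- function(s1, s2) {
  if (identical(s1, s2)) return(1)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s1), Biostrings::AAString(s2),
    substitutionMatrix = blosum62_matrix(), type = "global",
    gapOpening = 10, gapExtension = 1)
  Biostrings::pid(al, type = "PID1") / 100
}

# pair list -> two gapped aligned strings
pairs_to_alignment <- function(pairs, s1, s2) {
  a1 <- strsplit(s1, "")[[1]]; a2 <- strsplit(s2, "")[[1]]
  out1 <- character(0); out2 <- character(0)
  i <- 1L; j <- 1L
  emit <- function(x, y) { out1 <<- c(out1, x); out2 <<- c(out2, y) }
  for (k in seq_len(nrow(pairs))) {
    while (i < pairs[k, 1]) { emit(a1[i], "-"); i <- i + 1L }
    while (j < pairs[k, 2]) { emit("-", a2[j]); j <- j + 1L }
    emit(a1[i], a2[j]); i <- i + 1L; j <- j + 1L
  }
  while (i <= length(a1)) { emit(a1[i], "-"); i <- i + 1L }
  while (j <= length(a2)) { emit("-", a2[j]); j <- j + 1L }
  c(paste(out1, collapse = ""), paste(out2, collapse = ""))
}

# gapped alignment strings -> pair list
alignment_to_pairs <- function(aln1, aln2) {
  a1 <- strsplit(aln1, "")[[1]]; a2 <- strsplit(aln2, "")[[1]]
  i <- cumsum(a1 != "-"); j <- cumsum(a2 != "-")
  both <- a1 != "-" & a2 != "-"
  cbind(i[both], j[both])
}

# build a superposition result from a fixed correspondence
superposition_from_pairs <- function(A, B, pairs, L_norm) {
  caA <- ca_coords(A); caB <- ca_coords(B)
  k <- kabsch_superpose(caA[pairs[, 1], , drop = FALSE],
                        caB[pairs[, 2], , drop = FALSE])
  Bfit <- apply_transform(caB, k$rotation, k$translation)
  d <- sqrt(rowSums((caA[pairs[, 1], , drop = FALSE] -
                     Bfit[pairs[, 2], , drop = FALSE])^2))
  aln <- pairs_to_alignment(pairs, A$sequence, B$sequence)
  structure(
    list(id_a = A$structure_id, id_b = B$structure_id,
         correspondence = list(pairs = pairs, aligned = aln),
         rotation = k$rotation, translation = k$translation,
         rmsd = k$rmsd, tm_score = compute_tm_score(d, L_norm),
         n_aligned = nrow(pairs), d0 = tm_d0(L_norm)),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf(
    "<superposition> %s vs %s: %d aligned, RMSD %.3f A, TM-score %.4f (d0 %.2f)\n",
    x$id_a, x$id_b, x$n_aligned, x$rmsd, x$tm_score, x$d0))
  invisible(x)
}

#' Export a pairwise alignment as a FASTA pair
#'
#' @param sp a `superposition` result.
#' @param path output file.
#' @export
write_alignment_fasta <- function(sp, path) {
  writeLines(c(paste0(">", sp$id_a), sp$correspondence$aligned[1],
               paste0(">", sp$id_b), sp$correspondence$aligned[2]), path)
  invisible(path)
}

#' Export a superposition's rotation and translation as a plain-text 3x4 block
#'
#' Each line holds one rotation-matrix row followed by that row's
#' translation component.
#'
#' @param sp a `superposition` result.
#' @param path output file.
#' @export
write_superposition_matrix <- function(sp, path) {
  writeLines(vapply(1:3, function(i) {
    paste(sprintf("%12.8f", c(sp$rotation[i, ], sp$translation[i])),
          collapse = " ")
  }, ""), path)
  invisible(path)
}

#' Structure-based alignment and superposition of two chains
#'
#' For (near-)identical sequences (identity at or above
#' `identity_threshold`) the correspondence is fixed by the sequence
#' alignment's matched columns, so the reported RMSD is the plain Kabsch
#' value over those residue pairs -- the dominant path for within-group
#' comparisons. Otherwise an iterative structure-based aligner is used:
#' seed correspondences (sequence alignment plus the best gapless threading
#' offset) are refined by alternating Kabsch superposition with a
#' dynamic-programming re-alignment on the TM-score site similarity
#' `1 / (1 + (d_ij / d0)^2)` (linear gap penalty), until the pair set is
#' stable or `max_iter` rounds; the iterate with the highest TM-score wins
#' (ties keep the earlier iterate).
#'
#' @param A,B [chain_structure()] objects with >= 10 residues.
#' @param identity_threshold sequence identity above which the sequence
#'   alignment fixes the correspondence (default 0.99, the grouping
#'   threshold).
#' @param norm TM-score normalisation length policy: `"shorter"` (default)
#'   or `"average"`.
#' @param gap_penalty linear gap penalty of the structural DP (default 0.6).
#' @param max_iter refinement cap (default 30).
#' @return object of class `superposition`.
#' @export
structural_align <- function(A, B, identity_threshold = 0.99,
                             norm = c("shorter", "average"),
                             gap_penalty = 0.6, max_iter = 30) {
  norm <- match.arg(norm)
  nA <- length(A); nB <- length(B)
  if (nA < 10 || nB < 10) stop("both chains must have at least 10 residues")
  L_norm <- if (norm == "shorter") min(nA, nB) else (nA + nB) / 2

  if (identical(A$sequence, B$sequence)) {
    pairs <- cbind(seq_len(nA), seq_len(nA))
    return(superposition_from_pairs(A, B, pairs, L_norm))
  }
  aln <- nw_align(A$sequence, B$sequence)
  seq_pairs <- alignment_to_pairs(aln[1], aln[2])
  if (seq_identity(A$sequence, B$sequence) >= identity_threshold) {
    if (nrow(seq_pairs) < 10) stop("alignment failed: fewer than 10 aligned pairs")
    return(superposition_from_pairs(A, B, seq_pairs, L_norm))
  }

  caA <- ca_coords(A); caB <- ca_coords(B)
  d0 <- tm_d0(L_norm)

  refine <- function(pairs) {
    best <- NULL; prev_key <- ""
    for (it in seq_len(max_iter)) {
      if (nrow(pairs) < 3) break
      k <- kabsch_superpose(caA[pairs[, 1], , drop = FALSE],
                            caB[pairs[, 2], , drop = FALSE])
      Bfit <- apply_transform(caB, k$rotation, k$translation)
      D2 <- outer(rowSums(caA^2), rowSums(Bfit^2), "+") -
        2 * caA %*% t(Bfit)
      S <- 1 / (1 + pmax(D2, 0) / d0^2)
      pairs <- dp_align(S, gap = gap_penalty)
      if (nrow(pairs) == 0) break
      cand <- superposition_from_pairs(A, B, pairs, L_norm)
      if (is.null(best) || cand$tm_score > best$tm_score + 1e-12) best <- cand
      key <- paste(pairs, collapse = ",")
      if (key == prev_key) break
      prev_key <- key
    }
    best
  }

  # seed 1: sequence alignment; seed 2: best gapless threading offset
  seeds <- list()
  if (nrow(seq_pairs) >= 3) seeds <- c(seeds, list(seq_pairs))
  best_off <- NULL; best_off_rmsd <- Inf
  for (off in seq(-min(nA, nB) %/% 3, min(nA, nB) %/% 3)) {
    i0 <- max(1, 1 - off); i1 <- min(nA, nB - off)
    if (i1 - i0 + 1 < 10) next
    idx <- i0:i1
    k <- kabsch_superpose(caA[idx, , drop = FALSE],
                          caB[idx + off, , drop = FALSE])
    if (k$rmsd < best_off_rmsd) {
      best_off_rmsd <- k$rmsd
      best_off <- cbind(idx, idx + off)
    }
  }
  if (!is.null(best_off)) seeds <- c(seeds, list(best_off))
  if (length(seeds) == 0) stop("alignment failed: no seed correspondence")

  best <- NULL
  for (sd in seeds) {
    res <- refine(sd)
    if (!is.null(res) &&
        (is.null(best) || res$tm_score > best$tm_score + 1e-12)) {
      best <- res
    }
  }
  if (is.null(best) || best$n_aligned < 10) {
    stop("alignment failed: no correspondence of at least 10 pairs")
  }
  best
}
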