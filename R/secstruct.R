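#' Reduce an 8-state secondary-structure string to 3 states
#'
#' Fixed mapping: `E -> E` (sheet); `H`, `G`, `I -> H` (helix); `B`, `T`,
#' `S` and `-` `-> C` (coil).
#'
#' @param states8 string over `H G I E B T S -` (may be empty).
#' @return string of the same length over `H E C`.
#' @export
#' @examples
#' reduce_to_three_states("HGIEBTS-")   # "HHHECCCC"
reduce_to_three_states <- function(states8) {
  if (nchar(states8) == 0) return("")
  ch <- strsplit(states8, "")[[1]]
  map <- c(H = "H", G = "H", I = "H", E = "E", B = "C", T = "C", S = "C",
           "-" = "C", C = "C")   # accepting C makes the map idempotent
  out <- map[ch]
  if (anyNA(out)) {
    bad <- unique(ch[is.na(out)])
    stop("unknown secondary-structure letter(s): ", paste(bad, collapse = ", "))
  }
  paste(out, collapse = "")
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic energy of a backbone N-H...O=C contact from the four
#' inter-atomic distances, `E = 0.084 * (1/rON + 1/rCH - 1/rOH - 1/rCN) * 332`
#' kcal/mol. A bond is accepted when `E < -0.5` kcal/mol.
#'
#' @param rON,rCH,rOH,rCN distances in Angstroms (N/H of the donor, C/O of
#'   the acceptor). Distances below 0.5 A are clamped to 0.5 with a warning.
#' @return energy in kcal/mol.
#' @export
hbond_energy <- function(rON, rCH, rOH, rCN) {
  d <- c(rON, rCH, rOH, rCN)
  if (any(d < 0.5)) {
    warning("clashing geometry: distance(s) below 0.5 A clamped")
    d <- pmax(d, 0.5)
  }
  0.084 * (1 / d[1] + 1 / d[2] - 1 / d[3] - 1 / d[4]) * 332
}

.hbond_cutoff <- -0.5

# Backbone N-H...O=C hydrogen bonds of a chain. The amide hydrogen is
# imputed 1.01 A from N along the bisector opposite the C(i-1) and O(i-1)
# directions; residue 1 and prolines have no donor. Returns a logical matrix
# hb[i, j] = TRUE when the N-H of residue i donates to the C=O of residue j.
backbone_hbonds <- function(cs) {
  n <- length(cs)
  N <- cs$atoms$N; CA <- cs$atoms$CA; C <- cs$atoms$C; O <- cs$atoms$O
  aa <- strsplit(cs$sequence, "")[[1]]
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (aa[i] == "P") next
    if (any(!is.finite(N[i, ])) || any(!is.finite(C[i - 1, ])) ||
        any(!is.finite(O[i - 1, ]))) next
    u <- unit_vec(N[i, ] - C[i - 1, ]) + unit_vec(N[i, ] - O[i - 1, ])
    if (vec_norm(u) < 1e-6) next
    H[i, ] <- N[i, ] + 1.01 * unit_vec(u)
  }
  # all donor-acceptor energies at once; rows = donor i (N-H), cols =
  # acceptor j (C=O); clashing distances are clamped at 0.5 A
  pdist <- function(X, Y) {
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
    pmax(sqrt(pmax(d2, 0)), 0.5)
  }
  E <- 0.084 * 332 * (1 / pdist(N, O) + 1 / pdist(H, C) -
                      1 / pdist(H, O) - 1 / pdist(N, C))
  E[!is.finite(E)] <- 0
  idx <- seq_len(n)
  near <- abs(outer(idx, idx, "-")) >= 2
  hb <- E < .hbond_cutoff & near
  hb[!stats::complete.cases(H), ] <- FALSE
  hb[, !stats::complete.cases(O) | !stats::complete.cases(C)] <- FALSE
  hb
}

#' Assign secondary structure from backbone coordinates
#'
#' Simplified Kabsch-Sander assignment: hydrogen bonds from the
#' electrostatic model ([hbond_energy()]), n-turns (i -> i+3/4/5), helix
#' types from runs of at least two consecutive turns (`H`, `G`, `I`),
#' parallel/antiparallel bridge patterns with ladders of length >= 2 as `E`
#' and isolated bridges as `B`, remaining turn residues as `T`, everything
#' else `-`. The bend state `S` is never emitted. Chains shorter than 5
#' residues come back all `-`.
#'
#' @param cs a [chain_structure()] with backbone N, CA, C, O coordinates.
#' @return a [sec_structure()] with `source = "built-in"`.
#' @export
assign_secondary_structure <- function(cs) {
  n <- length(cs)
  if (n < 5) return(sec_structure(strrep("-", n)))
  hb <- backbone_hbonds(cs)

  # turn(i, k): C=O of residue i accepts from N-H of residue i+k
  turn <- function(k) {
    v <- rep(FALSE, n)
    idx <- seq_len(n - k)
    v[idx] <- hb[cbind(idx + k, idx)]
    v
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)

  ss <- rep("-", n)

  # turns first (lowest priority): residues spanned by any single n-turn
  for (k in c(3, 4, 5)) {
    tk <- list(`3` = t3, `4` = t4, `5` = t5)[[as.character(k)]]
    for (i in which(tk)) ss[(i + 1):(i + k - 1)] <- "T"
  }

  # bridges, Kabsch-Sander patterns; A[a, b] = CO(a) accepts from NH(b)
  A <- t(hb)
  B <- hb
  sr <- function(M, k) {   # row shift: out[i, j] = M[i + k, j]
    out <- matrix(FALSE, n, n)
    src <- intersect(seq_len(n) + k, seq_len(n))
    out[src - k, ] <- M[src, ]
    out
  }
  sc <- function(M, k) t(sr(t(M), k))
  par_b <- (sr(A, -1) & sr(B, 1)) | (sc(B, -1) & sc(A, 1))
  anti_b <- (A & B) | (sr(sc(A, 1), -1) & sr(sc(B, -1), 1))
  bridge <- (par_b | anti_b) & abs(outer(seq_len(n), seq_len(n), "-")) >= 3
  bridge[c(1, n), ] <- FALSE; bridge[, c(1, n)] <- FALSE
  bridge <- bridge | t(bridge)
  has_bridge <- apply(bridge, 1, any)
  if (any(has_bridge)) {
    # ladders: consecutive residues i, i+1 both bridged to adjacent partners
    in_ladder <- rep(FALSE, n)
    for (i in seq_len(n - 1)) {
      if (!has_bridge[i] || !has_bridge[i + 1]) next
      pi_ <- which(bridge[i, ]); pj <- which(bridge[i + 1, ])
      if (any(abs(outer(pi_, pj, "-")) == 1)) {
        in_ladder[c(i, i + 1)] <- TRUE
      }
    }
    # a residue bridged to a ladder residue belongs to the sheet too
    ss[has_bridge & !in_ladder] <- "B"
    ss[in_ladder] <- "E"
  }

  # helices: runs of >= 2 consecutive turns; 4-helix (H) has top priority
  mark_helix <- function(tk, k, letter) {
    for (i in 2:max(1, n - k)) {
      if (tk[i] && tk[i - 1]) {
        idx <- i:(i + k - 1)
        replace_ok <- switch(letter,
          I = ss[idx] %in% c("-", "T"),
          G = ss[idx] %in% c("-", "T"),
          H = rep(TRUE, length(idx)))
        ss[idx[replace_ok]] <<- letter
      }
    }
  }
  mark_helix(t5, 5, "I")
  mark_helix(t3, 3, "G")
  mark_helix(t4, 4, "H")

  sec_structure(paste(ss, collapse = ""))
}

#' Secondary structure for a chain, preferring a supplied DSSP file
#'
#' When `dssp_path` is given the classic DSSP file is parsed and takes
#' precedence (the residue count is validated against the chain); otherwise
#' the built-in assigner is used. The `source` field records which route
#' produced the string.
#'
#' @param cs a [chain_structure()].
#' @param dssp_path optional classic DSSP output file.
#' @param chain chain identifier inside the DSSP file (default from
#'   `cs$structure_id`).
#' @return a [sec_structure()].
#' @export
secondary_structure <- function(cs, dssp_path = NULL, chain = NULL) {
  if (!is.null(dssp_path)) {
    if (is.null(chain)) chain <- sub("^.*:", "", cs$structure_id)
    read_dssp_chain(dssp_path, chain, expect_length = length(cs))
  } else {
    assign_secondary_structure(cs)
  }
}
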