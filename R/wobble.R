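#' Wobble-site ratio (percent)
#'
#' `Rw = Nw / Na * 100`: the percentage of alignment sites showing more than
#' one 3-state secondary structure across a structural group.
#'
#' @param nw number of wobble sites.
#' @param na total number of sites.
#' @return percentage.
#' @export
#' @examples
#' wobble_ratio(72, 412)   # 17.48 (2 d.p.)
wobble_ratio <- function(nw, na) {
  if (na <= 0) stop("Na must be positive")
  100 * nw / na
}

# map each member's 3-state string onto the group MSA columns; returns a
# members x columns character matrix with NA where the member has a gap
states_on_msa <- function(msa, states3) {
  if (is.null(names(states3))) names(states3) <- names(msa)
  mat <- matrix(NA_character_, length(msa), nchar(msa[[1]]),
                dimnames = list(names(msa), NULL))
  for (id in names(msa)) {
    row <- strsplit(msa[[id]], "")[[1]]
    st <- strsplit(states3[[id]], "")[[1]]
    npos <- which(row != "-")
    if (length(npos) != length(st)) {
      stop(sprintf(
        "member '%s': 3-state string has %d states but the ungapped sequence has %d residues",
        id, length(st), length(npos)))
    }
    mat[id, npos] <- st
  }
  mat
}

#' Wobble sites of a structural group
#'
#' Collects, per MSA column, every member's 3-state secondary-structure
#' state (members gapped at a column contribute nothing there). A column is
#' a wobble site when at least two distinct states are observed. `Na` counts
#' columns with at least one observed state, and the ratio follows
#' [wobble_ratio()]. Transition-type tallies count, for every wobble column,
#' each unordered state pair present -- a three-state column increments all
#' three of `C<=>E`, `C<=>H` and `H<=>E`.
#'
#' @param group a [structural_group()].
#' @param states3 named character vector/list of 3-state strings (over
#'   `H E C`), one per member, names matching `group$msa`; or a list of
#'   [sec_structure()] objects.
#' @return object of class `wobble_table`: `group_id`, `site_states`
#'   (members x columns matrix), `wobble_flags`, `nw`, `na`, `rw`,
#'   `type_counts`.
#' @export
find_wobble_sites <- function(group, states3) {
  states3 <- vapply(states3, function(s) {
    if (inherits(s, "sec_structure")) s$states3 else s
  }, "")
  mat <- states_on_msa(group$msa, states3)
  n_states <- apply(mat, 2, function(col) length(unique(col[!is.na(col)])))
  observed <- apply(mat, 2, function(col) any(!is.na(col)))
  wobble <- n_states >= 2
  types <- c("C<=>E" = 0L, "C<=>H" = 0L, "H<=>E" = 0L)
  for (j in which(wobble)) {
    s <- unique(mat[, j][!is.na(mat[, j])])
    if (all(c("C", "E") %in% s)) types[["C<=>E"]] <- types[["C<=>E"]] + 1L
    if (all(c("C", "H") %in% s)) types[["C<=>H"]] <- types[["C<=>H"]] + 1L
    if (all(c("H", "E") %in% s)) types[["H<=>E"]] <- types[["H<=>E"]] + 1L
  }
  structure(
    list(group_id = group$group_id, site_states = mat,
         wobble_flags = wobble, nw = sum(wobble), na = sum(observed),
         rw = wobble_ratio(sum(wobble), sum(observed)),
         type_counts = types),
    class = "wobble_table"
  )
}

#' @export
print.wobble_table <- function(x, ...) {
  cat(sprintf("<wobble_table> %s: %d / %d sites wobble (Rw = %.2f%%)\n",
              x$group_id, x$nw, x$na, x$rw))
  cat(" types:", paste(names(x$type_counts), x$type_counts, sep = " ",
                       collapse = ", "), "\n")
  invisible(x)
}

#' Transition-type tallies of a wobble table
#'
#' @param wt a [find_wobble_sites()] result.
#' @return named integer vector over `C<=>E`, `C<=>H`, `H<=>E`.
#' @export
classify_wobble_types <- function(wt) wt$type_counts

#' Pairwise wobble ratios within a group
#'
#' The "wobble single" of a structure pair: over the columns of the group
#' alignment where at least one of the two structures carries a residue, the
#' percentage where both carry a state and the states differ. Reported with
#' the two structures' resolutions.
#'
#' @param group a [structural_group()].
#' @param wt the group's [find_wobble_sites()] result.
#' @return data frame, one row per unordered member pair: `id_a`, `id_b`,
#'   `wobble_single`, `resolution_a`, `resolution_b`.
#' @export
wobble_pair_summaries <- function(group, wt) {
  ids <- rownames(wt$site_states)
  res <- stats::setNames(vapply(group$members, function(m) m$resolution, 0),
                         vapply(group$members, function(m) m$structure_id, ""))
  out <- list()
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (b <= a) next
      sa <- wt$site_states[ids[a], ]; sb <- wt$site_states[ids[b], ]
      denom <- sum(!is.na(sa) | !is.na(sb))
      num <- sum(!is.na(sa) & !is.na(sb) & sa != sb)
      out[[length(out) + 1]] <- data.frame(
        id_a = ids[a], id_b = ids[b],
        wobble_single = wobble_ratio(num, denom),
        resolution_a = unname(res[ids[a]]),
        resolution_b = unname(res[ids[b]]))
    }
  }
  do.call(rbind, out)
}

#' Wobble-total versus maximum wobble-single regression
#'
#' Fits the group-level "wobble total" ratio on each group's maximum
#' pairwise "wobble single" ratio, through the origin (the reported slope)
#' and unconstrained. A slope `s > 1` implies a fraction `(s - 1) / s` of
#' wobble sites appearing only in intermediate conformations -- structures
#' other than the two most different ones.
#'
#' @param wobble_total numeric vector of group Rw percentages.
#' @param max_single numeric vector of the groups' maximum wobble-single
#'   percentages (same order).
#' @return list of class `wobble_regression`: `slope` (through origin),
#'   `intermediate_fraction`, `fit_origin`, `fit_free`, `n`.
#' @export
wobble_total_vs_single <- function(wobble_total, max_single) {
  if (length(wobble_total) != length(max_single)) stop("length mismatch")
  if (length(wobble_total) < 3) stop("need at least 3 groups")
  f0 <- linear_fit(max_single, wobble_total, through_origin = TRUE)
  f1 <- linear_fit(max_single, wobble_total, through_origin = FALSE)
  structure(
    list(slope = f0$slope,
         intermediate_fraction = (f0$slope - 1) / f0$slope,
         fit_origin = f0, fit_free = f1, n = length(wobble_total)),
    class = "wobble_regression"
  )
}

#' @export
print.wobble_regression <- function(x, ...) {
  cat(sprintf(
    "<wobble_regression> n = %d: slope through origin %.4f (implied intermediate-conformation fraction %.1f%%)\n",
    x$n, x$slope, 100 * x$intermediate_fraction))
  invisible(x)
}

#' Wobble enrichment at mutation sites
#'
#' Builds the 2x2 table (mutation sites: wobble / non-wobble) versus (all
#' sites: wobble / non-wobble) and tests it with the Yates-corrected
#' chi-square ([chi_square_2x2()]). Mutation sites are included in the
#' all-sites row. Returns "not applicable" when there are no mutation sites;
#' flags an exact-test fallback when an expected cell is zero.
#'
#' @param wt a [find_wobble_sites()] result (or a pooled table with `nw`,
#'   `na`, `wobble_flags`).
#' @param mutation_sites integer vector of MSA columns (e.g. from
#'   [detect_mutation_sites()]).
#' @return list of class `mutation_wobble`: `table`, `chi_square`,
#'   `applicable`, `exact_fallback`.
#' @export
mutation_wobble_stats <- function(wt, mutation_sites) {
  if (length(mutation_sites) == 0) {
    return(structure(list(table = NULL, chi_square = NULL,
                          applicable = FALSE, exact_fallback = FALSE),
                     class = "mutation_wobble"))
  }
  mut_w <- sum(wt$wobble_flags[mutation_sites])
  tab <- matrix(c(mut_w, length(mutation_sites) - mut_w,
                  wt$nw, wt$na - wt$nw),
                2, 2, byrow = TRUE,
                dimnames = list(c("mutation", "all"),
                                c("wobble", "non_wobble")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  fallback <- any(expected == 0)
  cs <- if (fallback) NULL else chi_square_2x2(tab, yates = TRUE)
  structure(list(table = tab, chi_square = cs, applicable = TRUE,
                 exact_fallback = fallback),
            class = "mutation_wobble")
}

#' @export
print.mutation_wobble <- function(x, ...) {
  if (!x$applicable) {
    cat("<mutation_wobble> not applicable: no mutation sites\n")
  } else {
    cat("<mutation_wobble>\n")
    print(x$table)
    if (!is.null(x$chi_square)) print(x$chi_square)
  }
  invisible(x)
}

#' Coil ratio of wobble-site states as a function of resolution
#'
#' For every wobble site between two structures of a group (their states at
#' a shared alignment column differ), each structure's state is attributed
#' to that structure's 0.1-Angstrom resolution bin (bin label = lower edge,
#' interval `[x, x + 0.1)`). Per bin, the coil ratio is the fraction of coil
#' states among all attributed states. The Pearson correlation and linear
#' fit of coil ratio against bin midpoint can be restricted to well
#' populated bins via `min_states`.
#'
#' @param groups list of [structural_group()] objects.
#' @param wobble_tables list of matching [find_wobble_sites()] results.
#' @param min_states only bins with more than this many attributed states
#'   enter the correlation/fit (default 0 = all populated bins).
#' @return list of class `resolution_coil_curve`: `bins` data frame
#'   (`lower`, `midpoint`, `coil`, `helix`, `sheet`, `n_states`,
#'   `coil_ratio`), `pcc`, `fit`, `min_states`.
#' @export
resolution_coil_curve <- function(groups, wobble_tables, min_states = 0) {
  counts <- list()   # keyed by bin lower edge -> c(C, H, E)
  add_state <- function(bin, st) {
    key <- sprintf("%.1f", bin)
    if (is.null(counts[[key]])) counts[[key]] <<- c(C = 0, H = 0, E = 0)
    counts[[key]][st] <<- counts[[key]][st] + 1
  }
  for (k in seq_along(groups)) {
    g <- groups[[k]]; wt <- wobble_tables[[k]]
    res <- stats::setNames(
      vapply(g$members, function(m) m$resolution, 0),
      vapply(g$members, function(m) m$structure_id, ""))
    if (any(is.na(res))) stop("member resolutions must be present")
    bins <- floor(res * 10) / 10
    ids <- rownames(wt$site_states)
    for (a in seq_along(ids)) {
      for (b in seq_along(ids)) {
        if (b <= a) next
        sa <- wt$site_states[ids[a], ]; sb <- wt$site_states[ids[b], ]
        hit <- which(!is.na(sa) & !is.na(sb) & sa != sb)
        for (j in hit) {
          add_state(bins[[ids[a]]], sa[j])
          add_state(bins[[ids[b]]], sb[j])
        }
      }
    }
  }
  if (length(counts) == 0) stop("no resolution bins populated")
  lower <- sort(as.numeric(names(counts)))
  tab <- do.call(rbind, lapply(sprintf("%.1f", lower), function(k) counts[[k]]))
  bins <- data.frame(lower = lower, midpoint = lower + 0.05,
                     coil = tab[, "C"], helix = tab[, "H"], sheet = tab[, "E"])
  bins$n_states <- bins$coil + bins$helix + bins$sheet
  bins$coil_ratio <- bins$coil / bins$n_states
  use <- bins$n_states > min_states
  pcc <- NULL; fit <- NULL
  x_ <- bins$midpoint[use]; y_ <- bins$coil_ratio[use]
  if (length(x_) >= 2 && stats::sd(x_) > 0) {
    fit <- linear_fit(x_, y_)
    if (stats::sd(y_) > 0) {
      if (length(x_) >= 3) {
        pcc <- pearson_cc(x_, y_)
      } else {
        # two points define the line exactly; r is +/-1, no p-value
        pcc <- list(r = stats::cor(x_, y_), p_value = NA_real_, n = 2L)
      }
    }
  }
  structure(list(bins = bins, pcc = pcc, fit = fit, min_states = min_states),
            class = "resolution_coil_curve")
}

#' @export
print.resolution_coil_curve <- function(x, ...) {
  cat(sprintf("<resolution_coil_curve> %d bin(s)", nrow(x$bins)))
  if (!is.null(x$pcc)) cat(sprintf(", PCC %.3f", x$pcc$r))
  if (!is.null(x$fit)) cat(sprintf(", slope %.4f", x$fit$slope))
  cat("\n")
  invisible(x)
}
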