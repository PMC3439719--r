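#' Greedy single-linkage-to-representative identity clustering
#'
#' Sequences are sorted longest-first (ties broken by lexicographic id) and
#' assigned greedily: each sequence joins the first existing cluster whose
#' representative (its founding, longest sequence) aligns to it with global
#' identity -- matches divided by alignment length, gaps included -- at or
#' above `threshold`; otherwise it founds a new cluster. Deterministic for a
#' given input set.
#'
#' @param sequences named character vector (names are ids) or list of
#'   sequences.
#' @param threshold identity fraction in `(0, 1]` (default 0.99).
#' @return named integer vector: cluster index per id (a partition).
#' @export
cluster_identity <- function(sequences, threshold = 0.99) {
  seqs <- unlist(sequences)
  if (length(seqs) == 0) stop("no sequences supplied")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named by id")
  }
  if (any(!nzchar(seqs))) stop("empty sequence in input")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  assign_to <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (seq_identity(reps[k], seqs[i]) >= threshold) {
        assign_to[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, seqs[i])
      assign_to[i] <- length(reps)
    }
  }
  stats::setNames(assign_to, names(seqs))
}

#' Structural group container
#'
#' A set of chains with (near-)identical sequences, their group multiple
#' alignment and the mutation-site columns.
#'
#' @param group_id identifier.
#' @param members list of [chain_structure()] objects (>= 2 to be
#'   comparable, singletons are allowed but flagged).
#' @param family_id family label from the metadata table.
#' @return object of class `structural_group` with `msa` (named character
#'   vector of gapped rows) and `mutation_sites` (1-based MSA columns).
#' @export
structural_group <- function(group_id, members, family_id = NA_character_) {
  ids <- vapply(members, function(m) m$structure_id, "")
  seqs <- stats::setNames(vapply(members, function(m) m$sequence, ""), ids)
  msa <- build_group_msa(seqs)
  structure(
    list(group_id = group_id, members = members, family_id = family_id,
         msa = msa, mutation_sites = detect_mutation_sites(msa)),
    class = "structural_group"
  )
}

#' @export
print.structural_group <- function(x, ...) {
  cat(sprintf(
    "<structural_group> %s (family %s): %d structures, %d MSA columns, %d mutation site(s)\n",
    x$group_id, x$family_id, length(x$members), nchar(x$msa[1]),
    length(x$mutation_sites)))
  invisible(x)
}

#' Progressive multiple alignment of near-identical sequences
#'
#' The longest sequence (lexicographic id tie-break) anchors the alignment;
#' every other member is aligned to it globally (BLOSUM62, affine gaps) and
#' the pairwise alignments are merged on anchor coordinates, inserting
#' shared gap columns where members carry insertions. Adequate for the
#' >= 99 percent identity sequences of a structural group; lower-identity
#' input is still aligned but draws a warning.
#'
#' @param seqs named character vector of sequences.
#' @param identity_warn warn when any member's identity to the anchor falls
#'   below this fraction (default 0.99).
#' @return named character vector of equal-length gapped rows, in input order.
#' @export
build_group_msa <- function(seqs, identity_warn = 0.99) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (length(seqs) == 1) return(seqs)
  anchor_id <- names(seqs)[order(-nchar(seqs), names(seqs))][1]
  anchor <- seqs[[anchor_id]]
  La <- nchar(anchor)
  others <- setdiff(names(seqs), anchor_id)

  # for each member: map of its characters onto anchor positions, plus
  # insertions keyed to the preceding anchor position (0 = before start)
  aligned <- list()
  ins_len <- rep(0L, La + 1)   # max insertion length after anchor pos 0..La
  for (id in others) {
    if (seq_identity(anchor, seqs[[id]]) < identity_warn) {
      warning(sprintf("sequence '%s' is below %.2f identity to the group anchor",
                      id, identity_warn))
    }
    al <- nw_align(anchor, seqs[[id]])
    ca <- strsplit(al[1], "")[[1]]; cm <- strsplit(al[2], "")[[1]]
    apos <- cumsum(ca != "-")
    # member characters at anchor columns; insertions where anchor has '-'
    res_at <- rep("-", La)
    res_at[apos[ca != "-"]] <- cm[ca != "-"]
    ins <- vector("list", La + 1)
    for (col in which(ca == "-")) {
      key <- apos[col] + 1L
      ins[[key]] <- c(ins[[key]], cm[col])
    }
    for (k in seq_len(La + 1)) {
      ins_len[k] <- max(ins_len[k], length(ins[[k]]))
    }
    aligned[[id]] <- list(res_at = res_at, ins = ins)
  }

  pad <- function(x, len) c(x, rep("-", len - length(x)))
  build_row <- function(res_at, ins) {
    out <- character(0)
    for (k in 0:La) {
      if (ins_len[k + 1] > 0) {
        out <- c(out, pad(if (is.null(ins[[k + 1]])) character(0) else ins[[k + 1]],
                          ins_len[k + 1]))
      }
      if (k < La) out <- c(out, res_at[k + 1])
    }
    paste(out, collapse = "")
  }

  rows <- stats::setNames(vector("character", length(seqs)), names(seqs))
  rows[anchor_id] <- build_row(strsplit(anchor, "")[[1]],
                               vector("list", La + 1))
  for (id in others) {
    rows[id] <- build_row(aligned[[id]]$res_at, aligned[[id]]$ins)
  }
  rows[names(seqs)]
}

#' Mutation-site columns of a group alignment
#'
#' Columns holding at least two distinct non-gap residues. A gap facing a
#' residue is not a mutation (mutations here are point substitutions).
#'
#' @param msa character vector of equal-length gapped rows.
#' @return integer vector of 1-based column indices.
#' @export
detect_mutation_sites <- function(msa) {
  if (length(msa) < 2) return(integer(0))
  mat <- do.call(rbind, strsplit(msa, ""))
  which(apply(mat, 2, function(col) {
    length(unique(col[col != "-"])) >= 2
  }))
}

#' Apply the dataset selection rules to structural groups
#'
#' Mirrors the survey's three filters: (1) members must be X-ray structures
#' with resolution strictly below `resolution_cutoff` (members with missing
#' resolution are removed); (2) a group must retain strictly more than
#' `min_members` structures; (3) a family must retain at least
#' `min_family_proteins` groups (unique proteins).
#'
#' @param groups list of [structural_group()] objects.
#' @param resolution_cutoff Angstroms (default 3.5).
#' @param min_members groups kept only when member count `> min_members`
#'   (default 4).
#' @param min_family_proteins minimum surviving groups per family (default 3).
#' @return object of class `selection_report`: list with `kept` (filtered
#'   groups), `dropped` (data frame of id + rule), `removed_members`, and the
#'   rule parameters.
#' @export
apply_selection_rules <- function(groups, resolution_cutoff = 3.5,
                                  min_members = 4, min_family_proteins = 3) {
  dropped <- data.frame(group_id = character(0), rule = character(0))
  removed <- character(0)
  surv <- list()
  for (g in groups) {
    res <- vapply(g$members, function(m) m$resolution, 0)
    ok <- !is.na(res) & res < resolution_cutoff
    removed <- c(removed,
                 vapply(g$members[!ok], function(m) m$structure_id, ""))
    if (sum(ok) == length(g$members)) {
      kept_g <- g
    } else if (sum(ok) >= 1) {
      kept_g <- structural_group(g$group_id, g$members[ok], g$family_id)
    } else {
      dropped <- rbind(dropped, data.frame(group_id = g$group_id,
                                           rule = "resolution"))
      next
    }
    if (length(kept_g$members) > min_members) {
      surv[[length(surv) + 1]] <- kept_g
    } else {
      dropped <- rbind(dropped, data.frame(group_id = g$group_id,
                                           rule = "min_members"))
    }
  }
  fams <- vapply(surv, function(g) g$family_id, "")
  fams[is.na(fams)] <- "<none>"
  fam_counts <- table(fams)
  final <- list()
  for (g in surv) {
    fam <- if (is.na(g$family_id)) "<none>" else g$family_id
    if (fam_counts[[fam]] >= min_family_proteins) {
      final[[length(final) + 1]] <- g
    } else {
      dropped <- rbind(dropped, data.frame(group_id = g$group_id,
                                           rule = "min_family_proteins"))
    }
  }
  structure(
    list(kept = final, dropped = dropped, removed_members = removed,
         parameters = list(resolution_cutoff = resolution_cutoff,
                           min_members = min_members,
                           min_family_proteins = min_family_proteins)),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(
    "<selection_report> kept %d group(s), dropped %d, removed %d member structure(s)\n",
    length(x$kept), nrow(x$dropped), length(x$removed_members)))
  if (nrow(x$dropped) > 0) print(x$dropped)
  invisible(x)
}

#' Read a group/family metadata table
#'
#' Tab-separated table with columns `structure_id`, `group_id`, `family_id`
#' and optional flag columns.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_group_metadata <- function(path) {
  md <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("structure_id", "group_id", "family_id")
  if (!all(need %in% names(md))) {
    stop("metadata table must have columns: ", paste(need, collapse = ", "))
  }
  md
}
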