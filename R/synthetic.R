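#' Configuration for the synthetic ensemble generator
#'
#' Defines the study conditions emulated by [generate_dataset()]: families
#' of structural groups whose members share an identical sequence and an
#' ideal segment-wise backbone, with a hinge linker whose dihedrals breathe
#' between structures, several short helices that cooperatively melt to
#' coil in alternative conformers (the designed wobble regions), occasional
#' point mutations, a few substitutions plus a short terminal deletion
#' between the groups of a family, and resolution drawn as a linear
#' function of each structure's coil fraction plus noise.
#'
#' Each structure adopts either the base conformer or, with probability
#' `flip_prob`, an alternative conformer in which `melt_subset_size` of the
#' designated wobble helices are melted. Because every alternative conformer
#' leaves at least one wobble helix intact, no single structure pair
#' exhibits all wobble sites: some appear only in intermediate conformers,
#' which is what drives the wobble-total versus maximum wobble-single slope
#' above 1.
#'
#' @param families number of protein families.
#' @param groups_per_family structural groups (unique sequences) per family.
#' @param structures_per_group structures per group.
#' @param segment_layout data frame with columns `state` (`H`, `E` or `C`)
#'   and `length`; the default is a 110-residue layout with two long rigid
#'   helices and three short wobble helices separated by coil linkers.
#' @param hinge_segments indices (into the layout) of coil segments acting
#'   as hinges.
#' @param hinge_spread standard deviation (degrees) of the per-structure
#'   phi/psi perturbation at the hinge centre.
#' @param wobble_segments indices of the helices that melt in alternative
#'   conformers.
#' @param flexible_prob probability that a group is conformationally
#'   flexible (hinge motion plus melting conformers); the rest are rigid
#'   apart from coordinate jitter, mirroring the predominance of
#'   near-rigid groups in real ensembles.
#' @param flip_prob probability that a structure of a flexible group adopts
#'   an alternative (partially melted) conformer.
#' @param melt_subset_size number of wobble helices melted per alternative
#'   conformer (must be < number of wobble segments for intermediate
#'   conformations to exist).
#' @param jitter named per-state Gaussian coordinate noise sigma in
#'   Angstroms.
#' @param mutation_prob probability that a group carries a point mutation in
#'   a subset of its members.
#' @param substitutions_between_groups residue substitutions separating each
#'   group's sequence from the family base sequence.
#' @param terminal_deletion_max groups after the first delete 0 to this many
#'   N-terminal residues (length variation that produces gap sites in
#'   cross-group alignments).
#' @param resolution_model named vector `c(a, b, sigma)`:
#'   `resolution = a + b * coil_fraction + N(0, sigma)`, clipped to
#'   `[0.8, 3.49]` Angstroms.
#' @param seed integer seed fixing the full output stream.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(families = 2,
                             groups_per_family = 3,
                             structures_per_group = 10,
                             segment_layout = data.frame(
                               state = c("C", "H", "C", "H", "C", "H", "C",
                                         "H", "C", "H", "C"),
                               length = c(5, 26, 6, 24, 6, 10, 4, 10, 4, 10, 5)),
                             hinge_segments = 3,
                             hinge_spread = 5,
                             wobble_segments = c(6, 8, 10),
                             flexible_prob = 0.5,
                             flip_prob = 0.6,
                             melt_subset_size = 2,
                             jitter = c(H = 0.05, E = 0.05, C = 0.10),
                             mutation_prob = 0.45,
                             substitutions_between_groups = 3,
                             terminal_deletion_max = 3,
                             resolution_model = c(a = 1.2, b = 1.5, sigma = 0.15),
                             seed = 1) {
  stopifnot(families >= 1, groups_per_family >= 1, structures_per_group >= 1,
            all(segment_layout$length >= 1),
            all(segment_layout$state %in% c("H", "E", "C")),
            all(jitter >= 0), flip_prob >= 0, flip_prob <= 1,
            hinge_spread >= 0, terminal_deletion_max >= 0,
            melt_subset_size >= 1,
            melt_subset_size <= max(1, length(wobble_segments)))
  if (sum(segment_layout$length) < 10) {
    stop("segment layout must total at least 10 residues")
  }
  structure(as.list(environment()), class = "generator_config")
}

# amino acids used for synthetic sequences; proline is excluded because its
# missing amide proton makes it a non-donor in the hydrogen-bond model, and
# glycine because of its atypical backbone preferences
.synth_alphabet <- strsplit("ACDEFHIKLMNQRSTVWY", "")[[1]]

.ideal_dihedrals <- list(H = c(phi = -57, psi = -47),
                         E = c(phi = -120, psi = 120))

# sample coil dihedrals from a permissive extended/PPII-like region that
# does not recreate helical hydrogen bonding
.sample_coil <- function(n) {
  cbind(phi = stats::runif(n, -150, -70), psi = stats::runif(n, 100, 170))
}

# compact irregular-loop dihedrals for melted helices: a per-residue mixture
# of extended and bridge-region draws keeps the melted segment near its
# original position instead of extending into a rod
.sample_loop <- function(n) {
  ext <- stats::runif(n) < 0.5
  cbind(phi = ifelse(ext, stats::runif(n, -140, -100), stats::runif(n, -100, -70)),
        psi = ifelse(ext, stats::runif(n, 120, 160), stats::runif(n, -30, 30)))
}

# expand the layout into per-residue state labels and segment ids
.layout_expand <- function(layout) {
  data.frame(state = rep(layout$state, layout$length),
             segment = rep(seq_len(nrow(layout)), layout$length))
}

#' Resolution from coil content
#'
#' `resolution = a + b * coil_fraction + N(0, sigma)`, clipped to
#' `[0.8, 3.49]` Angstroms: structures richer in coil diffract worse.
#' Draws from the ambient RNG stream.
#'
#' @param coil_fraction fraction of coil residues in `[0, 1]`.
#' @param model named vector `c(a, b, sigma)`.
#' @return resolution in Angstroms.
#' @export
assign_resolution <- function(coil_fraction,
                              model = c(a = 1.2, b = 1.5, sigma = 0.15)) {
  stopifnot(coil_fraction >= 0, coil_fraction <= 1)
  r <- model[["a"]] + model[["b"]] * coil_fraction +
    stats::rnorm(1, 0, model[["sigma"]])
  min(max(r, 0.8), 3.49)
}

# build a chain_structure from per-residue dihedrals + jitter
.build_structure <- function(id, sequence, phi, psi, jitter_sd) {
  bb <- build_backbone(phi, psi)
  n <- length(phi)
  for (a in names(bb)) {
    bb[[a]] <- bb[[a]] + matrix(stats::rnorm(3 * n, 0, rep(jitter_sd, 3)),
                                n, 3)
  }
  chain_structure(id, sequence, atoms = bb)
}

#' Generate one synthetic family of structural groups
#'
#' Uses the ambient RNG stream (seed it, or call through
#' [generate_dataset()], for reproducibility). See [generator_config()] for
#' the generative model.
#'
#' @param config a [generator_config()].
#' @param family_id label, e.g. `"FAM1"`.
#' @return list with `groups` (list of [structural_group()]),
#'   `ground_truth` (per group: true wobble sites, rigid-core sites, hinge
#'   sites, mutation sites, substitution positions, per-structure coil
#'   fraction / resolution / flip status).
#' @export
generate_family <- function(config, family_id = "FAM1") {
  lay_full <- .layout_expand(config$segment_layout)
  base_seq_full <- sample(.synth_alphabet, nrow(lay_full), replace = TRUE)

  wob_segs <- config$wobble_segments
  n_wob <- length(wob_segs)
  melt_k <- min(config$melt_subset_size, n_wob)
  combos <- if (n_wob > 0) utils::combn(n_wob, melt_k, simplify = FALSE) else list()

  groups <- list()
  gt <- list()
  for (g in seq_len(config$groups_per_family)) {
    group_id <- sprintf("%s-G%d", family_id, g)
    flexible <- stats::runif(1) < config$flexible_prob

    # length variation between groups: short N-terminal deletion
    del_n <- if (g > 1 && config$terminal_deletion_max > 0) {
      sample(0:config$terminal_deletion_max, 1)
    } else 0L
    keep_idx <- (del_n + 1):nrow(lay_full)
    lay <- lay_full[keep_idx, , drop = FALSE]
    L <- nrow(lay)
    seq_g <- base_seq_full[keep_idx]
    sub_pos <- integer(0)
    if (config$substitutions_between_groups > 0 && g > 1) {
      sub_pos <- sort(sample(L, config$substitutions_between_groups))
      for (p in sub_pos) {
        seq_g[p] <- sample(setdiff(.synth_alphabet, seq_g[p]), 1)
      }
    }
    seq_str <- paste(seq_g, collapse = "")
    hinge_res <- which(lay$segment %in% config$hinge_segments)
    flip_res <- which(lay$segment %in% wob_segs)

    # base conformer dihedrals: ideal H/E plus group-level coil sampling
    phi <- psi <- numeric(L)
    for (i in seq_len(L)) {
      st <- lay$state[i]
      if (st == "C") next
      phi[i] <- .ideal_dihedrals[[st]][["phi"]]
      psi[i] <- .ideal_dihedrals[[st]][["psi"]]
    }
    coil_idx <- which(lay$state == "C")
    cd <- .sample_coil(length(coil_idx))
    phi[coil_idx] <- cd[, "phi"]; psi[coil_idx] <- cd[, "psi"]

    # one melted (coil) conformation per wobble helix, shared by all
    # alternative conformers that include it
    melt_dihedrals <- lapply(seq_len(n_wob), function(w) {
      res <- which(lay$segment == wob_segs[w])
      .sample_loop(length(res))
    })
    conformer_dihedrals <- function(melted) {
      p <- phi; q <- psi
      for (w in melted) {
        res <- which(lay$segment == wob_segs[w])
        p[res] <- melt_dihedrals[[w]][, "phi"]
        q[res] <- melt_dihedrals[[w]][, "psi"]
      }
      list(phi = p, psi = q)
    }

    # noise-free template states for the base and each alternative conformer
    conf_sets <- if (flexible) c(list(integer(0)), combos) else list(integer(0))
    templates <- lapply(conf_sets, function(melted) {
      d <- conformer_dihedrals(melted)
      cs <- chain_structure(paste0(group_id, ":T"), seq_str,
                            build_backbone(d$phi, d$psi))
      list(melted = melted, phi = d$phi, psi = d$psi,
           states3 = assign_secondary_structure(cs)$states3)
    })
    state_mat <- do.call(rbind, lapply(templates, function(t)
      strsplit(t$states3, "")[[1]]))
    wob_true <- which(apply(state_mat, 2, function(col)
      length(unique(col)) >= 2))

    # rigid core: interiors of H/E segments that never melt in this group,
    # >= 2 residues from the segment ends, excluding any true wobble position
    rigid <- integer(0)
    for (sgi in unique(lay$segment)) {
      seg_state <- lay$state[lay$segment == sgi][1]
      if (seg_state == "C") next
      if (flexible && sgi %in% wob_segs) next
      res <- which(lay$segment == sgi)
      if (length(res) > 4) rigid <- c(rigid, res[3:(length(res) - 2)])
    }
    rigid <- setdiff(rigid, wob_true)

    # optional point mutation in a subset of members
    mut_site <- integer(0)
    mut_members <- integer(0)
    if (stats::runif(1) < config$mutation_prob) {
      mut_site <- sample(setdiff(seq_len(L), sub_pos), 1)
      mut_members <- sort(sample(config$structures_per_group,
                                 max(1, config$structures_per_group %/% 3)))
    }

    members <- list()
    info <- list()
    for (s in seq_len(config$structures_per_group)) {
      conf <- if (flexible && length(combos) > 0 &&
                  stats::runif(1) < config$flip_prob) {
        1L + sample.int(length(combos), 1)
      } else 1L
      tmpl <- templates[[conf]]
      p_phi <- tmpl$phi; p_psi <- tmpl$psi
      if (flexible && length(hinge_res) > 0 && config$hinge_spread > 0) {
        centre <- hinge_res[ceiling(length(hinge_res) / 2)]
        p_phi[centre] <- p_phi[centre] + stats::rnorm(1, 0, config$hinge_spread)
        p_psi[centre] <- p_psi[centre] + stats::rnorm(1, 0, config$hinge_spread)
      }
      seq_s <- seq_g
      if (length(mut_site) == 1 && s %in% mut_members) {
        seq_s[mut_site] <- sample(setdiff(.synth_alphabet, seq_g[mut_site]), 1)
      }
      coil_frac <- mean(strsplit(tmpl$states3, "")[[1]] == "C")
      resol <- assign_resolution(coil_frac, config$resolution_model)
      jit <- unname(config$jitter[lay$state])
      id <- sprintf("%s-S%02d:A", group_id, s)
      cs <- .build_structure(id, paste(seq_s, collapse = ""),
                             p_phi, p_psi, jit)
      cs$resolution <- resol
      members[[s]] <- cs
      info[[s]] <- data.frame(structure_id = id, conformer = conf,
                              coil_fraction = coil_frac, resolution = resol)
    }
    groups[[g]] <- structural_group(group_id, members, family_id)
    gt[[group_id]] <- list(
      flexible = flexible,
      wobble_sites = wob_true, rigid_core_sites = rigid,
      hinge_sites = hinge_res, flip_sites = flip_res,
      mutation_site = mut_site, mutated_members = mut_members,
      substitution_positions = sub_pos, terminal_deletion = del_n,
      template_states = vapply(templates, function(t) t$states3, ""),
      structures = do.call(rbind, info))
  }
  list(family_id = family_id, groups = groups, ground_truth = gt)
}

#' Generate a full synthetic dataset
#'
#' Seeds the RNG from `config$seed` (restoring the caller's RNG state on
#' exit), generates `config$families` families and assembles the group
#' metadata table. Identical configuration and seed give byte-identical
#' output.
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_dataset`: `families` (list from
#'   [generate_family()]), `groups` (flat list), `metadata` (data frame:
#'   `structure_id`, `group_id`, `family_id`), `ground_truth` (named by
#'   group id), `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  fams <- lapply(seq_len(config$families), function(f) {
    generate_family(config, sprintf("FAM%d", f))
  })
  groups <- unlist(lapply(fams, function(f) f$groups), recursive = FALSE)
  gt <- do.call(c, lapply(fams, function(f) f$ground_truth))
  md <- do.call(rbind, lapply(groups, function(g) {
    data.frame(structure_id = vapply(g$members, function(m) m$structure_id, ""),
               group_id = g$group_id, family_id = g$family_id)
  }))
  structure(list(families = fams, groups = groups, metadata = md,
                 ground_truth = gt, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d families, %d groups, %d structures (%d residues each), seed %d\n",
    length(x$families), length(x$groups), nrow(x$metadata),
    sum(x$config$segment_layout$length), x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' One PDB file per structure plus the grouping metadata table
#' (`metadata.tsv`) and a per-group ground-truth table
#' (`ground_truth.tsv`).
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in ds$groups) {
    for (m in g$members) {
      entry <- sub(":.*$", "", m$structure_id)
      write_pdb_chain(m, file.path(dir, paste0(entry, ".pdb")))
    }
  }
  utils::write.table(ds$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt_rows <- do.call(rbind, lapply(names(ds$ground_truth), function(gid) {
    gt <- ds$ground_truth[[gid]]
    data.frame(group_id = gid,
               wobble_sites = paste(gt$wobble_sites, collapse = ","),
               rigid_core_sites = paste(gt$rigid_core_sites, collapse = ","),
               hinge_sites = paste(gt$hinge_sites, collapse = ","),
               mutation_site = paste(gt$mutation_site, collapse = ","),
               substitutions = paste(gt$substitution_positions, collapse = ","))
  }))
  utils::write.table(gt_rows, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
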