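#' Read a directory of PDB files with a grouping metadata table
#'
#' Loads every structure listed in the metadata table (ids `"ENTRY:CHAIN"`,
#' files `<ENTRY>.pdb` in `dir`) and assembles [structural_group()] objects
#' by `group_id`.
#'
#' @param dir directory of PDB files.
#' @param metadata path to the tab-separated metadata table
#'   ([read_group_metadata()]) or an equivalent data frame.
#' @return list of [structural_group()] objects.
#' @export
read_structure_dir <- function(dir, metadata) {
  md <- if (is.character(metadata)) read_group_metadata(metadata) else metadata
  chains <- lapply(seq_len(nrow(md)), function(i) {
    id <- md$structure_id[i]
    entry <- sub(":.*$", "", id)
    chain <- sub("^.*:", "", id)
    read_pdb_chain(file.path(dir, paste0(entry, ".pdb")), chain = chain)
  })
  names(chains) <- md$structure_id
  lapply(split(seq_len(nrow(md)), md$group_id), function(idx) {
    structural_group(md$group_id[idx[1]], chains[idx],
                     family_id = md$family_id[idx[1]])
  })
}

#' Run the full flexibility / wobble / alignment-variation pipeline
#'
#' Stages, in order: load or take structures, group selection rules,
#' all-pairs within-group superpositions (flexibility), secondary-structure
#' assignment (built-in assigner, or DSSP files when `dssp_dir` is given),
#' the wobble suite (per-group wobble tables, pairwise wobble singles, the
#' total-versus-single regression, pooled mutation-site enrichment, the
#' resolution-coil curve), all-pairs cross-group superpositions within each
#' family, alignment-site classification with the secondary-structure state
#' distribution by class, and the evolutionary-distance exception analysis
#' under both the RMSD and the TM-score criterion. All-pairs comparisons are
#' exhaustive: `C(m, 2)` within a group of m structures, `m_A * m_B` across
#' a group pair.
#'
#' @param input a [generate_dataset()] result, a list of
#'   [structural_group()] objects, or a directory of PDB files (then
#'   `metadata` is required).
#' @param metadata metadata table path/data frame when `input` is a
#'   directory.
#' @param dssp_dir optional directory of classic DSSP files named
#'   `<ENTRY>.dssp`.
#' @param output_dir optional directory; when given, every stage's table is
#'   written there as TSV plus a `manifest.txt`.
#' @param resolution_cutoff,min_members,min_family_proteins selection rules
#'   ([apply_selection_rules()]).
#' @param norm TM-score normalisation policy ([structural_align()]).
#' @param ligand_filter optional filter on members before the wobble suite:
#'   one of `"free"` (no ligand/ion, not in a complex), `"complex"`,
#'   `"ligand"`, `"no_ligand"`; default `"all"`.
#' @param curve_min_states bin-population filter of the resolution-coil
#'   correlation ([resolution_coil_curve()]).
#' @param do_wobble,do_resolution,do_alnvar,do_evodist stage toggles.
#' @return object of class `flex_pipeline` (a list of stage results; see
#'   `print` method).
#' @export
run_pipeline <- function(input, metadata = NULL, dssp_dir = NULL,
                         output_dir = NULL,
                         resolution_cutoff = 3.5, min_members = 4,
                         min_family_proteins = 3,
                         norm = "shorter",
                         ligand_filter = c("all", "free", "complex",
                                           "ligand", "no_ligand"),
                         curve_min_states = 0,
                         do_wobble = TRUE, do_resolution = TRUE,
                         do_alnvar = TRUE, do_evodist = TRUE) {
  ligand_filter <- match.arg(ligand_filter)

  groups <- if (inherits(input, "synthetic_dataset")) {
    input$groups
  } else if (is.character(input)) {
    if (is.null(metadata)) stop("metadata table required for a PDB directory")
    read_structure_dir(input, metadata)
  } else {
    input
  }

  sel <- apply_selection_rules(groups, resolution_cutoff, min_members,
                               min_family_proteins)
  groups <- sel$kept
  if (length(groups) == 0) stop("stage selection: no groups survive the rules")

  # within-group flexibility: exhaustive member-pair superpositions
  within <- lapply(groups, function(g) {
    m <- g$members
    rows <- list()
    for (a in seq_along(m)) {
      for (b in seq_along(m)) {
        if (b <= a) next
        sp <- structural_align(m[[a]], m[[b]], norm = norm)
        rows[[length(rows) + 1]] <- data.frame(
          group_id = g$group_id, id_a = sp$id_a, id_b = sp$id_b,
          rmsd = sp$rmsd, tm_score = sp$tm_score, n_aligned = sp$n_aligned)
      }
    }
    do.call(rbind, rows)
  })
  within <- do.call(rbind, within)

  group_summary <- do.call(rbind, lapply(groups, function(g) {
    w <- within[within$group_id == g$group_id, ]
    data.frame(group_id = g$group_id, family_id = g$family_id,
               n_structures = length(g$members),
               n_comparisons = nrow(w),
               max_rmsd = max(w$rmsd), min_tm = min(w$tm_score),
               n_mutation_sites = length(g$mutation_sites))
  }))

  # secondary structure per member
  sec <- lapply(groups, function(g) {
    lapply(stats::setNames(g$members,
                           vapply(g$members, function(m) m$structure_id, "")),
           function(m) {
             dssp <- NULL
             if (!is.null(dssp_dir)) {
               f <- file.path(dssp_dir,
                              paste0(sub(":.*$", "", m$structure_id), ".dssp"))
               if (file.exists(f)) dssp <- f
             }
             secondary_structure(m, dssp_path = dssp)
           })
  })
  names(sec) <- vapply(groups, function(g) g$group_id, "")

  member_passes_filter <- function(m) {
    fl <- m$ligand_flags
    switch(ligand_filter,
           all = TRUE,
           free = !fl$has_ligand && !fl$has_ion && !fl$in_protein_complex,
           complex = fl$in_protein_complex,
           ligand = fl$has_ligand,
           no_ligand = !fl$has_ligand)
  }

  out <- list(selection = sel, groups = groups, within = within,
              group_summary = group_summary, secondary = sec,
              ligand_filter = ligand_filter)

  if (do_wobble) {
    wts <- list()
    pair_rows <- list()
    for (g in groups) {
      keep <- vapply(g$members, member_passes_filter, TRUE)
      gg <- if (all(keep)) g else {
        if (sum(keep) < 2) next
        structural_group(g$group_id, g$members[keep], g$family_id)
      }
      st3 <- lapply(sec[[g$group_id]][vapply(gg$members, function(m)
        m$structure_id, "")], function(s) s$states3)
      wt <- find_wobble_sites(gg, st3)
      wts[[gg$group_id]] <- wt
      ps <- wobble_pair_summaries(gg, wt)
      if (!is.null(ps)) {
        ps$group_id <- gg$group_id
        pair_rows[[length(pair_rows) + 1]] <- ps
      }
    }
    out$wobble_tables <- wts
    out$wobble_pairs <- do.call(rbind, pair_rows)
    out$group_summary$rw <-
      vapply(out$group_summary$group_id,
             function(id) if (!is.null(wts[[id]])) wts[[id]]$rw else NA_real_, 0)
    out$group_summary$max_wobble_single <-
      vapply(out$group_summary$group_id, function(id) {
        p <- out$wobble_pairs
        if (is.null(p)) return(NA_real_)
        p <- p[p$group_id == id, ]
        if (nrow(p) == 0) NA_real_ else max(p$wobble_single)
      }, 0)
    ok <- !is.na(out$group_summary$rw) & !is.na(out$group_summary$max_wobble_single)
    if (sum(ok) >= 3 && any(out$group_summary$max_wobble_single[ok] > 0)) {
      out$wobble_regression <- wobble_total_vs_single(
        out$group_summary$rw[ok], out$group_summary$max_wobble_single[ok])
    }
    # pooled mutation-site enrichment over all groups
    mut_w <- 0L; mut_n <- 0L; all_w <- 0L; all_n <- 0L
    for (g in groups) {
      wt <- wts[[g$group_id]]
      if (is.null(wt)) next
      all_w <- all_w + wt$nw; all_n <- all_n + wt$na
      ms <- g$mutation_sites
      if (length(ms) > 0) {
        mut_w <- mut_w + sum(wt$wobble_flags[ms])
        mut_n <- mut_n + length(ms)
      }
    }
    out$mutation_stats <- if (mut_n > 0) {
      pooled <- list(wobble_flags = c(rep(TRUE, mut_w), rep(FALSE, mut_n - mut_w)),
                     nw = all_w, na = all_n)
      mutation_wobble_stats(pooled, seq_len(mut_n))
    } else {
      mutation_wobble_stats(list(nw = all_w, na = all_n), integer(0))
    }
    if (do_resolution && length(wts) > 0) {
      gs <- groups[vapply(groups, function(g) g$group_id %in% names(wts), TRUE)]
      out$resolution_curve <- tryCatch(
        resolution_coil_curve(gs, wts[vapply(gs, function(g) g$group_id, "")],
                              min_states = curve_min_states),
        error = function(e) NULL)
    }
  }

  if (do_alnvar || do_evodist) {
    fams <- split(groups, vapply(groups, function(g) g$family_id, ""))
    gps <- list()
    for (fam in fams) {
      if (length(fam) < 2) next
      for (a in seq_along(fam)) {
        for (b in seq_along(fam)) {
          if (b <= a) next
          gps[[length(gps) + 1]] <- group_pair(fam[[a]], fam[[b]], norm = norm)
        }
      }
    }
    out$group_pairs <- gps
    if (do_alnvar && length(gps) > 0) {
      cls <- lapply(gps, classify_sites)
      out$site_classes <- cls
      fam_of <- stats::setNames(vapply(groups, function(g) g$family_id, ""),
                                vapply(groups, function(g) g$group_id, ""))
      out$alnvar <- do.call(rbind, lapply(seq_along(gps), function(i) {
        fam <- fam_of[[gps[[i]]$group_a]]
        data.frame(group_a = gps[[i]]$group_a, group_b = gps[[i]]$group_b,
                   family_id = fam,
                   rmsd_max = gps[[i]]$rmsd_max, rmsd_min = gps[[i]]$rmsd_min,
                   tm_max = gps[[i]]$tm_max, tm_min = gps[[i]]$tm_min,
                   rc = cls[[i]]$rc, rm = cls[[i]]$rm, rg = cls[[i]]$rg)
      }))
      if (!is.null(out$wobble_tables)) {
        wts <- out$wobble_tables
        dists <- list()
        for (i in seq_along(gps)) {
          wa <- wts[[gps[[i]]$group_a]]; wb <- wts[[gps[[i]]$group_b]]
          if (is.null(wa) || is.null(wb)) next
          dists[[length(dists) + 1]] <-
            list(family = out$alnvar$family_id[i],
                 dist = ss_distribution_by_class(cls[[i]], wa, wb))
        }
        if (length(dists) > 0) {
          fams_d <- unique(vapply(dists, function(d) d$family, ""))
          fam_avg <- lapply(stats::setNames(fams_d, fams_d), function(f) {
            mats <- lapply(Filter(function(d) d$family == f, dists),
                           function(d) d$dist$fractions)
            Reduce(`+`, mats) / length(mats)
          })
          out$ss_by_class_family <- fam_avg
          out$ss_by_class <- Reduce(`+`, fam_avg) / length(fam_avg)
        }
      }
    }
    if (do_evodist && length(gps) > 0) {
      out$evodist_rmsd <- exception_analysis(gps, "rmsd")
      out$evodist_tm <- exception_analysis(gps, "tm")
    }
  }

  class(out) <- "flex_pipeline"
  if (!is.null(output_dir)) write_pipeline_tables(out, output_dir)
  out
}

#' @export
print.flex_pipeline <- function(x, ...) {
  cat("<flex_pipeline>\n")
  cat(sprintf(" groups kept: %d (dropped %d)\n", length(x$groups),
              nrow(x$selection$dropped)))
  cat(sprintf(" within-group comparisons: %d, mean max RMSD %.3f A\n",
              nrow(x$within), mean(x$group_summary$max_rmsd)))
  if (!is.null(x$wobble_tables)) {
    rws <- vapply(x$wobble_tables, function(w) w$rw, 0)
    cat(sprintf(" wobble: %d group table(s), Rw max %.2f%%\n",
                length(rws), max(rws)))
  }
  if (!is.null(x$wobble_regression)) print(x$wobble_regression)
  if (!is.null(x$alnvar)) {
    cat(sprintf(" alnvar: %d group pair(s), mean Rc %.2f%% Rm %.2f%% Rg %.2f%%\n",
                nrow(x$alnvar), mean(x$alnvar$rc), mean(x$alnvar$rm),
                mean(x$alnvar$rg)))
  }
  if (!is.null(x$evodist_rmsd)) print(x$evodist_rmsd)
  if (!is.null(x$evodist_tm)) print(x$evodist_tm)
  invisible(x)
}

#' Write the pipeline's stage tables
#'
#' Tab-separated tables per stage plus a `manifest.txt` recording the
#' package version and stage row counts (no timestamps, so reruns are
#' byte-identical).
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df)) return()
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(report$group_summary, "groups.tsv")
  wt(report$within, "within_group_comparisons.tsv")
  if (!is.null(report$wobble_tables)) {
    sites <- do.call(rbind, lapply(report$wobble_tables, function(w) {
      data.frame(group_id = w$group_id, column = seq_along(w$wobble_flags),
                 wobble = w$wobble_flags,
                 states = apply(w$site_states, 2, function(col)
                   paste(sort(unique(col[!is.na(col)])), collapse = "")))
    }))
    wt(sites, "wobble_sites.tsv")
  }
  wt(report$wobble_pairs, "wobble_pairs.tsv")
  if (!is.null(report$resolution_curve)) {
    wt(report$resolution_curve$bins, "resolution_curve.tsv")
  }
  wt(report$alnvar, "alignment_variation.tsv")
  if (!is.null(report$evodist_rmsd)) {
    wt(report$evodist_rmsd$records, "evodist_rmsd.tsv")
  }
  if (!is.null(report$evodist_tm)) wt(report$evodist_tm$records, "evodist_tm.tsv")
  manifest <- c(
    sprintf("flexwobble version: %s", as.character(utils::packageVersion("flexwobble"))),
    sprintf("groups: %d", length(report$groups)),
    sprintf("within_comparisons: %d", nrow(report$within)),
    sprintf("group_pairs: %d", length(report$group_pairs)),
    sprintf("ligand_filter: %s", report$ligand_filter))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
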