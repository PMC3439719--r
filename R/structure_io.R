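#' Chain structure container
#'
#' Holds one protein chain: ordered residues with backbone atom coordinates,
#' the one-letter sequence, the crystallographic resolution and
#' ligand/complex flags. This is the unit every downstream stage consumes.
#'
#' @param structure_id identifier, conventionally `"ENTRY:CHAIN"`.
#' @param sequence one-letter amino-acid string (20-letter alphabet or `X`).
#' @param atoms list of `n x 3` matrices named `N`, `CA`, `C`, `O`
#'   (rows may be `NA` for missing N/C/O atoms; CA must be present and finite).
#' @param pdb_number character vector of author residue numbers (+ insertion
#'   code), kept as metadata only; defaults to `1:n`.
#' @param resolution X-ray resolution in Angstroms, or `NA` when absent.
#' @param ligand_flags named logical list/vector with `has_ligand`, `has_ion`,
#'   `in_protein_complex`.
#' @return object of class `chain_structure`.
#' @export
chain_structure <- function(structure_id, sequence, atoms,
                            pdb_number = NULL, resolution = NA_real_,
                            ligand_flags = c(has_ligand = FALSE,
                                             has_ion = FALSE,
                                             in_protein_complex = FALSE)) {
  seq_chars <- strsplit(sequence, "")[[1]]
  n <- length(seq_chars)
  if (n == 0) stop("empty chain")
  if (!all(seq_chars %in% c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"))) {
    stop("sequence contains letters outside the amino-acid alphabet / 'X'")
  }
  for (nm in c("N", "CA", "C", "O")) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- matrix(NA_real_, n, 3)
    atoms[[nm]] <- as.matrix(atoms[[nm]])
    if (nrow(atoms[[nm]]) != n) {
      stop(sprintf("atom matrix '%s' has %d rows but sequence has %d residues",
                   nm, nrow(atoms[[nm]]), n))
    }
  }
  if (any(!is.finite(atoms$CA))) stop("every residue needs a finite CA coordinate")
  if (is.null(pdb_number)) pdb_number <- as.character(seq_len(n))
  if (!is.na(resolution) && resolution <= 0) stop("resolution must be positive")
  structure(
    list(structure_id = structure_id,
         sequence = sequence,
         seq_index = seq_len(n),
         pdb_number = as.character(pdb_number),
         atoms = atoms[c("N", "CA", "C", "O")],
         resolution = as.numeric(resolution),
         ligand_flags = as.list(ligand_flags)),
    class = "chain_structure"
  )
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> %s: %d residues, resolution %s A\n",
              x$structure_id, nchar(x$sequence),
              if (is.na(x$resolution)) "NA" else sprintf("%.2f", x$resolution)))
  cat(" sequence:", substr(x$sequence, 1, 60),
      if (nchar(x$sequence) > 60) "..." else "", "\n")
  invisible(x)
}

#' @export
length.chain_structure <- function(x) nchar(x$sequence)

# CA coordinate matrix of a chain
ca_coords <- function(cs) cs$atoms$CA

.ion_resids <- c("NA", "K", "MG", "CA", "ZN", "MN", "FE", "CU", "NI", "CO",
                 "CL", "BR", "IOD", "CD", "HG", "SR", "CS", "LI", "RB", "BA",
                 "SO4", "PO4")

#' Read one chain from a PDB file
#'
#' Parses ATOM records of a single chain into a [chain_structure()]. The
#' resolution is taken from the first `REMARK   2 RESOLUTION` header value.
#' Only the first model of multi-model files is read; alternate locations
#' other than blank or 'A' are dropped; residues without a CA atom are
#' skipped with a warning; nonstandard residues map to `X`.
#'
#' @param path PDB file.
#' @param chain chain identifier (default first chain in the file).
#' @param model model number to read (only 1 is supported).
#' @return a [chain_structure()].
#' @export
read_pdb_chain <- function(path, chain = NULL, model = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (model != 1) stop("only the first model of a PDB file is read")
  utils::capture.output(
    pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  prot <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- prot$chain[1]
  sel <- prot[prot$chain %in% chain, , drop = FALSE]
  if (nrow(sel) == 0) stop(sprintf("chain not found: '%s' in %s", chain, path))
  sel <- sel[is.na(sel$alt) | sel$alt %in% c("", "A"), , drop = FALSE]

  ins <- ifelse(is.na(sel$insert), "", sel$insert)
  res_key <- paste0(sel$resno, ins)
  keys <- unique(res_key)

  n <- length(keys)
  atoms <- lapply(c(N = "N", CA = "CA", C = "C", O = "O"),
                  function(a) matrix(NA_real_, n, 3))
  aa <- character(n)
  keep <- logical(n)
  for (i in seq_along(keys)) {
    rows <- sel[res_key == keys[i], , drop = FALSE]
    aa[i] <- suppressWarnings(bio3d::aa321(rows$resid[1]))
    if (is.na(aa[i]) || !nzchar(aa[i])) aa[i] <- "X"
    for (a in c("N", "CA", "C", "O")) {
      hit <- which(rows$elety == a)
      if (length(hit) > 0) {
        atoms[[a]][i, ] <- as.numeric(rows[hit[1], c("x", "y", "z")])
      }
    }
    keep[i] <- all(is.finite(atoms$CA[i, ]))
  }
  if (any(!keep)) {
    warning(sprintf("%s: dropped %d residue(s) without CA coordinates",
                    path, sum(!keep)))
    for (a in c("N", "CA", "C", "O")) atoms[[a]] <- atoms[[a]][keep, , drop = FALSE]
    aa <- aa[keep]
    keys <- keys[keep]
  }
  if (length(aa) == 0) stop("no residues with CA atoms for chain ", chain)

  het <- at[at$type == "HETATM" & !(at$resid %in% c("HOH", "DOD", "WAT")), ,
            drop = FALSE]
  other_chains <- setdiff(unique(prot$chain[prot$elety == "CA"]), chain)
  flags <- c(has_ligand = any(!(het$resid %in% .ion_resids)),
             has_ion = any(het$resid %in% .ion_resids),
             in_protein_complex = length(other_chains) > 0)

  entry <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  chain_structure(structure_id = paste0(entry, ":", chain),
                  sequence = paste(aa, collapse = ""),
                  atoms = atoms, pdb_number = keys,
                  resolution = parse_pdb_resolution(path),
                  ligand_flags = flags)
}

#' Parse the REMARK 2 resolution from a PDB header
#'
#' @param path PDB file.
#' @return resolution in Angstroms, or `NA` if not stated. When an entry
#'   carries two resolution values the first is returned.
#' @export
parse_pdb_resolution <- function(path) {
  lines <- readLines(path, n = 2000L, warn = FALSE)
  rem <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem) == 0) return(NA_real_)
  m <- regmatches(rem, regexpr("[0-9]+\\.[0-9]+", rem))
  vals <- suppressWarnings(as.numeric(unlist(m)))
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) NA_real_ else vals[1]
}

#' Write a chain to a PDB file
#'
#' Emits a minimal single-chain PDB file (REMARK 2 resolution header when
#' known, then ATOM records N/CA/C/O per residue). Round-trips through
#' [read_pdb_chain()] reproduce the sequence exactly and coordinates to the
#' format's 3-decimal precision.
#'
#' @param cs a [chain_structure()]; all residues must have N, CA and C.
#' @param path output file.
#' @param chain chain identifier to write (default from `structure_id`).
#' @export
write_pdb_chain <- function(cs, path, chain = NULL) {
  stopifnot(inherits(cs, "chain_structure"))
  n <- length(cs)
  if (n == 0) stop("empty chain")
  for (a in c("N", "CA", "C")) {
    if (any(!is.finite(cs$atoms[[a]]))) {
      stop("all residues need N, CA and C coordinates to write a PDB file")
    }
  }
  if (is.null(chain)) {
    chain <- sub("^.*:", "", cs$structure_id)
    if (!nzchar(chain) || nchar(chain) > 1) chain <- "A"
  }
  xyz_all <- do.call(rbind, cs$atoms)
  if (any(abs(xyz_all) > 9999.999, na.rm = TRUE)) {
    stop("coordinates exceed the PDB fixed-width field range")
  }
  aa3 <- bio3d::aa123(strsplit(cs$sequence, "")[[1]])
  aa3[is.na(aa3) | aa3 == "---"] <- "UNK"
  lines <- character(0)
  if (!is.na(cs$resolution)) {
    lines <- sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", cs$resolution)
  }
  serial <- 0L
  for (i in seq_len(n)) {
    for (a in c("N", "CA", "C", "O")) {
      xyz <- cs$atoms[[a]][i, ]
      if (any(!is.finite(xyz))) next
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0(" ", a), " ", aa3[i], chain, i,
        xyz[1], xyz[2], xyz[3], 1.00, 0.00, substr(a, 1, 1)))
    }
  }
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write chain sequences to a FASTA file
#'
#' @param chains list of [chain_structure()] objects.
#' @param path output FASTA file.
#' @export
write_chain_fasta <- function(chains, path) {
  seqs <- Biostrings::AAStringSet(vapply(chains, function(x) x$sequence, ""))
  names(seqs) <- vapply(chains, function(x) x$structure_id, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Secondary-structure string container
#'
#' Pairs an 8-state DSSP-style string with its fixed 3-state reduction
#' (`E -> E`; `H`, `G`, `I -> H`; everything else `-> C`).
#'
#' @param states8 string over `H G I E B T S -`.
#' @param source provenance label, e.g. `"dssp-file"` or `"built-in"`.
#' @return object of class `sec_structure` with `states8`, `states3`, `source`.
#' @export
sec_structure <- function(states8, source = "built-in") {
  structure(list(states8 = states8,
                 states3 = reduce_to_three_states(states8),
                 source = source),
            class = "sec_structure")
}

#' @export
print.sec_structure <- function(x, ...) {
  cat(sprintf("<sec_structure> %d residues (%s)\n 8-state: %s\n 3-state: %s\n",
              nchar(x$states8), x$source,
              substr(x$states8, 1, 60), substr(x$states3, 1, 60)))
  invisible(x)
}

#' Read one chain's secondary structure from a classic DSSP file
#'
#' Parses the fixed-column residue table of classic (mkdssp v2/v3 text)
#' output. Chain-break rows (`!` in the AA column) are skipped; a blank
#' structure column maps to `-`.
#'
#' @param path DSSP output file.
#' @param chain chain identifier.
#' @param expect_length optional residue count to validate against (e.g. the
#'   parsed coordinate chain); a mismatch is an error naming both counts.
#' @return a [sec_structure()] with `source = "dssp-file"`.
#' @export
read_dssp_chain <- function(path, chain, expect_length = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) stop("not a classic DSSP file (missing residue table): ", path)
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  ch <- substr(body, 12, 12)
  aa <- substr(body, 14, 14)
  ss <- substr(body, 17, 17)
  keep <- ch == chain & aa != "!"
  if (!any(keep)) stop(sprintf("chain '%s' not found in DSSP file %s", chain, path))
  s8 <- ss[keep]
  s8[s8 == " "] <- "-"
  s8 <- paste(s8, collapse = "")
  if (!is.null(expect_length) && nchar(s8) != expect_length) {
    stop(sprintf(
      "DSSP chain '%s' has %d residues but the coordinate chain has %d",
      chain, nchar(s8), expect_length))
  }
  sec_structure(s8, source = "dssp-file")
}
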