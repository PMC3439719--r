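# BLOSUM62 (half-bit integer) matrix, cached; ambiguous 'X' scores 0
# against everything, and '*'/'B'/'Z'/'U' columns are dropped.
.fw_env <- new.env(parent = emptyenv())

blosum62_matrix <- function() {
  if (is.null(.fw_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    keep <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
    m <- m[keep, keep]
    m["X", ] <- 0L
    m[, "X"] <- 0L
    .fw_env$blosum62 <- m
  }
  .fw_env$blosum62
}

#' Evolutionary distance of an aligned sequence pair
#'
#' BLOSUM62-normalised dissimilarity of two equal-length gapped strings:
#' `ED = (1 - 2 * sum M(x_i, y_i) / (sum M(x_i, x_i) + sum M(y_i, y_i))) * 100`,
#' with the sums running only over the n columns where both rows carry a
#' residue (gap columns contribute to none of the three sums). Zero for a
#' gap-free self-comparison; symmetric in its arguments.
#'
#' @param sx,sy aligned strings of equal length over amino acids and `-`.
#' @return list of class `ed_result`: `ed`, `numerator` (sum M(x,y)),
#'   `denominator` (sum of the two self-score sums), `n` aligned columns.
#' @export
#' @examples
#' evolutionary_distance("AA", "AR")$ed   # 64.71
evolutionary_distance <- function(sx, sy) {
  if (nchar(sx) != nchar(sy)) stop("aligned strings must have equal length")
  cx <- strsplit(sx, "")[[1]]; cy <- strsplit(sy, "")[[1]]
  both <- cx != "-" & cy != "-"
  n <- sum(both)
  if (n == 0) stop("no aligned residues")
  M <- blosum62_matrix()
  x <- cx[both]; y <- cy[both]
  num <- sum(M[cbind(x, y)])
  den <- sum(M[cbind(x, x)]) + sum(M[cbind(y, y)])
  structure(list(ed = (1 - 2 * num / den) * 100,
                 numerator = num, denominator = den, n = n),
            class = "ed_result")
}

#' @export
print.ed_result <- function(x, ...) {
  cat(sprintf("<ed_result> ED = %.2f over %d aligned sites (2*%d / %d)\n",
              x$ed, x$n, x$numerator, x$denominator))
  invisible(x)
}

#' Best and worst comparison of a group pair under a criterion
#'
#' For `criterion = "rmsd"` the best comparison is the minimum RMSD and the
#' worst the maximum; for `"tm"` the best is the maximum TM-score and the
#' worst the minimum. Ties are broken by the lexicographic structure-id
#' pair, so the selection is deterministic.
#'
#' @param gp a [group_pair()] (or plain list of `superposition` objects in
#'   `$comparisons`).
#' @param criterion `"rmsd"` or `"tm"`.
#' @return list with `best` and `worst` superpositions.
#' @export
select_extreme_alignments <- function(gp, criterion = c("rmsd", "tm")) {
  criterion <- match.arg(criterion)
  comps <- gp$comparisons
  if (length(comps) < 2) stop("need at least 2 comparisons")
  key <- vapply(comps, function(s) paste(s$id_a, s$id_b), "")
  val <- vapply(comps, function(s) if (criterion == "rmsd") s$rmsd else s$tm_score, 0)
  pick <- function(v) {   # lexicographically first comparison attaining v
    cand <- which(val == v)
    comps[[cand[order(key[cand])[1]]]]
  }
  if (criterion == "rmsd") {
    list(best = pick(min(val)), worst = pick(max(val)))
  } else {
    list(best = pick(max(val)), worst = pick(min(val)))
  }
}

#' Gap openings and extensions of an aligned pair
#'
#' Terminal columns falling in a gap run that touches either end of either
#' row are deleted first (residues without an aligned partner at the ends),
#' then gap runs are counted in the trimmed core: a run of k >= 1 gaps is 1
#' opening plus k - 1 extensions.
#'
#' @param sx,sy aligned strings of equal length.
#' @return list of class `gap_counts` with per-row and `combined` counts
#'   (`openings`, `extensions`), the trimmed core strings, and a
#'   `degenerate` flag when trimming consumes the whole alignment.
#' @export
count_gaps <- function(sx, sy) {
  if (nchar(sx) != nchar(sy)) stop("aligned strings must have equal length")
  cx <- strsplit(sx, "")[[1]]; cy <- strsplit(sy, "")[[1]]
  L <- length(cx)
  lead_run <- function(ch) { r <- rle(ch == "-"); if (r$values[1]) r$lengths[1] else 0L }
  lead <- max(lead_run(cx), lead_run(cy))
  trail <- max(lead_run(rev(cx)), lead_run(rev(cy)))
  if (lead + trail >= L) {
    return(structure(list(
      row1 = c(openings = 0L, extensions = 0L),
      row2 = c(openings = 0L, extensions = 0L),
      combined = c(openings = 0L, extensions = 0L),
      core = c("", ""), degenerate = TRUE), class = "gap_counts"))
  }
  core_idx <- (lead + 1):(L - trail)
  runs_of <- function(ch) {
    r <- rle(ch[core_idx] == "-")
    k <- r$lengths[r$values]
    c(openings = length(k), extensions = sum(k) - length(k))
  }
  r1 <- runs_of(cx); r2 <- runs_of(cy)
  structure(list(row1 = r1, row2 = r2, combined = r1 + r2,
                 core = c(paste(cx[core_idx], collapse = ""),
                          paste(cy[core_idx], collapse = "")),
                 degenerate = FALSE),
            class = "gap_counts")
}

#' @export
print.gap_counts <- function(x, ...) {
  cat(sprintf("<gap_counts> combined: %d opening(s), %d extension(s)%s\n",
              x$combined[["openings"]], x$combined[["extensions"]],
              if (x$degenerate) " [degenerate: trimmed away]" else ""))
  invisible(x)
}

.quadrant_label <- function(dx, dy) {
  if (dx == 0 && dy == 0) return("origin")
  if (dx == 0 || dy == 0) return("axis")
  if (dx > 0 && dy > 0) return("I")
  if (dx < 0 && dy > 0) return("II")
  if (dx < 0 && dy < 0) return("III")
  "IV"
}

#' Evolutionary-distance exception analysis over group pairs
#'
#' For each group pair, the best and worst comparison under `criterion` are
#' selected ([select_extreme_alignments()]) and the evolutionary distance of
#' their alignments computed. The expectation is `ED(best) <= ED(worst)`; a
#' pair is an exception when `ED(best) > ED(worst)`, and a zero ED
#' difference is its own class. For exceptions, gap-opening and
#' gap-extension differences (best minus worst, after terminal trimming)
#' place the pair in a quadrant of the (delta-openings, delta-extensions)
#' plane, and a quadrant census is reported.
#'
#' @param group_pairs list of [group_pair()] objects.
#' @param criterion `"rmsd"` or `"tm"`.
#' @return list of class `exception_report`: `records` data frame (one row
#'   per group pair) and `census` (named counts over I, II, III, IV, axis,
#'   origin).
#' @export
exception_analysis <- function(group_pairs, criterion = c("rmsd", "tm")) {
  criterion <- match.arg(criterion)
  rows <- lapply(group_pairs, function(gp) {
    ex <- select_extreme_alignments(gp, criterion)
    ed_b <- evolutionary_distance(ex$best$correspondence$aligned[1],
                                  ex$best$correspondence$aligned[2])$ed
    ed_w <- evolutionary_distance(ex$worst$correspondence$aligned[1],
                                  ex$worst$correspondence$aligned[2])$ed
    gb <- count_gaps(ex$best$correspondence$aligned[1],
                     ex$best$correspondence$aligned[2])$combined
    gw <- count_gaps(ex$worst$correspondence$aligned[1],
                     ex$worst$correspondence$aligned[2])$combined
    status <- if (ed_b > ed_w) "exception"
              else if (ed_b == ed_w) "zero_difference" else "conforming"
    dx <- gb[["openings"]] - gw[["openings"]]
    dy <- gb[["extensions"]] - gw[["extensions"]]
    data.frame(
      pair_id = paste(gp$group_a, gp$group_b, sep = "|"),
      criterion = criterion,
      ed_best = ed_b, ed_worst = ed_w, ed_difference = ed_w - ed_b,
      status = status,
      d_openings = dx, d_extensions = dy,
      quadrant = if (status == "exception") .quadrant_label(dx, dy)
                 else NA_character_)
  })
  records <- do.call(rbind, rows)
  labs <- c("I", "II", "III", "IV", "axis", "origin")
  census <- stats::setNames(
    vapply(labs, function(l) sum(records$quadrant %in% l), 0L), labs)
  structure(list(records = records, census = census, criterion = criterion),
            class = "exception_report")
}

#' @export
print.exception_report <- function(x, ...) {
  n_ex <- sum(x$records$status == "exception")
  cat(sprintf(
    "<exception_report> (%s) %d group pair(s): %d exception(s), %d zero-difference\n",
    x$criterion, nrow(x$records), n_ex,
    sum(x$records$status == "zero_difference")))
  cat(" quadrant census:",
      paste(names(x$census), x$census, sep = "=", collapse = " "), "\n")
  invisible(x)
}
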