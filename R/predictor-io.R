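# Parsers for per-residue disorder-prediction output dialects, normalised
# into one score-track representation.
#
# Only the downloadable result files are consumed; the predictors themselves
# (web servers, PSSM/PSI-BLAST machinery) are never run from here. Parsers
# skip comment/header lines permissively since server output decoration
# drifts over time.

new_score_track <- function(position, residue, score, state, predictor) {
  if (!length(position)) stop("empty score track", call. = FALSE)
  if (any(is.na(position)) || is.unsorted(position, strictly = TRUE)) {
    stop("score track positions must be strictly increasing", call. = FALSE)
  }
  if (any(is.na(score)) || any(score < 0) || any(score > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  structure(
    data.frame(position = as.integer(position), residue = as.character(residue),
               score = as.numeric(score), state = as.character(state),
               stringsAsFactors = FALSE),
    predictor = predictor,
    class = c("score_track", "data.frame")
  )
}

#' @export
print.score_track <- function(x, ...) {
  cat("score_track [", attr(x, "predictor"), "]: ", nrow(x), " residues, ",
      "scores ", sprintf("%.2f-%.2f", min(x$score), max(x$score)),
      if (all(is.na(x$state))) ", no binary states" else "", "\n", sep = "")
  invisible(x)
}

strip_comments <- function(lines) {
  lines <- lines[!grepl("^\\s*(#|>)", lines)]
  lines[nzchar(trimws(lines))]
}

read_lines_arg <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
}

parse_fail <- function(what, i, line) {
  stop(sprintf("%s: cannot parse line %d: '%s'", what, i, line), call. = FALSE)
}

#' Read a DISOPRED3 per-residue output
#'
#' DISOPRED3's `.diso` dialect: comment lines, then one row per residue with
#' index, residue letter, the two-state mark (`*` = disordered, `.` =
#' ordered) and the score in `[0, 1]`.
#'
#' @param x Path or character vector of lines.
#' @return A `score_track` with both score and binary state set
#'   (`"D"`/`"O"`).
#' @export
read_disopred <- function(x) {
  lines <- strip_comments(read_lines_arg(x))
  if (!length(lines)) stop("read_disopred: empty input", call. = FALSE)
  parts <- strsplit(trimws(lines), "\\s+")
  pos <- res <- mark <- sc <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 4L || is.na(suppressWarnings(as.integer(p[1L]))) ||
        !p[3L] %in% c("*", ".")) {
      parse_fail("read_disopred", i, lines[i])
    }
    pos[[i]] <- as.integer(p[1L]); res[[i]] <- p[2L]
    mark[[i]] <- p[3L]
    sc[[i]] <- suppressWarnings(as.numeric(p[4L]))
    if (is.na(sc[[i]])) parse_fail("read_disopred", i, lines[i])
  }
  new_score_track(unlist(pos), unlist(res), unlist(sc),
                  ifelse(unlist(mark) == "*", "D", "O"), "disopred3")
}

#' Read a PrDOS per-residue CSV output
#'
#' PrDOS exports comma-separated rows of residue number, residue letter,
#' disorder probability and (optionally) a binary call (`1`/`0` or `D`/`O`).
#'
#' @param x Path or character vector of lines.
#' @return A `score_track`; binary state unset when the column is absent.
#' @export
read_prdos <- function(x) {
  lines <- strip_comments(read_lines_arg(x))
  # drop a non-numeric header row if present
  if (length(lines) &&
      is.na(suppressWarnings(as.integer(strsplit(lines[1L], ",")[[1L]][1L])))) {
    lines <- lines[-1L]
  }
  if (!length(lines)) stop("read_prdos: empty input", call. = FALSE)
  parts <- strsplit(trimws(lines), "\\s*,\\s*")
  n <- length(parts)
  pos <- integer(n); res <- character(n); sc <- numeric(n)
  st <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) < 3L) parse_fail("read_prdos", i, lines[i])
    pos[i] <- suppressWarnings(as.integer(p[1L]))
    res[i] <- p[2L]
    sc[i] <- suppressWarnings(as.numeric(p[3L]))
    if (is.na(pos[i]) || is.na(sc[i])) parse_fail("read_prdos", i, lines[i])
    if (length(p) >= 4L) {
      st[i] <- if (p[4L] %in% c("1", "D", "d")) "D" else "O"
    }
  }
  new_score_track(pos, res, sc, st, "prdos")
}

read_tab_track <- function(x, predictor, score_col = 3L) {
  lines <- strip_comments(read_lines_arg(x))
  if (!length(lines)) stop(sprintf("read_%s: empty input", predictor), call. = FALSE)
  parts <- strsplit(trimws(lines), "\\s+")
  n <- length(parts)
  pos <- integer(n); res <- character(n); sc <- numeric(n)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) < score_col) parse_fail(predictor, i, lines[i])
    pos[i] <- suppressWarnings(as.integer(p[1L]))
    res[i] <- p[2L]
    sc[i] <- suppressWarnings(as.numeric(p[score_col]))
    if (is.na(pos[i]) || is.na(sc[i])) parse_fail(predictor, i, lines[i])
  }
  new_score_track(pos, res, sc, rep(NA_character_, n), predictor)
}

#' Read an IUPred2A per-residue output
#'
#' Tab-separated rows of position, residue letter and IUPred2A score;
#' `#`-prefixed header lines are skipped.
#'
#' @param x Path or character vector of lines.
#' @return A `score_track` without binary states.
#' @export
read_iupred <- function(x) read_tab_track(x, "iupred2a")

#' Read an ANCHOR2 per-residue output
#'
#' Same dialect as IUPred2A; when a combined IUPred2A+ANCHOR2 file is given
#' (four columns), the ANCHOR2 score is the last column.
#'
#' @param x Path or character vector of lines.
#' @return A `score_track` without binary states.
#' @export
read_anchor <- function(x) {
  lines <- strip_comments(read_lines_arg(x))
  if (!length(lines)) stop("read_anchor: empty input", call. = FALSE)
  ncols <- length(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  read_tab_track(lines, "anchor2", score_col = if (ncols >= 4L) 4L else 3L)
}

#' Binarize a score track into order/disorder states
#'
#' @param track A `score_track`.
#' @param threshold Disorder iff score >= threshold (default 0.5, the
#'   midpoint of the score range; each server documents its own operating
#'   point, so this is configurable).
#' @param override If `FALSE` (default), states already present (e.g.,
#'   DISOPRED3's native two-state call) are preserved.
#' @return The track with `state` filled with `"D"`/`"O"`.
#' @export
binarize <- function(track, threshold = 0.5, override = FALSE) {
  stopifnot(inherits(track, "score_track"))
  new <- ifelse(track$score >= threshold, "D", "O")
  if (override) track$state <- new
  else track$state[is.na(track$state)] <- new[is.na(track$state)]
  track
}

#' Write a score track to the uniform CSV dialect
#'
#' Columns: position, residue, score, state, predictor.
#'
#' @param track A `score_track`.
#' @param file Output path.
#' @export
write_track_csv <- function(track, file) {
  out <- as.data.frame(track)
  out$predictor <- attr(track, "predictor")
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a score track written by [write_track_csv()]
#'
#' @param file CSV path.
#' @return A `score_track`.
#' @export
read_track_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  st <- as.character(d$state)
  st[st %in% c("", "NA")] <- NA_character_
  new_score_track(d$position, d$residue, d$score, st, d$predictor[1L])
}

#' Align a score track to ensemble positions
#'
#' Tracks are aligned by 1-based sequential index plus an optional constant
#' offset (track position + offset = ensemble position). When reference
#' residue letters are supplied, mismatches raise a warning, and 10% or more
#' mismatches an error.
#'
#' @param track A `score_track`.
#' @param positions Integer vector of ensemble positions to align to.
#' @param residues Optional reference one-letter residues (same length as
#'   `positions`).
#' @param offset Integer offset added to track positions (default 0).
#' @return The track rows matching `positions`, with `position` rewritten to
#'   the ensemble frame (unmatched positions absent).
#' @export
align_track <- function(track, positions, residues = NULL, offset = 0L) {
  stopifnot(inherits(track, "score_track"))
  shifted <- track$position + as.integer(offset)
  keep <- shifted %in% positions
  out <- track[keep, , drop = FALSE]
  out$position <- shifted[keep]
  if (!is.null(residues) && nrow(out)) {
    ref <- residues[match(out$position, positions)]
    cmp <- !is.na(ref) & toupper(ref) != toupper(out$residue)
    if (any(cmp)) {
      frac <- mean(cmp)
      if (frac >= 0.1) {
        stop(sprintf("align_track: %.0f%% residue-letter mismatches", 100 * frac),
             call. = FALSE)
      }
      warning(sprintf("align_track: %d residue-letter mismatch(es)", sum(cmp)),
              call. = FALSE)
    }
  }
  attr(out, "predictor") <- attr(track, "predictor")
  class(out) <- c("score_track", "data.frame")
  out
}
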