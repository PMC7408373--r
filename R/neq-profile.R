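# Per-position PB frequency profiles, the Neq entropy index and the
# rigid -> flexible -> highly flexible -> disordered classification.

#' Per-position PB frequencies of an ensemble
#'
#' For each position, the frequency of every PB label across the ensemble
#' models, counting only defined (non-`Z`) cells. Positions observed in
#' fewer than `min_models` models are left undefined: below two valid models
#' the frequency vector is degenerate by construction and carries no
#' heterogeneity information.
#'
#' @param pb_matrix Positions x models character matrix of PB labels
#'   (see [assign_ensemble()] or [sample_pb_matrix()]).
#' @param min_models Minimum number of defined models per position
#'   (default 2); positions below it get `NA` frequencies.
#' @param labels Alphabet labels (default the 16 PBs); frequencies are
#'   reported over exactly this set.
#' @return Object of class `pb_frequencies`: list with `freq` (positions x
#'   length(labels) matrix of fractions, rows summing to 1 or all-`NA`) and
#'   `valid_models` (integer vector).
#' @export
pb_frequencies <- function(pb_matrix, min_models = 2L, labels = pb_labels()) {
  m <- unclass(pb_matrix)
  if (!is.matrix(m)) m <- matrix(m, ncol = 1L)
  L <- nrow(m)
  counts <- matrix(0L, L, length(labels), dimnames = list(NULL, labels))
  for (j in seq_along(labels)) counts[, j] <- rowSums(m == labels[j])
  valid <- as.integer(rowSums(counts))
  freq <- counts / valid
  freq[valid < min_models, ] <- NA_real_
  structure(list(freq = freq, valid_models = valid,
                 residues = attr(pb_matrix, "residues")),
            class = "pb_frequencies")
}

#' Neq: the equivalent number of protein blocks
#'
#' The exponential of the Shannon entropy (natural logarithm) of a PB
#' frequency vector:
#' \deqn{N_{eq} = \exp\left(-\sum_{x} f_x \ln f_x\right)}
#' A value of 1 means a single PB is ever observed at the position (local
#' rigidity); the maximum, equal to the alphabet size (16), means every PB is
#' used with equal probability (maximal local heterogeneity). Zero
#' frequencies contribute nothing (0 ln 0 = 0).
#'
#' @param freq Numeric vector of frequencies summing to 1 (tolerance 1e-6),
#'   or a matrix with one frequency vector per row (`NA` rows give `NA`).
#' @return Neq value(s) in `[1, length(freq)]`.
#' @examples
#' neq(c(1, rep(0, 15)))      # 1
#' neq(rep(1 / 16, 16))       # 16
#' neq(c(0.5, 0.5, rep(0, 14)))  # 2
#' @export
neq <- function(freq) {
  if (is.matrix(freq)) return(apply(freq, 1L, neq_one))
  neq_one(freq)
}

neq_one <- function(f) {
  if (all(is.na(f))) return(NA_real_)
  if (any(is.na(f))) stop("neq: frequency vector mixes NA and values", call. = FALSE)
  if (any(f < 0)) stop("neq: negative frequency", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-6) stop("neq: frequencies must sum to 1", call. = FALSE)
  p <- f[f > 0]
  exp(-sum(p * log(p)))
}

#' Flexibility class of an Neq value
#'
#' Places positions on the order--disorder continuum: rigid below the first
#' threshold, then flexible, highly flexible, and disordered at or above the
#' last. Default anchors 4 / 6 / 8 (an Neq of 1 is fully rigid; above 8 a
#' position is in an entirely disordered regime). Intervals are left-closed:
#' `[1,4) [4,6) [6,8) [8,16]`.
#'
#' @param neq_value Numeric vector of Neq values (`NA` = undefined).
#' @param thresholds Increasing numeric triple (flexible, highly flexible,
#'   disordered); default `c(4, 6, 8)`.
#' @return Factor with levels `rigid`, `flexible`, `highly_flexible`,
#'   `disordered`; `NA` for undefined input.
#' @export
classify_neq <- function(neq_value, thresholds = c(4, 6, 8)) {
  stopifnot(length(thresholds) == 3L, !is.unsorted(thresholds, strictly = TRUE))
  cut(neq_value, breaks = c(-Inf, thresholds, Inf), right = FALSE,
      labels = c("rigid", "flexible", "highly_flexible", "disordered"))
}

#' Per-position Neq profile of an ensemble
#'
#' Combines PB frequencies, Neq and the flexibility classification into the
#' per-position table that drives all downstream comparisons (and is the data
#' behind a PB sequence-logo figure).
#'
#' @param pb_matrix Positions x models PB label matrix.
#' @param min_models Passed to [pb_frequencies()].
#' @param thresholds Passed to [classify_neq()].
#' @return A data.frame of class `neq_profile` with columns `position`,
#'   `resno`, `resname`, `valid_models`, `f_a` ... `f_p`, `neq`, `class`.
#' @export
neq_profile <- function(pb_matrix, min_models = 2L, thresholds = c(4, 6, 8)) {
  fr <- pb_frequencies(pb_matrix, min_models = min_models)
  n <- neq(fr$freq)
  res <- fr$residues
  L <- nrow(fr$freq)
  out <- data.frame(
    position = if (!is.null(res)) res$position else seq_len(L),
    resno = if (!is.null(res)) res$resno else seq_len(L),
    resname = if (!is.null(res)) res$resname else rep("ALA", L),
    valid_models = fr$valid_models,
    stringsAsFactors = FALSE
  )
  fcols <- as.data.frame(fr$freq)
  names(fcols) <- paste0("f_", colnames(fr$freq))
  out <- cbind(out, fcols)
  out$neq <- n
  out$class <- classify_neq(n, thresholds)
  class(out) <- c("neq_profile", "data.frame")
  out
}

#' Summary of an Neq distribution
#'
#' Fractions of defined positions that are entirely rigid (Neq equal to 1
#' within 1e-9), above 2, and above 8 (entirely disordered), plus a
#' histogram. Undefined positions are excluded from the denominator.
#'
#' @param profile An `neq_profile` (or numeric vector of Neq values).
#' @param bin_width Histogram bin width in Neq units (default 0.5).
#' @return List with `n_defined`, `frac_neq1`, `frac_gt2`, `frac_gt8` and
#'   `histogram` (data.frame of bin lower bound and count).
#' @export
distribution_summary <- function(profile, bin_width = 0.5) {
  v <- if (is.data.frame(profile)) profile$neq else as.numeric(profile)
  v <- v[!is.na(v)]
  if (!length(v)) stop("distribution_summary: no defined positions", call. = FALSE)
  breaks <- seq(1, 16 + bin_width, by = bin_width)
  bin <- findInterval(pmin(v, 16), breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  list(
    n_defined = length(v),
    frac_neq1 = mean(abs(v - 1) <= 1e-9),
    frac_gt2 = mean(v > 2),
    frac_gt8 = mean(v > 8),
    histogram = data.frame(bin_lower = breaks[-length(breaks)], count = counts)
  )
}

#' Write an Neq profile as CSV
#'
#' @param profile An `neq_profile`.
#' @param file Output path.
#' @export
write_profile_csv <- function(profile, file) {
  utils::write.csv(as.data.frame(profile), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read an Neq profile written by [write_profile_csv()]
#'
#' @param file CSV path.
#' @return An `neq_profile` data.frame.
#' @export
read_profile_csv <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE)
  out$class <- factor(out$class,
    levels = c("rigid", "flexible", "highly_flexible", "disordered"))
  class(out) <- c("neq_profile", "data.frame")
  out
}
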