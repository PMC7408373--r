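# Neq-versus-prediction comparison machinery: paired series, continuous
# Pearson correlations, stratified means, twelve-class binned averages,
# two-state agreement decomposition and the prediction-rate threshold sweep.

#' Pair an Neq profile with a score track
#'
#' Builds the paired continuous series (Neq, score) over positions where
#' both are defined. All correlation analyses run on continuous values,
#' never on binary classes.
#'
#' @param profile An `neq_profile` (or data.frame with `position` and `neq`).
#' @param track A `score_track` (aligned; see [align_track()]).
#' @return Object of class `paired_series`: data.frame with `position`,
#'   `neq`, `score`, `state`; attribute `dropped` counts positions present
#'   on one side only or with undefined Neq.
#' @export
pair_series <- function(profile, track) {
  stopifnot(inherits(track, "score_track"))
  ok <- !is.na(profile$neq)
  idx <- match(profile$position[ok], track$position)
  hit <- !is.na(idx)
  out <- data.frame(
    position = profile$position[ok][hit],
    neq = profile$neq[ok][hit],
    score = track$score[idx[hit]],
    state = track$state[idx[hit]],
    stringsAsFactors = FALSE
  )
  dropped <- (length(unique(c(profile$position, track$position))) - nrow(out))
  if (nrow(out) < 3L) {
    stop("pair_series: fewer than 3 overlapping defined positions", call. = FALSE)
  }
  structure(out, dropped = dropped, predictor = attr(track, "predictor"),
            class = c("paired_series", "data.frame"))
}

#' Pearson correlation of a paired series
#'
#' Product-moment correlation of the two continuous members; 1.0 is perfect
#' correlation, 0 the absence of correlation.
#'
#' @param series A `paired_series`, or any data.frame with two numeric
#'   columns `neq` and `score` (alternatively pass two numeric vectors via
#'   `x` and `y`).
#' @param x,y Optional explicit numeric vectors (override `series`).
#' @return Correlation in `[-1, 1]`.
#' @export
series_correlation <- function(series = NULL, x = NULL, y = NULL) {
  if (is.null(x)) { x <- series$neq; y <- series$score }
  if (length(x) < 3L) stop("correlation needs at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant series", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Mean predictor score within Neq strata
#'
#' Average score over the rigid-to-low-flexibility stratum (Neq < 4), the
#' flexible-to-border-of-disorder stratum (4 <= Neq <= 8) and the disordered
#' stratum (Neq > 8).
#'
#' @param series A `paired_series`.
#' @param cutpoints Numeric pair, default `c(4, 8)`.
#' @return data.frame with `stratum`, `n`, `mean_score` (strata without
#'   pairs have `n = 0` and `NA` mean).
#' @export
stratified_means <- function(series, cutpoints = c(4, 8)) {
  lo <- cutpoints[1L]; hi <- cutpoints[2L]
  g <- ifelse(series$neq < lo, "rigid",
       ifelse(series$neq <= hi, "intermediate", "disordered"))
  lev <- c("rigid", "intermediate", "disordered")
  n <- vapply(lev, function(s) sum(g == s), 0L)
  mean_score <- vapply(lev, function(s)
    if (n[[s]] > 0L) mean(series$score[g == s]) else NA_real_, 0)
  data.frame(stratum = lev,
             range = c(sprintf("Neq<%g", lo), sprintf("%g<=Neq<=%g", lo, hi),
                       sprintf("Neq>%g", hi)),
             n = as.integer(n), mean_score = mean_score,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Class-binned average scores over twelve Neq classes
#'
#' Bins pairs into the twelve classes `[1,2), [2,3), ..., [11,12)` and
#' `[12,16]`, averages the predictor score per class and correlates the
#' class representative (the class lower bound) with the class mean over
#' populated classes. Aggregation suppresses per-position noise, so this
#' class-level correlation typically exceeds the pair-level one.
#'
#' @param series A `paired_series`.
#' @return List with `classes` (data.frame `class_lower`, `n`, `mean_score`)
#'   and `correlation` (lower bound vs mean, over populated classes).
#' @export
class_binned_averages <- function(series) {
  lower <- 1:12
  cls <- findInterval(series$neq, c(lower, 16.0000001))
  cls[cls > 12L] <- 12L   # Neq of exactly 16 belongs to the top class
  cls[cls < 1L] <- 1L
  n <- vapply(1:12, function(k) sum(cls == k), 0L)
  mean_score <- vapply(1:12, function(k)
    if (n[k] > 0L) mean(series$score[cls == k]) else NA_real_, 0)
  populated <- n > 0L
  if (sum(populated) < 3L) {
    stop("class_binned_averages: fewer than 3 populated classes", call. = FALSE)
  }
  r <- series_correlation(x = lower[populated], y = mean_score[populated])
  list(classes = data.frame(class_lower = lower, n = as.integer(n),
                            mean_score = mean_score),
       correlation = r)
}

#' Two-state agreement between two predictors
#'
#' Decomposes the agreement between two binarized tracks into the fraction
#' of positions where both call disorder, both call order, and their sum
#' (the total agreement); each track's own disorder fraction is reported
#' alongside.
#'
#' @param a,b `score_track`s with states set, on a common position frame.
#' @return List with `n`, `common_disorder`, `common_order`, `agreement`,
#'   `disorder_fraction_a`, `disorder_fraction_b`.
#' @export
two_state_overlap <- function(a, b) {
  stopifnot(inherits(a, "score_track"), inherits(b, "score_track"))
  idx <- match(a$position, b$position)
  hit <- !is.na(idx)
  sa <- a$state[hit]; sb <- b$state[idx[hit]]
  ok <- !is.na(sa) & !is.na(sb)
  if (!any(ok)) stop("two_state_overlap: no aligned positions with states",
                     call. = FALSE)
  sa <- sa[ok]; sb <- sb[ok]
  dd <- mean(sa == "D" & sb == "D")
  oo <- mean(sa == "O" & sb == "O")
  list(n = length(sa), common_disorder = dd, common_order = oo,
       agreement = dd + oo,
       disorder_fraction_a = mean(sa == "D"),
       disorder_fraction_b = mean(sb == "D"))
}

#' Prediction-rate sweep over Neq thresholds
#'
#' For each threshold t, the "true" state of a position is disorder iff its
#' Neq exceeds t (Neq equal to t counts as order, so that t = 1 makes fully
#' rigid positions ordered). The prediction rate is the fraction of
#' positions whose predictor two-state call matches that truth; the truth
#' class balance at each t is reported with it.
#'
#' @param profile An `neq_profile`.
#' @param track A `score_track` with states set.
#' @param thresholds Numeric vector of Neq thresholds (default `1:12`).
#' @return data.frame with `threshold`, `n`, `rate`, `true_disorder_fraction`,
#'   `true_order_fraction`.
#' @export
prediction_rate_sweep <- function(profile, track, thresholds = 1:12) {
  s <- pair_series(profile, track)
  if (all(is.na(s$state))) {
    stop("prediction_rate_sweep: track has no binary states; run binarize()",
         call. = FALSE)
  }
  s <- s[!is.na(s$state), , drop = FALSE]
  pred_d <- s$state == "D"
  out <- lapply(thresholds, function(t) {
    truth_d <- s$neq > t
    data.frame(threshold = t, n = nrow(s),
               rate = mean(pred_d == truth_d),
               true_disorder_fraction = mean(truth_d),
               true_order_fraction = mean(!truth_d))
  })
  do.call(rbind, out)
}

#' Full comparison report of an ensemble against predictor tracks
#'
#' Runs every comparison for each track: pair-level correlation with Neq,
#' stratified means, twelve-class binned averages, the prediction-rate
#' sweep, plus pairwise track-vs-track correlations and two-state overlaps.
#'
#' @param profile An `neq_profile`.
#' @param tracks Named list of `score_track`s (aligned to the profile
#'   positions).
#' @param binarize_threshold Threshold used to fill missing binary states
#'   (default 0.5).
#' @param sweep_thresholds Neq thresholds for the sweep (default `1:12`).
#' @param strata_cutpoints Neq stratification cutpoints (default `c(4, 8)`).
#' @return Object of class `comparison_report`: list with per-track
#'   `correlations`, `strata`, `classes`, `sweeps`, and pairwise
#'   `track_correlations`, `overlaps`.
#' @export
compare_report <- function(profile, tracks, binarize_threshold = 0.5,
                           sweep_thresholds = 1:12,
                           strata_cutpoints = c(4, 8)) {
  stopifnot(length(tracks) >= 1L)
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    names(tracks) <- vapply(tracks, function(t)
      as.character(attr(t, "predictor")), "")
  }
  tracks <- lapply(tracks, binarize, threshold = binarize_threshold)
  series <- lapply(tracks, function(t) pair_series(profile, t))

  correlations <- data.frame(
    predictor = names(tracks),
    n = vapply(series, nrow, 0L),
    correlation = vapply(series, series_correlation, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  strata <- lapply(series, stratified_means, cutpoints = strata_cutpoints)
  classes <- lapply(series, function(s)
    tryCatch(class_binned_averages(s), error = function(e) NULL))
  sweeps <- lapply(tracks, function(t)
    prediction_rate_sweep(profile, t, thresholds = sweep_thresholds))

  nm <- names(tracks)
  track_correlations <- NULL
  overlaps <- list()
  if (length(tracks) >= 2L) {
    for (i in seq_along(tracks)) for (j in seq_along(tracks)) {
      if (i >= j) next
      a <- tracks[[i]]; b <- tracks[[j]]
      idx <- match(a$position, b$position); hit <- !is.na(idx)
      r <- if (sum(hit) >= 3L)
        series_correlation(x = a$score[hit], y = b$score[idx[hit]])
      else NA_real_
      track_correlations <- rbind(track_correlations,
        data.frame(track_a = nm[i], track_b = nm[j], n = sum(hit),
                   correlation = r, stringsAsFactors = FALSE))
      overlaps[[paste(nm[i], nm[j], sep = "|")]] <- two_state_overlap(a, b)
    }
  }
  structure(list(correlations = correlations, strata = strata,
                 classes = classes, sweeps = sweeps,
                 track_correlations = track_correlations,
                 overlaps = overlaps),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report\n-- Neq vs predictor correlations --\n")
  print(x$correlations)
  if (!is.null(x$track_correlations)) {
    cat("-- track vs track --\n")
    print(x$track_correlations)
  }
  invisible(x)
}
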