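#' Min-max normalization of a fluorescence trace
#'
#' Normalizes a calcium trace across the entire recording,
#' \eqn{(F - F_{min}) / (F_{max} - F_{min})}, mapping it onto \[0, 1\].
#' Putative event peaks are thresholded on this scale.
#'
#' @param f Numeric fluorescence trace.
#' @return Normalized trace in \[0, 1\].
#' @export
normalize_global <- function(f) {
  stopifnot(is.numeric(f), all(is.finite(f)))
  r <- range(f)
  if (diff(r) == 0) stop("cannot normalize a constant trace")
  (f - r[1]) / diff(r)
}

#' Baseline (dF/F) normalization of an event window
#'
#' Re-expresses a raw window relative to its own baseline,
#' \eqn{(F - F_0)/|F_0|}, where \eqn{F_0} is the mean over the baseline
#' samples (the 5 s preceding the peak).
#'
#' @param window Raw trace samples around an event.
#' @param baseline_idx Indices of `window` forming the baseline.
#' @return Window in dF/F units, or `NULL` (with a warning) if the
#'   baseline mean is numerically zero.
#' @export
normalize_baseline <- function(window, baseline_idx) {
  stopifnot(length(baseline_idx) >= 1,
            all(baseline_idx >= 1), all(baseline_idx <= length(window)))
  f0 <- mean(window[baseline_idx])
  if (abs(f0) < .Machine$double.eps^0.5 * max(abs(window), 1)) {
    warning("baseline mean is numerically zero; event dropped")
    return(NULL)
  }
  (window - f0) / abs(f0)
}

#' Detect calcium events in a fluorescence trace
#'
#' Putative events are local maxima of the min-max normalized trace
#' ([normalize_global()]) exceeding a level threshold (10 percent of the
#' maximum by default), with a minimum prominence and separation. Each
#' putative peak is extracted from the raw trace (5 s before to 10 s
#' after), re-expressed in dF/F units relative to its own 5 s baseline
#' ([normalize_baseline()]), and kept only if the peak exceeds the
#' baseline mean by more than `sd_mult` baseline standard deviations.
#' Peaks whose baseline or extraction window would be clipped by the
#' recording edges are dropped.
#'
#' @param f Raw fluorescence trace.
#' @param rate Sampling rate, Hz.
#' @param level Threshold on the normalized trace (fraction of maximum).
#' @param min_prominence Minimum peak prominence, normalized units.
#' @param min_separation Minimum separation between peaks, s.
#' @param baseline Baseline extent before the peak, s.
#' @param post Extraction extent after the peak, s.
#' @param sd_mult Baseline-SD multiple the dF/F peak must exceed.
#' @return A data.frame of class `calcium_events` with columns `index`,
#'   `time` (s), `peak_dff` and the per-event dF/F windows in attribute
#'   `windows` (one row per event).
#' @export
detect_calcium_events <- function(f, rate, level = 0.10,
                                  min_prominence = 0.05,
                                  min_separation = 1,
                                  baseline = 5, post = 10, sd_mult = 2) {
  stopifnot(rate > 0)
  if (length(f) / rate < baseline + post)
    stop("recording shorter than one event window (", baseline + post,
         " s)")
  g <- normalize_global(f)
  peaks <- .find_peaks(g, min_prominence = min_prominence,
                       min_separation = max(1L, round(min_separation * rate)))
  peaks <- peaks[g[peaks] > level]
  nb <- round(baseline * rate); np <- round(post * rate)
  # windows clipped at edges are dropped, not padded
  peaks <- peaks[peaks - nb >= 1 & peaks + np <= length(f)]
  keep <- logical(0); times <- numeric(0); amps <- numeric(0)
  wins <- list()
  for (p in peaks) {
    w <- f[(p - nb):(p + np)]
    dff <- normalize_baseline(w, seq_len(nb))
    if (is.null(dff)) next
    b <- dff[seq_len(nb)]
    pk <- dff[nb + 1]
    if (pk > mean(b) + sd_mult * stats::sd(b)) {
      times <- c(times, (p - 1) / rate)
      amps <- c(amps, pk)
      keep <- c(keep, TRUE)
      wins[[length(wins) + 1L]] <- dff
    }
  }
  out <- data.frame(index = round(times * rate) + 1L, time = times,
                    peak_dff = amps)
  attr(out, "windows") <- if (length(wins)) do.call(rbind, wins) else
    matrix(numeric(0), 0, nb + np + 1)
  attr(out, "rate") <- rate
  attr(out, "baseline_samples") <- nb
  class(out) <- c("calcium_events", "data.frame")
  out
}

#' Classify a vessel response to a calcium event
#'
#' A diameter window spanning -5 to +10 s around the event is expressed
#' in dF/F-style units relative to its 5 s pre-event baseline. The vessel
#' is responsive if a contiguous dilation longer than `min_dur` seconds
#' occurs within `within` seconds after the event, exceeding the baseline
#' mean by more than `sd_mult` baseline standard deviations. The dilation
#' peak is the maximum of the baseline-normalized window after the event.
#'
#' @param dwin Diameter samples covering \[-baseline, +post\] s around the
#'   event (the event at index `baseline * rate + 1`).
#' @param rate Sampling rate of the diameter trace, Hz.
#' @param baseline,post Window extents, s.
#' @param min_dur Minimum dilation duration, s.
#' @param within Response window after the event, s.
#' @param sd_mult Baseline-SD multiple the dilation must exceed.
#' @param max_missing Maximum tolerated fraction of missing samples.
#' @return A list of class `response_record`: `responsive`, `dilation_peak`
#'   (fraction of baseline diameter), `latency` (s, `NA` if not
#'   responsive), `valid`.
#' @export
classify_response <- function(dwin, rate, baseline = 5, post = 10,
                              min_dur = 0.5, within = 5, sd_mult = 1,
                              max_missing = 0.2) {
  nb <- round(baseline * rate)
  expected <- nb + round(post * rate) + 1
  stopifnot(length(dwin) == expected)
  if (mean(!is.finite(dwin)) > max_missing) {
    return(structure(list(responsive = NA, dilation_peak = NA_real_,
                          latency = NA_real_, valid = FALSE),
                     class = "response_record"))
  }
  b <- dwin[seq_len(nb)]
  f0 <- mean(b, na.rm = TRUE)
  norm <- (dwin - f0) / abs(f0)
  bs <- stats::sd(norm[seq_len(nb)], na.rm = TRUE)
  thr <- mean(norm[seq_len(nb)], na.rm = TRUE) + sd_mult * bs
  post_idx <- (nb + 2):(nb + 1 + round(within * rate))
  above <- norm[post_idx] > thr
  above[!is.finite(above)] <- FALSE
  runs <- .runs_true(above)
  need <- min_dur * rate
  responsive <- any(runs$length > need)
  # the j-th post-event sample sits at +j/rate seconds
  latency <- if (responsive)
    runs$start[which(runs$length > need)[1]] / rate else NA_real_
  peak_idx <- (nb + 1):length(norm)
  structure(list(responsive = responsive,
                 dilation_peak = max(norm[peak_idx], na.rm = TRUE),
                 latency = latency, valid = TRUE),
            class = "response_record")
}

#' @export
print.response_record <- function(x, ...) {
  if (!x$valid) cat("Response record: invalid (too many missing samples)\n")
  else cat(sprintf("Response record: %s, dilation peak %.3g%s\n",
                   if (x$responsive) "responsive" else "not responsive",
                   x$dilation_peak,
                   if (is.finite(x$latency))
                     sprintf(", latency %.2f s", x$latency) else ""))
  invisible(x)
}

#' Shuffled-null response rate
#'
#' Estimates the chance rate of the dilation-response classifier by
#' destroying the temporal alignment between vessel diameter and calcium
#' events: the diameter trace is randomly permuted across time (or
#' circularly shifted) on each iteration and every event is re-classified
#' against the shuffled trace.
#'
#' @param d Diameter trace values (full recording).
#' @param rate Sampling rate, Hz.
#' @param event_times Calcium event times, s.
#' @param n_iter Number of shuffle iterations.
#' @param seed Integer seed.
#' @param mode `"permute"` (unrestricted random permutation) or
#'   `"circular"` (random circular shift).
#' @param ... Passed to [classify_response()].
#' @return Fraction of event x iteration classifications that were
#'   responsive, with attribute `n` (number of classifications).
#' @export
shuffled_null <- function(d, rate, event_times, n_iter = 100, seed = 1,
                          mode = c("permute", "circular"), ...) {
  mode <- match.arg(mode)
  stopifnot(length(event_times) >= 1)
  set.seed(seed)
  nb <- round(5 * rate); np <- round(10 * rate)
  idx <- round(event_times * rate) + 1L
  idx <- idx[idx - nb >= 1 & idx + np <= length(d)]
  if (!length(idx)) stop("no event window fits inside the recording")
  hits <- 0L; total <- 0L
  for (it in seq_len(n_iter)) {
    ds <- if (mode == "permute") d[sample.int(length(d))] else {
      s <- sample.int(length(d), 1)
      d[c((s + 1):length(d), 1:s)[seq_along(d)]]
    }
    for (i in idx) {
      r <- classify_response(ds[(i - nb):(i + np)], rate, ...)
      if (isTRUE(r$valid)) {
        total <- total + 1L
        hits <- hits + as.integer(r$responsive)
      }
    }
  }
  structure(hits / total, n = total)
}

#' Single-vessel neurovascular coupling index
#'
#' Ratio of a vessel's dilation peak to the triggering calcium peak, both
#' in baseline-normalized (dF/F) units. Scale-free: doubling both inputs
#' leaves the index unchanged.
#'
#' @param dilation_peak Dilation peak, fraction of baseline diameter.
#' @param calcium_peak Calcium peak, dF/F. Must be positive; pairs with
#'   non-positive calcium peaks return `NA`.
#' @return `dilation_peak / calcium_peak` (vectorized).
#' @export
nvc_index <- function(dilation_peak, calcium_peak) {
  out <- dilation_peak / calcium_peak
  out[!is.finite(calcium_peak) | calcium_peak <= 0] <- NA_real_
  out
}

#' Pairwise Pearson correlation of ROI activity traces
#'
#' @param traces Matrix, time x ROI (>= 2 columns).
#' @return List: `R` (symmetric correlation matrix, unit diagonal;
#'   rows/columns of constant traces are `NA`) and `mean_offdiag` (mean
#'   off-diagonal correlation over defined pairs).
#' @export
roi_pairwise_correlation <- function(traces) {
  stopifnot(is.matrix(traces), ncol(traces) >= 2)
  ok <- apply(traces, 2, function(x) stats::sd(x) > 0)
  R <- matrix(NA_real_, ncol(traces), ncol(traces))
  if (any(ok)) R[ok, ok] <- stats::cor(traces[, ok, drop = FALSE])
  diag(R)[ok] <- 1
  off <- R[upper.tri(R)]
  list(R = R, mean_offdiag = mean(off, na.rm = TRUE))
}

#' Holm-Bonferroni step-down adjusted p values
#'
#' Ranks m p values in ascending order, multiplies the smallest by m, the
#' next by m - 1, and so on; adjusted values are made monotone
#' non-decreasing along the ranking and capped at 1, which carries the
#' procedure's stop-at-first-nonsignificant semantics.
#'
#' @param p Numeric p values in \[0, 1\].
#' @return Adjusted p values in the original order.
#' @export
holm_bonferroni <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}
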