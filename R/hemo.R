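#' Derive Hbt, SO2 and CMRO2 channels from an oxy-CBF probe trace
#'
#' Adds total haemoglobin `Hbt = HbO + Hbr`, oxygen saturation
#' `SO2 = 100 * HbO / Hbt` (percent) and the estimated cerebral metabolic
#' rate of oxygen `CMRO2 = CBF * Hbr / Hbt`, computed samplewise. Samples
#' with `Hbt = 0` get missing `SO2`/`CMRO2`.
#'
#' @param h A `hemo_trace` (see [make_hemo()], [load_hemo()]).
#' @return The trace with derived columns added.
#' @export
derive_channels <- function(h) {
  stopifnot(inherits(h, "hemo_trace"))
  d <- h$data
  stopifnot(all(c("flux", "HbO", "Hbr") %in% names(d)))
  d$Hbt <- d$HbO + d$Hbr
  ok <- d$Hbt > 0
  d$SO2 <- ifelse(ok, 100 * d$HbO / d$Hbt, NA_real_)
  d$CMRO2 <- ifelse(ok, d$flux * d$Hbr / d$Hbt, NA_real_)
  h$data <- d
  h
}

#' Resting-period mask
#'
#' Marks samples taken while the animal is immobile and in the dark:
#' locomotion below a speed threshold and no stimulus on screen, with an
#' exclusion pad around every locomotion bout and stimulus window.
#'
#' @param h A `hemo_trace` with `locomotion` and `stimulus` columns.
#' @param speed_thresh Locomotion threshold, cm/s.
#' @param pad Exclusion padding around bouts/stimuli, s.
#' @return Logical mask, `TRUE` during rest.
#' @export
segment_rest <- function(h, speed_thresh = 0.25, pad = 1) {
  stopifnot(inherits(h, "hemo_trace"))
  d <- h$data
  stopifnot(all(c("locomotion", "stimulus") %in% names(d)))
  active <- abs(d$locomotion) >= speed_thresh | as.logical(d$stimulus)
  np <- round(pad * h$rate)
  if (np > 0 && any(active)) {
    idx <- which(active)
    lo <- pmax(1L, idx - np); hi <- pmin(length(active), idx + np)
    padded <- logical(length(active))
    for (j in seq_along(idx)) padded[lo[j]:hi[j]] <- TRUE
    active <- padded
  }
  !active
}

#' Baseline haemodynamic summaries over resting periods
#'
#' Mean of each channel over the rest mask, per session, aggregated to
#' animal means (mean of session means).
#'
#' @param sessions List of `hemo_trace` objects (after
#'   [derive_channels()]).
#' @param masks List of rest masks (one per session), e.g. from
#'   [segment_rest()].
#' @param animal Character/factor of animal ids, one per session.
#' @param channels Channels to summarize.
#' @param min_rest Minimum rest coverage required per session, s.
#' @return A data.frame with one row per animal and one column per
#'   channel; attribute `sessions` holds the per-session means.
#' @export
baseline_summary <- function(sessions, masks, animal,
                             channels = c("flux", "speed", "HbO", "Hbr",
                                          "Hbt", "SO2", "CMRO2"),
                             min_rest = 10) {
  stopifnot(length(sessions) == length(masks),
            length(sessions) == length(animal))
  per_session <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    h <- sessions[[i]]; m <- masks[[i]]
    if (sum(m) / h$rate < min_rest)
      stop("session ", i, ": rest mask covers less than ", min_rest, " s")
    ch <- intersect(channels, names(h$data))
    vals <- vapply(ch, function(cn) mean(h$data[[cn]][m], na.rm = TRUE),
                   numeric(1))
    cbind(data.frame(animal = animal[i], session = i),
          as.data.frame(as.list(vals)))
  }))
  agg <- stats::aggregate(per_session[, -(1:2), drop = FALSE],
                          by = list(animal = per_session$animal), mean)
  attr(agg, "sessions") <- per_session
  agg
}

#' Detect metabolic (CMRO2) events and their Hbt excursions
#'
#' Runs the calcium event detector ([detect_calcium_events()], the shared
#' peak machinery) on the derived CMRO2 channel: putative peaks on the
#' min-max normalized trace, baseline (5 s) dF/F re-expression, and the
#' 2-SD-above-preceding-baseline exclusion rule. For each retained peak
#' the Hbt trace over the same window is extracted, its excursion within
#' `within` seconds of the peak measured, and the regional neurovascular
#' coupling index computed.
#'
#' @param h A `hemo_trace` after [derive_channels()].
#' @param within Window after the CMRO2 peak for the Hbt excursion, s.
#' @param direction `"hbt_over_cmro2"` (blood-volume excursion per unit
#'   metabolic excursion, default) or `"cmro2_over_hbt"`.
#' @param ... Passed to [detect_calcium_events()].
#' @return Data.frame of class `metabolic_events`: `time`, `cmro2_peak`
#'   (dF/F), `hbt_peak` (dF/F within the window), `nvc_index`.
#' @export
detect_metabolic_events <- function(h, within = 5,
                                    direction = c("hbt_over_cmro2",
                                                  "cmro2_over_hbt"), ...) {
  direction <- match.arg(direction)
  stopifnot(inherits(h, "hemo_trace"))
  if (is.null(h$data$CMRO2)) stop("derive channels first (derive_channels)")
  ev <- detect_calcium_events(h$data$CMRO2, rate = h$rate, ...)
  nb <- attr(ev, "baseline_samples")
  rate <- h$rate
  hbt_peak <- vapply(seq_len(nrow(ev)), function(j) {
    i <- ev$index[j]
    w <- h$data$Hbt[(i - nb):(i + round(within * rate))]
    dff <- normalize_baseline(w, seq_len(nb))
    if (is.null(dff)) return(NA_real_)
    max(dff[(nb + 1):length(dff)])
  }, numeric(1))
  idx <- if (direction == "hbt_over_cmro2")
    nvc_index(hbt_peak, ev$peak_dff) else nvc_index(ev$peak_dff, hbt_peak)
  out <- data.frame(time = ev$time, cmro2_peak = ev$peak_dff,
                    hbt_peak = hbt_peak, nvc_index = idx)
  class(out) <- c("metabolic_events", "data.frame")
  out
}

#' Regional neurovascular coupling index
#'
#' Blood-volume excursion per unit metabolic excursion for one event:
#' the Hbt peak (within 5 s of the CMRO2 peak) divided by the CMRO2 peak,
#' both baseline-normalized. Events with non-positive CMRO2 peaks are
#' dropped (`NA`).
#'
#' @param hbt_peak,cmro2_peak Baseline-normalized excursions.
#' @param direction See [detect_metabolic_events()].
#' @return The index (vectorized).
#' @export
regional_nvc_index <- function(hbt_peak, cmro2_peak,
                               direction = c("hbt_over_cmro2",
                                             "cmro2_over_hbt")) {
  direction <- match.arg(direction)
  if (direction == "hbt_over_cmro2") nvc_index(hbt_peak, cmro2_peak)
  else nvc_index(cmro2_peak, hbt_peak)
}
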