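#' Synthetic line-scan kymograph with known ground truth
#'
#' Renders a two-segment line-scan image (rows = successive scan lines,
#' columns = position along the scan path) as acquired along a capillary:
#' an along-vessel segment in which moving red blood cells cast dark
#' slanted shadows on the bright dye-filled lumen, and an across-vessel
#' segment carrying the lumen intensity profile used for diameter.
#'
#' RBC shadows are rendered as an anti-aliased periodic stripe pattern:
#' the spacing between consecutive RBCs is `velocity/flux`, so the slope of
#' each shadow is `velocity * dt_line / px` pixels per line and the number
#' of shadows crossing a fixed position per second equals `flux`. The
#' stripe width is `hematocrit * spacing`, so the dark fraction of the
#' binarized segment equals the haematocrit. When `velocity` is zero the
#' requested number of stationary shadows (`flux * duration`) is placed
#' instead.
#'
#' @param velocity RBC velocity, um/s (signed); scalar or one value per
#'   scan line.
#' @param flux RBC flux, RBC/s.
#' @param hematocrit Dark (RBC) fraction of the lumen, in \[0, 1\], or
#'   `NULL` to use a fixed `stripe_width` of 3 um.
#' @param diameter Vessel diameter, um; scalar or one value per line.
#' @param dt_line Line period, s.
#' @param px Pixel size, um.
#' @param duration Recording length, s.
#' @param noise_sd Additive Gaussian noise SD, fraction of dynamic range.
#' @param seed Integer seed; identical inputs give identical images.
#' @param along_len,across_len Segment lengths, um.
#' @param stripe_width Stripe width when `hematocrit` is `NULL`, um.
#' @param psf_sigma Spatial Gaussian blur SD, um (along the scan only).
#' @return An object of class `kymograph` with the image, scan metadata,
#'   and a `truth` list (including `n_crossings`, the exact number of
#'   shadows crossing the counting column).
#' @export
#' @examples
#' k <- make_linescan(velocity = 500, flux = 80, hematocrit = 0.3,
#'                    duration = 0.5, seed = 1)
#' dim(k$intensity)
make_linescan <- function(velocity, flux, hematocrit = NULL, diameter = 5,
                          dt_line = 0.001, px = 0.2, duration = 1,
                          noise_sd = 0, seed = 1,
                          along_len = 30, across_len = 12,
                          stripe_width = 3, psf_sigma = 0.4) {
  stopifnot(dt_line > 0, px > 0, flux >= 0, duration > 0)
  if (any(diameter <= 0)) stop("diameter must be positive")
  if (!is.null(hematocrit) &&
      (any(hematocrit < 0) || any(hematocrit > 1)))
    stop("hematocrit must lie in [0, 1]")
  n_lines <- floor(duration / dt_line)
  v <- rep_len(velocity, n_lines)
  diam <- rep_len(diameter, n_lines)
  n_along <- round(along_len / px)
  n_across <- round(across_len / px)

  disp <- cumsum(v) * dt_line              # displacement at each line, um
  xpos <- (seq_len(n_along) - 0.5) * px    # column centers, um

  mean_speed <- mean(abs(v))
  if (mean_speed > 0 && flux > 0) {
    spacing <- mean_speed / flux
  } else if (flux > 0) {
    spacing <- along_len / max(1, round(flux * duration))
  } else {
    spacing <- Inf
  }
  w <- if (!is.null(hematocrit)) hematocrit * spacing else stripe_width
  hct_true <- if (is.finite(spacing)) w / spacing else 0

  edge <- px / 2  # anti-aliasing half-width
  lum <- 1; bg <- 0.05
  img <- matrix(lum, n_lines, n_along + n_across)
  if (is.finite(spacing) && w > 0) {
    # occupancy of the periodic stripe pattern, by line; centers offset by
    # half a spacing so bands do not straddle the segment ends at t = 0
    for (i in seq_len(n_lines)) {
      phase <- (xpos - disp[i] - spacing / 2) / spacing
      dist <- abs(phase - round(phase)) * spacing   # to nearest RBC center
      occ <- pmin(1, pmax(0, (w / 2 - dist) / edge + 0.5))
      img[i, seq_len(n_along)] <- lum * (1 - occ) + bg * occ
    }
  }
  # exact count of dark intervals at the counting column (segment center):
  # shadows crossing the column plus any shadow already covering it
  xc <- xpos[ceiling(n_along / 2)]
  if (is.finite(spacing) && w > 0) {
    phase <- (xc - disp - spacing / 2) / spacing
    dark <- abs(phase - round(phase)) * spacing < w / 2
    n_crossings <- sum(diff(c(FALSE, dark)) == 1)
  } else n_crossings <- 0L

  # across-vessel segment: lumen tube profile, per-line diameter
  ypos <- (seq_len(n_across) - 0.5) * px
  yc <- across_len / 2
  for (i in seq_len(n_lines)) {
    inside <- pmin(1, pmax(0, (diam[i] / 2 - abs(ypos - yc)) / edge + 0.5))
    img[i, n_along + seq_len(n_across)] <- bg + (lum - bg) * inside
  }
  if (psf_sigma > 0) {
    sig_px <- psf_sigma / px
    rad <- max(1L, ceiling(3 * sig_px))
    kk <- stats::dnorm(seq(-rad, rad), sd = sig_px); kk <- kk / sum(kk)
    blur_cols <- function(cols) {
      m <- img[, cols, drop = FALSE]
      mp <- cbind(m[, rep(1, rad)], m, m[, rep(ncol(m), rad)])
      t(stats::filter(t(mp), kk, sides = 2))[, (rad + 1):(rad + ncol(m)),
                                             drop = FALSE]
    }
    img[, seq_len(n_along)] <- blur_cols(seq_len(n_along))
    img[, n_along + seq_len(n_across)] <- blur_cols(n_along + seq_len(n_across))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(length(img), sd = noise_sd),
                        nrow(img), ncol(img))
  }
  structure(list(
    intensity = img, dt_line = dt_line, px = px,
    segments = list(along = c(1L, n_along),
                    across = c(n_along + 1L, n_along + n_across)),
    truth = list(velocity = v, flux = flux, hematocrit = hct_true,
                 diameter = diam, spacing = spacing, stripe_width = w,
                 n_crossings = n_crossings, seed = seed,
                 noise_sd = noise_sd)),
    class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("Line-scan kymograph: %d lines x %d px (dt %.3g ms, px %.3g um)\n",
              nrow(x$intensity), ncol(x$intensity), 1000 * x$dt_line, x$px))
  cat(sprintf("  along-vessel cols %d-%d, across-vessel cols %d-%d\n",
              x$segments$along[1], x$segments$along[2],
              x$segments$across[1], x$segments$across[2]))
  invisible(x)
}

#' Synthetic two-channel vessel/calcium movie
#'
#' Generates an XY time-lapse with a lumen-dye channel containing a
#' horizontal vessel of per-frame diameter, and a calcium channel with
#' disk ROIs whose fluorescence carries exponential-decay transients at
#' specified times and amplitudes (in dF/F units of the ROI baseline).
#'
#' @param ny,nx Frame size, pixels.
#' @param n_frames Number of frames.
#' @param frame_rate Hz.
#' @param px Pixel size, um.
#' @param diameter Vessel diameter, um; scalar or per frame.
#' @param roi_centres List of `c(y, x)` pixel coordinates.
#' @param events Data frame with columns `roi`, `time` (s), `amp` (dF/F).
#' @param kernel_tau Decay time constant of the calcium kernel, s.
#' @param baseline_F ROI baseline fluorescence, a.u.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @param psf_sigma Gaussian PSF SD, um.
#' @param roi_radius ROI disk radius, pixels.
#' @return Class `nvc_movie`: channels `lumen` and `calcium`
#'   (y, x, frame arrays), `roi_traces` (frame x ROI), `diameter`
#'   (per frame, um), metadata and `truth`.
#' @export
make_movie <- function(ny = 64, nx = 64, n_frames = 150, frame_rate = 7.5,
                       px = 0.5, diameter = 5, roi_centres = list(c(16, 16)),
                       events = NULL, kernel_tau = 0.4, baseline_F = 1,
                       noise_sd = 0, seed = 1, psf_sigma = 0.4,
                       roi_radius = 4) {
  stopifnot(frame_rate > 0, px > 0, n_frames >= 2)
  if (any(diameter <= 0)) stop("diameter must be positive")
  for (rc in roi_centres)
    if (rc[1] - roi_radius < 1 || rc[1] + roi_radius > ny ||
        rc[2] - roi_radius < 1 || rc[2] + roi_radius > nx)
      stop("ROI outside frame")
  tt <- (seq_len(n_frames) - 1) / frame_rate
  diam <- rep_len(diameter, n_frames)
  if (!is.null(events)) {
    stopifnot(all(c("roi", "time", "amp") %in% names(events)))
    if (any(events$time < 0) || any(events$time > max(tt)))
      stop("event times must fall within the movie duration")
  }
  # ROI traces: baseline x (1 + sum of decaying transients)
  n_roi <- length(roi_centres)
  dff <- matrix(0, n_frames, n_roi)
  if (!is.null(events)) {
    for (j in seq_len(nrow(events))) {
      e <- events[j, ]
      on <- tt >= e$time
      dff[on, e$roi] <- dff[on, e$roi] +
        e$amp * exp(-(tt[on] - e$time) / kernel_tau)
    }
  }
  traces <- baseline_F * (1 + dff)

  yc <- ny / 2 * px
  ypos <- (seq_len(ny) - 0.5) * px
  edge <- px / 2
  lum <- array(0.05, c(ny, nx, n_frames))
  calc <- array(0.05 * baseline_F, c(ny, nx, n_frames))
  roi_mask <- matrix(FALSE, ny, nx)
  roi_id <- matrix(0L, ny, nx)
  for (k in seq_len(n_roi)) {
    rc <- roi_centres[[k]]
    yy <- outer(seq_len(ny) - rc[1], rep(1, nx))
    xx <- outer(rep(1, ny), seq_len(nx) - rc[2])
    inside <- yy^2 + xx^2 <= roi_radius^2
    roi_mask <- roi_mask | inside
    roi_id[inside] <- k
  }
  for (i in seq_len(n_frames)) {
    prof <- pmin(1, pmax(0, (diam[i] / 2 - abs(ypos - yc)) / edge + 0.5))
    lum[, , i] <- 0.05 + 0.95 * matrix(prof, ny, nx)
    fr <- calc[, , i]
    fr[roi_mask] <- traces[i, roi_id[roi_mask]]
    calc[, , i] <- fr
  }
  if (psf_sigma > 0) {
    sig <- psf_sigma / px
    for (i in seq_len(n_frames)) {
      lum[, , i] <- .gauss_smooth(lum[, , i], sig)
      calc[, , i] <- .gauss_smooth(calc[, , i], sig)
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    lum <- lum + array(stats::rnorm(length(lum), sd = noise_sd), dim(lum))
    calc <- calc + array(stats::rnorm(length(calc), sd = noise_sd), dim(calc))
  }
  structure(list(lumen = lum, calcium = calc, frame_rate = frame_rate,
                 px = px, t = tt,
                 roi_traces = traces, diameter = diam,
                 truth = list(events = events, kernel_tau = kernel_tau,
                              baseline_F = baseline_F, seed = seed,
                              roi_centres = roi_centres)),
            class = "nvc_movie")
}

#' @export
print.nvc_movie <- function(x, ...) {
  d <- dim(x$lumen)
  cat(sprintf("Two-channel movie: %d x %d px, %d frames at %.2f Hz (px %.2f um)\n",
              d[1], d[2], d[3], x$frame_rate, x$px))
  cat(sprintf("  %d calcium ROI(s), vessel diameter %.2g-%.2g um\n",
              ncol(x$roi_traces), min(x$diameter), max(x$diameter)))
  invisible(x)
}

#' Synthetic 3D vascular volume
#'
#' Renders a set of cylindrical vessel segments into a binary voxel
#' volume, either from an explicit segment list or by adding random
#' segments (uniform random chords) until a target capillary density is
#' reached; the final segment is trimmed so the true centerline density
#' matches the target closely.
#'
#' @param shape Volume dimensions in voxels, `c(nx, ny, nz)`.
#' @param voxel_size Voxel edge, um.
#' @param segments Optional list of segments, each
#'   `list(p1 = c(x, y, z), p2 = c(x, y, z), radius = r)` in um.
#' @param target_density Target centerline density, m of vessel per mm^3
#'   (used when `segments` is `NULL`).
#' @param radius_range Radii of random segments, um.
#' @param seed Integer seed.
#' @return Class `vascular_volume`: binary `voxels` array, `voxel_size`,
#'   segment list and `truth` (total centerline length um, density m/mm^3).
#' @export
#' @examples
#' v <- make_volume(shape = c(60, 60, 60), voxel_size = 1,
#'                  target_density = 400, seed = 2)
#' v$truth$density
make_volume <- function(shape = c(100, 100, 100), voxel_size = 1,
                        segments = NULL, target_density = NULL,
                        radius_range = c(2, 3), seed = 1) {
  stopifnot(length(shape) == 3, all(shape >= 4), voxel_size > 0)
  ext <- shape * voxel_size
  vol_um3 <- prod(ext)
  if (is.null(segments)) {
    if (is.null(target_density) || target_density <= 0)
      stop("provide segments or a positive target_density")
    # m/mm^3 == um of length per um^3 x 1e3; target length in um:
    target_len <- target_density * 1e-3 * vol_um3
    set.seed(seed)
    segments <- list(); total <- 0; tries <- 0L
    while (total < target_len) {
      tries <- tries + 1L
      if (tries > 20000L)
        stop("cannot reach target density ", target_density,
             " with non-overlapping chords in this volume")
      # full chords through the volume: a capillary entering the imaged
      # stack continues to its far side, as in vivo
      p0 <- stats::runif(3, 0, ext)
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      tmin <- -Inf; tmax <- Inf
      for (a in 1:3) {
        ts <- sort(c((0 - p0[a]) / dir[a], (ext[a] - p0[a]) / dir[a]))
        tmin <- max(tmin, ts[1]); tmax <- min(tmax, ts[2])
      }
      if (!is.finite(tmin) || !is.finite(tmax) || tmax <= tmin) next
      p1 <- p0 + tmin * dir; p2 <- p0 + tmax * dir
      len <- sqrt(sum((p2 - p1)^2))
      if (len < voxel_size) next
      rad <- stats::runif(1, radius_range[1], radius_range[2])
      # vessels running along a stack face are only half-imaged and have
      # no recoverable centerline; keep chords that cross the faces
      # rather than hug them (the ends necessarily touch a face, so only
      # the middle of the chord is examined)
      tts <- seq(0.1, 0.9, length.out = 64)
      pp <- outer(tts, p2 - p1) + rep(p1, each = 64)
      dface <- pmin(pp[, 1], ext[1] - pp[, 1], pp[, 2], ext[2] - pp[, 2],
                    pp[, 3], ext[3] - pp[, 3])
      if (min(dface) < rad) next
      # capillaries do not share lumens: reject chords running closer to
      # an existing segment than the sum of radii (crossings stay allowed
      # only as near-perpendicular contacts are rare under this rule)
      too_close <- FALSE
      for (sg in segments) {
        if (.seg_seg_dist(p1, p2, sg$p1, sg$p2) < 0.8 * (rad + sg$radius)) {
          too_close <- TRUE; break
        }
      }
      if (too_close) next
      if (total + len > target_len) {  # trim to land on the target
        keep <- (target_len - total) / len
        p2 <- p1 + (p2 - p1) * keep
        len <- target_len - total
      }
      segments <- c(segments, list(list(p1 = p1, p2 = p2, radius = rad)))
      total <- total + len
    }
  }
  if (!length(segments)) stop("empty segment list")
  for (s in segments) {
    if (s$radius <= 0) stop("segment radii must be positive")
    if (any(s$p1 < -1e-9) || any(s$p2 < -1e-9) ||
        any(s$p1 > ext + 1e-9) || any(s$p2 > ext + 1e-9))
      stop("segments must lie inside the volume")
  }
  # paint each segment as a capsule: union of balls of the segment radius
  # centered at closely spaced sample points along the axis (spacing a
  # quarter voxel, so the union is the cylinder to well below voxel
  # precision); only local voxel boxes are touched
  vox <- array(FALSE, shape)
  total_len <- 0
  for (s in segments) {
    p1 <- s$p1; p2 <- s$p2; r <- s$radius
    len <- sqrt(sum((p2 - p1)^2))
    total_len <- total_len + len
    n_samp <- max(2L, ceiling(len / (0.25 * voxel_size)) + 1L)
    ts <- seq(0, 1, length.out = n_samp)
    rv <- ceiling(r / voxel_size) + 1L
    og <- as.matrix(expand.grid(-rv:rv, -rv:rv, -rv:rv))
    og <- og[rowSums(og^2) <= (rv + 1)^2, , drop = FALSE]
    for (j in seq_len(n_samp)) {
      p <- p1 + ts[j] * (p2 - p1)
      i0 <- round(p / voxel_size + 0.5)
      cand <- sweep(og, 2, i0, `+`)
      ok <- cand[, 1] >= 1 & cand[, 1] <= shape[1] &
        cand[, 2] >= 1 & cand[, 2] <= shape[2] &
        cand[, 3] >= 1 & cand[, 3] <= shape[3]
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) next
      cc <- sweep((cand - 0.5) * voxel_size, 2, p)
      inside <- rowSums(cc^2) <= r^2
      if (any(inside)) vox[cand[inside, , drop = FALSE]] <- TRUE
    }
  }
  structure(list(voxels = vox, voxel_size = voxel_size, segments = segments,
                 truth = list(total_length = total_len,
                              density = total_len / vol_um3 * 1e3,  # m/mm^3
                              seed = seed)),
            class = "vascular_volume")
}

#' @export
print.vascular_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Vascular volume: %d x %d x %d voxels (%.2g um), %d segments\n",
              d[1], d[2], d[3], x$voxel_size, length(x$segments)))
  cat(sprintf("  true centerline length %.4g um (density %.4g m/mm^3)\n",
              x$truth$total_length, x$truth$density))
  invisible(x)
}

#' Synthetic combined laser-doppler/spectroscopy (oxy-CBF probe) session
#'
#' Generates coupled 40 Hz CBF, HbO and Hbr traces with metabolic (CMRO2)
#' events, locomotion bouts and stimulus windows. An event with gain `g`
#' multiplies CBF by `1 + g k(t)` (alpha-function kernel peaking at 1),
#' while total haemoglobin rises by `nvc_gain * g k(t)` at constant
#' Hbr/Hbt, so the derived CMRO2 = CBF x Hbr/Hbt shows a fractional peak
#' of exactly `g` and the Hbt excursion per unit CMRO2 equals `nvc_gain`.
#'
#' @param duration Session length, s.
#' @param rate Sampling rate, Hz.
#' @param baselines Named list with `CBF`, `HbO`, `Hbr` baseline levels.
#' @param event_times CMRO2 event times, s.
#' @param event_gain Fractional CMRO2 peak amplitude per event.
#' @param nvc_gain Hbt excursion per unit CMRO2 excursion.
#' @param kernel_peak Time-to-peak of the event kernel, s.
#' @param locomotion_bouts List of `c(start, duration)` s.
#' @param stimulus_windows List of `c(start, duration)` s.
#' @param locomotion_speed Speed during bouts, cm/s.
#' @param noise_sd Multiplicative noise SD (fraction of baseline).
#' @param seed Integer seed.
#' @return A `hemo_trace` object (see [load_hemo()]) with a `truth`
#'   attribute.
#' @export
make_hemo <- function(duration = 120, rate = 40,
                      baselines = list(CBF = 100, HbO = 60, Hbr = 40),
                      event_times = numeric(0), event_gain = 0.2,
                      nvc_gain = 0.3, kernel_peak = 1,
                      locomotion_bouts = list(), stimulus_windows = list(),
                      locomotion_speed = 5, noise_sd = 0, seed = 1) {
  stopifnot(duration > 0, rate > 0)
  n <- floor(duration * rate)
  tt <- (seq_len(n) - 1) / rate
  if (length(locomotion_bouts) > 1) {
    iv <- t(vapply(locomotion_bouts, function(b) c(b[1], b[1] + b[2]),
                   numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop("overlapping locomotion bouts")
  }
  gains <- rep_len(event_gain, length(event_times))
  kern <- function(t0) {
    s <- pmax(0, tt - t0) / kernel_peak
    s * exp(1 - s)
  }
  ev <- rep(0, n)
  for (i in seq_along(event_times)) ev <- ev + gains[i] * kern(event_times[i])
  Hbt0 <- baselines$HbO + baselines$Hbr
  ratio0 <- baselines$Hbr / Hbt0
  CBF <- baselines$CBF * (1 + ev)
  Hbt <- Hbt0 * (1 + nvc_gain * ev)
  Hbr <- ratio0 * Hbt
  HbO <- Hbt - Hbr
  speed_ch <- 0.2 * CBF / baselines$CBF  # doppler speed, a.u.
  locomotion <- rep(0, n)
  for (b in locomotion_bouts)
    locomotion[tt >= b[1] & tt < b[1] + b[2]] <- locomotion_speed
  stimulus <- rep(FALSE, n)
  for (w in stimulus_windows) stimulus[tt >= w[1] & tt < w[1] + w[2]] <- TRUE
  if (noise_sd > 0) {
    set.seed(seed)
    CBF <- CBF * (1 + stats::rnorm(n, sd = noise_sd))
    HbO <- pmax(0, HbO * (1 + stats::rnorm(n, sd = noise_sd)))
    Hbr <- pmax(0, Hbr * (1 + stats::rnorm(n, sd = noise_sd)))
  }
  h <- data.frame(t = tt, flux = CBF, speed = speed_ch, HbO = HbO,
                  Hbr = Hbr, locomotion = locomotion, stimulus = stimulus)
  structure(list(data = h, rate = rate,
                 truth = list(event_times = event_times, gains = gains,
                              nvc_gain = nvc_gain, baselines = baselines,
                              cmro2_baseline = baselines$CBF * ratio0,
                              seed = seed)),
            class = "hemo_trace")
}

#' @export
print.hemo_trace <- function(x, ...) {
  cat(sprintf("Oxy-CBF probe trace: %.1f s at %g Hz (%d samples)\n",
              nrow(x$data) / x$rate, x$rate, nrow(x$data)))
  cat("  channels:", paste(setdiff(names(x$data), "t"), collapse = ", "),
      "\n")
  invisible(x)
}
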