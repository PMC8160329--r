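#' Block series container
#'
#' Per-block estimates extracted from a line-scan kymograph (velocity,
#' haematocrit or flux), with block centers in seconds and a per-block
#' quality flag.
#'
#' @param t Block center times, s.
#' @param value Estimates.
#' @param quality Logical, `TRUE` where the block is informative.
#' @param block_len,stride Block length and stride, s.
#' @param kind Label, e.g. `"velocity"`.
#' @return An object of class `block_series`.
#' @keywords internal
block_series <- function(t, value, quality, block_len, stride, kind) {
  structure(list(t = t, value = value, quality = quality,
                 block_len = block_len, stride = stride, kind = kind),
            class = "block_series")
}

#' @export
print.block_series <- function(x, ...) {
  cat(sprintf("Block series (%s): %d blocks of %.0f ms, stride %.0f ms\n",
              x$kind, length(x$t), 1000 * x$block_len, 1000 * x$stride))
  good <- x$value[x$quality]
  if (length(good))
    cat(sprintf("  good blocks %d/%d, median %.4g\n",
                length(good), length(x$t), stats::median(good)))
  invisible(x)
}

#' @export
as.data.frame.block_series <- function(x, ...) {
  data.frame(t = x$t, value = x$value, quality = x$quality)
}

# Block index helper: start lines of successive blocks.
.block_starts <- function(n_lines, nb, stride_lines) {
  s <- seq(1L, n_lines - nb + 1L, by = stride_lines)
  if (!length(s)) stop("recording shorter than one block")
  s
}

# Variance of the stripe-direction projection at slope s (columns/line).
# The block is sampled bilinearly along candidate stripe lines
# col = q0 + s * line (half-line, half-pixel steps); aligned stripes give
# projection means with maximal variance across offsets q0. Continuous
# resampling in both coordinates avoids pixel-grid resonance at integer
# slopes, and a coverage-weighted variance keeps fast stripes (which cross
# the segment in fewer lines than the block holds) comparable.
.proj_variance <- function(block, s, dq = 0.5) {
  nl <- nrow(block); nc <- ncol(block)
  tt <- seq(0, nl - 1, by = 0.5)
  lo <- 1 - max(0, s * (nl - 1))
  hi <- nc - min(0, s * (nl - 1))
  q0 <- seq(lo, hi, by = dq)
  C <- outer(s * tt, q0, `+`)
  R <- tt + 1
  valid <- C >= 1 & C <= nc
  Cc <- pmin(pmax(C, 1), nc - 1e-9)
  c0 <- floor(Cc); fc <- Cc - c0
  r0 <- pmin(floor(R), nl - 1L); fr <- R - r0
  i00 <- (c0 - 1) * nl + r0        # img[r0, c0] as linear index
  v <- (1 - fr) * ((1 - fc) * block[i00] + fc * block[i00 + nl]) +
    fr * ((1 - fc) * block[i00 + 1] + fc * block[i00 + nl + 1])
  v[!valid] <- 0
  cnt <- .colSums(valid, nrow(C), ncol(C))
  keep <- cnt >= 0.5 * max(cnt) & cnt >= 4
  if (sum(keep) < 4) return(0)
  mu <- .colSums(v, nrow(C), ncol(C))[keep] / cnt[keep]
  w <- cnt[keep]
  wm <- sum(w * mu) / sum(w)
  sum(w * (mu - wm)^2) / sum(w)
}

#' RBC velocity from a line-scan kymograph
#'
#' Estimates red blood cell speed per time block from the angle of the
#' dark shadows RBCs cast on the bright lumen. For each block the stripe
#' slope (columns advanced per scan line) is found by maximizing the
#' variance of the image projected along candidate stripe directions
#' (a Radon-style rotation search), with golden-section refinement;
#' velocity is `px / dt_line` times the slope, signed by travel direction.
#'
#' @param k A `kymograph` (see [make_linescan()], [load_image()]).
#' @param block_len Block length, s.
#' @param overlap Overlap between consecutive blocks, s (stride =
#'   `block_len - overlap`).
#' @param max_speed Largest speed searched, um/s.
#' @param quality_ratio Blocks whose best-angle variance is less than this
#'   multiple of the median variance over angles are flagged low-quality.
#' @return A `block_series` of signed velocities, um/s.
#' @export
#' @examples
#' k <- make_linescan(velocity = 500, flux = 80, hematocrit = 0.3,
#'                    duration = 0.25, seed = 1)
#' v <- estimate_velocity(k)
#' stats::median(v$value[v$quality])
estimate_velocity <- function(k, block_len = 0.040, overlap = 0.010,
                              max_speed = 5000, quality_ratio = 1.2) {
  stopifnot(inherits(k, "kymograph"), overlap < block_len)
  if (is.null(k$segments$along)) stop("kymograph has no along-vessel segment")
  img <- k$intensity[, k$segments$along[1]:k$segments$along[2], drop = FALSE]
  nb <- round(block_len / k$dt_line)
  stride_lines <- max(1L, round((block_len - overlap) / k$dt_line))
  starts <- .block_starts(nrow(img), nb, stride_lines)
  smax <- max_speed * k$dt_line / k$px
  # candidate slopes: linear near zero, geometric (5% steps) beyond, both
  # signs -- matches the roughly constant *relative* width of the
  # projection-variance peak
  geo <- 0.2 * 1.05^(0:ceiling(log(smax / 0.2) / log(1.05)))
  geo <- geo[geo <= smax]
  slopes <- sort(unique(c(-geo, seq(-0.2, 0.2, by = 0.05), geo)))
  est <- vapply(starts, function(s0) {
    block <- img[s0:(s0 + nb - 1L), , drop = FALSE]
    if (diff(range(block)) == 0) return(c(NA_real_, 0))
    vv <- vapply(slopes, function(s) .proj_variance(block, s), numeric(1))
    i_best <- which.max(vv)
    lo <- slopes[max(1L, i_best - 1L)]
    hi <- slopes[min(length(slopes), i_best + 1L)]
    opt <- stats::optimize(function(s) .proj_variance(block, s),
                           c(lo, hi), maximum = TRUE,
                           tol = max(1e-4, 0.002 * abs(slopes[i_best])))
    ratio <- opt$objective / stats::median(vv)
    c(opt$maximum, ratio)
  }, numeric(2))
  slope <- est[1, ]
  velocity <- slope * k$px / k$dt_line
  quality <- is.finite(est[2, ]) & est[2, ] >= quality_ratio
  block_series(t = (starts - 1 + nb / 2) * k$dt_line, value = velocity,
               quality = quality, block_len = block_len,
               stride = stride_lines * k$dt_line, kind = "velocity")
}

#' RBC flux from a line-scan kymograph
#'
#' Counts red blood cells passing the center of the scanned path: the
#' along-vessel segment is binarized (Otsu threshold over the recording),
#' the intensity at the central columns is averaged into a single time
#' trace, and each connected group of dark samples is counted as one RBC
#' in the window containing its onset.
#'
#' @param k A `kymograph`.
#' @param window Counting window, s.
#' @param center_cols Number of central columns averaged.
#' @return A `block_series` of fluxes, RBC/s; windows that are entirely
#'   dark or entirely bright are flagged. The total count is attached as
#'   attribute `n_total`.
#' @export
count_flux <- function(k, window = 0.250, center_cols = 3) {
  stopifnot(inherits(k, "kymograph"))
  if (is.null(k$segments$along)) stop("kymograph has no along-vessel segment")
  img <- k$intensity[, k$segments$along[1]:k$segments$along[2], drop = FALSE]
  thr <- if (diff(range(img)) > 0) otsu_threshold(img) else min(img) - 1
  mid <- round(ncol(img) / 2)
  cols <- pmax(1L, pmin(ncol(img), mid + seq_len(center_cols) -
                          ceiling(center_cols / 2)))
  trace <- rowMeans(img[, cols, drop = FALSE])
  dark <- trace < thr
  runs <- .runs_true(dark)
  nw <- round(window / k$dt_line)
  if (nrow(img) < nw)
    stop("recording shorter than one counting window (", window, " s)")
  starts <- seq(1L, nrow(img) - nw + 1L, by = nw)
  counts <- vapply(starts, function(s0)
    sum(runs$start >= s0 & runs$start < s0 + nw), numeric(1))
  quality <- vapply(starts, function(s0) {
    d <- dark[s0:(s0 + nw - 1L)]
    any(d) != all(d) || !any(d)   # flagged only when entirely dark
  }, logical(1))
  quality <- quality & vapply(starts, function(s0)
    !all(dark[s0:(s0 + nw - 1L)]), logical(1))
  bs <- block_series(t = (starts - 1 + nw / 2) * k$dt_line,
                     value = counts / window, quality = quality,
                     block_len = window, stride = window, kind = "flux")
  attr(bs, "n_total") <- sum(runs$start <= max(starts) + nw - 1L)
  bs
}

#' Haematocrit from a line-scan kymograph
#'
#' Fraction of the binarized along-vessel segment occupied by dark (RBC)
#' pixels, per time block.
#'
#' @inheritParams estimate_velocity
#' @return A `block_series` of haematocrit fractions in \[0, 1\];
#'   degenerate (single-valued) blocks are flagged.
#' @export
estimate_hematocrit <- function(k, block_len = 0.040, overlap = 0.010) {
  stopifnot(inherits(k, "kymograph"), overlap < block_len)
  if (is.null(k$segments$along)) stop("kymograph has no along-vessel segment")
  img <- k$intensity[, k$segments$along[1]:k$segments$along[2], drop = FALSE]
  thr <- if (diff(range(img)) > 0) otsu_threshold(img) else min(img) - 1
  nb <- round(block_len / k$dt_line)
  stride_lines <- max(1L, round((block_len - overlap) / k$dt_line))
  starts <- .block_starts(nrow(img), nb, stride_lines)
  frac <- vapply(starts, function(s0)
    mean(img[s0:(s0 + nb - 1L), ] < thr), numeric(1))
  quality <- vapply(starts, function(s0)
    diff(range(img[s0:(s0 + nb - 1L), ])) > 0, logical(1))
  block_series(t = (starts - 1 + nb / 2) * k$dt_line, value = frac,
               quality = quality, block_len = block_len,
               stride = stride_lines * k$dt_line, kind = "hematocrit")
}

#' Vessel diameter from the across-vessel line-scan segment
#'
#' Full width at half maximum of the dye-filled lumen intensity profile,
#' per scan line (optionally averaged over blocks of lines), sub-pixel
#' interpolated.
#'
#' @param k A `kymograph` with an across-vessel segment.
#' @param block_lines Average the profile over this many consecutive
#'   lines before taking the FWHM (1 = per line).
#' @return A `diameter_trace`: times `t` (s), `value` (um, `NA` where the
#'   profile has no peak) and sampling `rate` (Hz).
#' @export
diameter_from_linescan <- function(k, block_lines = 1) {
  stopifnot(inherits(k, "kymograph"))
  if (is.null(k$segments$across))
    stop("kymograph has no across-vessel segment")
  img <- k$intensity[, k$segments$across[1]:k$segments$across[2],
                     drop = FALSE]
  starts <- seq(1L, nrow(img) - block_lines + 1L, by = block_lines)
  vals <- vapply(starts, function(s0)
    fwhm(colMeans(img[s0:(s0 + block_lines - 1L), , drop = FALSE]),
         px = k$px), numeric(1))
  diameter_trace(t = (starts - 1 + block_lines / 2) * k$dt_line,
                 value = vals, rate = 1 / (block_lines * k$dt_line))
}

#' Vessel diameter time series
#'
#' @param t Sample times, s.
#' @param value Diameters, um.
#' @param rate Sampling rate, Hz.
#' @return An object of class `diameter_trace`.
#' @export
diameter_trace <- function(t, value, rate) {
  stopifnot(length(t) == length(value), rate > 0)
  structure(list(t = t, value = value, rate = rate),
            class = "diameter_trace")
}

#' @export
print.diameter_trace <- function(x, ...) {
  ok <- is.finite(x$value)
  cat(sprintf("Diameter trace: %d samples at %.3g Hz, median %.3g um (%d missing)\n",
              length(x$value), x$rate,
              stats::median(x$value[ok]), sum(!ok)))
  invisible(x)
}

#' @export
plot.diameter_trace <- function(x, ...) {
  graphics::plot(x$t, x$value, type = "l", xlab = "time (s)",
                 ylab = "diameter (um)", ...)
  invisible(x)
}
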