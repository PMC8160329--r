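#' Otsu's threshold
#'
#' Histogram-based threshold maximizing between-class variance; used to
#' binarize line-scan kymographs (bright lumen vs dark RBC shadows) and
#' smoothed vascular volumes. One threshold per recording.
#'
#' @param x Numeric vector or array of intensities.
#' @param n_bins Number of histogram bins.
#' @return Threshold value on the scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) stop("cannot threshold a constant image")
  h <- tabulate(pmin(n_bins, 1L + as.integer((x - r[1]) / diff(r) * n_bins)),
                n_bins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(r)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}

#' Full width at half maximum of an intensity profile
#'
#' The lumen diameter measure: the baseline is a low percentile of the
#' profile and the peak the maximum of a despeckled (3-point median
#' filtered) profile; the half level is their midpoint, and the two
#' crossings are located by linear interpolation for sub-pixel precision.
#'
#' @param profile Numeric vector of intensities along a line crossing the
#'   vessel.
#' @param px Spatial sampling, um/pixel.
#' @param baseline_q Percentile defining the baseline.
#' @return Width in um, or `NA` if the profile has no peak above baseline.
#' @export
fwhm <- function(profile, px = 1, baseline_q = 0.05) {
  n <- length(profile)
  if (n < 3 || all(!is.finite(profile))) return(NA_real_)
  lo <- stats::quantile(profile, baseline_q, names = FALSE, na.rm = TRUE)
  # peak: located on a 3-point median-filtered profile (robust to
  # single-pixel specks), height from a parabolic fit through the raw
  # samples so narrow peaks are not clipped
  fin <- profile
  fin[!is.finite(fin)] <- lo
  sm <- stats::runmed(fin, 3)
  ip <- which.max(sm)
  if (ip > 1 && ip < n) {
    y1 <- fin[ip - 1]; y2 <- fin[ip]; y3 <- fin[ip + 1]
    den <- y1 - 2 * y2 + y3
    hi <- if (den < 0) y2 - (y1 - y3)^2 / (8 * den) else y2
  } else hi <- sm[ip]
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) return(NA_real_)
  half <- (lo + hi) / 2
  above <- profile >= half
  if (!any(above, na.rm = TRUE)) return(NA_real_)
  idx <- which(above)
  i1 <- idx[1]; i2 <- idx[length(idx)]
  # sub-pixel left crossing
  left <- if (i1 == 1) 1 else
    i1 - (profile[i1] - half) / (profile[i1] - profile[i1 - 1])
  right <- if (i2 == n) n else
    i2 + (profile[i2] - half) / (profile[i2] - profile[i2 + 1])
  (right - left) * px
}

# Local maxima of a numeric vector with minimum prominence and minimum
# separation (in samples). Prominence of a peak: height above the higher of
# the two deepest valleys separating it from a higher peak (or the edge).
# Ties in height are broken toward the earlier peak.
.find_peaks <- function(x, min_prominence = 0, min_separation = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  # plateau tops yield several candidates; keep the first sample of each
  cand <- cand[x[cand] > x[cand - 1L]]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    # walk left until a higher sample or edge; record min on the way
    lmin <- x[i]; j <- i
    while (j > 1 && x[j - 1] <= x[i]) { j <- j - 1; lmin <- min(lmin, x[j]) }
    rmin <- x[i]; j <- i
    while (j < n && x[j + 1] <= x[i]) { j <- j + 1; rmin <- min(rmin, x[j]) }
    x[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  # enforce minimum separation, keeping higher (earlier on ties) peaks
  ord <- order(-x[keep], keep)
  sel <- integer(0)
  for (i in keep[ord]) {
    if (!length(sel) || all(abs(sel - i) >= min_separation)) sel <- c(sel, i)
  }
  sort(sel)
}

# Contiguous runs of TRUE; returns data.frame(start, end, length).
.runs_true <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values],
             length = r$lengths[r$values])
}

# Minimum distance between two 3-D line segments.
.seg_seg_dist <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-12 && e <= 1e-12) return(sqrt(sum(r * r)))
  if (a <= 1e-12) {
    s <- 0; t <- min(1, max(0, f / e))
  } else {
    c_ <- sum(d1 * r)
    if (e <= 1e-12) {
      t <- 0; s <- min(1, max(0, -c_ / a))
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > 1e-12) min(1, max(0, (b * f - c_ * e) / den)) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(1, max(0, -c_ / a)) }
      else if (t > 1) { t <- 1; s <- min(1, max(0, (b - c_) / a)) }
    }
  }
  v <- (p1 + s * d1) - (q1 + t * d2)
  sqrt(sum(v * v))
}

# Separable Gaussian smoothing along each margin of an n-D array,
# replicate-padded at the edges.
.gauss_smooth <- function(a, sigma = 1) {
  if (sigma <= 0) return(a)
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-rad, rad), sd = sigma)
  k <- k / sum(k)
  d <- dim(a)
  nd <- length(d)
  for (axis in seq_len(nd)) {
    perm <- c(axis, setdiff(seq_len(nd), axis))
    b <- aperm(a, perm)
    db <- dim(b)
    m <- matrix(b, nrow = db[1])
    mp <- rbind(m[rep(1, rad), , drop = FALSE], m,
                m[rep(db[1], rad), , drop = FALSE])
    ms <- stats::filter(mp, k, sides = 2)[(rad + 1):(rad + db[1]), ,
                                          drop = FALSE]
    b <- array(as.numeric(ms), db)
    a <- aperm(b, order(perm))
  }
  a
}
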