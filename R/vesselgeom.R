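#' Euclidean distance transform
#'
#' Exact Euclidean distance (in physical units) from every voxel to the
#' nearest `TRUE` voxel of a 2-D or 3-D mask, computed with a separable
#' exact algorithm.
#'
#' @param mask Logical matrix or 3-D array of seed voxels.
#' @param voxel_size Voxel edge, um.
#' @return Numeric array of distances (0 on the seeds); `Inf` if the mask
#'   is empty.
#' @export
distance_transform <- function(mask, voxel_size = 1) {
  d <- dim(mask)
  stopifnot(length(d) %in% c(2L, 3L))
  nz <- if (length(d) == 3L) d[3] else 1L
  out <- sqrt(.edt3d_sq(as.logical(mask), d[1], d[2], nz)) * voxel_size
  array(out, d)
}

# Binarize a volume/frame: numeric data is smoothed (Gaussian, sigma in
# voxels) and Otsu-thresholded; logical data is used as is.
.binarize <- function(a, sigma = 1) {
  if (is.logical(a)) return(a)
  sm <- .gauss_smooth(a, sigma)
  sm > otsu_threshold(sm)
}

#' Skeletonize a 3-D vascular volume
#'
#' Reduces the binarized vasculature to a one-voxel centerline by
#' topological thinning, then reads each skeleton point's vessel radius
#' off the Euclidean distance map of the foreground (distance from the
#' centerline to the nearest background voxel) and its depth below the
#' first image plane.
#'
#' @param v A `vascular_volume` ([make_volume()], [load_image()]), or a
#'   logical/numeric 3-D array.
#' @param voxel_size Voxel edge, um (ignored when `v` is a
#'   `vascular_volume`).
#' @param smooth_sigma Gaussian smoothing (voxels) before thresholding
#'   numeric volumes.
#' @return Class `vessel_skeleton`: `points` (voxel indices, 0-based in
#'   the coordinate columns of `coords_um`), `radii` (um), `depth` (um),
#'   `is_branch` (>= 3 skeleton neighbours), `length` (total centerline
#'   length, um), `dims`, `voxel_size`.
#' @export
skeletonize_volume <- function(v, voxel_size = 1, smooth_sigma = 1) {
  if (inherits(v, "vascular_volume")) {
    voxel_size <- v$voxel_size
    a <- v$voxels
  } else a <- v
  stopifnot(length(dim(a)) == 3)
  mask <- .binarize(a, smooth_sigma)
  if (!any(mask)) stop("volume has no foreground after binarization")
  d <- dim(mask)
  skel <- array(.thin3d(as.logical(mask), d[1], d[2], d[3]), d)
  pts <- which(skel, arr.ind = TRUE)
  # radius: distance from centerline to nearest background voxel
  dist_fg <- distance_transform(!mask, voxel_size)
  radii <- dist_fg[pts]
  depth <- (pts[, 3] - 1) * voxel_size
  # neighbour counts on the skeleton (26-connectivity)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  nn <- integer(nrow(pts))
  skel_idx <- which(skel)
  lin <- function(m) (m[, 3] - 1) * d[1] * d[2] + (m[, 2] - 1) * d[1] + m[, 1]
  inside <- function(m) m[, 1] >= 1 & m[, 1] <= d[1] &
    m[, 2] >= 1 & m[, 2] <= d[2] & m[, 3] >= 1 & m[, 3] <= d[3]
  edges_from <- integer(0); edges_to <- integer(0); edges_w <- numeric(0)
  pos <- integer(prod(d))
  pos[lin(pts)] <- seq_len(nrow(pts))
  for (k in seq_len(nrow(off))) {
    sh <- sweep(pts, 2, off[k, ], `+`)
    okm <- inside(sh)
    hit <- logical(nrow(pts))
    hit[okm] <- skel[sh[okm, , drop = FALSE]]
    nn <- nn + hit
    # record each undirected edge once (second half of the offset list
    # mirrors the first)
    if (k <= nrow(off) / 2) next
    w <- sqrt(sum(off[k, ]^2)) * voxel_size
    from <- which(hit)
    if (length(from)) {
      to <- pos[lin(sh[from, , drop = FALSE])]
      edges_from <- c(edges_from, from)
      edges_to <- c(edges_to, to)
      edges_w <- c(edges_w, rep(w, length(from)))
    }
  }
  total_len <- 0
  if (length(edges_from)) {
    gr <- igraph::graph_from_data_frame(
      data.frame(from = edges_from, to = edges_to, weight = edges_w),
      directed = FALSE,
      vertices = data.frame(name = seq_len(nrow(pts))))
    total_len <- .skeleton_length(igraph::mst(gr), pts * voxel_size)
  }
  structure(list(points = pts, radii = radii, depth = depth,
                 is_branch = nn >= 3L, n_neighbours = nn,
                 length = total_len, dims = d, voxel_size = voxel_size),
            class = "vessel_skeleton")
}

# Total centerline length of a skeleton spanning tree: walk every
# degree-2 chain between junction/end nodes and sum chord lengths over a
# subsampled polyline (every `step`-th voxel), which suppresses the
# voxel-scale jitter of the thinned line. Short junction-to-endpoint
# chains (under `spur` voxels) are thinning spurs at vessel contacts and
# are not counted.
.skeleton_length <- function(tree, coords, step = 5, spur = 5) {
  deg <- igraph::degree(tree)
  adj <- igraph::as_adj_list(tree)
  n <- length(deg)
  visited_edge <- new.env(hash = TRUE)
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  chain_len <- function(path_idx) {
    if (length(path_idx) < 2) return(0)
    sub <- unique(c(seq(1, length(path_idx), by = step), length(path_idx)))
    p <- coords[path_idx[sub], , drop = FALSE]
    sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                        p[-nrow(p), , drop = FALSE])^2)))
  }
  total <- 0
  starts <- which(deg != 2)
  if (!length(starts)) starts <- which(deg > 0)[1]  # a pure cycle-free chain
  for (s in starts) {
    for (nb in as.integer(adj[[s]])) {
      if (!is.null(visited_edge[[ekey(s, nb)]])) next
      path <- c(s, nb)
      visited_edge[[ekey(s, nb)]] <- TRUE
      prev <- s; cur <- nb
      while (deg[cur] == 2) {
        nxt <- setdiff(as.integer(adj[[cur]]), prev)
        if (!length(nxt)) break
        visited_edge[[ekey(cur, nxt[1])]] <- TRUE
        path <- c(path, nxt[1])
        prev <- cur; cur <- nxt[1]
      }
      a <- path[1]; b <- path[length(path)]
      is_spur <- length(path) < spur &&
        ((deg[a] >= 3 && deg[b] == 1) || (deg[a] == 1 && deg[b] >= 3))
      if (!is_spur) total <- total + chain_len(path)
    }
  }
  total
}

#' @export
print.vessel_skeleton <- function(x, ...) {
  cat(sprintf("Vessel skeleton: %d points, total length %.4g um, %d branch points\n",
              nrow(x$points), x$length, sum(x$is_branch)))
  cat(sprintf("  radii %.2g-%.2g um, depth 0-%.4g um\n",
              min(x$radii), max(x$radii), max(x$depth)))
  invisible(x)
}

#' Capillary density of a skeletonized volume
#'
#' Total centerline length divided by the imaged tissue volume.
#'
#' @param s A `vessel_skeleton`.
#' @param unit `"m_per_mm3"` (default) or `"um_per_um3"`.
#' @return Density in the requested unit.
#' @export
capillary_density <- function(s, unit = c("m_per_mm3", "um_per_um3")) {
  unit <- match.arg(unit)
  vol_um3 <- prod(s$dims) * s$voxel_size^3
  if (vol_um3 <= 0) stop("zero tissue volume")
  dens <- s$length / vol_um3   # um per um^3
  if (unit == "m_per_mm3") dens * 1e3 else dens
}

#' Vessel diameter by depth
#'
#' Per-depth-bin mean vessel diameter (twice the skeleton-point radius)
#' with its standard error; half-open bins `[low, high)`.
#'
#' @param s A `vessel_skeleton`.
#' @param bin Bin width, um.
#' @return Data.frame: `depth_lo`, `depth_hi`, `n`, `mean_diameter`,
#'   `sem`; empty bins carry `NA`, not zero.
#' @export
diameter_depth_profile <- function(s, bin = 10) {
  stopifnot(bin > 0)
  dmax <- max(s$depth)
  edges <- seq(0, dmax + bin, by = bin)
  cut_idx <- findInterval(s$depth, edges, rightmost.closed = FALSE)
  diam <- 2 * s$radii
  out <- do.call(rbind, lapply(seq_len(length(edges) - 1), function(i) {
    vals <- diam[cut_idx == i]
    data.frame(depth_lo = edges[i], depth_hi = edges[i + 1],
               n = length(vals),
               mean_diameter = if (length(vals)) mean(vals) else NA_real_,
               sem = if (length(vals) > 1)
                 stats::sd(vals) / sqrt(length(vals)) else NA_real_)
  }))
  out[out$depth_lo <= dmax, ]
}

#' Tissue-to-vessel distance distribution
#'
#' Exact Euclidean distance of every tissue (background) voxel to the
#' nearest vessel voxel, histogrammed over `n` non-overlapping substacks
#' placed at seeded uniform random positions, with the 50th-95th centile
#' distances of the pooled distribution.
#'
#' @param v A `vascular_volume` or logical/numeric 3-D array.
#' @param voxel_size Voxel edge, um (ignored for `vascular_volume`).
#' @param substack Substack edge length, um.
#' @param n Number of substacks.
#' @param seed Integer seed for substack placement.
#' @param bin_width Histogram bin width, um.
#' @param centiles Centile ranks to report.
#' @param smooth_sigma Smoothing before binarization (numeric input).
#' @return Class `distance_distribution`: `bin_edges`, `mean_counts`,
#'   `sd_counts` (across substacks), `centiles` (um, named by rank),
#'   `n_substacks`.
#' @export
tissue_distance_distribution <- function(v, voxel_size = 1, substack = 100,
                                         n = 5, seed = 1, bin_width = 1,
                                         centiles = c(50, 60, 70, 80, 90, 95),
                                         smooth_sigma = 1) {
  if (inherits(v, "vascular_volume")) {
    voxel_size <- v$voxel_size
    a <- v$voxels
  } else a <- v
  stopifnot(length(dim(a)) == 3)
  mask <- .binarize(a, smooth_sigma)
  d <- dim(a)
  s_vox <- round(substack / voxel_size)
  if (any(d < s_vox))
    stop("volume smaller than the requested substack in at least one axis")
  dist <- distance_transform(mask, voxel_size)
  # seeded placement of non-overlapping substacks: sample cells of the
  # coarse partition into substack-sized blocks, jittered by whatever
  # slack the volume leaves
  set.seed(seed)
  kdim <- d %/% s_vox
  if (prod(kdim) < n)
    stop("cannot place ", n, " non-overlapping substacks of ", substack,
         " um in this volume")
  cells <- as.matrix(expand.grid(seq_len(kdim[1]), seq_len(kdim[2]),
                                 seq_len(kdim[3])))
  pick <- cells[sample.int(nrow(cells), n), , drop = FALSE]
  slack <- d - kdim * s_vox
  jit <- vapply(1:3, function(a_) sample.int(slack[a_] + 1L, 1L) - 1L,
                integer(1))
  placed <- sweep((pick - 1L) * s_vox + 1L, 2, jit, `+`)
  dists <- lapply(seq_len(nrow(placed)), function(i) {
    o <- placed[i, ]
    sub <- dist[o[1]:(o[1] + s_vox - 1), o[2]:(o[2] + s_vox - 1),
                o[3]:(o[3] + s_vox - 1)]
    subm <- mask[o[1]:(o[1] + s_vox - 1), o[2]:(o[2] + s_vox - 1),
                 o[3]:(o[3] + s_vox - 1)]
    sub[!subm]   # background voxels only
  })
  max_d <- max(vapply(dists, function(x) if (length(x)) max(x) else 0,
                      numeric(1)))
  edges <- seq(0, max_d + bin_width, by = bin_width)
  counts <- t(vapply(dists, function(x)
    graphics::hist(x, breaks = edges, plot = FALSE)$counts,
    numeric(length(edges) - 1)))
  pooled <- unlist(dists)
  cent <- stats::quantile(pooled, centiles / 100, names = FALSE)
  names(cent) <- paste0("p", centiles)
  structure(list(bin_edges = edges,
                 mean_counts = colMeans(counts),
                 sd_counts = apply(counts, 2, stats::sd),
                 centiles = cent, n_substacks = n,
                 substack_origins = placed, bin_width = bin_width),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("Tissue-to-vessel distance distribution (%d substacks)\n",
              x$n_substacks))
  cat("  centiles (um):",
      paste(names(x$centiles), round(x$centiles, 2), collapse = ", "),
      "\n")
  invisible(x)
}

# Order the pixels of a (nearly) path-like 2-D skeleton by walking from
# the endpoint farthest along the structure.
.order_skeleton_path <- function(pix) {
  n <- nrow(pix)
  if (n <= 2) return(seq_len(n))
  dmat <- as.matrix(stats::dist(pix))
  adj <- dmat > 0 & dmat < 1.9
  deg <- rowSums(adj)
  start <- which(deg == 1)[1]
  if (is.na(start)) start <- 1L
  order_idx <- integer(0)
  visited <- logical(n)
  cur <- start
  repeat {
    order_idx <- c(order_idx, cur)
    visited[cur] <- TRUE
    nxt <- which(adj[cur, ] & !visited)
    if (!length(nxt)) break
    cur <- nxt[which.min(dmat[cur, nxt])]
  }
  order_idx
}

#' Per-frame vessel diameter from an XY movie
#'
#' For every frame of the lumen channel: the vessel is segmented
#' (threshold at half the 95th-percentile intensity), reduced to a 2-D
#' skeleton, and the intensity profile of a line perpendicular to the
#' local vessel axis is sampled (bilinear interpolation) at every other
#' skeleton pixel, each profile averaged with a 5-pixel running window
#' along the axis; the diameter is the mean FWHM of these profiles.
#'
#' @param m An `nvc_movie` ([make_movie()], [load_image()]).
#' @param every Sample profiles at every `every`-th skeleton pixel.
#' @param avg_window Running window along the axis, in skeleton pixels.
#' @param profile_halflength Half length of the perpendicular profile,
#'   um; `NULL` chooses 3x the largest mask radius.
#' @return A `diameter_trace` (per-frame mean FWHM, um); per-position
#'   FWHM values are in attribute `per_position`.
#' @export
frame_diameter_trace <- function(m, every = 2, avg_window = 5,
                                 profile_halflength = NULL) {
  stopifnot(inherits(m, "nvc_movie"))
  lum <- m$lumen
  nf <- dim(lum)[3]
  px <- m$px
  vals <- rep(NA_real_, nf)
  per_pos <- vector("list", nf)
  for (fi in seq_len(nf)) {
    fr <- lum[, , fi]
    thr <- 0.5 * stats::quantile(fr, 0.95, names = FALSE)
    mask <- fr > thr
    if (!any(mask)) next
    d <- dim(mask)
    skel <- matrix(.thin2d(as.logical(mask), d[1], d[2]), d[1], d[2])
    pix <- which(skel, arr.ind = TRUE)
    if (nrow(pix) < 3) next
    ord <- .order_skeleton_path(pix)
    pix <- pix[ord, , drop = FALSE]
    if (is.null(profile_halflength)) {
      rmax <- max(distance_transform(!mask, px))
      Lh <- max(3 * rmax, 10 * px)
    } else Lh <- profile_halflength
    steps <- seq(-Lh, Lh, by = px / 2)
    npix <- nrow(pix)
    # local tangent by central differences along the ordered path
    span <- 3L
    profiles <- matrix(NA_real_, npix, length(steps))
    for (j in seq_len(npix)) {
      a <- pix[max(1, j - span), ]; b <- pix[min(npix, j + span), ]
      tg <- b - a
      nt <- sqrt(sum(tg^2))
      if (nt == 0) next
      pv <- c(-tg[2], tg[1]) / nt
      ry <- pix[j, 1] + pv[1] * steps / px
      cx <- pix[j, 2] + pv[2] * steps / px
      ok <- ry >= 1 & ry <= d[1] - 1e-9 & cx >= 1 & cx <= d[2] - 1e-9
      r0 <- floor(ry); c0 <- floor(cx)
      r0 <- pmin(pmax(r0, 1), d[1] - 1); c0 <- pmin(pmax(c0, 1), d[2] - 1)
      frr <- ry - r0; fcc <- cx - c0
      i00 <- (c0 - 1) * d[1] + r0
      val <- (1 - frr) * ((1 - fcc) * fr[i00] + fcc * fr[i00 + d[1]]) +
        frr * ((1 - fcc) * fr[i00 + 1] + fcc * fr[i00 + d[1] + 1])
      val[!ok] <- NA
      profiles[j, ] <- val
    }
    # running average along the axis, then FWHM at every other position
    half <- floor(avg_window / 2)
    use <- seq(1 + half, npix - half, by = every)
    fw <- vapply(use, function(j) {
      prof <- colMeans(profiles[(j - half):(j + half), , drop = FALSE],
                       na.rm = TRUE)
      fwhm(prof, px = px / 2)
    }, numeric(1))
    fw <- fw[is.finite(fw)]
    if (length(fw)) {
      vals[fi] <- mean(fw)
      per_pos[[fi]] <- fw
    }
  }
  out <- diameter_trace(t = m$t, value = vals, rate = m$frame_rate)
  attr(out, "per_position") <- per_pos
  out
}
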