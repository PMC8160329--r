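#' Write an image object to TIFF with a JSON sidecar
#'
#' Kymographs are written as single-page TIFF, movies as multi-page TIFF
#' (pages = channel-major frames), volumes as multi-page TIFF (pages =
#' z slices), all 32-bit float, with acquisition metadata (pixel size,
#' timing, channel roles, segment ranges) in `<path>.json`.
#'
#' @param x A `kymograph`, `nvc_movie` or `vascular_volume`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
save_image <- function(x, path) {
  meta <- list()
  if (inherits(x, "kymograph")) {
    pages <- list(x$intensity)
    meta <- list(type = "kymograph", dt_line = x$dt_line, px = x$px,
                 segments = x$segments)
  } else if (inherits(x, "nvc_movie")) {
    nf <- dim(x$lumen)[3]
    pages <- vector("list", 2 * nf)
    for (i in seq_len(nf)) {
      pages[[2 * i - 1]] <- x$calcium[, , i]
      pages[[2 * i]] <- x$lumen[, , i]
    }
    meta <- list(type = "movie", frame_rate = x$frame_rate, px = x$px,
                 channels = c("calcium", "lumen"), n_frames = nf)
  } else if (inherits(x, "vascular_volume")) {
    nz <- dim(x$voxels)[3]
    pages <- lapply(seq_len(nz), function(i) x$voxels[, , i] * 1)
    meta <- list(type = "volume", voxel_size = x$voxel_size,
                 dims = dim(x$voxels))
  } else stop("unsupported object")
  pages <- lapply(pages, function(p) pmin(pmax(p, 0), 1))  # TIFF range
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) stop("missing JSON sidecar: ", sc)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

.require_fields <- function(meta, fields) {
  miss <- setdiff(fields, names(meta))
  if (length(miss))
    stop("sidecar is missing required field(s): ",
         paste(miss, collapse = ", "))
}

#' Load a TIFF image written by [save_image()]
#'
#' Reconstructs the typed object (kymograph, movie or volume) from the
#' TIFF pages and the JSON sidecar; errors name any missing sidecar
#' field.
#'
#' @param path TIFF path (sidecar at `<path>.json`).
#' @return A `kymograph`, `nvc_movie` or `vascular_volume`.
#' @export
load_image <- function(path) {
  meta <- .sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (identical(meta$type, "kymograph")) {
    .require_fields(meta, c("dt_line", "px", "segments"))
    structure(list(intensity = pages[[1]], dt_line = meta$dt_line,
                   px = meta$px,
                   segments = lapply(meta$segments, as.integer),
                   truth = NULL),
              class = "kymograph")
  } else if (identical(meta$type, "movie")) {
    .require_fields(meta, c("frame_rate", "px", "channels", "n_frames"))
    nf <- meta$n_frames
    d <- dim(pages[[1]])
    calc <- array(0, c(d, nf)); lum <- array(0, c(d, nf))
    for (i in seq_len(nf)) {
      calc[, , i] <- pages[[2 * i - 1]]
      lum[, , i] <- pages[[2 * i]]
    }
    structure(list(lumen = lum, calcium = calc,
                   frame_rate = meta$frame_rate, px = meta$px,
                   t = (seq_len(nf) - 1) / meta$frame_rate,
                   roi_traces = NULL, diameter = NULL, truth = NULL),
              class = "nvc_movie")
  } else if (identical(meta$type, "volume")) {
    .require_fields(meta, c("voxel_size", "dims"))
    nz <- length(pages)
    a <- array(0, c(dim(pages[[1]]), nz))
    for (i in seq_len(nz)) a[, , i] <- pages[[i]]
    structure(list(voxels = a > 0.5, voxel_size = meta$voxel_size,
                   segments = NULL, truth = NULL),
              class = "vascular_volume")
  } else stop("unknown or missing sidecar 'type'")
}

#' Write an oxy-CBF probe trace to CSV
#'
#' @param h A `hemo_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_hemo <- function(h, path) {
  stopifnot(inherits(h, "hemo_trace"))
  utils::write.csv(h$data, path, row.names = FALSE)
  invisible(path)
}

#' Load an oxy-CBF probe recording from CSV
#'
#' Expects columns `t`, `flux`, `speed`, `HbO`, `Hbr`, `locomotion`,
#' `stimulus` (one row per sample at a nominally constant rate). Errors
#' name missing columns and reject non-monotone time; irregular sampling
#' is either linearly resampled onto the nominal grid or rejected.
#'
#' @param path CSV path.
#' @param resample Resample irregular time bases onto a regular grid
#'   (`TRUE`) or fail (`FALSE`).
#' @param tol Relative tolerance on sample-interval jitter before the
#'   recording counts as irregular.
#' @return A `hemo_trace`.
#' @export
load_hemo <- function(path, resample = FALSE, tol = 0.01) {
  d <- utils::read.csv(path)
  need <- c("t", "flux", "speed", "HbO", "Hbr", "locomotion", "stimulus")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("hemo CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (any(diff(d$t) <= 0)) stop("time column must be strictly increasing")
  dts <- diff(d$t)
  dt0 <- stats::median(dts)
  irregular <- any(abs(dts - dt0) > tol * dt0)
  if (irregular) {
    if (!resample)
      stop("irregular sampling detected; rerun with resample = TRUE")
    tt <- seq(d$t[1], d$t[nrow(d)], by = dt0)
    num <- setdiff(need, c("t", "stimulus"))
    out <- data.frame(t = tt)
    for (cn in num) out[[cn]] <- stats::approx(d$t, d[[cn]], xout = tt)$y
    out$stimulus <- stats::approx(d$t, as.numeric(d$stimulus), xout = tt,
                                  method = "constant", rule = 2)$y > 0.5
    d <- out
  }
  d$stimulus <- as.logical(d$stimulus)
  structure(list(data = d, rate = 1 / dt0, truth = NULL),
            class = "hemo_trace")
}
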