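#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages on synthetic or on-disk inputs and
#' writes CSV/JSON outputs plus a provenance log (package version, seed,
#' configuration hash) to the output directory. A stage failure is
#' logged and does not discard the results of completed stages.
#'
#' Supported stages and their inputs:
#' \describe{
#'   \item{`linescan`}{`kymograph` path (TIFF + sidecar) or a list of
#'     [make_linescan()] arguments under `cfg$linescan$truth`; writes
#'     per-block velocity/flux/haematocrit and the diameter trace.}
#'   \item{`movie`}{movie path or [make_movie()] arguments; writes the
#'     per-frame diameter trace and detected calcium events.}
#'   \item{`volume`}{volume path or [make_volume()] arguments; writes
#'     skeleton summary, capillary density, diameter-by-depth table and
#'     the tissue-distance distribution.}
#'   \item{`hemo`}{CSV path or [make_hemo()] arguments; writes resting
#'     baselines and metabolic events.}
#'   \item{`oxygen`}{[oxygen_model()] arguments (plus optional
#'     `calibrate_target`); writes the steady profile and midpoint
#'     metrics.}
#' }
#'
#' @param cfg Nested list: `seed`, `outdir`, `stages` (character vector),
#'   and one entry per stage as described above.
#' @return Named list of stage results (errors as `try-error`),
#'   invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$outdir))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  stages <- cfg$stages
  cfg_path <- file.path(cfg$outdir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  # provenance hash covers the analysis-relevant configuration, not where
  # it is written, so identical runs match across output directories
  hcfg <- cfg; hcfg$outdir <- NULL
  htmp <- tempfile(fileext = ".json")
  jsonlite::write_json(hcfg, htmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  cfg_hash <- unname(tools::md5sum(htmp))
  unlink(htmp)
  results <- list()
  log <- c(sprintf("nvcoxy %s | seed %d | config %s",
                   as.character(utils::packageVersion("nvcoxy")), seed,
                   cfg_hash))
  out_csv <- function(df, name) {
    utils::write.csv(cbind(df, config = cfg_hash),
                     file.path(cfg$outdir, name), row.names = FALSE)
  }
  for (st in stages) {
    res <- try({
      switch(st,
        linescan = {
          k <- if (!is.null(cfg$linescan$path)) load_image(cfg$linescan$path)
            else do.call(make_linescan, c(cfg$linescan$truth,
                                          list(seed = seed)))
          v <- estimate_velocity(k)
          fl <- count_flux(k)
          hc <- estimate_hematocrit(k)
          dm <- diameter_from_linescan(k)
          out_csv(as.data.frame(v), "linescan_velocity.csv")
          out_csv(as.data.frame(fl), "linescan_flux.csv")
          out_csv(as.data.frame(hc), "linescan_hematocrit.csv")
          out_csv(data.frame(t = dm$t, value = dm$value),
                  "linescan_diameter.csv")
          list(velocity = v, flux = fl, hematocrit = hc, diameter = dm)
        },
        movie = {
          m <- if (!is.null(cfg$movie$path)) load_image(cfg$movie$path)
            else do.call(make_movie, c(cfg$movie$truth, list(seed = seed)))
          dm <- frame_diameter_trace(m)
          out_csv(data.frame(t = dm$t, value = dm$value),
                  "movie_diameter.csv")
          ev <- NULL
          if (!is.null(m$roi_traces)) {
            ev <- detect_calcium_events(rowMeans(m$roi_traces),
                                        m$frame_rate)
            out_csv(as.data.frame(ev), "movie_events.csv")
          }
          list(diameter = dm, events = ev)
        },
        volume = {
          v <- if (!is.null(cfg$volume$path)) load_image(cfg$volume$path)
            else do.call(make_volume, c(cfg$volume$truth,
                                        list(seed = seed)))
          s <- skeletonize_volume(v)
          dd <- do.call(tissue_distance_distribution,
                        c(list(v, seed = seed),
                          cfg$volume$distance))
          prof <- diameter_depth_profile(s)
          out_csv(prof, "volume_diameter_by_depth.csv")
          out_csv(data.frame(centile = names(dd$centiles),
                             distance_um = unname(dd$centiles)),
                  "volume_distance_centiles.csv")
          out_csv(data.frame(density_m_per_mm3 = capillary_density(s)),
                  "volume_density.csv")
          list(skeleton = s, distances = dd,
               density = capillary_density(s))
        },
        hemo = {
          h <- if (!is.null(cfg$hemo$path)) load_hemo(cfg$hemo$path)
            else do.call(make_hemo, c(cfg$hemo$truth, list(seed = seed)))
          h <- derive_channels(h)
          mask <- segment_rest(h)
          ev <- detect_metabolic_events(h)
          out_csv(ev, "hemo_events.csv")
          base <- baseline_summary(list(h), list(mask), "animal1")
          out_csv(base, "hemo_baselines.csv")
          list(trace = h, rest = mask, events = ev, baselines = base)
        },
        oxygen = {
          args <- cfg$oxygen
          target <- args$calibrate_target
          args$calibrate_target <- NULL
          if (!is.null(target) && is.null(args$r_max)) {
            args$r_max <- 20  # placeholder replaced by calibration
            m0 <- do.call(oxygen_model, args)
            args$r_max <- calibrate_rmax(m0, target)
          }
          m <- do.call(oxygen_model, args)
          p <- steady_profile(m)
          out_csv(data.frame(r_um = p$r, C_uM = p$C,
                             VO2_frac = p$VO2_frac),
                  "oxygen_profile.csv")
          p
        },
        stop("unknown stage: ", st))
    }, silent = TRUE)
    ok <- !inherits(res, "try-error")
    log <- c(log, sprintf("stage %-8s %s", st,
                          if (ok) "ok" else paste("FAILED:",
                                                  attr(res, "condition")$message)))
    results[[st]] <- res
  }
  writeLines(log, file.path(cfg$outdir, "provenance.log"))
  invisible(results)
}
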