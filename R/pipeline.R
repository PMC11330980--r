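# Orchestration: configuration, end-to-end runs, per-track quantification,
# summary JSON and logging.

pipeline_defaults <- function() {
  list(
    protocol = "longterm_WT",
    seed = 1,
    input = "simulate",      # or a path to an OME-TIFF written by the package
    out_dir = NULL,          # NULL: keep results in memory only
    sim = list(),            # simulate_experiment() config
    detect = list(),         # detect_spots() config
    link = list(),           # link_tracks() config
    assign = list(),         # assign_compartment() config
    frap = list(),           # fit_frap() config
    pulsechase = list(),     # pulse_chase_metrics() config
    roi_radius = 4,          # px, fixed per series
    cytosol_dilate = 2,      # px dilation of aggregate exclusion footprints
    write_images = FALSE,    # write the rendered series as OME-TIFF
    count_days = c(6, 12))   # experiment days at which counts are reported
}

#' Somatodendritic and whole-cytosol masks of a geometry
#'
#' @param geom A [make_geometry()] object.
#' @return List of Y x X logical masks: `somatodendritic` (soma plus
#'   dendrites) and `cytosol` (additionally axons).
#' @export
geometry_masks <- function(geom) {
  Y <- geom$fov_shape[1]; X <- geom$fov_shape[2]
  sd_mask <- geom$soma_mask
  cy_mask <- geom$soma_mask
  num <- matrix(0, Y, X)
  for (sk in geom$skeletons) {
    w <- if (sk$compartment == "dendrite") geom$config$dendrite_width / 2
         else max(0.5, geom$config$axon_width / 2)
    num0 <- stamp_points(matrix(0, Y, X), sk$pts, w, 1)
    if (sk$compartment == "dendrite") sd_mask <- sd_mask | num0 > 0
    cy_mask <- cy_mask | num0 > 0
  }
  list(somatodendritic = sd_mask, cytosol = cy_mask)
}

# per-track ROI traces on the requested channels; long data frame.
# bg_subtract switches to annulus-subtracted punctum photometry (used for
# pulse-chase, where diffuse cytosolic label would otherwise contaminate
# the aggregate trace).
quantify_tracks <- function(series, tracks, channels, roi_radius = 4,
                            bg_subtract = FALSE) {
  det <- tracks$detections
  out <- list()
  times <- frame_times(series)
  meas <- if (bg_subtract) {
    function(proj, ctr) measure_punctum(proj, ctr, roi_radius)
  } else {
    function(proj, ctr) measure_roi(proj, ctr, roi_radius)
  }
  for (f in sort(unique(det$frame))) {
    fr <- get_frame(series, f)
    rows <- which(det$frame == f)
    for (ch in channels) {
      ci <- match(ch, series$channel_names)
      if (is.na(ci)) stop("channel '", ch, "' not in series")
      proj <- max_project(array(fr[ci, , , ], dim = dim(fr)[2:4]))
      out[[length(out) + 1L]] <- data.frame(
        track_id = det$track_id[rows], channel = ch, frame = f,
        time_h = times[f],
        value = vapply(rows, function(r) {
          meas(proj, c(det$x[r], det$y[r]))
        }, 0))
    }
  }
  df <- do.call(rbind, out)
  df[order(df$track_id, df$channel, df$frame), ]
}

track_trace <- function(quant, id, channel) {
  q <- quant[quant$track_id == id & quant$channel == channel, ]
  new_trace(q$time_h, q$value, subject = id, channel = channel)
}

log_stage <- function(log, stage, t0, ...) {
  msg <- sprintf("[%s] %.2fs %s", stage,
                 as.numeric(Sys.time() - t0, units = "secs"),
                 paste(sprintf(...), collapse = ""))
  message(msg)
  c(log, msg)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> detect -> track -> quantify -> classify
#' and the protocol's turnover analysis (FRAP fitting or pulse-chase
#' metrics), writes CSV/JSON artifacts when `out_dir` is set, and returns a
#' result bundle with a machine-readable summary. Inputs are never mutated;
#' a stage failure marks the bundle `failed` with the stage name.
#'
#' @param config Named list overriding `aggflux:::pipeline_defaults()`, or
#'   a path to a YAML file with the same structure.
#' @return A list bundle: `status` ("ok"/"failed"), `failed_stage`,
#'   `summary` (headline metrics), `tracks`, `calls`, `counts`, `traces`,
#'   `frap_fits`, `pulse_chase`, `sim`, `config`, `log`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_defaults()
  for (key in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[key]]) && is.list(config[[key]])) {
      config[[key]] <- utils::modifyList(defaults[[key]], config[[key]])
    }
  }
  cfg <- merge_config(defaults, config)
  bundle <- list(status = "ok", failed_stage = NA_character_,
                 config = cfg, log = character())
  t_all <- Sys.time()
  stage <- function(name, expr) {
    if (bundle$status == "failed") return(NULL)
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      bundle$status <<- "failed"
      bundle$failed_stage <<- name
      bundle$log <<- log_stage(bundle$log, name, t0, "FAILED: %s",
                               conditionMessage(res))
      return(NULL)
    }
    res
  }

  sim <- stage("simulate", {
    if (identical(cfg$input, "simulate")) {
      s <- simulate_experiment(cfg$protocol, cfg$sim, seed = cfg$seed)
      bundle$log <- log_stage(bundle$log, "simulate", t_all,
                              "protocol=%s seed=%d frames=%d", cfg$protocol,
                              cfg$seed, n_frames(s$series))
      s
    } else {
      s <- list(protocol = cfg$protocol, series = read_series(cfg$input),
                truth = NULL, geometry = NULL, reference_id = NA,
                bleach_time = NA_real_)
      bundle$log <- log_stage(bundle$log, "read", t_all, "input=%s",
                              cfg$input)
      s
    }
  })
  if (bundle$status == "failed") return(bundle)
  bundle$sim <- sim

  det_channel <- if (startsWith(cfg$protocol, "pulsechase")) "OG" else "EGFP"
  detections <- stage("detect", {
    t0 <- Sys.time()
    d <- detect_series(sim$series, det_channel, cfg$detect)
    bundle$log <- log_stage(bundle$log, "detect", t0, "n=%d", nrow(d))
    d
  })
  if (bundle$status == "failed") return(bundle)

  tracks <- stage("track", {
    t0 <- Sys.time()
    tk <- link_tracks(detections, cfg$link)
    bundle$log <- log_stage(bundle$log, "track", t0, "tracks=%d",
                            length(unique(tk$detections$track_id)))
    tk
  })
  if (bundle$status == "failed") return(bundle)
  bundle$tracks <- tracks

  quant <- stage("quantify", {
    t0 <- Sys.time()
    is_pc <- startsWith(cfg$protocol, "pulsechase")
    channels <- if (is_pc) c("OG", "JF635") else "EGFP"
    q <- quantify_tracks(sim$series, tracks, channels, cfg$roi_radius,
                         bg_subtract = is_pc)
    counts <- count_curve(tracks, frame_times(sim$series))
    res <- list(quant = q, counts = counts)
    # cytosolic and morphology traces on the somatodendritic mask
    if (!is.null(sim$geometry)) {
      masks <- geometry_masks(sim$geometry)
      vals <- numeric(0); mvals <- numeric(0)
      has_morph <- "morph" %in% sim$series$channel_names
      for (f in seq_len(n_frames(sim$series))) {
        fr <- get_frame(sim$series, f)
        ci <- match(det_channel, sim$series$channel_names)
        proj <- max_project(array(fr[ci, , , ], dim = dim(fr)[2:4]))
        dts <- detections[detections$frame == f, ]
        vals[f] <- measure_cytosol(proj, masks$somatodendritic, dts,
                                   cfg$roi_radius, cfg$cytosol_dilate)
        if (has_morph) {
          mi <- match("morph", sim$series$channel_names)
          mproj <- max_project(array(fr[mi, , , ], dim = dim(fr)[2:4]))
          mvals[f] <- measure_cytosol(mproj, masks$somatodendritic, dts,
                                      cfg$roi_radius, cfg$cytosol_dilate)
        }
      }
      res$cytosol_trace <- new_trace(frame_times(sim$series), vals,
                                     subject = "cytosol",
                                     channel = det_channel)
      if (has_morph) {
        res$morph_trace <- new_trace(frame_times(sim$series), mvals,
                                     subject = "cytosol", channel = "morph")
      }
    }
    bundle$log <- log_stage(bundle$log, "quantify", t0,
                            "rows=%d", nrow(q))
    res
  })
  if (bundle$status == "failed") return(bundle)
  bundle$counts <- quant$counts
  bundle$traces <- quant

  calls <- NULL
  if (!startsWith(cfg$protocol, "pulsechase") && !is.null(sim$geometry)) {
    calls <- stage("classify", {
      t0 <- Sys.time()
      morph_proj <- NULL
      if ("morph" %in% sim$series$channel_names) {
        fr <- get_frame(sim$series, 1)
        mi <- match("morph", sim$series$channel_names)
        morph_proj <- max_project(array(fr[mi, , , ], dim = dim(fr)[2:4]))
      }
      cl <- assign_compartments(tracks, sim$geometry, morph_proj,
                                cfg$assign)
      bundle$log <- log_stage(bundle$log, "classify", t0, "axon=%d/%d",
                              sum(cl$label == "axon"), nrow(cl))
      cl
    })
    if (bundle$status == "failed") return(bundle)
    bundle$calls <- calls
  }

  frap_fits <- NULL
  if (cfg$protocol == "frap") {
    frap_fits <- stage("frap", {
      t0 <- Sys.time()
      # bleached aggregates disappear from detection, so each aggregate
      # identified in the pre-bleach frame is followed at its pre-bleach
      # ROI position across all frames (5-min transport is << ROI radius);
      # raw detections are used — a bleached aggregate has no second
      # detection, so it never forms a multi-frame track
      det1 <- detections[detections$frame == 1, ]
      ci <- match("EGFP", sim$series$channel_names)
      times <- frame_times(sim$series)
      vals <- matrix(0, nrow(det1), n_frames(sim$series))
      for (f in seq_len(n_frames(sim$series))) {
        fr <- get_frame(sim$series, f)
        proj <- max_project(array(fr[ci, , , ], dim = dim(fr)[2:4]))
        for (i in seq_len(nrow(det1))) {
          vals[i, f] <- measure_roi(proj, c(det1$x[i], det1$y[i]),
                                    cfg$roi_radius)
        }
      }
      ff <- lapply(seq_len(nrow(det1)), function(i) {
        tr <- new_trace(times, vals[i, ], subject = i, channel = "EGFP")
        fit_frap(tr, bleach_time = sim$bleach_time, fit_config = cfg$frap)
      })
      bundle$log <- log_stage(bundle$log, "frap", t0, "fits=%d",
                              length(ff))
      ff
    })
    if (bundle$status == "failed") return(bundle)
    bundle$frap_fits <- frap_fits
  }

  pc <- NULL
  if (startsWith(cfg$protocol, "pulsechase")) {
    pc <- stage("pulsechase", {
      t0 <- Sys.time()
      pc_cfg <- cfg$pulsechase
      if (is.null(pc_cfg$t_new_start) && !is.null(sim$schedule)) {
        pc_cfg$t_new_start <-
          sim$t_start + sim$schedule$time[sim$schedule$action == "label_L2"]
      }
      ids <- sort(unique(tracks$detections$track_id))
      out <- lapply(ids, function(id) {
        old <- track_trace(quant$quant, id, "OG")
        new <- track_trace(quant$quant, id, "JF635")
        if (length(old$times) < 3) return(NULL)
        pulse_chase_metrics(old, new, pc_cfg)
      })
      out <- out[!vapply(out, is.null, TRUE)]
      bundle$log <- log_stage(bundle$log, "pulsechase", t0, "tracks=%d",
                              length(out))
      out
    })
    if (bundle$status == "failed") return(bundle)
    bundle$pulse_chase <- pc
  }

  bundle$summary <- stage("summarize", {
    s <- list(protocol = cfg$protocol, seed = cfg$seed,
              n_frames = n_frames(sim$series),
              n_tracks = length(unique(tracks$detections$track_id)),
              n_detections = nrow(detections))
    times <- frame_times(sim$series)
    for (d in cfg$count_days) {
      tday <- times[1] + 24 * d
      if (tday <= max(times) + 1e-9) {
        s[[sprintf("count_day%d", d)]] <-
          quant$counts$count[which.min(abs(quant$counts$time_h - tday))]
      }
    }
    if (!is.null(calls)) {
      s$axon_fraction <- mean(calls$label == "axon")
      s$nuclear_fraction <- mean(calls$label == "nucleus")
      s$unresolved_fraction <- mean(calls$label == "unresolved")
    }
    if (!is.null(frap_fits)) {
      taus <- vapply(frap_fits, function(f) {
        if (isTRUE(f$converged)) f$tau else NA_real_
      }, 0)
      s$frap_tau_median <- stats::median(taus, na.rm = TRUE)
      s$frap_n_converged <- sum(!is.na(taus))
    }
    if (!is.null(pc)) {
      s$t_peak_old_median <-
        stats::median(vapply(pc, `[[`, 0, "t_peak_old"))
      s$new_rise_fraction <-
        mean(vapply(pc, `[[`, TRUE, "new_rise_present"))
    }
    s
  })
  if (bundle$status == "failed") return(bundle)

  if (!is.null(cfg$out_dir)) {
    stage("write", {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      p <- function(f) file.path(cfg$out_dir, f)
      write_tracks_csv(tracks, p("tracks.csv"))
      utils::write.csv(quant$counts, p("counts.csv"), row.names = FALSE)
      utils::write.csv(quant$quant, p("track_traces.csv"),
                       row.names = FALSE)
      if (!is.null(quant$cytosol_trace)) {
        tr <- list(quant$cytosol_trace)
        if (!is.null(quant$morph_trace)) tr <- c(tr, list(quant$morph_trace))
        write_traces_csv(tr, p("cytosol_traces.csv"))
      }
      if (!is.null(calls)) {
        utils::write.csv(calls, p("compartment_calls.csv"),
                         row.names = FALSE)
      }
      if (isTRUE(cfg$write_images) && identical(cfg$input, "simulate")) {
        write_series(sim$series, p("series.ome.tiff"))
      }
      jsonlite::write_json(bundle$summary, p("summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      writeLines(bundle$log, p("run.log"))
      NULL
    })
  }
  bundle$log <- log_stage(bundle$log, "done", t_all, "status=%s",
                          bundle$status)
  bundle
}
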