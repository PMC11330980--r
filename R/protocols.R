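# Experiment protocols: wire kinetics + label schedule + geometry + renderer
# into the acquisition regimes of the study design being emulated.
#
# Timeline convention: kinetic time t = 0 at transduction. Long-term imaging
# of the wild-type construct starts 8 days (192 h) later; the K6,9R
# construct is imaged from day 10 (240 h) to compensate for its slower
# aggregate appearance; pulse-chase labeling and FRAP bleaching happen at
# 240 h. Frame intervals: long-term 2 h, pulse-chase 1.5 h, FRAP 5 min.

PROTOCOLS <- c("longterm_WT", "longterm_KR", "pulsechase_WT",
               "pulsechase_KR", "frap", "localization_WT",
               "localization_KR")

#' Default configuration of a simulation protocol
#'
#' @param protocol One of the protocol names (see [simulate_experiment()]).
#' @return Named list of default configuration values (frame interval,
#'   duration, imaging start, optics overrides, ...).
#' @export
protocol_defaults <- function(protocol) {
  base <- list(
    fov_shape = c(480L, 640L),
    n_z = 12L,
    n_neurons = NULL,      # default: scaled with FOV area, >= 1
    volume = NULL,         # default: FOV area / full-FOV area
    geometry = list(),     # extra make_geometry() config
    optics = list(),
    deterministic = FALSE,
    lazy = FALSE,
    channels = NULL)
  extra <- switch(
    protocol,
    longterm_WT = list(preset = "WT", t_start = 192, duration_h = 288,
                       frame_dt = 2,
                       # nucleation sites deplete local monomer: new
                       # aggregates do not form on top of existing ones
                       optics = list(min_spacing = 6)),
    longterm_KR = list(preset = "KR", t_start = 240, duration_h = 288,
                       frame_dt = 2,
                       optics = list(min_spacing = 6)),
    pulsechase_WT = list(preset = "WT", t_start = 240, duration_h = 60,
                         frame_dt = 1.5, block_h = 4, add_reference = TRUE),
    pulsechase_KR = list(preset = "KR", t_start = 240, duration_h = 60,
                         frame_dt = 1.5, block_h = 4, add_reference = TRUE),
    frap = list(preset = "WT", t_start = 240, duration_h = 5,
                frame_dt = 5 / 60,
                # transport distance per 5-min frame is small
                optics = list(motion_step = 0.15)),
    localization_WT = list(preset = "WT", n_aggregates = 32L,
                           content_range = c(3, 8), cytosol = 60,
                           duration_h = 16, frame_dt = 2, t_start = 0,
                           optics = list(min_spacing = 8, motion_step = 0.5)),
    localization_KR = list(preset = "KR", n_aggregates = 10L,
                           content_range = c(3, 8), cytosol = 60,
                           duration_h = 16, frame_dt = 2, t_start = 0,
                           optics = list(min_spacing = 8, motion_step = 0.5)))
  utils::modifyList(base, extra)
}

# quota compartment allocation: floor(p * n) deterministic seats plus the
# remaining seats drawn by the fractional remainders. The placed sample's
# composition then matches the preset's proportions with sub-aggregate
# scatter, emulating a reported sample composition rather than an
# independent draw per aggregate.
quota_compartments <- function(prob, n) {
  base <- floor(prob * n)
  rem <- prob * n - base
  k <- n - sum(base)
  comps <- rep(names(prob), base)
  if (k > 0) {
    extra <- sample(names(prob), k, replace = FALSE,
                    prob = pmax(rem, 1e-12))
    comps <- c(comps, extra)
  }
  sample(comps)  # shuffle order
}

# constant-content trajectory with directly placed aggregates (emulates a
# late-stage snapshot series for localization analyses)
placed_trajectory <- function(params, n_agg, content_range, cytosol,
                              t_start, duration_h, frame_dt) {
  times <- seq(t_start, t_start + duration_h, by = frame_dt)
  nt <- length(times)
  comps <- quota_compartments(params$placement, n_agg)
  content <- stats::runif(n_agg, content_range[1], content_range[2])
  cyt <- matrix(0, nt, length(AGG_LABELS),
                dimnames = list(NULL, AGG_LABELS))
  cyt[, "L1"] <- cytosol
  A <- array(0, dim = c(length(AGG_LABELS), n_agg, nt),
             dimnames = list(AGG_LABELS, NULL, NULL))
  A["L1", , ] <- matrix(content, n_agg, nt)
  agg <- data.frame(id = seq_len(n_agg), birth_time = t_start,
                    compartment = comps, stringsAsFactors = FALSE)
  structure(
    list(times = times, cyt = cyt, agg = agg, A = A,
         final_state = NULL, params = params, schedule = NULL),
    class = "kinetic_trajectory")
}

#' Simulate a complete imaging experiment
#'
#' Runs the kinetic model under the named protocol, generates a neuron
#' geometry, and renders the imaging window into a multi-channel z-stack
#' time-lapse with paired ground truth.
#'
#' Protocols: `longterm_WT` / `longterm_KR` (2-h frames for 12 days;
#' morphology + reporter channels), `pulsechase_WT` / `pulsechase_KR`
#' (labeling schedule 1 h first ligand, 4 h blocker, second ligand kept in
#' the media; 1.5-h frames for 60 h; old- and new-ligand channels),
#' `frap` (all aggregates photobleached at imaging start; 5-min frames for
#' 5 h), and `localization_WT` / `localization_KR` (a fixed number of
#' aggregates placed directly according to the preset's compartment
#' probabilities, rendered as a short series for compartment-assignment
#' studies).
#'
#' Kinetic rates are defined at full-FOV scale (640 x 480); smaller fields
#' scale the simulated volume with FOV area, so per-FOV counts scale with
#' area while concentrations and per-aggregate contents are preserved.
#'
#' @param protocol One of the names above.
#' @param config Named list overriding the protocol defaults
#'   (`aggflux:::protocol_defaults()`): `fov_shape`, `n_z`, `frame_dt`,
#'   `duration_h`, `deterministic`, `lazy`, `optics`, `geometry`, ...
#' @param seed Integer seed; the same (protocol, config, seed) gives a
#'   bit-identical series.
#'
#' @return List with `protocol`, `series`, `truth`, `trajectory`,
#'   `geometry`, `params`, `schedule`, `reference_id` (pulse-chase reference
#'   aggregate id or `NA`), `t_start`, and the merged `config`.
#' @export
simulate_experiment <- function(protocol, config = list(), seed = 1) {
  if (!protocol %in% PROTOCOLS) {
    stop("unknown protocol '", protocol, "'; valid protocols: ",
         paste(PROTOCOLS, collapse = ", "))
  }
  defaults <- protocol_defaults(protocol)
  # optics and geometry sub-lists merge key-wise rather than wholesale
  for (key in c("optics", "geometry")) {
    if (!is.null(config[[key]])) {
      config[[key]] <- utils::modifyList(defaults[[key]], config[[key]])
    }
  }
  cfg <- merge_config(defaults, config)
  set.seed(seed)
  params <- kinetic_preset(cfg$preset)
  area_frac <- prod(cfg$fov_shape) / (480 * 640)
  params$volume <- if (is.null(cfg$volume)) area_frac else cfg$volume
  if (is.null(cfg$n_neurons)) {
    cfg$n_neurons <- max(1L, round(2 * area_frac))
  }
  geom_cfg <- merge_config(
    list(fov_shape = cfg$fov_shape, n_z = cfg$n_z,
         n_neurons = cfg$n_neurons),
    cfg$geometry)
  geom <- make_geometry(seed + 1L, geom_cfg)

  reference_id <- NA_integer_
  schedule <- NULL
  if (startsWith(protocol, "localization")) {
    traj <- placed_trajectory(params, cfg$n_aggregates, cfg$content_range,
                              cfg$cytosol, cfg$t_start, cfg$duration_h,
                              cfg$frame_dt)
    channels <- c(morph = "morph", EGFP = "L1")
  } else if (startsWith(protocol, "longterm")) {
    pre <- simulate_kinetics(params, horizon = cfg$t_start,
                             record_dt = cfg$t_start,
                             schedule = label_schedule(0, "label_L1"),
                             deterministic = cfg$deterministic)
    traj <- simulate_kinetics(params, horizon = cfg$duration_h,
                              record_dt = cfg$frame_dt,
                              state = pre$final_state,
                              deterministic = cfg$deterministic)
    channels <- c(morph = "morph", EGFP = "L1")
  } else if (startsWith(protocol, "pulsechase")) {
    pre <- simulate_kinetics(params, horizon = cfg$t_start,
                             record_dt = cfg$t_start,
                             deterministic = cfg$deterministic)
    st <- pre$final_state
    if (isTRUE(cfg$add_reference)) {
      st$agg <- rbind(st$agg,
                      data.frame(id = st$next_id, birth_time = st$t,
                                 compartment = "axon",
                                 stringsAsFactors = FALSE))
      st$A <- cbind(st$A, 0)
      reference_id <- st$next_id
      st$next_id <- st$next_id + 1L
    }
    schedule <- pulse_chase_schedule(0, block_h = cfg$block_h)
    traj <- simulate_kinetics(params, horizon = cfg$duration_h,
                              record_dt = cfg$frame_dt, schedule = schedule,
                              state = st, deterministic = cfg$deterministic)
    channels <- c(OG = "L1", JF635 = "L2")
  } else {  # frap: first frame is the pre-bleach baseline
    pre <- simulate_kinetics(params, horizon = cfg$t_start,
                             record_dt = cfg$t_start,
                             schedule = label_schedule(0, "label_L1"),
                             deterministic = cfg$deterministic)
    st <- pre$final_state
    schedule <- label_schedule(cfg$frame_dt, "bleach")
    traj <- simulate_kinetics(params, horizon = cfg$duration_h,
                              record_dt = cfg$frame_dt, schedule = schedule,
                              state = st, deterministic = cfg$deterministic)
    channels <- c(morph = "morph", EGFP = "L1")
  }
  if (!is.null(cfg$channels)) channels <- cfg$channels

  rend <- render_series(traj, geom, optics = cfg$optics, seed = seed + 2L,
                        channels = channels, lazy = cfg$lazy)
  list(protocol = protocol, series = rend$series, truth = rend$truth,
       trajectory = traj, geometry = geom, params = params,
       schedule = schedule, reference_id = reference_id,
       t_start = cfg$t_start,
       bleach_time = if (protocol == "frap") cfg$t_start + cfg$frame_dt
                     else NA_real_,
       config = cfg)
}
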