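# Particle status codes
STATUS_RESERVOIR <- 0L
STATUS_ACTIVE <- 1L
STATUS_CLEARED <- 2L

#' Region-dependent speed multiplier
#'
#' Particle speed in a region is `base_speed * (1 - viscosity)`: 1.0 in the
#' FOV (the reference), `1 - viscosity_epr` inside the EPR zone (0.1 at the
#' default viscosity of 0.9) and `1 - viscosity_roi` inside the ROI (0.845
#' at the default 0.155).
#'
#' @param region Character vector of `"FOV"`, `"EPR"`, `"ROI"`.
#' @param config A [sim_config()].
#' @return Numeric multipliers, same length as `region`.
#' @examples
#' speed_multiplier(c("FOV", "EPR", "ROI"), sim_config())
#' @export
speed_multiplier <- function(region, config) {
  if (!all(region %in% c("FOV", "EPR", "ROI")))
    abort_invalid("region must be one of 'FOV', 'EPR', 'ROI'")
  mult <- c(FOV = 1, EPR = 1 - config$viscosity_epr,
            ROI = 1 - config$viscosity_roi)
  unname(mult[region])
}

#' Construct a simulation state
#'
#' Particles start in the reservoir at the injection site. `positions` /
#' `directions` / `status` allow constructing bespoke states (e.g. particles
#' seeded inside the EPR shell for the escape-probability experiment);
#' directions are normalized to unit length.
#'
#' @param config A [sim_config()].
#' @param positions Optional n x 3 matrix of particle positions.
#' @param directions Optional n x 3 matrix of particle directions.
#' @param status Optional integer vector (0 reservoir, 1 active, 2 cleared).
#' @return An object of class `sim_state`: frame counter, particle arrays,
#'   cumulative EPR-collision counters, and sample/event accumulators.
#' @seealso [particles()] for a tibble view, [advance_frame()] to step it.
#' @export
sim_state <- function(config, positions = NULL, directions = NULL,
                      status = NULL) {
  n <- if (is.null(positions)) config$n_particles else nrow(positions)
  if (is.null(positions))
    positions <- matrix(rep(config$geometry$injection_site, each = n), n, 3)
  if (is.null(directions))
    directions <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  else {
    nrm <- sqrt(rowSums(directions^2))
    directions <- directions / ifelse(nrm > 0, nrm, 1)
  }
  if (is.null(status))
    status <- rep(STATUS_RESERVOIR, n)
  stopifnot(nrow(directions) == n, length(status) == n)
  structure(
    list(frame = 0L,
         pos = positions,
         dir = directions,
         status = as.integer(status),
         entered_roi = rep(FALSE, n),
         entered_epr = rep(FALSE, n),
         epr_hits = 0L,
         epr_escapes = 0L,
         samples = list(),
         events = list()),
    class = "sim_state")
}

#' Particle table of a state
#'
#' @param state A [sim_state()].
#' @param config The matching [sim_config()] (needed to derive region and
#'   emission).
#' @return A tibble with one row per particle: position, direction, region,
#'   `status`, `entered_roi` and `emitting` (in always-on mode every active
#'   particle emits; in responsive mode only active particles that have
#'   entered the ROI do).
#' @export
particles <- function(state, config) {
  active <- state$status == STATUS_ACTIVE
  region <- rep(NA_character_, length(state$status))
  if (any(active)) {
    pts <- tibble(x = state$pos[active, 1], y = state$pos[active, 2],
                  z = state$pos[active, 3])
    region[active] <-
      classify_region(pts, config$geometry, config$epr_enabled)$region
  }
  tibble(id = seq_along(state$status),
         x = state$pos[, 1], y = state$pos[, 2], z = state$pos[, 3],
         dx = state$dir[, 1], dy = state$dir[, 2], dz = state$dir[, 3],
         region = region,
         status = c("reservoir", "active", "cleared")[state$status + 1L],
         entered_roi = state$entered_roi,
         emitting = emitting_mask(state, config))
}

emitting_mask <- function(state, config) {
  active <- state$status == STATUS_ACTIVE
  if (config$mode == "responsive") active & state$entered_roi else active
}

# squared distance of every particle to the ROI centre
roi_dist2 <- function(state, config) {
  ctr <- config$geometry$roi_center
  (state$pos[, 1] - ctr[1])^2 + (state$pos[, 2] - ctr[2])^2 +
    (state$pos[, 3] - ctr[3])^2
}

in_roi_mask <- function(state, config) {
  state$status == STATUS_ACTIVE &
    roi_dist2(state, config) < config$geometry$roi_radius^2
}

# inward wall normal at the injection site (NULL if strictly interior)
inward_normal <- function(geometry) {
  s <- geometry$injection_site
  h <- geometry$chamber_half_extents
  ratio <- abs(s) / h
  a <- which.max(ratio)
  if (ratio[a] < 1 - 1e-9) return(NULL)
  n <- c(0, 0, 0)
  n[a] <- -sign(s[a])
  n
}

# k unit vectors uniform on the sphere, mirrored into the hemisphere around
# the inward normal (uniform-on-hemisphere); 2 uniforms consumed per vector
random_hemisphere <- function(k, n_in) {
  z <- 2 * runif(k) - 1
  phi <- 2 * pi * runif(k)
  s <- sqrt(pmax(0, 1 - z^2))
  d <- cbind(s * cos(phi), s * sin(phi), z)
  if (!is.null(n_in)) {
    dn <- as.vector(d %*% n_in)
    flip <- dn < 0
    if (any(flip))
      d[flip, ] <- d[flip, , drop = FALSE] -
        2 * dn[flip] * matrix(n_in, sum(flip), 3, byrow = TRUE)
  }
  d
}

log_event <- function(state, event, n) {
  state$events[[length(state$events) + 1L]] <-
    list(frame = state$frame, event = event, n = as.integer(n))
  state
}

#' Batch release of reservoir particles
#'
#' When the frame counter is a multiple of `release_cadence` and the
#' reservoir is non-empty, activates up to `batch_size` particles at the
#' injection site, each with an independent random unit direction drawn
#' uniformly from the hemisphere pointing into the chamber interior.
#'
#' @param state A [sim_state()].
#' @param config A [sim_config()].
#' @return The updated state.
#' @export
release_step <- function(state, config) {
  if (state$frame %% config$release_cadence != 0L) return(state)
  res <- which(state$status == STATUS_RESERVOIR)
  if (!length(res)) return(state)
  k <- min(config$batch_size, length(res))
  idx <- res[seq_len(k)]
  state$pos[idx, ] <- matrix(config$geometry$injection_site, k, 3,
                             byrow = TRUE)
  state$dir[idx, ] <- random_hemisphere(k, inward_normal(config$geometry))
  state$status[idx] <- STATUS_ACTIVE
  log_event(state, "release", k)
}

#' One frame of particle kinetics
#'
#' Advances every active particle independently along its rectilinear
#' trajectory by `base_speed` times the region speed multiplier, after an
#' optional EPR funnel rotation (a turn of at most `attraction_strength`
#' radians toward the ROI centre for particles starting the frame inside
#' the zone). Surface crossings are resolved continuously, in order:
#' chamber walls reflect specularly; the ROI sphere is a one-way trap
#' (entered from outside it is passed through, recording first uptake and
#' switching responsive-mode emission on; hit from inside it reflects); the
#' EPR sphere, when enabled, passes entering particles through and gives
#' in-zone particles hitting it a Bernoulli(`epr_escape_prob`) chance to
#' escape back into the FOV, otherwise reflecting them inward. After each
#' crossing the remaining within-frame displacement is rescaled by the new
#' region's multiplier.
#'
#' @inheritParams release_step
#' @return The updated state (positions, directions, uptake flags, and
#'   cumulative EPR boundary-collision / escape counters).
#' @export
motion_step <- function(state, config) {
  res <- motion_kernel(state$pos, state$dir, state$status,
                       state$entered_roi, state$entered_epr,
                       geom_vec(config$geometry), config$epr_enabled,
                       config$mode == "responsive", config$base_speed,
                       config$viscosity_epr, config$viscosity_roi,
                       config$epr_escape_prob, config$attraction_strength)
  if (isTRUE(res$out_of_bounds))
    abort(sprintf("engine invariant violation: particle outside chamber after frame %d",
                  state$frame),
          class = "eprsim_engine_error")
  state$pos <- res$pos
  state$dir <- res$dir
  state$entered_roi <- res$entered_roi
  state$entered_epr <- res$entered_epr
  state$epr_hits <- state$epr_hits + res$n_epr_hits
  state$epr_escapes <- state$epr_escapes + res$n_epr_escapes
  state
}

#' Scheduled stochastic clearance
#'
#' From frame `delay` onward, every `cadence` frames, removes up to `rate`
#' uniformly selected particles from the compartment pool to the clearance
#' site (status `cleared`). The FOV pool is every active particle outside
#' the ROI sphere — EPR-zone particles count as FOV for clearance — and the
#' ROI pool every active particle inside it. FOV clearance is applied before
#' ROI clearance within a frame. Every scheduled firing is logged in the
#' state's event log, including firings that find an empty pool.
#'
#' @inheritParams release_step
#' @return The updated state.
#' @export
clearance_step <- function(state, config) {
  f <- state$frame
  due <- function(delay, cadence)
    f >= delay && (f - delay) %% cadence == 0L
  if (due(config$fov_delay, config$fov_clear_cadence)) {
    pool <- which(state$status == STATUS_ACTIVE & !in_roi_mask(state, config))
    k <- min(config$fov_rate, length(pool))
    if (k > 0) {
      sel <- pool[sample.int(length(pool), k)]
      state$status[sel] <- STATUS_CLEARED
      state$pos[sel, ] <- matrix(config$geometry$clearance_site, k, 3,
                                 byrow = TRUE)
    }
    state <- log_event(state, "fov_clearance", k)
  }
  if (due(config$roi_delay, config$roi_clear_cadence)) {
    pool <- which(in_roi_mask(state, config))
    k <- min(config$roi_rate, length(pool))
    if (k > 0) {
      sel <- pool[sample.int(length(pool), k)]
      state$status[sel] <- STATUS_CLEARED
      state$pos[sel, ] <- matrix(config$geometry$clearance_site, k, 3,
                                 byrow = TRUE)
    }
    state <- log_event(state, "roi_clearance", k)
  }
  state
}

#' Advance the simulation by one frame
#'
#' Applies, in fixed order: [release_step()], [motion_step()],
#' [clearance_step()], distribution sampling (see [sample_distribution()]),
#' then increments the frame counter. Particle counts are conserved by
#' every sub-step.
#'
#' @inheritParams release_step
#' @return The updated state.
#' @export
advance_frame <- function(state, config) {
  state <- release_step(state, config)
  state <- motion_step(state, config)
  state <- clearance_step(state, config)
  s <- sample_distribution(state, config)
  if (!is.null(s))
    state$samples[[length(state$samples) + 1L]] <- s
  state$frame <- state$frame + 1L
  state
}

#' Run a full biodistribution simulation
#'
#' Seeds the RNG from `config$seed`, executes `max_frames` frames and
#' returns the sampled distribution series together with its contrast
#' summary. Runs are bit-reproducible for a given config: the single RNG
#' stream is consumed in a fixed order (release directions, escape
#' coin-flips in particle order, clearance selection).
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_run` with elements `series` (the sampled
#'   distribution tibble, see [tidy.sim_run()]), `events` (release/clearance
#'   event log), `summary` (see [summarize_distribution()]), `state` (final
#'   engine state) and `config`.
#' @examples
#' run <- simulate_biodistribution(
#'   sim_preset("sim2", n_particles = 200, max_frames = 600))
#' glance(run)
#' @export
simulate_biodistribution <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  state <- sim_state(config)
  for (f in seq_len(config$max_frames))
    state <- advance_frame(state, config)
  if (config$max_frames %% config$sample_cadence == 0L)
    state$samples[[length(state$samples) + 1L]] <-
      distribution_row(state, config)
  series <- dplyr::bind_rows(state$samples)
  events <- if (length(state$events))
    dplyr::bind_rows(lapply(state$events, as_tibble))
  else
    tibble(frame = integer(), event = character(), n = integer())
  structure(list(series = series,
                 events = events,
                 summary = summarize_distribution(series),
                 state = state,
                 config = config),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat("<sim_run>\n")
  cat(sprintf("  %d particles, %d frames, mode %s, EPR %s, seed %d\n",
              x$config$n_particles, x$config$max_frames, x$config$mode,
              if (x$config$epr_enabled) "on" else "off", x$config$seed))
  cat(sprintf("  %d distribution samples, %d logged events\n",
              nrow(x$series), nrow(x$events)))
  print(x$summary)
  invisible(x)
}

#' Tidiers for simulation runs
#'
#' `tidy()` returns the sampled distribution series (one row per sampled
#' frame: percentage of administered particles in the FOV pool, in the ROI,
#' cleared, plus emitting-particle counts); `glance()` returns the one-row
#' contrast summary of [summarize_distribution()].
#'
#' @param x A `sim_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sim_run <- function(x, ...) x$series

#' @rdname tidy.sim_run
#' @export
glance.sim_run <- function(x, ...) x$summary

#' Empirical EPR escape-probability experiment
#'
#' Measures the engine's realized escape fraction at the EPR zone boundary:
#' particles are seeded inside the shell with random directions and the
#' attraction turned off, and stepped until at least `n_events`
#' inside-surface collisions with the zone boundary have occurred. Each such
#' collision is an independent Bernoulli(`epr_escape_prob`) escape trial, so
#' the empirical fraction estimates the configured probability (0.5 by
#' default) to binomial accuracy. A deliberately small ROI keeps particles
#' from being trapped in the tumor during the experiment.
#'
#' @param n_events Minimum number of boundary collisions to observe.
#' @param n_particles Particles used to accumulate collisions.
#' @param epr_escape_prob Escape probability under test.
#' @param seed RNG seed.
#' @return A one-row tibble: `n_collisions`, `n_escapes`, `escape_fraction`
#'   (in `[0, 1]`) and `frames` stepped.
#' @examples
#' estimate_epr_escape(n_events = 500, n_particles = 200, seed = 7)
#' @export
estimate_epr_escape <- function(n_events = 10000, n_particles = 2000,
                                epr_escape_prob = 0.5, seed = 1) {
  geom <- sim_geometry(chamber_half_extents = c(1, 0.6, 0.6),
                       roi_radius = 0.02, epr_radius = 0.5)
  config <- sim_config(n_particles = n_particles, epr_enabled = TRUE,
                       attraction_strength = 0, base_speed = 0.1,
                       epr_escape_prob = epr_escape_prob,
                       fov_rate = 0, roi_rate = 0,
                       geometry = geom, seed = seed)
  set.seed(config$seed)
  # seed particles mid-shell with random directions
  mid_r <- geom$roi_radius + 0.5 * (geom$epr_radius - geom$roi_radius)
  dirs <- random_hemisphere(n_particles, NULL)
  pts <- random_hemisphere(n_particles, NULL) * mid_r
  state <- sim_state(config, positions = pts, directions = dirs,
                     status = rep(STATUS_ACTIVE, n_particles))
  frames <- 0L
  while (state$epr_hits < n_events && frames < 100000L) {
    state <- motion_step(state, config)
    frames <- frames + 1L
  }
  tibble(n_collisions = state$epr_hits,
         n_escapes = state$epr_escapes,
         escape_fraction = state$epr_escapes / state$epr_hits,
         frames = frames)
}
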