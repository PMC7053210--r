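config_schema_version <- 1L

# canonical field order; also the serialized JSON key order
config_fields <- c("schema_version", "n_particles", "batch_size",
                   "release_cadence", "base_speed", "epr_enabled", "mode",
                   "viscosity_epr", "viscosity_roi", "epr_escape_prob",
                   "attraction_strength", "fov_delay", "fov_rate",
                   "roi_delay", "roi_rate", "fov_clear_cadence",
                   "roi_clear_cadence", "sample_cadence", "max_frames",
                   "seed", "geometry")

geometry_fields <- c("chamber_half_extents", "roi_center", "roi_radius",
                     "epr_radius", "injection_site", "clearance_site")

#' Build a simulation configuration
#'
#' Collects every tunable of the particle engine. Defaults are the model's
#' stated operating point: particles are released in batches of 100 every 5
#' frames, the EPR-zone viscosity is 0.9 (so in-zone speed is 0.1 x the FOV
#' speed), the ROI viscosity is 0.155 (0.845 x), an in-zone particle hitting
#' the zone boundary escapes back into the FOV with probability 0.5,
#' background (FOV) clearance events fire every 20 frames and tumor (ROI)
#' clearance events every 40, and the distribution chart is sampled every 30
#' frames. Delay and rate values are in relative arbitrary units: a delay is
#' a frame count before clearance commences, a rate the number of particles
#' removed per clearance event.
#'
#' @param n_particles Total particles administered. Default 2000.
#' @param batch_size Particles activated per release event. Default 100.
#' @param release_cadence Frames between release events. Default 5.
#' @param base_speed Particle speed in the FOV, chamber-lengths/frame.
#'   Default 0.02.
#' @param epr_enabled Is the EPR attraction zone active? Default `FALSE`.
#' @param mode `"always_on"` (particles emit whenever present) or
#'   `"responsive"` (off-to-on: a particle emits only after its first uptake
#'   into the ROI). The mode never alters trajectories, only emission flags.
#' @param viscosity_epr,viscosity_roi Viscosity fractions in `[0, 1)`; the
#'   speed multiplier in a region is `1 - viscosity`.
#' @param epr_escape_prob Probability that an in-zone particle colliding with
#'   the EPR boundary escapes back into the FOV (otherwise it is reflected
#'   inward). Default 0.5.
#' @param attraction_strength Maximum turn toward the ROI centre, in
#'   radians/frame, applied to particles inside the EPR zone (the
#'   gravity-like funnel). Rotation preserves speed. Default 0.2.
#' @param fov_delay,fov_rate,roi_delay,roi_rate Clearance schedule: no event
#'   fires before `delay` frames; from frame `delay` onward an event fires
#'   every clearance-cadence frames, each removing up to `rate` randomly
#'   selected particles from the compartment pool to the clearance site.
#'   For clearance (and the distribution chart) EPR-zone particles count as
#'   FOV. Defaults are the moderate-clearance setting (FOV 250/25,
#'   ROI 750/10).
#' @param fov_clear_cadence,roi_clear_cadence Frames between clearance
#'   events. Defaults 20 (FOV) and 40 (ROI).
#' @param sample_cadence Frames between distribution-chart samples.
#'   Default 30.
#' @param max_frames Frames to simulate. Default 6000.
#' @param seed Integer seed; drives release directions, escape coin-flips
#'   and clearance selection through a single RNG stream consumed in a fixed
#'   per-frame order (release, motion, FOV clearance, ROI clearance).
#' @param geometry A [sim_geometry()].
#'
#' @return A validated object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_particles = 200, max_frames = 500)
#' cfg$batch_size
#' @seealso [sim_preset()] for the six documented presets,
#'   [read_sim_config()]/[write_sim_config()] for JSON round-trips.
#' @export
sim_config <- function(n_particles = 2000,
                       batch_size = 100,
                       release_cadence = 5,
                       base_speed = 0.02,
                       epr_enabled = FALSE,
                       mode = c("always_on", "responsive"),
                       viscosity_epr = 0.9,
                       viscosity_roi = 0.155,
                       epr_escape_prob = 0.5,
                       attraction_strength = 0.2,
                       fov_delay = 250,
                       fov_rate = 25,
                       roi_delay = 750,
                       roi_rate = 10,
                       fov_clear_cadence = 20,
                       roi_clear_cadence = 40,
                       sample_cadence = 30,
                       max_frames = 6000,
                       seed = 1,
                       geometry = sim_geometry()) {
  mode <- match.arg(mode)
  cfg <- structure(
    list(schema_version = config_schema_version,
         n_particles = as.integer(n_particles),
         batch_size = as.integer(batch_size),
         release_cadence = as.integer(release_cadence),
         base_speed = as.numeric(base_speed),
         epr_enabled = isTRUE(epr_enabled),
         mode = mode,
         viscosity_epr = as.numeric(viscosity_epr),
         viscosity_roi = as.numeric(viscosity_roi),
         epr_escape_prob = as.numeric(epr_escape_prob),
         attraction_strength = as.numeric(attraction_strength),
         fov_delay = as.integer(fov_delay),
         fov_rate = as.integer(fov_rate),
         roi_delay = as.integer(roi_delay),
         roi_rate = as.integer(roi_rate),
         fov_clear_cadence = as.integer(fov_clear_cadence),
         roi_clear_cadence = as.integer(roi_clear_cadence),
         sample_cadence = as.integer(sample_cadence),
         max_frames = as.integer(max_frames),
         seed = as.integer(seed),
         geometry = geometry),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every engine invariant (viscosities in `[0, 1)`, escape probability
#' in `[0, 1]`, cadences at least 1, non-negative rates and delays, positive
#' base speed, a complete valid geometry, ...). Errors name the offending
#' key and signal condition class `eprsim_validation_error`.
#'
#' @param config A `sim_config` object (or plain list with the same fields).
#' @return The config, invisibly, if valid.
#' @export
validate_sim_config <- function(config) {
  need <- function(ok, key, what) {
    if (!isTRUE(ok))
      abort_invalid(sprintf("config key '%s' %s", key, what))
  }
  missing <- setdiff(config_fields, names(config))
  if (length(missing))
    abort_invalid(paste0("config is missing key(s): ",
                         paste0("'", missing, "'", collapse = ", ")))
  scalar_num <- function(key) {
    v <- config[[key]]
    need(length(v) == 1 && is.numeric(v) && is.finite(v), key,
         "must be a single finite number")
    v
  }
  for (key in c("n_particles", "batch_size", "release_cadence", "fov_delay",
                "fov_rate", "roi_delay", "roi_rate", "fov_clear_cadence",
                "roi_clear_cadence", "sample_cadence", "max_frames", "seed")) {
    v <- scalar_num(key)
    need(abs(v - round(v)) < 1e-9, key, "must be an integer")
  }
  need(config$n_particles >= 0, "n_particles", "must be >= 0")
  need(config$batch_size >= 1, "batch_size", "must be >= 1")
  need(config$release_cadence >= 1, "release_cadence", "must be >= 1")
  need(scalar_num("base_speed") > 0, "base_speed", "must be > 0")
  need(is.logical(config$epr_enabled) && length(config$epr_enabled) == 1,
       "epr_enabled", "must be TRUE or FALSE")
  need(is.character(config$mode) &&
         config$mode %in% c("always_on", "responsive"),
       "mode", "must be 'always_on' or 'responsive'")
  for (key in c("viscosity_epr", "viscosity_roi")) {
    v <- scalar_num(key)
    need(v >= 0 && v < 1, key, "must be in [0, 1)")
  }
  p <- scalar_num("epr_escape_prob")
  need(p >= 0 && p <= 1, "epr_escape_prob", "must be in [0, 1]")
  need(scalar_num("attraction_strength") >= 0, "attraction_strength",
       "must be >= 0")
  need(config$fov_delay >= 0, "fov_delay", "must be >= 0")
  need(config$roi_delay >= 0, "roi_delay", "must be >= 0")
  need(config$fov_rate >= 0, "fov_rate", "must be >= 0")
  need(config$roi_rate >= 0, "roi_rate", "must be >= 0")
  need(config$fov_clear_cadence >= 1, "fov_clear_cadence", "must be >= 1")
  need(config$roi_clear_cadence >= 1, "roi_clear_cadence", "must be >= 1")
  need(config$sample_cadence >= 1, "sample_cadence", "must be >= 1")
  need(config$max_frames >= 1, "max_frames", "must be >= 1")
  validate_geometry(config$geometry)
  invisible(config)
}

#' The six documented simulation presets
#'
#' `sim1`/`sim2` contrast fast vs moderate clearance with an always-on
#' fluorophore and no EPR zone: `sim1` clears the background quickly (FOV
#' delay 250, rate 50; ROI delay 500, rate 25) emulating a short-half-life
#' dye, `sim2` slows both compartments while keeping background clearance
#' more than twofold faster than tumor clearance (FOV 250/25, ROI 750/10)
#' emulating a long-circulating conjugate. `sim3`/`sim4` are the off-to-on
#' responsive twins of `sim1`/`sim2` (identical kinetics, only emission
#' flags differ). `sim5` is `sim2` with the EPR zone enabled; `sim6` adds
#' responsive mode to `sim5`. All other fields sit at [sim_config()]
#' defaults.
#'
#' @param name One of `"sim1"` ... `"sim6"`.
#' @param ... Overrides forwarded to [sim_config()] (e.g. `seed`,
#'   `max_frames`).
#' @return A `sim_config`.
#' @examples
#' sim_preset("sim5")$epr_enabled
#' @export
sim_preset <- function(name, ...) {
  presets <- list(
    sim1 = list(fov_delay = 250, fov_rate = 50, roi_delay = 500,
                roi_rate = 25, epr_enabled = FALSE, mode = "always_on"),
    sim2 = list(fov_delay = 250, fov_rate = 25, roi_delay = 750,
                roi_rate = 10, epr_enabled = FALSE, mode = "always_on"),
    sim3 = list(fov_delay = 250, fov_rate = 50, roi_delay = 500,
                roi_rate = 25, epr_enabled = FALSE, mode = "responsive"),
    sim4 = list(fov_delay = 250, fov_rate = 25, roi_delay = 750,
                roi_rate = 10, epr_enabled = FALSE, mode = "responsive"),
    sim5 = list(fov_delay = 250, fov_rate = 25, roi_delay = 750,
                roi_rate = 10, epr_enabled = TRUE, mode = "always_on"),
    sim6 = list(fov_delay = 250, fov_rate = 25, roi_delay = 750,
                roi_rate = 10, epr_enabled = TRUE, mode = "responsive"))
  if (length(name) != 1 || !name %in% names(presets))
    abort_invalid(paste0("unknown preset '", paste(name, collapse = ","),
                         "'; valid names: ",
                         paste(names(presets), collapse = ", ")))
  args <- modifyList(presets[[name]], list(...))
  do.call(sim_config, args)
}

#' Read / write a simulation configuration as JSON
#'
#' The JSON schema is the flat field set of [sim_config()] with a nested
#' `geometry` object and a `schema_version` marker; keys are written in a
#' fixed canonical order so that save -> load -> save is byte-identical.
#' Loading rejects malformed JSON, unknown keys, missing keys and any value
#' violating [validate_sim_config()], naming the offending key.
#'
#' @param path File path.
#' @param config A `sim_config`.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".json")
#' write_sim_config(sim_preset("sim2"), path)
#' cfg <- read_sim_config(path)
#' @export
read_sim_config <- function(path) {
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) abort_invalid(
                    paste0("malformed JSON in '", path, "': ",
                           conditionMessage(e))))
  unknown <- setdiff(names(raw), config_fields)
  if (length(unknown))
    abort_invalid(paste0("unknown config key(s): ",
                         paste0("'", unknown, "'", collapse = ", ")))
  missing <- setdiff(config_fields, names(raw))
  if (length(missing))
    abort_invalid(paste0("config is missing key(s): ",
                         paste0("'", missing, "'", collapse = ", ")))
  if (!identical(as.integer(raw$schema_version), config_schema_version))
    abort_invalid(sprintf("config key 'schema_version' must be %d",
                          config_schema_version))
  gu <- setdiff(names(raw$geometry), geometry_fields)
  if (length(gu))
    abort_invalid(paste0("unknown geometry key(s): ",
                         paste0("'", gu, "'", collapse = ", ")))
  gm <- setdiff(geometry_fields, names(raw$geometry))
  if (length(gm))
    abort_invalid(paste0("geometry is missing key(s): ",
                         paste0("'", gm, "'", collapse = ", ")))
  geom <- do.call(sim_geometry, raw$geometry)
  args <- raw[setdiff(config_fields, c("schema_version", "geometry"))]
  args$geometry <- geom
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  validate_sim_config(config)
  x <- config[config_fields]
  x$geometry <- unclass(config$geometry)[geometry_fields]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d particles, batches of %d every %d frames, %d frames total\n",
              x$n_particles, x$batch_size, x$release_cadence, x$max_frames))
  cat(sprintf("  mode %s | EPR zone %s | base speed %g\n", x$mode,
              if (x$epr_enabled) "on" else "off", x$base_speed))
  cat(sprintf("  clearance: FOV delay %d rate %d /%d frames; ROI delay %d rate %d /%d frames\n",
              x$fov_delay, x$fov_rate, x$fov_clear_cadence,
              x$roi_delay, x$roi_rate, x$roi_clear_cadence))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
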