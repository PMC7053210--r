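#' Simulation chamber geometry
#'
#' The simulated tissue volume is an axis-aligned box centred at the origin
#' (the imaging field of view, FOV) containing two concentric spheres: the
#' tumor region of interest (ROI) and, around it, the enhanced permeability
#' and retention (EPR) zone, a spherical shell in which particle trajectories
#' are funnelled toward the tumor. Particles enter the chamber at the
#' injection site (a point on a chamber wall) and cleared particles are
#' parked, inert, at the clearance site outside the chamber.
#'
#' All coordinates are dimensionless chamber-lengths; the model has no
#' absolute physical scale.
#'
#' @param chamber_half_extents Numeric length 3, half-widths of the box along
#'   x, y, z. Default `c(1, 0.6, 0.6)`.
#' @param roi_center Numeric length 3, centre of the ROI and EPR spheres.
#' @param roi_radius Radius of the tumor ROI sphere.
#' @param epr_radius Outer radius of the EPR shell; must exceed `roi_radius`
#'   and the shell must fit inside the chamber.
#' @param injection_site Numeric length 3, point on/inside a chamber wall and
#'   outside the EPR sphere where particles are released.
#' @param clearance_site Numeric length 3, point outside the chamber where
#'   cleared particles are parked.
#'
#' @return An object of class `sim_geometry` (a validated named list).
#' @examples
#' g <- sim_geometry()
#' g$roi_radius
#' @export
sim_geometry <- function(chamber_half_extents = c(1, 0.6, 0.6),
                         roi_center = c(0, 0, 0),
                         roi_radius = 0.15,
                         epr_radius = 0.30,
                         injection_site = c(-1, 0, 0),
                         clearance_site = c(1.5, 0, 0)) {
  g <- structure(
    list(chamber_half_extents = as.numeric(chamber_half_extents),
         roi_center = as.numeric(roi_center),
         roi_radius = as.numeric(roi_radius)[1],
         epr_radius = as.numeric(epr_radius)[1],
         injection_site = as.numeric(injection_site),
         clearance_site = as.numeric(clearance_site)),
    class = "sim_geometry")
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  chk_vec3 <- function(v, key) {
    if (length(v) != 3 || !is.numeric(v) || any(!is.finite(v)))
      abort_invalid(sprintf("geometry key '%s' must be 3 finite numbers", key))
  }
  chk_vec3(g$chamber_half_extents, "chamber_half_extents")
  chk_vec3(g$roi_center, "roi_center")
  chk_vec3(g$injection_site, "injection_site")
  chk_vec3(g$clearance_site, "clearance_site")
  h <- g$chamber_half_extents
  if (any(h <= 0))
    abort_invalid("geometry key 'chamber_half_extents' must be positive")
  if (!is.finite(g$roi_radius) || g$roi_radius <= 0)
    abort_invalid("geometry key 'roi_radius' must be > 0")
  if (!is.finite(g$epr_radius) || g$epr_radius <= g$roi_radius)
    abort_invalid("geometry key 'epr_radius' must exceed 'roi_radius'")
  if (any(abs(g$roi_center) + g$epr_radius > h))
    abort_invalid("ROI/EPR spheres must lie entirely inside the chamber")
  if (any(abs(g$injection_site) > h + 1e-12))
    abort_invalid("geometry key 'injection_site' must be on/inside a chamber wall")
  if (sqrt(sum((g$injection_site - g$roi_center)^2)) < g$epr_radius)
    abort_invalid("geometry key 'injection_site' must lie outside the EPR sphere")
  if (all(abs(g$clearance_site) <= h))
    abort_invalid("geometry key 'clearance_site' must lie outside the chamber")
  invisible(g)
}

# flat numeric layout consumed by the C++ kernel:
# (hx, hy, hz, cx, cy, cz, r_roi, r_epr)
geom_vec <- function(g) {
  c(g$chamber_half_extents, g$roi_center, g$roi_radius, g$epr_radius)
}

surface_names <- c("wall_x+", "wall_x-", "wall_y+", "wall_y-",
                   "wall_z+", "wall_z-", "roi_sphere", "epr_sphere")

#' Classify points into FOV / EPR / ROI regions
#'
#' Each in-chamber point belongs to exactly one region: `"ROI"` if strictly
#' inside the ROI sphere, `"EPR"` if inside the EPR shell while the EPR zone
#' is enabled, otherwise `"FOV"`. With the EPR zone disabled the shell is
#' inert and its points classify as FOV.
#'
#' @param points A data frame with numeric columns `x`, `y`, `z` (positions
#'   in chamber-lengths).
#' @param geometry A [sim_geometry()] object.
#' @param epr_enabled Is the EPR zone active?
#'
#' @return The input as a tibble with a `region` character column appended.
#' @examples
#' pts <- tibble::tibble(x = c(0, 0.2, 0.9), y = 0, z = 0)
#' classify_region(pts, sim_geometry(), epr_enabled = TRUE)
#' @export
classify_region <- function(points, geometry, epr_enabled = FALSE) {
  stopifnot(is.data.frame(points), all(c("x", "y", "z") %in% names(points)))
  g <- geometry
  h <- g$chamber_half_extents
  out_of_chamber <- abs(points$x) > h[1] + 1e-12 |
    abs(points$y) > h[2] + 1e-12 | abs(points$z) > h[3] + 1e-12
  if (any(out_of_chamber))
    abort(sprintf("classify_region: %d point(s) outside the chamber (engine collision-handling bug?)",
                  sum(out_of_chamber)),
          class = "eprsim_classification_error")
  d2 <- (points$x - g$roi_center[1])^2 + (points$y - g$roi_center[2])^2 +
    (points$z - g$roi_center[3])^2
  region <- rep("FOV", nrow(points))
  if (isTRUE(epr_enabled)) region[d2 < g$epr_radius^2] <- "EPR"
  region[d2 < g$roi_radius^2] <- "ROI"
  dplyr::mutate(as_tibble(points), region = region)
}

#' Specular reflection of a velocity off a surface
#'
#' Returns `v - 2 (v . n) n` for unit normal `n`; the speed (vector norm) is
#' preserved exactly, which keeps the engine's viscosity-derived speed
#' multipliers invariant across wall and sphere bounces.
#'
#' @param velocity Numeric length 3.
#' @param unit_normal Numeric length 3 with norm 1.
#' @return The reflected velocity, numeric length 3.
#' @examples
#' reflect_specular(c(1, 0, 0), c(-1, 0, 0))
#' @export
reflect_specular <- function(velocity, unit_normal) {
  stopifnot(length(velocity) == 3, length(unit_normal) == 3)
  nn <- sum(unit_normal^2)
  if (nn < 1e-24) abort_invalid("reflect_specular: zero-norm normal")
  if (abs(nn - 1) > 1e-6)
    abort_invalid("reflect_specular: normal must have unit norm")
  velocity - 2 * sum(velocity * unit_normal) * unit_normal
}

#' First surface crossing along a straight displacement
#'
#' Continuous-collision helper used by the motion step: finds the earliest
#' parametric intersection `t` in (0, 1] of the segment from `start` to
#' `start + displacement` with any active surface (the six chamber walls,
#' the ROI sphere and — when the EPR zone is enabled — the EPR sphere).
#'
#' @inheritParams classify_region
#' @param start Numeric length 3, inside the chamber.
#' @param displacement Numeric length 3.
#' @return `NULL` if the segment crosses no surface, otherwise a list with
#'   `t`, `surface` (one of `"wall_x+"`, ..., `"roi_sphere"`, `"epr_sphere"`),
#'   `point`, `normal` (outward unit normal at the hit) and `entering`
#'   (`TRUE` when the segment is heading into the sphere's interior; always
#'   `FALSE` for walls, which can only be exited).
#' @examples
#' first_crossing(c(0, 0, 0), c(0.4, 0, 0), sim_geometry())
#' @export
first_crossing <- function(start, displacement, geometry, epr_enabled = FALSE) {
  stopifnot(length(start) == 3, length(displacement) == 3)
  if (all(displacement == 0)) return(NULL)
  res <- first_crossing_cpp(as.numeric(start), as.numeric(displacement),
                            geom_vec(geometry), isTRUE(epr_enabled))
  if (!res$hit) return(NULL)
  list(t = res$t,
       surface = surface_names[res$surface + 1L],
       point = res$point,
       normal = res$normal,
       entering = res$entering)
}
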