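# helper: a state with given active particle positions/directions
active_state <- function(config, pos, dir) {
  sim_state(config, positions = pos, directions = dir,
            status = rep(1L, nrow(pos)))
}

test_that("speed multipliers follow 1 - viscosity", {
  cfg <- sim_config()
  expect_equal(speed_multiplier("FOV", cfg), 1.0)
  expect_equal(speed_multiplier("EPR", cfg), 0.1)
  expect_equal(speed_multiplier("ROI", cfg), 0.845)
  expect_equal(speed_multiplier(c("ROI", "FOV"), sim_config(viscosity_roi = 0.25)),
               c(0.75, 1))
  expect_error(speed_multiplier("TUBE", cfg), class = "eprsim_validation_error")
})

test_that("release activates batches on cadence, from the interior hemisphere", {
  cfg <- sim_config(n_particles = 2000)
  set.seed(1)
  st <- sim_state(cfg)

  st1 <- release_step(st, cfg)          # frame 0: one full batch
  expect_identical(sum(st1$status == 1L), 100L)
  expect_identical(sum(st1$status == 0L), 1900L)

  st1$frame <- 3L                        # off-cadence: nothing released
  expect_identical(sum(release_step(st1, cfg)$status == 1L), 100L)

  # released directions are unit vectors pointing into the chamber (+x wall)
  d <- st1$dir[st1$status == 1L, ]
  expect_equal(rowSums(d^2), rep(1, 100), tolerance = 1e-12)
  expect_true(all(d[, 1] >= 0))

  # a nearly-empty reservoir releases only what remains
  cfg40 <- sim_config(n_particles = 40)
  st40 <- release_step(sim_state(cfg40), cfg40)
  expect_identical(sum(st40$status == 1L), 40L)
  expect_identical(sum(st40$status == 0L), 0L)
})

test_that("motion advances free particles exactly and scales speed by region", {
  g <- sim_geometry()
  cfg <- sim_config(base_speed = 0.01, epr_enabled = FALSE, geometry = g)
  st <- active_state(cfg, matrix(c(0.5, 0.2, 0), 1), matrix(c(1, 0, 0), 1))
  st <- motion_step(st, cfg)
  expect_equal(st$pos[1, ], c(0.51, 0.2, 0), tolerance = 1e-15)

  # one particle per region, none near a surface, attraction off
  cfg <- sim_config(base_speed = 0.02, epr_enabled = TRUE,
                    attraction_strength = 0, geometry = g)
  pos <- rbind(c(0.6, 0.2, 0),     # FOV
               c(0.22, 0, 0),      # EPR shell
               c(0, 0, 0))         # ROI centre
  dir <- rbind(c(0, 1, 0), c(0, 1, 0), c(0, 1, 0))
  st <- active_state(cfg, pos, dir)
  st2 <- motion_step(st, cfg)
  norms <- sqrt(rowSums((st2$pos - pos)^2))
  expect_equal(norms[1] / cfg$base_speed, 1.0, tolerance = 1e-9)
  expect_equal(norms[2] / cfg$base_speed, 0.1, tolerance = 1e-9)
  expect_equal(norms[3] / cfg$base_speed, 0.845, tolerance = 1e-9)
})

test_that("EPR boundary collisions obey the escape rule at its extremes", {
  g <- sim_geometry()
  mk <- function(p) sim_config(epr_enabled = TRUE, attraction_strength = 0,
                               base_speed = 0.05, epr_escape_prob = p,
                               geometry = g)
  start <- matrix(c(0.28, 0, 0), 1)       # in the shell, heading outward
  outward <- matrix(c(1, 0, 0), 1)

  # escape_prob 0: always reflected back, never reaches the FOV
  cfg <- mk(0)
  set.seed(5)
  st <- active_state(cfg, start, outward)
  for (i in 1:200) st <- motion_step(st, cfg)
  expect_gt(st$epr_hits, 0)
  expect_identical(st$epr_escapes, 0L)

  # escape_prob 1: the first boundary hit always escapes
  cfg <- mk(1)
  set.seed(5)
  st <- active_state(cfg, matrix(c(0.297, 0, 0), 1), outward)
  st <- motion_step(st, cfg)              # in-shell speed 0.005 reaches 0.30
  expect_identical(st$epr_hits, 1L)
  expect_identical(st$epr_escapes, 1L)
  r <- sqrt(sum(st$pos[1, ]^2))
  expect_gt(r, g$epr_radius)              # now in the FOV
})

test_that("EPR attraction turns trajectories toward the tumor without rescaling", {
  g <- sim_geometry()
  cfg <- sim_config(epr_enabled = TRUE, attraction_strength = 0.2,
                    base_speed = 0.001, geometry = g)
  # tangentially-moving particle in the shell
  st <- active_state(cfg, matrix(c(0.25, 0, 0), 1), matrix(c(0, 1, 0), 1))
  to_ctr0 <- -st$pos[1, ] / sqrt(sum(st$pos[1, ]^2))
  ang0 <- acos(sum(st$dir[1, ] * to_ctr0))
  st <- motion_step(st, cfg)
  to_ctr1 <- -st$pos[1, ] / sqrt(sum(st$pos[1, ]^2))
  ang1 <- acos(sum(st$dir[1, ] * to_ctr1))
  expect_lt(ang1, ang0)                       # turned toward the centre
  expect_equal(sqrt(sum(st$dir[1, ]^2)), 1, tolerance = 1e-12)
})

test_that("clearance respects delays, cadences and pool definitions", {
  g <- sim_geometry()
  cfg <- sim_config(n_particles = 10, fov_delay = 250, fov_rate = 5,
                    roi_delay = 1000, geometry = g)
  pos <- matrix(rep(c(0.6, 0.2, 0), each = 10), 10)
  st <- active_state(cfg, pos, matrix(rep(c(1, 0, 0), each = 10), 10))

  st$frame <- 249L                       # one frame before the delay
  expect_identical(sum(clearance_step(st, cfg)$status == 2L), 0L)

  st$frame <- 250L                       # the first event fires at the delay
  set.seed(2)
  st2 <- clearance_step(st, cfg)
  expect_identical(sum(st2$status == 2L), 5L)
  # cleared particles are parked at the clearance site, outside the chamber
  cleared <- which(st2$status == 2L)
  expect_true(all(st2$pos[cleared, 1] == g$clearance_site[1]))

  st2$frame <- 260L                      # off-cadence: nothing happens
  expect_identical(sum(clearance_step(st2, cfg)$status == 2L), 5L)

  # a 3-particle ROI pool with rate 10 is emptied, not overdrawn
  cfgroi <- sim_config(n_particles = 3, roi_delay = 40, roi_rate = 10,
                       fov_delay = 10000, geometry = g)
  stroi <- active_state(cfgroi, matrix(rep(c(0.05, 0, 0), each = 3), 3),
                        matrix(rep(c(1, 0, 0), each = 3), 3))
  stroi$frame <- 40L
  set.seed(3)
  expect_identical(sum(clearance_step(stroi, cfgroi)$status == 2L), 3L)

  # EPR-zone particles belong to the FOV clearance pool
  cfge <- sim_config(n_particles = 4, epr_enabled = TRUE, fov_delay = 0,
                     fov_rate = 10, roi_delay = 10000, geometry = g)
  ste <- active_state(cfge, matrix(rep(c(0.22, 0, 0), each = 4), 4),
                      matrix(rep(c(1, 0, 0), each = 4), 4))
  set.seed(4)
  expect_identical(sum(clearance_step(ste, cfge)$status == 2L), 4L)
})

test_that("clearance event frames form the configured arithmetic progressions", {
  run <- simulate_biodistribution(
    sim_preset("sim2", n_particles = 400, max_frames = 1200, seed = 8))
  ev <- run$events
  fov <- ev$frame[ev$event == "fov_clearance"]
  roi <- ev$frame[ev$event == "roi_clearance"]
  expect_identical(fov[1], 250L)
  expect_true(all(diff(fov) == 20L))
  expect_identical(roi[1], 750L)
  expect_true(all(diff(roi) == 40L))
  rel <- ev$frame[ev$event == "release"]
  expect_identical(rel, seq(0L, 15L, by = 5L))  # 400 particles, batches of 100
})

test_that("advance_frame composes the sub-steps, conserves particles and replays", {
  cfg <- tiny_config(seed = 11)
  set.seed(cfg$seed)
  st <- sim_state(cfg)
  prev_roi <- st$entered_roi
  prev_cleared <- st$status == 2L
  for (k in 1:300) {
    st <- advance_frame(st, cfg)
    expect_identical(st$frame, k)
    # conservation: no particle created or destroyed
    expect_identical(length(st$status), cfg$n_particles)
    expect_identical(sum(st$status == 0L) + sum(st$status == 1L) +
                       sum(st$status == 2L), cfg$n_particles)
    # monotone lifecycle flags
    expect_true(all(st$entered_roi >= prev_roi))
    expect_true(all((st$status == 2L) >= prev_cleared))
    prev_roi <- st$entered_roi
    prev_cleared <- st$status == 2L
  }

  # bit-identical replay under the same config and seed
  r1 <- simulate_biodistribution(cfg)
  r2 <- simulate_biodistribution(cfg)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(r1$state$pos, r2$state$pos)
  expect_identical(r1$state$dir, r2$state$dir)
})

test_that("particles do not interact: each trajectory is unchanged when stepped alone", {
  g <- sim_geometry()
  # EPR off and no clearance: the motion step consumes no randomness
  cfg <- sim_config(epr_enabled = FALSE, base_speed = 0.03, geometry = g)
  set.seed(21)
  n <- 5
  pos <- cbind(runif(n, -0.9, 0.9), runif(n, -0.5, 0.5), runif(n, -0.5, 0.5))
  dir <- matrix(rnorm(3 * n), n)
  dir <- dir / sqrt(rowSums(dir^2))

  st <- active_state(cfg, pos, dir)
  for (i in 1:200) st <- motion_step(st, cfg)

  for (j in seq_len(n)) {
    stj <- active_state(cfg, pos[j, , drop = FALSE], dir[j, , drop = FALSE])
    for (i in 1:200) stj <- motion_step(stj, cfg)
    expect_identical(stj$pos[1, ], st$pos[j, ])
    expect_identical(stj$dir[1, ], st$dir[j, ])
  }
})

test_that("run with zero particles yields an identically-zero series", {
  run <- simulate_biodistribution(sim_config(n_particles = 0, max_frames = 90))
  s <- tidy(run)
  expect_identical(nrow(s), 4L)  # frames 0, 30, 60, 90
  expect_true(all(s$pct_fov == 0) && all(s$pct_roi == 0) &&
                all(s$pct_cleared == 0))
})
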