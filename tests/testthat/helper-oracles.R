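# Independent brute-force oracles used to cross-check the fast paths.

# Dense-sampling collision oracle: walks the segment in n tiny steps and
# reports the first step at which any surface membership flips.
brute_force_crossing <- function(start, disp, geometry, epr_enabled,
                                 n = 1e4) {
  ts <- seq(0, 1, length.out = n + 1)
  pts <- cbind(start[1] + ts * disp[1],
               start[2] + ts * disp[2],
               start[3] + ts * disp[3])
  h <- geometry$chamber_half_extents
  ctr <- geometry$roi_center
  d2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 + (pts[, 3] - ctr[3])^2
  cand <- list()
  in_roi <- d2 < geometry$roi_radius^2
  flip <- which(in_roi != in_roi[1])
  if (length(flip))
    cand[[length(cand) + 1]] <- list(t = ts[flip[1]], surface = "roi_sphere")
  if (epr_enabled) {
    in_epr <- d2 < geometry$epr_radius^2
    flip <- which(in_epr != in_epr[1])
    if (length(flip))
      cand[[length(cand) + 1]] <- list(t = ts[flip[1]], surface = "epr_sphere")
  }
  for (a in 1:3) {
    out_hi <- pts[, a] > h[a]
    out_lo <- pts[, a] < -h[a]
    flip <- which(out_hi)
    if (length(flip))
      cand[[length(cand) + 1]] <- list(
        t = ts[flip[1]], surface = paste0("wall_", c("x", "y", "z")[a], "+"))
    flip <- which(out_lo)
    if (length(flip))
      cand[[length(cand) + 1]] <- list(
        t = ts[flip[1]], surface = paste0("wall_", c("x", "y", "z")[a], "-"))
  }
  if (!length(cand)) return(NULL)
  cand[[which.min(vapply(cand, function(x) x$t, numeric(1)))]]
}

# Plain-loop summary scan, independent of summarize_distribution()'s
# vectorized implementation.
brute_force_summary <- function(series) {
  peak <- -Inf; peak_frame <- NA_integer_
  cross <- NA_integer_
  ws <- NA_integer_; we <- NA_integer_; in_win <- FALSE; done_win <- FALSE
  for (i in seq_len(nrow(series))) {
    roi <- series$pct_roi[i]; fov <- series$pct_fov[i]
    if (roi > peak) { peak <- roi; peak_frame <- series$frame[i] }
    if (is.na(cross) && roi >= fov && !(roi == 0 && fov == 0))
      cross <- series$frame[i]
    win <- fov == 0 && roi > 0
    if (win && !in_win && !done_win) { ws <- series$frame[i]; in_win <- TRUE }
    if (in_win && win) we <- series$frame[i]
    if (in_win && !win) { in_win <- FALSE; done_win <- TRUE }
  }
  list(peak_roi_pct = peak, peak_roi_frame = peak_frame,
       crossover_frame = cross, window_start_frame = ws,
       window_end_frame = we)
}

# Run-length scan over a logical vector, as (start, end) index pairs.
brute_force_runs <- function(above) {
  runs <- list()
  i <- 1
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

# Small fast configs for unit tests.
tiny_config <- function(...) {
  sim_config(n_particles = 200, max_frames = 300, ...)
}
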