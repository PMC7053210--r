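# one-row distribution snapshot of a state; percentages are of the total
# administered dose so FOV and ROI curves can both decay to zero
distribution_row <- function(state, config) {
  n <- length(state$status)
  in_roi <- in_roi_mask(state, config)
  fov_pool <- state$status == STATUS_ACTIVE & !in_roi
  emitting <- emitting_mask(state, config)
  denom <- if (n > 0) n else 1
  tibble(frame = state$frame,
         pct_fov = 100 * sum(fov_pool) / denom,
         pct_roi = 100 * sum(in_roi) / denom,
         pct_cleared = 100 * sum(state$status == STATUS_CLEARED) / denom,
         n_emitting_roi = sum(emitting & in_roi),
         n_emitting_fov = sum(emitting & fov_pool))
}

#' Sample the fluorophore distribution chart
#'
#' Returns a one-row tibble when the state's frame counter is a multiple of
#' `sample_cadence` (every 30 frames by default), else `NULL`. Percentages
#' are relative to the total number of administered particles; EPR-zone
#' particles count toward the FOV curve, matching the clearance bookkeeping.
#'
#' @param state A [sim_state()].
#' @param config A [sim_config()].
#' @return A tibble with columns `frame`, `pct_fov`, `pct_roi`,
#'   `pct_cleared`, `n_emitting_roi`, `n_emitting_fov`, or `NULL` off-cadence.
#' @export
sample_distribution <- function(state, config) {
  if (state$frame %% config$sample_cadence != 0L) return(NULL)
  distribution_row(state, config)
}

#' Summarize contrast phenomenology of a distribution series
#'
#' Single-pass summary of a sampled distribution series:
#' \describe{
#'   \item{peak_roi_pct, peak_roi_frame}{maximum ROI percentage and the
#'     frame of the first sample attaining it (ties broken earliest).}
#'   \item{crossover_frame}{frame of the first sample with
#'     `pct_roi >= pct_fov` — the point of equal tumor and background
#'     fluorophore load. Samples where both percentages are exactly zero
#'     never count (no signal implies no contrast); `NA` if no crossover.}
#'   \item{window_start_frame, window_end_frame}{the contrast window: the
#'     first maximal run of samples with `pct_fov == 0` while
#'     `pct_roi > 0`, i.e. full background clearance with fluorophore
#'     remaining in the tumor. `NA` if none.}
#'   \item{detect_onset_frame}{first sample with at least one emitting
#'     particle inside the ROI — in responsive (off-to-on) mode, the moment
#'     the tumor first becomes detectable. `NA` if never, or if the series
#'     lacks emission counts.}
#' }
#'
#' @param series A distribution series tibble (from [tidy.sim_run()] or
#'   [read_distribution_csv()]) with at least `frame`, `pct_fov`, `pct_roi`.
#' @return A one-row tibble.
#' @examples
#' run <- simulate_biodistribution(
#'   sim_preset("sim1", n_particles = 200, max_frames = 900))
#' summarize_distribution(tidy(run))
#' @export
summarize_distribution <- function(series) {
  if (!is.data.frame(series) || nrow(series) == 0)
    abort_invalid("summarize_distribution: series must be a nonempty data frame")
  stopifnot(all(c("frame", "pct_fov", "pct_roi") %in% names(series)))
  peak_i <- which.max(series$pct_roi)
  cross <- which(series$pct_roi >= series$pct_fov &
                   !(series$pct_roi == 0 & series$pct_fov == 0))
  crossover_frame <- if (length(cross)) series$frame[cross[1]] else NA_integer_
  win <- series$pct_fov == 0 & series$pct_roi > 0
  if (any(win)) {
    r <- rle(win)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values)[1]
    ws <- series$frame[starts[k]]
    we <- series$frame[ends[k]]
  } else {
    ws <- we <- NA_integer_
  }
  onset <- NA_integer_
  if ("n_emitting_roi" %in% names(series)) {
    d <- which(series$n_emitting_roi > 0)
    if (length(d)) onset <- series$frame[d[1]]
  }
  tibble(peak_roi_pct = series$pct_roi[peak_i],
         peak_roi_frame = series$frame[peak_i],
         crossover_frame = crossover_frame,
         window_start_frame = ws,
         window_end_frame = we,
         detect_onset_frame = onset)
}

#' Read / write a distribution series as CSV
#'
#' RFC-4180 CSV with header
#' `frame,pct_fov,pct_roi,pct_cleared,n_emitting_roi,n_emitting_fov`, one
#' row per sample. Write -> read -> write round-trips byte-identically.
#'
#' @param series A distribution series tibble.
#' @param path File path.
#' @return `write_distribution_csv()` returns `path` invisibly;
#'   `read_distribution_csv()` returns the series tibble.
#' @export
write_distribution_csv <- function(series, path) {
  cols <- c("frame", "pct_fov", "pct_roi", "pct_cleared",
            "n_emitting_roi", "n_emitting_fov")
  stopifnot(all(cols %in% names(series)))
  readr::write_csv(series[cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_distribution_csv
#' @export
read_distribution_csv <- function(path) {
  readr::read_csv(path, progress = FALSE, show_col_types = FALSE,
                  col_types = readr::cols(
                    frame = readr::col_integer(),
                    pct_fov = readr::col_double(),
                    pct_roi = readr::col_double(),
                    pct_cleared = readr::col_double(),
                    n_emitting_roi = readr::col_integer(),
                    n_emitting_fov = readr::col_integer()))
}

#' Plot a fluorophore distribution time course
#'
#' Line chart of %FOV, %ROI and %cleared against frame, with the contrast
#' window (full background clearance with fluorophore remaining in the ROI)
#' shaded when present.
#'
#' @param series A distribution series tibble, or a `sim_run`.
#' @return A ggplot object.
#' @export
plot_distribution <- function(series) {
  if (inherits(series, "sim_run")) series <- series$series
  summ <- summarize_distribution(series)
  long <- tidyr::pivot_longer(
    series[c("frame", "pct_fov", "pct_roi", "pct_cleared")],
    -"frame", names_to = "compartment", values_to = "pct")
  long$compartment <- factor(long$compartment,
                             levels = c("pct_fov", "pct_roi", "pct_cleared"),
                             labels = c("FOV", "ROI", "cleared"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$pct,
                                          colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "% of administered fluorophore",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(summ$window_start_frame))
    p <- p + ggplot2::annotate("rect",
                               xmin = summ$window_start_frame,
                               xmax = summ$window_end_frame,
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  p
}

#' @rdname plot_distribution
#' @param object A `sim_run`.
#' @param ... Unused.
#' @export
autoplot.sim_run <- function(object, ...) plot_distribution(object$series)
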