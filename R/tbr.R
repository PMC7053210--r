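bg_cols <- c("bg1_tre", "bg2_tre", "bg3_tre")

check_intensity_cols <- function(data) {
  need <- c("time_h", "tumor_tre", bg_cols)
  miss <- setdiff(need, names(data))
  if (length(miss))
    abort_invalid(paste0("intensity data is missing column(s): ",
                         paste(miss, collapse = ", ")))
  if (any(data$tumor_tre < 0, na.rm = TRUE) ||
      any(as.matrix(data[bg_cols]) < 0, na.rm = TRUE))
    abort_invalid("intensities must be non-negative")
  if (is.unsorted(data$time_h, strictly = TRUE))
    abort_invalid("column 'time_h' must be strictly increasing")
  invisible(data)
}

#' Tumor-to-background ratio from total radiant efficiencies
#'
#' TBR at each imaging time point is the tumor ROI total radiant efficiency
#' (TRE, (p/sec)/(uW/cm2)) divided by the mean TRE of three equal-area
#' background ROIs. The ratio is unitless and scale-invariant: rescaling
#' every intensity at a time point by a common factor leaves it unchanged.
#'
#' @param data A data frame with columns `time_h`, `tumor_tre`, `bg1_tre`,
#'   `bg2_tre`, `bg3_tre` (e.g. from [read_intensity_csv()] or
#'   [synth_timecourse()]).
#' @return The input as a tibble with `bg_mean_tre` and `tbr` columns
#'   appended.
#' @examples
#' tbr(tibble::tibble(time_h = 24, tumor_tre = 6,
#'                    bg1_tre = 2, bg2_tre = 3, bg3_tre = 4))
#' @export
tbr <- function(data) {
  check_intensity_cols(data)
  bg_mean <- rowMeans(as.matrix(data[bg_cols]))
  if (any(!is.finite(bg_mean)) || any(bg_mean <= 0))
    abort_invalid(paste0(
      "undefined TBR: mean background TRE must be > 0 at every time point ",
      "(offending time_h: ",
      paste(data$time_h[!is.finite(bg_mean) | bg_mean <= 0], collapse = ", "),
      ")"))
  dplyr::mutate(as_tibble(data), bg_mean_tre = bg_mean,
                tbr = .data$tumor_tre / bg_mean)
}

#' Threshold crossings of a TBR time course
#'
#' Finds the maximal runs of consecutive samples at or above the TBR
#' threshold (2 by default, the conventional clinically relevant contrast
#' level). No interpolation is performed between imaging time points:
#' crossing times are reported at sample resolution, and an interval's
#' bounds are the first and last sample times of its run.
#'
#' @param data A data frame with `time_h` and `tbr` columns (see [tbr()]),
#'   or intensity columns from which TBR can be computed.
#' @param threshold TBR threshold. Default 2.
#' @return A tibble of intervals with columns `start_time`, `end_time`,
#'   `n_samples`; zero rows when the threshold is never reached. The first
#'   time above threshold is `min(start_time)`.
#' @examples
#' d <- tibble::tibble(time_h = c(1, 9, 24, 48),
#'                     tbr = c(1.1, 1.5, 2.0, 2.3))
#' tbr_crossings(d)
#' @export
tbr_crossings <- function(data, threshold = 2) {
  if (!"tbr" %in% names(data)) data <- tbr(data)
  if (nrow(data) == 0)
    abort_invalid("tbr_crossings: series must be nonempty")
  if (is.unsorted(data$time_h, strictly = TRUE))
    abort_invalid("column 'time_h' must be strictly increasing")
  above <- data$tbr >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble(start_time = data$time_h[starts[keep]],
         end_time = data$time_h[ends[keep]],
         n_samples = r$lengths[keep])
}

#' One-row summary of a TBR time course
#'
#' @inheritParams tbr_crossings
#' @return A tibble with `first_time_above` (first sample time with
#'   `tbr >= threshold`, `NA` if never), `n_intervals`, `peak_tbr`,
#'   `peak_time` and `threshold`.
#' @export
tbr_summary <- function(data, threshold = 2) {
  if (!"tbr" %in% names(data)) data <- tbr(data)
  iv <- tbr_crossings(data, threshold)
  peak_i <- which.max(data$tbr)
  tibble(first_time_above = if (nrow(iv)) min(iv$start_time) else NA_real_,
         n_intervals = nrow(iv),
         peak_tbr = data$tbr[peak_i],
         peak_time = data$time_h[peak_i],
         threshold = threshold)
}

#' Fold change between two sampled time points
#'
#' Ratio of an intensity at a reference time over the intensity at a later
#' time, e.g. the relative decrease of tumor fluorescence from the time of
#' maximum emission to the end of a study as an indicator of enhanced
#' retention. Times must be actual sample times — the analysis operates at
#' acquisition resolution and never interpolates.
#'
#' @param data A data frame with a `time_h` column.
#' @param t_ref,t_end Sample times (hours); both must be present in `data`.
#' @param col Name of the intensity column. Default `"tumor_tre"`.
#' @return A single ratio `value(t_ref) / value(t_end)`.
#' @examples
#' d <- tibble::tibble(time_h = c(9, 168), tumor_tre = c(7.7e8, 1e8))
#' fold_change(d, 9, 168)
#' @export
fold_change <- function(data, t_ref, t_end, col = "tumor_tre") {
  stopifnot(is.data.frame(data), "time_h" %in% names(data),
            col %in% names(data))
  pick <- function(t) {
    i <- which(abs(data$time_h - t) < 1e-9)
    if (length(i) != 1)
      abort_invalid(sprintf(
        "fold_change: time %g h is not a sampled time point (no interpolation)", t))
    data[[col]][i]
  }
  num <- pick(t_ref)
  den <- pick(t_end)
  if (!is.finite(den) || den <= 0)
    abort_invalid("fold_change: intensity at t_end must be > 0")
  num / den
}

#' Synthetic longitudinal intensity time course
#'
#' Generates tumor and triplicate background TRE records with the
#' qualitative shape of an off-to-on probe's in vivo profile: complete
#' silence until `onset_delay` (the switch stays off in circulation), a
#' rise governed by `uptake_rate` to a peak, then slow monoexponential
#' decay, with the background clearing faster than the tumor so the TBR
#' keeps growing in the tail. The noise-free tumor curve is
#' `amplitude * (1 - exp(-uptake_rate * s)) * exp(-clearance_rate_tumor * s)`
#' with `s = max(time - onset_delay, 0)`; backgrounds follow the same form
#' with `bg_amplitude` and `clearance_rate_bg`. Each observation is
#' multiplied by independent lognormal noise with coefficient of variation
#' `noise_cv` (unit mean).
#'
#' Defaults place the tumor peak near 24 h with an early-tail TBR of about
#' 1.1 growing through the clinically relevant threshold of 2 at 24 h, and
#' sample at a typical acquisition grid from 10 min to 168 h.
#'
#' @param times Sample times in hours.
#' @param amplitude Tumor amplitude, TRE units.
#' @param bg_amplitude Background amplitude; the default `amplitude / 1.1`
#'   pins the noise-free TBR to 1.1 just after onset.
#' @param uptake_rate Uptake rate constant, 1/h.
#' @param clearance_rate_tumor,clearance_rate_bg Clearance rate constants,
#'   1/h; retention requires `clearance_rate_tumor < clearance_rate_bg`.
#' @param onset_delay Hours of complete pre-switch-on silence.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise; 0 gives the exact closed form.
#' @param baseline Additive intensity floor applied after the delay
#'   (instrument/autofluorescence); default 0.
#' @param seed Optional integer seed for reproducible noise.
#' @return A tibble with columns `time_h`, `tumor_tre`, `bg1_tre`,
#'   `bg2_tre`, `bg3_tre`.
#' @examples
#' synth_timecourse(noise_cv = 0) |> dplyr::filter(time_h > 1) |> tbr()
#' @export
synth_timecourse <- function(times = c(0.17, 0.5, 1, 3, 6, 9, 24, 48, 72,
                                       96, 168),
                             amplitude = 1e9,
                             bg_amplitude = amplitude / 1.1,
                             uptake_rate = 0.10,
                             clearance_rate_tumor = 0.01,
                             clearance_rate_bg = 0.036,
                             onset_delay = 1,
                             noise_cv = 0.1,
                             baseline = 0,
                             seed = NULL) {
  if (uptake_rate <= 0 || clearance_rate_tumor <= 0 || clearance_rate_bg <= 0)
    abort_invalid("rates must be > 0")
  if (noise_cv < 0) abort_invalid("noise_cv must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  s <- pmax(times - onset_delay, 0)
  shape <- function(A, k_clear)
    ifelse(s > 0, A * (1 - exp(-uptake_rate * s)) * exp(-k_clear * s) +
             baseline, 0)
  noisy <- function(mu) {
    if (noise_cv == 0) return(mu)
    sdlog <- sqrt(log(1 + noise_cv^2))
    mu * rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  tibble(time_h = times,
         tumor_tre = noisy(shape(amplitude, clearance_rate_tumor)),
         bg1_tre = noisy(shape(bg_amplitude, clearance_rate_bg)),
         bg2_tre = noisy(shape(bg_amplitude, clearance_rate_bg)),
         bg3_tre = noisy(shape(bg_amplitude, clearance_rate_bg)))
}

#' Read / write TBR-related CSV files
#'
#' `read_intensity_csv()` expects header
#' `time_h,tumor_tre,bg1_tre,bg2_tre,bg3_tre`; `write_tbr_csv()` writes
#' `time_h,tbr`.
#'
#' @param path File path.
#' @param data A data frame with `time_h` and `tbr` columns.
#' @return `read_intensity_csv()` returns a tibble of intensity records;
#'   `write_tbr_csv()` returns `path` invisibly.
#' @export
read_intensity_csv <- function(path) {
  d <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_double()))
  check_intensity_cols(d)
  d
}

#' @rdname read_intensity_csv
#' @export
write_tbr_csv <- function(data, path) {
  if (!"tbr" %in% names(data)) data <- tbr(data)
  readr::write_csv(data[c("time_h", "tbr")], path, progress = FALSE)
  invisible(path)
}

#' Plot a TBR time course
#'
#' TBR against time with the threshold drawn as a dashed reference line.
#'
#' @param data A data frame with `time_h` and `tbr` (computed via [tbr()]
#'   if absent).
#' @param threshold Reference TBR threshold. Default 2.
#' @return A ggplot object.
#' @export
plot_tbr <- function(data, threshold = 2) {
  if (!"tbr" %in% names(data)) data <- tbr(data)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$time_h, y = .data$tbr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "time (h)", y = "tumor-to-background ratio") +
    ggplot2::theme_minimal()
}
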