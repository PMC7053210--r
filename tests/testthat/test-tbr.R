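record <- function(time_h, tumor, bg) {
  tibble::tibble(time_h = time_h, tumor_tre = tumor,
                 bg1_tre = bg[1], bg2_tre = bg[2], bg3_tre = bg[3])
}

test_that("tbr is tumor TRE over the mean of three background TREs", {
  expect_equal(tbr(record(24, 6, c(2, 3, 4)))$tbr, 2.0)
  expect_equal(tbr(record(24, 5, c(5, 5, 5)))$tbr, 1.0)
  expect_equal(tbr(record(24, 0, c(1, 2, 3)))$tbr, 0)

  expect_error(tbr(record(24, 6, c(0, 0, 0))), "time_h: 24",
               class = "eprsim_validation_error")
  expect_error(tbr(record(24, -1, c(1, 1, 1))),
               class = "eprsim_validation_error")

  # scale invariance: a common factor at a time point cancels
  set.seed(14)
  for (i in 1:20) {
    vals <- runif(4, 0.5, 9)
    r0 <- tbr(record(1, vals[1], vals[2:4]))$tbr
    c0 <- runif(1, 0.01, 100)
    r1 <- tbr(record(1, c0 * vals[1], c0 * vals[2:4]))$tbr
    expect_equal(r1, r0, tolerance = 1e-12)
  }
})

test_that("threshold crossings report maximal runs at sample resolution", {
  d <- tibble::tibble(time_h = c(1, 9, 24, 48), tbr = c(1.1, 1.5, 2.0, 2.3))
  iv <- tbr_crossings(d, threshold = 2)
  expect_identical(nrow(iv), 1L)
  expect_equal(iv$start_time, 24)
  expect_equal(iv$end_time, 48)
  expect_equal(tbr_summary(d)$first_time_above, 24)

  # never above threshold
  low <- tibble::tibble(time_h = 1:4, tbr = c(0.5, 1, 1.5, 1.9))
  expect_identical(nrow(tbr_crossings(low)), 0L)
  expect_true(is.na(tbr_summary(low)$first_time_above))

  # a dip below threshold splits the run in two
  dip <- tibble::tibble(time_h = c(1, 2, 3, 4, 5),
                        tbr = c(2.5, 1.2, 2.1, 2.2, 1.0))
  iv <- tbr_crossings(dip)
  expect_identical(nrow(iv), 2L)
  expect_equal(iv$start_time, c(1, 3))
  expect_equal(iv$end_time, c(1, 4))

  expect_error(tbr_crossings(dip[0, ]), class = "eprsim_validation_error")

  # agreement with an independent run-length scan on random series
  set.seed(55)
  for (i in 1:50) {
    k <- sample(2:30, 1)
    d <- tibble::tibble(time_h = sort(runif(k, 0, 200)),
                        tbr = runif(k, 0, 4))
    iv <- tbr_crossings(d, threshold = 2)
    runs <- brute_force_runs(d$tbr >= 2)
    expect_identical(nrow(iv), length(runs))
    for (j in seq_along(runs)) {
      expect_equal(iv$start_time[j], d$time_h[runs[[j]][1]])
      expect_equal(iv$end_time[j], d$time_h[runs[[j]][2]])
    }
  }
})

test_that("fold_change ratios sampled intensities without interpolation", {
  d <- tibble::tibble(time_h = c(9, 168), tumor_tre = c(7.7, 1.0))
  expect_equal(fold_change(d, 9, 168), 7.7)

  flat <- tibble::tibble(time_h = c(9, 168), tumor_tre = c(3, 3))
  expect_equal(fold_change(flat, 9, 168), 1.0)
  expect_equal(fold_change(flat, 9, 9), 1.0)

  expect_error(fold_change(d, 10, 168), "not a sampled",
               class = "eprsim_validation_error")
  zero <- tibble::tibble(time_h = c(9, 168), tumor_tre = c(3, 0))
  expect_error(fold_change(zero, 9, 168), class = "eprsim_validation_error")

  # biexponential generator output matches its closed form at the two times
  tc <- synth_timecourse(times = c(9, 168), noise_cv = 0)
  s <- c(9, 168) - 1                               # default onset delay 1 h
  closed <- 1e9 * (1 - exp(-0.10 * s)) * exp(-0.01 * s)
  expect_equal(fold_change(tc, 9, 168), closed[1] / closed[2],
               tolerance = 1e-12)
})

test_that("synthetic time courses are silent pre-onset and exact when noise-free", {
  tc <- synth_timecourse(noise_cv = 0)
  # complete first-hour silence (onset delay 1 h)
  early <- tc[tc$time_h <= 1, ]
  expect_true(all(as.matrix(early[-1]) == 0))

  # exact closed-form values after onset
  s <- pmax(tc$time_h - 1, 0)
  expect_equal(tc$tumor_tre, 1e9 * (1 - exp(-0.10 * s)) * exp(-0.01 * s))
  expect_equal(tc$bg1_tre, 1e9 / 1.1 * (1 - exp(-0.10 * s)) * exp(-0.036 * s))
  expect_identical(tc$bg1_tre, tc$bg2_tre)

  # noise is reproducible under a seed and centred on the closed form
  n1 <- synth_timecourse(seed = 9)
  n2 <- synth_timecourse(seed = 9)
  expect_identical(n1, n2)

  # slower tumor clearance than background: noise-free TBR is increasing
  # over the sampled tail and crosses the threshold as a single suffix run
  post <- tbr(tc[tc$time_h > 1, ])
  expect_true(all(diff(post$tbr) > 0))
  iv <- tbr_crossings(post, threshold = 2)
  expect_identical(nrow(iv), 1L)
  expect_equal(iv$end_time, max(post$time_h))
})

test_that("intensity and TBR CSV interfaces round-trip", {
  tc <- synth_timecourse(seed = 4)
  p <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tc, p)
  back <- read_intensity_csv(p)
  expect_equal(as.data.frame(back), as.data.frame(tc))

  post <- tbr(tc[tc$time_h > 1, ])
  write_tbr_csv(post, p)
  lines <- readLines(p)
  expect_identical(lines[1], "time_h,tbr")
  expect_identical(length(lines), nrow(post) + 1L)
  expect_s3_class(plot_tbr(post), "ggplot")
})
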