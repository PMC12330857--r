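test_that("RV windows: zero variance, missing rule, amplitude oracle", {
  # constant waveform: RV = 0 at every volume
  rv <- compute_rv(rep(3, 1000), 100, 2, 5)
  expect_equal(rv$values, rep(0, 5))
  expect_identical(rv$kind, "RV")

  # missing rule: a window at/above 20% missing is NA, below is kept
  resp <- sin(2 * pi * 0.3 * (1:6000) / 100)
  resp_25 <- resp
  resp_25[251:400] <- NA  # 150 of ~600 in-window samples around volume 2
  rv25 <- compute_rv(resp_25, 100, 2, 10, window_s = 6)
  expect_true(is.na(rv25$values[2]))
  resp_10 <- resp
  resp_10[271:330] <- NA  # 60/600 = 10% missing
  rv10 <- compute_rv(resp_10, 100, 2, 10, window_s = 6)
  expect_false(is.na(rv10$values[2]))

  # sinusoid with window >> period: RV ~ A / sqrt(2), and equals the
  # direct sample-SD oracle exactly
  amp <- 2.5
  w <- amp * sin(2 * pi * 1 * (1:3000) / 100)
  rvs <- compute_rv(w, 100, 3, 8, window_s = 6)
  expect_equal(rvs$values[4], amp / sqrt(2), tolerance = 0.01)
  center <- (4 - 0.5) * 3
  idx <- ceiling((center - 3) * 100):floor((center + 3) * 100)
  expect_equal(rvs$values[4], sd(w[idx]))

  # RV scales linearly with waveform amplitude
  expect_equal(compute_rv(2 * w, 100, 3, 8)$values,
               2 * compute_rv(w, 100, 3, 8)$values)

  expect_error(compute_rv(numeric(0), 100, 2, 5),
               class = "vigifc_parameter_error")
  expect_error(compute_rv(w, 100, 2, 5, window_s = 0),
               class = "vigifc_parameter_error")
})

test_that("beat detection: pulse trains, noise robustness, failures", {
  sfreq <- 100
  tt <- (1:3000) / sfreq
  train <- rowSums(sapply(seq(0.5, 29.5, by = 1), function(b) {
    exp(-(tt - b)^2 / (2 * 0.05^2))
  }))
  beats <- detect_beats(train, sfreq)
  expect_equal(beats$ibi_s, rep(1, length(beats$ibi_s)))
  expect_equal(length(beats$beat_times_s), 30)

  # low-amplitude noise leaves the beat count unchanged (noiseless oracle)
  set.seed(4)
  noisy <- train + rnorm(3000, 0, 0.02)
  expect_equal(length(detect_beats(noisy, sfreq)$beat_times_s), 30)

  expect_error(detect_beats(rep(0, 1000), sfreq),
               class = "vigifc_unusable_recording")
  expect_error(detect_beats(c(1, NA, 2), sfreq),
               class = "vigifc_parameter_error")
})

test_that("IBI outlier interpolation matches the hand/brute-force oracle", {
  mk <- function(ibi) new_beats_for_test(ibi)
  # all-equal IBIs: zero SD handled as outlier-free
  b <- interpolate_ibi_outliers(mk(rep(0.9, 8)))
  expect_false(any(b$outlier_flags))
  expect_equal(b$ibi_s, rep(0.9, 8))

  # hand oracle: single spike among many regular beats
  ibi <- c(rep(1, 5), 3, rep(1, 4))
  flags_hand <- abs(ibi - mean(ibi)) > 2.5 * sd(ibi)
  expect_true(flags_hand[6])  # the spike is beyond the cutoff here
  b2 <- interpolate_ibi_outliers(mk(ibi))
  expect_equal(b2$outlier_flags, flags_hand)
  expect_equal(b2$ibi_s, brute_interp(ibi, flags_hand))
  expect_equal(b2$ibi_s[6], 1)

  # two adjacent outliers interpolate across the valid bracket
  ibi3 <- c(rep(1, 10), 3.0, 3.2, rep(1, 10))
  flags3 <- abs(ibi3 - mean(ibi3)) > 2.5 * sd(ibi3)
  expect_equal(which(flags3), c(11L, 12L))
  b3 <- interpolate_ibi_outliers(mk(ibi3))
  expect_equal(b3$ibi_s, brute_interp(ibi3, flags3))

  # flagged endpoint extrapolates from the nearest valid value
  ibi4 <- c(4, rep(1, 9))
  b4 <- interpolate_ibi_outliers(mk(ibi4))
  expect_equal(b4$ibi_s[1], 1)

  # idempotence: a second pass flags nothing
  for (case in list(ibi, ibi3, ibi4)) {
    once <- interpolate_ibi_outliers(mk(case))
    twice <- interpolate_ibi_outliers(once)
    expect_false(any(twice$outlier_flags))
    expect_equal(twice$ibi_s, once$ibi_s)
  }

  expect_error(interpolate_ibi_outliers(mk(c(1, 5))),
               class = "vigifc_parameter_error")
})

test_that("HR windows: 1/median-IBI against a sort-based oracle", {
  mk_beats <- function(times) {
    structure(list(beat_times_s = times, ibi_s = diff(times),
                   outlier_flags = rep(FALSE, length(times) - 1)),
              class = "vigi_beats")
  }
  hr1 <- compute_hr(mk_beats(seq(0, 30, by = 1)), tr_s = 2, n_volumes = 10)
  expect_equal(hr1$values, rep(1, 10))
  hr2 <- compute_hr(mk_beats(seq(0, 30, by = 0.5)), tr_s = 2, n_volumes = 10)
  expect_equal(hr2$values, rep(2, 10))

  # mixed IBIs: exhaustive median oracle inside one window
  set.seed(9)
  times <- cumsum(c(0, runif(40, 0.6, 1.4)))
  bt <- mk_beats(times)
  hrm <- compute_hr(bt, tr_s = 3, n_volumes = 8, window_s = 6)
  v <- 4
  center <- (v - 0.5) * 3
  sel <- times[-1] > center - 3 & times[-length(times)] < center + 3
  med <- sort(bt$ibi_s[sel])[c(floor((sum(sel) + 1) / 2),
                               ceiling((sum(sel) + 1) / 2))]
  expect_equal(hrm$values[v], 1 / mean(med))

  # window with no overlapping IBI is missing
  hr_gap <- compute_hr(mk_beats(c(0, 1, 2)), tr_s = 2,
                       n_volumes = 12, window_s = 4)
  expect_true(is.na(hr_gap$values[10]))

  # window-mean HR tracks the generator's programmed IBI within 2%
  lat <- frozen_latent(300, "alert")
  ph <- generate_physio(lat, mean_ibi_s = 0.8, seed = 12,
                        ibi_outlier_frac = 0.01)
  beats <- interpolate_ibi_outliers(detect_beats(ph$pulse$values, 100))
  hr <- compute_hr(beats, tr_s = 2.1, n_volumes = 140)
  expect_lt(abs(mean(hr$values, na.rm = TRUE) - 1 / 0.8) / (1 / 0.8), 0.02)
})

test_that("percent eye closure: fractions, logit clamp, truncation", {
  win <- data.frame(start_volume = 0, end_volume = 20)
  # all-zero trace
  r1 <- percent_eye_closure(rep(0, 6000), 60, win, tr_s = 2, shift_s = 0)
  expect_equal(r1$fraction, 1)
  n <- 20 * 2 * 60
  expect_equal(r1$logit, log((1 - 1 / (2 * n)) / (1 / (2 * n))))
  # no zeros
  r2 <- percent_eye_closure(rep(4, 6000), 60, win, tr_s = 2, shift_s = 0)
  expect_equal(r2$fraction, 0)
  # alternating: fraction 0.5, logit 0
  r3 <- percent_eye_closure(rep(c(0, 4), 3000), 60, win, tr_s = 2,
                            shift_s = 0)
  expect_equal(r3$fraction, 0.5)
  expect_equal(r3$logit, 0)

  # the forward trace shift reads earlier samples
  pupil <- c(rep(0, 240), rep(4, 5760))  # closed for the first 4 s only
  w1 <- data.frame(start_volume = 2, end_volume = 4)  # 4-8 s on BOLD clock
  r4 <- percent_eye_closure(pupil, 60, w1, tr_s = 2, shift_s = 4)
  expect_equal(r4$fraction, 1)  # reads 0-4 s
  r5 <- percent_eye_closure(pupil, 60, w1, tr_s = 2, shift_s = 0)
  expect_equal(r5$fraction, 0)

  # shifted window leaving the recording is truncated and flagged
  w2 <- data.frame(start_volume = 0, end_volume = 2)
  r6 <- percent_eye_closure(pupil, 60, w2, tr_s = 2, shift_s = 4)
  expect_true(r6$truncated)
})
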