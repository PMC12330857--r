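test_that("latent trajectory honors rates, determinism, and validation", {
  # frozen chain
  t0 <- generate_latent(100, 0, seed = 1, start = "alert")
  expect_true(all(t0$states == "alert"))
  expect_length(t0$states, 100)

  # determinism contract
  a <- generate_latent(500, 0.05, seed = 11)
  b <- generate_latent(500, 0.05, seed = 11)
  expect_identical(a$states, b$states)

  # binomial oracle on the switch count: rate 0.05 over 3600 s
  tr <- generate_latent(3600, 0.05, seed = 2)
  switches <- sum(tr$states[-1] != tr$states[-3600])
  expected <- 3599 * 0.05
  sd3 <- 3 * sqrt(3599 * 0.05 * 0.95)
  expect_lt(abs(switches - expected), sd3)

  # asymmetric rates set the stationary occupancy
  tr2 <- generate_latent(20000, 0.05, seed = 3,
                         rate_alert_to_drowsy = 0.03,
                         rate_drowsy_to_alert = 0.01)
  expect_lt(abs(mean(tr2$states == "drowsy") - 0.75), 0.08)

  expect_error(generate_latent(0, 0.1, seed = 1), class = "vigifc_parameter_error")
  expect_error(generate_latent(100, 1.2, seed = 1), class = "vigifc_parameter_error")
})

test_that("synthetic EEG carries the programmed state-dependent spectra", {
  alert <- frozen_latent(40, "alert")
  drowsy <- frozen_latent(40, "drowsy")
  ea <- generate_eeg(alert, seed = 5)
  ed <- generate_eeg(drowsy, seed = 5)
  bpa <- epoch_band_powers(ea)
  bpd <- epoch_band_powers(ed)
  occ <- bpa$montage == "occipital"

  # alert: occipital alpha dominates theta by > 2x
  expect_gt(mean(bpa$power[, occ, "alpha"]) / mean(bpa$power[, occ, "theta"]), 2)
  # drowsy: alpha/theta ratio < 1 on every channel
  ratios <- colMeans(bpd$power[, , "alpha"]) / colMeans(bpd$power[, , "theta"])
  expect_true(all(ratios < 1))

  # noise disabled: spectra contain only the programmed bands
  clean <- generate_eeg(alert, seed = 6, noise = FALSE)
  spec <- Mod(stats::fft(clean[1, 1:250]))^2
  freq <- 0:249
  in_band <- (freq >= 1 & freq < 13) | (freq > 237 & freq <= 249)
  expect_lt(sum(spec[!in_band]) / sum(spec), 1e-3)

  # determinism and validation
  expect_identical(unclass(generate_eeg(alert, seed = 7)),
                   unclass(generate_eeg(alert, seed = 7)))
  expect_error(generate_eeg(alert, sfreq = 32, seed = 1),
               class = "vigifc_parameter_error")
  expect_error(generate_eeg(alert, montage = c(O1 = "occipital"), seed = 1),
               class = "vigifc_montage_error")
})

test_that("synthetic BOLD plants the requested state-dependent shift", {
  # null effect: no drowsy/alert correlation difference anywhere
  lat <- generate_latent(1800, 1 / 200, seed = 21)
  b0 <- generate_bold(lat, 12, 2.1, rep(0, 12), seed = 22)
  vs <- attr(b0, "volume_state")
  expect_true(all(c("alert", "drowsy") %in% vs))
  x <- unclass(b0)
  sd_ <- colMeans(x[1:3, ])
  dz0 <- atanh(cor(sd_[vs == "drowsy"], t(x[, vs == "drowsy"]))) -
    atanh(cor(sd_[vs == "alert"], t(x[, vs == "alert"])))
  expect_lt(max(abs(dz0[4:12])), 0.15)  # ~3 SE at these segment lengths

  # determinism
  expect_identical(unclass(generate_bold(lat, 12, 2.1, rep(0, 12), seed = 9)),
                   unclass(generate_bold(lat, 12, 2.1, rep(0, 12), seed = 9)))

  # Monte-Carlo oracle: planted delta-z recovered across replicate sessions
  es <- numeric(10); es[6:8] <- 0.2
  diffs <- replicate(60, {
    lat_i <- generate_latent(1800, 1 / 200, seed = sample.int(1e6, 1))
    bb <- unclass(generate_bold(lat_i, 10, 2.1, es,
                                seed = sample.int(1e6, 1)))
    v <- attr(generate_bold(lat_i, 10, 2.1, es, seed = 1), "volume_state")
    s <- colMeans(bb[1:3, ])
    mean(atanh(cor(s[v == "drowsy"], t(bb[6:8, v == "drowsy"]))) -
           atanh(cor(s[v == "alert"], t(bb[6:8, v == "alert"]))))
  })
  mc_se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 0.2), 3 * mc_se)

  # unattainable shift rejected
  expect_error(generate_bold(lat, 10, 2.1, c(rep(0, 9), 3.5), seed = 1),
               class = "vigifc_parameter_error")
})

test_that("synthetic physio: dropout, beats, and pupil closures behave", {
  lat <- generate_latent(120, 0.01, seed = 31)
  ph <- generate_physio(lat, dropout_frac = 0, seed = 32)
  expect_false(anyNA(ph$resp$values))

  ph2 <- generate_physio(lat, dropout_frac = 0.1, seed = 33)
  frac <- mean(is.na(ph2$resp$values))
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.2)
  # dropout is contiguous: few distinct NA runs
  runs <- rle(is.na(ph2$resp$values))
  expect_lt(sum(runs$values), 10)

  # jitter-free, outlier-free, noiseless pulse: detected IBIs exactly 1 s
  ph3 <- generate_physio(lat, mean_ibi_s = 1.0, seed = 34,
                         ibi_jitter_s = 0, ibi_outlier_frac = 0,
                         pulse_noise_sd = 0)
  beats <- detect_beats(ph3$pulse$values, ph3$pulse$sfreq)
  expect_true(all(abs(beats$ibi_s - 1.0) < 1e-9))
  # with the default baseline noise the count is still the oracle's
  ph3n <- generate_physio(lat, mean_ibi_s = 1.0, seed = 34,
                          ibi_jitter_s = 0, ibi_outlier_frac = 0)
  expect_equal(length(detect_beats(ph3n$pulse$values, 100)$beat_times_s),
               length(beats$beat_times_s))

  # pupil closures cover more of drowsy than alert time
  pa <- generate_physio(frozen_latent(300, "alert"), seed = 35)
  pd <- generate_physio(frozen_latent(300, "drowsy"), seed = 35)
  expect_gt(mean(pd$pupil$values == 0), mean(pa$pupil$values == 0))

  expect_error(generate_physio(lat, dropout_frac = 0.9, seed = 1),
               class = "vigifc_parameter_error")
})

test_that("cross-signal consistency: all modalities track the latent state", {
  spec <- study_spec(n_subjects = 1, sessions_per_subject = 1,
                     duration_s = 1200, transition_rate = 1 / 150,
                     rng_seed = 77)
  rec <- generate_session(spec, 1, 1)
  drowsy_sec <- latent_indicator(rec$latent)
  minute <- rep(seq_len(20), each = 60)
  drowsy_frac <- tapply(drowsy_sec, minute, mean)
  expect_gt(stats::sd(drowsy_frac), 0)  # both states visited

  bp <- epoch_band_powers(rec$eeg)
  occ <- bp$montage == "occipital"
  at_ratio <- tapply(seq_len(1200), minute, function(ix) {
    mean(bp$power[ix, occ, "alpha"]) / mean(bp$power[ix, occ, "theta"])
  })
  pup_min <- rep(seq_len(20), each = 60 * rec$physio$pupil$sfreq)
  closure <- tapply(rec$physio$pupil$values == 0, pup_min, mean)

  # alpha/theta anti-tracks drowsiness; closure tracks it
  expect_lt(cor(at_ratio, drowsy_frac, method = "spearman"), 0)
  expect_gt(cor(closure, drowsy_frac, method = "spearman"), 0)
})

test_that("session records round-trip through the TSV representation", {
  spec <- study_spec(n_subjects = 1, sessions_per_subject = 1,
                     duration_s = 70, n_parcels = 6, seed_parcels = 1:2,
                     effect_support = 4:5, n_tissue = c(wm = 2, csf = 2, fv = 1),
                     rng_seed = 99)
  rec <- generate_session(spec, 1, 1)
  dir <- withr::local_tempdir()
  write_session(rec, dir, spec)
  back <- read_session(dir)
  expect_equal(unclass(back$bold), unclass(rec$bold), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(back$latent$states, rec$latent$states)
  expect_equal(back$physio$resp$values, rec$physio$resp$values,
               tolerance = 1e-6)
  expect_identical(is.na(back$physio$resp$values),
                   is.na(rec$physio$resp$values))
  expect_equal(attr(back$bold, "effect_spec"), spec$effect_spec)
})
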