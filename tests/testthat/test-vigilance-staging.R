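mk_frame <- function(delta, theta, alpha_occ, alpha_fro) {
  # 4 channels: O1, O2 occipital; F3, F4 frontal
  f <- cbind(delta = rep(delta, 4), theta = rep(theta, 4),
             alpha = c(alpha_occ, alpha_occ, alpha_fro, alpha_fro))
  f
}
tags4 <- c(O1 = "occipital", O2 = "occipital",
           F3 = "frontal", F4 = "frontal")

test_that("band powers place pure tones and white noise correctly", {
  sfreq <- 128
  tt <- (1:(sfreq * 8)) / sfreq
  mont <- c(O1 = "occipital", F3 = "frontal")
  mk_eeg <- function(f) {
    m <- rbind(sin(2 * pi * f * tt), sin(2 * pi * f * tt))
    structure(m, sfreq = sfreq, montage = mont)
  }
  bp10 <- epoch_band_powers(mk_eeg(10))
  expect_true(all(bp10$power[, , "alpha"] > 10 * bp10$power[, , "theta"]))
  expect_true(all(bp10$power[, , "delta"] < 1e-6 * bp10$power[, , "alpha"]))
  bp6 <- epoch_band_powers(mk_eeg(6))
  expect_true(all(bp6$power[, , "theta"] > 10 * bp6$power[, , "alpha"]))

  # white noise: band powers proportional to bandwidths (3/4/4 Hz)
  set.seed(31)
  wn <- structure(matrix(rnorm(2 * sfreq * 400), 2), sfreq = sfreq,
                  montage = mont)
  bpw <- epoch_band_powers(wn)
  m <- colMeans(bpw$power[, 1, ])
  expect_equal(m[["theta"]] / m[["delta"]], 4 / 3, tolerance = 0.1)
  expect_equal(m[["alpha"]] / m[["theta"]], 1, tolerance = 0.1)

  expect_error(epoch_band_powers(wn, montage_tags = c("occipital", "bad")),
               class = "vigifc_montage_error")
  expect_error(epoch_band_powers(wn, montage_tags = c("frontal", "other")),
               class = "vigifc_montage_error")
})

test_that("stage classifier follows the documented rule", {
  # occipital-only alpha: A1 = 5
  expect_identical(classify_stage(mk_frame(0, 0, 10, 0), tags4), 5L)
  # anteriorized alpha: A2 (ratio in [1, 2)) or A3 (ratio < 1)
  expect_identical(classify_stage(mk_frame(0.1, 0.1, 6, 4), tags4), 4L)
  expect_identical(classify_stage(mk_frame(0.1, 0.1, 3, 8), tags4), 3L)
  # non-alpha-dominant: theta-led B1 = 2, delta-led B2/3 = 1
  expect_identical(classify_stage(mk_frame(0.5, 5, 1, 1), tags4), 2L)
  expect_identical(classify_stage(mk_frame(5, 0.5, 1, 1), tags4), 1L)
  # boundary of occipital dominance: alpha must strictly exceed delta+theta
  expect_identical(classify_stage(mk_frame(1, 1, 2, 0), tags4), 2L)
})

test_that("signed-rank z matches exact enumeration (moments, sign, label)", {
  # extreme cases hit the label threshold trivially
  expect_gt(signed_rank_z(rep(5, 63)), 1.5)
  expect_lt(signed_rank_z(rep(1, 63)), -1.5)

  # stage integers vs center 2.75 can never produce a zero difference
  expect_true(all((1:5 - 2.75) != 0))

  # enumeration oracle: z equals the exact null standardization, and the
  # ternary label agrees, across random tied vectors with n <= 12
  set.seed(101)
  for (rep_i in 1:300) {
    n <- sample(10:12, 1)
    v <- sample(1:5, n, replace = TRUE)
    z_impl <- signed_rank_z(v)
    oracle <- exact_signed_rank_oracle(v)
    expect_equal(z_impl, oracle$z, tolerance = 1e-10)
    lab <- function(z) if (z >= 1.5) "alert" else if (z <= -1.5) "drowsy" else "intermediate"
    expect_identical(lab(z_impl), lab(oracle$z))
  }

  # the alternating 2,3 pattern sits below the center: the larger absolute
  # deviations (-0.75) outrank the +0.25s, so z is negative (and crosses
  # the -1.5 drowsy threshold at full 63-s epoch length)
  z_alt <- signed_rank_z(rep(c(2, 3), 6))
  expect_equal(z_alt, exact_signed_rank_oracle(rep(c(2, 3), 6))$z,
               tolerance = 1e-10)
  expect_lt(z_alt, 0)
  expect_lt(signed_rank_z(rep(c(2, 3), 31)), -1.5)

  expect_error(signed_rank_z(rep(5, 9)), class = "vigifc_insufficient_epoch")
  expect_error(signed_rank_z(c(rep(3, 10), 2.75)),
               class = "vigifc_parameter_error")
})

mk_stages <- function(v) {
  structure(list(stages = as.integer(v),
                 labels = c("B2/3", "B1", "A3", "A2", "A1")[v],
                 sfreq_out = 1), class = "vigi_stages")
}

test_that("epoch assignment: merging, thresholds, shift, truncation", {
  tr <- 2.1
  # 19 all-alert epochs merge into one 570-volume epoch pre-shift
  st <- mk_stages(rep(5, 1197))
  ep0 <- assign_epoch_states(st, tr, n_volumes = 570, shift_s = 0)
  expect_equal(nrow(ep0), 1)
  expect_equal(ep0$n_volumes, 570)
  expect_identical(ep0$state, "alert")

  # 5-s shift at TR 2.1 is 2 volumes
  ep <- assign_epoch_states(st, tr, n_volumes = 570, shift_s = 5)
  expect_equal(ep$start_volume, 2)
  expect_equal(ep$end_volume, 570)  # truncated at scan end

  # mixed run: drowsy block then alert block, boundaries merge per state
  sec_per_ep <- 63
  v <- c(rep(1, 6 * sec_per_ep), rep(5, 13 * sec_per_ep))
  ep2 <- assign_epoch_states(mk_stages(v), tr, n_volumes = 570, shift_s = 0)
  expect_equal(ep2$state, c("drowsy", "alert"))
  expect_equal(ep2$start_volume, c(0, 180))
  expect_equal(ep2$n_volumes, c(180, 390))

  # a balanced mixture of stages 2/3/4 sits between the thresholds
  v3 <- rep(c(rep(2, 28), rep(3, 21), rep(4, 14)), 19)
  ep3 <- assign_epoch_states(mk_stages(v3), tr, n_volumes = 570, shift_s = 0)
  expect_true(all(ep3$state == "intermediate"))
  expect_true(all(abs(ep3$z_stat) < 1.5))

  # trailing partial epoch dropped with a message
  expect_message(
    assign_epoch_states(mk_stages(rep(5, 200)), 1, n_volumes = 95,
                        epoch_volumes = 30, shift_s = 0),
    "partial epoch")

  # time covariance: shifting the stage series by one epoch shifts labels
  v4 <- c(rep(1, 63), rep(5, 63), rep(1, 63), rep(5, 63 * 16))
  e_a <- assign_epoch_states(mk_stages(v4), tr, n_volumes = 570, shift_s = 0)
  v5 <- c(rep(1, 63), v4[1:(length(v4) - 63)])
  e_b <- assign_epoch_states(mk_stages(v5), tr, n_volumes = 570, shift_s = 0)
  expect_equal(e_b$start_volume[-1], e_a$start_volume[-1] + 30)
})

test_that("alpha/theta validation ratio separates synthetic states", {
  spec <- study_spec(n_subjects = 1, sessions_per_subject = 1,
                     duration_s = 900, transition_rate = 1 / 200,
                     rng_seed = 55)
  rec <- generate_session(spec, 1, 1)
  bp <- epoch_band_powers(rec$eeg)
  st <- classify_stages(bp)
  ep <- assign_epoch_states(st, rec$tr_s, n_volumes = ncol(rec$bold))
  ratios <- alpha_theta_ratio(bp, ep, rec$tr_s)
  al <- ratios[ep$state == "alert"]
  dr <- ratios[ep$state == "drowsy"]
  expect_gt(length(al), 0)
  expect_gt(length(dr), 0)
  # rank-sum oracle: alert ratios stochastically dominate drowsy ones
  expect_true(all(outer(al, dr, ">")))

  # hand cases
  bp_flat <- list(power = array(1, c(70, 2, 3),
                                dimnames = list(NULL, NULL,
                                                c("delta", "theta", "alpha"))),
                  montage = c(a = "occipital", b = "frontal"))
  class(bp_flat) <- "vigi_bandpower"
  ep1 <- data.frame(start_volume = 0, end_volume = 30)
  expect_equal(alpha_theta_ratio(bp_flat, ep1, 2.1), 1)
  bp_zero_alpha <- bp_flat
  bp_zero_alpha$power[, , "alpha"] <- 0
  expect_equal(alpha_theta_ratio(bp_zero_alpha, ep1, 2.1), 0)
  bp_zero_theta <- bp_flat
  bp_zero_theta$power[, , "theta"] <- 0
  expect_true(is.na(alpha_theta_ratio(bp_zero_theta, ep1, 2.1)))
})
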