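#' @name staging
#' @title EEG vigilance staging
#'
#' @description
#' A band-power stand-in for proprietary EEG vigilance-staging software:
#' each 1-s EEG epoch is assigned one of five ordered stages from the
#' spatial distribution of delta (1-4 Hz), theta (4-8 Hz), and alpha
#' (8-12 Hz) power. The integer coding is fixed: A1 = 5 (most alert,
#' occipitally dominant alpha), A2 = 4, A3 = 3 (anteriorized alpha),
#' B1 = 2, B2/3 = 1 (most drowsy, delta/theta dominant).
NULL

stage_labels <- c("B2/3", "B1", "A3", "A2", "A1")

#' Per-second band powers from multichannel EEG
#'
#' Splits the recording into non-overlapping 1-s windows and integrates the
#' periodogram over the delta (1-4 Hz), theta (4-8 Hz), and alpha
#' (8-12 Hz) bands (half-open bins) for every channel.
#'
#' @param eeg channels x samples matrix (a `vigi_eeg`, or any matrix).
#' @param sfreq sampling rate; taken from the `sfreq` attribute if absent.
#' @param montage_tags named region tags per channel ("occipital",
#'   "frontal", "other"); taken from the `montage` attribute if absent.
#' @return a `vigi_bandpower` object: list with `power`, an array
#'   `[seconds, channels, bands]`, and the montage tags.
#' @export
epoch_band_powers <- function(eeg, sfreq = attr(eeg, "sfreq"),
                              montage_tags = attr(eeg, "montage")) {
  if (is.null(sfreq) || sfreq < 64) {
    vf_stop("sfreq must be given and >= 64 Hz", "vigifc_parameter_error")
  }
  if (is.null(montage_tags) || length(montage_tags) != nrow(eeg) ||
      any(!montage_tags %in% c("occipital", "frontal", "other"))) {
    vf_stop("every channel needs a region tag (occipital/frontal/other)",
            "vigifc_montage_error")
  }
  if (!any(montage_tags == "occipital")) {
    vf_stop("montage must include an occipital channel",
            "vigifc_montage_error")
  }
  n_sec <- floor(ncol(eeg) / sfreq)
  bands <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12))
  freq <- (seq_len(sfreq) - 1) / 1  # 1-s windows: 1-Hz resolution
  half <- freq <= sfreq / 2
  band_sel <- lapply(bands, function(b) which(freq >= b[1] & freq < b[2] & half))
  pow <- array(0, c(n_sec, nrow(eeg), 3),
               dimnames = list(NULL, rownames(eeg), names(bands)))
  for (ci in seq_len(nrow(eeg))) {
    m <- matrix(eeg[ci, seq_len(n_sec * sfreq)], nrow = sfreq)
    spec <- Mod(stats::mvfft(m))^2 / sfreq^2  # one column per second
    for (b in 1:3) {
      pow[, ci, b] <- 2 * colSums(spec[band_sel[[b]], , drop = FALSE])
    }
  }
  structure(list(power = pow, montage = montage_tags),
            class = "vigi_bandpower")
}

#' Stage one band-power frame (1 second) into an integer vigilance stage
#'
#' The rule (documented, deterministic, and total over valid frames):
#' a frame is *alpha-dominant* when occipital alpha power exceeds occipital
#' delta-plus-theta power. Alpha-dominant frames are split by the
#' occipital/frontal alpha ratio: ratio >= `rho` gives A1 (5); ratio in
#' `[anterior, rho)` gives A2 (4); ratio below `anterior` (anteriorized
#' alpha) gives A3 (3). Non-alpha-dominant frames are B2/3 (1) when delta
#' power exceeds theta power and B1 (2) otherwise.
#'
#' @param frame channels x 3 matrix of band powers (columns delta, theta,
#'   alpha) with a `montage` attribute, or a row slice of a
#'   `vigi_bandpower` array.
#' @param montage_tags region tags per channel.
#' @param thresholds list with `rho` (occipital dominance ratio, default 2)
#'   and `anterior` (anteriorization cutoff, default 1).
#' @return integer stage in 1..5.
#' @export
classify_stage <- function(frame, montage_tags,
                           thresholds = list(rho = 2, anterior = 1)) {
  occ <- montage_tags == "occipital"
  fro <- montage_tags == "frontal"
  alpha_occ <- mean(frame[occ, 3])
  alpha_fro <- if (any(fro)) mean(frame[fro, 3]) else 0
  low_occ <- mean(frame[occ, 1]) + mean(frame[occ, 2])
  if (alpha_occ > low_occ) {
    ratio <- if (alpha_fro > 0) alpha_occ / alpha_fro else Inf
    if (ratio >= thresholds$rho) 5L
    else if (ratio >= thresholds$anterior) 4L
    else 3L
  } else {
    delta_all <- mean(frame[, 1])
    theta_all <- mean(frame[, 2])
    if (delta_all > theta_all) 1L else 2L
  }
}

#' Stage a whole recording second-by-second
#'
#' @param band_powers a `vigi_bandpower` object.
#' @param thresholds see [classify_stage()].
#' @return a `vigi_stages` object: list with integer `stages` (one per
#'   second, 1..5), `labels`, and `sfreq_out = 1`.
#' @export
classify_stages <- function(band_powers,
                            thresholds = list(rho = 2, anterior = 1)) {
  stopifnot(inherits(band_powers, "vigi_bandpower"))
  pw <- band_powers$power
  stages <- vapply(seq_len(dim(pw)[1]), function(s) {
    classify_stage(pw[s, , , drop = TRUE], band_powers$montage, thresholds)
  }, integer(1))
  structure(list(stages = stages, labels = stage_labels[stages],
                 sfreq_out = 1), class = "vigi_stages")
}

#' Signed-rank z-statistic of stage values against a center
#'
#' One-sample Wilcoxon signed-rank statistic on the differences
#' `values - center`, standardized with the tie-corrected normal
#' approximation (no continuity correction). Positive z means the stage
#' median sits above the center (more alert). The default center 2.75 is a
#' weighted midpoint of the 1..5 stage scale, which guarantees no
#' difference can be exactly zero.
#'
#' @param values integer stage values (n >= 10 for the approximation).
#' @param center comparison center (default 2.75).
#' @return the signed z value.
#' @export
signed_rank_z <- function(values, center = 2.75) {
  n <- length(values)
  if (n < 10) {
    vf_stop("need at least 10 values for the signed-rank normal approximation",
            "vigifc_insufficient_epoch")
  }
  d <- values - center
  if (any(d == 0)) {
    vf_stop("zero differences are not supported (choose a non-attainable center)",
            "vigifc_parameter_error")
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  e_w <- n * (n + 1) / 4
  tie_tab <- table(abs(d))
  v_w <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  (w - e_w) / sqrt(v_w)
}

#' Segment a stage series into alert/intermediate/drowsy epochs
#'
#' The scan is cut into consecutive epochs of `epoch_volumes` BOLD volumes
#' (default 30, i.e. 63 s at TR = 2.1 s; a trailing partial epoch is
#' dropped). Each epoch's 1-s stages are tested against the center with
#' [signed_rank_z()]; epochs with `z >= z_thresh` are alert, `z <=
#' -z_thresh` drowsy, otherwise intermediate. Adjacent epochs with the same
#' state are concatenated (the reported `z_stat` of a merged epoch is
#' recomputed over its full span). Finally all epoch boundaries are shifted
#' forward by `round(shift_s / tr_s)` volumes to account for the
#' hemodynamic delay, truncating at the scan end.
#'
#' @param stage_series a `vigi_stages` object covering the scan.
#' @param tr_s BOLD repetition time in seconds.
#' @param n_volumes number of BOLD volumes in the scan; defaults to
#'   `floor(n_seconds / tr_s)`.
#' @param epoch_volumes epoch length in volumes (default 30).
#' @param z_thresh state threshold on the signed-rank z (default 1.5).
#' @param shift_s forward shift in seconds (default 5, ~2 TRs at 2.1 s).
#' @return data.frame of epochs with 0-based half-open `start_volume`,
#'   `end_volume`, plus `state`, `z_stat`, `n_volumes`.
#' @export
assign_epoch_states <- function(stage_series, tr_s,
                                n_volumes = NULL, epoch_volumes = 30,
                                z_thresh = 1.5, shift_s = 5) {
  stopifnot(inherits(stage_series, "vigi_stages"))
  stages <- stage_series$stages
  n_sec <- length(stages)
  if (is.null(n_volumes)) n_volumes <- floor(n_sec / tr_s)
  n_epochs <- floor(n_volumes / epoch_volumes)
  if (n_epochs < 1) {
    vf_stop("scan shorter than one epoch", "vigifc_parameter_error")
  }
  if (n_volumes %% epoch_volumes != 0) {
    message(sprintf("dropping trailing partial epoch (%d volumes)",
                    n_volumes %% epoch_volumes))
  }
  ep <- lapply(seq_len(n_epochs) - 1L, function(e) {
    sec_lo <- floor(e * epoch_volumes * tr_s) + 1L
    sec_hi <- min(n_sec, floor((e + 1) * epoch_volumes * tr_s))
    z <- signed_rank_z(stages[sec_lo:sec_hi])
    data.frame(start_volume = e * epoch_volumes,
               end_volume = (e + 1) * epoch_volumes,
               state = if (z >= z_thresh) "alert"
                       else if (z <= -z_thresh) "drowsy"
                       else "intermediate",
               z_stat = z)
  })
  ep <- do.call(rbind, ep)
  # concatenate adjacent same-state epochs
  run <- cumsum(c(TRUE, ep$state[-1] != ep$state[-nrow(ep)]))
  merged <- do.call(rbind, lapply(split(ep, run), function(grp) {
    sv <- min(grp$start_volume); ev <- max(grp$end_volume)
    sec_lo <- floor(sv * tr_s) + 1L
    sec_hi <- min(n_sec, floor(ev * tr_s))
    data.frame(start_volume = sv, end_volume = ev, state = grp$state[1],
               z_stat = signed_rank_z(stages[sec_lo:sec_hi]))
  }))
  rownames(merged) <- NULL
  # hemodynamic shift
  k <- round(shift_s / tr_s)
  merged$start_volume <- merged$start_volume + k
  merged$end_volume <- pmin(merged$end_volume + k, n_volumes)
  merged <- merged[merged$start_volume < n_volumes, , drop = FALSE]
  merged$n_volumes <- merged$end_volume - merged$start_volume
  merged
}

#' Occipital alpha/theta power ratio per epoch
#'
#' A classical quantitative vigilance index used to validate the staging:
#' the ratio of mean occipital alpha power to mean occipital theta power
#' over each epoch's time span.
#'
#' @param band_powers a `vigi_bandpower` object.
#' @param epochs epoch table from [assign_epoch_states()].
#' @param tr_s BOLD repetition time.
#' @return numeric vector, one ratio per epoch (`NA` where theta power is
#'   zero; exactly 0 when alpha power is zero).
#' @export
alpha_theta_ratio <- function(band_powers, epochs, tr_s) {
  stopifnot(inherits(band_powers, "vigi_bandpower"))
  occ <- band_powers$montage == "occipital"
  n_sec <- dim(band_powers$power)[1]
  vapply(seq_len(nrow(epochs)), function(i) {
    sec_lo <- floor(epochs$start_volume[i] * tr_s) + 1L
    sec_hi <- min(n_sec, floor(epochs$end_volume[i] * tr_s))
    a <- mean(band_powers$power[sec_lo:sec_hi, occ, 3])
    t <- mean(band_powers$power[sec_lo:sec_hi, occ, 2])
    if (t == 0) NA_real_ else a / t
  }, numeric(1))
}
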