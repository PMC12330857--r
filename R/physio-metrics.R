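#' Respiratory volume (RV) per BOLD volume
#'
#' RV is the temporal standard deviation of the respiratory-belt waveform in
#' a sliding window (default 6 s) centered at each volume's temporal
#' midpoint, matched to the fMRI sampling rate. A window's RV is computed
#' from all available samples provided fewer than `max_missing_frac` of its
#' sample slots are missing; otherwise the output is missing (`NA`). Edge
#' windows are truncated to the recorded extent.
#'
#' @param resp numeric waveform; `NA` marks transducer dropout.
#' @param resp_sfreq waveform sampling rate in Hz.
#' @param tr_s BOLD repetition time in seconds.
#' @param n_volumes number of BOLD volumes.
#' @param window_s sliding-window length in seconds (default 6).
#' @param max_missing_frac missing-sample fraction at or above which the
#'   window's value is set missing (default 0.2).
#' @return a `vigi_physio` series: list with `values` (length
#'   `n_volumes`), `kind = "RV"`, and `tr_s`.
#' @export
compute_rv <- function(resp, resp_sfreq, tr_s, n_volumes, window_s = 6,
                       max_missing_frac = 0.2) {
  if (length(resp) == 0) {
    vf_stop("empty respiratory waveform", "vigifc_parameter_error")
  }
  assert_scalar_number(window_s, "window_s", 0, strict_lower = TRUE)
  n <- length(resp)
  values <- rep(NA_real_, n_volumes)
  for (v in seq_len(n_volumes)) {
    center <- (v - 0.5) * tr_s
    lo <- max(1L, ceiling((center - window_s / 2) * resp_sfreq))
    hi <- min(n, floor((center + window_s / 2) * resp_sfreq))
    if (hi < lo) next
    w <- resp[lo:hi]
    if (mean(is.na(w)) < max_missing_frac) {
      values[v] <- stats::sd(w[!is.na(w)])
    }
  }
  structure(list(values = values, kind = "RV", tr_s = tr_s),
            class = "vigi_physio")
}

#' Detect heart beats in a pulse (PPG) waveform
#'
#' Beats are local maxima exceeding an adaptive amplitude threshold
#' (median plus half the median-to-maximum excursion), subject to a
#' refractory spacing of `min_ibi_s`; when two candidate peaks fall closer
#' than the refractory interval the larger one is kept.
#'
#' @param pulse finite numeric waveform.
#' @param sfreq sampling rate in Hz.
#' @param min_ibi_s minimum physiologically plausible inter-beat interval
#'   (default 0.4 s, i.e. 150 bpm).
#' @return a `vigi_beats` object: list with `beat_times_s`, `ibi_s`
#'   (successive differences) and `outlier_flags` (all `FALSE` here).
#' @export
detect_beats <- function(pulse, sfreq, min_ibi_s = 0.4) {
  if (any(!is.finite(pulse))) {
    vf_stop("pulse waveform must be finite", "vigifc_parameter_error")
  }
  assert_scalar_number(min_ibi_s, "min_ibi_s", 0, strict_lower = TRUE)
  n <- length(pulse)
  if (n < 3) vf_stop("pulse waveform too short", "vigifc_unusable_recording")
  mid <- pulse[2:(n - 1)]
  is_peak <- mid > pulse[1:(n - 2)] & mid >= pulse[3:n]
  thr <- stats::median(pulse) + 0.5 * (max(pulse) - stats::median(pulse))
  cand <- which(is_peak & mid > thr) + 1L
  if (length(cand) >= 2) {
    # enforce refractory spacing, keeping the taller of clashing peaks
    ord <- cand[order(pulse[cand], decreasing = TRUE)]
    keep <- logical(0)
    min_gap <- min_ibi_s * sfreq
    for (p in ord) {
      if (all(abs(keep - p) >= min_gap)) keep <- c(keep, p)
    }
    cand <- sort(keep)
  }
  if (length(cand) < 2) {
    vf_stop("fewer than 2 beats found: unusable recording",
            "vigifc_unusable_recording")
  }
  times <- (cand - 1) / sfreq
  new_beats(times, diff(times), rep(FALSE, length(times) - 1L))
}

new_beats <- function(times, ibi, flags) {
  structure(list(beat_times_s = times, ibi_s = ibi, outlier_flags = flags),
            class = "vigi_beats")
}

#' Flag and interpolate inter-beat-interval outliers
#'
#' IBIs farther than `sd_cutoff` standard deviations from the series mean
#' (mean and SD computed once, on the raw IBIs) are flagged and replaced by
#' linear interpolation between the nearest non-outlier neighbours;
#' flagged endpoints take the nearest valid value. A zero-SD series is
#' defined outlier-free.
#'
#' The rule is single-pass by design (mean and SD are not re-estimated
#' after correction). A large outlier can inflate the SD enough to mask a
#' smaller one, in which case re-applying the function may flag additional
#' intervals; on typical pulse recordings the first pass removes all
#' outliers and the operation is idempotent.
#'
#' @param beats a `vigi_beats` object (>= 3 IBIs).
#' @param sd_cutoff outlier cutoff in SD units (default 2.5).
#' @return a `vigi_beats` object with corrected `ibi_s` and updated
#'   `outlier_flags`. `beat_times_s` is kept as detected; the corrected
#'   IBI series is authoritative for rate estimation.
#' @export
interpolate_ibi_outliers <- function(beats, sd_cutoff = 2.5) {
  stopifnot(inherits(beats, "vigi_beats"))
  ibi <- beats$ibi_s
  if (length(ibi) < 3) {
    vf_stop("need at least 3 inter-beat intervals", "vigifc_parameter_error")
  }
  mu <- mean(ibi)
  s <- stats::sd(ibi)
  flags <- if (s == 0) rep(FALSE, length(ibi)) else abs(ibi - mu) > sd_cutoff * s
  if (all(flags)) {
    vf_stop("all inter-beat intervals flagged as outliers",
            "vigifc_unusable_recording")
  }
  if (any(flags)) {
    good <- which(!flags)
    ibi[flags] <- stats::approx(good, ibi[good], xout = which(flags),
                                rule = 2)$y
  }
  new_beats(beats$beat_times_s, ibi, flags)
}

#' Heart rate (HR) per BOLD volume
#'
#' HR is the inverse of the median inter-beat interval within a sliding
#' window (default 6 s) centered at each volume's temporal midpoint, in
#' beats per second. An IBI contributes to a window when its beat interval
#' overlaps the window. Windows containing no IBI are missing.
#'
#' @param beats an outlier-corrected `vigi_beats` object.
#' @param tr_s BOLD repetition time.
#' @param n_volumes number of BOLD volumes.
#' @param window_s window length in seconds (default 6).
#' @return a `vigi_physio` series with `kind = "HR"` (beats/s; multiply by
#'   60 for bpm).
#' @export
compute_hr <- function(beats, tr_s, n_volumes, window_s = 6) {
  stopifnot(inherits(beats, "vigi_beats"))
  t0 <- beats$beat_times_s[-length(beats$beat_times_s)]
  t1 <- beats$beat_times_s[-1]
  values <- rep(NA_real_, n_volumes)
  for (v in seq_len(n_volumes)) {
    center <- (v - 0.5) * tr_s
    lo <- center - window_s / 2
    hi <- center + window_s / 2
    sel <- t1 > lo & t0 < hi
    if (any(sel)) values[v] <- 1 / stats::median(beats$ibi_s[sel])
  }
  structure(list(values = values, kind = "HR", tr_s = tr_s),
            class = "vigi_physio")
}

#' Percent eye closure per analysis window
#'
#' For each window on the BOLD clock, the pupil trace is shifted forward by
#' `shift_s` (default 4 s) to account for the delay between the pupil and
#' the peak BOLD response — i.e. a window `[t0, t1)` reads the original
#' samples `[t0 - shift_s, t1 - shift_s)` — and the fraction of zero
#' (closed-eye) samples is computed, together with its logit after clamping
#' to `[eps, 1 - eps]` with `eps = 1 / (2 * n_window_samples)`. Windows
#' whose shifted extent falls partly outside the recording are truncated
#' and flagged.
#'
#' @param pupil numeric pupil-diameter trace; zeros encode closure.
#' @param pupil_sfreq sampling rate in Hz.
#' @param windows data.frame with 0-based half-open `start_volume`,
#'   `end_volume` columns.
#' @param tr_s BOLD repetition time.
#' @param shift_s forward shift in seconds (default 4).
#' @return data.frame with columns `fraction`, `logit`, `truncated`.
#' @export
percent_eye_closure <- function(pupil, pupil_sfreq, windows, tr_s,
                                shift_s = 4) {
  stopifnot(is.data.frame(windows),
            all(c("start_volume", "end_volume") %in% names(windows)))
  n <- length(pupil)
  out <- lapply(seq_len(nrow(windows)), function(i) {
    t_lo <- windows$start_volume[i] * tr_s - shift_s
    t_hi <- windows$end_volume[i] * tr_s - shift_s
    lo <- floor(t_lo * pupil_sfreq) + 1L
    hi <- min(n, floor(t_hi * pupil_sfreq))
    truncated <- hi < floor(t_hi * pupil_sfreq) || lo < 1L
    lo <- max(1L, lo)
    if (lo > n || hi < lo) {
      return(data.frame(fraction = NA_real_, logit = NA_real_,
                        truncated = TRUE))
    }
    w <- pupil[lo:hi]
    frac <- mean(w == 0)
    eps <- 1 / (2 * length(w))
    data.frame(fraction = frac, logit = clamped_logit(frac, eps),
               truncated = truncated)
  })
  do.call(rbind, out)
}
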