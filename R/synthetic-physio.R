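#' Generate synthetic peripheral recordings (respiration, pulse, pupil)
#'
#' Three waveforms tied to the same latent vigilance trajectory:
#' \describe{
#'   \item{resp}{a respiratory-belt-like oscillation whose amplitude is
#'     larger during drowsy seconds, with contiguous transducer-dropout
#'     segments encoded as `NA` covering a configurable fraction of the
#'     recording.}
#'   \item{pulse}{a quasi-periodic train of Gaussian-shaped pulse-oximeter
#'     beats with configurable inter-beat-interval (IBI) jitter and a small
#'     fraction of injected outlier beats (skipped-beat-like long IBIs).}
#'   \item{pupil}{a pupil-diameter trace in which zeros mark eye closure;
#'     closures are short and rare while alert (blinks) and frequent and
#'     prolonged while drowsy.}
#' }
#'
#' @param latent a `vigi_latent` trajectory.
#' @param resp_rate_hz respiratory frequency (default 0.3 Hz).
#' @param mean_ibi_s mean inter-beat interval in seconds (default 1.0).
#' @param dropout_frac fraction of the respiratory recording replaced by
#'   missing-value dropout segments; in `[0, 0.5)` (default 0.05, matching
#'   typical transducer malfunction rates of a few percent).
#' @param seed integer RNG seed.
#' @param sfreq sampling rate for resp and pulse (default 100 Hz).
#' @param pupil_sfreq sampling rate for the pupil trace (default 60 Hz).
#' @param ibi_jitter_s SD of the beat-to-beat IBI jitter (default 0.03 s).
#' @param ibi_outlier_frac probability that a beat interval is an injected
#'   outlier (1.6-2.2x the mean IBI; default 0.012).
#' @param pulse_noise_sd SD of the additive baseline noise on the pulse
#'   waveform (default 0.02; set 0 for an exactly periodic train).
#' @return list with elements `resp`, `pulse`, `pupil`, each a list of
#'   `values` and `sfreq`, plus `beat_times_s` (ground-truth beat times).
#' @export
generate_physio <- function(latent, resp_rate_hz = 0.3, mean_ibi_s = 1.0,
                            dropout_frac = 0.05, seed, sfreq = 100,
                            pupil_sfreq = 60, ibi_jitter_s = 0.03,
                            ibi_outlier_frac = 0.012,
                            pulse_noise_sd = 0.02) {
  stopifnot(inherits(latent, "vigi_latent"))
  assert_scalar_number(dropout_frac, "dropout_frac", 0, 0.5,
                       strict_upper = TRUE)
  assert_scalar_number(mean_ibi_s, "mean_ibi_s", 0, strict_lower = TRUE)

  dur <- latent$duration_s
  drowsy <- latent_indicator(latent) == 1L
  n <- dur * sfreq
  tt <- seq_len(n) / sfreq
  sec_idx <- pmin(dur, floor(tt) + 1L)

  withr_seed(seed, {
    ## respiration: state-modulated amplitude + measurement noise
    amp <- ifelse(drowsy, 1.4, 1.0)
    resp <- amp[sec_idx] * sin(2 * pi * resp_rate_hz * tt) +
      stats::rnorm(n, 0, 0.1)
    ## contiguous dropout segments
    if (dropout_frac > 0) {
      target <- round(dropout_frac * n)
      miss <- logical(n)
      guard <- 0
      while (sum(miss) < target && guard < 10000) {
        guard <- guard + 1
        len <- round(stats::runif(1, 5, 15) * sfreq)
        len <- min(len, target - sum(miss) + round(2 * sfreq))
        start <- sample.int(max(1L, n - len), 1L)
        miss[start:min(n, start + len - 1L)] <- TRUE
      }
      resp[miss] <- NA_real_
    }

    ## pulse: beat train with jitter and injected outliers
    n_beats_max <- ceiling(dur / mean_ibi_s) + 10L
    ibi <- mean_ibi_s + stats::rnorm(n_beats_max, 0, ibi_jitter_s)
    ibi <- pmax(ibi, 0.3 * mean_ibi_s)
    if (ibi_outlier_frac > 0) {
      out_idx <- which(stats::runif(n_beats_max) < ibi_outlier_frac)
      ibi[out_idx] <- ibi[out_idx] * stats::runif(length(out_idx), 1.6, 2.2)
    }
    beat_times <- cumsum(c(mean_ibi_s / 2, ibi))
    beat_times <- beat_times[beat_times < dur - mean_ibi_s / 4]
    pulse <- stats::rnorm(n, 0, pulse_noise_sd)
    width <- 0.05
    for (bt in beat_times) {
      lo <- max(1L, ceiling((bt - 4 * width) * sfreq))
      hi <- min(n, floor((bt + 4 * width) * sfreq))
      idx <- lo:hi
      pulse[idx] <- pulse[idx] + exp(-((tt[idx] - bt)^2) / (2 * width^2))
    }

    ## pupil: open/closed two-state process, closure rates tied to vigilance
    np <- dur * pupil_sfreq
    psec <- pmin(dur, floor(seq_len(np) / pupil_sfreq) + 1L)
    p_close <- ifelse(drowsy, 0.15, 0.05) / pupil_sfreq   # open -> closed
    p_open <- ifelse(drowsy, 0.5, 4.0) / pupil_sfreq      # closed -> open
    u <- stats::runif(np)
    closed <- logical(np)
    state <- FALSE
    for (i in seq_len(np)) {
      s <- psec[i]
      state <- if (state) u[i] >= p_open[s] else u[i] < p_close[s]
      closed[i] <- state
    }
    pupil <- 4 + 0.3 * sin(2 * pi * 0.05 * seq_len(np) / pupil_sfreq) +
      stats::rnorm(np, 0, 0.05)
    pupil[closed] <- 0
  })

  list(
    resp = list(values = resp, sfreq = sfreq),
    pulse = list(values = pulse, sfreq = sfreq),
    pupil = list(values = pupil, sfreq = pupil_sfreq),
    beat_times_s = beat_times
  )
}
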