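#' Default synthetic EEG montage
#'
#' Six channels with the region tags consumed by the vigilance stager:
#' occipital (O1, O2), central (C3, C4, tagged "other"), and frontal
#' (F3, F4).
#'
#' @return named character vector mapping channel name to region tag.
#' @export
default_montage <- function() {
  c(O1 = "occipital", O2 = "occipital",
    C3 = "other", C4 = "other",
    F3 = "frontal", F4 = "frontal")
}

#' Generate synthetic multichannel EEG driven by a latent vigilance process
#'
#' Alert seconds carry a narrowband 8-12 Hz (alpha) oscillation that is
#' strongest over the occipital channels and attenuated frontally, which is
#' the classic signature of relaxed wakefulness. Drowsy seconds suppress
#' alpha and add delta (1-4 Hz) and theta (4-8 Hz) oscillations on all
#' channels. Broadband Gaussian noise is added at a configurable band SNR.
#'
#' @param latent a `vigi_latent` trajectory (1-s resolution).
#' @param montage named character vector mapping channel names to region
#'   tags; must contain at least one "occipital" and one "frontal" channel.
#' @param sfreq sampling rate in Hz (>= 64; default 250).
#' @param snr ratio of the dominant oscillation's power to the broadband
#'   noise power falling in the same 4-Hz band (default 4).
#' @param seed integer RNG seed.
#' @param noise set `FALSE` to disable the broadband noise entirely
#'   (infinite SNR); useful for spectral unit checks.
#' @return a channels x samples numeric matrix of class `vigi_eeg` with
#'   attributes `sfreq` and `montage`.
#' @export
generate_eeg <- function(latent, montage = default_montage(), sfreq = 250,
                         snr = 4, seed, noise = TRUE) {
  stopifnot(inherits(latent, "vigi_latent"))
  if (sfreq < 64) {
    vf_stop("sfreq must be >= 64 Hz for reliable band estimation",
            "vigifc_parameter_error")
  }
  if (!any(montage == "occipital") || !any(montage == "frontal")) {
    vf_stop("montage must include at least one occipital and one frontal channel",
            "vigifc_montage_error")
  }
  assert_scalar_number(snr, "snr", lower = 0, strict_lower = TRUE)

  n_sec <- latent$duration_s
  n_samp <- n_sec * sfreq
  drowsy <- latent_indicator(latent) == 1L
  ch_names <- names(montage)
  n_ch <- length(montage)

  # amplitude giving `snr` between a sinusoid's power (a^2/2) and the
  # broadband unit-variance noise power inside a 4-Hz band (4 / (fs/2))
  a0 <- sqrt(2 * snr * 4 / (sfreq / 2))
  sigma <- if (noise) 1 else 0

  tt <- seq_len(n_samp) / sfreq
  sec_idx <- rep(seq_len(n_sec), each = sfreq)

  # per-second amplitude envelopes, by band
  env_alpha_occ <- ifelse(drowsy, 0.20, 1.00) * a0
  env_alpha_fro <- ifelse(drowsy, 0.05, 0.25) * a0
  env_theta <- ifelse(drowsy, 0.90, 0.15) * a0
  env_delta <- ifelse(drowsy, 0.80, 0.15) * a0

  out <- matrix(0, n_ch, n_samp, dimnames = list(ch_names, NULL))
  withr_seed(seed, {
    for (ci in seq_len(n_ch)) {
      region <- montage[[ci]]
      alpha_env <- switch(region,
        occipital = env_alpha_occ,
        frontal = env_alpha_fro,
        0.5 * env_alpha_fro + 0.5 * env_alpha_occ * 0.3
      )
      # mild multiplicative second-to-second variability
      jit <- function(env) env * exp(stats::rnorm(n_sec, 0, 0.1))
      ph <- stats::runif(3, 0, 2 * pi)
      x <- jit(alpha_env)[sec_idx] * sin(2 * pi * 10.0 * tt + ph[1]) +
        jit(env_theta)[sec_idx] * sin(2 * pi * 5.5 * tt + ph[2]) +
        jit(env_delta)[sec_idx] * sin(2 * pi * 2.5 * tt + ph[3])
      if (sigma > 0) x <- x + stats::rnorm(n_samp, 0, sigma)
      out[ci, ] <- x
    }
  })
  structure(out, sfreq = sfreq, montage = montage,
            class = c("vigi_eeg", class(out)))
}
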