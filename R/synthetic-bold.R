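#' Generate synthetic parcel-level BOLD with a planted state effect
#'
#' Parcel signals follow a one-factor model: every parcel loads on a shared
#' "global" latent component plus independent unit-variance noise. During
#' drowsy seconds, parcels on the effect support increase their loading so
#' that the Fisher-z correlation between the seed ROI mean and the target
#' exceeds its alert-state value by the requested shift; all other parcels
#' keep a state-invariant loading. This reproduces, with a single knob, the
#' stronger global correlation structure typical of low-vigilance states.
#'
#' The shared factor and the noise are spectrally white, so linear temporal
#' filtering (detrending, band-pass) applied uniformly across parcels leaves
#' the planted correlation structure unchanged in expectation.
#'
#' @param latent a `vigi_latent` trajectory.
#' @param n_parcels number of parcels (targets) to simulate.
#' @param tr_s repetition time in seconds; `floor(duration_s / tr_s)`
#'   volumes are generated.
#' @param effect_spec numeric vector of length `n_parcels`: the planted
#'   drowsy-minus-alert shift in Fisher-z units per parcel (0 off support).
#' @param seed integer RNG seed.
#' @param r_baseline seed-to-parcel-level baseline coupling: every parcel's
#'   alert-state loading is chosen so two baseline parcels correlate at this
#'   value (default 0.3).
#' @param seed_parcels indices of the parcels averaged into the seed ROI
#'   (default `1:3`); the planted z-shift is defined against the seed mean.
#' @param hemodynamic_lag_s fixed lag between the latent (neural) state
#'   and the BOLD state switch (default 5 s): a volume follows the latent
#'   state `hemodynamic_lag_s` seconds before its temporal midpoint.
#' @param baseline constant signal offset added to every parcel (default
#'   100), giving the series a scanner-like mean for tSNR computation;
#'   removed by detrending and irrelevant to correlations.
#' @return parcels x volumes matrix of class `vigi_bold` with attributes
#'   `tr_s`, `effect_spec`, `seed_parcels`, `loading_alert`,
#'   `loading_drowsy`, `volume_state` (state at each volume midpoint) and
#'   `global_factor` (the shared component, for building nuisance series).
#' @export
generate_bold <- function(latent, n_parcels, tr_s, effect_spec, seed,
                          r_baseline = 0.3, seed_parcels = 1:3,
                          hemodynamic_lag_s = 5, baseline = 100) {
  stopifnot(inherits(latent, "vigi_latent"))
  assert_scalar_number(tr_s, "tr_s", lower = 0, strict_lower = TRUE)
  assert_scalar_number(n_parcels, "n_parcels", lower = 2)
  if (length(effect_spec) != n_parcels || !all(is.finite(effect_spec))) {
    vf_stop("effect_spec must be a finite numeric vector of length n_parcels",
            "vigifc_parameter_error")
  }
  if (any(effect_spec[seed_parcels] != 0)) {
    vf_stop("seed parcels cannot carry a planted effect",
            "vigifc_parameter_error")
  }

  n_vol <- floor(latent$duration_s / tr_s)
  # state at each volume's temporal midpoint, minus the hemodynamic lag
  mid_sec <- floor((seq_len(n_vol) - 0.5) * tr_s - hemodynamic_lag_s) + 1L
  mid_sec <- pmin(latent$duration_s, pmax(1L, mid_sec))
  vol_drowsy <- latent_indicator(latent)[mid_sec] == 1L

  a <- sqrt(r_baseline / (1 - r_baseline))      # alert loading, all parcels
  m <- length(seed_parcels)
  var_seed <- a^2 + 1 / m                       # variance of the seed mean
  z_alert <- atanh(a * a / sqrt(var_seed * (a^2 + 1)))

  loading_drowsy <- rep(a, n_parcels)
  for (p in which(effect_spec != 0)) {
    r_target <- tanh(z_alert + effect_spec[p])
    if (abs(r_target) >= 1) {
      vf_stop("requested correlation outside (-1, 1) after shift",
              "vigifc_parameter_error")
    }
    k <- r_target * sqrt(var_seed)
    if (a^2 - k^2 <= 0) {
      vf_stop(sprintf(
        "planted shift %.3f on parcel %d is unattainable with this factor model",
        effect_spec[p], p), "vigifc_parameter_error")
    }
    loading_drowsy[p] <- k / sqrt(a^2 - k^2)
  }

  withr_seed(seed, {
    g <- stats::rnorm(n_vol)
    noise <- matrix(stats::rnorm(n_parcels * n_vol), n_parcels, n_vol)
  })
  load_mat <- matrix(rep(a, n_parcels), n_parcels, n_vol)
  if (any(vol_drowsy)) {
    load_mat[, vol_drowsy] <- matrix(loading_drowsy, n_parcels,
                                     sum(vol_drowsy))
  }
  bold <- load_mat * matrix(g, n_parcels, n_vol, byrow = TRUE) + noise +
    baseline
  rownames(bold) <- sprintf("parcel_%03d", seq_len(n_parcels))
  structure(bold, tr_s = tr_s, effect_spec = effect_spec,
            seed_parcels = seed_parcels,
            loading_alert = rep(a, n_parcels),
            loading_drowsy = loading_drowsy,
            volume_state = ifelse(vol_drowsy, "drowsy", "alert"),
            global_factor = g,
            class = c("vigi_bold", class(bold)))
}
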