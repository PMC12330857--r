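#' Simulate a latent alert/drowsy vigilance trajectory
#'
#' The unobserved vigilance process shared by all the synthetic signal
#' generators is modeled as a two-state ("alert"/"drowsy") Markov chain at
#' 1-second resolution. Dwell times are geometric; with the default,
#' symmetric switching rate the chain spends about half its time in each
#' state. The default rate (1/450 per second, i.e. a mean dwell time of
#' 7.5 minutes) mirrors the length of same-state runs observed in
#' resting-state EEG-fMRI staging studies.
#'
#' @param duration_s total duration in seconds (positive integer).
#' @param transition_rate per-second probability of switching state when the
#'   same rate applies in both directions; in (0, 1), or 0 for a frozen
#'   chain.
#' @param seed integer RNG seed; identical seeds reproduce the trajectory
#'   bit-for-bit.
#' @param start initial state, `"alert"` or `"drowsy"`; if `NULL` the start
#'   state is drawn from the stationary distribution.
#' @param rate_alert_to_drowsy,rate_drowsy_to_alert optional asymmetric
#'   switch rates overriding `transition_rate`, giving stationary drowsy
#'   occupancy `r12 / (r12 + r21)`.
#' @return an object of class `vigi_latent`: list with `states` (character
#'   vector of length `duration_s`), the rates, and `duration_s`.
#' @examples
#' traj <- generate_latent(600, 1 / 450, seed = 1)
#' table(traj$states)
#' @export
generate_latent <- function(duration_s, transition_rate = 1 / 450, seed,
                            start = NULL,
                            rate_alert_to_drowsy = NULL,
                            rate_drowsy_to_alert = NULL) {
  assert_scalar_number(duration_s, "duration_s", lower = 1)
  duration_s <- as.integer(duration_s)
  r12 <- rate_alert_to_drowsy %||% transition_rate  # alert -> drowsy
  r21 <- rate_drowsy_to_alert %||% transition_rate  # drowsy -> alert
  assert_scalar_number(r12, "rate_alert_to_drowsy", 0, 1, strict_upper = TRUE)
  assert_scalar_number(r21, "rate_drowsy_to_alert", 0, 1, strict_upper = TRUE)
  assert_scalar_number(seed, "seed")

  states <- character(duration_s)
  withr_seed(seed, {
    if (is.null(start)) {
      p_drowsy <- if (r12 + r21 > 0) r12 / (r12 + r21) else 0.5
      start <- if (stats::runif(1) < p_drowsy) "drowsy" else "alert"
    }
    start <- match.arg(start, c("alert", "drowsy"))
    u <- stats::runif(duration_s - 1L)
    cur <- start
    states[1L] <- cur
    for (t in seq_len(duration_s - 1L)) {
      rate <- if (cur == "alert") r12 else r21
      if (u[t] < rate) cur <- if (cur == "alert") "drowsy" else "alert"
      states[t + 1L] <- cur
    }
  })
  structure(
    list(states = states, transition_rate = transition_rate,
         rate_alert_to_drowsy = r12, rate_drowsy_to_alert = r21,
         duration_s = duration_s, seed = seed),
    class = "vigi_latent"
  )
}

# evaluate expr with a local RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Per-second state indicator (1 = drowsy) for a latent trajectory
#' @param latent a `vigi_latent` object.
#' @return integer vector, 0 for alert seconds, 1 for drowsy seconds.
#' @export
latent_indicator <- function(latent) {
  stopifnot(inherits(latent, "vigi_latent"))
  as.integer(latent$states == "drowsy")
}

#' Majority latent state over half-open second intervals
#'
#' Maps the 1-s latent states onto analysis intervals (epochs or sliding
#' windows expressed on the BOLD clock) and reports, per interval, the
#' majority state and the fraction of seconds spent in it.
#'
#' @param latent a `vigi_latent` object.
#' @param start_s,end_s vectors of interval bounds in seconds (half-open).
#' @return data.frame with columns `state`, `frac` (majority fraction), and
#'   `pure` (TRUE when the interval is single-state).
#' @export
latent_majority <- function(latent, start_s, end_s) {
  stopifnot(inherits(latent, "vigi_latent"), length(start_s) == length(end_s))
  ind <- latent_indicator(latent)
  n <- length(ind)
  out <- lapply(seq_along(start_s), function(i) {
    lo <- max(1L, floor(start_s[i]) + 1L)
    hi <- min(n, ceiling(end_s[i]))
    if (hi < lo) return(data.frame(state = NA_character_, frac = NA_real_,
                                   pure = NA))
    f_drowsy <- mean(ind[lo:hi])
    data.frame(
      state = if (f_drowsy >= 0.5) "drowsy" else "alert",
      frac = max(f_drowsy, 1 - f_drowsy),
      pure = f_drowsy %in% c(0, 1)
    )
  })
  do.call(rbind, out)
}
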