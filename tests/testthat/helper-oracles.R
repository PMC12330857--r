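# Independent brute-force oracles used across the suite. These stay
# deliberately naive (enumeration, direct summation) and share no code with
# the implementation paths they check.

# exact null distribution of the one-sample signed-rank statistic W+ for
# the observed tie structure, by enumeration over all 2^n sign assignments
exact_signed_rank_oracle <- function(values, center = 2.75) {
  d <- values - center
  stopifnot(all(d != 0))
  r <- rank(abs(d))
  n <- length(d)
  stopifnot(n <= 16)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  w_obs <- sum(r[d > 0])
  list(w = w_obs, mean = mean(w_all), sd = stats::sd(w_all) *
         sqrt((length(w_all) - 1) / length(w_all)),
       z = (w_obs - mean(w_all)) /
         (stats::sd(w_all) * sqrt((length(w_all) - 1) / length(w_all))),
       p_ge = mean(w_all >= w_obs))
}

# direct-summation signed overlap
brute_signed_overlap <- function(sgn, mask) {
  num <- 0
  for (i in seq_along(sgn)) num <- num + sign(sgn[i]) * mask[i]
  num / sum(mask)
}

# set-count multiclass Dice
brute_multiclass_dsc <- function(a, b) {
  ap <- which(a > 0); an <- which(a < 0)
  bp <- which(b > 0); bn <- which(b < 0)
  denom <- length(ap) + length(an) + length(bp) + length(bn)
  if (denom == 0) return(0)
  2 * (length(intersect(ap, bp)) + length(intersect(an, bn))) / denom
}

# naive linear interpolation over flagged entries (index-based)
brute_interp <- function(x, flags) {
  good <- which(!flags)
  out <- x
  for (i in which(flags)) {
    lo <- good[good < i]
    hi <- good[good > i]
    if (length(lo) == 0) out[i] <- x[min(hi)]
    else if (length(hi) == 0) out[i] <- x[max(lo)]
    else {
      l <- max(lo); h <- min(hi)
      out[i] <- x[l] + (x[h] - x[l]) * (i - l) / (h - l)
    }
  }
  out
}

# small random signed map
random_signed_map <- function(n) sample(c(-1L, 0L, 1L), n, replace = TRUE)

# construct a beat sequence directly from an IBI vector
new_beats_for_test <- function(ibi) {
  structure(list(beat_times_s = cumsum(c(0.5, ibi)), ibi_s = ibi,
                 outlier_flags = rep(FALSE, length(ibi))),
            class = "vigi_beats")
}

# tiny all-one-state latent helper
frozen_latent <- function(duration_s, state, seed = 1) {
  generate_latent(duration_s, 0, seed = seed, start = state)
}
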