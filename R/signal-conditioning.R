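#' Remove slow scanner drift with a Legendre polynomial basis
#'
#' Per-target least-squares projection onto Legendre polynomials of orders
#' 0..`order` evaluated on `[-1, 1]` over the scan; the projection is
#' subtracted, removing the mean and any polynomial trend up to the given
#' order.
#'
#' @param ts targets x volumes numeric matrix (a vector is treated as one
#'   target).
#' @param order highest polynomial order removed (default 4).
#' @return detrended matrix of the same shape.
#' @export
detrend_legendre <- function(ts, order = 4) {
  ts <- as_ts_matrix(ts)
  n <- ncol(ts)
  if (n <= order + 1) {
    vf_stop("series too short for the requested detrending order",
            "vigifc_parameter_error")
  }
  basis <- legendre_basis(n, order)
  qrb <- qr(basis)
  ts - t(qr.fitted(qrb, t(ts)))
}

legendre_basis <- function(n, order) {
  x <- seq(-1, 1, length.out = n)
  p <- matrix(0, n, order + 1)
  p[, 1] <- 1
  if (order >= 1) p[, 2] <- x
  if (order >= 2) {
    for (k in 2:order) {  # Bonnet recursion
      p[, k + 1] <- ((2 * k - 1) * x * p[, k] - (k - 1) * p[, k - 1]) / k
    }
  }
  p
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass (designed by bilinear
#' transform of the analog prototype, realized as second-order sections for
#' numerical stability) forward and backward, giving zero phase and a
#' squared magnitude response. Edge effects are controlled by odd-reflection
#' padding with steady-state initial conditions, as is conventional for
#' forward-backward filtering.
#'
#' @param ts targets x volumes matrix (or vector).
#' @param tr_s repetition time in seconds (sampling rate is `1 / tr_s`).
#' @param low,high pass-band edges in Hz (defaults 0.01 and 0.15).
#' @param order analog prototype order (default 4).
#' @return filtered matrix of the same shape.
#' @export
bandpass <- function(ts, tr_s, low = 0.01, high = 0.15, order = 4) {
  ts <- as_ts_matrix(ts)
  fs <- 1 / tr_s
  if (high >= fs / 2) {
    vf_stop("high cutoff must be below the Nyquist frequency",
            "vigifc_parameter_error")
  }
  if (low <= 0 || low >= high) {
    vf_stop("need 0 < low < high", "vigifc_parameter_error")
  }
  sos <- butter_bandpass_sos(low, high, fs, order)
  t(apply_filtfilt(sos, t(ts), fs, low))
}

# Butterworth band-pass design: analog prototype poles -> low-pass-to-
# band-pass transform -> bilinear transform -> second-order sections.
# Returns a list of biquads (b0, b1, b2, a1, a2), overall gain folded into
# the first section.
butter_bandpass_sos <- function(low, high, fs, order = 4) {
  n <- order
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k - 1) / (2 * n) + 1i * pi / 2)  # LHP poles
  w1 <- 2 * fs * tan(pi * low / fs)   # prewarped edges (rad/s)
  w2 <- 2 * fs * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # each prototype pole maps to a pair of band-pass poles
  pb <- unlist(lapply(proto, function(p) {
    d <- sqrt((p * bw / 2)^2 - w0^2 + 0i)
    c(p * bw / 2 + d, p * bw / 2 - d)
  }))
  zd <- (2 * fs + pb) / (2 * fs - pb)  # bilinear transform of poles
  # digital zeros: n at z = +1 (from s = 0), n at z = -1 (from s = Inf)
  # pair conjugate poles into biquads
  pos <- zd[Im(zd) > 0]
  pos <- pos[order(abs(pos), decreasing = TRUE)]
  sections <- lapply(seq_len(n), function(i) {
    p <- pos[i]
    a1 <- -2 * Re(p)
    a2 <- Mod(p)^2
    list(b0 = 1, b1 = 0, b2 = -1, a1 = a1, a2 = a2)  # zeros at +/-1
  })
  # normalize to unit gain at the digital center frequency
  wc <- 2 * atan(w0 / (2 * fs))
  z <- exp(1i * wc)
  h <- prod(vapply(sections, function(s) {
    Mod((s$b0 * z^2 + s$b1 * z + s$b2) / (z^2 + s$a1 * z + s$a2))
  }, numeric(1)))
  g <- (1 / h)^(1 / n)
  for (i in seq_len(n)) {
    sections[[i]]$b0 <- sections[[i]]$b0 * g
    sections[[i]]$b1 <- sections[[i]]$b1 * g
    sections[[i]]$b2 <- sections[[i]]$b2 * g
  }
  sections
}

# single forward pass of one biquad over the columns of x (matrix:
# samples x series), direct form II transposed, with initial conditions
# scaled to the first row (steady-state step response).
sosfilt1 <- function(sec, x) {
  ns <- nrow(x)
  g0 <- (sec$b0 + sec$b1 + sec$b2) / (1 + sec$a1 + sec$a2)
  s1 <- (sec$b1 + sec$b2 - (sec$a1 + sec$a2) * g0) * x[1, ]
  s2 <- (sec$b2 - sec$a2 * g0) * x[1, ]
  y <- x
  for (i in seq_len(ns)) {
    xi <- x[i, ]
    yi <- sec$b0 * xi + s1
    s1 <- sec$b1 * xi - sec$a1 * yi + s2
    s2 <- sec$b2 * xi - sec$a2 * yi
    y[i, ] <- yi
  }
  y
}

# forward-backward second-order-section filtering with odd-reflection
# padding; x is samples x series.
apply_filtfilt <- function(sos, x, fs, low) {
  ns <- nrow(x)
  padlen <- min(ns - 1L, max(30L, ceiling(2 * fs / low)))
  head_pad <- 2 * x[rep(1L, padlen), , drop = FALSE] -
    x[seq(padlen + 1L, 2L), , drop = FALSE]
  tail_pad <- 2 * x[rep(ns, padlen), , drop = FALSE] -
    x[seq(ns - 1L, ns - padlen), , drop = FALSE]
  xp <- rbind(head_pad, x, tail_pad)
  for (sec in sos) xp <- sosfilt1(sec, xp)
  xp <- xp[rev(seq_len(nrow(xp))), , drop = FALSE]
  for (sec in sos) xp <- sosfilt1(sec, xp)
  xp <- xp[rev(seq_len(nrow(xp))), , drop = FALSE]
  xp[padlen + seq_len(ns), , drop = FALSE]
}

#' Analytic amplitude gain of the zero-phase Butterworth band-pass
#'
#' The forward-backward pass has amplitude response `|H(f)|^2`, the squared
#' magnitude of the analog prototype; that quantity is returned here and
#' serves as the independent frequency-response oracle in the test suite.
#'
#' @param f frequency in Hz (vectorized).
#' @param low,high band edges in Hz.
#' @param order prototype order (default 4).
#' @return amplitude gain in `[0, 1]` (0.5 at the band edges).
#' @export
butter_gain <- function(f, low = 0.01, high = 0.15, order = 4) {
  w <- 2 * pi * f
  w1 <- 2 * pi * low
  w2 <- 2 * pi * high
  bw <- w2 - w1
  w0sq <- w1 * w2
  1 / (1 + ((w^2 - w0sq) / (bw * w))^(2 * order))
}

as_ts_matrix <- function(ts) {
  if (is.null(dim(ts))) ts <- matrix(ts, nrow = 1)
  storage.mode(ts) <- "double"
  ts
}

# ---------------------------------------------------------------------------
# Confound pipelines

# canonical respiratory response function (Birn et al. 2008 shape)
rrf <- function(t) 0.6 * t^2.1 * exp(-t / 1.6) -
  0.0023 * t^3.54 * exp(-t / 4.25)

# canonical cardiac response function (Chang et al. 2009 shape)
crf <- function(t) 0.6 * t^2.7 * exp(-t / 1.6) -
  16 / sqrt(2 * pi * 9) * exp(-(t - 12)^2 / 18)

# five-function response basis: canonical, 1st/2nd temporal derivatives,
# and 1st/2nd dispersion (width) derivatives, sampled at the TR grid
response_basis <- function(fun, tr_s, span_s = 40) {
  t <- seq(0, span_s, by = tr_s)
  dt <- tr_s
  f0 <- fun(t)
  d1 <- c(0, diff(f0)) / dt
  d2 <- c(0, diff(d1)) / dt
  disp <- function(scale) fun(t / scale) - f0
  cbind(canonical = f0, tder1 = d1, tder2 = d2,
        disp1 = disp(1.1) / 0.1, disp2 = disp(1.25) / 0.25)
}

# linear convolution of x (with NAs) against kernel k; output entries with
# any missing contribution are NA (to be zero-filled by the caller)
conv_na <- function(x, k) {
  n <- length(x)
  x0 <- ifelse(is.na(x), 0, x)
  y <- Re(stats::convolve(x0, rev(k), type = "open"))[seq_len(n)]
  bad <- Re(stats::convolve(as.numeric(is.na(x)),
                            rev(as.numeric(abs(k) > 0)),
                            type = "open"))[seq_len(n)]
  y[bad > 1e-9] <- NA_real_
  y
}

#' Assemble a confound-regressor matrix for one of three pipelines
#'
#' \describe{
#'   \item{`"mcsf_wm"`}{3 columns: the mean white-matter, mean deep-CSF,
#'     and mean fourth-ventricle signals.}
#'   \item{`"acompcor"`}{the first 5 principal components of the pooled,
#'     per-series centered and variance-normalized WM + deep-CSF series.
#'     Rank-deficient inputs yield zero-variance trailing components,
#'     flagged with a warning and a `rank_deficient` attribute.}
#'   \item{`"physio"`}{10 columns: the respiratory-volume and heart-rate
#'     series convolved with a 5-function respiratory and cardiac response
#'     basis respectively; convolved entries with missing contributions are
#'     set to 0 (the published missing-data rule).}
#' }
#'
#' @param pipeline one of "mcsf_wm", "acompcor", "physio".
#' @param tissue_ts for the tissue pipelines: list with targets x volumes
#'   matrices `wm`, `csf`, and (mCSF/WM only) `fv`.
#' @param physio_series for the physio pipeline: list with `rv` and `hr`
#'   `vigi_physio` objects.
#' @param tr_s repetition time (needed to sample the response basis).
#' @param n_components number of aCompCor components (default 5).
#' @return a `vigi_confounds` object: volumes x k matrix with `pipeline`
#'   and per-column `provenance` attributes.
#' @export
build_confounds <- function(pipeline = c("mcsf_wm", "acompcor", "physio"),
                            tissue_ts = NULL, physio_series = NULL,
                            tr_s = NULL, n_components = 5) {
  pipeline <- match.arg(pipeline)
  if (pipeline == "mcsf_wm") {
    need <- c("wm", "csf", "fv")
    if (is.null(tissue_ts) || !all(need %in% names(tissue_ts))) {
      vf_stop("mcsf_wm pipeline needs tissue_ts$wm, $csf, $fv",
              "vigifc_config_error")
    }
    reg <- sapply(tissue_ts[need], function(m) colMeans(as_ts_matrix(m)))
    colnames(reg) <- c("mean_wm", "mean_csf", "mean_fv")
    prov <- colnames(reg)
  } else if (pipeline == "acompcor") {
    if (is.null(tissue_ts) || !all(c("wm", "csf") %in% names(tissue_ts))) {
      vf_stop("acompcor pipeline needs tissue_ts$wm and $csf",
              "vigifc_config_error")
    }
    pooled <- rbind(as_ts_matrix(tissue_ts$wm), as_ts_matrix(tissue_ts$csf))
    centered <- t(scale(t(pooled)))           # per-series center + unit SD
    centered[!is.finite(centered)] <- 0       # zero-variance series
    sv <- svd(t(centered), nu = n_components, nv = 0)
    reg <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
    colnames(reg) <- sprintf("acompcor_pc%d", seq_len(n_components))
    prov <- colnames(reg)
    var_comp <- apply(reg, 2, stats::var)
    rank_def <- var_comp <= 1e-10 * max(var_comp, 1e-300)
    if (any(rank_def)) {
      warning(sprintf("aCompCor input rank-deficient: %d component(s) carry no variance",
                      sum(rank_def)))
    }
    attr(reg, "rank_deficient") <- rank_def
  } else {
    if (is.null(physio_series) ||
        !all(c("rv", "hr") %in% names(physio_series)) || is.null(tr_s)) {
      vf_stop("physio pipeline needs physio_series$rv, $hr and tr_s",
              "vigifc_config_error")
    }
    basis_r <- response_basis(rrf, tr_s)
    basis_c <- response_basis(crf, tr_s)
    conv_all <- function(x, basis, tag) {
      out <- sapply(seq_len(ncol(basis)),
                    function(j) conv_na(x, basis[, j]))
      out[is.na(out)] <- 0
      colnames(out) <- sprintf("%s_%s", tag, colnames(basis))
      out
    }
    rv <- physio_series$rv$values
    hr <- physio_series$hr$values
    reg <- cbind(conv_all(rv, basis_r, "rv"), conv_all(hr, basis_c, "hr"))
    prov <- colnames(reg)
  }
  structure(reg, pipeline = pipeline, provenance = prov,
            class = c("vigi_confounds", class(reg)))
}

#' Regress confounds out of a time-series matrix
#'
#' Ordinary least-squares residualization per target; an intercept column is
#' always included. Collinear confound columns are dropped (with a warning)
#' using a pivoted QR rank check.
#'
#' @param ts targets x volumes matrix.
#' @param confounds volumes x k matrix (e.g. from [build_confounds()]).
#' @return residual matrix, same shape as `ts`.
#' @export
regress_confounds <- function(ts, confounds) {
  ts <- as_ts_matrix(ts)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != ncol(ts)) {
    vf_stop("confounds and time series must share the volume count",
            "vigifc_parameter_error")
  }
  design <- cbind(intercept = 1, confounds)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop_idx <- qrd$pivot[seq(qrd$rank + 1L, ncol(design))]
    warning(sprintf("dropping %d collinear confound column(s): %s",
                    length(drop_idx),
                    paste(colnames(design)[drop_idx], collapse = ", ")))
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    qrd <- qr(design)
  }
  t(qr.resid(qrd, t(ts)))
}

#' Temporal signal-to-noise ratio per target
#'
#' Mean over standard deviation of each target's time-course, computed on
#' the denoised-but-not-band-passed series. Zero-variance targets are
#' reported as `Inf` with a warning.
#'
#' @param ts_raw targets x volumes matrix.
#' @return numeric vector of tSNR values, one per target.
#' @export
tsnr <- function(ts_raw) {
  ts_raw <- as_ts_matrix(ts_raw)
  mu <- rowMeans(ts_raw)
  sd_ <- apply(ts_raw, 1, stats::sd)
  out <- ifelse(sd_ > 0, mu / sd_, Inf)
  if (any(sd_ == 0)) warning("zero-variance target(s): tSNR reported as Inf")
  out
}

#' Full conditioning pipeline for one session's BOLD matrix
#'
#' Fixed order: Legendre detrend, band-pass, then confound regression with
#' confounds that have themselves been identically band-passed (detrended
#' where they come from tissue series). With `pipeline = "none"` only
#' detrending and band-pass are applied.
#'
#' @param bold parcels x volumes matrix.
#' @param tr_s repetition time.
#' @param pipeline "none", "mcsf_wm", "acompcor", or "physio".
#' @param tissue_ts,physio_series inputs forwarded to [build_confounds()].
#' @param detrend_order,low,high pipeline parameters.
#' @return conditioned parcels x volumes matrix.
#' @export
condition_bold <- function(bold, tr_s, pipeline = "none", tissue_ts = NULL,
                           physio_series = NULL, detrend_order = 4,
                           low = 0.01, high = 0.15) {
  x <- detrend_legendre(as_ts_matrix(bold), detrend_order)
  x <- bandpass(x, tr_s, low, high)
  if (pipeline == "none") return(x)
  if (pipeline %in% c("mcsf_wm", "acompcor")) {
    tissue_ts <- lapply(tissue_ts, function(m) {
      bandpass(detrend_legendre(as_ts_matrix(m), detrend_order), tr_s,
               low, high)
    })
    conf <- build_confounds(pipeline, tissue_ts = tissue_ts)
  } else {
    conf <- build_confounds(pipeline, physio_series = physio_series,
                            tr_s = tr_s)
    conf_f <- t(bandpass(t(conf), tr_s, low, high))
    attributes(conf_f) <- attributes(conf)[c("dim", "dimnames", "pipeline",
                                             "provenance", "class")]
    conf <- conf_f
  }
  regress_confounds(x, conf)
}
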