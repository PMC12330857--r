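#' @name pipeline
#' @title End-to-end analysis runners
#'
#' @description
#' Orchestration of the full analysis on a synthetic study: per-session
#' vigilance staging, signal conditioning, seed correlation mapping
#' (static, per-epoch, and sliding-window), mixed-effects group maps with
#' dual thresholding, and dynamic-state clustering with vigilance
#' association. The runners stream sessions one at a time so the default
#' 20-subject study stays memory-light.
NULL

# per-volume BOLD state labels; falls back to deriving them from the
# latent trajectory with the generator's fixed hemodynamic lag
session_volume_states <- function(rec, lag_s = 5) {
  vs <- attr(rec$bold, "volume_state")
  if (!is.null(vs)) return(vs)
  if (is.null(rec$latent$states)) return(NULL)
  n_vol <- ncol(rec$bold)
  sec <- floor((seq_len(n_vol) - 0.5) * rec$tr_s - lag_s) + 1L
  sec <- pmin(length(rec$latent$states), pmax(1L, sec))
  rec$latent$states[sec]
}

# build the RV/HR physio series for one session record
session_physio_series <- function(rec, n_vol) {
  rv <- compute_rv(rec$physio$resp$values, rec$physio$resp$sfreq,
                   rec$tr_s, n_vol)
  beats <- interpolate_ibi_outliers(
    detect_beats(rec$physio$pulse$values, rec$physio$pulse$sfreq))
  hr <- compute_hr(beats, rec$tr_s, n_vol)
  list(rv = rv, hr = hr)
}

# detrend + band-pass, extract the seed pre-confound, then residualize
# both seed and targets against the (identically filtered) confounds
condition_and_extract <- function(rec, pipeline) {
  x <- bandpass(detrend_legendre(as_ts_matrix(unclass(rec$bold))), rec$tr_s)
  seed <- extract_seed(x, attr(rec$bold, "seed_parcels"))
  if (pipeline == "none") return(list(seed = seed, targets = x))
  conf <- if (pipeline %in% c("mcsf_wm", "acompcor")) {
    tis <- lapply(rec$tissue, function(m) {
      bandpass(detrend_legendre(as_ts_matrix(m)), rec$tr_s)
    })
    build_confounds(pipeline, tissue_ts = tis)
  } else {
    ps <- session_physio_series(rec, ncol(x))
    cf <- build_confounds("physio", physio_series = ps, tr_s = rec$tr_s)
    t(bandpass(t(as.matrix(cf)), rec$tr_s))
  }
  list(seed = as.numeric(regress_confounds(matrix(seed, 1), conf)),
       targets = regress_confounds(x, conf))
}

#' Analyze a single session: staging, conditioning, correlation maps
#'
#' @param rec a session record ([generate_session()] / [read_session()]).
#' @param pipeline confound pipeline: "none", "mcsf_wm", "acompcor",
#'   "physio".
#' @param epoch_volumes,z_thresh,shift_s staging parameters (see
#'   [assign_epoch_states()]).
#' @param min_volumes minimum epoch length for epoch maps.
#' @param window_volumes sliding-window length in volumes; `NULL` for
#'   4 minutes at the session TR.
#' @param overlap window overlap fraction (default 0.5).
#' @return list with the epoch table, per-epoch maps, windowed FC set with
#'   its per-window EEG vigilance metric, staging-accuracy bookkeeping,
#'   and the static map.
#' @export
analyze_session <- function(rec, pipeline = "none", epoch_volumes = 30,
                            z_thresh = 1.5, shift_s = 5, min_volumes = 30,
                            window_volumes = NULL, overlap = 0.5) {
  tr_s <- rec$tr_s
  n_vol <- ncol(rec$bold)
  bp <- epoch_band_powers(rec$eeg)
  stages <- classify_stages(bp)
  epochs <- suppressMessages(
    assign_epoch_states(stages, tr_s, n_volumes = n_vol,
                        epoch_volumes = epoch_volumes, z_thresh = z_thresh,
                        shift_s = shift_s))
  ce <- condition_and_extract(rec, pipeline)

  static_map <- correlation_map(ce$seed, ce$targets, scope = "static",
                                subject_id = rec$subject_id,
                                session_id = rec$session_id)
  emaps <- suppressMessages(
    epoch_fc(ce$seed, ce$targets, epochs, min_volumes = min_volumes,
             subject_id = rec$subject_id, session_id = rec$session_id))

  if (is.null(window_volumes)) window_volumes <- round(240 / tr_s)
  wf <- NULL
  metric <- NULL
  if (window_volumes <= n_vol) {
    wf <- windowed_fc(ce$seed, ce$targets, window_volumes, overlap,
                      subject_id = rec$subject_id,
                      session_id = rec$session_id)
    # EEG vigilance score per window: signed-rank z of the stages over the
    # window's neural span (window minus the hemodynamic shift)
    n_sec <- length(stages$stages)
    metric <- vapply(seq_len(nrow(wf$windows)), function(i) {
      lo <- max(1L, floor(wf$windows$start_volume[i] * tr_s - shift_s) + 1L)
      hi <- min(n_sec, floor(wf$windows$end_volume[i] * tr_s - shift_s))
      signed_rank_z(stages$stages[lo:hi])
    }, numeric(1))
    wf$metric <- metric
  }

  # staging accuracy on unambiguous (single-latent-state) epochs; each
  # epoch's EEG span is its volume span shifted back to neural time
  acc <- NULL
  if (!is.null(rec$latent$states)) {
    k <- round(shift_s / tr_s)
    maj <- latent_majority(rec$latent,
                           (epochs$start_volume - k) * tr_s,
                           (epochs$end_volume - k) * tr_s)
    decided <- epochs$state %in% c("alert", "drowsy")
    usable <- maj$pure & decided
    acc <- list(n_unambiguous = sum(maj$pure),
                n_scored = sum(usable),
                n_correct = sum(usable & epochs$state == maj$state))
  }
  list(epochs = epochs, epoch_maps = emaps, windowed = wf,
       static_map = static_map, stages = stages, band_powers = bp,
       staging = acc, subject_id = rec$subject_id,
       session_id = rec$session_id)
}

collect_epoch_samples <- function(session_results) {
  rows <- list()
  zmat <- list()
  for (sr in session_results) {
    for (m in sr$epoch_maps) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sr$subject_id, session = sr$session_id,
        state = m$state, x = m$n_volumes)
      zmat[[length(zmat) + 1L]] <- m$z_values
    }
  }
  list(info = do.call(rbind, rows), z = do.call(rbind, zmat))
}

#' Fit per-target group models and threshold the resulting t-map
#'
#' @param z maps x targets Fisher-z matrix.
#' @param info data.frame aligned with the rows of `z`; needs `subject`
#'   and, for the two-state contrast, `state` and `x`.
#' @param model "intercept", "two_state", or "single_state".
#' @param gm_mask,top_frac,q thresholding parameters
#'   (see [threshold_tmap()]).
#' @return list with the t/p table (`tmap`), the thresholded
#'   `vigi_signedmap`, and the count of non-converged targets.
#' @export
group_map <- function(z, info, model = c("two_state", "intercept",
                                         "single_state"),
                      gm_mask = rep(TRUE, ncol(z)), top_frac = 0.4,
                      q = 0.05) {
  model <- match.arg(model)
  n_targets <- ncol(z)
  tv <- pv <- rep(NA_real_, n_targets)
  bad <- 0L
  for (j in seq_len(n_targets)) {
    df <- cbind(info, r = z[, j])
    fit <- switch(model,
      intercept = fit_lme_intercept(df),
      two_state = suppressWarnings(fit_lme_two_state(df)),
      single_state = suppressWarnings(fit_lme_single_state(df)))
    ci <- switch(model, two_state = which(fit$coef_names == "state"), 1L)
    if (!isTRUE(fit$converged) || !is.finite(fit$t[ci]) ||
        !is.finite(fit$p[ci])) {
      bad <- bad + 1L
      next
    }
    tv[j] <- fit$t[ci]
    pv[j] <- fit$p[ci]
  }
  tmap <- data.frame(target = seq_len(n_targets), t = tv, p = pv)
  signed <- if (all(is.na(tv))) {
    warning("no target yielded an analyzable group fit; signed map omitted")
    NULL
  } else {
    threshold_tmap(tmap, gm_mask, top_frac = top_frac, q = q)
  }
  list(tmap = tmap, signed = signed, n_nonconverged = bad)
}

#' Run the full vigilance-state analysis on a synthetic study
#'
#' Streams every session through [analyze_session()], then fits the
#' two-state (drowsy vs. alert) and per-state group maps, thresholds them,
#' scores them against the study's planted ground truth, clusters the
#' pooled sliding-window maps into two dynamic FC states, and tests the
#' per-window EEG vigilance score between the states.
#'
#' @param spec a `vigi_study_spec`.
#' @param pipeline confound pipeline (default "none": the synthetic world
#'   has no planted vascular confounds).
#' @param cluster_seed RNG seed for the k-medians restarts.
#' @param progress print one line per session.
#' @param ... parameters forwarded to [analyze_session()].
#' @return a `vigi_state_result` list; see Details in the package
#'   vignette. Key elements: `staging_accuracy`, `contrast` (group map +
#'   DSC vs. truth), `alert`/`drowsy` single-state maps, `clusters`,
#'   `cluster_ari`, `state_summary`.
#' @export
run_state_pipeline <- function(spec, pipeline = "none", cluster_seed = 7,
                               progress = FALSE, ...) {
  stopifnot(inherits(spec, "vigi_study_spec"))
  idx <- study_sessions(spec)
  providers <- lapply(seq_len(nrow(idx)), function(i) {
    local({
      s <- idx$subject[i]; j <- idx$session[i]
      function() generate_session(spec, s, j)
    })
  })
  out <- run_state_core(providers, truth = truth_signed_map(spec),
                        pipeline = pipeline, cluster_seed = cluster_seed,
                        progress = progress, ...)
  out$spec <- spec
  out
}

# core state analysis over a list of zero-argument session providers
run_state_core <- function(providers, truth = NULL, pipeline = "none",
                           cluster_seed = 7, progress = FALSE, ...) {
  n_sess <- length(providers)
  session_results <- vector("list", n_sess)
  win_z <- list(); win_metric <- list(); win_subject <- list()
  win_majority <- list()
  for (i in seq_len(n_sess)) {
    rec <- providers[[i]]()
    sr <- analyze_session(rec, pipeline = pipeline, ...)
    if (progress) {
      message(sprintf("session %d/%d: %d epochs, %d epoch maps",
                      i, n_sess, nrow(sr$epochs),
                      length(sr$epoch_maps)))
    }
    if (!is.null(sr$windowed)) {
      wz <- do.call(rbind, lapply(sr$windowed$maps, `[[`, "z_values"))
      win_z[[i]] <- wz
      win_metric[[i]] <- sr$windowed$metric
      win_subject[[i]] <- rep(rec$subject_id, nrow(wz))
      vs <- session_volume_states(rec)
      if (!is.null(vs)) {
        win_majority[[i]] <- vapply(seq_len(nrow(sr$windowed$windows)),
          function(w) {
            vols <- (sr$windowed$windows$start_volume[w] + 1L):
              sr$windowed$windows$end_volume[w]
            if (mean(vs[vols] == "drowsy") >= 0.5) "drowsy" else "alert"
          }, character(1))
      }
    }
    sr$band_powers <- NULL  # drop bulky per-second spectra
    sr$stages <- NULL
    session_results[[i]] <- sr
    rm(rec)
  }

  samples <- collect_epoch_samples(session_results)

  result <- list(pipeline = pipeline, sessions = session_results)

  stg <- Filter(Negate(is.null), lapply(session_results, `[[`, "staging"))
  if (length(stg) > 0) {
    acc <- Reduce(function(a, b) Map(`+`, a, b), stg)
    result$staging_accuracy <- acc$n_correct / acc$n_scored
    result$staging_counts <- acc
  }

  if (!is.null(samples$info) && length(unique(samples$info$state)) == 2) {
    contrast <- suppressWarnings(group_map(samples$z, samples$info,
                                           "two_state"))
    if (!is.null(truth) && !is.null(contrast$signed)) {
      contrast$dsc_vs_truth <- multiclass_dsc(contrast$signed, truth)
    }
    result$contrast <- contrast
    for (st in c("alert", "drowsy")) {
      sel <- samples$info$state == st
      if (sum(sel) >= 3) {
        result[[st]] <- suppressWarnings(
          group_map(samples$z[sel, , drop = FALSE],
                    samples$info[sel, , drop = FALSE], "single_state"))
      }
    }
  }
  result$epoch_samples <- samples

  if (length(win_z) > 0) {
    X <- do.call(rbind, win_z)
    metric <- unlist(win_metric)
    subj <- unlist(win_subject)
    majority <- unlist(win_majority)
    cl <- kmedians_cluster(X, k = 2, restarts = 20, seed = cluster_seed)
    cl <- canonicalize_states(cl, metric)
    result$clusters <- cl
    if (length(majority) == length(cl$labels)) {
      result$cluster_ari <- adjusted_rand(cl$labels, majority)
      result$window_majority <- majority
    }
    result$window_metric <- metric
    if (length(unique(cl$labels)) == 2) {
      result$state_summary <- state_vigilance_test(cl, metric, subj)
    }
  }
  class(result) <- "vigi_state_result"
  result
}

#' Run the static (whole-scan) analysis on a synthetic study
#'
#' One static map per session, an intercept-only group model per target,
#' and the dual-thresholded signed map.
#'
#' @param spec a `vigi_study_spec`.
#' @param pipeline confound pipeline.
#' @param ... forwarded to [analyze_session()].
#' @return list with `z` (sessions x targets), `info`, `group` (group map
#'   list), and `tsnr` (per-session seed tSNR).
#' @export
run_static_pipeline <- function(spec, pipeline = "none", ...) {
  stopifnot(inherits(spec, "vigi_study_spec"))
  idx <- study_sessions(spec)
  zrows <- list(); info <- list(); snr <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    rec <- generate_session(spec, idx$subject[i], idx$session[i])
    ce <- condition_and_extract(rec, pipeline)
    m <- correlation_map(ce$seed, ce$targets, scope = "static")
    zrows[[i]] <- m$z_values
    info[[i]] <- data.frame(subject = idx$subject[i],
                            session = idx$session[i])
    raw_seed <- extract_seed(unclass(rec$bold), attr(rec$bold, "seed_parcels"))
    snr[i] <- tsnr(raw_seed)
  }
  z <- do.call(rbind, zrows)
  info <- do.call(rbind, info)
  list(z = z, info = info,
       group = group_map(z, info, "intercept"),
       tsnr = snr)
}
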