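#' Extract a seed ROI time-course
#'
#' Unweighted mean of the member targets' series. Extraction is meant to be
#' performed on data conditioned up to (but not including) confound
#' regression; the pipeline runner applies the confound regression to the
#' seed series afterwards so seed and targets see identical denoising.
#'
#' @param ts_matrix targets x volumes matrix.
#' @param seed_ids integer indices (or rownames) of the seed members.
#' @return numeric seed series of length `ncol(ts_matrix)`.
#' @export
extract_seed <- function(ts_matrix, seed_ids) {
  ts_matrix <- as_ts_matrix(ts_matrix)
  if (length(seed_ids) == 0) {
    vf_stop("empty seed", "vigifc_parameter_error")
  }
  colMeans(ts_matrix[seed_ids, , drop = FALSE])
}

new_correlation_map <- function(z, scope, n_volumes, subject_id = NA,
                                session_id = NA, index = NA) {
  structure(list(z_values = z, scope = scope, n_volumes = n_volumes,
                 subject_id = subject_id, session_id = session_id,
                 index = index),
            class = "vigi_cormap")
}

#' Seed-to-target correlation map with Fisher z transform
#'
#' Pearson correlation of the seed series against every target, clipped to
#' `|r| <= 1 - 1e-7` and transformed with `atanh`.
#'
#' @param seed numeric seed series.
#' @param targets targets x volumes matrix.
#' @param scope map scope label ("static", "epoch", "window").
#' @param ... metadata (`subject_id`, `session_id`, `index`) stored on the
#'   map.
#' @return a `vigi_cormap`: list with `z_values` (one per target),
#'   `n_volumes`, scope and metadata.
#' @export
correlation_map <- function(seed, targets, scope = "static", ...) {
  targets <- as_ts_matrix(targets)
  if (length(seed) != ncol(targets)) {
    vf_stop("seed and targets must share the volume count",
            "vigifc_parameter_error")
  }
  if (length(seed) < 3) {
    vf_stop("need at least 3 paired volumes", "vigifc_parameter_error")
  }
  if (stats::sd(seed) == 0) {
    vf_stop("zero-variance seed", "vigifc_parameter_error")
  }
  tsd <- apply(targets, 1, stats::sd)
  r <- suppressWarnings(as.numeric(stats::cor(seed, t(targets))))
  r[tsd == 0] <- 0
  z <- fisher_z(r)
  m <- new_correlation_map(z, scope, length(seed), ...)
  m$flagged_zero_variance <- which(tsd == 0)
  m
}

#' Per-epoch seed correlation maps
#'
#' One map per surviving alert/drowsy epoch (intermediate epochs are
#' excluded); epochs shorter than `min_volumes` are skipped with a message.
#' Each map carries its epoch's volume count for use as the epoch-length
#' covariate in the mixed-effects models.
#'
#' @param seed seed series (full scan).
#' @param targets targets x volumes matrix (full scan).
#' @param epochs epoch table from [assign_epoch_states()].
#' @param min_volumes minimum epoch length in volumes (default 30, one raw
#'   staging epoch).
#' @param ... metadata forwarded to the maps.
#' @return list of `vigi_cormap` objects, each with a `state` element.
#' @export
epoch_fc <- function(seed, targets, epochs, min_volumes = 30, ...) {
  targets <- as_ts_matrix(targets)
  keep <- epochs$state %in% c("alert", "drowsy")
  out <- list()
  for (i in which(keep)) {
    nv <- epochs$n_volumes[i]
    if (nv < min_volumes) {
      message(sprintf("skipping %s epoch of %d volumes (< %d)",
                      epochs$state[i], nv, min_volumes))
      next
    }
    idx <- (epochs$start_volume[i] + 1L):epochs$end_volume[i]
    m <- correlation_map(seed[idx], targets[, idx, drop = FALSE],
                         scope = "epoch", index = i, ...)
    m$state <- epochs$state[i]
    out[[length(out) + 1L]] <- m
  }
  out
}

#' Sliding-window seed correlation maps
#'
#' Windows of `window_volumes` volumes whose starts advance by
#' `window_volumes * (1 - overlap)` volumes, anchored at volume 0; a
#' trailing partial window is dropped.
#'
#' @param seed seed series.
#' @param targets targets x volumes matrix.
#' @param window_volumes window length in volumes (e.g. 114 for 4 min at
#'   TR = 2.1 s).
#' @param overlap fractional overlap between consecutive windows
#'   (default 0.5).
#' @param ... metadata forwarded to the maps.
#' @return a `vigi_winfc` object: list with `maps` (list of
#'   `vigi_cormap`), `windows` (data.frame of 0-based half-open volume
#'   ranges), `window_volumes`, `overlap`, and a `metric` slot (filled
#'   later with the per-window vigilance metric).
#' @export
windowed_fc <- function(seed, targets, window_volumes, overlap = 0.5, ...) {
  targets <- as_ts_matrix(targets)
  n_vol <- ncol(targets)
  if (window_volumes > n_vol) {
    vf_stop("window longer than session", "vigifc_parameter_error")
  }
  stride <- max(1L, round(window_volumes * (1 - overlap)))
  starts <- seq(0L, n_vol - window_volumes, by = stride)
  maps <- lapply(seq_along(starts), function(i) {
    idx <- (starts[i] + 1L):(starts[i] + window_volumes)
    correlation_map(seed[idx], targets[, idx, drop = FALSE],
                    scope = "window", index = i, ...)
  })
  structure(list(
    maps = maps,
    windows = data.frame(start_volume = starts,
                         end_volume = starts + window_volumes),
    window_volumes = window_volumes, overlap = overlap,
    metric = rep(NA_real_, length(starts))
  ), class = "vigi_winfc")
}
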