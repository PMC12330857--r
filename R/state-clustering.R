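#' City-block k-medians clustering of windowed correlation maps
#'
#' Lloyd-style alternation under the L1 (city-block) distance: assignments
#' go to the nearest centroid, centroids are component-wise medians of
#' their members (the L1-optimal center). The best of `restarts` random
#' initializations by total inertia is kept; a restart that empties a
#' cluster is re-seeded. Labels are canonicalized afterwards by
#' [canonicalize_states()] so "state 2" is the drowsier one.
#'
#' @param window_maps windows x targets numeric matrix (each row one
#'   vectorized Fisher-z map).
#' @param k number of clusters (default 2).
#' @param restarts random restarts (default 20).
#' @param seed integer RNG seed.
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @return a `vigi_clusters` object: list with `labels` (1..k per
#'   window), `centroids` (k x targets), `inertia`, `k`, `seed`.
#' @export
kmedians_cluster <- function(window_maps, k = 2, restarts = 20, seed,
                             max_iter = 100) {
  X <- as.matrix(window_maps)
  n <- nrow(X)
  if (k > n) vf_stop("k exceeds the number of windows",
                     "vigifc_parameter_error")
  l1_to_centroids <- function(C) {
    # n x k matrix of L1 distances
    sapply(seq_len(nrow(C)), function(j) {
      rowSums(abs(X - matrix(C[j, ], n, ncol(X), byrow = TRUE)))
    })
  }
  best <- NULL
  withr_seed(seed, {
    for (r in seq_len(restarts)) {
      C <- X[sample.int(n, k), , drop = FALSE]
      labels <- rep(1L, n)
      for (it in seq_len(max_iter)) {
        D <- l1_to_centroids(C)
        new_labels <- max.col(-D, ties.method = "first")
        if (length(unique(new_labels)) < k) {
          # empty cluster: re-seed it at the point farthest from its centroid
          missing_k <- setdiff(seq_len(k), unique(new_labels))
          far <- order(D[cbind(seq_len(n), new_labels)], decreasing = TRUE)
          for (mi in seq_along(missing_k)) {
            C[missing_k[mi], ] <- X[far[mi], ]
          }
          next
        }
        if (all(new_labels == labels) && it > 1) break
        labels <- new_labels
        for (j in seq_len(k)) {
          C[j, ] <- apply(X[labels == j, , drop = FALSE], 2, stats::median)
        }
      }
      D <- l1_to_centroids(C)
      inertia <- sum(D[cbind(seq_len(n), labels)])
      if (is.null(best) || inertia < best$inertia) {
        best <- list(labels = labels, centroids = C, inertia = inertia)
      }
    }
  })
  structure(list(labels = best$labels, centroids = best$centroids,
                 inertia = best$inertia, k = k, seed = seed),
            class = "vigi_clusters")
}

#' Mean silhouette width under the city-block distance
#'
#' @param X windows x targets matrix.
#' @param labels cluster labels.
#' @return mean silhouette width over all points.
#' @export
silhouette_l1 <- function(X, labels) {
  D <- as.matrix(stats::dist(X, method = "manhattan"))
  n <- nrow(D)
  ks <- sort(unique(labels))
  s <- vapply(seq_len(n), function(i) {
    own <- labels[i]
    same <- which(labels == own & seq_len(n) != i)
    if (length(same) == 0) return(0)
    a <- mean(D[i, same])
    b <- min(vapply(ks[ks != own], function(kk) {
      mean(D[i, labels == kk])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Select the cluster count by the silhouette criterion
#'
#' Runs [kmedians_cluster()] for every k in `k_range` and returns the k
#' maximizing the mean city-block silhouette width.
#'
#' @param window_maps windows x targets matrix.
#' @param k_range candidate cluster counts (default 2:6).
#' @param seed integer RNG seed.
#' @param restarts restarts per k (default 10).
#' @return list with `best_k`, `silhouette` (named per k), `fits`.
#' @export
silhouette_select_k <- function(window_maps, k_range = 2:6, seed,
                                restarts = 10) {
  X <- as.matrix(window_maps)
  if (all(stats::dist(X[seq_len(min(nrow(X), 50)), ]) == 0)) {
    vf_stop("degenerate input: all maps identical", "vigifc_parameter_error")
  }
  fits <- lapply(k_range, function(k) {
    kmedians_cluster(X, k, restarts = restarts, seed = child_seed(seed, k))
  })
  sil <- vapply(fits, function(f) silhouette_l1(X, f$labels), numeric(1))
  names(sil) <- k_range
  list(best_k = k_range[which.max(sil)], silhouette = sil, fits = fits)
}

#' Canonicalize a two-state clustering so state 2 is the drowsier state
#'
#' Swaps labels (and centroids) if needed so that state 2 has the lower
#' mean vigilance metric. For eye-closure metrics, pass
#' `higher_is_drowsier = TRUE`.
#'
#' @param assignment a `vigi_clusters` object with k = 2.
#' @param metric per-window vigilance metric (e.g. EEG vigilance z-score,
#'   or logit percent eye closure).
#' @param higher_is_drowsier direction of the metric (default `FALSE`:
#'   higher metric = more alert).
#' @return the assignment, relabeled if necessary.
#' @export
canonicalize_states <- function(assignment, metric,
                                higher_is_drowsier = FALSE) {
  stopifnot(inherits(assignment, "vigi_clusters"), assignment$k == 2)
  m1 <- mean(metric[assignment$labels == 1], na.rm = TRUE)
  m2 <- mean(metric[assignment$labels == 2], na.rm = TRUE)
  drowsier_is_2 <- if (higher_is_drowsier) m2 > m1 else m2 < m1
  if (!drowsier_is_2) {
    assignment$labels <- 3L - assignment$labels
    assignment$centroids <- assignment$centroids[2:1, , drop = FALSE]
  }
  assignment
}

#' Test the vigilance metric difference between the two FC states
#'
#' Reuses the two-state mixed model (state fixed effect, subject random
#' intercept, referenced to state 1) on the per-window vigilance metric,
#' and reports the proportion of windows per state classified alert or
#' drowsy by thresholding the vigilance z-scores at +/-`z_thresh`.
#'
#' @param assignment a canonicalized `vigi_clusters` (k = 2).
#' @param metric per-window vigilance metric.
#' @param subject_ids per-window subject identifiers.
#' @param z_thresh alert/drowsy threshold applied to the metric when it is
#'   a vigilance z-score (default 1.5).
#' @param metric_is_z set `FALSE` when the metric is not on the z scale
#'   (proportions are then omitted).
#' @return a `vigi_statesummary`: per-state mean metric, the state-2
#'   fixed-effect fit, and per-state alert/intermediate/drowsy proportions.
#' @export
state_vigilance_test <- function(assignment, metric, subject_ids,
                                 z_thresh = 1.5, metric_is_z = TRUE) {
  stopifnot(inherits(assignment, "vigi_clusters"))
  if (length(unique(assignment$labels)) < 2) {
    vf_stop("assignment has a single state", "vigifc_parameter_error")
  }
  ok <- is.finite(metric)
  fit <- fit_lme_two_state(data.frame(
    r = metric[ok], subject = subject_ids[ok],
    state = paste0("state", assignment$labels[ok])
  ))
  props <- NULL
  if (metric_is_z) {
    props <- t(sapply(1:2, function(s) {
      z <- metric[ok][assignment$labels[ok] == s]
      c(alert = mean(z >= z_thresh),
        intermediate = mean(abs(z) < z_thresh),
        drowsy = mean(z <= -z_thresh))
    }))
    rownames(props) <- c("state1", "state2")
  }
  structure(list(
    mean_metric = tapply(metric[ok], assignment$labels[ok], mean),
    fit = fit,
    state_t = fit$t[which(fit$coef_names == "state")],
    state_p = fit$p[which(fit$coef_names == "state")],
    proportions = props
  ), class = "vigi_statesummary")
}
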