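#' @name lme
#' @title Random-intercept linear mixed-effects models for correlation maps
#'
#' @description
#' Group inference on Fisher-z correlation samples uses linear
#' mixed-effects models with a per-subject random intercept separating
#' inter-subject from intra-subject variance, fitted by REML. Because the
#' random structure is a single intercept, the REML criterion can be
#' profiled down to a one-dimensional search over the variance ratio
#' `lambda = var(subject) / var(residual)`; the fitter below exploits
#' that, making per-target map fitting fast and free of convergence
#' failures away from the boundary.
#'
#' Three model shapes are used: an intercept-only model for static maps
#' (`r_ij = mu + delta_i + eps_ij`), a two-state model with a state
#' indicator (alert = 0 reference, drowsy/state-2 = 1) and an
#' epoch-length covariate, and a single-state model with the length
#' covariate centered so the intercept is the group-average correlation at
#' the mean epoch length.
NULL

# core profiled-REML random-intercept fit
# y: response; X: fixed-effects design (with intercept); subject: factor
reml_random_intercept <- function(y, X, subject) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  groups <- split(seq_len(n), subject)
  q <- length(groups)
  Xg <- lapply(groups, function(i) X[i, , drop = FALSE])
  yg <- lapply(groups, function(i) y[i])
  ng <- vapply(groups, length, integer(1))
  sums_x <- lapply(Xg, colSums)
  sums_y <- vapply(yg, sum, numeric(1))
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)

  profile_fit <- function(lambda) {
    cc <- lambda / (1 + lambda * ng)
    A <- XtX
    b <- Xty
    s_yVy <- yty
    for (i in seq_len(q)) {
      A <- A - cc[i] * tcrossprod(sums_x[[i]])
      b <- b - cc[i] * sums_x[[i]] * sums_y[i]
      s_yVy <- s_yVy - cc[i] * sums_y[i]^2
    }
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- backsolve(ch, forwardsolve(t(ch), b))
    rss <- s_yVy - 2 * sum(beta * b) + sum(beta * (A %*% beta))
    rss <- max(rss, 1e-300)
    logdet_v <- sum(log1p(lambda * ng))
    logdet_a <- 2 * sum(log(diag(ch)))
    crit <- logdet_v + logdet_a + (n - p) * log(rss)
    list(crit = crit, beta = beta, A = A, rss = rss, chol = ch)
  }

  obj <- function(loglam) {
    f <- profile_fit(exp(loglam))
    if (is.null(f)) Inf else f$crit
  }
  opt <- stats::optimize(obj, interval = c(-14, 14))
  cand <- list(lambda = exp(opt$minimum), crit = opt$objective)
  f0 <- profile_fit(0)
  converged <- TRUE
  # prefer the lambda = 0 boundary when it is not measurably worse; this
  # also resolves the flat-criterion case (one sample per subject) exactly
  if (is.null(f0)) {
    converged <- FALSE
    fit <- profile_fit(cand$lambda)
  } else if (f0$crit <= cand$crit + 1e-6) {
    cand$lambda <- 0
    fit <- f0
  } else {
    fit <- profile_fit(cand$lambda)
  }
  if (is.null(fit)) {
    return(list(converged = FALSE))
  }
  lambda <- cand$lambda
  sigma2 <- fit$rss / (n - p)
  vcov_beta <- sigma2 * chol2inv(fit$chol)
  se <- sqrt(diag(vcov_beta))
  # containment degrees of freedom; degenerates to N - p when every
  # subject contributes a single sample (classical t-test case)
  df_cont <- n - p - (q - 1)
  if (df_cont < 1) df_cont <- n - p
  se_use <- se
  df_use <- rep(df_cont, p)
  kr <- kr_small_sample(X, subject, ng, sigma2, lambda, vcov_beta)
  if (!is.null(kr)) {
    se_use <- kr$se
    df_use <- kr$df
  }
  tval <- as.numeric(fit$beta) / se_use
  if (fit$rss <= n * 1e-20 * (1 + mean(y^2))) {
    # perfectly fit response: no residual information, t undefined
    se_use <- rep(NaN, p)
    tval <- rep(NaN, p)
  }
  pvals <- rep(NA_real_, p)
  ok <- is.finite(tval) & df_use >= 1
  pvals[ok] <- 2 * stats::pt(-abs(tval[ok]), df_use[ok])
  list(beta = as.numeric(fit$beta), se = se_use, t = tval, df = df_use,
       p = pvals,
       se_plugin = se, df_containment = df_cont,
       sigma2_resid = sigma2, sigma2_subject = lambda * sigma2,
       lambda = lambda, converged = converged, n = n, q = q,
       kr_adjusted = !is.null(kr),
       coef_names = colnames(X))
}

# Kenward-Roger-type small-sample correction for the random-intercept
# model: adjusted fixed-effects covariance plus Satterthwaite degrees of
# freedom per coefficient. Returns NULL (caller falls back to the plug-in
# SE with containment df) when the variance-parameter information matrix
# is singular, e.g. with one sample per subject where residual and
# subject variances are indistinguishable.
kr_small_sample <- function(X, subject, ng, sigma2, lambda, vcov_beta) {
  n <- nrow(X)
  p <- ncol(X)
  groups <- split(seq_len(n), subject)
  # V and its inverse in closed form
  Vi <- diag(n) / sigma2
  ZZt <- matrix(0, n, n)
  for (g in groups) {
    ZZt[g, g] <- 1
    Vi[g, g] <- Vi[g, g] - (lambda / (1 + lambda * length(g))) / sigma2
  }
  d1 <- diag(n)          # dV / d sigma2_resid
  d2 <- ZZt              # dV / d sigma2_subject
  if (!is.finite(sigma2) || sigma2 <= 0) return(NULL)
  Phi <- vcov_beta   # equals (X' V^-1 X)^-1 with V on the full scale
  ViX <- Vi %*% X
  Pmat <- Vi - ViX %*% Phi %*% t(ViX)
  PV1 <- Pmat %*% d1
  PV2 <- Pmat %*% d2
  info <- matrix(c(sum(PV1 * t(PV1)), sum(PV1 * t(PV2)),
                   sum(PV2 * t(PV1)), sum(PV2 * t(PV2))) / 2, 2, 2)
  if (any(!is.finite(info)) || kappa(info) > 1e10) return(NULL)
  W <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(W) || any(!is.finite(W))) return(NULL)
  Pk <- list(t(ViX) %*% d1 %*% ViX, t(ViX) %*% d2 %*% ViX)
  Qf <- function(a, b) t(ViX) %*% a %*% Vi %*% b %*% ViX
  Qk <- list(Qf(d1, d1), Qf(d1, d2), Qf(d2, d1), Qf(d2, d2))
  acc <- matrix(0, p, p)
  idx <- 1
  for (i in 1:2) for (j in 1:2) {
    acc <- acc + W[i, j] * (Qk[[idx]] - Pk[[i]] %*% Phi %*% Pk[[j]])
    idx <- idx + 1
  }
  Phi_A <- Phi + 2 * Phi %*% acc %*% Phi
  se <- sqrt(pmax(diag(Phi_A), 0))
  if (any(se <= 0) || any(!is.finite(se))) return(NULL)
  df <- vapply(seq_len(p), function(k) {
    g1 <- (Phi %*% Pk[[1]] %*% Phi)[k, k]
    g2 <- (Phi %*% Pk[[2]] %*% Phi)[k, k]
    denom <- W[1, 1] * g1^2 + 2 * W[1, 2] * g1 * g2 + W[2, 2] * g2^2
    if (denom <= 0) return(Inf)
    2 * Phi[k, k]^2 / denom
  }, numeric(1))
  df <- pmax(df, 1)
  list(se = se, df = df)
}

as_samples_df <- function(samples) {
  df <- as.data.frame(samples)
  if (!all(c("r", "subject") %in% names(df))) {
    vf_stop("samples need columns `r` (Fisher z) and `subject`",
            "vigifc_parameter_error")
  }
  df
}

#' Intercept-only mixed model: group-average correlation
#'
#' Fits `r_ij = mu + delta_i + eps_ij` by REML. With one sample per
#' subject this reduces exactly to the classical one-sample t-test on the
#' subject values.
#'
#' @param samples data.frame with columns `r` (Fisher-z correlation) and
#'   `subject`.
#' @return a `vigi_lme` fit: fixed effects with SEs, t, df, p, variance
#'   components and a convergence flag.
#' @export
fit_lme_intercept <- function(samples) {
  df <- as_samples_df(samples)
  if (length(unique(df$subject)) < 2) {
    vf_stop("need at least 2 subjects", "vigifc_parameter_error")
  }
  X <- matrix(1, nrow(df), 1, dimnames = list(NULL, "mu"))
  out <- reml_random_intercept(df$r, X, df$subject)
  structure(c(out, list(model = "intercept")), class = "vigi_lme")
}

#' Two-state mixed model: fixed effect of vigilance state
#'
#' Fits `r_ij = a0 + a1 * c_ij + beta * x_ij + delta_i + eps_ij` where
#' `c_ij` is the state indicator referenced to the alert (or state-1)
#' level and `x_ij` the number of volumes per epoch/window, entered
#' untransformed. If the length covariate is constant it is dropped with a
#' warning (collinear with the intercept).
#'
#' @param samples data.frame with columns `r`, `subject`, `state`
#'   (two-level: reference first by factor order, "alert" preferred), and
#'   optionally `x` (volumes per epoch).
#' @return a `vigi_lme` fit; the state effect is coefficient "state".
#' @export
fit_lme_two_state <- function(samples) {
  df <- as_samples_df(samples)
  st <- as.character(df$state)
  lev <- unique(st)
  if (length(lev) != 2) {
    vf_stop("two-state model needs exactly two states in the samples",
            "vigifc_parameter_error")
  }
  ref <- if ("alert" %in% lev) "alert" else sort(lev)[1]
  cij <- as.numeric(st != ref)
  X <- cbind(intercept = 1, state = cij)
  if (!is.null(df$x)) {
    if (stats::sd(df$x) == 0) {
      warning("epoch-length covariate is constant; dropping it")
    } else {
      X <- cbind(X, x = df$x)
    }
  }
  out <- reml_random_intercept(df$r, X, df$subject)
  structure(c(out, list(model = "two_state", reference = ref)),
            class = "vigi_lme")
}

#' Single-state mixed model: group average at mean epoch length
#'
#' Fits `r_ij = mu + beta * (x_ij - mean(x_ij)) + delta_i + eps_ij` on one
#' state's samples; centering makes `mu` the group-average correlation at
#' the mean epoch length.
#'
#' @param samples data.frame with columns `r`, `subject`, and optionally
#'   `x`.
#' @return a `vigi_lme` fit.
#' @export
fit_lme_single_state <- function(samples) {
  df <- as_samples_df(samples)
  if (!is.null(df$state) && length(unique(df$state)) > 1) {
    vf_stop("single-state model requires samples from one state",
            "vigifc_parameter_error")
  }
  X <- matrix(1, nrow(df), 1, dimnames = list(NULL, "mu"))
  if (!is.null(df$x)) {
    xc <- df$x - mean(df$x)
    if (stats::sd(xc) == 0) {
      warning("epoch-length covariate is constant; dropping it")
    } else {
      X <- cbind(X, x = xc)
    }
  }
  out <- reml_random_intercept(df$r, X, df$subject)
  structure(c(out, list(model = "single_state")), class = "vigi_lme")
}

#' Benjamini-Hochberg step-up false-discovery-rate adjustment
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @param q target FDR level used by [fdr_reject()] (default 0.05).
#' @return vector of BH-adjusted p-values (monotone, `>=` raw p).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    vf_stop("p-values must lie in [0, 1]", "vigifc_parameter_error")
  }
  m <- length(p_values)
  ord <- order(p_values, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * p_values[ord]))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' BH rejection set at level q
#' @param p_values raw p-values.
#' @param q FDR level (default 0.05).
#' @return logical rejection vector.
#' @export
fdr_reject <- function(p_values, q = 0.05) {
  fdr_bh(p_values) < q
}

#' Dual-threshold a group t-map into a signed map
#'
#' Survivors are targets that are simultaneously (a) among the top
#' `top_frac` of |t| values within the gray-matter mask (ties at the
#' cutoff are all included) and (b) FDR-significant at level `q` over the
#' same mask. Survivors keep the sign of t; everything else is 0.
#'
#' @param tmap data.frame with columns `t` and `p` (one row per target).
#' @param gm_mask logical vector: targets belonging to gray matter.
#' @param top_frac fraction of top |t| values retained (default 0.4).
#' @param q FDR level (default 0.05).
#' @return a `vigi_signedmap`: list with `sign` (-1/0/+1 per target,
#'   zero outside the mask), `t_surviving`, `mask`, `p_fdr`.
#' @export
threshold_tmap <- function(tmap, gm_mask = rep(TRUE, nrow(tmap)),
                           top_frac = 0.4, q = 0.05) {
  if (!any(gm_mask)) vf_stop("empty GM mask", "vigifc_parameter_error")
  tv <- tmap$t
  keep <- which(gm_mask & is.finite(tv) & is.finite(tmap$p))
  if (length(keep) == 0) vf_stop("no analyzable targets in the mask",
                                 "vigifc_parameter_error")
  p_fdr <- rep(NA_real_, length(tv))
  p_fdr[keep] <- fdr_bh(tmap$p[keep])
  abs_t <- abs(tv[keep])
  k <- ceiling(top_frac * length(keep))
  cutoff <- sort(abs_t, decreasing = TRUE)[k]
  surv <- keep[abs_t >= cutoff & p_fdr[keep] < q]
  sgn <- integer(length(tv))
  sgn[surv] <- sign(tv[surv])
  tsurv <- rep(NA_real_, length(tv))
  tsurv[surv] <- tv[surv]
  structure(list(sign = sgn, t_surviving = tsurv, mask = gm_mask,
                 p_fdr = p_fdr, top_frac = top_frac, q = q),
            class = "vigi_signedmap")
}
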