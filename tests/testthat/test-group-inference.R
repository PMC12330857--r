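sim_ri_data <- function(n_subj, per_subj, mu = 0.3, sd_subj = 0.1,
                        sd_eps = 0.15) {
  subj <- rep(seq_len(n_subj), each = per_subj)
  data.frame(
    r = mu + rnorm(n_subj, 0, sd_subj)[subj] + rnorm(length(subj), 0, sd_eps),
    subject = subj)
}

test_that("intercept model: degenerate, balanced, and lme4-checked fits", {
  # identical responses: mean recovered, both variance components zero
  f0 <- fit_lme_intercept(data.frame(r = rep(0.3, 8),
                                     subject = rep(1:4, 2)))
  expect_equal(f0$beta, 0.3)
  expect_equal(f0$sigma2_resid, 0, tolerance = 1e-12)
  expect_equal(f0$sigma2_subject, 0, tolerance = 1e-12)

  # balanced design: estimate is the grand mean
  set.seed(81)
  d <- sim_ri_data(10, 2)
  f1 <- fit_lme_intercept(d)
  expect_equal(f1$beta, mean(d$r), tolerance = 1e-8)

  # dual route: profiled REML agrees with lme4 on unbalanced data
  set.seed(82)
  for (i in 1:5) {
    ns <- sample(1:4, 12, replace = TRUE)
    subj <- rep(seq_len(12), ns)
    d2 <- data.frame(r = 0.2 + rnorm(12, 0, 0.1)[subj] +
                       rnorm(length(subj), 0, 0.15),
                     subject = subj)
    ours <- fit_lme_intercept(d2)
    ref <- lme4::lmer(r ~ 1 + (1 | subject), data = d2, REML = TRUE)
    expect_equal(ours$beta, unname(lme4::fixef(ref)), tolerance = 1e-6)
    expect_equal(ours$se_plugin, sqrt(diag(as.matrix(vcov(ref))))[[1]],
                 tolerance = 1e-5)
    # the small-sample adjustment can only widen the plug-in SE
    expect_gte(ours$se + 1e-12, ours$se_plugin)
    vc <- as.data.frame(lme4::VarCorr(ref))$vcov
    expect_equal(ours$sigma2_subject, vc[1], tolerance = 1e-4)
    expect_equal(ours$sigma2_resid, vc[2], tolerance = 1e-4)
  }

  expect_error(fit_lme_intercept(data.frame(r = 1:3, subject = 1)),
               class = "vigifc_parameter_error")
})

test_that("one sample per subject degenerates to the classical t-test", {
  set.seed(83)
  for (i in 1:20) {
    y <- rnorm(24, 0.1, 0.2)
    fit <- fit_lme_intercept(data.frame(r = y, subject = seq_along(y)))
    tt <- t.test(y)
    expect_equal(fit$t, unname(tt$statistic), tolerance = 1e-8)
    expect_equal(fit$df, unname(tt$parameter))
    expect_equal(fit$p, tt$p.value, tolerance = 1e-8)
  }
})

test_that("two-state model recovers a planted state effect", {
  set.seed(84)
  gen2 <- function(a1) {
    subj <- rep(1:24, each = 2)
    st <- rep(c("alert", "drowsy"), 24)
    x <- rnorm(48, 150, 40)
    data.frame(r = 0.25 + a1 * (st == "drowsy") + 0.0005 * x +
                 rnorm(24, 0, 0.1)[subj] + rnorm(48, 0, 0.15),
               subject = subj, state = st, x = x)
  }
  est <- replicate(60, {
    f <- fit_lme_two_state(gen2(0.2))
    f$beta[f$coef_names == "state"]
  })
  expect_lt(abs(mean(est) - 0.2), 3 * sd(est) / sqrt(length(est)))

  # lme4 dual route on one draw
  d <- gen2(0.2)
  ours <- fit_lme_two_state(d)
  ref <- lme4::lmer(r ~ state + x + (1 | subject),
                    data = transform(d, state = factor(state,
                                                       c("alert", "drowsy"))),
                    REML = TRUE)
  expect_equal(ours$beta, unname(lme4::fixef(ref)), tolerance = 1e-6)

  # constant length covariate dropped with a warning
  d$x <- 100
  expect_warning(fc <- fit_lme_two_state(d), "constant")
  expect_false("x" %in% fc$coef_names)

  expect_error(fit_lme_two_state(data.frame(r = 1:4, subject = 1:4,
                                            state = "alert")),
               class = "vigifc_parameter_error")
})

test_that("single-state model centers its covariate and nests correctly", {
  set.seed(85)
  subj <- rep(1:10, each = 3)
  d <- data.frame(r = 0.3 + rnorm(10, 0, 0.1)[subj] + rnorm(30, 0, 0.15),
                  subject = subj, x = rnorm(30, 150, 40))
  fs <- fit_lme_single_state(d)
  fi <- fit_lme_intercept(d[c("r", "subject")])
  expect_equal(fs$beta[1], fi$beta[1], tolerance = 1e-6)

  # planted length effect recovered (fresh data each replicate)
  slope <- replicate(60, {
    subj2 <- rep(1:10, each = 3)
    x2 <- rnorm(30, 150, 40)
    d2 <- data.frame(r = 0.3 + 0.002 * x2 + rnorm(10, 0, 0.1)[subj2] +
                       rnorm(30, 0, 0.15),
                     subject = subj2, x = x2)
    f <- fit_lme_single_state(d2)
    f$beta[f$coef_names == "x"]
  })
  expect_lt(abs(mean(slope) - 0.002), 3 * sd(slope) / sqrt(length(slope)))

  expect_error(
    fit_lme_single_state(data.frame(r = 1:4, subject = c(1, 1, 2, 2),
                                    state = c("a", "a", "b", "b"))),
    class = "vigifc_parameter_error")
})

test_that("BH adjustment matches p.adjust and handles edge cases", {
  expect_true(all(fdr_reject(rep(0.001, 100))))
  expect_equal(fdr_bh(0.04), 0.04)
  expect_true(fdr_reject(0.04))
  set.seed(86)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(fdr_bh(p), p.adjust(p, "BH"))
  }
  p <- runif(50)
  expect_true(all(fdr_bh(p) >= p))
  expect_error(fdr_bh(c(0.5, 1.2)), class = "vigifc_parameter_error")
})

test_that("dual thresholding: brute-force set oracle and monotonicity", {
  set.seed(87)
  for (i in 1:50) {
    m <- sample(8:40, 1)
    tmap <- data.frame(t = rnorm(m, 0, 3), p = runif(m)^2)
    sm <- threshold_tmap(tmap, top_frac = 0.4, q = 0.05)
    # oracle: independent reconstruction of the survivor set
    k <- ceiling(0.4 * m)
    cut <- sort(abs(tmap$t), decreasing = TRUE)[k]
    fdr_ok <- p.adjust(tmap$p, "BH") < 0.05
    surv_oracle <- which(abs(tmap$t) >= cut & fdr_ok)
    expect_identical(which(sm$sign != 0), surv_oracle)
    expect_equal(sm$sign[surv_oracle], sign(tmap$t)[surv_oracle])
    # monotonicity in top_frac
    sm3 <- threshold_tmap(tmap, top_frac = 0.3, q = 0.05)
    expect_true(all(which(sm3$sign != 0) %in% which(sm$sign != 0)))
  }
  # no FDR survivors: empty map
  tm <- data.frame(t = rnorm(20), p = runif(20, 0.5, 1))
  expect_true(all(threshold_tmap(tm)$sign == 0))
  # everything significant and top_frac = 1: all survive with sign(t)
  tm2 <- data.frame(t = c(-3, 2, 5, -1), p = rep(1e-6, 4))
  sm2 <- threshold_tmap(tm2, top_frac = 1)
  expect_equal(sm2$sign, c(-1, 1, 1, -1))
  expect_error(threshold_tmap(tm2, gm_mask = rep(FALSE, 4)),
               class = "vigifc_parameter_error")
})
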