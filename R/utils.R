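# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a classed condition
#'
#' All user-facing validation failures in the package raise conditions with a
#' package-specific class so callers (and tests) can distinguish parameter
#' errors from unusable-data errors.
#'
#' @param msg message string.
#' @param class condition subclass, e.g. "vigifc_parameter_error".
#' @noRd
vf_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "vigifc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok) {
    vf_stop(sprintf("`%s` must be a finite number in %s%s, %s%s (got: %s)",
                    name,
                    if (strict_lower) "(" else "[", format(lower),
                    format(upper), if (strict_upper) ")" else "]",
                    paste(format(x), collapse = ", ")),
            "vigifc_parameter_error")
  }
  invisible(x)
}

#' Logit with small-sample clamp
#'
#' @param p proportion in \[0, 1\].
#' @param eps clamp width; `p` is clipped to `[eps, 1 - eps]` before the
#'   transform. The standard continuity choice is `1 / (2 n)` for a
#'   proportion estimated from `n` samples.
#' @return `log(p / (1 - p))` after clamping.
#' @keywords internal
clamped_logit <- function(p, eps) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' Fisher r-to-z transform with clipping
#'
#' Correlations are clipped to `|r| <= 1 - 1e-7` so the transform stays
#' finite for degenerate (perfectly correlated) inputs.
#'
#' @param r correlation value(s).
#' @return `atanh` of the clipped correlations.
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}

#' Adjusted Rand index between two labelings
#'
#' Used to score cluster-versus-ground-truth agreement; invariant to label
#' permutation.
#'
#' @param a,b integer/character label vectors of equal length.
#' @return adjusted Rand index (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) {
    vf_stop("labelings must have equal length", "vigifc_parameter_error")
  }
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# derive a bounded child seed from a base seed and a small index
# (arithmetic in double precision: products stay far below 2^53)
child_seed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 2147483587) * 97 +
                as.numeric(i) * 1009) %% 2147483587)
}
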