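#' Signed Szymkiewicz-Simpson overlap of a signed map with a template
#'
#' `sum_i sgn(t_i) * m_i / sum_i m_i`, where `sgn` of a thresholded-out
#' target is 0 and `m_i` is the binary template inclusion. +1 means the
#' template is fully covered by positive survivors, -1 fully by negative
#' ones.
#'
#' @param signed_map a `vigi_signedmap` (or a -1/0/+1 vector).
#' @param template logical/binary inclusion vector on the same target
#'   index (at least one included target).
#' @param name template name carried into the result.
#' @return list with `coefficient` in `[-1, 1]` and `template`.
#' @export
signed_overlap <- function(signed_map, template, name = NA_character_) {
  sgn <- map_sign_vector(signed_map)
  m <- as.numeric(as.logical(template))
  if (length(m) != length(sgn)) {
    vf_stop("map and template must share the target index",
            "vigifc_parameter_error")
  }
  if (sum(m) == 0) vf_stop("empty template", "vigifc_parameter_error")
  list(coefficient = sum(sgn * m) / sum(m), template = name)
}

map_sign_vector <- function(x) {
  if (inherits(x, "vigi_signedmap")) x$sign else as.integer(sign(x))
}

#' Multiclass Dice similarity between two signed maps
#'
#' Generalizes the Dice coefficient to signed maps by treating positive
#' and negative survivors as two classes (background zeros are excluded):
#' `DSC = 2 (|A+ ∩ B+| + |A- ∩ B-|) / (|A+| + |A-| + |B+| + |B-|)`.
#' Reduces to ordinary Dice when both maps are sign-uniform. Two empty
#' maps give 0 with a warning.
#'
#' @param map_a,map_b `vigi_signedmap` objects or -1/0/+1 vectors on a
#'   common target index.
#' @return a `vigi_dsc` result: list with `dsc` in `[0, 1]` and `band`.
#' @export
multiclass_dsc <- function(map_a, map_b) {
  a <- map_sign_vector(map_a)
  b <- map_sign_vector(map_b)
  if (length(a) != length(b)) {
    vf_stop("maps must share the target index", "vigifc_parameter_error")
  }
  denom <- sum(a != 0) + sum(b != 0)
  if (denom == 0) {
    warning("both maps empty; DSC defined as 0")
    dsc <- 0
  } else {
    agree <- sum(a == 1 & b == 1) + sum(a == -1 & b == -1)
    dsc <- 2 * agree / denom
  }
  structure(list(dsc = dsc, band = reproducibility_band(dsc)),
            class = "vigi_dsc")
}

#' Qualitative reproducibility band for a Dice coefficient
#'
#' Standard fMRI convention: poor below 0.4, moderate in `[0.4, 0.6)`,
#' good at 0.6 and above.
#'
#' @param dsc Dice coefficient in `[0, 1]`.
#' @return "poor", "moderate", or "good".
#' @export
reproducibility_band <- function(dsc) {
  assert_scalar_number(dsc, "dsc", 0, 1)
  if (dsc < 0.4) "poor" else if (dsc < 0.6) "moderate" else "good"
}
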