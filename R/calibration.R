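# FNR calibration: empirical-CDF transform of raw scores.
#
# Raw network scores depend strongly on hyperparameters (notably the
# absence ratio), so maps are reported as false negative rates: the
# fraction of known presence examples whose score falls strictly below the
# score in question. An FNR of s means the location outranks a fraction s
# of the date-locations where the species was actually recorded -- a "risk
# percentile". Ties count as detected (strictly-below counting), the
# conservative direction. The empirical CDF is used as a step function; no
# smoothing.

#' Build a calibration reference from presence scores
#'
#' The reference population is, by default, the training-split presences
#' (the examples the FNR semantics are defined on).
#'
#' @param scores Raw model scores of presence examples, in `(0, 1)`,
#'   length >= 2.
#' @return A `calibration_reference`: sorted scores plus their count.
#' @export
calibration_reference <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) < 2) stop("calibration reference needs at least 2 scores")
  if (anyNA(scores) || any(scores <= 0) || any(scores >= 1))
    stop("reference scores must lie strictly inside (0, 1)")
  structure(list(scores = sort(scores), n_ref = length(scores)),
            class = "calibration_reference")
}

#' Transform raw scores to false negative rates
#'
#' `FNR(s) = #{reference scores < s} / N_ref`: the fraction of known
#' presences that would be missed were `s` used as the detection threshold.
#' Monotone non-decreasing in `s`; `NA` propagates.
#'
#' @param score Numeric score(s).
#' @param ref A [calibration_reference()].
#' @return FNR value(s) in `[0, 1]`.
#' @examples
#' ref <- calibration_reference(c(0.2, 0.5, 0.8))
#' fnr_transform(c(0.1, 0.5, 0.9), ref)  # 0, 1/3, 1
#' @export
fnr_transform <- function(score, ref) {
  stopifnot(inherits(ref, "calibration_reference"))
  out <- rep(NA_real_, length(score))
  ok <- !is.na(score)
  out[ok] <- findInterval(score[ok], ref$scores, left.open = TRUE) / ref$n_ref
  out
}

#' Calibrate a raw-score map or stack to FNR
#'
#' Elementwise [fnr_transform()]; missing cells propagate. Accepts a
#' matrix (one day) or a 3-d array (a stack).
#'
#' @param raw Raw-score matrix or array.
#' @param ref A [calibration_reference()].
#' @return Object of the same shape with FNR values.
#' @export
calibrate_map <- function(raw, ref) {
  out <- fnr_transform(as.vector(raw), ref)
  dim(out) <- dim(raw)
  out
}

#' Predict a calibrated FNR stack
#'
#' Convenience wrapper: raw-score prediction via [predict_stack()] followed
#' by [calibrate_map()] with the model's own calibration reference.
#'
#' @param model A `trained_model`.
#' @param derived A `derived_cube`.
#' @param dates `Date` vector.
#' @return A [risk_map_stack()].
#' @export
predict_fnr_stack <- function(model, derived, dates) {
  raw <- predict_stack(model, derived, dates)
  risk_map_stack(derived$grid, dates, calibrate_map(raw, model$calibration))
}

#' Kolmogorov-Smirnov uniformity check of held-out presence FNRs
#'
#' If held-out presences are exchangeable with the reference presences,
#' their FNR values are approximately Uniform(0, 1); this is the sanity
#' check behind the "risk percentile" reading of the calibrated maps.
#'
#' @param fnrs FNR values of held-out presence examples.
#' @return List with `statistic` (KS D) and `p_value` (one-sample test
#'   against Uniform(0, 1)).
#' @export
uniformity_check <- function(fnrs) {
  fnrs <- fnrs[!is.na(fnrs)]
  kt <- suppressWarnings(stats::ks.test(fnrs, "punif"))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n = length(fnrs))
}
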