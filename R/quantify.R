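#' Standardized uptake value (SUV) normalisation
#'
#' `SUV = concentration / (injected dose / body weight)`, with
#' concentration in kBq/cm^3, dose in kBq and weight in g; taking 1 cm^3
#' of brain as 1 g makes the SUV unitless. Applied elementwise, so it is
#' linear in the concentration and halves when the dose doubles.
#'
#' @param x numeric vector/array of concentrations, a
#'   [TimeActivityCurve-class], or a [DynamicStudy-class].
#' @param dose injected dose in kBq (> 0); defaults to the subject's for
#'   curve/study methods.
#' @param weight body weight in g (> 0).
#' @return Same shape as the input: numeric for numeric input, a
#'   SUV-unit [TimeActivityCurve-class] for a curve, a 4D SUV array for a
#'   study.
#' @examples
#' suvTransform(2.0, dose = 400, weight = 200)  # 1.0
#' @export
setGeneric("suvTransform", function(x, dose, weight) {
  standardGeneric("suvTransform")
})

checkDoseWeight <- function(dose, weight) {
  if (!is.finite(dose) || dose <= 0)
    petStop("dose", "injected dose must be > 0 kBq")
  if (!is.finite(weight) || weight <= 0)
    petStop("dose", "body weight must be > 0 g")
}

#' @rdname suvTransform
setMethod("suvTransform", "numeric", function(x, dose, weight) {
  checkDoseWeight(dose, weight)
  x / (dose / weight)
})

#' @rdname suvTransform
setMethod("suvTransform", "array", function(x, dose, weight) {
  checkDoseWeight(dose, weight)
  x / (dose / weight)
})

#' @rdname suvTransform
setMethod("suvTransform", "TimeActivityCurve", function(x, dose, weight) {
  if (missing(dose) || missing(weight))
    petStop("dose", "dose and weight are required to convert a curve to SUV")
  if (x@unit == "SUV")
    petStop("units", "curve is already in SUV units")
  checkDoseWeight(dose, weight)
  new("TimeActivityCurve", midTimes = x@midTimes,
      values = x@values / (dose / weight), unit = "SUV",
      region = x@region, subjectId = x@subjectId)
})

#' @rdname suvTransform
setMethod("suvTransform", "DynamicStudy", function(x, dose, weight) {
  if (missing(dose)) dose <- x@subject@injectedDose
  if (missing(weight)) weight <- x@subject@bodyWeight
  checkDoseWeight(dose, weight)
  x@voxels / (dose / weight)
})

#' Extract a regional time-activity curve
#'
#' Per-frame unweighted mean over the voxels of a named region, with frame
#' mid-times converted to minutes.
#'
#' @param study a [DynamicStudy-class].
#' @param labels a [LabelVolume-class] on the same grid.
#' @param region region name (must exist in the label map and be
#'   non-empty).
#' @return A [TimeActivityCurve-class] in kBq/cm^3.
#' @export
extractTac <- function(study, labels, region) {
  stopifnot(is(study, "DynamicStudy"), is(labels, "LabelVolume"))
  idx <- regionVoxels(labels, region)
  nf <- nFrames(study@schedule)
  flat <- matrix(study@voxels, ncol = nf)
  new("TimeActivityCurve",
      midTimes = frameMidTimes(study@schedule, "min"),
      values = colMeans(flat[idx, , drop = FALSE]),
      unit = "kBq/cm3", region = region,
      subjectId = study@subject@subjectId)
}

regionVoxels <- function(labels, region) {
  if (!region %in% names(labels@regionNames))
    petStop("region", "region '%s' not present in the label map", region)
  idx <- which(labels@labels == labels@regionNames[[region]])
  if (!length(idx))
    petStop("region", "region '%s' contains no voxels", region)
  idx
}

#' Late-window static average image
#'
#' Duration-weighted mean of the frames whose mid-time lies inside the
#' window (default 25.5 to 60 min, the standard late uptake window used
#' for static SUV comparison). Frames are selected by mid-time membership,
#' which is unambiguous for frames straddling a window edge.
#'
#' @param study a [DynamicStudy-class].
#' @param window numeric(2), minutes.
#' @return 3D numeric array (same units as the study).
#' @export
staticAverage <- function(study, window = c(25.5, 60)) {
  stopifnot(is(study, "DynamicStudy"))
  mids <- frameMidTimes(study@schedule, "min")
  sel <- which(mids >= window[1] & mids <= window[2])
  if (!length(sel))
    petStop("window", "no frame mid-time falls inside [%g, %g] min",
            window[1], window[2])
  w <- frameDurations(study@schedule)[sel]
  out <- array(0, dim(study@voxels)[1:3])
  for (j in seq_along(sel))
    out <- out + w[j] * study@voxels[, , , sel[j]]
  out / sum(w)
}

#' Area under a time-activity curve (SUV·min)
#'
#' Trapezoidal rule over the curve's frame mid-times restricted to the
#' interval, with the curve anchored at (0, 0) when the first sample lies
#' after time zero (the tracer concentration is zero at injection).
#' Interval edges falling between samples are linearly interpolated; an
#' upper edge beyond the last sample truncates the integral at the last
#' sample rather than extrapolating.
#'
#' @param tac a SUV-unit [TimeActivityCurve-class].
#' @param interval numeric(2), minutes (default `c(0, 60)`).
#' @return An [AUCValue-class] in SUV·min.
#' @export
tacAuc <- function(tac, interval = c(0, 60)) {
  stopifnot(is(tac, "TimeActivityCurve"))
  validObject(tac)
  if (tac@unit != "SUV")
    petStop("units", "AUC is defined on SUV curves; convert with suvTransform()")
  t <- tac@midTimes; v <- tac@values
  if (t[1] > 0) { t <- c(0, t); v <- c(0, v) }
  if (interval[1] < t[1] - 1e-9 || interval[1] >= t[length(t)])
    petStop("window", "interval start %g min outside curve support",
            interval[1])
  t1 <- min(interval[2], t[length(t)])
  f <- stats::approxfun(t, v)
  keep <- t > interval[1] & t < t1
  tt <- c(interval[1], t[keep], t1)
  vv <- c(f(interval[1]), v[keep], f(t1))
  auc <- sum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2)
  new("AUCValue", value = auc, interval = as.numeric(interval),
      region = tac@region, subjectId = tac@subjectId)
}

#' Target-to-reference AUC ratio
#'
#' Ratio of a target region's AUC to a (pseudo-)reference region's AUC for
#' the same subject over the same interval — the pons-to-striatum ratio in
#' the default pipeline, with the striatum acting as a pseudo-reference
#' region with negligible specific binding.
#'
#' @param target,reference [AUCValue-class] objects from the same subject
#'   and interval; the reference AUC must be positive.
#' @return Unitless ratio (target / reference).
#' @export
aucRatio <- function(target, reference) {
  stopifnot(is(target, "AUCValue"), is(reference, "AUCValue"))
  if (!identical(target@subjectId, reference@subjectId))
    petStop("ratio", "AUC ratio requires the same subject")
  if (any(abs(target@interval - reference@interval) > 1e-9))
    petStop("ratio", "AUC ratio requires the same interval")
  if (reference@value <= 0)
    petStop("ratio", "reference AUC must be positive")
  target@value / reference@value
}

setMethod("show", "TimeActivityCurve", function(object) {
  cat(sprintf("TimeActivityCurve [%s] %s/%s: %d frames, %.2f-%.2f min, peak %.3g\n",
              object@unit, object@subjectId, object@region,
              length(object@midTimes),
              min(object@midTimes), max(object@midTimes),
              max(object@values)))
})

setMethod("show", "AUCValue", function(object) {
  cat(sprintf("AUC %s/%s [%g, %g] min: %.4g SUV.min\n", object@subjectId,
              object@region, object@interval[1], object@interval[2],
              object@value))
})
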