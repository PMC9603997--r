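#' Image-derived input function (IDIF)
#'
#' Per-frame unweighted mean over the blood-pool VOI (the abstract left
#' cardiac ventricle in the phantom) across the full scan; negative frame
#' means (possible under noise) are clipped to zero. Used directly as the
#' whole-blood input of the Logan analysis — no plasma-parent or
#' metabolite correction is applied, a documented bias source of
#' whole-blood graphical methods.
#'
#' @param study a [DynamicStudy-class].
#' @param labels a [LabelVolume-class].
#' @param bloodRegion name of the blood-pool region (default
#'   `"blood_pool"`).
#' @return An [InputFunction-class] with provenance `"image-derived"`.
#' @export
extractIdif <- function(study, labels, bloodRegion = "blood_pool") {
  tac <- extractTac(study, labels, bloodRegion)
  new("InputFunction", midTimes = tac@midTimes,
      values = pmax(tac@values, 0), provenance = "image-derived")
}

#' Tissue-to-blood concentration ratio curve
#'
#' Elementwise `C_T / C_b` on a common frame grid, with frames where the
#' blood concentration is zero masked as `NA` rather than infinite. For a
#' reversible tracer the ratio approaches V_T, so its stabilisation is
#' the practical diagnostic for choosing the Logan equilibration time t*.
#'
#' @param tac a [TimeActivityCurve-class].
#' @param idif an [InputFunction-class] on the same mid-times.
#' @return data.frame with `mid_time_min` and `ratio` (NA where
#'   `C_b = 0`).
#' @export
tissueToBloodRatio <- function(tac, idif) {
  stopifnot(is(tac, "TimeActivityCurve"), is(idif, "InputFunction"))
  if (length(tac@midTimes) != length(idif@midTimes) ||
      any(abs(tac@midTimes - idif@midTimes) > 1e-9))
    petStop("grid", "tissue curve and input function must share mid-times")
  ratio <- ifelse(idif@values > 0, tac@values / idif@values, NA_real_)
  data.frame(mid_time_min = tac@midTimes, ratio = ratio)
}

# Running integrals at frame mid-times: trapezoid with a (0, 0) anchor.
# Returns the integral evaluated at each mid-time.
runningIntegral <- function(mid, v) {
  cumTrapz(c(0, mid), c(0, v))[-1]
}

#' Logan graphical analysis of a regional TAC
#'
#' Computes the running integrals of the tissue and whole-blood curves at
#' each frame mid-time T (trapezoid, anchored at the origin) and fits, by
#' ordinary least squares restricted to `T >= tStar`,
#' `int(C_T)/C_T(T) = V_T * int(C_b)/C_T(T) + b`. For a reversible tracer
#' the plot is asymptotically linear and the slope is the total volume of
#' distribution V_T (mL/cm^3).
#'
#' @param tac a kBq/cm^3 [TimeActivityCurve-class].
#' @param idif an [InputFunction-class] on the same mid-times.
#' @param tStar equilibration time in minutes (default 22.5); frames are
#'   included when their mid-time is >= `tStar`.
#' @return A [LoganResult-class].
#' @examples
#' sim <- simulateStudy(defaultPhantomSpec(), defaultFrameSchedule(),
#'                      16900, 100, seed = 1)
#' idif <- extractIdif(sim@study, sim@labels)
#' loganFit(extractTac(sim@study, sim@labels, "pons"), idif)
#' @export
loganFit <- function(tac, idif, tStar = 22.5) {
  stopifnot(is(tac, "TimeActivityCurve"), is(idif, "InputFunction"))
  if (tac@unit != "kBq/cm3")
    petStop("units", "Logan analysis expects a kBq/cm3 tissue curve")
  if (length(tac@midTimes) != length(idif@midTimes) ||
      any(abs(tac@midTimes - idif@midTimes) > 1e-9))
    petStop("grid", "tissue curve and input function must share mid-times")
  mid <- tac@midTimes
  sel <- which(mid >= tStar - 1e-9)
  if (length(sel) < 2L)
    petStop("logan_points",
            "need >= 2 frame mid-times at or after t* = %g min (have %d)",
            tStar, length(sel))
  if (any(tac@values[sel] <= 0))
    petStop("logan_nonpositive",
            "%d non-positive tissue value(s) after t*; Logan coordinates undefined",
            sum(tac@values[sel] <= 0))
  intT <- runningIntegral(mid, tac@values)
  intB <- runningIntegral(mid, idif@values)
  x <- intB[sel] / tac@values[sel]
  y <- intT[sel] / tac@values[sel]
  ols <- olsLine(x, y)
  new("LoganResult", vt = ols$slope, intercept = ols$intercept,
      nPoints = length(sel), rSquared = ols$r2, tStar = as.numeric(tStar),
      region = tac@region, subjectId = tac@subjectId)
}

olsLine <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0)
    petStop("logan_degenerate", "Logan abscissa is constant; no slope defined")
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  ssres <- sum((y - (intercept + slope * x))^2)
  sstot <- sum((y - my)^2)
  r2 <- if (sstot <= .Machine$double.eps * max(1, my^2)) 1 else 1 - ssres / sstot
  list(slope = slope, intercept = intercept, r2 = min(max(r2, 0), 1))
}

#' Voxel-wise Logan analysis producing a V_T parametric map
#'
#' Applies the Logan fit of [loganFit()] independently to every voxel
#' inside an analysis mask, sharing the precomputed blood running
#' integral. The default mask keeps voxels whose late-window mean exceeds
#' a configurable fraction of the mean over brain voxels (all labelled
#' non-blood voxels when a label map is given, positive voxels
#' otherwise). Voxels with any non-positive tissue value after t* are
#' dropped from the fit and counted in `nDropped`; out-of-mask voxels are
#' 0 and excluded from any region summary.
#'
#' @param study a [DynamicStudy-class] (kBq/cm^3).
#' @param idif an [InputFunction-class] on the study's mid-times.
#' @param tStar minutes (default 22.5).
#' @param labels optional [LabelVolume-class] used to define the brain
#'   reference mean and region summaries.
#' @param maskFraction mask threshold as a fraction of the brain
#'   late-window mean (default 0.2).
#' @param window late window (minutes) for the masking image (default
#'   `c(25.5, 60)`).
#' @param bloodRegion blood-pool region name excluded from the brain mean.
#' @return A [ParametricMap-class].
#' @export
loganParametricMap <- function(study, idif, tStar = 22.5, labels = NULL,
                               maskFraction = 0.2, window = c(25.5, 60),
                               bloodRegion = "blood_pool") {
  stopifnot(is(study, "DynamicStudy"), is(idif, "InputFunction"))
  mids <- frameMidTimes(study@schedule, "min")
  if (length(mids) != length(idif@midTimes) ||
      any(abs(mids - idif@midTimes) > 1e-9))
    petStop("grid", "input function must be sampled on the study's mid-times")
  late <- staticAverage(study, window)
  if (!is.null(labels)) {
    stopifnot(is(labels, "LabelVolume"))
    brain <- labels@labels != 0L
    if (bloodRegion %in% names(labels@regionNames))
      brain <- brain & labels@labels != labels@regionNames[[bloodRegion]]
    brainMean <- mean(late[brain])
  } else {
    brainMean <- mean(late[late > 0])
  }
  if (!is.finite(brainMean) || brainMean <= 0)
    petStop("mask", "cannot define mask: brain late-window mean is not positive")
  mask <- late > maskFraction * brainMean
  if (!any(mask)) petStop("mask", "analysis mask is empty")

  nf <- length(mids)
  flat <- matrix(study@voxels, ncol = nf)
  V <- flat[mask, , drop = FALSE]
  sel <- which(mids >= tStar - 1e-9)
  if (length(sel) < 2L)
    petStop("logan_points", "need >= 2 frames at or after t* = %g min", tStar)

  usable <- rowSums(V[, sel, drop = FALSE] <= 0) == 0L
  nDropped <- sum(!usable)

  intB <- runningIntegral(mids, idif@values)
  # anchored cumulative trapezoid of every voxel TAC, frame loop only
  tt <- c(0, mids)
  intT <- matrix(0, nrow(V), nf)
  prevV <- 0
  acc <- 0
  for (k in seq_len(nf)) {
    acc <- acc + (tt[k + 1] - tt[k]) * (prevV + V[, k]) / 2
    intT[, k] <- acc
    prevV <- V[, k]
  }

  vt <- rep(0, nrow(V))
  if (any(usable)) {
    Vu <- V[usable, sel, drop = FALSE]
    X <- matrix(intB[sel], nrow = sum(usable), ncol = length(sel),
                byrow = TRUE) / Vu
    Y <- intT[usable, sel, drop = FALSE] / Vu
    mx <- rowMeans(X); my <- rowMeans(Y)
    sxx <- rowSums((X - mx)^2)
    sxy <- rowSums((X - mx) * (Y - my))
    vt[usable] <- sxy / sxx
  }

  values <- array(0, dim(study@voxels)[1:3])
  maskKept <- mask
  maskKept[mask] <- usable
  values[maskKept] <- vt[usable]
  new("ParametricMap", values = values, mask = maskKept,
      tStar = as.numeric(tStar), grid = study@grid,
      nDropped = as.integer(nDropped))
}

#' Summarise a parametric map over labelled regions
#'
#' Median (and mean) V_T over the in-mask voxels of each region.
#'
#' @param map a [ParametricMap-class].
#' @param labels a [LabelVolume-class] on the same grid.
#' @param regions region names (default: all named regions).
#' @return data.frame: region, n_voxels, median_VT, mean_VT.
#' @export
summarizeParametricMap <- function(map, labels,
                                   regions = names(labels@regionNames)) {
  stopifnot(is(map, "ParametricMap"), is(labels, "LabelVolume"))
  do.call(rbind, lapply(regions, function(rn) {
    idx <- which(labels@labels == labels@regionNames[[rn]] & map@mask)
    data.frame(region = rn, n_voxels = length(idx),
               median_VT = if (length(idx)) stats::median(map@values[idx])
                           else NA_real_,
               mean_VT = if (length(idx)) mean(map@values[idx]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

setMethod("show", "LoganResult", function(object) {
  cat(sprintf(
    "LoganResult %s/%s: V_T = %.4f mL/cm3 (intercept %.3f min, n = %d, R2 = %.4f, t* = %g min)\n",
    object@subjectId, object@region, object@vt, object@intercept,
    object@nPoints, object@rSquared, object@tStar))
})

setMethod("show", "ParametricMap", function(object) {
  cat(sprintf(
    "ParametricMap: %s, %d voxels in mask (%d dropped), t* = %g min, median V_T = %.4f\n",
    paste(dim(object@values), collapse = " x "), sum(object@mask),
    object@nDropped, object@tStar, stats::median(object@values[object@mask])))
})
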