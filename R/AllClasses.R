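#' @import methods
NULL

## ---------------------------------------------------------------------------
## Acquisition geometry and timing
## ---------------------------------------------------------------------------

#' Voxel grid specification
#'
#' Describes the sampling grid of an image volume: array shape, voxel
#' spacing in mm, and the world-space (mm) position of the centre of voxel
#' (1,1,1). World coordinates follow the RAS+ convention; voxel indices are
#' 1-based inside R and only converted at I/O boundaries.
#'
#' @slot shape integer(3), voxels per axis.
#' @slot spacing numeric(3), mm per voxel along each axis, all > 0.
#' @slot origin numeric(3), mm offset of the first voxel centre.
#' @exportClass GridSpec
setClass("GridSpec",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"),
  prototype(shape = c(1L, 1L, 1L), spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be three integers >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive numbers (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite numbers (mm)")
  if (length(msg)) msg else TRUE
})

#' Dynamic acquisition frame schedule
#'
#' Start times and durations, in seconds, of the frames of a dynamic PET
#' acquisition. Frames must be contiguous: each frame starts exactly where
#' the previous one ends, and the first frame starts at 0 s.
#'
#' @slot starts numeric, frame start times in seconds, ascending, first 0.
#' @slot durations numeric, frame durations in seconds, all > 0.
#' @seealso [FrameSchedule()], [defaultFrameSchedule()]
#' @exportClass FrameSchedule
setClass("FrameSchedule",
  representation(starts = "numeric", durations = "numeric")
)

setValidity("FrameSchedule", function(object) {
  s <- object@starts; d <- object@durations
  msg <- character()
  if (length(s) == 0L || length(s) != length(d))
    msg <- c(msg, "starts and durations must be non-empty and equal length")
  else {
    if (any(!is.finite(s)) || any(!is.finite(d)))
      msg <- c(msg, "frame times must be finite")
    if (isTRUE(s[1] != 0)) msg <- c(msg, "first frame must start at 0 s")
    if (any(d <= 0)) msg <- c(msg, "all frame durations must be > 0")
    if (length(s) > 1L &&
        any(abs(s[-1] - (s[-length(s)] + d[-length(d)])) > 1e-9))
      msg <- c(msg, "frames must be contiguous (starts[i+1] = starts[i] + durations[i])")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Subject metadata, study and label containers
## ---------------------------------------------------------------------------

#' Subject metadata
#'
#' @slot subjectId character scalar.
#' @slot group character scalar, one of `"DIPG"` or `"sham"`.
#' @slot injectedDose numeric scalar, injected activity in kBq, > 0.
#' @slot bodyWeight numeric scalar, body weight in g, > 0.
#' @exportClass SubjectMeta
setClass("SubjectMeta",
  representation(subjectId = "character", group = "character",
                 injectedDose = "numeric", bodyWeight = "numeric")
)

setValidity("SubjectMeta", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    msg <- c(msg, "subjectId must be a non-empty string")
  if (length(object@group) != 1L || !object@group %in% c("DIPG", "sham"))
    msg <- c(msg, "group must be 'DIPG' or 'sham'")
  if (length(object@injectedDose) != 1L || !is.finite(object@injectedDose) ||
      object@injectedDose <= 0)
    msg <- c(msg, "injectedDose (kBq) must be a single positive number")
  if (length(object@bodyWeight) != 1L || !is.finite(object@bodyWeight) ||
      object@bodyWeight <= 0)
    msg <- c(msg, "bodyWeight (g) must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' A dynamic PET study
#'
#' 4D activity-concentration image (kBq/cm^3, decay-corrected) on a voxel
#' grid, with its frame schedule and subject metadata. The fourth array
#' dimension indexes frames and must match the schedule length.
#'
#' @slot voxels 4D numeric array (x, y, z, frame) in kBq/cm^3.
#' @slot grid a [GridSpec-class].
#' @slot schedule a [FrameSchedule-class].
#' @slot subject a [SubjectMeta-class].
#' @exportClass DynamicStudy
setClass("DynamicStudy",
  representation(voxels = "array", grid = "GridSpec",
                 schedule = "FrameSchedule", subject = "SubjectMeta")
)

setValidity("DynamicStudy", function(object) {
  msg <- character()
  dm <- dim(object@voxels)
  if (length(dm) != 4L)
    msg <- c(msg, "voxels must be a 4D array (x, y, z, frame)")
  else {
    if (!identical(dm[1:3], unname(object@grid@shape)))
      msg <- c(msg, "spatial dimensions must match the grid shape")
    if (dm[4] != length(object@schedule@starts))
      msg <- c(msg, sprintf("frame axis (%d) must match schedule length (%d)",
                            dm[4], length(object@schedule@starts)))
  }
  if (any(!is.finite(object@voxels)))
    msg <- c(msg, "all voxel values must be finite")
  if (length(msg)) msg else TRUE
})

#' Integer-labelled volume of interest map
#'
#' A 3D integer array on the same grid as a companion image; 0 is reserved
#' for background and every non-zero label present in the array must be
#' named in `regionNames`.
#'
#' @slot labels 3D integer array.
#' @slot grid a [GridSpec-class].
#' @slot regionNames named integer vector mapping region name -> label.
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(labels = "array", grid = "GridSpec", regionNames = "integer")
)

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  else if (!identical(dim(object@labels), unname(object@grid@shape)))
    msg <- c(msg, "label dimensions must match the grid shape")
  if (!is.integer(object@labels) && any(object@labels != round(object@labels)))
    msg <- c(msg, "labels must be integers")
  used <- setdiff(unique(as.integer(object@labels)), 0L)
  nm <- object@regionNames
  if (is.null(names(nm)) || any(!nzchar(names(nm))))
    msg <- c(msg, "regionNames must be a named integer vector")
  if (any(nm == 0L)) msg <- c(msg, "label 0 is reserved for background")
  if (anyDuplicated(nm)) msg <- c(msg, "duplicate labels in regionNames")
  if (anyDuplicated(names(nm))) msg <- c(msg, "duplicate region names")
  miss <- setdiff(used, nm)
  if (length(miss))
    msg <- c(msg, paste("unnamed labels present in volume:",
                        paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Curves and derived quantities
## ---------------------------------------------------------------------------

#' Regional time-activity curve
#'
#' Frame mid-times (minutes) paired with the mean activity concentration
#' (kBq/cm^3) or SUV in a region.
#'
#' @slot midTimes numeric, minutes, ascending.
#' @slot values numeric, same length as `midTimes`.
#' @slot unit character scalar, `"kBq/cm3"` or `"SUV"`.
#' @slot region character scalar region name.
#' @slot subjectId character scalar.
#' @exportClass TimeActivityCurve
setClass("TimeActivityCurve",
  representation(midTimes = "numeric", values = "numeric", unit = "character",
                 region = "character", subjectId = "character"),
  prototype(unit = "kBq/cm3", region = "", subjectId = "")
)

setValidity("TimeActivityCurve", function(object) {
  msg <- character()
  if (length(object@midTimes) != length(object@values))
    msg <- c(msg, "midTimes and values must have equal length")
  if (length(object@midTimes) && is.unsorted(object@midTimes, strictly = TRUE))
    msg <- c(msg, "midTimes must be strictly ascending")
  if (!object@unit %in% c("kBq/cm3", "SUV"))
    msg <- c(msg, "unit must be 'kBq/cm3' or 'SUV'")
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' Whole-blood input function
#'
#' Per-frame whole-blood activity concentration (kBq/cm^3), either measured
#' from a blood-pool VOI (image-derived) or produced by the simulator.
#'
#' @slot midTimes numeric, minutes, ascending.
#' @slot values numeric, non-negative, kBq/cm^3.
#' @slot provenance character, `"image-derived"` or `"simulated"`.
#' @exportClass InputFunction
setClass("InputFunction",
  representation(midTimes = "numeric", values = "numeric",
                 provenance = "character"),
  prototype(provenance = "simulated")
)

setValidity("InputFunction", function(object) {
  msg <- character()
  if (length(object@midTimes) != length(object@values))
    msg <- c(msg, "midTimes and values must have equal length")
  if (length(object@midTimes) && is.unsorted(object@midTimes, strictly = TRUE))
    msg <- c(msg, "midTimes must be strictly ascending")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "values must be finite and non-negative")
  if (!object@provenance %in% c("image-derived", "simulated"))
    msg <- c(msg, "provenance must be 'image-derived' or 'simulated'")
  if (length(msg)) msg else TRUE
})

#' Area under a time-activity curve
#'
#' @slot value numeric scalar, SUV·min.
#' @slot interval numeric(2), integration interval in minutes.
#' @slot region character scalar.
#' @slot subjectId character scalar.
#' @exportClass AUCValue
setClass("AUCValue",
  representation(value = "numeric", interval = "numeric",
                 region = "character", subjectId = "character")
)

setValidity("AUCValue", function(object) {
  msg <- character()
  if (length(object@value) != 1L || !is.finite(object@value))
    msg <- c(msg, "value must be a finite scalar")
  if (length(object@interval) != 2L || object@interval[1] >= object@interval[2])
    msg <- c(msg, "interval must be [t0, t1] with t0 < t1")
  if (length(msg)) msg else TRUE
})

#' Logan graphical-analysis result
#'
#' The slope of the Logan plot is the total volume of distribution V_T
#' (mL/cm^3); the intercept (minutes) and fit diagnostics are retained.
#'
#' @slot vt numeric scalar, V_T in mL/cm^3.
#' @slot intercept numeric scalar, minutes.
#' @slot nPoints integer, number of fitted frames (>= 2).
#' @slot rSquared numeric in \[0, 1\].
#' @slot tStar numeric, equilibration time in minutes.
#' @slot region,subjectId character scalars (may be empty).
#' @exportClass LoganResult
setClass("LoganResult",
  representation(vt = "numeric", intercept = "numeric", nPoints = "integer",
                 rSquared = "numeric", tStar = "numeric",
                 region = "character", subjectId = "character"),
  prototype(region = "", subjectId = "")
)

setValidity("LoganResult", function(object) {
  msg <- character()
  if (object@nPoints < 2L) msg <- c(msg, "nPoints must be >= 2")
  if (!is.finite(object@rSquared) ||
      object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Voxel-wise V_T parametric map
#'
#' @slot values 3D numeric array of V_T (mL/cm^3); 0 outside the mask.
#' @slot mask 3D logical array; V_T is defined (finite) exactly on the mask.
#' @slot tStar numeric, minutes.
#' @slot grid a [GridSpec-class].
#' @slot nDropped integer, voxels excluded from fitting because a
#'   late-window frame was non-positive.
#' @exportClass ParametricMap
setClass("ParametricMap",
  representation(values = "array", mask = "array", tStar = "numeric",
                 grid = "GridSpec", nDropped = "integer"),
  prototype(nDropped = 0L)
)

setValidity("ParametricMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask must share dimensions")
  if (!identical(dim(object@values), unname(object@grid@shape)))
    msg <- c(msg, "map dimensions must match the grid shape")
  if (any(!is.finite(object@values[object@mask])))
    msg <- c(msg, "V_T must be finite on the mask")
  if (length(object@values[!object@mask]) &&
      any(object@values[!object@mask] != 0))
    msg <- c(msg, "V_T must be 0 outside the mask")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Simulator specifications
## ---------------------------------------------------------------------------

#' Two-tissue-compartment kinetic parameters
#'
#' Standard reversible two-tissue-compartment model (2TCM) rate constants.
#' `K1` (mL·cm^-3·min^-1) and `k2` (min^-1) govern exchange between blood
#' and the free tissue compartment; `k3`, `k4` (min^-1) govern specific
#' binding. `vB` is the fractional blood volume. Reversibility (`k4 > 0`
#' whenever `k3 > 0`) is required for a finite volume of distribution and
#' hence for Logan analysis to apply.
#'
#' @slot K1 numeric >= 0, mL·cm^-3·min^-1.
#' @slot k2 numeric > 0, min^-1.
#' @slot k3,k4 numeric >= 0, min^-1.
#' @slot vB numeric in \[0, 1), unitless.
#' @exportClass KineticParams
setClass("KineticParams",
  representation(K1 = "numeric", k2 = "numeric", k3 = "numeric",
                 k4 = "numeric", vB = "numeric"),
  prototype(k3 = 0, k4 = 0, vB = 0)
)

setValidity("KineticParams", function(object) {
  msg <- character()
  ok1 <- function(x) length(x) == 1L && is.finite(x)
  if (!ok1(object@K1) || object@K1 < 0) msg <- c(msg, "K1 must be >= 0")
  if (!ok1(object@k2) || object@k2 <= 0) msg <- c(msg, "k2 must be > 0")
  if (!ok1(object@k3) || object@k3 < 0) msg <- c(msg, "k3 must be >= 0")
  if (!ok1(object@k4) || object@k4 < 0) msg <- c(msg, "k4 must be >= 0")
  if (ok1(object@k3) && ok1(object@k4) && object@k3 > 0 && object@k4 == 0)
    msg <- c(msg, "k3 > 0 requires k4 > 0 (reversible tracer; Logan analysis needs a finite V_T)")
  if (!ok1(object@vB) || object@vB < 0 || object@vB >= 1)
    msg <- c(msg, "vB must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Parametric whole-blood input-function model
#'
#' Tri-exponential arterial/whole-blood model
#' `Cb(t) = (A1*t - A2 - A3)*exp(-l1*t) + A2*exp(-l2*t) + A3*exp(-l3*t)`,
#' clipped at zero, with `Cb(0) = 0`. Eigenvalues must satisfy
#' `l1 > l2 > l3 > 0`.
#'
#' @slot A1 numeric, kBq·cm^-3·min^-1.
#' @slot A2,A3 numeric, kBq/cm^3.
#' @slot l1,l2,l3 numeric, min^-1, strictly decreasing and positive.
#' @exportClass InputFunctionParams
setClass("InputFunctionParams",
  representation(A1 = "numeric", A2 = "numeric", A3 = "numeric",
                 l1 = "numeric", l2 = "numeric", l3 = "numeric")
)

setValidity("InputFunctionParams", function(object) {
  msg <- character()
  v <- c(object@A1, object@A2, object@A3, object@l1, object@l2, object@l3)
  if (length(v) != 6L || any(!is.finite(v)))
    msg <- c(msg, "all parameters must be finite scalars")
  else if (!(object@l1 > object@l2 && object@l2 > object@l3 && object@l3 > 0))
    msg <- c(msg, "eigenvalues must satisfy l1 > l2 > l3 > 0")
  if (length(msg)) msg else TRUE
})

#' Digital phantom specification
#'
#' Geometry (shape primitives in world mm), per-region kinetics, the blood
#' input-function model, and the noise model of a simulated dynamic study.
#' The seven brain VOIs (pons, medulla, cerebellum, choroid plexus,
#' midbrain, striatum, forebrain) plus a blood-pool region must all be
#' present and mutually disjoint; voxels are painted in the order regions
#' are listed and overlap is rejected.
#'
#' @slot grid a [GridSpec-class].
#' @slot regions data.frame with columns name, label, shape
#'   (`"ellipsoid"`, `"box"` or `"cylinder"`), cx, cy, cz, rx, ry, rz (mm).
#' @slot kinetics named list of [KineticParams-class], one per brain region.
#' @slot inputParams an [InputFunctionParams-class].
#' @slot bloodRegion character, name of the blood-pool region.
#' @slot noiseLevel numeric >= 0, unitless scale of the voxel noise model.
#' @slot noiseFloor numeric >= 0, kBq/cm^3 added inside the noise SD so the
#'   background carries a noise floor.
#' @slot decayCorrected logical; images represent decay-corrected activity.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(grid = "GridSpec", regions = "data.frame",
                 kinetics = "list", inputParams = "InputFunctionParams",
                 bloodRegion = "character", noiseLevel = "numeric",
                 noiseFloor = "numeric", decayCorrected = "logical"),
  prototype(bloodRegion = "blood_pool", noiseLevel = 0, noiseFloor = 0.05,
            decayCorrected = TRUE)
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  need <- c("name", "label", "shape", "cx", "cy", "cz", "rx", "ry", "rz")
  if (!all(need %in% names(object@regions)))
    msg <- c(msg, paste("regions must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@regions$name) || anyDuplicated(object@regions$label))
      msg <- c(msg, "region names and labels must be unique")
    if (any(object@regions$label == 0)) msg <- c(msg, "label 0 is background")
    if (!all(object@regions$shape %in% c("ellipsoid", "box", "cylinder")))
      msg <- c(msg, "shape must be ellipsoid, box or cylinder")
    brain <- setdiff(object@regions$name, object@bloodRegion)
    if (!object@bloodRegion %in% object@regions$name)
      msg <- c(msg, "blood-pool region missing from geometry")
    if (!all(brain %in% names(object@kinetics)))
      msg <- c(msg, "every brain region needs kinetic parameters")
  }
  if (object@noiseLevel < 0) msg <- c(msg, "noiseLevel must be >= 0")
  if (object@noiseFloor < 0) msg <- c(msg, "noiseFloor must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Cohort simulation specification
#'
#' Group sizes, the tumour-group kinetic override (a V_T multiplier applied
#' to the pons via k3, holding K1/k2 fixed), and dose / body-weight
#' distributions of the simulated study population.
#'
#' @slot nDipg,nSham integer >= 1, subjects per group (defaults 6 and 4).
#' @slot vtMultiplier numeric > 0, pons V_T multiplier for the DIPG group.
#' @slot tumorRegion character, region the multiplier is applied to.
#' @slot dosePerGramMean,dosePerGramSd numeric, injected dose in kBq per g
#'   of body weight (defaults 169 and 39).
#' @slot weightMean,weightSd numeric, body weight in g.
#' @slot phantom a [PhantomSpec-class].
#' @slot schedule a [FrameSchedule-class].
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nDipg = "integer", nSham = "integer",
                 vtMultiplier = "numeric", tumorRegion = "character",
                 dosePerGramMean = "numeric", dosePerGramSd = "numeric",
                 weightMean = "numeric", weightSd = "numeric",
                 phantom = "PhantomSpec", schedule = "FrameSchedule")
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nDipg < 1L || object@nSham < 1L)
    msg <- c(msg, "need at least one subject per group")
  if (!is.finite(object@vtMultiplier) || object@vtMultiplier <= 0)
    msg <- c(msg, "vtMultiplier must be > 0")
  if (object@dosePerGramMean <= 0 || object@weightMean <= 0)
    msg <- c(msg, "dose and weight means must be positive")
  if (length(msg)) msg else TRUE
})

#' A simulated dynamic study with its ground truth
#'
#' Returned by [simulateStudy()]: the noisy [DynamicStudy-class], the
#' phantom [LabelVolume-class], the per-region true kinetic parameters and
#' analytic V_T, and the noiseless frame-averaged TACs (regions x frames,
#' kBq/cm^3).
#'
#' @slot study a [DynamicStudy-class].
#' @slot labels a [LabelVolume-class].
#' @slot truth data.frame: region, K1, k2, k3, k4, vB, true_VT.
#' @slot noiselessTacs numeric matrix, regions x frames.
#' @slot inputParams the [InputFunctionParams-class] used (already scaled
#'   for the subject's injected dose per gram).
#' @exportClass SimulatedStudy
setClass("SimulatedStudy",
  representation(study = "DynamicStudy", labels = "LabelVolume",
                 truth = "data.frame", noiselessTacs = "matrix",
                 inputParams = "InputFunctionParams")
)
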