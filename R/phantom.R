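# Injected dose per gram (kBq/g) at which the default input-function
# amplitudes are defined; simulateStudy() scales the blood curve linearly
# with each subject's dose per gram relative to this.
REF_DOSE_PER_GRAM <- 169

#' Construct a grid specification
#'
#' @param shape integer(3) voxels per axis; `spacing` mm per axis;
#'   `origin` mm of the first voxel centre.
#' @param spacing,origin see `shape`.
#' @return A [GridSpec-class].
#' @export
GridSpec <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("GridSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Default rat-brain digital phantom
#'
#' A 28 x 24 x 18 voxel grid (1 mm isotropic) holding simple disjoint
#' shape primitives for the seven brain VOIs used throughout the package
#' (pons, medulla, cerebellum, choroid plexus, midbrain, striatum and the
#' rest of the forebrain) plus an abstract left-ventricle blood-pool
#' cylinder placed in a separate slab of the field of view. Shapes are
#' deliberately schematic: region identities and kinetics matter for the
#' quantification pipeline, anatomical realism does not.
#'
#' Default kinetics are calibrated so that the analytic pons V_T is about
#' 0.15 mL/cm^3, the striatum (the designated pseudo-reference region) has
#' the lowest V_T (~0.095), and the remaining regions fall in between;
#' a tumour-group V_T multiplier of 2 (see [CohortSpec()]) then raises the
#' pons to about 0.30 mL/cm^3. All brain regions use a fractional blood
#' volume of 0.05; the blood pool carries the pure whole-blood curve.
#'
#' @param noiseLevel unitless scale of the voxel noise model (default 0 =
#'   noiseless). The per-voxel, per-frame noise SD is
#'   `noiseLevel * sqrt((value + noiseFloor) / w)` with `w` the frame
#'   duration divided by the mean frame duration.
#' @param noiseFloor kBq/cm^3 inside the SD so background is 0 plus a
#'   noise floor (default 0.05).
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- defaultPhantomSpec()
#' spec@regions$name
#' @export
defaultPhantomSpec <- function(noiseLevel = 0, noiseFloor = 0.05) {
  regions <- data.frame(
    name  = c("pons", "medulla", "cerebellum", "choroid_plexus",
              "midbrain", "striatum", "forebrain", "blood_pool"),
    label = 1:8,
    shape = c(rep("ellipsoid", 7), "cylinder"),
    cx = c(7, 7, 7, 14, 14, 14, 22, 7),
    cy = c(5, 12, 19, 5, 12, 19, 12, 12),
    cz = c(6, 6, 6, 6, 6, 6, 6, 13),
    rx = c(3, 3, 3, 2.5, 3, 3, 4, 2.5),
    ry = c(2.5, 2.5, 2.5, 2, 2.5, 2.5, 6, 2.5),
    rz = c(2.5, 2.5, 2.5, 2, 2.5, 2.5, 3, 3),
    stringsAsFactors = FALSE
  )
  vB <- 0.05
  kinetics <- list(
    pons           = KineticParams(0.12, 1.2, 0.030,  0.06, vB),
    medulla        = KineticParams(0.11, 1.1, 0.018,  0.06, vB),
    cerebellum     = KineticParams(0.12, 1.3, 0.018,  0.06, vB),
    choroid_plexus = KineticParams(0.14, 1.2, 0.0223, 0.06, vB),
    midbrain       = KineticParams(0.11, 1.2, 0.0185, 0.06, vB),
    striatum       = KineticParams(0.09, 1.5, 0.020,  0.06, vB),
    forebrain      = KineticParams(0.11, 1.3, 0.018,  0.06, vB)
  )
  new("PhantomSpec",
      grid = GridSpec(c(28L, 24L, 18L)),
      regions = regions, kinetics = kinetics,
      inputParams = defaultInputFunctionParams(),
      bloodRegion = "blood_pool",
      noiseLevel = as.numeric(noiseLevel),
      noiseFloor = as.numeric(noiseFloor),
      decayCorrected = TRUE)
}

# World-space coordinates (mm) of every voxel centre, as three arrays.
voxelCoordinates <- function(grid) {
  ax <- lapply(1:3, function(i)
    grid@origin[i] + (seq_len(grid@shape[i]) - 1) * grid@spacing[i])
  list(x = array(rep(ax[[1]], times = prod(grid@shape[2:3])), grid@shape),
       y = array(rep(rep(ax[[2]], each = grid@shape[1]), grid@shape[3]),
                 grid@shape),
       z = array(rep(ax[[3]], each = prod(grid@shape[1:2])), grid@shape))
}

regionMask <- function(grid, row, co) {
  dx <- co$x - row$cx; dy <- co$y - row$cy; dz <- co$z - row$cz
  switch(row$shape,
    ellipsoid = (dx / row$rx)^2 + (dy / row$ry)^2 + (dz / row$rz)^2 <= 1,
    box       = abs(dx) <= row$rx & abs(dy) <= row$ry & abs(dz) <= row$rz,
    cylinder  = (dx / row$rx)^2 + (dy / row$ry)^2 <= 1 & abs(dz) <= row$rz)
}

#' Rasterise the phantom geometry into a label volume
#'
#' Paints each region's primitive onto the grid; overlapping regions are a
#' specification error and are rejected, so the resulting labels are
#' mutually disjoint by construction.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [LabelVolume-class].
#' @export
phantomLabels <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  grid <- spec@grid
  co <- voxelCoordinates(grid)
  lab <- array(0L, grid@shape)
  for (i in seq_len(nrow(spec@regions))) {
    row <- spec@regions[i, ]
    m <- regionMask(grid, row, co)
    if (!any(m))
      petStop("geometry", "region '%s' rasterises to zero voxels", row$name)
    if (any(lab[m] != 0L))
      petStop("geometry", "region '%s' overlaps a previously painted region",
              row$name)
    lab[m] <- as.integer(row$label)
  }
  nm <- structure(as.integer(spec@regions$label), names = spec@regions$name)
  new("LabelVolume", labels = lab, grid = grid, regionNames = nm)
}

#' Rescale a V_T target through the binding rate k3
#'
#' Multiplies the analytic V_T of a reversible two-tissue model by `m`
#' while holding K1/k2 (delivery) fixed: `k3' = k4 * (m*(1 + k3/k4) - 1)`.
#'
#' @param kp a [KineticParams-class] with `k3, k4 > 0`.
#' @param m V_T multiplier, > 0.
#' @return A [KineticParams-class] with `analyticVt` scaled by `m`.
#' @export
applyVtMultiplier <- function(kp, m) {
  stopifnot(is(kp, "KineticParams"))
  if (m == 1) return(kp)
  if (kp@k3 <= 0 || kp@k4 <= 0)
    petStop("kinetics", "V_T multiplier needs a reversible binding compartment (k3, k4 > 0)")
  k3new <- kp@k4 * (m * (1 + kp@k3 / kp@k4) - 1)
  if (k3new < 0)
    petStop("kinetics", "multiplier %g would require negative k3", m)
  KineticParams(kp@K1, kp@k2, k3new, kp@k4, kp@vB)
}

#' Frame-averaged simulated input function
#'
#' Averages the parametric whole-blood model over the acquisition frames,
#' yielding the input function a noiseless blood-pool VOI would measure.
#'
#' @param params an [InputFunctionParams-class].
#' @param schedule a [FrameSchedule-class].
#' @return An [InputFunction-class] with provenance `"simulated"`.
#' @export
simulatedInputFunction <- function(params, schedule) {
  vals <- frameAverage(function(t) fengInputFunction(params, t), schedule)
  new("InputFunction", midTimes = frameMidTimes(schedule, "min"),
      values = vals, provenance = "simulated")
}

scaleInputParams <- function(params, s) {
  InputFunctionParams(params@A1 * s, params@A2 * s, params@A3 * s,
                      params@l1, params@l2, params@l3)
}

#' Simulate one dynamic PET study from a phantom
#'
#' Every voxel of a brain region carries that region's noiseless
#' frame-averaged two-tissue-compartment TAC plus zero-mean Gaussian noise
#' with SD `noiseLevel * sqrt((value + noiseFloor) / w)`, `w` being the
#' frame duration relative to the mean frame duration (longer frames are
#' less noisy). Blood-pool voxels carry the frame-averaged whole-blood
#' curve; background is zero plus the noise floor. The blood curve is
#' scaled by the subject's injected dose per gram relative to the 169
#' kBq/g reference, so SUVs are dose-invariant. Identical inputs and seed
#' give bit-identical output.
#'
#' @param spec a [PhantomSpec-class].
#' @param schedule a [FrameSchedule-class].
#' @param dose injected dose, kBq (> 0).
#' @param weight body weight, g (> 0).
#' @param seed integer seed for the noise stream.
#' @param subjectId,group subject metadata (defaults `"sim01"`, `"sham"`).
#' @return A [SimulatedStudy-class] bundling the noisy study, the label
#'   volume, the ground-truth kinetics/V_T table and the noiseless TACs.
#' @examples
#' sim <- simulateStudy(defaultPhantomSpec(), defaultFrameSchedule(),
#'                      dose = 16900, weight = 100, seed = 1)
#' sim@truth[, c("region", "true_VT")]
#' @export
simulateStudy <- function(spec, schedule, dose, weight, seed,
                          subjectId = "sim01", group = "sham") {
  stopifnot(is(spec, "PhantomSpec"), is(schedule, "FrameSchedule"))
  validObject(spec); validObject(schedule)
  if (!is.finite(dose) || dose <= 0) petStop("dose", "dose must be > 0 kBq")
  if (!is.finite(weight) || weight <= 0) petStop("dose", "weight must be > 0 g")

  labels <- phantomLabels(spec)
  nf <- nFrames(schedule)
  ip <- scaleInputParams(spec@inputParams, (dose / weight) / REF_DOSE_PER_GRAM)

  brain <- setdiff(spec@regions$name, spec@bloodRegion)
  tmax <- totalDuration(schedule) / 60
  fineT <- fineGrid(tmax)
  cbFine <- fengInputFunction(ip, fineT)
  cbFun <- stats::approxfun(fineT, cbFine)

  tacs <- matrix(0, nrow = nrow(spec@regions), ncol = nf,
                 dimnames = list(spec@regions$name, NULL))
  for (rn in brain) {
    fine <- tissueCurveFine(spec@kinetics[[rn]], ip, tmax)
    f <- stats::approxfun(fine$t, fine$values)
    tacs[rn, ] <- frameAverage(f, schedule)
  }
  tacs[spec@bloodRegion, ] <- frameAverage(cbFun, schedule)

  vox <- array(0, c(spec@grid@shape, nf))
  nspatial <- prod(spec@grid@shape)
  flat <- matrix(0, nspatial, nf)
  for (i in seq_len(nrow(spec@regions))) {
    idx <- which(labels@labels == spec@regions$label[i])
    flat[idx, ] <- rep(tacs[spec@regions$name[i], ], each = length(idx))
  }
  if (spec@noiseLevel > 0) {
    w <- frameDurations(schedule) / mean(frameDurations(schedule))
    sd <- spec@noiseLevel *
      sqrt(sweep(pmax(flat, 0) + spec@noiseFloor, 2, w, "/"))
    noise <- withSeed(seed, matrix(stats::rnorm(nspatial * nf), nspatial, nf))
    flat <- flat + sd * noise
  }
  vox[] <- flat

  truth <- do.call(rbind, lapply(brain, function(rn) {
    kp <- spec@kinetics[[rn]]
    data.frame(region = rn, K1 = kp@K1, k2 = kp@k2, k3 = kp@k3, k4 = kp@k4,
               vB = kp@vB, true_VT = analyticVt(kp), stringsAsFactors = FALSE)
  }))

  study <- new("DynamicStudy", voxels = vox, grid = spec@grid,
               schedule = schedule,
               subject = new("SubjectMeta", subjectId = subjectId,
                             group = group, injectedDose = as.numeric(dose),
                             bodyWeight = as.numeric(weight)))
  new("SimulatedStudy", study = study, labels = labels, truth = truth,
      noiselessTacs = tacs, inputParams = ip)
}

#' Construct a cohort specification
#'
#' Defaults mirror the study design the package emulates: 6 tumour-bearing
#' (DIPG) and 4 sham subjects, injected dose 169 +/- 39 kBq per gram of
#' body weight, body weight 100 +/- 10 g, and a pons V_T doubled in the
#' DIPG group (applied through k3 at fixed K1/k2, so delivery and early
#' kinetics are unchanged). Striatum kinetics are identical across groups.
#'
#' @param nDipg,nSham subjects per group.
#' @param vtMultiplier pons V_T multiplier for the DIPG group (> 0).
#' @param tumorRegion region the multiplier applies to (default `"pons"`).
#' @param dosePerGramMean,dosePerGramSd kBq/g.
#' @param weightMean,weightSd g.
#' @param phantom a [PhantomSpec-class].
#' @param schedule a [FrameSchedule-class].
#' @return A [CohortSpec-class].
#' @export
CohortSpec <- function(nDipg = 6L, nSham = 4L, vtMultiplier = 2,
                       tumorRegion = "pons",
                       dosePerGramMean = 169, dosePerGramSd = 39,
                       weightMean = 100, weightSd = 10,
                       phantom = defaultPhantomSpec(),
                       schedule = defaultFrameSchedule()) {
  new("CohortSpec", nDipg = as.integer(nDipg), nSham = as.integer(nSham),
      vtMultiplier = as.numeric(vtMultiplier), tumorRegion = tumorRegion,
      dosePerGramMean = dosePerGramMean, dosePerGramSd = dosePerGramSd,
      weightMean = weightMean, weightSd = weightSd,
      phantom = phantom, schedule = schedule)
}

#' Simulate a DIPG-versus-sham cohort
#'
#' Draws per-subject dose-per-gram and body weight from the cohort
#' distributions (truncated at half the mean to stay positive), applies
#' the tumour-region V_T multiplier to DIPG subjects, and simulates every
#' study with a per-subject seed derived deterministically from the master
#' seed.
#'
#' @param cohort a [CohortSpec-class].
#' @param seed master seed.
#' @return A list with `studies` (list of [SimulatedStudy-class]) and
#'   `truth` (data.frame: subject_id, group, region, K1..k4, vB, true_VT).
#' @examples
#' \donttest{
#' coh <- simulateCohort(CohortSpec(nDipg = 2L, nSham = 2L), seed = 1)
#' subset(coh$truth, region == "pons")
#' }
#' @export
simulateCohort <- function(cohort, seed) {
  stopifnot(is(cohort, "CohortSpec"))
  validObject(cohort)
  n <- cohort@nDipg + cohort@nSham
  groups <- rep(c("DIPG", "sham"), c(cohort@nDipg, cohort@nSham))
  ids <- sprintf("%s%02d", tolower(groups),
                 c(seq_len(cohort@nDipg), seq_len(cohort@nSham)))
  seeds <- deriveSeeds(seed, n)
  draws <- withSeed(seed + 1, list(
    dpg = stats::rnorm(n, cohort@dosePerGramMean, cohort@dosePerGramSd),
    wt  = stats::rnorm(n, cohort@weightMean, cohort@weightSd)))
  dpg <- pmax(draws$dpg, cohort@dosePerGramMean / 2)
  wt <- pmax(draws$wt, cohort@weightMean / 2)

  dipgPhantom <- cohort@phantom
  dipgPhantom@kinetics[[cohort@tumorRegion]] <- applyVtMultiplier(
    cohort@phantom@kinetics[[cohort@tumorRegion]], cohort@vtMultiplier)

  studies <- vector("list", n)
  names(studies) <- ids
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- if (groups[i] == "DIPG") dipgPhantom else cohort@phantom
    sim <- simulateStudy(spec, cohort@schedule,
                         dose = dpg[i] * wt[i], weight = wt[i],
                         seed = seeds[i], subjectId = ids[i],
                         group = groups[i])
    studies[[i]] <- sim
    truth[[i]] <- cbind(subject_id = ids[i], group = groups[i], sim@truth,
                        stringsAsFactors = FALSE)
  }
  list(studies = studies, truth = do.call(rbind, truth))
}

#' Add proportional measurement noise to a sampled curve
#'
#' Adds zero-mean Gaussian noise with SD equal to `cv` times each frame
#' value (a constant coefficient-of-variation model, used for curve-level
#' noise studies, as opposed to the phantom's duration-weighted voxel
#' noise).
#'
#' @param values numeric vector of frame values.
#' @param cv coefficient of variation (e.g. 0.05 for 5% frame noise).
#' @return Noisy values (uses the caller's RNG stream).
#' @export
addFrameNoise <- function(values, cv = 0.05) {
  values + stats::rnorm(length(values), 0, cv * abs(values))
}

setMethod("show", "SimulatedStudy", function(object) {
  cat(sprintf("SimulatedStudy: subject %s (%s), %d regions, %d frames\n",
              object@study@subject@subjectId, object@study@subject@group,
              nrow(object@truth), nFrames(object@study@schedule)))
  cat("  true V_T (mL/cm3):",
      paste(sprintf("%s=%.3f", object@truth$region, object@truth$true_VT),
            collapse = ", "), "\n")
})

setMethod("show", "DynamicStudy", function(object) {
  dm <- dim(object@voxels)
  cat(sprintf("DynamicStudy: %d x %d x %d voxels, %d frames (%.1f min), subject %s (%s)\n",
              dm[1], dm[2], dm[3], dm[4],
              totalDuration(object@schedule) / 60,
              object@subject@subjectId, object@subject@group))
})

setMethod("show", "LabelVolume", function(object) {
  cat(sprintf("LabelVolume: %s, %d named regions\n",
              paste(dim(object@labels), collapse = " x "),
              length(object@regionNames)))
  tab <- table(object@labels[object@labels != 0])
  nm <- names(object@regionNames)[match(names(tab), object@regionNames)]
  cat(" ", paste(sprintf("%s(%s vox)", nm, tab), collapse = ", "), "\n")
})
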