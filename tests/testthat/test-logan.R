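test_that("IDIF recovers the simulated blood curve and clips negatives", {
  sim <- defaultNoiselessSim()
  idif <- extractIdif(sim@study, sim@labels)
  expect_equal(idif@values, unname(sim@noiselessTacs["blood_pool", ]),
               tolerance = 1e-12)
  expect_identical(idif@provenance, "image-derived")
  # uniform static value in the region gives a constant curve
  flat <- sim@study
  flat@voxels <- array(4.2, dim(sim@study@voxels))
  expect_equal(extractIdif(flat, sim@labels)@values, rep(4.2, 24))
})

test_that("mean IDIF over noisy replicates stays within 2% of truth", {
  spec <- miniPhantomSpec(noiseLevel = 1)
  sched <- defaultFrameSchedule()
  truth <- simulateStudy(miniPhantomSpec(0), sched, 16900, 100,
                         seed = 1)@noiselessTacs["blood_pool", ]
  nrep <- 100
  acc <- 0
  for (r in seq_len(nrep)) {
    s <- simulateStudy(spec, sched, 16900, 100, seed = 5000 + r)
    acc <- acc + extractIdif(s@study, s@labels)@values
  }
  expect_lt(max(abs(acc / nrep - truth) / truth), 0.02)
})

test_that("tissue-to-blood ratio masks zero blood and approaches V_T", {
  sched <- defaultFrameSchedule()
  p <- defaultInputFunctionParams()
  idif <- simulatedInputFunction(p, sched)
  tac <- makeTac(KineticParams(0.1, 0.3), p, sched)
  same <- tissueToBloodRatio(
    new("TimeActivityCurve", midTimes = idif@midTimes, values = idif@values,
        unit = "kBq/cm3", region = "blood", subjectId = "s"), idif)
  expect_equal(same$ratio, rep(1, 24))
  # zero blood frame is masked, not infinite
  z <- idif; z@values[24] <- 0
  r <- tissueToBloodRatio(tac, z)
  expect_true(is.na(r$ratio[24]) && all(is.finite(r$ratio[-24])))
  # late-time ratio approaches V_T = K1/k2 under a constant infusion
  long <- FrameSchedule(seq(0, 290, by = 10) * 60, rep(600, 30))
  cb1 <- function(t) rep(1, length(t))
  idifL <- new("InputFunction", midTimes = frameMidTimes(long, "min"),
               values = frameAverage(cb1, long), provenance = "simulated")
  tacL <- new("TimeActivityCurve", midTimes = frameMidTimes(long, "min"),
              values = frameAverage(function(t)
                twoTissueTac(KineticParams(0.1, 0.3), cb1, t), long),
              unit = "kBq/cm3", region = "roi", subjectId = "s")
  rl <- tissueToBloodRatio(tacL, idifL)
  expect_equal(rl$ratio[30], 0.1 / 0.3, tolerance = 0.005)
})

test_that("a tissue curve equal to the input gives the identity Logan fit", {
  sched <- defaultFrameSchedule()
  idif <- simulatedInputFunction(defaultInputFunctionParams(), sched)
  tac <- new("TimeActivityCurve", midTimes = idif@midTimes,
             values = idif@values, unit = "kBq/cm3", region = "blood",
             subjectId = "s")
  fit <- loganFit(tac, idif)
  expect_equal(fit@vt, 1, tolerance = 1e-12)
  expect_equal(fit@intercept, 0, tolerance = 1e-9)
  expect_equal(fit@rSquared, 1, tolerance = 1e-12)
  expect_equal(fit@nPoints, 9L)
})

test_that("noiseless V_T estimates stay within 5% of the analytic value", {
  sched <- defaultFrameSchedule()
  p <- defaultInputFunctionParams()
  idif <- simulatedInputFunction(p, sched)
  for (kp in paramGrid12()) {
    fit <- loganFit(makeTac(kp, p, sched), idif, tStar = 22.5)
    expect_lt(abs(fit@vt / analyticVt(kp) - 1), 0.05)
    expect_gt(fit@rSquared, 0.999)
  }
})

test_that("Logan slope carries the tissue-to-blood scale", {
  sched <- defaultFrameSchedule()
  p <- defaultInputFunctionParams()
  idif <- simulatedInputFunction(p, sched)
  tac <- makeTac(KineticParams(0.1, 0.4, 0.03, 0.06), p, sched)
  base <- loganFit(tac, idif)@vt
  # V_T is a tissue-to-blood ratio: input scaled by c divides the slope
  # by c, tissue scaled by c multiplies it by c, and a joint rescaling
  # (e.g. a unit change of the scanner calibration) leaves it unchanged
  half <- idif; half@values <- idif@values / 2
  expect_equal(loganFit(tac, half)@vt, 2 * base, tolerance = 1e-10)
  tac3 <- tac; tac3@values <- 3 * tac@values
  expect_equal(loganFit(tac3, idif)@vt, 3 * base, tolerance = 1e-10)
  idif3 <- idif; idif3@values <- 3 * idif@values
  expect_equal(loganFit(tac3, idif3)@vt, base, tolerance = 1e-10)
})

test_that("estimated V_T increases strictly with the binding ratio k3/k4", {
  sched <- defaultFrameSchedule()
  p <- defaultInputFunctionParams()
  idif <- simulatedInputFunction(p, sched)
  vts <- vapply(c(0.01, 0.02, 0.04, 0.08), function(k3)
    loganFit(makeTac(KineticParams(0.1, 0.6, k3, 0.05), p, sched), idif)@vt,
    numeric(1))
  expect_true(all(diff(vts) > 0))
})

test_that("degenerate Logan inputs raise typed errors", {
  sched <- defaultFrameSchedule()
  p <- defaultInputFunctionParams()
  idif <- simulatedInputFunction(p, sched)
  tac <- makeTac(KineticParams(0.1, 0.4, 0.03, 0.06), p, sched)
  expect_error(loganFit(tac, idif, tStar = 59),
               class = "ponsPET_error_logan_points")
  bad <- tac; bad@values[24] <- -0.01
  expect_error(loganFit(bad, idif),
               class = "ponsPET_error_logan_nonpositive")
  suv <- tac; suv@unit <- "SUV"
  expect_error(loganFit(suv, idif), class = "ponsPET_error_units")
})

test_that("voxel-wise map agrees with ROI fits on noiseless phantoms", {
  sim <- defaultNoiselessSim()
  idif <- extractIdif(sim@study, sim@labels)
  map <- loganParametricMap(sim@study, idif, labels = sim@labels)
  summ <- summarizeParametricMap(map, sim@labels,
                                 rownames(sim@noiselessTacs)[1:7])
  for (i in seq_len(nrow(summ))) {
    roi <- loganFit(extractTac(sim@study, sim@labels, summ$region[i]), idif)
    expect_lt(abs(summ$median_VT[i] / roi@vt - 1), 1e-6)
  }
  # background stays identically zero outside the mask
  expect_true(all(map@values[sim@labels@labels == 0L] == 0))
  expect_equal(map@nDropped, 0L)
})
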