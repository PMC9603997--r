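test_that("SUV normalisation follows dose-per-weight scaling", {
  expect_equal(suvTransform(2.0, dose = 400, weight = 200), 1.0)
  expect_equal(suvTransform(0, dose = 400, weight = 200), 0)
  x <- c(0.5, 1, 7)
  expect_equal(suvTransform(2 * x, 400, 200), 2 * suvTransform(x, 400, 200))
  expect_equal(suvTransform(x, 800, 200), suvTransform(x, 400, 200) / 2)
  expect_error(suvTransform(1, -400, 200), class = "ponsPET_error_dose")
  expect_error(suvTransform(1, 400, 0), class = "ponsPET_error_dose")
})

test_that("TAC extraction equals a brute-force voxel loop", {
  sim <- simulateStudy(miniPhantomSpec(0.6), defaultFrameSchedule(),
                       16900, 100, seed = 11)
  lab <- sim@labels
  tac <- extractTac(sim@study, lab, "striatum")
  idx <- which(lab@labels == lab@regionNames[["striatum"]],
               arr.ind = TRUE)
  oracle <- vapply(seq_len(24), function(f) {
    acc <- 0
    for (r in seq_len(nrow(idx)))
      acc <- acc + sim@study@voxels[idx[r, 1], idx[r, 2], idx[r, 3], f]
    acc / nrow(idx)
  }, numeric(1))
  expect_equal(tac@values, oracle, tolerance = 1e-12)
  expect_error(extractTac(sim@study, lab, "cortex"),
               class = "ponsPET_error_region")
})

test_that("single-voxel regions return that voxel's series", {
  sim <- simulateStudy(miniPhantomSpec(0.5), defaultFrameSchedule(),
                       16900, 100, seed = 3)
  lab <- sim@labels
  ijk <- which(lab@labels == 1L, arr.ind = TRUE)[1, ]
  solo <- array(0L, dim(lab@labels))
  solo[ijk[1], ijk[2], ijk[3]] <- 9L
  labSolo <- new("LabelVolume", labels = solo, grid = lab@grid,
                 regionNames = c(one = 9L))
  tac <- extractTac(sim@study, labSolo, "one")
  expect_equal(tac@values, sim@study@voxels[ijk[1], ijk[2], ijk[3], ])
})

test_that("TAC extraction commutes with the SUV transform", {
  sim <- simulateStudy(miniPhantomSpec(0.5), defaultFrameSchedule(),
                       16900, 100, seed = 4)
  dose <- 16900; wt <- 100
  a <- suvTransform(extractTac(sim@study, sim@labels, "pons"), dose, wt)
  suvStudy <- sim@study
  suvStudy@voxels <- suvTransform(sim@study, dose, wt)
  b <- extractTac(suvStudy, sim@labels, "pons")
  expect_equal(a@values, b@values, tolerance = 1e-12)
})

test_that("static averaging selects frames by mid-time and weights by duration", {
  sim <- defaultNoiselessSim()
  sched <- sim@study@schedule
  mids <- frameMidTimes(sched, "min")
  sel <- which(mids >= 25.5 & mids <= 60)
  expect_length(sel, 8L)  # late 240-s, 300-s and 150-s frames
  img <- staticAverage(sim@study, c(25.5, 60))
  # brute-force duration weighting at one voxel
  ijk <- which(sim@labels@labels == 1L, arr.ind = TRUE)[1, ]
  w <- frameDurations(sched)[sel]
  oracle <- sum(w * sim@study@voxels[ijk[1], ijk[2], ijk[3], sel]) / sum(w)
  expect_equal(img[ijk[1], ijk[2], ijk[3]], oracle, tolerance = 1e-12)
  # constant image stays constant
  const <- sim@study
  const@voxels <- array(2.5, dim(sim@study@voxels))
  expect_equal(unique(as.numeric(staticAverage(const))), 2.5)
  expect_error(staticAverage(sim@study, c(61, 62)),
               class = "ponsPET_error_window")
})

test_that("AUC handles constants, ramps and clipping analytically", {
  mkSuv <- function(t, v) new("TimeActivityCurve", midTimes = t, values = v,
                              unit = "SUV", region = "pons",
                              subjectId = "s1")
  tt <- seq(0, 60, by = 2.5)
  expect_equal(tacAuc(mkSuv(tt, rep(1, length(tt))))@value, 60)
  expect_equal(tacAuc(mkSuv(tt, tt / 60))@value, 30)
  # origin anchoring when the first sample is after t = 0
  expect_equal(tacAuc(mkSuv(c(30, 60), c(1, 1)))@value, 0.5 * 30 + 30)
  # additivity over adjacent intervals with interior interpolation
  curve <- mkSuv(tt, sqrt(tt))
  whole <- tacAuc(curve, c(0, 60))@value
  split <- tacAuc(curve, c(0, 17.3))@value + tacAuc(curve, c(17.3, 60))@value
  expect_equal(whole, split, tolerance = 1e-10)
  expect_error(tacAuc(mkSuv(tt, tt), c(70, 80)),
               class = "ponsPET_error_window")
  kb <- new("TimeActivityCurve", midTimes = tt, values = tt, unit = "kBq/cm3",
            region = "pons", subjectId = "s1")
  expect_error(tacAuc(kb), class = "ponsPET_error_units")
})

test_that("AUC of a smooth synthetic curve matches fine quadrature", {
  sched <- defaultFrameSchedule()
  f <- function(t) 3 * t * exp(-0.5 * t) + 0.2 * (1 - exp(-0.1 * t))
  vals <- frameAverage(f, sched)
  tac <- new("TimeActivityCurve", midTimes = frameMidTimes(sched, "min"),
             values = vals, unit = "SUV", region = "r", subjectId = "s")
  got <- tacAuc(tac, c(0, 60))@value
  oracle <- stats::integrate(f, 0, 60, rel.tol = 1e-10)$value
  expect_equal(got, oracle, tolerance = 0.02)
})

test_that("AUC ratios behave as ratios", {
  mk <- function(v, region) new("AUCValue", value = v, interval = c(0, 60),
                                region = region, subjectId = "s1")
  expect_equal(aucRatio(mk(20, "pons"), mk(10, "striatum")), 2)
  expect_equal(aucRatio(mk(7, "pons"), mk(7, "pons")), 1)
  expect_error(aucRatio(mk(1, "pons"), mk(0, "striatum")),
               class = "ponsPET_error_ratio")
  other <- new("AUCValue", value = 5, interval = c(0, 60), region = "striatum",
               subjectId = "s2")
  expect_error(aucRatio(mk(1, "pons"), other), class = "ponsPET_error_ratio")
})
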