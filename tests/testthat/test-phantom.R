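test_that("phantom labels are disjoint and match geometry volumes", {
  spec <- defaultPhantomSpec()
  lab <- phantomLabels(spec)
  expect_setequal(setdiff(unique(as.integer(lab@labels)), 0L),
                  spec@regions$label)
  # volumes within voxelization error of the analytic primitive volumes
  voxVol <- prod(spec@grid@spacing)
  for (i in seq_len(nrow(spec@regions))) {
    r <- spec@regions[i, ]
    vol <- sum(lab@labels == r$label) * voxVol
    ana <- switch(r$shape,
                  ellipsoid = 4 / 3 * pi * r$rx * r$ry * r$rz,
                  cylinder = pi * r$rx * r$ry * (2 * r$rz),
                  box = 8 * r$rx * r$ry * r$rz)
    expect_lt(abs(vol - ana) / ana, 0.35)
  }
  # every region admits a finite analytic V_T (reversibility guard)
  for (kp in spec@kinetics) expect_true(is.finite(analyticVt(kp)))
})

test_that("noiseless voxels carry the exact frame-averaged TACs", {
  sim <- defaultNoiselessSim()
  lab <- sim@labels
  for (rn in rownames(sim@noiselessTacs)) {
    tac <- extractTac(sim@study, lab, rn)
    ref <- sim@noiselessTacs[rn, ]
    expect_lt(max(abs(tac@values - ref)) / max(ref), 1e-9)
  }
  # background voxels are exactly zero without noise
  expect_true(all(sim@study@voxels[sim@labels@labels == 0L] == 0))
})

test_that("identical seeds reproduce bit-identical studies", {
  spec <- miniPhantomSpec(noiseLevel = 0.8)
  sched <- defaultFrameSchedule()
  a <- simulateStudy(spec, sched, 16900, 100, seed = 7)
  b <- simulateStudy(spec, sched, 16900, 100, seed = 7)
  expect_identical(a@study@voxels, b@study@voxels)
  d <- simulateStudy(spec, sched, 16900, 100, seed = 8)
  expect_false(identical(a@study@voxels, d@study@voxels))
})

test_that("voxel noise follows the configured duration-weighted SD", {
  level <- 0.5
  spec <- miniPhantomSpec(noiseLevel = level)
  sched <- defaultFrameSchedule()
  lab <- phantomLabels(spec)
  vox <- which(lab@labels == 1L)[1]
  nrep <- 200
  frames <- c(2L, 24L)
  vals <- matrix(0, nrep, length(frames))
  for (r in seq_len(nrep)) {
    s <- simulateStudy(spec, sched, 16900, 100, seed = 1000 + r)
    flat <- matrix(s@study@voxels, ncol = nFrames(sched))
    vals[r, ] <- flat[vox, frames]
  }
  noiseless <- simulateStudy(miniPhantomSpec(0), sched, 16900, 100, seed = 1)
  w <- frameDurations(sched) / mean(frameDurations(sched))
  for (j in seq_along(frames)) {
    mu <- noiseless@noiselessTacs["pons", frames[j]]
    expected <- level * sqrt((mu + spec@noiseFloor) / w[frames[j]])
    expect_lt(abs(sd(vals[, j]) - expected) / expected, 0.10)
  }
})

test_that("dose and weight must be positive and scale the blood curve", {
  spec <- miniPhantomSpec()
  sched <- defaultFrameSchedule()
  expect_error(simulateStudy(spec, sched, -1, 100, 1), "dose")
  expect_error(simulateStudy(spec, sched, 16900, 0, 1), "weight")
  lo <- simulateStudy(spec, sched, 169 * 100, 100, seed = 1)
  hi <- simulateStudy(spec, sched, 2 * 169 * 100, 100, seed = 1)
  expect_equal(hi@noiselessTacs["blood_pool", ],
               2 * lo@noiselessTacs["blood_pool", ], tolerance = 1e-12)
})

test_that("cohort multiplier acts only on the tumour region of DIPG rats", {
  mini <- miniPhantomSpec()
  base <- CohortSpec(nDipg = 2L, nSham = 2L, phantom = mini)
  coh1 <- simulateCohort(CohortSpec(nDipg = 2L, nSham = 2L, vtMultiplier = 1,
                                    phantom = mini), seed = 3)
  ponsVt <- function(coh) tapply(
    coh$truth$true_VT[coh$truth$region == "pons"],
    coh$truth$group[coh$truth$region == "pons"], unique)
  v1 <- ponsVt(coh1)
  expect_equal(unname(v1["DIPG"]), unname(v1["sham"]))
  coh2 <- simulateCohort(base, seed = 3)
  v2 <- ponsVt(coh2)
  expect_equal(unname(v2["DIPG"]), 2 * unname(v2["sham"]), tolerance = 1e-12)
  stri <- coh2$truth[coh2$truth$region == "striatum", "true_VT"]
  expect_equal(length(unique(stri)), 1L)
  # per-subject seeds derive deterministically from the master seed
  coh3 <- simulateCohort(base, seed = 3)
  expect_identical(coh2$studies[[1]]@study@voxels,
                   coh3$studies[[1]]@study@voxels)
})
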