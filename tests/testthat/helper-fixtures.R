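# Shared fixtures, all generated in code. Expensive noiseless simulations
# are cached per test run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# 12-point kinetic grid with plausible rat-brain magnitudes (1TCM and
# reversible 2TCM rows), vB = 0 so estimates are compared to the analytic
# tissue V_T.
paramGrid12 <- function() {
  grid <- list()
  for (K1 in c(0.08, 0.12)) for (k2 in c(0.4, 1.2))
    for (b in list(c(0, 0), c(0.03, 0.06), c(0.05, 0.04)))
      grid[[length(grid) + 1L]] <- KineticParams(K1, k2, b[1], b[2], 0)
  grid
}

# Noiseless frame-averaged tissue TAC for given kinetics on a schedule.
makeTac <- function(kp, inputParams, schedule, region = "roi",
                    subjectId = "sim") {
  vals <- frameAverage(function(t) twoTissueTac(kp, inputParams, t), schedule)
  new("TimeActivityCurve", midTimes = frameMidTimes(schedule, "min"),
      values = vals, unit = "kBq/cm3", region = region,
      subjectId = subjectId)
}

# Small three-region phantom (pons, striatum, blood pool) for Monte-Carlo
# noise tests where the full seven-region phantom would be wasteful.
miniPhantomSpec <- function(noiseLevel = 0) {
  full <- defaultPhantomSpec(noiseLevel = noiseLevel)
  regions <- data.frame(
    name = c("pons", "striatum", "blood_pool"),
    label = 1:3,
    shape = c("ellipsoid", "ellipsoid", "cylinder"),
    cx = c(3, 8, 3), cy = c(2.5, 2.5, 7), cz = c(3.5, 3.5, 3.5),
    rx = c(2, 2, 1.5), ry = c(2, 2, 1.5), rz = c(1.5, 1.5, 2),
    stringsAsFactors = FALSE)
  new("PhantomSpec", grid = GridSpec(c(12L, 10L, 10L)),
      regions = regions,
      kinetics = full@kinetics[c("pons", "striatum")],
      inputParams = full@inputParams, bloodRegion = "blood_pool",
      noiseLevel = noiseLevel, noiseFloor = full@noiseFloor,
      decayCorrected = TRUE)
}

# Noiseless simulation of the default seven-region phantom (shared).
defaultNoiselessSim <- function() {
  cached("noiselessSim",
         simulateStudy(defaultPhantomSpec(), defaultFrameSchedule(),
                       dose = 169 * 100, weight = 100, seed = 101))
}

# Deterministic synthetic measurement table for the statistics layer.
syntheticMeasurementTable <- function(nPerCell = 5, regions = 7,
                                      regionEffect = 0.02,
                                      groupEffect = 0.05, sd = 0.01,
                                      seed = 99, measure = "VT") {
  set.seed(seed)
  rn <- sprintf("region%02d", seq_len(regions))
  rows <- expand.grid(region = rn, group = c("DIPG", "sham"),
                      rep = seq_len(nPerCell), stringsAsFactors = FALSE)
  rows$subject_id <- sprintf("%s%02d", tolower(rows$group), rows$rep)
  rows$measure <- measure
  rows$value <- 0.15 + regionEffect * as.integer(factor(rows$region)) +
    groupEffect * (rows$group == "DIPG") + rnorm(nrow(rows), 0, sd)
  rows[c("subject_id", "group", "region", "measure", "value")]
}
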