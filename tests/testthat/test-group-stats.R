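test_that("summaries report mean and n-1 SD, with single-subject SD missing", {
  tab <- data.frame(subject_id = c("a", "b", "c", "d"),
                    group = c("DIPG", "DIPG", "DIPG", "sham"),
                    region = "pons", measure = "VT",
                    value = c(1, 2, 3, 5))
  s <- summarizeMeasures(tab, "VT")
  dipg <- s[s$group == "DIPG", ]
  expect_equal(dipg$mean, 2)
  expect_equal(dipg$sd, 1)
  expect_true(is.na(s$sd[s$group == "sham"]))
})

test_that("summaries equal a brute-force loop on a random table", {
  tab <- syntheticMeasurementTable(nPerCell = 4, regions = 3, seed = 17)
  s <- summarizeMeasures(tab, "VT")
  for (i in seq_len(nrow(s))) {
    v <- tab$value[tab$region == s$region[i] & tab$group == s$group[i]]
    expect_equal(s$mean[i], sum(v) / length(v))
    expect_equal(s$sd[i], sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
  }
})

test_that("two-group test separates separated groups and is null on identical ones", {
  tabEq <- data.frame(subject_id = sprintf("s%d", 1:8),
                      group = rep(c("DIPG", "sham"), each = 4),
                      region = "pons", measure = "VT",
                      value = rep(c(1, 2, 3, 4), 2))
  r <- twoGroupTest(tabEq, "pons", "VT")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1, tolerance = 1e-12)
  set.seed(1)
  tabSep <- tabEq
  tabSep$value <- rep(c(0, 1), each = 4) + rnorm(8, 0, 1e-4)
  expect_lt(twoGroupTest(tabSep, "pons", "VT")$p_value, 1e-6)
  # Welch and Student flavours are both exposed
  expect_match(twoGroupTest(tabSep, "pons", "VT", welch = FALSE)$method,
               "Student")
})

test_that("Welch test on simulated null cohorts keeps its nominal size", {
  sched <- defaultFrameSchedule()
  p <- defaultInputFunctionParams()
  kp <- defaultPhantomSpec()@kinetics$pons
  idif <- simulatedInputFunction(p, sched)
  noiseless <- makeTac(kp, p, sched)@values
  mids <- frameMidTimes(sched, "min")
  fitOne <- function() {
    tac <- new("TimeActivityCurve", midTimes = mids,
               values = addFrameNoise(noiseless, 0.05), unit = "kBq/cm3",
               region = "pons", subjectId = "s")
    loganFit(tac, idif)@vt
  }
  set.seed(2024)
  nrep <- 400
  rej <- mean(replicate(nrep, {
    tab <- data.frame(subject_id = sprintf("s%d", 1:10),
                      group = rep(c("DIPG", "sham"), c(6, 4)),
                      region = "pons", measure = "VT",
                      value = replicate(10, fitOne()))
    twoGroupTest(tab, "pons", "VT")$p_value < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("two-way ANOVA matches explicit sums-of-squares on balanced data", {
  tab <- syntheticMeasurementTable(nPerCell = 5, regions = 7, seed = 31)
  got <- structureGroupAnova(tab, "VT")
  # brute-force textbook decomposition
  y <- tab$value
  A <- factor(tab$region); B <- factor(tab$group)
  g <- mean(y); n <- 5; a <- nlevels(A); b <- nlevels(B)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  ssA <- b * n * sum((mA - g)^2)
  ssB <- a * n * sum((mB - g)^2)
  ssAB <- n * sum((mAB - outer(mA - g, mB - g, "+") - g)^2)
  ssE <- sum((y - mAB[cbind(A, B)])^2)
  Fs <- c(ssA / (a - 1), ssB / (b - 1), ssAB / ((a - 1) * (b - 1))) /
    (ssE / (a * b * (n - 1)))
  expect_equal(got$anova$sum_sq, c(ssA, ssB, ssAB, ssE), tolerance = 1e-8)
  expect_equal(got$anova$statistic[1:3], unname(Fs), tolerance = 1e-8)
  # total SS decomposition
  expect_equal(sum(got$anova$sum_sq), sum((y - g)^2), tolerance = 1e-8)
})

test_that("degenerate and adjusted cases of the ANOVA layer behave", {
  tab <- syntheticMeasurementTable(nPerCell = 3, regions = 7, seed = 8)
  tab$value <- 1  # all equal: every effect sum of squares is 0
  flat <- structureGroupAnova(tab, "VT")
  expect_equal(flat$anova$sum_sq, rep(0, 4), tolerance = 1e-20)
  # Bonferroni: adjusted p = min(1, 7 * raw p), monotone, capped at 1
  tab2 <- syntheticMeasurementTable(nPerCell = 5, regions = 7,
                                    groupEffect = 0.002, seed = 12)
  got <- structureGroupAnova(tab2, "VT")
  expect_equal(got$pairwise$p_adjusted,
               pmin(1, got$pairwise$p_value * 7))
  o <- order(got$pairwise$p_value)
  expect_true(!is.unsorted(got$pairwise$p_adjusted[o]))
  expect_true(all(got$pairwise$p_adjusted <= 1 &
                  got$pairwise$p_adjusted >= got$pairwise$p_value))
})
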