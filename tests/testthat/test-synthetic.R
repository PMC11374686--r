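test_that("generation is bit-identical under a fixed seed", {
  pp <- synthParams(nBlocks = 1)
  b1 <- generateBehavior(pp, seed = 7)
  b2 <- generateBehavior(pp, seed = 7)
  expect_identical(positions(b1$bat1), positions(b2$bat1))
  expect_identical(positions(b1$humans$H1$coat), positions(b2$humans$H1$coat))
  s1 <- generateSpikes(b1, list(unitId = "u", baseline = 2), seed = 3)
  s2 <- generateSpikes(b2, list(unitId = "u", baseline = 2), seed = 3)
  expect_identical(spikeTimes(s1), spikeTimes(s2))
})

test_that("zero jitter gives identical flight shapes, jitter separates templates", {
  pp0 <- synthParams(nBlocks = 1, pathJitterSd = 0, trackingNoiseSd = 0)
  beh <- generateBehavior(pp0, seed = 1)
  tf <- beh$truth$flights
  ts <- timestamps(beh$bat1)
  path <- function(i) positions(beh$bat1)[ts >= tf$start_s[i] &
                                            ts <= tf$end_s[i], ]
  outT1 <- which(tf$leg == "out" & tf$tripod == "T1")
  p1 <- path(outT1[1]); p2 <- path(outT1[2])
  n <- min(nrow(p1), nrow(p2))
  expect_gt(cor(as.numeric(p1[1:n, ]), as.numeric(p2[1:n, ])), 0.999999)

  ppJ <- synthParams(nBlocks = 2, pathJitterSd = 0.05, trackingNoiseSd = 0)
  behJ <- generateBehavior(ppJ, seed = 2)
  tfJ <- behJ$truth$flights
  tsJ <- timestamps(behJ$bat1)
  shape <- function(i) as.numeric(downsampleFlight(
    positions(behJ$bat1)[tsJ >= tfJ$start_s[i] & tsJ <= tfJ$end_s[i], ]))
  outs <- which(tfJ$leg == "out")
  shapes <- vapply(outs, shape, numeric(21))
  tpl <- tfJ$tripod[outs]
  cm <- cor(shapes)
  same <- cm[outer(tpl, tpl, "==") & upper.tri(cm)]
  diff <- cm[outer(tpl, tpl, "!=") & upper.tri(cm)]
  expect_gt(mean(same), mean(diff))
})

test_that("without traverses the coat tag only moves during swap walks", {
  pp <- synthParams(nBlocks = 2, traversesPerBlockPerHuman = 0,
                    trackingNoiseSd = 0)
  beh <- generateBehavior(pp, seed = 3)
  coat <- computeVelocity(beh$humans$H1$coat)
  ts <- timestamps(coat)
  # swap walks start at block boundaries; exclude a window around them
  swap <- rep(FALSE, length(ts))
  for (b in 2:pp$nBlocks) {
    t0 <- (b - 1) * pp$blockDur
    swap <- swap | (ts > t0 - 1 & ts < t0 + 15)
  }
  expect_lt(max(speed(coat)[!swap]), 0.4)
  expect_equal(nrow(beh$truth$traverses), 0)
})

test_that("homogeneous Poisson spike counts match their expectation", {
  pp <- synthParams(nBlocks = 1, blockDur = 100, flightsPerBlockPerHuman = 0,
                    traversesPerBlockPerHuman = 0, conspecific = FALSE,
                    trackingNoiseSd = 0)
  beh <- generateBehavior(pp, seed = 1)
  counts <- vapply(1:500, function(sd)
    length(spikeTimes(generateSpikes(beh, list(baseline = 3), seed = sd))),
    numeric(1))
  # mean of 500 Poisson(300) draws: SE = sqrt(300/500)
  expect_lt(abs(mean(counts) - 300), 3 * sqrt(300 / 500))
  expect_equal(length(spikeTimes(generateSpikes(beh, list(baseline = 0),
                                                seed = 1))), 0)
})

test_that("spike counts scale linearly with field peak rate", {
  pp <- synthParams(nBlocks = 1, trackingNoiseSd = 0)
  beh <- generateBehavior(pp, seed = 4)
  mid <- (pp$restCorner1 + synthGeometry(pp)@tripods["T1", ]) / 2
  counts <- vapply(c(2, 4, 8), function(pk) {
    mean(vapply(1:20, function(sd) length(spikeTimes(generateSpikes(
      beh, list(baseline = 0,
                selfField = list(center = mid[1:2], width = 0.4, peak = pk)),
      seed = sd))), numeric(1)))
  }, numeric(1))
  fit <- lm(counts ~ c(2, 4, 8))
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_lt(abs(coef(fit)[1]) / counts[2], 0.15)  # near-zero intercept
})

test_that("negative instantaneous rate is rejected", {
  pp <- synthParams(nBlocks = 1, blockDur = 60, flightsPerBlockPerHuman = 0,
                    traversesPerBlockPerHuman = 0, conspecific = FALSE)
  beh <- generateBehavior(pp, seed = 1)
  expect_error(generateSpikes(beh, list(baseline = -1), seed = 1),
               "negative")
})

test_that("generated behavior passes the session invariants", {
  sim <- smallSim()
  expect_true(validObject(sim$session))
  b <- batSeries(sim$session)
  expect_false(is.unsorted(timestamps(b)))
  ext <- sim$session@geometry@extent
  expect_true(all(positions(b) >= -0.5 & positions(b) <=
                    rep(ext, each = nrow(positions(b))) + 0.5))
})

test_that("the fixture suite writes loadable sessions with ground truth", {
  dir <- withr::local_tempdir()
  paths <- makeFixtureSuite(dir, seed = 1,
                            params = synthParams(nBlocks = 1))
  expect_setequal(basename(list.dirs(dir, recursive = FALSE)),
                  c("null", "place", "identity", "human_position"))
  sess <- suppressWarnings(loadSession(file.path(dir, "place")))
  expect_s4_class(sess, "Session")
  gt <- jsonlite::read_json(file.path(dir, "place", "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_true(gt$is_spatial_self[1])
  expect_false(gt$is_identity_modulated[1])
})
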