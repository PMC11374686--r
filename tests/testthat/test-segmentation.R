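test_that("local quadratic smoothing reproduces quadratic paths exactly", {
  tt <- seq(0, 10, by = 0.01)
  xyz <- cbind(tt^2 / 50, 2 + 0.1 * tt, 1 + tt - tt^2 / 20)
  s <- trackedSeries("b", "body", tt, xyz)
  sm <- smoothBatPositions(s)
  interior <- tt > 1 & tt < 9   # away from filter edge transients
  expect_lt(max(abs(positions(sm)[interior, ] - xyz[interior, ])), 1e-9)
  # constant position: unchanged, velocity identically 0
  s2 <- trackedSeries("b", "body", tt, matrix(1, length(tt), 3))
  sm2 <- smoothBatPositions(s2)
  expect_equal(positions(sm2), matrix(1, length(tt), 3))
  expect_equal(max(speed(sm2)), 0)
})

test_that("smoothing reduces white-noise RMSE by more than half", {
  tt <- seq(0, 20, by = 0.01)
  truth <- cbind(sin(tt / 3), cos(tt / 4), 1 + tt / 40)
  set.seed(5)
  noisy <- truth + matrix(rnorm(length(truth), 0, 0.05), ncol = 3)
  sm <- smoothBatPositions(trackedSeries("b", "body", tt, noisy))
  interior <- tt > 1 & tt < 19
  rmse0 <- sqrt(mean((noisy[interior, ] - truth[interior, ])^2))
  rmse1 <- sqrt(mean((positions(sm)[interior, ] - truth[interior, ])^2))
  expect_lt(rmse1, rmse0 / 2)
})

test_that("the coat median filter removes outliers and keeps ramps", {
  tt <- seq(0, 30, by = 0.01)
  xyz <- cbind(tt / 10, 2, 1.2)
  xyz[1500, 1] <- 50                      # single-sample glitch
  sm <- smoothHumanCoat(trackedSeries("h", "coat", tt, xyz))
  expect_lt(max(abs(positions(sm)[, 1] - tt / 10)), 0.02)
  # step function: median-preserved step within 1 s of the edge
  xyz2 <- cbind(ifelse(tt < 15, 0, 1), 2, 1.2)
  sm2 <- smoothHumanCoat(trackedSeries("h", "coat", tt, xyz2))
  x <- positions(sm2)[, 1]
  expect_equal(x[tt < 13.9], rep(0, sum(tt < 13.9)))
  expect_equal(x[tt > 16.1], rep(1, sum(tt > 16.1)))
})

test_that("flight segmentation recovers jitter-free ground truth exactly", {
  pp <- synthParams(nBlocks = 2, pathJitterSd = 0, trackingNoiseSd = 0)
  beh <- generateBehavior(pp, seed = 11)
  bat <- smoothBatPositions(beh$bat1)
  fl <- segmentFlights(bat, beh$geometry, beh$schedule)
  tf <- beh$truth$flights
  expect_equal(nrow(fl), nrow(tf))
  expect_lt(max(abs(fl$start_s - tf$start_s)), 0.2)
  expect_lt(max(abs(fl$end_s - tf$end_s)), 0.2)
  out <- tf$leg == "out"
  expect_equal(fl$landing_tripod[out], tf$tripod[out])
  expect_equal(fl$human_at_landing[out], tf$human[out])
  # flight epochs are disjoint
  expect_true(all(fl$start_s[-1] >= fl$end_s[-nrow(fl)]))
  # stationary series yields no flights
  still <- computeVelocity(trackedSeries("b", "body", seq(0, 10, 0.01),
                                         matrix(1, 1001, 3)))
  expect_equal(nrow(segmentFlights(still, beh$geometry)), 0)
})

test_that("two flights separated by a rest are segmented separately", {
  pp <- synthParams(nBlocks = 1, flightsPerBlockPerHuman = 1,
                    pathJitterSd = 0, trackingNoiseSd = 0,
                    traversesPerBlockPerHuman = 0, conspecific = FALSE)
  beh <- generateBehavior(pp, seed = 1)
  fl <- segmentFlights(smoothBatPositions(beh$bat1), beh$geometry,
                       beh$schedule)
  # each trial contributes two epochs (outbound + return, 3 s sit between)
  expect_equal(nrow(fl), nrow(beh$truth$flights))
  expect_gte(nrow(fl), 2)
})

test_that("rest detection finds the occupied corner and the rest mask rules hold", {
  sim <- smallSim()
  fr <- smallFrames()
  pp <- sim$behavior$params
  rl <- detectRestLocations(fr$bat, k = 2, seed = 1)
  d <- sqrt(sum((as.numeric(rl[1, 1:3]) - pp$restCorner1)^2))
  expect_lt(d, 0.05)
  expect_error(detectRestLocations(
    computeVelocity(lineSeries(c(0, 0, 0), c(50, 0, 0), 10)), vThresh = 0.4),
    "no sub-threshold")

  # rest-mask truth table on a constructed series
  tt <- seq(0, 4, by = 0.01)
  centroid <- c(1, 1, 2)
  xyz <- matrix(rep(centroid, each = length(tt)), ncol = 3)
  still <- computeVelocity(trackedSeries("b", "body", tt, xyz))
  expect_true(all(restMask(still, centroid)))
  far <- computeVelocity(trackedSeries("b", "body", tt,
                                       matrix(rep(centroid + c(2.5, 0, 0),
                                                  each = length(tt)), ncol = 3)))
  expect_false(any(restMask(far, centroid)))      # 2.5 m away
  moving <- computeVelocity(trackedSeries("b", "body", tt,
                                          cbind(1 + 0.6 * tt, 1, 2)))
  expect_false(any(restMask(moving, centroid)[10:390]))  # 0.6 m/s
})

test_that("traverse segmentation matches ground truth and discards stops", {
  pp <- synthParams(nBlocks = 2, pathJitterSd = 0, trackingNoiseSd = 0)
  beh <- generateBehavior(pp, seed = 12)
  cfg <- analysisConfig()
  for (h in names(beh$humans)) {
    coat <- smoothHumanCoat(beh$humans[[h]]$coat)
    ev <- beh$events[beh$events$human == h, ]
    sp <- data.frame(start = ev$start_s - 1, end = ev$end_s + 1)
    tr <- suppressMessages(segmentTraverses(coat, beh$geometry@traverseStart,
                                            cfg, sp))
    tru <- beh$truth$traverses[beh$truth$traverses$human == h, ]
    expect_equal(nrow(tr), nrow(tru))
    expect_lt(max(abs(tr$start_s - tru$start_s)), 0.2)
    expect_lt(max(abs(tr$end_s - tru$end_s)), 0.2)
    expect_true(all(tr$end_s - tr$start_s > 12))
    # without the feed-pause exclusion the mid-traverse stop kills them all
    tr2 <- suppressMessages(segmentTraverses(coat,
                                             beh$geometry@traverseStart, cfg))
    expect_equal(nrow(tr2), 0)
  }
  expect_error(segmentTraverses(smoothHumanCoat(beh$humans$H1$coat), NULL),
               "required")
})

test_that("handling exclusion buffers events by 1 s and merges overlaps", {
  trav <- data.frame(start_s = 100, end_s = 120)
  sp <- excludeHandling(trav, data.frame(start_s = 105, end_s = 107))
  expect_equal(sp$start, 104)
  expect_equal(sp$end, 108)
  sp2 <- excludeHandling(trav, data.frame(start_s = c(105, 107),
                                          end_s = c(107, 109)))
  expect_equal(nrow(sp2), 1)               # abutting events merge
  expect_equal(c(sp2$start, sp2$end), c(104, 110))
  expect_equal(nrow(excludeHandling(trav, data.frame(start_s = numeric(0),
                                                     end_s = numeric(0)))), 0)
  expect_error(excludeHandling(trav, data.frame(start_s = 95, end_s = 97)),
               "outside")
})

test_that("conspecific presence needs proximity and sub-threshold speed", {
  tt <- seq(0, 10, by = 0.01)
  tripod <- c(1, 1, 1.4)
  at <- computeVelocity(trackedSeries("b2", "body", tt,
                                      matrix(rep(tripod, each = length(tt)),
                                             ncol = 3)))
  expect_true(conspecificPresence(at, tripod, 5))
  far <- computeVelocity(trackedSeries("b2", "body", tt,
                                       matrix(rep(tripod + c(3, 0, 0),
                                                  each = length(tt)), ncol = 3)))
  expect_false(conspecificPresence(far, tripod, 5))
  flying <- computeVelocity(trackedSeries("b2", "body", tt,
                                          cbind(1 + 2 * (tt - 5), 1, 1.4)))
  expect_false(conspecificPresence(flying, tripod, 5))
  expect_true(is.na(conspecificPresence(at, tripod, 25)))  # untracked time
})
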