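test_that("remapping score closed forms, symmetry and scale invariance", {
  expect_equal(remappingScore(5, 5), 0)
  expect_equal(remappingScore(5, 0), 1)
  expect_equal(remappingScore(3, 1), 0.5)
  expect_true(is.na(remappingScore(0, 0)))
  expect_error(remappingScore(-1, 2), ">= 0")
  set.seed(6)
  a <- runif(10000, 0, 20); b <- runif(10000, 0, 20)
  s <- remappingScore(a, b)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(s, remappingScore(b, a))                      # symmetry
  k <- runif(10000, 0.1, 10)
  expect_equal(remappingScore(k * a, k * b), s)              # scale invariance
})

mk1D <- function(rate) {
  n <- length(rate)
  new("RateMap1D", binSize = 0.15, occupancy = rep(1, n),
      spikeCount = rate, smoothedOccupancy = rep(1, n), rate = rate,
      valid = rep(TRUE, n), meanRate = mean(rate), nSpikes = sum(rate),
      nFlights = 10)
}

test_that("1D map metrics: correlation, peak distance, tie-break", {
  r <- dnorm(1:40, 15, 3)
  m1 <- mk1D(r)
  same <- mapMetrics1D(m1, mk1D(r))
  expect_equal(same$pearson_r, 1)
  expect_equal(same$peak_distance_m, 0)
  shifted <- mk1D(c(rep(0, 10), r)[1:40])
  expect_equal(mapMetrics1D(m1, shifted)$peak_distance_m, 10 * 0.15)
  # positive affine transform keeps r = 1; doubling gives score 1/3
  m2 <- mk1D(2 * r)
  expect_equal(mapMetrics1D(m1, m2)$pearson_r, 1)
  expect_equal(remappingScore(m1@meanRate, m2@meanRate), 1 / 3)
  # peak ties break to the smallest bin index
  tied <- mk1D(c(0, 3, 0, 3, 0))
  expect_equal(mapMetrics1D(tied, mk1D(c(3, 0, 0, 0, 0)))$peak_distance_m,
               0.15)
  # too few common bins: correlation not analyzable
  sparse <- mk1D(r)
  sparse@valid[3:40] <- FALSE
  expect_true(is.na(mapMetrics1D(m1, sparse)$pearson_r))
})

test_that("the non-paired null never pairs a unit with itself", {
  set.seed(7)
  maps1 <- lapply(1:8, function(i) mk1D(runif(40)))
  maps2 <- lapply(1:8, function(i) mk1D(runif(40)))
  for (sd in 1:20) {
    nn <- nullNonpaired(maps1, maps2, seed = sd)
    expect_equal(nrow(nn), 8)
  }
  # independent random fields: null correlations center near 0
  big1 <- lapply(1:200, function(i) mk1D(runif(40)))
  big2 <- lapply(1:200, function(i) mk1D(runif(40)))
  nn <- nullNonpaired(big1, big2, seed = 1)
  expect_lt(abs(mean(nn$r)), 0.1)
  expect_error(nullNonpaired(maps1[1], maps2[1]), "at least 2")
})

test_that("the trial-shuffle null flags identity-gain units, spares null units", {
  set.seed(13)
  fl <- data.frame(start_s = seq(0, 390, by = 10),
                   end_s = seq(3, 393, by = 10),
                   human = rep(c("H1", "H2"), 20))
  gain <- sort(c(runif(100, 0, 400),
                 unlist(lapply(fl$start_s[fl$human == "H1"],
                               function(s) runif(12, s, s + 3)))))
  rg <- nullTrialShuffle(fl, gain, 1000, seed = 2)
  expect_gt(rg$empirical, quantile(rg$null, 0.95))
  # label shuffling conserves total spikes/time: null scores sane
  expect_true(all(rg$null >= 0 & rg$null <= 1))
  flat <- sort(runif(400, 0, 400))
  r0 <- nullTrialShuffle(fl, flat, 1000, seed = 3)
  expect_lt(r0$empirical, quantile(r0$null, 0.95))
})

test_that("even/odd split stability is 1 for per-flight-identical spiking", {
  flts <- 12
  gen <- local({
    dt <- 0.01; dur <- 2; gap <- 2
    rows <- list(); tt <- c(); xx <- c(); t0 <- 1
    for (i in seq_len(flts)) {
      ft <- seq(0, dur, by = dt)
      tt <- c(tt, t0 + ft); xx <- c(xx, ft * 3)
      rows[[i]] <- data.frame(start_s = t0, end_s = t0 + dur)
      t0 <- t0 + dur + gap
    }
    list(series = trackedSeries("b", "body", tt, cbind(xx, 2.5, 1.5)),
         flights = do.call(rbind, rows))
  })
  spk <- sort(unlist(lapply(gen$flights$start_s,
                            function(s) s + c(0.6, 0.62, 0.64, 1.3))))
  r <- stabilityEvenOdd(gen$series, gen$flights, spk)
  expect_true(r$analyzable)
  expect_equal(r$spearman_r, 1, tolerance = 1e-6)
  # a stable generator field stays strongly correlated
  sim <- smallSim(); fr <- smallFrames()
  fl <- fr$flights[fr$flights$landing_tripod %in% "T1" &
                     !is.na(fr$flights$landing_tripod), ]
  r2 <- stabilityEvenOdd(fr$bat, fl, spikeTimes(unitByName(sim, "place")))
  expect_true(r2$analyzable)
  expect_gt(r2$spearman_r, 0.8)
  expect_false(stabilityEvenOdd(gen$series, gen$flights[1:3, ],
                                spk)$analyzable)
})

test_that("temporal stability separates stationary from drifting modulation", {
  mkGen <- function(nf) {
    dt <- 0.01; dur <- 2; gap <- 2
    rows <- list(); tt <- c(); xx <- c(); t0 <- 1
    for (i in seq_len(nf)) {
      ft <- seq(0, dur, by = dt)
      tt <- c(tt, t0 + ft); xx <- c(xx, ft * 3)
      rows[[i]] <- data.frame(start_s = t0, end_s = t0 + dur)
      t0 <- t0 + dur + gap
    }
    list(series = trackedSeries("b", "body", tt, cbind(xx, 2.5, 1.5)),
         flights = do.call(rbind, rows))
  }
  gen <- mkGen(20)
  set.seed(17)
  stationary <- sort(unlist(lapply(gen$flights$start_s,
                                   function(s) s + runif(6, 0.5, 0.9))))
  rs <- temporalStabilityHalves(gen$series, gen$flights, stationary,
                                nShuffles = 100, seed = 2)
  expect_true(rs$analyzable)
  expect_gt(rs$empirical_r, quantile(rs$null_r, 0.05))
  # drifting field: early flights fire at 0.7 s, late flights at 1.6 s
  drifting <- sort(unlist(lapply(seq_len(20), function(i) {
    s <- gen$flights$start_s[i]
    ctr <- if (i <= 10) 0.7 else 1.6
    s + runif(6, ctr - 0.1, ctr + 0.1)
  })))
  rd <- temporalStabilityHalves(gen$series, gen$flights, drifting,
                                nShuffles = 100, seed = 2)
  expect_lt(rd$empirical_r, quantile(rd$null_r, 0.05))
  expect_false(temporalStabilityHalves(gen$series, gen$flights[1:3, ],
                                       stationary)$analyzable)
})

test_that("2D context pairs gate on shared pixels and spikes", {
  sim <- fullSim(); fr <- fullFrames()
  cp <- contextPair2D(sim$session, spikeTimes(unitByName(sim, "null")),
                      fr, nShuffles = 200, seed = 4)
  expect_true(cp$analyzable)
  expect_equal(length(cp$contexts), 2)
  expect_gte(cp$shared_fraction, 0.3)
  expect_true(all(cp$n_spikes >= 20))
  # an untuned unit's rate does not depend on the context: score inside null
  expect_lt(cp$score, quantile(cp$score_null, 0.99))
  # a stable place field keeps its map across contexts: high correlation
  cpp <- contextPair2D(sim$session, spikeTimes(unitByName(sim, "place")),
                       fr, nShuffles = 200, seed = 4)
  expect_true(cpp$analyzable)
  expect_gt(cpp$pearson_r, 0.5)
  expect_lt(cpp$score, quantile(cpp$score_null, 0.99))
  # spike starvation: not analyzable
  few <- spikeTimes(unitByName(sim, "null"))[1:30]
  cpf <- contextPair2D(sim$session, few, fr, nShuffles = 10, seed = 4)
  expect_false(cpf$analyzable)
})
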