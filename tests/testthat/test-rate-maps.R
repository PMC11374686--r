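# Straight back-and-forth flight series along x at constant speed, with a
# rest gap between flights; returns series + flight epochs.
straightFlights <- function(nFlights, len = 6, speed = 3, gap = 2,
                            fs = 100) {
  dt <- 1 / fs
  dur <- len / speed
  rows <- list()
  tt <- c(); xx <- c()
  t0 <- 1
  for (i in seq_len(nFlights)) {
    ft <- seq(0, dur, by = dt)
    x <- if (i %% 2 == 1) ft * speed else len - ft * speed
    tt <- c(tt, t0 + ft, t0 + dur + gap / 2)
    xx <- c(xx, x, x[length(x)])
    rows[[i]] <- data.frame(start_s = t0, end_s = t0 + dur)
    t0 <- t0 + dur + gap
  }
  list(series = trackedSeries("b", "body", tt, cbind(xx, 2.5, 1.5)),
       flights = do.call(rbind, rows), len = len, dur = dur)
}

test_that("a constant-rate unit yields a flat 2D map at that rate", {
  # boustrophedon sweep covering the room uniformly, regular 5 Hz spiking
  fs <- 100; v <- 1
  rowsY <- seq(0.2, 5.0, by = 0.1)
  xs <- c(); ys <- c()
  for (i in seq_along(rowsY)) {
    xg <- seq(0.2, 5.4, by = v / fs)
    if (i %% 2 == 0) xg <- rev(xg)
    xs <- c(xs, xg); ys <- c(ys, rep(rowsY[i], length(xg)))
  }
  tt <- seq(0, by = 1 / fs, length.out = length(xs))
  ser <- trackedSeries("b", "body", tt, cbind(xs, ys, 1.5))
  eps <- data.frame(start = 0, end = max(tt) + 0.01)
  spikes <- seq(0.025, max(tt), by = 0.05)      # 20 Hz, regular
  m <- rateMap2D(ser, eps, spikes, extent = c(5.6, 5.2))
  r <- rateValues(m)[validBins(m)]
  inner <- which(validBins(m), arr.ind = TRUE)
  keep <- inner[, 1] > 4 & inner[, 1] < max(inner[, 1]) - 3 &
    inner[, 2] > 4 & inner[, 2] < max(inner[, 2]) - 3
  expect_lt(max(abs(r[keep] - 20) / 20), 0.02)
  expect_equal(mapMeanRate(m), 20, tolerance = 0.02)
  # zero spikes: all-zero map
  m0 <- rateMap2D(ser, eps, numeric(0), extent = c(5.6, 5.2))
  expect_true(all(rateValues(m0)[validBins(m0)] == 0))
  expect_equal(m0@nSpikes, 0)
})

test_that("spike mass is conserved pre-smoothing and doubles when superposed", {
  sf <- straightFlights(20)
  eps <- data.frame(start = sf$flights$start_s, end = sf$flights$end_s)
  set.seed(2)
  spk1 <- sort(runif(300, 0, max(sf$flights$end_s) + 1))
  m1 <- rateMap2D(sf$series, eps, spk1, extent = c(5.6, 5.2))
  inEpochs <- sum(vapply(spk1, function(s)
    any(s >= eps$start & s < eps$end), logical(1)))
  expect_equal(sum(m1@spikeCount), inEpochs)
  spk2 <- sort(runif(300, 0, max(sf$flights$end_s) + 1))
  m12 <- rateMap2D(sf$series, eps, sort(c(spk1, spk2)), extent = c(5.6, 5.2))
  v <- validBins(m1) & validBins(m12)
  expect_equal(mapMeanRate(m12) / m1@nSpikes * sum(m1@spikeCount),
               2 * mapMeanRate(m1), tolerance = 0.25)
})

test_that("sub-cutoff bins survive only next to valid neighbors", {
  occ <- matrix(0, 9, 9)
  occ[3:7, 3:7] <- 1                    # a valid block
  occ[5, 8] <- 0.1                      # low-occupancy, touching the block
  occ[1, 1] <- 0.1                      # low-occupancy, isolated
  valid <- batmap:::rescueBins(occ, 0.15)
  expect_true(valid[5, 8])
  expect_false(valid[1, 1])
  expect_true(all(valid[3:7, 3:7]))
  expect_false(valid[2, 1])             # unvisited stays invalid
})

test_that("zero included occupancy is an error", {
  sf <- straightFlights(4)
  expect_error(rateMap2D(sf$series, data.frame(start = 1e5, end = 1e5 + 1),
                         numeric(0), extent = c(5.6, 5.2)),
               "no behavior samples")
})

test_that("linearization rescales speed away and bins at 0.15 m", {
  sf <- straightFlights(8)
  lin <- linearizeFlights(sf$series, sf$flights)
  expect_equal(lin$templateLength, 6, tolerance = 0.01)
  ctx <- mapContext1D(lin)
  expect_equal(ctx$nbins, ceiling(lin$templateLength / 0.15))  # 40 bins
  # same path at half speed: identical spatial bin occupancy profile shape
  sfSlow <- straightFlights(8, speed = 1.5)
  linS <- linearizeFlights(sfSlow$series, sfSlow$flights)
  ctxS <- mapContext1D(linS)
  expect_equal(ctxS$nbins, ctx$nbins)
  p1 <- ctx$occ / sum(ctx$occ); p2 <- ctxS$occ / sum(ctxS$occ)
  expect_lt(max(abs(p1 - p2)), 0.01)
})

test_that("a 1D field at 2 m peaks in the right bin and inclusion rules gate", {
  sf <- straightFlights(12)
  # one spike burst each time the bat crosses x = 2 m
  cross <- vapply(seq_len(nrow(sf$flights)), function(i) {
    ts <- timestamps(sf$series)
    sel <- ts >= sf$flights$start_s[i] & ts <= sf$flights$end_s[i]
    x <- positions(sf$series)[sel, 1]
    ts[sel][which.min(abs(x - 2))]
  }, numeric(1))
  spk <- sort(c(cross, cross + 0.01, cross + 0.02))
  m <- rateMap1D(sf$series, sf$flights, spk)
  expect_s4_class(m, "RateMap1D")
  peakBin <- which.max(rateValues(m))
  expect_lt(abs((peakBin - 0.5) * 0.15 - 2), 0.15 + 0.075)
  # 6 flights only: not analyzable
  expect_null(rateMap1D(sf$series, sf$flights[1:6, ], spk))
  # < 15 spikes: not analyzable
  expect_null(rateMap1D(sf$series, sf$flights, cross[1:7]))
})

test_that("a constant-rate unit yields a flat 1D map at that rate", {
  sf <- straightFlights(200)
  tmax <- max(sf$flights$end_s)
  spikes <- seq(0.001, tmax, by = 1 / 7)      # 7 Hz regular
  m <- rateMap1D(sf$series, sf$flights, spikes)
  r <- rateValues(m)[validBins(m)]
  mid <- 4:(length(r) - 4)
  expect_lt(max(abs(r[mid] - 7) / 7), 0.05)
})
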