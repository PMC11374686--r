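test_that("Skaggs SI closed forms hold", {
  # uniform map: 0 bits/spike
  expect_equal(skaggsSI(rep(3.7, 25), rep(1, 25)), 0)
  # one-hot over 2^k equal-occupancy bins: k bits/spike
  expect_equal(skaggsSI(c(2, 0), c(1, 1)), 1)
  expect_equal(skaggsSI(c(4, 0, 0, 0), rep(1, 4)), 2)
  expect_equal(skaggsSI(c(8, rep(0, 7)), rep(1, 8)), 3)
  # scale invariance (per-spike normalization)
  set.seed(1)
  r <- runif(50); o <- runif(50)
  expect_equal(skaggsSI(7.3 * r, o), skaggsSI(r, o))
  # non-negativity on random maps (Jensen)
  sis <- vapply(1:10000, function(i) {
    n <- sample(2:30, 1)
    skaggsSI(runif(n, 0, 10), runif(n))
  }, numeric(1))
  expect_true(all(sis >= -1e-12))
  # zero mean rate: not analyzable
  expect_true(is.na(skaggsSI(rep(0, 5), rep(1, 5))))
})

test_that("circular shifts preserve spike count and an identity shift the SI", {
  sf <- smallFrames()
  fl <- sf$flights
  ctx <- mapContext2D(sf$bat, data.frame(start = fl$start_s, end = fl$end_s),
                      smallSim()$session@geometry@extent)
  spk <- spikeTimes(unitByName(smallSim(), "place"))
  ct <- batmap:::toConcatTime(spk, ctx$epochs)
  ct <- ct[!is.na(ct)]
  emp <- batmap:::siFromCounts(ctx, spikeBinCounts(ctx, ct, concat = TRUE))
  # a full-period shift is the identity
  shifted <- (ct + ctx$total) %% ctx$total
  expect_equal(
    batmap:::siFromCounts(ctx, spikeBinCounts(ctx, shifted, concat = TRUE)),
    emp)
  # every shuffle preserves the spike count
  for (off in c(5, 133.7, ctx$total - 2)) {
    sh <- (ct + off) %% ctx$total
    expect_equal(sum(spikeBinCounts(ctx, sh, concat = TRUE)), length(ct))
  }
  # timeline too short for the minimum shift
  expect_error(batmap:::nullSIConcat(ctx, ct, 10, 1, minShift = 1e5),
               "shorter")
})

test_that("significance calls follow the (1+k)/(1+n) and quantile rules", {
  null <- seq_len(1000) / 1000
  above <- testSignificance(2, null)
  expect_equal(above$p, 1 / 1001)
  expect_true(above$significant)
  mid <- testSignificance(0.5, null)
  expect_equal(mid$p, 0.5, tolerance = 0.01)
  expect_false(mid$significant)
  # Bonferroni 5 moves the threshold to the 99th percentile
  bon <- testSignificance(0.985, null, alpha = 0.05, bonferroniN = 5)
  expect_equal(bon$threshold, quantile(null, 0.99), ignore_attr = TRUE)
  expect_false(bon$significant)
  expect_true(testSignificance(0.995, null, bonferroniN = 5)$significant)
  expect_error(testSignificance(1, null, bonferroniN = 0), "bonferroniN")
  expect_equal(above$normalized, 2 / mean(null))
})

test_that("a place unit beats all 1000 shuffles; frames gate by inclusion", {
  sim <- smallSim(); fr <- smallFrames()
  fl <- fr$flights
  ctx <- mapContext2D(fr$bat, data.frame(start = fl$start_s, end = fl$end_s),
                      sim$session@geometry@extent)
  res <- circularShiftNull(ctx, spikeTimes(unitByName(sim, "place")),
                           nShuffles = 1000, seed = 5)
  expect_gt(res$empirical, max(res$null))
  # self-2D frame: the same conclusion through the frame interface
  si <- siByFrame(sim$session, unitByName(sim, "place"), "self_2d", fr,
                  seed = 5)
  expect_true(si$significant)
  expect_gt(si$normalized_si, 1)
  # a 0.1 Hz unit fails the 0.2 Hz active-cell floor
  quiet <- unitRecord(spikeTrain("quiet", seq(10, 500, by = 10),
                                 sessionSpan(sim$session)))
  siQ <- siByFrame(sim$session, quiet, "self_2d", fr, seed = 5)
  expect_true(is.na(siQ$significant))
})

test_that("human-frame SI flags the tuned human only", {
  sim <- fullSim(); fr <- fullFrames()
  si <- siByFrame(sim$session, unitByName(sim, "hpos"), "human_2d_identity",
                  fr, seed = 3)
  expect_equal(nrow(si), 2)
  expect_true(si$significant[si$target == "H1"])
  expect_false(si$significant[si$target == "H2"])
  expect_equal(unique(si$bonferroni_n), 2)
  pooled <- siByFrame(sim$session, unitByName(sim, "hpos"),
                      "human_2d_pooled", fr, seed = 3)
  expect_true(pooled$significant)
})

test_that("preferred vs non-preferred comparison behaves symmetrically", {
  same <- preferredVsNonpreferred(rep(2, 6), rep(2, 6))
  expect_equal(same$p, 1)
  set.seed(4)
  a <- 2 + runif(12); b <- a - 0.5 + rnorm(12, 0, 0.1)
  fwd <- preferredVsNonpreferred(a, b)
  rev <- preferredVsNonpreferred(b, a)
  expect_equal(fwd$p, rev$p)                  # test symmetry
  expect_lt(fwd$p, 0.05)
  expect_true(is.na(preferredVsNonpreferred(a[1:3], b[1:3])$p))
})

test_that("one-human-tuned units show higher normalized SI for that human", {
  sim <- fullSim(); fr <- fullFrames()
  si <- siByFrame(sim$session, unitByName(sim, "hpos"), "human_2d_identity",
                  fr, seed = 3)
  expect_gt(si$normalized_si[si$target == "H1"],
            si$normalized_si[si$target == "H2"])
})
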