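test_that("window rates use half-open 2-s windows", {
  cfg <- analysisConfig()
  spk <- c(10.0, 10.5, 11.0, 11.5)
  expect_equal(windowRate(spk, 10.25, "landing", cfg), 2)   # 4 spikes / 2 s
  expect_equal(windowRate(numeric(0), 10, "landing", cfg), 0)
  # start included, end excluded
  expect_equal(windowRate(c(9.75), 10, "landing", cfg), 0.5)
  expect_equal(windowRate(c(11.75), 10, "landing", cfg), 0)
  expect_equal(windowRate(c(8.25), 10, "takeoff", cfg), 0.5)
  expect_equal(windowRate(c(10.25), 10, "takeoff", cfg), 0)
  # vectorized over events
  expect_equal(windowRate(spk, c(10.25, 50), "landing", cfg), c(2, 0))
})

test_that("4v4 trials give 70 distinct assignments and pass the resolution cap", {
  rates <- c(5, 6, 4, 5, 1, 2, 1, 0)
  lab <- rep(c("H1", "H2"), each = 4)
  pn <- batmap:::permDiffNull(rates, lab, method = "exact")
  expect_equal(pn$nDistinct, choose(8, 4))           # 70
  expect_equal(pn$nPerm, 70)
  expect_lt(pn$resolution, 0.02)
  r <- identityPermutationTest(rates, lab, config = analysisConfig())
  expect_true(r$analyzable)
  expect_true(r$significant)
  # 3 trials for one human: below the inclusion minimum
  r2 <- identityPermutationTest(rates[-1], lab[-1])
  expect_false(r2$analyzable)
})

test_that("the test is symmetric in group labels", {
  set.seed(8)
  rates <- rgamma(12, 4)
  lab <- rep(c("H1", "H2"), 6)
  a <- identityPermutationTest(rates, lab, seed = 3)
  b <- identityPermutationTest(rates, ifelse(lab == "H1", "H2", "H1"),
                               seed = 3)
  expect_equal(a$p, b$p)
  expect_equal(a$empirical, b$empirical)
  expect_gte(a$empirical, 0)
})

test_that("Monte-Carlo p matches exact enumeration within 0.01", {
  set.seed(11)
  for (rep in 1:5) {
    # a clear group effect keeps the exact p small, so the Monte-Carlo
    # estimator's standard error sits well inside the 0.01 oracle tolerance
    rates <- c(rpois(5, 10), rpois(5, 4)) / 2
    lab <- rep(c("a", "b"), each = 5)
    pe <- batmap:::permDiffNull(rates, lab, method = "exact")
    pm <- batmap:::permDiffNull(rates, lab, nPerm = 10000, seed = rep,
                                method = "montecarlo")
    expect_lt(abs(pe$p - pm$p), 0.01)
  }
})

test_that("type-I error of the identity test is controlled on null units", {
  set.seed(21)
  nUnits <- 500
  sig <- logical(nUnits)
  for (i in seq_len(nUnits)) {
    rates <- rpois(16, 8) / 2               # exchangeable: no identity effect
    lab <- rep(c("H1", "H2"), each = 8)
    r <- identityPermutationTest(rates, lab, nPerm = 200, seed = i,
                                 method = "montecarlo",
                                 checkInclusion = FALSE)
    sig[i] <- isTRUE(r$significant)
  }
  se <- sqrt(0.05 * 0.95 / nUnits)
  expect_lte(mean(sig), 0.05 + 3 * se)
})

test_that("the identity-gain fixture is significant at its tripod only", {
  sim <- fullSim(); fr <- fullFrames()
  u <- unitByName(sim, "ident")
  res <- identityModulation(spikeTimes(u), fr$flights, "landing",
                            config = sessionConfig(sim$session), seed = 7,
                            unit = "ident")
  expect_true(res$significant[res$location == "T1"])
  expect_false(res$significant[res$location == "T2"])
  expect_equal(res$bonferroni_n[1], sum(!is.na(res$significant)))
})

test_that("conspecific-presence test requires label variation and finds gains", {
  cfg <- analysisConfig()
  r <- conspecificPresenceTest(rpois(10, 6) / 2, rep(TRUE, 10), config = cfg)
  expect_false(r$analyzable)
  set.seed(5)
  pres <- rep(c(TRUE, FALSE), each = 8)
  rates <- ifelse(pres, rpois(16, 16), rpois(16, 4)) / 2
  r2 <- conspecificPresenceTest(rates, pres, seed = 2, config = cfg)
  expect_true(r2$analyzable)
  expect_true(r2$significant)
})

test_that("excluding conspecific trials leaves untouched tests identical", {
  sim <- fullSim(); fr <- fullFrames()
  u <- unitByName(sim, "ident")
  fl <- fr$flights
  flNone <- fl
  flNone$conspecific_present <- FALSE       # pretend the other bat never came
  a <- identityModulation(spikeTimes(u), flNone, "landing", FALSE,
                          sessionConfig(sim$session), 7, "ident")
  b <- identityModulation(spikeTimes(u), flNone, "landing", TRUE,
                          sessionConfig(sim$session), 7, "ident")
  expect_equal(a$p, b$p)
  expect_equal(a$diff_hz, b$diff_hz)
  # with real presence labels the exclusion drops trials but keeps the effect
  c2 <- identityModulation(spikeTimes(u), fl, "landing", TRUE,
                           sessionConfig(sim$session), 7, "ident")
  t1row <- c2[c2$location == "T1", ]
  expect_true(t1row$n1 + t1row$n2 <
                sum(fl$landing_tripod == "T1", na.rm = TRUE))
  expect_true(t1row$significant)
})

test_that("reward metrics are 1 for baseline-flat units and gate on spikes", {
  cfg <- analysisConfig()
  span <- c(0, 1000)
  landings <- seq(50, 950, by = 50)
  humans <- rep(c("H1", "H2"), length.out = length(landings))
  # exactly 4 Hz, one spike centered in every 0.25 s PSTH bin: the peri-event
  # rate equals baseline bin for bin, so both ratios are exactly 1
  spk <- seq(0.125, 999.875, by = 0.25)
  m <- rewardMetrics(spk, landings, humans, span, config = cfg)
  expect_true(m$analyzable)
  expect_equal(m$mean_rate_change, 1, tolerance = 1e-6)
  expect_equal(m$peak_rate_change, 1, tolerance = 1e-6)
  expect_equal(m$baseline_hz, 4, tolerance = 1e-6)
  # identical peri-landing spiking across humans: Spearman r = 1
  spk2 <- sort(c(spk, unlist(lapply(landings,
                                    function(e) e + c(0.11, 0.31, 0.51)))))
  m2 <- rewardMetrics(spk2, landings, humans, span, config = cfg)
  expect_equal(m2$spearman_r, 1)
  # no baseline spikes: not analyzable
  m3 <- rewardMetrics(sort(unlist(lapply(landings[1:5], function(e)
    e + runif(4, 0, 1)))), landings[1:5], humans[1:5], span, config = cfg)
  expect_false(m3$analyzable)
})
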