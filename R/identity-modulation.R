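# Peri-event window rates and label-permutation tests for human identity,
# conspecific presence, and the conspecific-excluded control.

#' Firing rate in the 2-s peri-event window
#'
#' Take-off window [-1.75, +0.25) s; landing window [-0.25, +1.75) s (both
#' half-open: a spike exactly at the window start counts, one at the end does
#' not). Rate = spikes in window / 2 s.
#'
#' @param spikes spike times (s).
#' @param eventTime take-off or landing time (s).
#' @param event "landing" or "takeoff".
#' @param config an [AnalysisConfig-class] (window bounds).
#' @return rate in Hz.
#' @export
windowRate <- function(spikes, eventTime, event = c("landing", "takeoff"),
                       config = analysisConfig()) {
  event <- match.arg(event)
  w <- if (event == "landing") config@params$landingWindow
       else config@params$takeoffWindow
  vapply(eventTime, function(e)
    sum(inWindow(spikes, e + w[1], e + w[2])) / (w[2] - w[1]), numeric(1))
}

# Two-group label-permutation null of |mean(a) - mean(b)|.
# Exact enumeration over distinct assignments when feasible, else Monte
# Carlo relabeling with the (1+k)/(1+n) p-value convention.
permDiffNull <- function(rates, labels, nPerm = 1000, seed = 1,
                         method = c("auto", "exact", "montecarlo"),
                         maxExact = 1e5) {
  method <- match.arg(method)
  labels <- as.character(labels)
  grp <- sort(unique(labels))
  stopifnot(length(grp) == 2)
  a <- rates[labels == grp[1]]; b <- rates[labels == grp[2]]
  n <- length(rates); n1 <- length(a)
  emp <- abs(mean(a) - mean(b))
  nDistinct <- choose(n, n1)
  tot <- sum(rates)
  if (method == "exact" ||
      (method == "auto" && choose(n, min(n1, n - n1)) <= maxExact)) {
    idx <- combn(n, n1)
    null <- apply(idx, 2, function(ii)
      abs(mean(rates[ii]) - (tot - sum(rates[ii])) / (n - n1)))
    p <- mean(null >= emp - 1e-12)
    nUsed <- ncol(idx)
  } else {
    null <- withSeed(seed, vapply(seq_len(nPerm), function(k) {
      ii <- sample.int(n, n1)
      abs(mean(rates[ii]) - (tot - sum(rates[ii])) / (n - n1))
    }, numeric(1)))
    p <- (1 + sum(null >= emp - 1e-12)) / (1 + nPerm)
    nUsed <- nPerm
  }
  list(empirical = emp, null = null, p = p, nPerm = nUsed,
       nDistinct = nDistinct, resolution = 1 / nDistinct,
       n1 = n1, n2 = n - n1)
}

#' Permutation test for human-identity modulation at one landing location
#'
#' The empirical statistic is the absolute difference of mean peri-event
#' window rates between flights to the two humans at the same location; the
#' null shuffles the human label across trials ("1,000 times, or for as many
#' permutations as the number of trials per human permitted"). Inclusion: at
#' least 4 trials to each human, 15 spikes across all trials in the window,
#' at least 4 trials with spikes, and permutation resolution (1 / distinct
#' assignments) at most 0.02.
#'
#' @param rates peri-event window rates (Hz), one per trial.
#' @param labels human identity per trial (2 levels).
#' @param nPerm maximum permutations (default 1000).
#' @param seed RNG seed.
#' @param bonferroniN Bonferroni family size (locations/events examined for
#'   the unit).
#' @param config an [AnalysisConfig-class].
#' @param method "auto" (exact enumeration when feasible), "exact" or
#'   "montecarlo".
#' @param checkInclusion apply the inclusion rules (default TRUE).
#' @return list: analyzable, empirical (Hz), sign, p, significant, n_perm,
#'   resolution, n1, n2.
#' @export
identityPermutationTest <- function(rates, labels, nPerm = 1000, seed = 1,
                                    bonferroniN = 1,
                                    config = analysisConfig(),
                                    method = "auto", checkInclusion = TRUE) {
  p <- config@params
  labels <- as.character(labels)
  grp <- sort(unique(labels))
  counts <- rates * diff(p$landingWindow)   # windows are 2 s by construction
  notA <- list(analyzable = FALSE, empirical = NA_real_, sign = NA_real_,
               p = NA_real_, significant = NA, n_perm = NA_integer_,
               resolution = NA_real_,
               n1 = if (length(grp)) sum(labels == grp[1]) else 0L,
               n2 = if (length(grp) > 1) sum(labels == grp[2]) else 0L)
  if (length(grp) != 2) return(notA)
  if (checkInclusion) {
    nn <- table(labels)
    if (any(nn < p$minTrialsPerHuman) ||
        sum(counts) < p$minSpikesIdentity ||
        sum(counts > 0) < p$minTrialsWithSpikesIdentity) return(notA)
  }
  pn <- permDiffNull(rates, labels, nPerm, seed, method)
  if (checkInclusion && pn$resolution > p$permResolutionMax) {
    notA$resolution <- pn$resolution
    return(notA)
  }
  sg <- sign(mean(rates[labels == grp[1]]) - mean(rates[labels == grp[2]]))
  thr <- as.numeric(quantile(pn$null, 1 - p$alpha / bonferroniN))
  list(analyzable = TRUE, empirical = pn$empirical, sign = sg, p = pn$p,
       significant = pn$empirical > thr, n_perm = pn$nPerm,
       resolution = pn$resolution, n1 = pn$n1, n2 = pn$n2)
}

#' Permutation test for conspecific-presence modulation
#'
#' Same machinery as [identityPermutationTest()] with presence/absence of
#' the other bat at the landing location as the trial label; Bonferroni over
#' the landing locations examined. All-same-label inputs are not analyzable.
#'
#' @inheritParams identityPermutationTest
#' @param present logical per trial: conspecific at the landing location.
#' @return as [identityPermutationTest()].
#' @export
conspecificPresenceTest <- function(rates, present, nPerm = 1000, seed = 1,
                                    bonferroniN = 1,
                                    config = analysisConfig(),
                                    method = "auto") {
  keep <- !is.na(present)
  identityPermutationTest(rates[keep],
                          ifelse(present[keep], "present", "absent"),
                          nPerm, seed, bonferroniN, config, method)
}

# Window rates + labels for flights landing at (or taking off from) tripods.
eventTrials <- function(spikes, flights, event = "landing",
                        config = analysisConfig()) {
  if (event == "landing") {
    tm <- flights$end_s; loc <- flights$landing_tripod
    hum <- flights$human_at_landing
  } else {
    tm <- flights$start_s; loc <- flights$takeoff_tripod
    hum <- flights$human_at_takeoff
  }
  data.frame(time = tm, location = loc, human = hum,
             conspecific_present = flights$conspecific_present,
             rate = windowRate(spikes, tm, event, config))
}

#' Identity-modulation tests for one unit across landing/take-off locations
#'
#' Runs the label-permutation test at every location examined (per event
#' kind), Bonferroni-correcting over the number of analyzable locations x
#' events for the unit. With `excludeConspecific = TRUE`, trials on which the
#' other bat was present (or its presence unknown) at the landing location
#' are removed before testing, and only locations still meeting the
#' inclusion criterion are analyzed.
#'
#' @param spikes the unit's spike times (s).
#' @param flights [segmentFlights()] output (with schedule labels).
#' @param events character subset of c("landing", "takeoff").
#' @param excludeConspecific drop conspecific-present trials first.
#' @param config an [AnalysisConfig-class].
#' @param seed RNG seed.
#' @param unit unit id for the output table.
#' @return data.frame: unit, variant, event, location, n1, n2, diff_hz, sign,
#'   p, n_perm, resolution, bonferroni_n, significant (NA when not
#'   analyzable).
#' @export
identityModulation <- function(spikes, flights, events = c("landing",
                                                           "takeoff"),
                               excludeConspecific = FALSE,
                               config = analysisConfig(), seed = 1,
                               unit = "unit") {
  p <- config@params
  variant <- if (excludeConspecific) "conspecific_excluded" else "full"
  cand <- list()
  for (ev in events) {
    tr <- eventTrials(spikes, flights, ev, config)
    tr <- tr[!is.na(tr$location) & !is.na(tr$human), , drop = FALSE]
    if (excludeConspecific)
      tr <- tr[!is.na(tr$conspecific_present) & !tr$conspecific_present, ,
               drop = FALSE]
    for (loc in sort(unique(tr$location))) {
      sub <- tr[tr$location == loc, , drop = FALSE]
      cand[[length(cand) + 1]] <- list(event = ev, location = loc, sub = sub)
    }
  }
  if (!length(cand)) {
    return(data.frame(unit = character(0), variant = character(0),
                      event = character(0), location = character(0),
                      n1 = integer(0), n2 = integer(0), diff_hz = numeric(0),
                      sign = numeric(0), p = numeric(0), n_perm = integer(0),
                      resolution = numeric(0), bonferroni_n = integer(0),
                      significant = logical(0)))
  }
  # first pass: which location x event combinations are analyzable
  pre <- lapply(cand, function(cc)
    identityPermutationTest(cc$sub$rate, cc$sub$human, nPerm = 2, seed = 1,
                            config = config, method = "montecarlo"))
  bonfN <- max(1, sum(vapply(pre, function(x) x$analyzable, logical(1))))
  rows <- lapply(seq_along(cand), function(i) {
    cc <- cand[[i]]
    r <- identityPermutationTest(cc$sub$rate, cc$sub$human,
                                 nPerm = p$nShuffles,
                                 seed = deriveSeed(seed, i),
                                 bonferroniN = bonfN, config = config)
    data.frame(unit = unit, variant = variant, event = cc$event,
               location = cc$location, n1 = r$n1, n2 = r$n2,
               diff_hz = r$empirical, sign = r$sign, p = r$p,
               n_perm = r$n_perm, resolution = r$resolution,
               bonferroni_n = bonfN,
               significant = if (r$analyzable) r$significant else NA)
  })
  do.call(rbind, rows)
}

#' Conspecific-presence tests for one unit across landing locations
#'
#' @inheritParams identityModulation
#' @return data.frame as [identityModulation()] with variant "presence".
#' @export
presenceModulation <- function(spikes, flights, config = analysisConfig(),
                               seed = 1, unit = "unit") {
  p <- config@params
  tr <- eventTrials(spikes, flights, "landing", config)
  tr <- tr[!is.na(tr$location) & !is.na(tr$conspecific_present), ,
           drop = FALSE]
  locs <- sort(unique(tr$location))
  pre <- lapply(locs, function(loc) {
    sub <- tr[tr$location == loc, , drop = FALSE]
    conspecificPresenceTest(sub$rate, sub$conspecific_present, nPerm = 2,
                            seed = 1, config = config,
                            method = "montecarlo")
  })
  bonfN <- max(1, sum(vapply(pre, function(x) x$analyzable, logical(1))))
  rows <- lapply(seq_along(locs), function(i) {
    sub <- tr[tr$location == locs[i], , drop = FALSE]
    r <- conspecificPresenceTest(sub$rate, sub$conspecific_present,
                                 nPerm = p$nShuffles,
                                 seed = deriveSeed(seed, i),
                                 bonferroniN = bonfN, config = config)
    data.frame(unit = unit, variant = "presence", event = "landing",
               location = locs[i], n1 = r$n1, n2 = r$n2,
               diff_hz = r$empirical, sign = r$sign, p = r$p,
               n_perm = r$n_perm, resolution = r$resolution,
               bonferroni_n = bonfN,
               significant = if (r$analyzable) r$significant else NA)
  })
  do.call(rbind, rows)
}

#' Peri-landing firing-rate change and cross-human rate similarity
#'
#' Peak rate change = peak of the trial-averaged peri-landing rate (0.25 s
#' bins over the [-0.25, +1.75] s window) divided by the unit's baseline
#' rate; mean rate change uses the mean rate in the [0, +1.75] s window.
#' Baseline is the session-wide mean rate excluding all peri-landing
#' windows. The Spearman correlation compares the two humans' trial-averaged
#' peri-landing rate time courses.
#'
#' @param spikes spike times (s).
#' @param landingTimes landing times (s), one per trial.
#' @param humans human landing target per trial.
#' @param span session [t0, t1].
#' @param binWidth PSTH bin width, s.
#' @param config an [AnalysisConfig-class].
#' @return list(peak_rate_change, mean_rate_change, spearman_r, baseline_hz,
#'   analyzable).
#' @export
rewardMetrics <- function(spikes, landingTimes, humans, span,
                          binWidth = 0.25, config = analysisConfig()) {
  p <- config@params
  w <- p$landingWindow
  perTrial <- windowRate(spikes, landingTimes, "landing", config) *
    (w[2] - w[1])
  if (sum(perTrial > 0) < p$minTrialsWithSpikesIdentity ||
      sum(perTrial) < p$minSpikesIdentity)
    return(list(peak_rate_change = NA_real_, mean_rate_change = NA_real_,
                spearman_r = NA_real_, baseline_hz = NA_real_,
                analyzable = FALSE))
  periIv <- mergeIntervals(data.frame(start = landingTimes + w[1],
                                      end = landingTimes + w[2]))
  baseIv <- subtractIntervals(data.frame(start = span[1], end = span[2]),
                              periIv)
  baseDur <- intervalDuration(baseIv)
  inBase <- vapply(spikes, function(s)
    any(s >= baseIv$start & s < baseIv$end), logical(1))
  baseline <- sum(inBase) / baseDur
  if (!is.finite(baseline) || baseline <= 0)
    return(list(peak_rate_change = NA_real_, mean_rate_change = NA_real_,
                spearman_r = NA_real_, baseline_hz = baseline,
                analyzable = FALSE))
  edges <- seq(w[1], w[2], by = binWidth)
  psth <- function(times) {
    if (!length(times)) return(rep(0, length(edges) - 1))
    rel <- unlist(lapply(times, function(e)
      spikes[inWindow(spikes, e + w[1], e + w[2])] - e))
    h <- if (length(rel)) tabulate(findInterval(rel, edges,
                                                rightmost.closed = FALSE),
                                   length(edges) - 1)
         else rep(0L, length(edges) - 1)
    h / (length(times) * binWidth)
  }
  avg <- psth(landingTimes)
  meanWinRate <- mean(vapply(landingTimes, function(e)
    sum(inWindow(spikes, e, e + w[2])) / w[2], numeric(1)))
  hs <- sort(unique(humans))
  sr <- NA_real_
  if (length(hs) == 2) {
    p1 <- psth(landingTimes[humans == hs[1]])
    p2 <- psth(landingTimes[humans == hs[2]])
    if (sd(p1) > 0 && sd(p2) > 0)
      sr <- suppressWarnings(cor(p1, p2, method = "spearman"))
  }
  list(peak_rate_change = max(avg) / baseline,
       mean_rate_change = meanWinRate / baseline,
       spearman_r = sr, baseline_hz = baseline, analyzable = TRUE)
}
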