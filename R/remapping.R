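# Rate vs global remapping metrics and their null constructions.

#' Remapping score of two mean firing rates
#'
#' score = |r1 - r2| / (r1 + r2): 0 means no rate change, 1 means one rate
#' fully dominates. Undefined (NA, not analyzable) when both rates are 0.
#'
#' @param r1,r2 non-negative mean rates, Hz (vectorized).
#' @return score in [0, 1], NA where r1 = r2 = 0.
#' @export
remappingScore <- function(r1, r2) {
  if (any(c(r1, r2) < 0, na.rm = TRUE)) stop("mean rates must be >= 0")
  out <- abs(r1 - r2) / (r1 + r2)
  out[(r1 + r2) == 0] <- NA_real_
  out
}

#' Correlation and peak distance between two 1D rate maps
#'
#' Pearson correlation over the bins valid in both maps (at least 3
#' required); peak distance = |argmax1 - argmax2| x bin size, ties broken by
#' the smallest-index bin.
#'
#' @param map1,map2 [RateMap1D-class] objects on the same binning.
#' @return list(pearson_r, peak_distance_m, n_common_bins).
#' @export
mapMetrics1D <- function(map1, map2) {
  n <- min(length(map1@rate), length(map2@rate))
  r1 <- map1@rate[seq_len(n)]; r2 <- map2@rate[seq_len(n)]
  common <- map1@valid[seq_len(n)] & map2@valid[seq_len(n)]
  r <- NA_real_
  if (sum(common) >= 3 && sd(r1[common]) > 0 && sd(r2[common]) > 0)
    r <- cor(r1[common], r2[common])
  pk <- function(v) which.max(ifelse(is.na(v), -Inf, v))  # smallest index wins
  dist <- abs(pk(r1) - pk(r2)) * map1@binSize
  list(pearson_r = r, peak_distance_m = dist, n_common_bins = sum(common))
}

#' Non-paired-unit null for map correlation and peak distance
#'
#' The global-remapping null: each unit's human-1 map is paired with the
#' human-2 map of a different, randomly drawn unit (one draw per unit, never
#' itself), and the correlation and peak distance computed across this
#' mismatched pair.
#'
#' @param mapsH1,mapsH2 lists of [RateMap1D-class] maps (one per unit, same
#'   trajectory, the two human landing targets).
#' @param seed RNG seed.
#' @return data.frame(r, peak_distance_m), one row per unit.
#' @export
nullNonpaired <- function(mapsH1, mapsH2, seed = 1) {
  n <- length(mapsH1)
  stopifnot(length(mapsH2) == n)
  if (n < 2) stop("non-paired null needs at least 2 eligible units")
  partner <- withSeed(seed, vapply(seq_len(n), function(i)
    sample(setdiff(seq_len(n), i), 1), numeric(1)))
  rows <- lapply(seq_len(n), function(i)
    mapMetrics1D(mapsH1[[i]], mapsH2[[partner[i]]]))
  data.frame(r = vapply(rows, `[[`, numeric(1), "pearson_r"),
             peak_distance_m = vapply(rows, `[[`, numeric(1),
                                      "peak_distance_m"))
}

#' Trial-shuffle null for the remapping score on one trajectory
#'
#' The human landing-target labels are shuffled between the trajectory's
#' flights; each shuffle's mean rates (spikes / time per label group) give a
#' null remapping score representing no rate remapping. Per-trial rates are
#' untouched - only labels move.
#'
#' @param flights data.frame(start_s, end_s, human) for one trajectory.
#' @param spikes the unit's spike times (s).
#' @param nShuffles number of label shuffles (default 1000).
#' @param seed RNG seed.
#' @return list(empirical, null, rates): empirical score, null scores, and
#'   the two empirical mean rates.
#' @export
nullTrialShuffle <- function(flights, spikes, nShuffles = 1000, seed = 1) {
  hs <- sort(unique(flights$human))
  stopifnot(length(hs) == 2)
  nSpk <- vapply(seq_len(nrow(flights)), function(i)
    sum(spikes >= flights$start_s[i] & spikes <= flights$end_s[i]),
    numeric(1))
  dur <- flights$end_s - flights$start_s
  grpRate <- function(lab) {
    c(sum(nSpk[lab == hs[1]]) / sum(dur[lab == hs[1]]),
      sum(nSpk[lab == hs[2]]) / sum(dur[lab == hs[2]]))
  }
  rr <- grpRate(flights$human)
  empirical <- remappingScore(rr[1], rr[2])
  null <- withSeed(seed, vapply(seq_len(nShuffles), function(k) {
    lab <- sample(flights$human)
    r <- grpRate(lab)
    remappingScore(r[1], r[2])
  }, numeric(1)))
  list(empirical = empirical, null = null, rates = rr)
}

# Rate-weighted center of mass of a 2D map over its valid bins (m).
mapCentroid <- function(map) {
  idx <- which(map@valid, arr.ind = TRUE)
  w <- map@rate[map@valid]
  if (sum(w) == 0) return(c(NA_real_, NA_real_))
  xy <- (idx - 0.5) * map@binSize
  c(sum(xy[, 1] * w), sum(xy[, 2] * w)) / sum(w)
}

#' 2D context-pair remapping metrics for one unit
#'
#' Flights are grouped into "contexts" by the human-configuration in force at
#' take-off (which human stood at which tripod). The two contexts with the
#' most flight occupancy among those with at least 20 spikes are compared:
#' Pearson correlation over common valid bins, Euclidean distance between
#' rate centers of mass, and the remapping score of the two mean rates, plus
#' a context-label trial-shuffle null for the score. Pairs sharing fewer
#' than 30% of valid pixels (intersection over union) are not analyzable.
#'
#' @param sess a [Session-class].
#' @param spikes the unit's spike times (s).
#' @param frames precomputed [sessionFrames()].
#' @param nShuffles label shuffles for the score null.
#' @param seed RNG seed.
#' @param minSpikes per-context spike minimum (default 20).
#' @param minSharedFraction minimum shared-valid-pixel fraction (default
#'   0.3).
#' @return list(analyzable, contexts, pearson_r, centroid_distance_m, score,
#'   score_null, shared_fraction, n_spikes), or analyzable = FALSE with a
#'   reason.
#' @export
contextPair2D <- function(sess, spikes, frames = NULL, nShuffles = 1000,
                          seed = 1, minSpikes = 20, minSharedFraction = 0.3) {
  if (is.null(frames)) frames <- sessionFrames(sess)
  p <- sess@config@params
  fl <- frames$flights
  if (nrow(fl) == 0) return(list(analyzable = FALSE, reason = "no flights"))
  sched <- sess@schedule
  configOf <- function(t) {
    rows <- sched[sched$start_s <= t & sched$end_s > t, , drop = FALSE]
    if (nrow(rows) == 0) return(NA_character_)
    rows <- rows[order(rows$human), ]
    paste(paste0(rows$human, "@", rows$tripod), collapse = "|")
  }
  ctxLab <- vapply(fl$start_s, configOf, character(1))
  ok <- !is.na(ctxLab)
  fl <- fl[ok, , drop = FALSE]; ctxLab <- ctxLab[ok]
  buildMap <- function(sel) {
    eps <- data.frame(start = fl$start_s[sel], end = fl$end_s[sel])
    rateMap2D(frames$bat, eps, spikes, frames$geometry@extent, p$binSize,
              p$occCutoffBat, p$smoothSigma2D)
  }
  labs <- unique(ctxLab)
  occ <- vapply(labs, function(l)
    sum(fl$end_s[ctxLab == l] - fl$start_s[ctxLab == l]), numeric(1))
  spk <- vapply(labs, function(l) {
    sel <- ctxLab == l
    sum(vapply(which(sel), function(i)
      sum(spikes >= fl$start_s[i] & spikes <= fl$end_s[i]), numeric(1)))
  }, numeric(1))
  cand <- labs[spk >= minSpikes]
  if (length(cand) < 2)
    return(list(analyzable = FALSE, reason = "fewer than 2 contexts with enough spikes"))
  top <- cand[order(occ[match(cand, labs)], decreasing = TRUE)][1:2]
  m1 <- buildMap(ctxLab == top[1]); m2 <- buildMap(ctxLab == top[2])
  shared <- sum(m1@valid & m2@valid) / sum(m1@valid | m2@valid)
  if (shared < minSharedFraction)
    return(list(analyzable = FALSE, reason = "shared valid fraction below 0.3",
                shared_fraction = shared))
  common <- m1@valid & m2@valid
  r <- if (sum(common) >= 3 && sd(m1@rate[common]) > 0 &&
           sd(m2@rate[common]) > 0) cor(m1@rate[common], m2@rate[common])
       else NA_real_
  cd <- sqrt(sum((mapCentroid(m1) - mapCentroid(m2))^2))
  sc <- remappingScore(m1@meanRate, m2@meanRate)
  # context-label shuffle null for the score
  sel12 <- ctxLab %in% top
  fl2 <- fl[sel12, , drop = FALSE]
  lab2 <- ctxLab[sel12]
  nSpk <- vapply(seq_len(nrow(fl2)), function(i)
    sum(spikes >= fl2$start_s[i] & spikes <= fl2$end_s[i]), numeric(1))
  dur <- fl2$end_s - fl2$start_s
  null <- withSeed(seed, vapply(seq_len(nShuffles), function(k) {
    lab <- sample(lab2)
    remappingScore(sum(nSpk[lab == top[1]]) / sum(dur[lab == top[1]]),
                   sum(nSpk[lab == top[2]]) / sum(dur[lab == top[2]]))
  }, numeric(1)))
  list(analyzable = TRUE, contexts = top, pearson_r = r,
       centroid_distance_m = cd, score = sc, score_null = null,
       shared_fraction = shared,
       n_spikes = spk[match(top, labs)], maps = list(m1, m2))
}

# Build a 1D map for a subset of already-linearized flights, keeping the
# full cluster's template length so maps stay bin-comparable.
map1DSubset <- function(lin, idx, binSize = 0.15, sigma = 1.0, spikes) {
  sub <- list(flights = lin$flights[idx], templateLength = lin$templateLength)
  ctx <- mapContext1D(sub, binSize, sigma)
  rateMapFromContext(ctx, spikes)
}

#' Even/odd flight split stability of a 1D field
#'
#' 1D maps are computed separately on even- and odd-numbered flights of a
#' trajectory (sharing the full cluster's binning) and compared by Spearman
#' correlation over common valid bins.
#'
#' @param series the flying bat's [TrackedSeries-class].
#' @param flights data.frame(start_s, end_s) for the trajectory, in order.
#' @param spikes spike times (s).
#' @param config an [AnalysisConfig-class].
#' @return list(spearman_r, n_common_bins, analyzable).
#' @export
stabilityEvenOdd <- function(series, flights, spikes,
                             config = analysisConfig()) {
  p <- config@params
  if (nrow(flights) < 4)
    return(list(spearman_r = NA_real_, n_common_bins = 0, analyzable = FALSE))
  lin <- linearizeFlights(series, flights)
  nf <- length(lin$flights)
  odd <- seq(1, nf, by = 2); even <- seq(2, nf, by = 2)
  mo <- map1DSubset(lin, odd, p$binSize, p$smoothSigma1D, spikes)
  me <- map1DSubset(lin, even, p$binSize, p$smoothSigma1D, spikes)
  if (mo@nSpikes == 0 || me@nSpikes == 0)
    return(list(spearman_r = NA_real_, n_common_bins = 0, analyzable = FALSE))
  common <- mo@valid & me@valid
  r <- if (sum(common) >= 3) suppressWarnings(
    cor(mo@rate[common], me@rate[common], method = "spearman")) else NA_real_
  list(spearman_r = r, n_common_bins = sum(common), analyzable = TRUE)
}

#' First-half vs second-half temporal stability with a random-split null
#'
#' The empirical statistic is the correlation between 1D maps built from the
#' first and second halves of a trajectory's flights (to a given human, in
#' session order). The null repeats the correlation for random half-splits:
#' a stationary modulation lands inside the null, a drifting one below it.
#'
#' @param series the flying bat's [TrackedSeries-class].
#' @param flights data.frame(start_s, end_s), time-ordered.
#' @param spikes spike times (s).
#' @param nShuffles random splits (default 200).
#' @param seed RNG seed.
#' @param config an [AnalysisConfig-class].
#' @return list(empirical_r, null_r, analyzable).
#' @export
temporalStabilityHalves <- function(series, flights, spikes, nShuffles = 200,
                                    seed = 1, config = analysisConfig()) {
  p <- config@params
  nf0 <- nrow(flights)
  if (nf0 < 4)       # two flights per half minimum
    return(list(empirical_r = NA_real_, null_r = numeric(0),
                analyzable = FALSE))
  flights <- flights[order(flights$start_s), , drop = FALSE]
  lin <- linearizeFlights(series, flights)
  nf <- length(lin$flights)
  half <- floor(nf / 2)
  splitR <- function(idx1) {
    idx2 <- setdiff(seq_len(nf), idx1)
    m1 <- map1DSubset(lin, idx1, p$binSize, p$smoothSigma1D, spikes)
    m2 <- map1DSubset(lin, idx2, p$binSize, p$smoothSigma1D, spikes)
    common <- m1@valid & m2@valid
    if (sum(common) < 3 || sd(m1@rate[common]) == 0 ||
        sd(m2@rate[common]) == 0) return(NA_real_)
    cor(m1@rate[common], m2@rate[common])
  }
  emp <- splitR(seq_len(half))
  null <- withSeed(seed, vapply(seq_len(nShuffles), function(k)
    splitR(sample(seq_len(nf), half)), numeric(1)))
  list(empirical_r = emp, null_r = null[is.finite(null)], analyzable = TRUE)
}
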