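# Spatial information testing: circular-shift shuffle nulls, significance
# calls, per-frame orchestration, and null calibration.

# Shared core: empirical + shuffled SI for spikes already on the
# concatenated included-behavior timeline.
nullSIConcat <- function(ctx, ct, nShuffles = 1000, seed = 1, minShift = 1) {
  if (ctx$total < 2 * minShift)
    stop("included timeline shorter than twice the minimum shift")
  emp <- siFromCounts(ctx, spikeBinCounts(ctx, ct, concat = TRUE))
  offs <- withSeed(seed, runif(nShuffles, minShift, ctx$total - minShift))
  n <- length(ctx$binIdx)
  C <- matrix(0L, ctx$nbins, nShuffles)
  for (k in seq_len(nShuffles)) {
    sh <- (ct + offs[k]) %% ctx$total
    idx <- pmin(pmax(floor(sh / ctx$dt) + 1L, 1L), n)
    C[, k] <- tabulate(ctx$binIdx[idx], ctx$nbins)
  }
  list(empirical = emp, null = siFromCounts(ctx, C))
}

#' Circular-shift shuffle null for spatial information
#'
#' Spikes inside the included epochs are mapped onto the concatenated
#' (gap-removed) behavioral timeline and shifted circularly by a uniform
#' random offset (minimum 1 s) for each of 1,000 shuffles; the rate map and
#' its spatial information are recomputed per shuffle. Spike count is
#' preserved exactly in every shuffle.
#'
#' @param ctx a context from [mapContext2D()] or [mapContext1D()].
#' @param spikes spike times (s, session clock).
#' @param nShuffles number of shuffles (default 1000).
#' @param seed RNG seed.
#' @param minShift minimum circular offset, s.
#' @return list(empirical, null): empirical SI and the vector of shuffled SI
#'   values (bits/spike).
#' @export
circularShiftNull <- function(ctx, spikes, nShuffles = 1000, seed = 1,
                              minShift = 1) {
  ct <- toConcatTime(spikes, ctx$epochs)
  nullSIConcat(ctx, ct[!is.na(ct)], nShuffles, seed, minShift)
}

#' Significance of an empirical statistic against a shuffle null
#'
#' p = (1 + #\{null >= empirical\}) / (1 + n_null); the statistic is called
#' significant when it exceeds the upper bound of the null distribution (the
#' (1 - alpha/bonferroniN) quantile; alternatively mean + z sd).
#'
#' @param empirical the empirical statistic.
#' @param null numeric vector of null values.
#' @param alpha nominal level (default 0.05).
#' @param bonferroniN correction factor (number of comparisons in the
#'   family; default 1).
#' @param upper "quantile" (default) or "normal" for mean + z sd.
#' @return list(p, significant, threshold, nullMean, normalized): `normalized`
#'   is empirical / mean(null).
#' @export
testSignificance <- function(empirical, null, alpha = 0.05, bonferroniN = 1,
                             upper = c("quantile", "normal")) {
  upper <- match.arg(upper)
  if (bonferroniN < 1) stop("bonferroniN must be >= 1")
  null <- null[is.finite(null)]
  if (!length(null)) stop("empty null distribution")
  p <- (1 + sum(null >= empirical)) / (1 + length(null))
  q <- 1 - alpha / bonferroniN
  thr <- if (upper == "quantile") as.numeric(quantile(null, q))
         else mean(null) + stats::qnorm(q) * sd(null)
  list(p = p, significant = is.finite(empirical) && empirical > thr,
       threshold = thr, nullMean = mean(null),
       normalized = empirical / mean(null))
}

#' Precompute the per-session behavioral frames for SI analyses
#'
#' Runs smoothing and segmentation once per session: recorded-bat flights and
#' trajectory clusters, conspecific flights/clusters (when a second bat is
#' tracked), preferred resting location and rest mask, and per-human
#' traverses with buffered feed/handling exclusions.
#'
#' @param sess a [Session-class].
#' @return an opaque list consumed by [siByFrame()] and the pipeline.
#' @export
sessionFrames <- function(sess) {
  cfg <- sess@config
  p <- cfg@params
  geom <- sess@geometry
  bat <- smoothBatPositions(sess@bats[[1]])
  other <- if (length(sess@bats) > 1)
    smoothBatPositions(sess@bats[[2]]) else NULL
  flights <- segmentFlights(bat, geom, sess@schedule, other, cfg)
  clusters <- NULL
  if (nrow(flights) > 0) {
    paths <- flightPaths(bat, flights)
    clusters <- clusterFlights(paths, p$linkageDistance, p$linkageMethod)
  }
  rests <- detectRestLocations(bat, p$restVThresh, p$restK, seed = p$seed)
  restM <- restMask(bat, as.numeric(rests[1, 1:3]), p$restVThresh,
                    p$restDistMax)

  otherFlights <- NULL; otherClusters <- NULL
  if (!is.null(other)) {
    otherFlights <- segmentFlights(other, geom, sess@schedule, NULL, cfg)
    if (nrow(otherFlights) > 0) {
      op <- flightPaths(other, otherFlights)
      otherClusters <- clusterFlights(op, p$linkageDistance, p$linkageMethod)
    }
  }

  traverses <- list()
  for (h in names(sess@humans)) {
    coat <- smoothHumanCoat(sess@humans[[h]]$coat)
    ev <- sess@events[sess@events$human == h, , drop = FALSE]
    sp <- if (nrow(ev)) mergeIntervals(data.frame(
      start = ev$start_s - p$handlingBufferS,
      end = ev$end_s + p$handlingBufferS)) else NULL
    tr <- segmentTraverses(coat, geom@traverseStart, cfg, excludedSpans = sp)
    traverses[[h]] <- list(coat = coat, epochs = tr,
                           excluded = sp %||% data.frame(start = numeric(0),
                                                         end = numeric(0)))
  }
  list(bat = bat, other = other, flights = flights, clusters = clusters,
       otherFlights = otherFlights, otherClusters = otherClusters,
       rests = rests, restMask = restM, traverses = traverses, config = cfg,
       geometry = geom)
}

# Extract per-flight position matrices.
flightPaths <- function(series, flights) {
  ts <- series@timestamps
  lapply(seq_len(nrow(flights)), function(i)
    series@xyz[ts >= flights$start_s[i] & ts <= flights$end_s[i], ,
               drop = FALSE])
}

# Intervals during which a logical per-sample mask is TRUE.
maskIntervals <- function(series, mask) {
  runs <- thresholdRuns(mask)
  if (nrow(runs) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  data.frame(start = series@timestamps[runs$i0],
             end = series@timestamps[runs$i1])
}

# Set difference of interval lists: a \ b.
subtractIntervals <- function(a, b) {
  if (is.null(b) || nrow(b) == 0) return(a)
  b <- mergeIntervals(b)
  out <- list()
  for (i in seq_len(nrow(a))) {
    s <- a$start[i]; e <- a$end[i]
    cur <- s
    for (j in seq_len(nrow(b))) {
      if (b$end[j] <= cur || b$start[j] >= e) next
      if (b$start[j] > cur)
        out[[length(out) + 1]] <- data.frame(start = cur, end = b$start[j])
      cur <- max(cur, b$end[j])
    }
    if (cur < e) out[[length(out) + 1]] <- data.frame(start = cur, end = e)
  }
  if (!length(out)) return(data.frame(start = numeric(0), end = numeric(0)))
  do.call(rbind, out)
}

# Intersection of two interval lists.
intersectIntervals <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
    if (e > s) out[[length(out) + 1]] <- data.frame(start = s, end = e)
  }
  if (!length(out)) return(data.frame(start = numeric(0), end = numeric(0)))
  mergeIntervals(do.call(rbind, out))
}

#' Spatial information tests for one unit in a given reference frame
#'
#' Frames:
#' \describe{
#'   \item{self_2d}{2D map of the recorded bat's own flight positions.
#'     Inclusion: session mean rate >= 0.2 Hz, >= 12 flights, >= 5 flights
#'     with >= 5 spikes. One test per unit (Bonferroni n = 1).}
#'   \item{self_1d}{1D linearized maps per trajectory cluster. Inclusion per
#'     trajectory: >= 7 flights, >= 4 with spikes, >= 15 spikes. Bonferroni
#'     over the trajectories examined.}
#'   \item{conspecific_1d}{1D maps built from the conspecific's trajectories
#'     (flown while the recorded bat rests) and the recorded unit's spikes.}
#'   \item{human_2d_pooled}{2D map of human coat position during traverses
#'     (both humans pooled), recorded bat at rest, handling spans excluded;
#'     occupancy cutoff 1 s. Inclusion: >= 6 traverses, >= 4 with spikes,
#'     >= 15 spikes.}
#'   \item{human_2d_identity}{as pooled but per human (>= 6 traverses for
#'     that human), Bonferroni over the humans examined.}
#' }
#'
#' @param sess a [Session-class].
#' @param unit a [UnitRecord-class] (or its index in the session).
#' @param frame one of the frames above.
#' @param frames precomputed [sessionFrames()] (recomputed if omitted).
#' @param seed RNG seed for the shuffles.
#' @return data.frame: unit, frame, target, n_trials, empirical_si,
#'   null_mean, p, bonferroni_n, significant, normalized_si. Not-analyzable
#'   targets appear with NA statistics.
#' @export
siByFrame <- function(sess, unit, frame = c("self_2d", "self_1d",
                                            "conspecific_1d",
                                            "human_2d_pooled",
                                            "human_2d_identity"),
                      frames = NULL, seed = NULL) {
  frame <- match.arg(frame)
  if (is.numeric(unit)) unit <- sess@units[[unit]]
  if (is.null(frames)) frames <- sessionFrames(sess)
  p <- sess@config@params
  seed <- seed %||% p$seed
  spikes <- unit@spikes@times
  row0 <- function(target, n) data.frame(
    unit = unit@unitId, frame = frame, target = target, n_trials = n,
    empirical_si = NA_real_, null_mean = NA_real_, p = NA_real_,
    bonferroni_n = NA_real_, significant = NA, normalized_si = NA_real_)
  runTest <- function(ctx, spk, target, n, bonfN, sd) {
    res <- tryCatch(circularShiftNull(ctx, spk, p$nShuffles, sd, p$minShift),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$empirical)) return(row0(target, n))
    tst <- testSignificance(res$empirical, res$null, p$alpha, bonfN,
                            p$nullUpper)
    data.frame(unit = unit@unitId, frame = frame, target = target,
               n_trials = n, empirical_si = res$empirical,
               null_mean = tst$nullMean, p = tst$p, bonferroni_n = bonfN,
               significant = tst$significant, normalized_si = tst$normalized)
  }

  if (frame == "self_2d") {
    fl <- frames$flights
    perFl <- vapply(seq_len(nrow(fl)), function(i)
      sum(spikes >= fl$start_s[i] & spikes <= fl$end_s[i]), numeric(1))
    ok <- unit@meanRate >= p$minRate2D && nrow(fl) >= p$minFlights2D &&
      sum(perFl >= p$minSpikesPerFlight2D) >= p$minFlightsWithSpikes2D
    if (!ok) return(row0("self", nrow(fl)))
    ctx <- mapContext2D(frames$bat,
                        data.frame(start = fl$start_s, end = fl$end_s),
                        frames$geometry@extent, p$binSize, p$occCutoffBat,
                        p$smoothSigma2D)
    return(runTest(ctx, spikes, "self", nrow(fl), 1, seed))
  }

  if (frame %in% c("self_1d", "conspecific_1d")) {
    if (frame == "self_1d") {
      fl <- frames$flights; cl <- frames$clusters; ser <- frames$bat
    } else {
      if (is.null(frames$other) || is.null(frames$otherClusters))
        return(row0("none", 0))
      fl <- frames$otherFlights; cl <- frames$otherClusters
      ser <- frames$other
      # recorded bat must be resting while the conspecific flies
      atRest <- vapply(seq_len(nrow(fl)), function(i) {
        sel <- frames$bat@timestamps >= fl$start_s[i] &
          frames$bat@timestamps <= fl$end_s[i]
        if (!any(sel)) return(FALSE)
        mean(frames$restMask[sel]) > 0.9
      }, logical(1))
      fl <- fl[atRest, , drop = FALSE]; cl <- cl[atRest]
    }
    rows <- list()
    analyzableCl <- integer(0)
    for (k in sort(unique(cl))) {
      sub <- fl[cl == k, , drop = FALSE]
      if (analyzable1D(sub, spikes, p$minFlights1D, p$minFlightsWithSpikes1D,
                       p$minSpikes1D))
        analyzableCl <- c(analyzableCl, k)
    }
    bonfN <- max(1, length(analyzableCl))
    for (k in sort(unique(cl))) {
      sub <- fl[cl == k, , drop = FALSE]
      if (!(k %in% analyzableCl)) {
        rows[[length(rows) + 1]] <- row0(paste0("traj", k), nrow(sub))
        next
      }
      lin <- linearizeFlights(ser, sub)
      ctx <- mapContext1D(lin, p$binSize, p$smoothSigma1D)
      rows[[length(rows) + 1]] <- runTest(ctx, spikes, paste0("traj", k),
                                          nrow(sub), bonfN,
                                          deriveSeed(seed, k))
    }
    return(do.call(rbind, rows))
  }

  # human-frame 2D maps
  trv <- frames$traverses
  restIv <- maskIntervals(frames$bat, frames$restMask)
  humanCtxInput <- function(hs) {
    eps <- list(); segs <- list()
    for (h in hs) {
      te <- trv[[h]]$epochs
      if (nrow(te) == 0) next
      iv <- subtractIntervals(data.frame(start = te$start_s, end = te$end_s),
                              trv[[h]]$excluded)
      iv <- intersectIntervals(iv, restIv)
      if (nrow(iv) == 0) next
      eps[[length(eps) + 1]] <- iv
      coat <- trv[[h]]$coat
      for (i in seq_len(nrow(iv))) {
        sel <- coat@timestamps >= iv$start[i] & coat@timestamps <= iv$end[i]
        segs[[length(segs) + 1]] <- list(t = coat@timestamps[sel],
                                         p = coat@xyz[sel, , drop = FALSE])
      }
    }
    if (!length(segs)) return(NULL)
    ord <- order(vapply(segs, function(s) s$t[1], numeric(1)))
    ts <- unlist(lapply(segs[ord], function(s) s$t))
    xyz <- do.call(rbind, lapply(segs[ord], function(s) s$p))
    list(series = trackedSeries("human_pool", "coat", ts, xyz),
         epochs = mergeIntervals(do.call(rbind, eps)))
  }
  traverseSpikeStats <- function(h) {
    te <- trv[[h]]$epochs
    if (nrow(te) == 0) return(c(0, 0, 0))
    perTr <- vapply(seq_len(nrow(te)), function(i)
      sum(spikes >= te$start_s[i] & spikes <= te$end_s[i]), numeric(1))
    c(nrow(te), sum(perTr > 0), sum(perTr))
  }

  if (frame == "human_2d_pooled") {
    st <- Reduce(`+`, lapply(names(trv), traverseSpikeStats))
    ok <- st[1] >= p$minTraversesHuman && st[2] >= p$minTraversesWithSpikes &&
      st[3] >= p$minSpikesHuman
    if (!ok) return(row0("pooled", st[1]))
    inp <- humanCtxInput(names(trv))
    if (is.null(inp)) return(row0("pooled", st[1]))
    ctx <- mapContext2D(inp$series, inp$epochs, frames$geometry@extent,
                        p$binSize, p$occCutoffHuman, p$smoothSigma2D)
    return(runTest(ctx, spikes, "pooled", st[1], 1, seed))
  }

  # human_2d_identity: one test per human, Bonferroni over humans examined
  stats <- lapply(names(trv), traverseSpikeStats)
  names(stats) <- names(trv)
  okH <- vapply(stats, function(st)
    st[1] >= p$minTraversesHuman && st[2] >= p$minTraversesWithSpikes &&
      st[3] >= p$minSpikesHuman, logical(1))
  bonfN <- max(1, sum(okH))
  rows <- list()
  for (h in names(trv)) {
    if (!okH[[h]]) { rows[[length(rows) + 1]] <- row0(h, stats[[h]][1]); next }
    inp <- humanCtxInput(h)
    if (is.null(inp)) { rows[[length(rows) + 1]] <- row0(h, stats[[h]][1]); next }
    ctx <- mapContext2D(inp$series, inp$epochs, frames$geometry@extent,
                        p$binSize, p$occCutoffHuman, p$smoothSigma2D)
    rows[[length(rows) + 1]] <- runTest(ctx, spikes, h, stats[[h]][1], bonfN,
                                        deriveSeed(seed, match(h, names(trv))))
  }
  do.call(rbind, rows)
}

#' Preferred vs non-preferred human: paired normalized SI comparison
#'
#' For units whose human-frame SI is significant for exactly one human, the
#' normalized SI for that (preferred) human is compared to the normalized SI
#' for the other human with a two-sided Wilcoxon signed-rank test.
#'
#' @param preferred,nonpreferred paired normalized SI values, one pair per
#'   one-human unit.
#' @return list(n, medianPreferred, medianNonpreferred, p, statistic); p is
#'   NA (descriptive only) with fewer than 5 pairs.
#' @export
preferredVsNonpreferred <- function(preferred, nonpreferred) {
  stopifnot(length(preferred) == length(nonpreferred))
  keep <- is.finite(preferred) & is.finite(nonpreferred)
  preferred <- preferred[keep]; nonpreferred <- nonpreferred[keep]
  n <- length(preferred)
  out <- list(n = n, medianPreferred = median(preferred),
              medianNonpreferred = median(nonpreferred),
              p = NA_real_, statistic = NA_real_)
  if (n >= 5) {
    if (all(preferred == nonpreferred)) {  # degenerate: no paired differences
      out$p <- 1
      out$statistic <- 0
    } else {
      wt <- suppressWarnings(wilcox.test(preferred, nonpreferred,
                                         paired = TRUE, exact = FALSE))
      out$p <- wt$p.value
      out$statistic <- unname(wt$statistic)
    }
  }
  out
}

#' Calibration of the SI shuffle test on homogeneous-Poisson null units
#'
#' Simulates `nUnits` units with constant-rate Poisson spiking (no spatial
#' tuning) over a fixed behavioral context, runs the circular-shift SI test
#' for each, and reports how many empirical SI values stay at or below the
#' upper bound (95th percentile) of their own null distribution. Under the
#' null this should be about 95% of units.
#'
#' @param ctx a map context ([mapContext2D()] over the session's flights).
#' @param nUnits number of simulated null units (>= 1000 for calibration).
#' @param rate constant firing rate, Hz.
#' @param nShuffles shuffles per unit.
#' @param seed RNG seed.
#' @param alpha criterion level (default 0.05).
#' @return data.frame(empirical_si, upper, exceeded), one row per unit.
#' @export
calibrateSINull <- function(ctx, nUnits = 1000, rate = 1, nShuffles = 1000,
                            seed = 1, alpha = 0.05) {
  rows <- vector("list", nUnits)
  for (u in seq_len(nUnits)) {
    sd1 <- deriveSeed(seed, u)
    ct <- withSeed(sd1, {
      n <- rpois(1, rate * ctx$total)
      sort(runif(n, 0, ctx$total))
    })
    res <- nullSIConcat(ctx, ct, nShuffles, deriveSeed(seed, u, 7L))
    up <- as.numeric(quantile(res$null, 1 - alpha, na.rm = TRUE))
    rows[[u]] <- c(res$empirical, up)
  }
  m <- do.call(rbind, rows)
  data.frame(empirical_si = m[, 1], upper = m[, 2],
             exceeded = is.finite(m[, 1]) & m[, 1] > m[, 2])
}
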