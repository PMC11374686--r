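# Preprocessing and behavioral segmentation: flights, rests, traverses.

#' Central-difference speed for a tracked series
#'
#' Velocity is the norm of the 3D central difference of (smoothed) positions;
#' endpoints use one-sided differences. A constant-position series has
#' identically zero speed. For median-filtered streams (whose sample-to-
#' sample steps are noise-dominated) a wider half-window keeps the estimate
#' stable; the coat tag uses 0.25 s.
#'
#' @param series a [TrackedSeries-class].
#' @param halfWindow half-width of the central difference, s (default one
#'   sample).
#' @return the series with its `velocity` slot filled.
#' @export
computeVelocity <- function(series, halfWindow = 0) {
  series@velocity <- rowNorms(axisVelocity(series, halfWindow))
  series
}

# Per-axis central-difference velocity, n x 3 (m/s).
axisVelocity <- function(series, halfWindow = 0) {
  ts <- series@timestamps
  p <- series@xyz
  n <- length(ts)
  if (n < 2) return(matrix(0, n, 3))
  dt0 <- median(diff(ts))
  k <- max(1L, round(halfWindow / dt0))
  v <- matrix(0, n, 3)
  if (n > 2 * k) {
    mid <- seq(k + 1, n - k)
    dt <- ts[mid + k] - ts[mid - k]
    v[mid, ] <- (p[mid + k, , drop = FALSE] - p[mid - k, , drop = FALSE]) / dt
    v[seq_len(k), ] <- matrix(rep(v[k + 1, ], each = k), k, 3)
    v[seq(n - k + 1, n), ] <- matrix(rep(v[n - k, ], each = k), k, 3)
  } else {
    v[2:(n - 1), ] <- (p[3:n, , drop = FALSE] -
                         p[1:(n - 2), , drop = FALSE]) /
      (ts[3:n] - ts[1:(n - 2)])
    v[1, ] <- (p[2, ] - p[1, ]) / (ts[2] - ts[1])
    v[n, ] <- (p[n, ] - p[n - 1, ]) / (ts[n] - ts[n - 1])
  }
  v
}

#' Smooth bat positions by local quadratic regression (1-s window)
#'
#' Savitzky-Golay filtering (polynomial order 2) over a centered window is
#' exactly a local quadratic least-squares fit with uniform weights, so an
#' exactly quadratic path is reproduced to machine precision.
#'
#' @param series a [TrackedSeries-class].
#' @param window window length in seconds (default 1).
#' @return the smoothed series (velocity recomputed).
#' @export
smoothBatPositions <- function(series, window = 1.0) {
  ts <- series@timestamps
  if (length(ts) < 2 || diff(range(ts)) < window)
    stop("series shorter than the smoothing window")
  dt <- median(diff(ts))
  n <- round(window / dt)
  if (n %% 2 == 0) n <- n + 1
  n <- max(n, 5)
  if (n > length(ts)) stop("smoothing window longer than the series")
  for (j in 1:3) series@xyz[, j] <- signal::sgolayfilt(series@xyz[, j],
                                                       p = 2, n = n)
  computeVelocity(series)
}

#' Smooth a human coat-tag series with a 2-s moving median
#'
#' @param series the coat-pocket [TrackedSeries-class].
#' @param window window length in seconds (default 2).
#' @return the smoothed series (velocity recomputed).
#' @export
smoothHumanCoat <- function(series, window = 2.0) {
  ts <- series@timestamps
  if (length(ts) < 3 || diff(range(ts)) < window)
    stop("series shorter than the smoothing window")
  dt <- median(diff(ts))
  n <- round(window / dt)
  if (n %% 2 == 0) n <- n + 1
  for (j in 1:3) series@xyz[, j] <- as.numeric(
    stats::runmed(series@xyz[, j], n, endrule = "median"))
  computeVelocity(series, halfWindow = 0.1)
}

#' Segment a bat's session into flight epochs
#'
#' Runs of speed above the 0.5 m/s flight threshold are merged when separated
#' by less than 0.3 s, then extended at both ends to the nearest sample where
#' every axis velocity has converged to (near) zero (|v| < 0.05 m/s per axis,
#' the automated stand-in for manual endpoint trimming). The landing (and
#' take-off) location is the nearest tripod within 2 m, if any; the human at
#' each location is looked up in the block schedule.
#'
#' @param series the recorded bat's smoothed [TrackedSeries-class] (velocity
#'   is computed if absent).
#' @param geometry a [RoomGeometry-class].
#' @param schedule optional block schedule data.frame(start_s, end_s, human,
#'   tripod).
#' @param otherBat optional conspecific [TrackedSeries-class]; fills
#'   `conspecific_present`.
#' @param config an [AnalysisConfig-class].
#' @return data.frame, one row per flight: start_s, end_s, takeoff_x/y/z,
#'   landing_x/y/z, takeoff_tripod, landing_tripod, human_at_takeoff,
#'   human_at_landing, conspecific_present.
#' @export
segmentFlights <- function(series, geometry, schedule = NULL, otherBat = NULL,
                           config = analysisConfig()) {
  if (!length(series@velocity)) series <- computeVelocity(series)
  p <- config@params
  ts <- series@timestamps
  v <- series@velocity
  va <- axisVelocity(series)
  calm <- rowSums(abs(va) < p$trimVThresh) == 3

  runs <- thresholdRuns(v > p$flightVThresh)
  if (nrow(runs) == 0) return(emptyFlights())
  # merge runs separated by < mergeGap seconds
  merged <- list(runs[1, ])
  for (i in seq_len(nrow(runs))[-1]) {
    last <- merged[[length(merged)]]
    if (ts[runs$i0[i]] - ts[last$i1] < p$mergeGap) {
      last$i1 <- runs$i1[i]
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1]] <- runs[i, ]
  }

  rows <- lapply(merged, function(r) {
    js <- r$i0
    while (js > 1 && !calm[js]) js <- js - 1
    je <- r$i1
    while (je < length(ts) && !calm[je]) je <- je + 1
    toff <- series@xyz[js, ]
    land <- series@xyz[je, ]
    data.frame(start_s = ts[js], end_s = ts[je],
               takeoff_x = toff[1], takeoff_y = toff[2], takeoff_z = toff[3],
               landing_x = land[1], landing_y = land[2], landing_z = land[3],
               takeoff_tripod = nearestTripod(toff, geometry, p$restDistMax),
               landing_tripod = nearestTripod(land, geometry, p$restDistMax))
  })
  fl <- do.call(rbind, rows)
  fl <- fl[!duplicated(fl$start_s), , drop = FALSE]
  fl$human_at_takeoff <- humanAtTripod(schedule, fl$takeoff_tripod, fl$start_s)
  fl$human_at_landing <- humanAtTripod(schedule, fl$landing_tripod, fl$end_s)
  fl$conspecific_present <- NA
  if (!is.null(otherBat)) {
    for (i in seq_len(nrow(fl))) {
      tp <- fl$landing_tripod[i]
      if (!is.na(tp)) {
        fl$conspecific_present[i] <- conspecificPresence(
          otherBat, geometry@tripods[tp, ], fl$end_s[i], config = config)
      }
    }
  }
  rownames(fl) <- NULL
  fl
}

emptyFlights <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0),
             takeoff_x = numeric(0), takeoff_y = numeric(0),
             takeoff_z = numeric(0), landing_x = numeric(0),
             landing_y = numeric(0), landing_z = numeric(0),
             takeoff_tripod = character(0), landing_tripod = character(0),
             human_at_takeoff = character(0), human_at_landing = character(0),
             conspecific_present = logical(0))
}

thresholdRuns <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(i0 = starts[r$values], i1 = ends[r$values])
}

nearestTripod <- function(xyz, geometry, distMax) {
  tp <- geometry@tripods
  d <- sqrt(colSums((t(tp) - xyz)^2))
  i <- which.min(d)
  if (length(i) && d[i] < distMax) rownames(tp)[i] else NA_character_
}

humanAtTripod <- function(schedule, tripod, time) {
  out <- rep(NA_character_, length(tripod))
  if (is.null(schedule) || nrow(schedule) == 0) return(out)
  for (i in seq_along(tripod)) {
    if (is.na(tripod[i])) next
    hit <- schedule$tripod == tripod[i] & schedule$start_s <= time[i] &
      schedule$end_s > time[i]
    if (any(hit)) out[i] <- schedule$human[which(hit)[1]]
  }
  out
}

#' Detect preferred resting locations by k-means on sub-threshold positions
#'
#' @param series the bat's smoothed [TrackedSeries-class].
#' @param vThresh rest velocity threshold, m/s (default 0.4).
#' @param k number of clusters (default 2: bats rest almost exclusively in
#'   two upper corners).
#' @param seed RNG seed for k-means starts.
#' @return data.frame(x, y, z, n) of centroids, sorted by membership count.
#' @export
detectRestLocations <- function(series, vThresh = 0.4, k = 2, seed = 1) {
  if (!length(series@velocity)) series <- computeVelocity(series)
  pts <- series@xyz[series@velocity < vThresh, , drop = FALSE]
  if (nrow(pts) == 0) stop("no sub-threshold samples to cluster")
  k <- min(k, nrow(unique(pts)))
  km <- withSeed(seed, kmeans(pts, centers = k, nstart = 10))
  ord <- order(km$size, decreasing = TRUE)
  data.frame(x = km$centers[ord, 1], y = km$centers[ord, 2],
             z = km$centers[ord, 3], n = km$size[ord], row.names = NULL)
}

#' Mask of samples where the bat is at rest near a centroid
#'
#' True where speed is below 0.4 m/s and the Euclidean distance to the
#' resting-location centroid is below 200 cm.
#'
#' @param series the bat's smoothed [TrackedSeries-class].
#' @param centroid numeric(3), resting centroid.
#' @param vThresh rest velocity threshold, m/s.
#' @param distMax max distance to the centroid, m.
#' @return logical vector, one element per sample.
#' @export
restMask <- function(series, centroid, vThresh = 0.4, distMax = 2.0) {
  if (!length(series@velocity)) series <- computeVelocity(series)
  d <- sqrt(colSums((t(series@xyz) - as.numeric(centroid))^2))
  series@velocity < vThresh & d < distMax
}

#' Segment human traverses from the coat-tag series
#'
#' A traverse starts when the coat tag's speed exceeds 0.4 m/s while the
#' human is within 0.1 m (xy) of the traverse start position, and ends at the
#' first time more than 12 s later when speed is below 0.4 m/s within 0.3 m
#' (xy) of the start position. Traverses in which speed dips below 0.2 m/s
#' mid-traverse (outside any excluded feed/handling span) are discarded;
#' walks that never return to the start yield no epoch.
#'
#' @param series the smoothed coat [TrackedSeries-class].
#' @param traverseStart numeric(3) (only xy used).
#' @param config an [AnalysisConfig-class].
#' @param excludedSpans optional data.frame(start, end) of spans whose
#'   low-speed samples are tolerated (feeding/handling pauses).
#' @return data.frame(start_s, end_s, human).
#' @export
segmentTraverses <- function(series, traverseStart, config = analysisConfig(),
                             excludedSpans = NULL) {
  if (is.null(traverseStart)) stop("traverseStart is required")
  p <- config@params
  if (!length(series@velocity)) series <- computeVelocity(series)
  ts <- series@timestamps
  v <- series@velocity
  dxy <- sqrt((series@xyz[, 1] - traverseStart[1])^2 +
              (series@xyz[, 2] - traverseStart[2])^2)
  inExcluded <- rep(FALSE, length(ts))
  if (!is.null(excludedSpans) && nrow(excludedSpans)) {
    for (i in seq_len(nrow(excludedSpans)))
      inExcluded <- inExcluded |
        (ts >= excludedSpans$start[i] & ts <= excludedSpans$end[i])
  }

  out <- list()
  i <- 2
  n <- length(ts)
  while (i <= n) {
    isStart <- v[i] > p$traverseVThresh && v[i - 1] <= p$traverseVThresh &&
      dxy[i] < p$traverseStartDist
    if (!isStart) { i <- i + 1; next }
    after <- which(ts > ts[i] + p$traverseMinDur & v < p$traverseVThresh &
                     dxy < p$traverseEndDist)
    after <- after[after > i]
    if (!length(after)) { # open traverse: never returned to the start
      message(sprintf("open traverse at t=%.1f s discarded", ts[i]))
      i <- i + 1
      while (i <= n && v[i] > p$traverseVThresh) i <- i + 1
      next
    }
    j <- after[1]
    mid <- seq(i + 1, j - 1)
    dipped <- any(v[mid] < p$traverseDipThresh & !inExcluded[mid])
    if (!dipped) {
      out[[length(out) + 1]] <- data.frame(
        start_s = ts[i], end_s = ts[j], human = series@subjectId)
    } else {
      message(sprintf("traverse at t=%.1f s discarded (mid-traverse stop)",
                      ts[i]))
    }
    i <- j + 1
  }
  if (!length(out))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      human = character(0)))
  do.call(rbind, out)
}

#' Buffer feeding/handling events into excluded spans within a traverse
#'
#' Each event interval is extended by 100 positional samples (1 s at the
#' nominal 100 Hz, applied in time units) on both sides; overlapping spans
#' are merged and clipped to the traverse.
#'
#' @param traverse one row of [segmentTraverses()] output (or a list with
#'   start_s, end_s).
#' @param events data.frame(start_s, end_s) of hand-tag event intervals.
#' @param buffer buffer in seconds (default 1).
#' @return data.frame(start, end) of excluded spans.
#' @export
excludeHandling <- function(traverse, events, buffer = 1.0) {
  if (is.null(events) || nrow(events) == 0)
    return(data.frame(start = numeric(0), end = numeric(0)))
  if (any(events$start_s < traverse$start_s - 1e-9 |
          events$end_s > traverse$end_s + 1e-9))
    stop("handling event outside the traverse epoch")
  iv <- data.frame(start = pmax(events$start_s - buffer, traverse$start_s),
                   end = pmin(events$end_s + buffer, traverse$end_s))
  mergeIntervals(iv)
}

#' Is the conspecific present at a landing location at a given time?
#'
#' True when the other bat is within 200 cm of the tripod and its speed is
#' below the 0.4 m/s threshold at the landing time. Returns NA (unknown) when
#' the other bat is untracked around that time; such trials are excluded
#' downstream.
#'
#' @param otherBat the conspecific's [TrackedSeries-class].
#' @param tripodXyz numeric(3).
#' @param tLanding landing time, s.
#' @param distMax presence radius, m (default 2).
#' @param vThresh m/s (default 0.4).
#' @param config optional [AnalysisConfig-class] overriding the thresholds.
#' @return TRUE/FALSE, or NA if untracked at `tLanding`.
#' @export
conspecificPresence <- function(otherBat, tripodXyz, tLanding, distMax = 2.0,
                                vThresh = 0.4, config = NULL) {
  if (!is.null(config)) {
    distMax <- config@params$restDistMax
    vThresh <- config@params$restVThresh
  }
  if (!length(otherBat@velocity)) otherBat <- computeVelocity(otherBat)
  ts <- otherBat@timestamps
  i <- which.min(abs(ts - tLanding))
  if (!length(i) || abs(ts[i] - tLanding) > 0.5) return(NA)
  d <- sqrt(sum((otherBat@xyz[i, ] - as.numeric(tripodXyz))^2))
  d < distMax && otherBat@velocity[i] < vThresh
}
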