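#' Construct a RoomGeometry
#'
#' @param extent numeric(3), room size in meters; default the 5.6 x 5.2 x
#'   2.5 m flight room.
#' @param tripods n x 3 matrix of tripod positions with labels as rownames.
#' @param traverseStart 3D start point of human traverses.
#' @param restCentroids optional matrix of resting-spot centroids.
#' @return a [RoomGeometry-class].
#' @export
roomGeometry <- function(extent = c(5.6, 5.2, 2.5),
                         tripods = defaultTripods(extent),
                         traverseStart = c(extent[1] / 2, extent[2] / 2, 0),
                         restCentroids = matrix(numeric(0), 0, 3)) {
  new("RoomGeometry", extent = as.numeric(extent),
      tripods = tripods, traverseStart = as.numeric(traverseStart),
      restCentroids = restCentroids)
}

# Four tripods around the room, 0.8 m in from the walls, at 1.4 m height.
defaultTripods <- function(extent = c(5.6, 5.2, 2.5)) {
  m <- rbind(
    T1 = c(0.8, 0.8, 1.4),
    T2 = c(extent[1] - 0.8, 0.8, 1.4),
    T3 = c(extent[1] - 0.8, extent[2] - 0.8, 1.4),
    T4 = c(0.8, extent[2] - 0.8, 1.4)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

#' Construct a TrackedSeries
#'
#' @param subjectId,tagId character labels.
#' @param timestamps seconds, strictly increasing.
#' @param xyz n x 3 matrix, meters.
#' @param velocity optional speed (m/s); computed on demand otherwise.
#' @return a [TrackedSeries-class].
#' @export
trackedSeries <- function(subjectId, tagId, timestamps, xyz,
                          velocity = numeric(0)) {
  new("TrackedSeries", subjectId = as.character(subjectId),
      tagId = as.character(tagId), timestamps = as.numeric(timestamps),
      xyz = as.matrix(xyz), velocity = as.numeric(velocity))
}

#' Construct a SpikeTrain
#'
#' @param unitId character.
#' @param times spike times (s); sorted on construction.
#' @param span session [t0, t1].
#' @return a [SpikeTrain-class].
#' @export
spikeTrain <- function(unitId, times, span) {
  new("SpikeTrain", unitId = as.character(unitId),
      times = sort(as.numeric(times)), span = as.numeric(span))
}

#' Classify a unit as principal cell or interneuron
#'
#' Putative interneurons are units whose session-wide mean firing rate is
#' strictly greater than 5 Hz; all other units are principal cells.
#'
#' @param spikes a [SpikeTrain-class], or a numeric vector of spike times.
#' @param span session span in seconds (taken from the SpikeTrain if given).
#' @return "interneuron" or "principal".
#' @export
classifyUnit <- function(spikes, span = NULL) {
  if (is(spikes, "SpikeTrain")) {
    n <- length(spikes@times)
    dur <- diff(spikes@span)
  } else {
    n <- length(spikes)
    dur <- if (length(span) == 2) diff(span) else span
  }
  if (is.null(dur) || length(dur) != 1 || dur <= 0)
    stop("session span must be positive")
  if (n / dur > 5) "interneuron" else "principal"
}

#' Construct a UnitRecord (spike train + mean rate + classification)
#'
#' @param spikes a [SpikeTrain-class].
#' @return a [UnitRecord-class].
#' @export
unitRecord <- function(spikes) {
  mr <- length(spikes@times) / diff(spikes@span)
  new("UnitRecord", unitId = spikes@unitId, spikes = spikes,
      meanRate = mr, unitClass = classifyUnit(spikes))
}

#' Analysis configuration with the pipeline's default thresholds
#'
#' Defaults (meters, seconds, Hz): flight segmentation at 0.5 m/s with runs
#' merged across gaps < 0.3 s and endpoints trimmed where per-axis |v| <
#' 0.05 m/s; rest at < 0.4 m/s within 2 m of the rest centroid; traverses
#' start at coat speed > 0.4 m/s within 0.1 m of the traverse start, end
#' > 12 s later within 0.3 m of the start, and are discarded if speed dips
#' below 0.2 m/s mid-traverse; rate maps use 0.15 m bins, a sigma = 1.5-bin
#' 2D Gaussian, a 7-tap (sigma = 1 bin) 1D window and occupancy cutoffs of
#' 150 ms (bat frames) / 1 s (human frames); 1000 circular-shift shuffles
#' with a 1 s minimum shift; peri-event windows [-1.75, +0.25] s at take-off
#' and [-0.25, +1.75] s at landing; alpha 0.05; permutation resolution cap
#' 0.02; trajectory linkage distance 1.3 m.
#'
#' @param ... overrides for any parameter, by name.
#' @return an [AnalysisConfig-class].
#' @export
analysisConfig <- function(...) {
  p <- list(
    flightVThresh = 0.5,
    restVThresh = 0.4,
    traverseVThresh = 0.4,
    traverseDipThresh = 0.2,
    restDistMax = 2.0,
    traverseStartDist = 0.1,
    traverseEndDist = 0.3,
    traverseMinDur = 12,
    binSize = 0.15,
    smoothSigma2D = 1.5,
    smoothSigma1D = 1.0,
    occCutoffBat = 0.150,
    occCutoffHuman = 1.0,
    nShuffles = 1000,
    takeoffWindow = c(-1.75, 0.25),
    landingWindow = c(-0.25, 1.75),
    minRate2D = 0.2,
    minFlights2D = 12,
    minFlightsWithSpikes2D = 5,
    minSpikesPerFlight2D = 5,
    minFlights1D = 7,
    minFlightsWithSpikes1D = 4,
    minSpikes1D = 15,
    minTraversesHuman = 6,
    minTraversesWithSpikes = 4,
    minSpikesHuman = 15,
    minTrialsPerHuman = 4,
    minSpikesIdentity = 15,
    minTrialsWithSpikesIdentity = 4,
    alpha = 0.05,
    permResolutionMax = 0.02,
    linkageDistance = 1.3,
    linkageMethod = "single",
    mergeGap = 0.3,
    trimVThresh = 0.05,
    handlingBufferS = 1.0,
    minShift = 1.0,
    nullUpper = "quantile",
    restK = 2,
    seed = 1L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown config parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  new("AnalysisConfig", params = p)
}

#' Get a configuration parameter
#'
#' @param config an [AnalysisConfig-class].
#' @param name parameter name.
#' @return the parameter value.
#' @export
configParam <- function(config, name) {
  v <- config@params[[name]]
  if (is.null(v)) stop("no such config parameter: ", name)
  v
}

#' Assemble a Session
#'
#' @param geometry a [RoomGeometry-class].
#' @param bats list of bat [TrackedSeries-class] (recorded bat first).
#' @param humans named list of 2 humans, each a named list of 3 tag series.
#' @param units list of [UnitRecord-class].
#' @param schedule data.frame(start_s, end_s, human, tripod).
#' @param events data.frame(start_s, end_s, human, kind) of feed/handle
#'   intervals.
#' @param rewardVolumes named numeric, mL per reward per human.
#' @param config an [AnalysisConfig-class].
#' @return a [Session-class].
#' @export
session <- function(geometry, bats, humans, units = list(),
                    schedule, events = emptyEvents(),
                    rewardVolumes = numeric(0),
                    config = analysisConfig()) {
  new("Session", geometry = geometry, bats = bats, humans = humans,
      units = units, schedule = schedule, events = events,
      rewardVolumes = rewardVolumes, config = config)
}

emptyEvents <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0),
             human = character(0), kind = character(0))
}
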