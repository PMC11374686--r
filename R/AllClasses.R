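#' @import methods
#' @importFrom stats approx dnorm kmeans lm anova coef quantile median runif
#'   rpois rbinom cor cor.test wilcox.test sd complete.cases cutree hclust
#'   dist setNames aggregate
#' @importFrom utils head tail combn read.csv write.csv write.table
NULL

#' Room geometry for a recording session
#'
#' Describes the flight room: its extents, the labeled tripod positions where
#' the human experimenters stand, the start point of human traverses, and
#' (optionally) the bats' preferred resting-corner centroids. All coordinates
#' are meters, z-up, origin at a floor corner.
#'
#' @slot extent numeric(3), room size in meters (x, y, z).
#' @slot tripods numeric matrix, one row per tripod (x, y, z), rownames are
#'   the tripod labels.
#' @slot traverseStart numeric(3), where human traverses begin.
#' @slot restCentroids numeric matrix (possibly 0 rows) of resting-spot
#'   centroids.
#' @exportClass RoomGeometry
setClass("RoomGeometry", representation(
  extent = "numeric",
  tripods = "matrix",
  traverseStart = "numeric",
  restCentroids = "matrix"
))

setValidity("RoomGeometry", function(object) {
  msg <- character(0)
  if (length(object@extent) != 3 || any(object@extent <= 0))
    msg <- c(msg, "extent must be 3 positive lengths (m)")
  tp <- object@tripods
  if (ncol(tp) != 3) msg <- c(msg, "tripods must be an n x 3 matrix")
  if (is.null(rownames(tp)) || anyDuplicated(rownames(tp)))
    msg <- c(msg, "tripod labels must be unique rownames")
  inside <- function(p) all(p >= -1e-9) && all(p <= object@extent + 1e-9)
  if (nrow(tp) > 0 && !all(apply(tp, 1, inside)))
    msg <- c(msg, "all tripods must lie inside the room extent")
  if (length(object@traverseStart) != 3 || !inside(object@traverseStart))
    msg <- c(msg, "traverseStart must be a 3D point inside the room")
  if (length(msg)) msg else TRUE
})

#' Uniformly sampled 3D position stream for one subject/tag
#'
#' Position samples (nominally 100 Hz) for one tracked tag, with speed derived
#' by central differencing of the (smoothed) positions. Timestamps are seconds
#' on the common session clock; positions are meters.
#'
#' @slot subjectId character, e.g. "bat1" or "humanA".
#' @slot tagId character, e.g. "coat", "left_hand", "right_hand", "body".
#' @slot timestamps numeric, strictly increasing, seconds.
#' @slot xyz numeric n x 3 matrix, meters.
#' @slot velocity numeric n, speed in m/s (0-length until computed).
#' @exportClass TrackedSeries
setClass("TrackedSeries", representation(
  subjectId = "character",
  tagId = "character",
  timestamps = "numeric",
  xyz = "matrix",
  velocity = "numeric"
))

setValidity("TrackedSeries", function(object) {
  msg <- character(0)
  n <- length(object@timestamps)
  if (n > 1 && any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (anyNA(object@timestamps) || anyNA(object@xyz))
    msg <- c(msg, "timestamps/xyz must not contain NA after preprocessing")
  if (nrow(object@xyz) != n) msg <- c(msg, "xyz must have one row per timestamp")
  if (ncol(object@xyz) != 3) msg <- c(msg, "xyz must have 3 columns")
  if (length(object@velocity) && length(object@velocity) != n)
    msg <- c(msg, "velocity must match timestamps in length")
  if (length(msg)) msg else TRUE
})

#' Sorted spike timestamps for one unit
#'
#' @slot unitId character.
#' @slot times numeric, seconds, ascending, on the session clock.
#' @slot span numeric(2), session [t0, t1] the unit was recorded over.
#' @exportClass SpikeTrain
setClass("SpikeTrain", representation(
  unitId = "character",
  times = "numeric",
  span = "numeric"
))

setValidity("SpikeTrain", function(object) {
  msg <- character(0)
  if (length(object@span) != 2 || diff(object@span) <= 0)
    msg <- c(msg, "span must be [t0, t1] with t1 > t0")
  if (is.unsorted(object@times))
    msg <- c(msg, "spike times must be sorted ascending")
  if (length(object@times) &&
      (min(object@times) < object@span[1] - 1e-9 ||
       max(object@times) > object@span[2] + 1e-9))
    msg <- c(msg, "all spikes must lie within the session span")
  if (length(msg)) msg else TRUE
})

#' One recorded unit with its classification
#'
#' Units with a session-wide mean firing rate strictly above 5 Hz are
#' classified as putative interneurons; all others as principal cells.
#'
#' @slot unitId character.
#' @slot spikes a [SpikeTrain-class].
#' @slot meanRate numeric, Hz (spike count / session duration).
#' @slot unitClass "principal" or "interneuron".
#' @exportClass UnitRecord
setClass("UnitRecord", representation(
  unitId = "character",
  spikes = "SpikeTrain",
  meanRate = "numeric",
  unitClass = "character"
))

setValidity("UnitRecord", function(object) {
  msg <- character(0)
  expect <- length(object@spikes@times) / diff(object@spikes@span)
  if (abs(object@meanRate - expect) > 1e-6)
    msg <- c(msg, "meanRate must equal spike count / session duration")
  if (!object@unitClass %in% c("principal", "interneuron"))
    msg <- c(msg, "unitClass must be principal or interneuron")
  if (object@unitClass != (if (object@meanRate > 5) "interneuron" else "principal"))
    msg <- c(msg, "unitClass inconsistent with the >5 Hz mean-rate rule")
  if (length(msg)) msg else TRUE
})

#' Analysis configuration
#'
#' All thresholds used downstream, in one serializable object. Units are
#' meters, seconds, Hz. Defaults follow the analysis conventions documented
#' in the methods vignette.
#'
#' @slot params named list of parameters; see [analysisConfig()].
#' @exportClass AnalysisConfig
setClass("AnalysisConfig", representation(params = "list"))

setValidity("AnalysisConfig", function(object) {
  p <- object@params
  msg <- character(0)
  pos <- c("flightVThresh", "restVThresh", "traverseVThresh", "traverseDipThresh",
           "restDistMax", "traverseStartDist", "traverseEndDist", "traverseMinDur",
           "binSize", "smoothSigma2D", "smoothSigma1D", "occCutoffBat",
           "occCutoffHuman", "nShuffles", "handlingBufferS", "minShift",
           "linkageDistance", "mergeGap", "trimVThresh", "permResolutionMax")
  for (nm in pos) {
    if (is.null(p[[nm]]) || p[[nm]] <= 0)
      msg <- c(msg, sprintf("%s must be positive", nm))
  }
  if (is.null(p$alpha) || p$alpha <= 0 || p$alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' One recording session
#'
#' Bundles the room geometry, tracked series for up to two bats (the recorded
#' bat first) and exactly two humans (three tags each: coat pocket and both
#' wrists), the sorted units, the 5-minute block schedule stating which human
#' stood at which tripod, optional feed/handling event intervals, and optional
#' reward volumes per human.
#'
#' @slot geometry a [RoomGeometry-class].
#' @slot bats list of [TrackedSeries-class]; element 1 is the recorded bat.
#' @slot humans named list (2 humans), each a named list of 3 TrackedSeries
#'   (tags "coat", "left_hand", "right_hand").
#' @slot units list of [UnitRecord-class].
#' @slot schedule data.frame(start_s, end_s, human, tripod): one row per
#'   human per block.
#' @slot events data.frame(start_s, end_s, human, kind) of feed/handle
#'   intervals (may have 0 rows).
#' @slot rewardVolumes named numeric (mL per reward, per human; may be empty).
#' @slot config an [AnalysisConfig-class].
#' @exportClass Session
setClass("Session", representation(
  geometry = "RoomGeometry",
  bats = "list",
  humans = "list",
  units = "list",
  schedule = "data.frame",
  events = "data.frame",
  rewardVolumes = "numeric",
  config = "AnalysisConfig"
))

setValidity("Session", function(object) {
  msg <- character(0)
  if (length(object@humans) != 2)
    msg <- c(msg, "a session has exactly 2 humans")
  if (length(object@bats) < 1 || length(object@bats) > 2)
    msg <- c(msg, "a session has 1 or 2 bats (recorded bat first)")
  sched <- object@schedule
  need <- c("start_s", "end_s", "human", "tripod")
  if (!all(need %in% names(sched)))
    msg <- c(msg, "schedule needs columns start_s, end_s, human, tripod")
  if (length(msg)) msg else TRUE
})

#' Occupancy-normalized 2D firing rate map
#'
#' 0.15 m square bins over the room's xy plane. Both the spike-count and
#' occupancy maps are smoothed with a Gaussian kernel (sigma = 1.5 bins,
#' truncated at 3 sigma, renormalized over the valid support) and the rate is
#' their bin-by-bin ratio. Bins occupied for less than the cutoff are invalid
#' unless at least one of their 8 neighbors is valid; smoothing never bleeds
#' across invalid bins.
#'
#' @slot binSize numeric, m.
#' @slot origin numeric(2), xy of the (1,1) bin's lower-left corner.
#' @slot occupancy matrix of raw seconds per bin.
#' @slot spikeCount matrix of raw spike counts per bin.
#' @slot smoothedOccupancy matrix (NA outside the valid mask).
#' @slot rate matrix, Hz (NA outside the valid mask).
#' @slot valid logical matrix.
#' @slot meanRate occupancy-weighted mean rate over valid bins, Hz.
#' @slot nSpikes spikes inside the included epochs.
#' @exportClass RateMap2D
setClass("RateMap2D", representation(
  binSize = "numeric",
  origin = "numeric",
  occupancy = "matrix",
  spikeCount = "matrix",
  smoothedOccupancy = "matrix",
  rate = "matrix",
  valid = "matrix",
  meanRate = "numeric",
  nSpikes = "numeric"
))

setValidity("RateMap2D", function(object) {
  msg <- character(0)
  if (any(object@rate[object@valid] < 0, na.rm = TRUE))
    msg <- c(msg, "rates must be non-negative")
  if (any(is.na(object@rate[object@valid])))
    msg <- c(msg, "valid bins must carry a finite rate")
  if (length(msg)) msg else TRUE
})

#' Linearized 1D firing rate map along a flight trajectory
#'
#' Bins of 0.15 m along the rescaled take-off-to-landing axis; spike-count and
#' occupancy vectors smoothed with a 7-tap Gaussian window before the ratio.
#'
#' @slot binSize numeric, m.
#' @slot occupancy numeric, raw seconds per bin.
#' @slot spikeCount numeric, raw counts per bin.
#' @slot smoothedOccupancy numeric.
#' @slot rate numeric, Hz (NA where invalid).
#' @slot valid logical.
#' @slot meanRate numeric, Hz.
#' @slot nSpikes numeric.
#' @slot nFlights numeric, flights contributing to the map.
#' @exportClass RateMap1D
setClass("RateMap1D", representation(
  binSize = "numeric",
  occupancy = "numeric",
  spikeCount = "numeric",
  smoothedOccupancy = "numeric",
  rate = "numeric",
  valid = "logical",
  meanRate = "numeric",
  nSpikes = "numeric",
  nFlights = "numeric"
))

setMethod("show", "RoomGeometry", function(object) {
  cat(sprintf("RoomGeometry %.1f x %.1f x %.1f m, %d tripods\n",
              object@extent[1], object@extent[2], object@extent[3],
              nrow(object@tripods)))
})

setMethod("show", "TrackedSeries", function(object) {
  n <- length(object@timestamps)
  cat(sprintf("TrackedSeries %s/%s: %d samples", object@subjectId,
              object@tagId, n))
  if (n) cat(sprintf(" over %.1f s", diff(range(object@timestamps))))
  cat("\n")
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain %s: %d spikes in [%.1f, %.1f] s\n", object@unitId,
              length(object@times), object@span[1], object@span[2]))
})

setMethod("show", "Session", function(object) {
  cat(sprintf("Session: %d bat(s), %d humans, %d units, %d schedule blocks\n",
              length(object@bats), length(object@humans),
              length(object@units), nrow(object@schedule) / 2))
})

setMethod("show", "RateMap2D", function(object) {
  cat(sprintf(
    "RateMap2D %dx%d bins (%.2f m), %d valid, %d spikes, mean rate %.2f Hz\n",
    nrow(object@rate), ncol(object@rate), object@binSize,
    sum(object@valid), object@nSpikes, object@meanRate))
})

setMethod("show", "RateMap1D", function(object) {
  cat(sprintf(
    "RateMap1D %d bins (%.2f m), %d flights, %d spikes, mean rate %.2f Hz\n",
    length(object@rate), object@binSize, object@nFlights, object@nSpikes,
    object@meanRate))
})
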