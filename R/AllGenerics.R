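#' Skaggs spatial information of a rate map, in bits per spike
#'
#' SI = sum_i (p_i * lambda_i / lambda) * log2(lambda_i / lambda), summed
#' across valid bins, where p_i is the probability of being in bin i (smoothed
#' occupancy, normalized over valid bins), lambda_i the smoothed rate in that
#' bin and lambda the occupancy-weighted mean rate. Bins with lambda_i = 0
#' contribute 0 (x log x limit convention).
#'
#' @param map a [RateMap2D-class] or [RateMap1D-class].
#' @return bits/spike (non-negative), or NA if the mean rate is 0
#'   (not analyzable).
#' @export
setGeneric("spatialInformation", function(map) standardGeneric("spatialInformation"))

#' @describeIn spatialInformation on a 2D map
#' @export
setMethod("spatialInformation", "RateMap2D", function(map) {
  skaggsSI(map@rate[map@valid], map@smoothedOccupancy[map@valid])
})

#' @describeIn spatialInformation on a 1D map
#' @export
setMethod("spatialInformation", "RateMap1D", function(map) {
  skaggsSI(map@rate[map@valid], map@smoothedOccupancy[map@valid])
})

# Accessors -------------------------------------------------------------

#' Accessors for tracked series and spike trains
#'
#' @param x a [TrackedSeries-class] or [SpikeTrain-class].
#' @return `timestamps()`/`spikeTimes()` return seconds; `positions()` an
#'   n x 3 matrix (m); `speed()` m/s; `subjectId()` a character label.
#' @name accessors
NULL

#' @rdname accessors
#' @export
timestamps <- function(x) x@timestamps

#' @rdname accessors
#' @export
positions <- function(x) x@xyz

#' @rdname accessors
#' @export
speed <- function(x) x@velocity

#' @rdname accessors
#' @export
subjectId <- function(x) x@subjectId

#' @rdname accessors
#' @export
spikeTimes <- function(x) {
  if (is(x, "UnitRecord")) x@spikes@times else x@times
}

#' @rdname accessors
#' @export
unitId <- function(x) x@unitId

#' Accessors for rate maps
#'
#' @param map a [RateMap2D-class] or [RateMap1D-class].
#' @return `rateValues()` the smoothed rate (matrix or vector, NA at invalid
#'   bins); `occupancySeconds()` the raw occupancy; `validBins()` the logical
#'   validity mask; `mapMeanRate()` the occupancy-weighted mean rate (Hz).
#' @name map-accessors
NULL

#' @rdname map-accessors
#' @export
rateValues <- function(map) map@rate

#' @rdname map-accessors
#' @export
occupancySeconds <- function(map) map@occupancy

#' @rdname map-accessors
#' @export
validBins <- function(map) map@valid

#' @rdname map-accessors
#' @export
mapMeanRate <- function(map) map@meanRate

#' Accessors for sessions
#'
#' @param session a [Session-class].
#' @param which for `batSeries()`, 1 = recorded bat, 2 = conspecific; for
#'   `humanSeries()`, the human id; `tag` the tag name.
#' @return the requested component.
#' @name session-accessors
NULL

#' @rdname session-accessors
#' @export
sessionGeometry <- function(session) session@geometry

#' @rdname session-accessors
#' @export
batSeries <- function(session, which = 1) {
  if (which > length(session@bats)) NULL else session@bats[[which]]
}

#' @rdname session-accessors
#' @param tag tag name for `humanSeries()`.
#' @export
humanSeries <- function(session, which, tag = "coat") {
  session@humans[[which]][[tag]]
}

#' @rdname session-accessors
#' @export
sessionUnits <- function(session) session@units

#' @rdname session-accessors
#' @export
sessionSchedule <- function(session) session@schedule

#' @rdname session-accessors
#' @export
sessionConfig <- function(session) session@config

#' @rdname session-accessors
#' @export
humanIds <- function(session) names(session@humans)

#' @rdname session-accessors
#' @export
sessionSpan <- function(session) {
  ts <- session@bats[[1]]@timestamps
  c(ts[1], ts[length(ts)])
}
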