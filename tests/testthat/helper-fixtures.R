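# Shared fixtures, generated once per test run and cached in-process.

.fixtures <- new.env(parent = emptyenv())

# A small 2-block session (32 flight legs, 2 traverses per human) with four
# canonical units: homogeneous null, self-frame place field, identity gain 3
# at one tripod, human-position field on human 1's arc.
smallSim <- function() {
  if (is.null(.fixtures$smallSim)) {
    pp <- synthParams(nBlocks = 2)
    geom <- synthGeometry(pp)
    ctrl <- (geom@traverseStart + pp$feedPoint) / 2 + c(pp$arcBow, 0, 0)
    u <- 0.3
    arcPt <- (1 - u)^2 * geom@traverseStart + 2 * u * (1 - u) * ctrl +
      u^2 * pp$feedPoint
    corridorMid <- (pp$restCorner1 + geom@tripods["T1", ]) / 2
    .fixtures$smallSim <- suppressMessages(simulateSession(pp, list(
      list(unitId = "null", baseline = 1),
      list(unitId = "place", baseline = 0.5,
           selfField = list(center = corridorMid[1:2], width = 0.5,
                            peak = 15)),
      list(unitId = "ident", baseline = 2,
           identityGain = list(human = "H1", tripod = "T1", gain = 3)),
      list(unitId = "hpos", baseline = 0.3,
           humanField = list(human = "H1", center = arcPt[1:2],
                             width = 0.15, peak = 25))
    ), seed = 42))
  }
  .fixtures$smallSim
}

smallFrames <- function() {
  if (is.null(.fixtures$smallFrames))
    .fixtures$smallFrames <- suppressMessages(sessionFrames(smallSim()$session))
  .fixtures$smallFrames
}

# A full-size (6-block, ~96-flight) session with the stronger statistics the
# identity and human-frame tests need.
fullSim <- function() {
  if (is.null(.fixtures$fullSim)) {
    pp <- synthParams()
    geom <- synthGeometry(pp)
    ctrl <- (geom@traverseStart + pp$feedPoint) / 2 + c(pp$arcBow, 0, 0)
    u <- 0.3
    arcPt <- (1 - u)^2 * geom@traverseStart + 2 * u * (1 - u) * ctrl +
      u^2 * pp$feedPoint
    corridorMid <- (pp$restCorner1 + geom@tripods["T1", ]) / 2
    .fixtures$fullSim <- suppressMessages(simulateSession(pp, list(
      list(unitId = "null", baseline = 1),
      list(unitId = "place", baseline = 0.5,
           selfField = list(center = corridorMid[1:2], width = 0.5,
                            peak = 15)),
      list(unitId = "ident", baseline = 2,
           identityGain = list(human = "H1", tripod = "T1", gain = 3)),
      list(unitId = "hpos", baseline = 0.3,
           humanField = list(human = "H1", center = arcPt[1:2],
                             width = 0.15, peak = 25))
    ), seed = 42))
  }
  .fixtures$fullSim
}

fullFrames <- function() {
  if (is.null(.fixtures$fullFrames))
    .fixtures$fullFrames <- suppressMessages(sessionFrames(fullSim()$session))
  .fixtures$fullFrames
}

unitByName <- function(sim, name) {
  units <- sessionUnits(sim$session)
  units[[which(vapply(units, unitId, character(1)) == name)]]
}

# Straight-line tracked series at 100 Hz between two points.
lineSeries <- function(a, b, dur, subject = "s", tag = "body", fs = 100) {
  tt <- seq(0, dur, by = 1 / fs)
  u <- tt / dur
  xyz <- cbind(a[1] + u * (b[1] - a[1]), a[2] + u * (b[2] - a[2]),
               a[3] + u * (b[3] - a[3]))
  trackedSeries(subject, tag, tt, xyz)
}
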