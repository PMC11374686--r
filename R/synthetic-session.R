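# Synthetic-session generator: stereotyped flights between rest corners and
# tripods, human location-swap blocks, arced traverses with feeding pauses,
# and inhomogeneous-Poisson spike trains with configurable tuning. Every
# session carries ground truth for parameter-recovery tests.

#' Parameters of the synthetic-session generator
#'
#' Defaults emulate the study conditions: a 5.6 x 5.2 x 2.5 m room, two
#' humans on a pair of tripods swapping locations every 5-minute block, a
#' recorded bat resting in an upper corner and flying stereotyped paths to
#' the occupied tripods (minimum-jerk speed profile, ~3 m/s peak), an
#' optional conspecific accompanying a subset of trials, and two arced
#' traverses per human per block with a feeding pause. 6 blocks x 8 trials
#' give ~96 flight legs and 12 traverses per human per session.
#'
#' @param ... overrides by name; see the source for the full list.
#' @return named list of parameters.
#' @export
synthParams <- function(...) {
  p <- list(
    fs = 100,                    # Hz
    nBlocks = 6,                 # 5-min blocks
    blockDur = 300,              # s
    tripodPair = c("T1", "T2"),  # occupied tripods
    humans = c("H1", "H2"),
    flightsPerBlockPerHuman = 4,
    peakSpeed = 3,               # m/s, min-jerk peak
    pathJitterSd = 0.05,         # m, control-point jitter
    trackingNoiseSd = 0.01,      # m, white positional noise
    sitDur = 3,                  # s at the tripod after landing
    traversesPerBlockPerHuman = 2,
    traverseSpeed = 0.5,         # m/s cruise along the arc legs
    traversePause = 5,           # s feeding pause at the arc apex
    arcBow = 1.0,                # m lateral bow of the traverse arc
    walkSpeed = 1.0,             # m/s, swap walks and approach walks
    conspecific = TRUE,
    conspecificTrialEvery = 4,   # bat 2 accompanies every k-th trial
    coatHeight = 1.2,            # m
    restCorner1 = c(0.4, 4.8, 2.3),
    restCorner2 = c(5.2, 4.8, 2.3),
    feedPoint = c(2.8, 4.2, 1.2),  # traverse apex near the resting bats
    extent = c(5.6, 5.2, 2.5)
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown synth parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  stopifnot(p$pathJitterSd >= 0, p$trackingNoiseSd >= 0, p$peakSpeed > 0)
  p
}

#' Room geometry matching a set of synthetic parameters
#' @param params from [synthParams()].
#' @return a [RoomGeometry-class].
#' @export
synthGeometry <- function(params = synthParams()) {
  roomGeometry(extent = params$extent,
               traverseStart = c(params$extent[1] / 2, params$extent[2] / 2,
                                 params$coatHeight),
               restCentroids = rbind(params$restCorner1, params$restCorner2))
}

# Quadratic Bezier through a jittered control point, reparametrized by arc
# length: returns function(frac in [0,1]) -> n x 3 positions.
bezierSampler <- function(a, b, bow = c(0, 0, 0.5), jitter = c(0, 0, 0)) {
  ctrl <- (a + b) / 2 + bow + jitter
  bez <- function(u) {
    u2 <- (1 - u)^2; w <- 2 * u * (1 - u); v2 <- u^2
    cbind(u2 * a[1] + w * ctrl[1] + v2 * b[1],
          u2 * a[2] + w * ctrl[2] + v2 * b[2],
          u2 * a[3] + w * ctrl[3] + v2 * b[3])
  }
  uu <- seq(0, 1, length.out = 400)
  pts <- bez(uu)
  s <- c(0, cumsum(rowNorms(diff(pts))))
  L <- s[length(s)]
  list(at = function(frac) bez(approx(s / L, uu, frac, rule = 2)$y), len = L)
}

# Minimum-jerk arc-length schedule: m samples over the leg duration.
minJerkFrac <- function(m) {
  tau <- seq(1 / m, 1, length.out = m)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# Trapezoidal arc-length schedule (quick accel so threshold crossings stay
# near the endpoints), given total length, cruise speed and ramp time.
trapFrac <- function(L, vmax, accelT, dt) {
  a <- vmax / accelT
  dRamp <- 0.5 * vmax * accelT
  if (2 * dRamp >= L) {
    vpk <- sqrt(L * a); tAcc <- vpk / a
    total <- 2 * tAcc
    tt <- seq(dt, total, by = dt)
    s <- ifelse(tt <= tAcc, 0.5 * a * tt^2,
                L - 0.5 * a * (total - tt)^2)
  } else {
    cruise <- (L - 2 * dRamp) / vmax
    total <- 2 * accelT + cruise
    tt <- seq(dt, total, by = dt)
    s <- ifelse(tt <= accelT, 0.5 * a * tt^2,
         ifelse(tt <= accelT + cruise, dRamp + vmax * (tt - accelT),
                L - 0.5 * a * pmax(total - tt, 0)^2))
  }
  pmin(s / L, 1)
}

# Mutable position track: hold-then-move segment filler over a fixed grid.
newTrack <- function(n, start) {
  list(pos = matrix(rep(start, each = n), n, 3), cursor = 1L, hold = start)
}
trackMove <- function(tr, t0, frames, dt) {
  i0 <- max(1L, floor(t0 / dt) + 1L)
  m <- nrow(frames)
  i1 <- min(i0 + m - 1L, nrow(tr$pos))
  if (i0 > tr$cursor)
    tr$pos[tr$cursor:(i0 - 1L), ] <- matrix(rep(tr$hold, each = i0 - tr$cursor),
                                            ncol = 3)
  tr$pos[i0:i1, ] <- frames[seq_len(i1 - i0 + 1L), , drop = FALSE]
  tr$hold <- frames[m, ]
  tr$cursor <- i1 + 1L
  tr
}
trackFinish <- function(tr) {
  n <- nrow(tr$pos)
  if (tr$cursor <= n)
    tr$pos[tr$cursor:n, ] <- matrix(rep(tr$hold, each = n - tr$cursor + 1L),
                                    ncol = 3)
  tr$pos
}

#' Generate synthetic session behavior with ground-truth epochs
#'
#' Produces 100 Hz tracked series for the recorded bat, an optional
#' conspecific, and two humans (coat + both wrist tags), together with the
#' block schedule, feed-event intervals, and the true flight and traverse
#' epochs used to validate segmentation.
#'
#' @param params from [synthParams()].
#' @param seed RNG seed (path jitter, tracking noise).
#' @return list(bat1, bat2, humans, schedule, events, truth, geometry,
#'   params); `truth$flights` has start_s, end_s, leg, tripod, human,
#'   conspecific_present; `truth$traverses` has start_s, end_s, human.
#' @export
generateBehavior <- function(params = synthParams(), seed = 1) {
  withSeed(seed, generateBehaviorImpl(params))
}

generateBehaviorImpl <- function(pp) {
  fs <- pp$fs; dt <- 1 / fs
  total <- pp$nBlocks * pp$blockDur
  n <- total * fs
  geom <- synthGeometry(pp)
  tripods <- geom@tripods
  stand <- function(tp) c(tripods[tp, 1], tripods[tp, 2], pp$coatHeight)
  perch <- function(tp) tripods[tp, ]

  # block schedule: humans swap tripods every block
  sched <- list()
  for (b in seq_len(pp$nBlocks)) {
    hA <- pp$humans[1 + (b + 1) %% 2]; hB <- pp$humans[1 + b %% 2]
    sched[[length(sched) + 1]] <- data.frame(
      start_s = (b - 1) * pp$blockDur, end_s = b * pp$blockDur,
      human = c(hA, hB), tripod = pp$tripodPair)
  }
  sched <- do.call(rbind, sched)

  tripodOf <- function(h, t) {
    r <- sched[sched$human == h & sched$start_s <= t & sched$end_s > t, ]
    if (nrow(r)) r$tripod[1] else NA_character_
  }

  # ---- recorded bat trials -------------------------------------------------
  trialsPerBlock <- 2 * pp$flightsPerBlockPerHuman
  flightWindow <- 0.5 * pp$blockDur
  spacing <- (flightWindow - 15) / max(trialsPerBlock, 1)
  trials <- list()
  k <- 0
  for (b in seq_len(pp$nBlocks)) {
    for (j in seq_len(trialsPerBlock)) {
      k <- k + 1
      tgtHuman <- pp$humans[1 + (j + 1) %% 2]
      t0 <- (b - 1) * pp$blockDur + 12 + (j - 1) * spacing
      trials[[k]] <- list(t0 = t0, human = tgtHuman,
                          tripod = tripodOf(tgtHuman, t0),
                          accompanied = pp$conspecific &&
                            (k %% pp$conspecificTrialEvery == 0))
    }
  }

  bat1 <- newTrack(n, pp$restCorner1)
  bat2 <- if (pp$conspecific) newTrack(n, pp$restCorner2) else NULL
  truthFl <- list()

  flightLeg <- function(a, b) {
    jit <- if (pp$pathJitterSd > 0) stats::rnorm(3, 0, pp$pathJitterSd)
           else c(0, 0, 0)
    samp <- bezierSampler(a, b, bow = c(0, 0, 0.5), jitter = jit)
    dur <- samp$len * 1.875 / pp$peakSpeed
    m <- max(2L, round(dur * fs))
    samp$at(minJerkFrac(m))
  }

  for (tr in trials) {
    dest <- perch(tr$tripod)
    out <- flightLeg(pp$restCorner1, dest)
    back <- flightLeg(dest, pp$restCorner1)
    tLand <- tr$t0 + nrow(out) * dt
    tBack <- tLand + pp$sitDur
    bat1 <- trackMove(bat1, tr$t0, out, dt)
    bat1 <- trackMove(bat1, tBack, back, dt)
    truthFl[[length(truthFl) + 1]] <- data.frame(
      start_s = tr$t0, end_s = tLand, leg = "out", tripod = tr$tripod,
      human = tr$human, conspecific_present = isTRUE(tr$accompanied))
    truthFl[[length(truthFl) + 1]] <- data.frame(
      start_s = tBack, end_s = tBack + nrow(back) * dt, leg = "back",
      tripod = NA_character_, human = NA_character_,
      conspecific_present = FALSE)
    if (isTRUE(tr$accompanied)) {
      # conspecific arrives first and sits through the landing
      t2 <- tr$t0 - 5
      out2 <- flightLeg(pp$restCorner2, dest + c(0, 0.3, 0))
      back2 <- flightLeg(dest + c(0, 0.3, 0), pp$restCorner2)
      tLand2 <- t2 + nrow(out2) * dt
      tBack2 <- tLand + 4
      bat2 <- trackMove(bat2, t2, out2, dt)
      bat2 <- trackMove(bat2, tBack2, back2, dt)
    }
  }

  # ---- humans --------------------------------------------------------------
  coatTracks <- list(); truthTrav <- list(); events <- list()
  trvStart <- geom@traverseStart
  for (hi in seq_along(pp$humans)) {
    h <- pp$humans[hi]
    tp0 <- tripodOf(h, 0)
    trk <- newTrack(n, stand(tp0))
    bowSign <- if (hi == 1) 1 else -1
    for (b in seq_len(pp$nBlocks)) {
      bStart <- (b - 1) * pp$blockDur
      if (b > 1) { # swap walk at the block boundary
        fromTp <- tripodOf(h, bStart - 1); toTp <- tripodOf(h, bStart)
        if (!identical(fromTp, toTp)) {
          a <- stand(fromTp); d <- stand(toTp)
          L <- sqrt(sum((d - a)^2))
          fr <- trapFrac(L, pp$walkSpeed, 0.3, dt)
          seg <- outer(1 - fr, a) + outer(fr, d)
          trk <- trackMove(trk, bStart + 1, seg, dt)
        }
      }
      if (pp$traversesPerBlockPerHuman < 1) next
      for (q in seq_len(pp$traversesPerBlockPerHuman)) {
        # traverses sit in the last third of the block, humans alternating
        tq <- bStart + flightWindow + 10 +
          ((hi - 1) + (q - 1) * length(pp$humans)) * 36
        tpNow <- tripodOf(h, tq)
        a <- stand(tpNow)
        # walk tripod -> traverse start
        L1 <- sqrt(sum((trvStart - a)^2))
        fr <- trapFrac(L1, pp$walkSpeed, 0.3, dt)
        seg <- outer(1 - fr, a) + outer(fr, trvStart)
        trk <- trackMove(trk, tq, seg, dt)
        tArr <- tq + nrow(seg) * dt
        # arced traverse out, pause to feed, arc back
        arc <- bezierSampler(trvStart, pp$feedPoint,
                             bow = c(bowSign * pp$arcBow, 0, 0))
        legOut <- arc$at(trapFrac(arc$len, pp$traverseSpeed, 0.15, dt))
        tGo <- tArr + 2
        trk <- trackMove(trk, tGo, legOut, dt)
        tPause <- tGo + nrow(legOut) * dt
        tReturn <- tPause + pp$traversePause
        legBack <- legOut[rev(seq_len(nrow(legOut))), , drop = FALSE]
        trk <- trackMove(trk, tReturn, legBack, dt)
        tEnd <- tReturn + nrow(legBack) * dt
        events[[length(events) + 1]] <- data.frame(
          start_s = tPause, end_s = tReturn, human = h, kind = "feed")
        truthTrav[[length(truthTrav) + 1]] <- data.frame(
          start_s = tGo, end_s = tEnd, human = h)
        # amble back to the tripod below the traverse-start threshold so the
        # departure from the start point cannot read as a new traverse
        fr <- trapFrac(L1, 0.35, 0.3, dt)
        seg <- outer(1 - fr, trvStart) + outer(fr, a)
        trk <- trackMove(trk, tEnd + 2, seg, dt)
      }
    }
    coatTracks[[h]] <- trackFinish(trk)
  }

  tt <- seq(0, by = dt, length.out = n)
  noisy <- function(m) {
    if (pp$trackingNoiseSd > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, pp$trackingNoiseSd),
                      nrow(m), 3)
    m
  }
  mkSeries <- function(sub, tag, m) trackedSeries(sub, tag, tt, noisy(m))

  humans <- list()
  for (h in pp$humans) {
    coat <- coatTracks[[h]]
    humans[[h]] <- list(
      coat = mkSeries(h, "coat", coat),
      left_hand = mkSeries(h, "left_hand",
                           sweep(coat, 2, c(-0.2, 0.1, 0.1), "+")),
      right_hand = mkSeries(h, "right_hand",
                            sweep(coat, 2, c(0.2, 0.1, 0.1), "+")))
  }

  list(bat1 = mkSeries("bat1", "body", trackFinish(bat1)),
       bat2 = if (!is.null(bat2)) mkSeries("bat2", "body", trackFinish(bat2))
              else NULL,
       humans = humans, schedule = sched,
       events = if (length(events)) do.call(rbind, events) else emptyEvents(),
       truth = list(
         flights = do.call(rbind, truthFl),
         traverses = if (length(truthTrav)) do.call(rbind, truthTrav)
                     else data.frame(start_s = numeric(0), end_s = numeric(0),
                                     human = character(0))),
       geometry = geom, params = pp)
}

#' Simulate an inhomogeneous-Poisson spike train for one unit
#'
#' The instantaneous rate on the 100 Hz behavior grid is baseline plus
#' Gaussian place-field terms evaluated in the self, conspecific and human
#' reference frames, multiplied by an identity gain inside the peri-landing
#' window of flights to a configured human x tripod and by a presence gain
#' on conspecific-accompanied trials. Spikes are drawn by thinning a
#' homogeneous Poisson process at the peak rate.
#'
#' Tuning fields (all optional except baseline): `baseline` (Hz);
#' `selfField`/`conspecificField` = list(center = xy, width m, peak Hz);
#' `humanField` = list(human, center, width, peak); `identityGain` =
#' list(human, tripod, gain); `presenceGain` (scalar gain).
#'
#' @param behavior from [generateBehavior()].
#' @param tuning named list as above.
#' @param seed RNG seed.
#' @return a [SpikeTrain-class].
#' @export
generateSpikes <- function(behavior, tuning, seed = 1) {
  tt <- behavior$bat1@timestamps
  dt <- tt[2] - tt[1]
  rate <- rep(tuning$baseline %||% 0, length(tt))
  gauss <- function(xyz, f) {
    d2 <- (xyz[, 1] - f$center[1])^2 + (xyz[, 2] - f$center[2])^2
    f$peak * exp(-d2 / (2 * f$width^2))
  }
  if (!is.null(tuning$selfField))
    rate <- rate + gauss(behavior$bat1@xyz, tuning$selfField)
  if (!is.null(tuning$conspecificField) && !is.null(behavior$bat2))
    rate <- rate + gauss(behavior$bat2@xyz, tuning$conspecificField)
  if (!is.null(tuning$humanField)) {
    hf <- tuning$humanField
    rate <- rate + gauss(behavior$humans[[hf$human]]$coat@xyz, hf)
  }
  fl <- behavior$truth$flights
  w <- c(-0.25, 1.75)            # landing analysis window
  if (!is.null(tuning$identityGain)) {
    ig <- tuning$identityGain
    sel <- fl$leg == "out" & fl$human %in% ig$human & fl$tripod %in% ig$tripod
    for (tl in fl$end_s[sel]) {
      idx <- tt >= tl + w[1] & tt < tl + w[2]
      rate[idx] <- rate[idx] * ig$gain
    }
  }
  if (!is.null(tuning$presenceGain)) {
    sel <- fl$leg == "out" & fl$conspecific_present
    for (tl in fl$end_s[sel]) {
      idx <- tt >= tl + w[1] & tt < tl + w[2]
      rate[idx] <- rate[idx] * tuning$presenceGain
    }
  }
  if (any(rate < 0)) stop("negative instantaneous rate")
  span <- c(tt[1], tt[length(tt)] + dt)
  lmax <- max(rate)
  if (lmax == 0) return(spikeTrain(tuning$unitId %||% "unit", numeric(0), span))
  withSeed(seed, {
    nCand <- rpois(1, lmax * (span[2] - span[1]))
    cand <- sort(runif(nCand, span[1], span[2]))
    idx <- pmin(floor((cand - span[1]) / dt) + 1L, length(rate))
    keep <- runif(nCand) < rate[idx] / lmax
    spikeTrain(tuning$unitId %||% "unit", cand[keep], span)
  })
}

#' Simulate a complete session with ground truth
#'
#' @param params from [synthParams()].
#' @param tunings list of per-unit tuning lists (see [generateSpikes()]).
#' @param seed global RNG seed; per-unit substreams are derived from it, so
#'   adding a unit never changes earlier units' spikes.
#' @return list(session = [Session-class], truth = ground-truth table +
#'   epochs, behavior).
#' @export
simulateSession <- function(params = synthParams(), tunings = list(),
                            seed = 1) {
  beh <- generateBehavior(params, seed)
  units <- list()
  gt <- list()
  for (i in seq_along(tunings)) {
    tun <- tunings[[i]]
    tun$unitId <- tun$unitId %||% sprintf("unit%02d", i)
    st <- generateSpikes(beh, tun, deriveSeed(seed, 1000L + i))
    units[[i]] <- unitRecord(st)
    gt[[i]] <- data.frame(
      unit = tun$unitId,
      is_spatial_self = !is.null(tun$selfField),
      is_identity_modulated = !is.null(tun$identityGain),
      identity_location = if (!is.null(tun$identityGain))
        tun$identityGain$tripod else NA_character_,
      is_human_position_tuned = !is.null(tun$humanField),
      tuned_human = if (!is.null(tun$humanField)) tun$humanField$human
                    else NA_character_,
      is_conspecific_tuned = !is.null(tun$conspecificField),
      coding_class = tun$codingClass %||% "none")
  }
  bats <- list(beh$bat1)
  if (!is.null(beh$bat2)) bats[[2]] <- beh$bat2
  sess <- session(beh$geometry, bats, beh$humans, units, beh$schedule,
                  beh$events, config = analysisConfig(seed = seed))
  list(session = sess,
       truth = list(units = if (length(gt)) do.call(rbind, gt) else NULL,
                    flights = beh$truth$flights,
                    traverses = beh$truth$traverses),
       behavior = beh)
}

#' Write the canonical fixture suite
#'
#' Four small sessions in the package's on-disk formats, each with one unit
#' and a `ground_truth.json`: "null" (homogeneous 1 Hz), "place" (8 Hz
#' self-frame field on the flight corridor), "identity" (gain 3 at one
#' tripod for one human), "human_position" (field on one human's traverse
#' arc).
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param params generator parameters shared by all fixtures.
#' @return named vector of fixture directories, invisibly.
#' @export
makeFixtureSuite <- function(dir, seed = 1, params = synthParams()) {
  geom <- synthGeometry(params)
  corridorMid <- (params$restCorner1 + geom@tripods[params$tripodPair[1], ]) / 2
  # a point ~30% along human 1's traverse arc, clear of the excluded
  # feeding pause at the apex (quadratic Bezier, control = midpoint + bow)
  ctrl <- (geom@traverseStart + params$feedPoint) / 2 +
    c(params$arcBow, 0, 0)
  u <- 0.3
  arcMid <- (1 - u)^2 * geom@traverseStart + 2 * u * (1 - u) * ctrl +
    u^2 * params$feedPoint
  tunings <- list(
    null = list(baseline = 1),
    place = list(baseline = 0.5,
                 selfField = list(center = corridorMid[1:2], width = 0.5,
                                  peak = 8)),
    identity = list(baseline = 2,
                    identityGain = list(human = params$humans[1],
                                        tripod = params$tripodPair[1],
                                        gain = 3)),
    human_position = list(baseline = 0.3,
                          humanField = list(human = params$humans[1],
                                            center = arcMid[1:2],
                                            width = 0.15, peak = 25))
  )
  out <- character(0)
  for (nm in names(tunings)) {
    sim <- simulateSession(params, list(c(tunings[[nm]], unitId = nm)),
                           deriveSeed(seed, match(nm, names(tunings))))
    d <- file.path(dir, nm)
    writeSession(sim$session, d)
    jsonlite::write_json(sim$truth$units, file.path(d, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    out[nm] <- d
  }
  invisible(out)
}
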