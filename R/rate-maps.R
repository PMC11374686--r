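# Occupancy-normalized rate maps (2D room bins, 1D linearized trajectories)
# and the binned-behavior "map contexts" that make shuffle nulls cheap: the
# behavior, binning, validity mask and masked smoothing operator are computed
# once, after which rebuilding a map for a (shifted) spike train is a sparse
# matrix-vector product.

#' Skaggs spatial information from paired rate/occupancy vectors
#'
#' @param rate smoothed rates over valid bins, Hz.
#' @param occ smoothed occupancy over the same bins, s.
#' @return bits/spike, or NA when the occupancy-weighted mean rate is 0.
#' @export
skaggsSI <- function(rate, occ) {
  keep <- is.finite(rate) & is.finite(occ) & occ > 0
  rate <- rate[keep]; occ <- occ[keep]
  if (!length(rate)) return(NA_real_)
  p <- occ / sum(occ)
  lambda <- sum(p * rate)
  if (lambda <= 0) return(NA_real_)
  ratio <- rate / lambda
  term <- p * ratio * log2(ratio)
  term[rate == 0] <- 0            # x log x -> 0 limit convention
  sum(term)
}

# Zero-padded separable convolution of a matrix with a 1D kernel g applied
# along both dimensions.
sepConv2 <- function(M, g) {
  r <- (length(g) - 1) / 2
  n <- nrow(M); m <- ncol(M)
  P <- rbind(matrix(0, r, m), M, matrix(0, r, m))
  A <- matrix(0, n, m)
  for (k in seq_along(g)) A <- A + g[k] * P[k:(k + n - 1), , drop = FALSE]
  P <- cbind(matrix(0, n, r), A, matrix(0, n, r))
  B <- matrix(0, n, m)
  for (k in seq_along(g)) B <- B + g[k] * P[, k:(k + m - 1), drop = FALSE]
  B
}

gaussTaps <- function(sigma, radius = max(1L, round(3 * sigma))) {
  g <- dnorm(seq(-radius, radius), 0, sigma)
  g / sum(g)
}

# Masked 2D Gaussian smoothing: values outside `valid` neither receive nor
# contribute mass; weights renormalize over the valid support.
smoothMasked2D <- function(M, valid, sigma) {
  g <- gaussTaps(sigma)
  Mv <- M; Mv[!valid] <- 0
  num <- sepConv2(Mv, g)
  den <- sepConv2(valid + 0, g)
  out <- num / den
  out[!valid] <- NA
  out
}

smoothMasked1D <- function(x, valid, sigma, taps = 7) {
  g <- dnorm(seq_len(taps) - (taps + 1) / 2, 0, sigma)
  g <- g / sum(g)
  xv <- ifelse(valid, x, 0)
  r <- (taps - 1) / 2
  pad <- function(v) c(rep(0, r), v, rep(0, r))
  conv <- function(v) {
    p <- pad(v); n <- length(v)
    out <- numeric(n)
    for (k in seq_len(taps)) out <- out + g[k] * p[k:(k + n - 1)]
    out
  }
  out <- conv(xv) / conv(valid + 0)
  out[!valid] <- NA
  out
}

# 8-neighborhood rescue: bins below the occupancy cutoff (but visited) stay
# valid if at least one neighbor is valid.
rescueBins <- function(occ, cutoff) {
  valid <- occ >= cutoff
  low <- occ > 0 & !valid
  if (!any(low)) return(valid)
  nb <- matrix(FALSE, nrow(occ), ncol(occ))
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    xs <- seq_len(nrow(occ)); ys <- seq_len(ncol(occ))
    xs2 <- xs + dx; ys2 <- ys + dy
    okx <- xs2 >= 1 & xs2 <= nrow(occ); oky <- ys2 >= 1 & ys2 <= ncol(occ)
    nb[xs[okx], ys[oky]] <- nb[xs[okx], ys[oky]] |
      valid[xs2[okx], ys2[oky], drop = FALSE]
  }
  valid | (low & nb)
}

# Sparse row-normalized masked smoothing operator mapping raw per-bin counts
# to smoothed values at valid bins (2D grid flattened column-major).
buildSmoother2D <- function(valid, sigma) {
  nx <- nrow(valid); ny <- ncol(valid)
  r <- max(1L, round(3 * sigma))
  g <- gaussTaps(sigma, r)
  vIdx <- which(valid)                      # flat indices of valid bins
  vRow <- ((vIdx - 1) %% nx) + 1
  vCol <- ((vIdx - 1) %/% nx) + 1
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (dx in -r:r) for (dy in -r:r) {
    w <- g[dx + r + 1] * g[dy + r + 1]
    sx <- vRow + dx; sy <- vCol + dy
    ok <- sx >= 1 & sx <= nx & sy >= 1 & sy <= ny
    if (!any(ok)) next
    src <- (sy[ok] - 1) * nx + sx[ok]
    ok2 <- valid[src]
    if (!any(ok2)) next
    rows <- c(rows, which(ok)[ok2])
    cols <- c(cols, src[ok2])
    vals <- c(vals, rep(w, sum(ok2)))
  }
  S <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(length(vIdx), nx * ny))
  den <- Matrix::rowSums(S)
  S / den
}

#' Build a 2D map context from behavior
#'
#' Restricts a tracked series to the included epochs, projects onto the xy
#' plane, bins positions into 0.15 m bins anchored at the room origin, and
#' precomputes occupancy, the validity mask (occupancy cutoff with
#' 8-neighbor rescue) and the masked smoothing operator. The same context
#' serves the empirical map and all circular-shift shuffles.
#'
#' @param series a [TrackedSeries-class] (the bat, or a human coat tag for
#'   human-frame maps).
#' @param epochs data.frame(start, end) of included intervals (e.g. flights,
#'   or traverses).
#' @param extent numeric(2+): room xy extent, m.
#' @param binSize bin side, m.
#' @param cutoff occupancy cutoff, s (0.15 for bat frames, 1 for human
#'   frames).
#' @param sigma Gaussian smoothing sigma, bins.
#' @return an opaque context list for [rateMapFromContext()],
#'   [spikeBinCounts()] and [circularShiftNull()].
#' @export
mapContext2D <- function(series, epochs, extent, binSize = 0.15,
                         cutoff = 0.15, sigma = 1.5) {
  epochs <- mergeIntervals(epochs)
  ts <- series@timestamps
  ct <- toConcatTime(ts, epochs)
  keep <- !is.na(ct)
  if (!any(keep)) stop("no behavior samples inside the included epochs")
  dt <- median(diff(ts))
  nx <- ceiling(extent[1] / binSize)
  ny <- ceiling(extent[2] / binSize)
  ix <- pmin(pmax(floor(series@xyz[keep, 1] / binSize) + 1L, 1L), nx)
  iy <- pmin(pmax(floor(series@xyz[keep, 2] / binSize) + 1L, 1L), ny)
  bin <- (iy - 1L) * nx + ix
  occ <- matrix(tabulate(bin, nx * ny) * dt, nx, ny)
  valid <- rescueBins(occ, cutoff)
  smOcc <- smoothMasked2D(occ, valid, sigma)
  list(kind = "2d", epochs = epochs, dt = dt,
       total = sum(keep) * dt, binIdx = bin, nbins = nx * ny,
       dims = c(nx, ny), binSize = binSize, origin = c(0, 0),
       occ = occ, valid = valid, smOcc = smOcc,
       S = buildSmoother2D(valid, sigma),
       smOccValid = smOcc[valid],
       p = smOcc[valid] / sum(smOcc[valid]))
}

#' Map spike times to per-bin raw counts under a context
#'
#' @param ctx a context from [mapContext2D()] or [mapContext1D()].
#' @param spikes spike times on the session clock (s), or concatenated-
#'   timeline times if `concat = TRUE`.
#' @param concat whether `spikes` are already on the concatenated timeline.
#' @return integer vector of counts, one per bin.
#' @export
spikeBinCounts <- function(ctx, spikes, concat = FALSE) {
  ct <- if (concat) spikes else toConcatTime(spikes, ctx$epochs)
  ct <- ct[!is.na(ct)]
  idx <- pmin(pmax(floor(ct / ctx$dt) + 1L, 1L), length(ctx$binIdx))
  tabulate(ctx$binIdx[idx], ctx$nbins)
}

# Vectorized SI over columns of a (nbins x m) count matrix.
siFromCounts <- function(ctx, counts) {
  counts <- as.matrix(counts)
  sm <- as.matrix(ctx$S %*% counts)
  rate <- sm / ctx$smOccValid
  lambda <- colSums(ctx$p * rate)
  ratio <- sweep(rate, 2, lambda, "/")
  term <- ctx$p * ratio * log2(ratio)
  term[rate == 0] <- 0
  si <- colSums(term)
  si[lambda <= 0] <- NA_real_
  si
}

#' Materialize a rate map from a context and a spike train
#'
#' @param ctx a context from [mapContext2D()] or [mapContext1D()].
#' @param spikes spike times (s, session clock).
#' @return a [RateMap2D-class] or [RateMap1D-class].
#' @export
rateMapFromContext <- function(ctx, spikes) {
  counts <- spikeBinCounts(ctx, spikes)
  smValid <- as.numeric(ctx$S %*% counts)
  rateValid <- smValid / ctx$smOccValid
  meanRate <- sum(ctx$p * rateValid)
  if (ctx$kind == "2d") {
    rate <- matrix(NA_real_, ctx$dims[1], ctx$dims[2])
    rate[ctx$valid] <- rateValid
    new("RateMap2D", binSize = ctx$binSize, origin = ctx$origin,
        occupancy = ctx$occ,
        spikeCount = matrix(counts, ctx$dims[1], ctx$dims[2]),
        smoothedOccupancy = ctx$smOcc, rate = rate, valid = ctx$valid,
        meanRate = meanRate, nSpikes = sum(counts))
  } else {
    rate <- rep(NA_real_, ctx$nbins)
    rate[ctx$valid] <- rateValid
    smOcc <- rep(NA_real_, ctx$nbins)
    smOcc[ctx$valid] <- ctx$smOccValid
    new("RateMap1D", binSize = ctx$binSize, occupancy = as.numeric(ctx$occ),
        spikeCount = as.numeric(counts), smoothedOccupancy = smOcc,
        rate = rate, valid = as.logical(ctx$valid), meanRate = meanRate,
        nSpikes = sum(counts), nFlights = ctx$nFlights %||% NA_real_)
  }
}

#' Build a 2D occupancy-normalized rate map
#'
#' Positions during the included epochs are projected onto the xy plane and
#' binned (0.15 m); the spike-count and occupancy maps are smoothed with a
#' Gaussian kernel (sigma = 1.5 bins, masked and renormalized over valid
#' bins) and the rate is their bin-by-bin ratio. Bins occupied less than the
#' cutoff are invalidated unless at least one 8-neighbor is valid.
#'
#' @inheritParams mapContext2D
#' @param spikes spike times (s).
#' @return a [RateMap2D-class].
#' @export
rateMap2D <- function(series, epochs, spikes, extent, binSize = 0.15,
                      cutoff = 0.15, sigma = 1.5) {
  ctx <- mapContext2D(series, epochs, extent, binSize, cutoff, sigma)
  rateMapFromContext(ctx, spikes)
}

#' Linearize a cluster's flights to arc-length coordinates
#'
#' Each flight's samples are mapped to cumulative distance from take-off and
#' rescaled to the cluster's common template length (the mean flight path
#' length), so the same path flown at different speeds bins identically.
#'
#' @param series the flying bat's [TrackedSeries-class].
#' @param flights data.frame with start_s, end_s for the cluster's flights.
#' @return list(flights = per-flight list(t, s), templateLength). Zero-length
#'   flights are dropped with a message.
#' @export
linearizeFlights <- function(series, flights) {
  ts <- series@timestamps
  out <- list()
  lens <- numeric(0)
  for (i in seq_len(nrow(flights))) {
    keep <- ts >= flights$start_s[i] & ts <= flights$end_s[i]
    if (sum(keep) < 2) next
    p <- series@xyz[keep, , drop = FALSE]
    s <- c(0, cumsum(rowNorms(diff(p))))
    L <- s[length(s)]
    if (L <= 0) {
      message(sprintf("zero-length flight at t=%.1f s excluded",
                      flights$start_s[i]))
      next
    }
    out[[length(out) + 1]] <- list(t = ts[keep], s = s, len = L,
                                   start_s = flights$start_s[i],
                                   end_s = flights$end_s[i])
    lens <- c(lens, L)
  }
  if (!length(out)) stop("no usable flights to linearize")
  L0 <- mean(lens)
  for (i in seq_along(out)) out[[i]]$s <- out[[i]]$s * (L0 / out[[i]]$len)
  list(flights = out, templateLength = L0)
}

#' Build a 1D map context from linearized flights
#'
#' Occupancy and spikes are binned at 0.15 m along the rescaled
#' take-off-to-landing axis, pooled over flights; both maps are smoothed
#' with a 7-tap Gaussian window (sigma = 1 bin) before their ratio.
#'
#' @param lin output of [linearizeFlights()].
#' @param binSize bin size along the trajectory, m.
#' @param sigma 1D Gaussian sigma, bins.
#' @param taps window length, bins.
#' @return a context for [rateMapFromContext()] / [circularShiftNull()].
#' @export
mapContext1D <- function(lin, binSize = 0.15, sigma = 1.0, taps = 7) {
  nbins <- max(1L, ceiling(lin$templateLength / binSize))
  epochs <- do.call(rbind, lapply(lin$flights, function(f)
    data.frame(start = f$start_s, end = f$end_s)))
  epochs <- epochs[order(epochs$start), , drop = FALSE]
  dt <- median(unlist(lapply(lin$flights, function(f) diff(f$t))))
  binIdx <- integer(0)
  ord <- order(vapply(lin$flights, function(f) f$start_s, numeric(1)))
  for (f in lin$flights[ord]) {
    b <- pmin(pmax(floor(f$s / binSize) + 1L, 1L), nbins)
    binIdx <- c(binIdx, b)
  }
  occ <- tabulate(binIdx, nbins) * dt
  valid <- occ > 0
  g <- dnorm(seq_len(taps) - (taps + 1) / 2, 0, sigma); g <- g / sum(g)
  r <- (taps - 1) / 2
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  vIdx <- which(valid)
  for (d in -r:r) {
    src <- vIdx + d
    ok <- src >= 1 & src <= nbins
    ok[ok] <- valid[src[ok]]
    rows <- c(rows, which(ok)); cols <- c(cols, src[ok])
    vals <- c(vals, rep(g[d + r + 1], sum(ok)))
  }
  S <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(length(vIdx), nbins))
  S <- S / Matrix::rowSums(S)
  smOcc <- rep(NA_real_, nbins)
  smOcc[valid] <- as.numeric(S %*% occ)
  list(kind = "1d", epochs = epochs, dt = dt, total = length(binIdx) * dt,
       binIdx = binIdx, nbins = nbins, dims = nbins, binSize = binSize,
       origin = 0, occ = occ, valid = valid, smOcc = smOcc, S = S,
       smOccValid = smOcc[valid], p = smOcc[valid] / sum(smOcc[valid]),
       nFlights = length(lin$flights))
}

#' Build a 1D trajectory rate map (with inclusion check)
#'
#' A unit x trajectory is analyzable with at least 7 flights, at least 4
#' flights with spikes, and at least 15 spikes across all flights; otherwise
#' NULL is returned (not an error).
#'
#' @param series the flying bat's [TrackedSeries-class].
#' @param flights data.frame(start_s, end_s) for one trajectory cluster.
#' @param spikes spike times (s).
#' @param config an [AnalysisConfig-class].
#' @param checkInclusion apply the inclusion minima (default TRUE).
#' @return a [RateMap1D-class], or NULL when not analyzable.
#' @export
rateMap1D <- function(series, flights, spikes, config = analysisConfig(),
                      checkInclusion = TRUE) {
  p <- config@params
  if (checkInclusion &&
      !analyzable1D(flights, spikes, p$minFlights1D,
                    p$minFlightsWithSpikes1D, p$minSpikes1D))
    return(NULL)
  lin <- linearizeFlights(series, flights)
  ctx <- mapContext1D(lin, binSize = p$binSize, sigma = p$smoothSigma1D)
  rateMapFromContext(ctx, spikes)
}

# Trial-count / spike-count inclusion test for 1D analyses.
analyzable1D <- function(flights, spikes, minFlights = 7,
                         minWithSpikes = 4, minSpikes = 15) {
  if (nrow(flights) < minFlights) return(FALSE)
  perFlight <- vapply(seq_len(nrow(flights)), function(i)
    sum(spikes >= flights$start_s[i] & spikes <= flights$end_s[i]),
    numeric(1))
  sum(perFlight > 0) >= minWithSpikes && sum(perFlight) >= minSpikes
}
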