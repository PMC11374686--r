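# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded subcomputations (per-unit spike draws, per-test permutations) never
#' perturb each other.
#' @noRd
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed from a base seed and integer tags.
# Keeps results stable when only a subset of units/locations is re-run.
deriveSeed <- function(base, ...) {
  tags <- c(...)
  x <- as.double(base %% 2147483647L)
  for (t in c(tags, 0)) {
    x <- (x * 69069 + as.double(abs(as.integer(t))) + 1) %% 2147483647
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Euclidean norm by row for an n x k matrix.
rowNorms <- function(m) sqrt(rowSums(m * m))

# Half-open interval membership: t in [a, b)
inWindow <- function(t, a, b) t >= a & t < b

# Merge overlapping/abutting intervals given as a 2-column matrix or
# data.frame with columns start, end. Returns a data.frame(start, end).
mergeIntervals <- function(iv) {
  if (is.matrix(iv)) iv <- data.frame(start = iv[, 1], end = iv[, 2])
  if (nrow(iv) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  iv <- iv[order(iv$start), , drop = FALSE]
  out.s <- iv$start[1]; out.e <- iv$end[1]
  ss <- c(); ee <- c()
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= out.e) {
      out.e <- max(out.e, iv$end[i])
    } else {
      ss <- c(ss, out.s); ee <- c(ee, out.e)
      out.s <- iv$start[i]; out.e <- iv$end[i]
    }
  }
  data.frame(start = c(ss, out.s), end = c(ee, out.e))
}

# Total duration covered by a set of (already disjoint) intervals.
intervalDuration <- function(iv) sum(iv$end - iv$start)

# Restrict times to intervals and map them onto the concatenated
# (gap-removed) timeline. Times outside every interval map to NA.
toConcatTime <- function(times, iv) {
  if (nrow(iv) == 0) return(rep(NA_real_, length(times)))
  iv <- iv[order(iv$start), , drop = FALSE]
  offs <- cumsum(c(0, head(iv$end - iv$start, -1)))
  idx <- findInterval(times, iv$start)
  ok <- idx >= 1 & idx <= nrow(iv)
  ok[ok] <- times[ok] < iv$end[idx[ok]]
  out <- rep(NA_real_, length(times))
  out[ok] <- times[ok] - iv$start[idx[ok]] + offs[idx[ok]]
  out
}
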