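# Trajectory clustering and flight/traverse similarity.

#' Spatially downsample a flight path to seven points
#'
#' Points sit at equal cumulative arc-length fractions {0, 1/6, ..., 1}, so
#' the first and last points are exactly the take-off and landing positions.
#' A degenerate zero-length path returns seven copies of the single point.
#'
#' @param path n x 3 matrix of flight positions (m), time-ordered.
#' @param nPoints number of points (default 7).
#' @return nPoints x 3 matrix.
#' @export
downsampleFlight <- function(path, nPoints = 7) {
  path <- as.matrix(path)
  if (nrow(path) == 1 || sum(rowNorms(diff(path))) == 0)
    return(matrix(rep(path[1, ], each = nPoints), nPoints, 3))
  s <- c(0, cumsum(rowNorms(diff(path))))
  keep <- c(TRUE, diff(s) > 0)          # collapse stationary samples
  s <- s[keep]; path <- path[keep, , drop = FALSE]
  target <- s[length(s)] * seq(0, 1, length.out = nPoints)
  out <- cbind(approx(s, path[, 1], target)$y,
               approx(s, path[, 2], target)$y,
               approx(s, path[, 3], target)$y)
  out[1, ] <- path[1, ]
  out[nPoints, ] <- path[nrow(path), ]
  out
}

#' Cluster flights into stereotyped trajectories
#'
#' Each flight is downsampled to seven 3D points; the Euclidean distance
#' between the concatenated 21-dimensional shape vectors measures flight
#' similarity. Agglomerative hierarchical clustering (single linkage by
#' default, configurable) is cut at the linkage distance (default 1.3 m, the
#' midpoint of the 1.2-1.4 m working range).
#'
#' @param paths list of flight position matrices (n x 3 each).
#' @param linkageDistance cophenetic cut height, m.
#' @param method linkage criterion for [stats::hclust()].
#' @return integer vector of cluster ids (1 = largest cluster), one per
#'   flight, with the per-cluster mean 7 x 3 shape in
#'   `attr(, "templates")`.
#' @export
clusterFlights <- function(paths, linkageDistance = 1.3, method = "single") {
  stopifnot(length(paths) >= 1)
  shapes <- t(vapply(paths, function(p) as.numeric(downsampleFlight(p)),
                     numeric(21)))
  if (length(paths) == 1) {
    cl <- 1L
  } else {
    hc <- hclust(dist(shapes), method = method)
    cl <- cutree(hc, h = linkageDistance)
  }
  # relabel so cluster 1 is the most populous (ties by first appearance)
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  cl <- as.integer(relabel[as.character(cl)])
  templates <- lapply(seq_len(max(cl)), function(k) {
    m <- colMeans(shapes[cl == k, , drop = FALSE])
    matrix(m, 7, 3)
  })
  attr(cl, "templates") <- templates
  cl
}

# Resample a path to m equal-time points per axis and concatenate the axes.
concatResampled <- function(path, m = 100, axes = 1:3) {
  path <- as.matrix(path)
  n <- nrow(path)
  if (n == m) return(as.numeric(path[, axes]))
  tt <- seq(0, 1, length.out = n)
  to <- seq(0, 1, length.out = m)
  as.numeric(vapply(axes, function(j) approx(tt, path[, j], to)$y,
                    numeric(m)))
}

#' Pairwise Pearson correlations of flights within and across human targets
#'
#' Flights are resampled to 100 equal-time points, their x, y and z
#' coordinates concatenated, and the Pearson correlation computed for every
#' pair within a cluster. Pairs with the same human landing target are pooled
#' into the within-human distribution, the rest into the across-human
#' distribution. Clusters with fewer than `minPerHuman` flights to either
#' human are skipped.
#'
#' @param paths list of flight position matrices.
#' @param humans character vector of human landing targets, one per flight.
#' @param clusters optional cluster ids (default: all one cluster).
#' @param minPerHuman minimum repeated flights per human per cluster
#'   (default 4).
#' @return list(within_r, across_r, n_within, n_across, skipped_clusters).
#' @export
flightPairCorrelations <- function(paths, humans, clusters = NULL,
                                   minPerHuman = 4) {
  if (is.null(clusters)) clusters <- rep(1L, length(paths))
  stopifnot(length(paths) == length(humans),
            length(paths) == length(clusters))
  within <- numeric(0); across <- numeric(0); skipped <- integer(0)
  for (k in unique(clusters)) {
    idx <- which(clusters == k & !is.na(humans))
    tab <- table(humans[idx])
    if (length(tab) < 2 || any(tab < minPerHuman)) {
      skipped <- c(skipped, k)
      next
    }
    vecs <- vapply(paths[idx], concatResampled, numeric(300))
    cm <- cor(vecs)
    h <- humans[idx]
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in seq(i + 1, length(idx))) {
        if (h[i] == h[j]) within <- c(within, cm[i, j])
        else across <- c(across, cm[i, j])
      }
    }
  }
  list(within_r = within, across_r = across,
       n_within = length(within), n_across = length(across),
       skipped_clusters = skipped)
}

#' Pairwise Pearson correlations of human traverses
#'
#' Traverses are resampled to 100 equal-time points and their x and y
#' coordinates concatenated (traverses are ground walks; z is ignored).
#' Same-human pairs pool into the within distribution, cross-human pairs into
#' the across distribution.
#'
#' @param paths list of traverse position matrices (n x 2 or n x 3).
#' @param humans character vector, one human id per traverse.
#' @return list(within_r, across_r, n_within, n_across).
#' @export
traverseCorrelations <- function(paths, humans) {
  stopifnot(length(paths) == length(humans))
  n <- length(paths)
  if (n < 2) return(list(within_r = numeric(0), across_r = numeric(0),
                         n_within = 0, n_across = 0))
  vecs <- vapply(paths, concatResampled, numeric(200), axes = 1:2)
  cm <- cor(vecs)
  within <- numeric(0); across <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (humans[i] == humans[j]) within <- c(within, cm[i, j])
      else across <- c(across, cm[i, j])
    }
  }
  list(within_r = within, across_r = across,
       n_within = length(within), n_across = length(across))
}
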