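#' Trim neurites beyond a Euclidean radius from the soma
#'
#' Walks the tree root-outward and cuts each branch at its first node whose
#' Euclidean distance from the soma center exceeds `radius`; everything
#' distal to a cut is removed, including any re-entrant portion that would
#' return inside the radius. The result is a connected tree containing the
#' root. The default radius of 300 (in the morphology's native length
#' units) restricts analysis to neurites traced confidently near the soma.
#'
#' @param n A [neuron()].
#' @param radius Positive trimming radius.
#' @return The trimmed [neuron()].
#' @export
trim_neuron <- function(n, radius = 300) {
  stopifnot(inherits(n, "neuron"))
  assert_that(radius > 0, "radius must be positive")
  ctr <- soma_center(n)
  d <- sqrt((n$x - ctr[1])^2 + (n$y - ctr[2])^2 + (n$z - ctr[3])^2)
  idx <- match(n$parent, n$id)
  keep <- rep(NA, nrow(n))
  keep[n$parent == -1L] <- TRUE
  pending <- which(is.na(keep))
  while (length(pending) > 0) {
    ready <- pending[!is.na(keep[idx[pending]])]
    keep[ready] <- keep[idx[ready]] & d[ready] <= radius
    pending <- setdiff(pending, ready)
  }
  out <- n[keep, , drop = FALSE]
  neuron(out, group_label = attr(n, "group_label"))
}

# tricube weights on within-window rank distance
tricube <- function(r, span) (1 - pmin(1, abs(r) / span)^3)^3

#' LOESS smoothing of dendrite polylines
#'
#' Replaces every non-endpoint, non-bifurcation vertex by a locally
#' quadratic fit (per coordinate, against arc length) over the
#' `k_neighbors` vertices before and after it along its branch, with
#' tricube weights on rank distance. Endpoints and bifurcation points are
#' excluded from filtering and remain bit-identical; branches shorter than
#' the window use all available vertices. Topology, ids and node count are
#' unchanged. This regularizes tortuosity inflated by anisotropic sampling
#' of curved dendrites.
#'
#' @param n A [neuron()].
#' @param k_neighbors Window half-width in vertices (default 5).
#' @return The smoothed [neuron()].
#' @export
loess_smooth_neuron <- function(n, k_neighbors = 5L) {
  stopifnot(inherits(n, "neuron"))
  assert_that(k_neighbors >= 1, "k_neighbors must be >= 1")
  out <- n
  for (path in branch_paths(n)) {
    np <- length(path)
    if (np < 3) next
    xyz <- cbind(n$x[path], n$y[path], n$z[path])
    s <- c(0, cumsum(sqrt(rowSums(diff(xyz)^2))))
    for (j in 2:(np - 1)) {
      lo <- max(1L, j - k_neighbors); hi <- min(np, j + k_neighbors)
      win <- lo:hi
      w <- tricube(win - j, k_neighbors + 1)
      t0 <- s[win] - s[j]
      X <- cbind(1, t0, t0^2)
      # weighted least squares; quadratic in arc length per coordinate
      wx <- X * w
      xtx <- crossprod(wx, X)
      fit <- tryCatch(solve(xtx, crossprod(wx, xyz[win, , drop = FALSE])),
                      error = function(e) NULL)
      if (is.null(fit)) next
      out$x[path[j]] <- fit[1, 1]
      out$y[path[j]] <- fit[1, 2]
      out$z[path[j]] <- fit[1, 3]
    }
  }
  out
}
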