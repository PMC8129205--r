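#' Classic Sholl analysis
#'
#' For each radius, counts the number of dendritic segments crossing the
#' sphere of that radius centered at the soma. Each straight segment
#' between consecutive nodes is intersected with the sphere exactly (roots
#' of the quadratic `|p + t d| = r` within the segment), so a segment that
#' dips in and out of a shell contributes both crossings.
#'
#' @param n A [neuron()].
#' @param radii Increasing positive radii.
#' @return Data frame with `radius` and `crossings`.
#' @export
sholl_classic <- function(n, radii) {
  stopifnot(inherits(n, "neuron"))
  assert_that(all(radii > 0) && !is.unsorted(radii, strictly = TRUE),
              "radii must be positive and strictly increasing")
  ctr <- soma_center(n)
  segs <- segment_rows(n)
  p0 <- cbind(n$x[segs[, 1]] - ctr[1], n$y[segs[, 1]] - ctr[2],
              n$z[segs[, 1]] - ctr[3])
  p1 <- cbind(n$x[segs[, 2]] - ctr[1], n$y[segs[, 2]] - ctr[2],
              n$z[segs[, 2]] - ctr[3])
  d <- p1 - p0
  a <- rowSums(d^2)
  b <- 2 * rowSums(p0 * d)
  c0 <- rowSums(p0^2)
  crossings <- vapply(radii, function(r) {
    cc <- c0 - r^2
    disc <- b^2 - 4 * a * cc
    hits <- 0L
    pos <- which(disc > 0 & a > 0)
    for (i in pos) {
      rt <- (-b[i] + c(-1, 1) * sqrt(disc[i])) / (2 * a[i])
      hits <- hits + sum(rt >= 0 & rt <= 1)
    }
    hits
  }, integer(1))
  data.frame(radius = radii, crossings = crossings)
}

#' Sholl-like dendritic surface-area distribution
#'
#' Distributes dendritic membrane surface over relative path distance from
#' the soma: each segment's frustum lateral area is assigned to the bin
#' containing its midpoint's path distance divided by the neuron's maximum
#' path distance. Bin sums conserve the total dendritic surface area.
#'
#' @param n A [neuron()].
#' @param n_bins Number of equal-width bins over `[0, 1]` relative path
#'   distance.
#' @return Data frame with `bin_center`, `area` and `fraction` per bin.
#' @export
sholl_surface <- function(n, n_bins = 20L) {
  stopifnot(inherits(n, "neuron"))
  assert_that(n_bins >= 1, "n_bins must be >= 1")
  segs <- segment_rows(n)
  assert_that(nrow(segs) > 0, "neuron has no dendritic segments")
  len <- segment_lengths(n, segs)
  pd <- path_distance(n)
  maxd <- max(pd[n$type != 1L], 0)
  assert_that(maxd > 0, "neuron has zero spatial extent")
  r0 <- n$radius[segs[, 1]]; r1 <- n$radius[segs[, 2]]
  slant <- sqrt(len^2 + (r1 - r0)^2)
  area <- pi * (r0 + r1) * slant
  mid <- (pd[segs[, 1]] + pd[segs[, 2]]) / 2 / maxd
  bin <- pmin(n_bins, pmax(1L, ceiling(mid * n_bins)))
  sums <- vapply(seq_len(n_bins), function(b) sum(area[bin == b]), numeric(1))
  data.frame(bin_center = (seq_len(n_bins) - 0.5) / n_bins, area = sums,
             fraction = sums / sum(area))
}
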