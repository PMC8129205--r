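#' Domain-labeled tracer pixel coordinates
#'
#' Container for per-atlas-level 2D point coordinates carrying anatomical
#' domain labels, the training data for domain-boundary demarcation. Class
#' labels are stored as a factor; when the labels are the canonical domain
#' set, the level order is fixed to medial < lateral < caudal (the
#' deterministic tie-break order of the ensemble vote).
#'
#' @param x,y Numeric pixel coordinates.
#' @param label Domain label per point.
#' @param level_id Atlas-level tag shared by all points.
#' @return A `labeled_points` data frame with columns `x`, `y`, `label` and
#'   attribute `level_id`.
#' @export
labeled_points <- function(x, y, label, level_id) {
  assert_that(length(x) == length(y) && length(x) == length(label),
              "x, y and label must have equal length")
  canon <- c("medial", "lateral", "caudal")
  if (is.factor(label)) {
    lev <- levels(label)
  } else if (all(unique(label) %in% canon)) {
    lev <- canon
  } else {
    lev <- sort(unique(as.character(label)))
  }
  out <- data.frame(x = as.numeric(x), y = as.numeric(y),
                    label = factor(as.character(label), levels = lev))
  attr(out, "level_id") <- level_id
  class(out) <- c("labeled_points", class(out))
  out
}

#' Reference nucleus outline polygon for a synthetic atlas level
#'
#' Deterministic closed polygon emulating the elongated, slightly kidney
#' shaped outline of an amygdalar nucleus on a coronal plate. The outline
#' deforms smoothly with the level index so consecutive synthetic levels
#' resemble consecutive atlas plates.
#'
#' @param level_id Integer level index (any integer; shape varies smoothly).
#' @param width,height Bounding box of the outline in pixels.
#' @param n_vertices Number of polygon vertices.
#' @return A two-column matrix of `(x, y)` vertices.
#' @export
nucleus_polygon <- function(level_id = 1L, width = 160, height = 110,
                            n_vertices = 72L) {
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  lv <- as.numeric(level_id)
  # Fourier-perturbed ellipse; fixed low-order coefficients, phase drifts
  # with level to mimic plate-to-plate shape change
  r <- 1 + 0.14 * cos(2 * t + 0.35 * lv) + 0.08 * sin(3 * t - 0.2 * lv) +
    0.04 * cos(5 * t + 0.1 * lv)
  cx <- width / 2; cy <- height / 2
  cbind(x = cx + 0.44 * width * r * cos(t),
        y = cy + 0.40 * height * r * sin(t))
}

#' Specification of synthetic domain-labeled point clouds
#'
#' Describes three spatially segregated but (optionally) partially
#' overlapping point clouds inside a nucleus-shaped polygon mask, one per
#' anatomical domain (medial, lateral, caudal). Points are drawn from
#' truncated anisotropic Gaussians. When `overlap_fraction > 0` the per-domain
#' spreads are rescaled by a single global factor, solved numerically so that
#' the expected fraction of points lying nearer a foreign domain center
#' equals `overlap_fraction`; the calibration is deterministic, so generation
#' remains bit-reproducible under `seed`.
#'
#' @param level_id Atlas-level tag (also selects the default mask shape).
#' @param centers 3x2 matrix of domain centers `(x, y)`; default centers are
#'   placed inside the level's polygon with medial/lateral along the long
#'   axis and caudal below.
#' @param spreads Base spread (Gaussian sigma, pixels) per domain;
#'   recycled to length 3. The y-spread is 0.8 times the x-spread
#'   (anisotropic, matching elongated nuclear geometry).
#' @param n_points Points per domain (recycled to length 3).
#' @param overlap_fraction Target fraction of points closer to a foreign
#'   center, in `[0, 1)`. Zero keeps `spreads` untouched.
#' @param mask Polygon vertices (two-column matrix); default
#'   [nucleus_polygon()] for `level_id`.
#' @param seed Integer seed.
#' @return An object of class `domain_cloud_spec` (with calibrated
#'   `sigma` field: 3x2 matrix of x/y standard deviations).
#' @export
domain_cloud_spec <- function(level_id = 1L, centers = NULL, spreads = 9,
                              n_points = 500L, overlap_fraction = 0,
                              mask = NULL, seed = 1L) {
  if (is.null(mask)) mask <- nucleus_polygon(level_id)
  assert_that(is.matrix(mask) && ncol(mask) == 2 && nrow(mask) >= 3,
              "mask must be a polygon with at least 3 vertices")
  if (is.null(centers)) {
    bx <- range(mask[, 1]); by <- range(mask[, 2])
    centers <- rbind(
      medial  = c(bx[1] + 0.30 * diff(bx), by[1] + 0.42 * diff(by)),
      lateral = c(bx[1] + 0.68 * diff(bx), by[1] + 0.40 * diff(by)),
      caudal  = c(bx[1] + 0.48 * diff(bx), by[1] + 0.72 * diff(by)))
  }
  centers <- as.matrix(centers)
  assert_that(nrow(centers) == 3 && ncol(centers) == 2,
              "centers must be a 3x2 matrix")
  inside <- pracma::inpolygon(centers[, 1], centers[, 2],
                              mask[, 1], mask[, 2])
  assert_that(all(inside), "all domain centers must lie inside the mask")
  assert_that(overlap_fraction >= 0 && overlap_fraction < 1,
              "overlap_fraction must be in [0,1)")
  spreads <- rep_len(as.numeric(spreads), 3L)
  n_points <- rep_len(as.integer(n_points), 3L)
  assert_that(all(spreads > 0) && all(n_points > 0),
              "spreads and n_points must be positive")

  spec <- list(level_id = level_id, centers = centers, spreads = spreads,
               n_points = n_points, overlap_fraction = overlap_fraction,
               mask = mask, seed = as.integer(seed))
  spec$sigma <- calibrate_sigma(spec)
  structure(spec, class = "domain_cloud_spec")
}

# per-domain (x,y) Gaussian sigmas; with overlap_fraction > 0 a single global
# scale is solved so the expected foreign-closer fraction matches. The pilot
# sample uses a fixed internal seed, so the result is a deterministic
# function of the spec.
calibrate_sigma <- function(spec) {
  base <- cbind(spec$spreads, 0.8 * spec$spreads)
  if (spec$overlap_fraction == 0) return(base)
  foreign_frac <- function(scale) {
    pts <- withr::with_seed(20240201L, {
      sample_clouds(spec$centers, scale * base, rep(1200L, 3L), spec$mask)
    })
    d <- point_center_dist(pts[, c("x", "y")], spec$centers)
    mean(max.col(-d) != as.integer(pts$dom))
  }
  sol <- tryCatch(
    uniroot(function(s) foreign_frac(s) - spec$overlap_fraction,
            interval = c(0.1, 4), extendInt = "upX", tol = 0.005),
    error = function(e) stopf("cannot calibrate spreads to overlap_fraction %.3f: %s",
                              spec$overlap_fraction, conditionMessage(e)))
  sol$root * base
}

# Euclidean distances from points (n x 2) to each center (3 x 2)
point_center_dist <- function(p, centers) {
  p <- as.matrix(p)
  sapply(seq_len(nrow(centers)), function(k) {
    sqrt((p[, 1] - centers[k, 1])^2 + (p[, 2] - centers[k, 2])^2)
  })
}

# rejection-sample truncated anisotropic Gaussians inside a polygon;
# returns data.frame(x, y, dom) with dom an integer factor 1..3
sample_clouds <- function(centers, sigma, n_points, mask) {
  out <- vector("list", 3L)
  for (k in 1:3) {
    got <- 0L; acc <- matrix(0, 0, 2)
    guard <- 0L
    while (got < n_points[k]) {
      m <- max(2L * (n_points[k] - got), 64L)
      cand <- cbind(rnorm(m, centers[k, 1], sigma[k, 1]),
                    rnorm(m, centers[k, 2], sigma[k, 2]))
      keep <- pracma::inpolygon(cand[, 1], cand[, 2], mask[, 1], mask[, 2])
      acc <- rbind(acc, cand[keep, , drop = FALSE])
      got <- nrow(acc)
      guard <- guard + 1L
      if (guard > 200L) stopf("rejection sampling failed: domain %d lies almost entirely outside the mask", k)
    }
    out[[k]] <- data.frame(x = acc[1:n_points[k], 1],
                           y = acc[1:n_points[k], 2], dom = k)
  }
  res <- do.call(rbind, out)
  res$dom <- factor(res$dom, levels = 1:3)
  res
}

#' Generate domain-labeled point clouds with ground truth
#'
#' Draws the three domain clouds described by a [domain_cloud_spec()] and
#' returns them as [labeled_points()] together with the generating spec,
#' whose calibrated sigmas define the ground-truth domain surface (see
#' [ground_truth_map()]).
#'
#' @param spec A [domain_cloud_spec()].
#' @return A [labeled_points()] data frame; the spec is attached as
#'   attribute `spec`.
#' @export
gen_domain_points <- function(spec) {
  stopifnot(inherits(spec, "domain_cloud_spec"))
  withr::local_seed(spec$seed)
  pts <- sample_clouds(spec$centers, spec$sigma, spec$n_points, spec$mask)
  lab <- c("medial", "lateral", "caudal")[as.integer(pts$dom)]
  out <- labeled_points(pts$x, pts$y, lab, spec$level_id)
  attr(out, "spec") <- spec
  out
}

#' Ground-truth domain label surface of a synthetic level
#'
#' Classifies every pixel inside the mask polygon by the highest truncated
#' Gaussian class density of the generating spec (the Bayes rule of the
#' generative model), yielding the reference domain map that automated
#' demarcations are scored against.
#'
#' @param spec A [domain_cloud_spec()].
#' @param resolution Pixel step of the evaluation grid (1 = native pixels).
#' @return A `boundary_map`: list with `labels` (integer matrix, NA outside
#'   the mask), `levels` (domain names), `mask` (logical matrix), `xs`, `ys`
#'   (grid coordinates) and `level_id`.
#' @export
ground_truth_map <- function(spec, resolution = 1) {
  stopifnot(inherits(spec, "domain_cloud_spec"))
  bx <- range(spec$mask[, 1]); by <- range(spec$mask[, 2])
  xs <- seq(bx[1], bx[2], by = resolution)
  ys <- seq(by[1], by[2], by = resolution)
  gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
  inside <- pracma::inpolygon(gx, gy, spec$mask[, 1], spec$mask[, 2])
  dens <- sapply(1:3, function(k) {
    dnorm(gx, spec$centers[k, 1], spec$sigma[k, 1]) *
      dnorm(gy, spec$centers[k, 2], spec$sigma[k, 2])
  })
  lab <- max.col(dens, ties.method = "first")
  lab[!inside] <- NA_integer_
  labels <- matrix(lab, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  mask <- matrix(inside, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  structure(list(labels = labels, levels = c("medial", "lateral", "caudal"),
                 mask = mask, xs = xs, ys = ys, level_id = spec$level_id),
            class = "boundary_map")
}
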