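#' Specification of a synthetic tracer section image
#'
#' Describes a single grayscale section image containing one bright,
#' irregularly shaped injection-site blob over a textured background of
#' labeled fibers and sensor noise. Serves as ground-truth input for the
#' injection-site extraction pipeline.
#'
#' @param height,width Raster dimensions in pixels.
#' @param blob_center Numeric length-2, blob center `(x, y)` in pixel
#'   coordinates (origin top-left, x rightward, y downward).
#' @param blob_radius Characteristic blob radius in pixels. The blob is a
#'   randomly oriented superellipse whose axes multiply to `blob_radius^2`,
#'   so its area stays close to a disk of this radius.
#' @param blob_peak Peak blob intensity in `(0, 1]`.
#' @param background_level Constant background intensity in `[0, 1)`.
#' @param fiber_density Fraction of pixels covered by bright fiber-like
#'   streaks, in `[0, 1)`.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Integer seed; generation is bit-reproducible for a fixed seed.
#'
#' @return An object of class `section_spec`.
#' @seealso [gen_section_image()]
#' @export
section_spec <- function(height = 192, width = 192,
                         blob_center = c(width / 2, height / 2),
                         blob_radius = 20, blob_peak = 0.95,
                         background_level = 0.15, fiber_density = 0.02,
                         noise_sd = 0.02, seed = 1L) {
  assert_that(height >= 8 && width >= 8, "raster must be at least 8x8")
  assert_that(blob_peak > 0 && blob_peak <= 1, "blob_peak must be in (0,1]")
  assert_that(background_level >= 0 && background_level < 1,
              "background_level must be in [0,1)")
  assert_that(fiber_density >= 0 && fiber_density < 1,
              "fiber_density must be in [0,1)")
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  # superellipse axes can stretch the radius by up to ~1.25x; require the
  # stretched blob to fit fully inside the raster
  margin <- 1.3 * blob_radius
  if (blob_center[1] - margin < 0 || blob_center[1] + margin > width ||
      blob_center[2] - margin < 0 || blob_center[2] + margin > height) {
    stopf("blob (center %.1f,%.1f radius %.1f) does not lie fully inside the %dx%d raster",
          blob_center[1], blob_center[2], blob_radius, width, height)
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 blob_center = as.numeric(blob_center),
                 blob_radius = blob_radius, blob_peak = blob_peak,
                 background_level = background_level,
                 fiber_density = fiber_density, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "section_spec")
}

#' Generate a synthetic section image with a known injection-site blob
#'
#' Renders the blob as a smoothed, randomly oriented superellipse with
#' multiplicative speckle (so it is bright but irregular, like saturated
#' tracer deposits), draws thin bright fiber streaks over a constant
#' background, and adds Gaussian noise. All intensities are clamped to
#' `[0, 1]`. Every blob pixel is guaranteed an intensity of at least half
#' the blob peak.
#'
#' @param spec A [section_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{image}{`gray_image` matrix (rows = y, cols = x) in `[0, 1]`.}
#'     \item{mask}{Logical matrix marking exactly the blob support.}
#'     \item{spec}{The generating spec (machine-readable ground truth).}
#'   }
#' @export
gen_section_image <- function(spec) {
  stopifnot(inherits(spec, "section_spec"))
  withr::local_seed(spec$seed)
  h <- spec$height; w <- spec$width
  # pixel centers: column x, row y
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)

  # superellipse blob: |u/a|^n + |v/b|^n <= 1 with a*b = r^2
  theta <- runif(1, 0, pi)
  aspect <- runif(1, 0.85, 1.2)
  nexp <- runif(1, 2.0, 2.6)
  a <- spec$blob_radius * aspect
  b <- spec$blob_radius / aspect
  u <- (xs - spec$blob_center[1]) * cos(theta) +
       (ys - spec$blob_center[2]) * sin(theta)
  v <- -(xs - spec$blob_center[1]) * sin(theta) +
       (ys - spec$blob_center[2]) * cos(theta)
  rho <- (abs(u / a)^nexp + abs(v / b)^nexp)^(1 / nexp)
  mask <- rho <= 1

  img <- matrix(spec$background_level, h, w)

  # fiber streaks: short random bright line segments
  if (spec$fiber_density > 0) {
    target <- spec$fiber_density * h * w
    covered <- 0
    while (covered < target) {
      x0 <- runif(1, 1, w); y0 <- runif(1, 1, h)
      ang <- runif(1, 0, pi); len <- runif(1, 10, 40)
      tt <- seq(0, len, by = 0.5)
      fx <- round(x0 + tt * cos(ang)); fy <- round(y0 + tt * sin(ang))
      keep <- fx >= 1 & fx <= w & fy >= 1 & fy <= h
      if (!any(keep)) next
      ij <- cbind(fy[keep], fx[keep])
      img[ij] <- pmin(1, spec$background_level + runif(1, 0.25, 0.5))
      covered <- covered + nrow(ij)
    }
  }

  # blob intensity: saturated core with a mild falloff to ~0.8*peak at the
  # rim (tracer deposits are near-saturated), multiplicative speckle,
  # floored at 0.5*peak inside the support
  if (any(mask)) {
    profile <- 1 - 0.2 * rho[mask]^4
    speckle <- exp(rnorm(sum(mask), 0, 0.05))
    val <- spec$blob_peak * profile * speckle
    img[mask] <- pmin(1, pmax(0.5 * spec$blob_peak, val))
  }

  if (spec$noise_sd > 0) {
    img <- img + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
  }
  img <- clamp01(img)
  list(image = as_gray_image(img), mask = mask, spec = spec)
}
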