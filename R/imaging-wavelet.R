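# Orthonormal Daubechies low-pass filters (perfect reconstruction with the
# periodized transform used below). The default transform is the symmetric
# CDF 5/3 biorthogonal wavelet implemented by lifting (below): its linear
# phase keeps image structures in place when detail bands are modified,
# whereas minimum-phase Daubechies filters translate them diagonally.
wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453414, 0.8365163037378079,
          0.2241438680420134, -0.12940952255126037),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032)
)

qmf <- function(h) rev(h) * (-1)^(seq_along(h) - 1)

# CDF 5/3 lifting steps along columns (periodic, N even): predict then
# update; exactly invertible and zero phase
lift_cols <- function(m) {
  n <- nrow(m); half <- n %/% 2L
  xe <- m[seq(1L, n, 2L), , drop = FALSE]
  xo <- m[seq(2L, n, 2L), , drop = FALSE]
  nxt <- c(seq_len(half)[-1L], 1L)            # k+1 mod half
  prv <- c(half, seq_len(half)[-half])        # k-1 mod half
  d <- xo - 0.5 * (xe + xe[nxt, , drop = FALSE])
  a <- xe + 0.25 * (d[prv, , drop = FALSE] + d)
  list(low = a, high = d)
}

unlift_cols <- function(a, d) {
  half <- nrow(a)
  nxt <- c(seq_len(half)[-1L], 1L)
  prv <- c(half, seq_len(half)[-half])
  xe <- a - 0.25 * (d[prv, , drop = FALSE] + d)
  xo <- d + 0.5 * (xe + xe[nxt, , drop = FALSE])
  out <- matrix(0, 2L * half, ncol(a))
  out[seq(1L, 2L * half, 2L), ] <- xe
  out[seq(2L, 2L * half, 2L), ] <- xo
  out
}

# one periodized analysis step along columns: N x C -> list(low, high),
# each N/2 x C
dwt_step_cols <- function(m, h) {
  g <- qmf(h)
  n <- nrow(m)
  half <- n %/% 2L
  ks <- 2L * (seq_len(half) - 1L)            # 0-based even offsets
  low <- matrix(0, half, ncol(m))
  high <- matrix(0, half, ncol(m))
  for (j in seq_along(h)) {
    src <- ((ks + j - 1L) %% n) + 1L
    low <- low + h[j] * m[src, , drop = FALSE]
    high <- high + g[j] * m[src, , drop = FALSE]
  }
  list(low = low, high = high)
}

# inverse of dwt_step_cols
idwt_step_cols <- function(low, high, h) {
  g <- qmf(h)
  half <- nrow(low)
  n <- 2L * half
  ks <- 2L * (seq_len(half) - 1L)
  out <- matrix(0, n, ncol(low))
  for (j in seq_along(h)) {
    dst <- ((ks + j - 1L) %% n) + 1L
    out[dst, ] <- out[dst, ] + h[j] * low + g[j] * high
  }
  out
}

# single 2D analysis step: rows = y, cols = x; h = NULL selects the
# CDF 5/3 lifting transform
dwt2_step <- function(m, h) {
  step1 <- if (is.null(h)) lift_cols else function(x) dwt_step_cols(x, h)
  y <- step1(m)                                  # filter along y
  ll_lh <- step1(t(y$low))                       # filter along x
  hl_hh <- step1(t(y$high))
  list(LL = t(ll_lh$low),
       V = t(ll_lh$high),    # low y, high x: vertical structures
       H = t(hl_hh$low),     # high y, low x: horizontal structures
       D = t(hl_hh$high))    # high-high: diagonal detail
}

idwt2_step <- function(bands, h) {
  istep <- if (is.null(h)) unlift_cols else function(a, d) idwt_step_cols(a, d, h)
  low_x <- t(istep(t(bands$LL), t(bands$V)))
  high_x <- t(istep(t(bands$H), t(bands$D)))
  istep(low_x, high_x)
}

#' Multi-level 2D discrete wavelet decomposition
#'
#' Separable orthonormal DWT with periodization. Images whose dimensions are
#' not multiples of `2^levels` are symmetric-reflection padded (bottom/right)
#' before the transform and cropped after reconstruction, so the round trip
#' through [wavelet_reconstruct()] reproduces the input to floating-point
#' accuracy.
#'
#' @param img A [as_gray_image()] (or plain matrix in `[0, 1]`).
#' @param levels Decomposition depth `L >= 1`.
#' @param wavelet_name One of `"cdf53"` (default; symmetric biorthogonal
#'   5/3 via lifting, linear phase), `"haar"`, `"db2"`, `"db4"`.
#' @return A `wavelet_pyramid`: list with `low` (level-L approximation),
#'   `details` (per level, arrays `H`, `V`, `D`), `wavelet_name`, `levels`,
#'   and the original image size.
#' @export
wavelet_decompose <- function(img, levels = 5L, wavelet_name = "cdf53") {
  m <- unclass(as_gray_image(img))
  levels <- as.integer(levels)
  assert_that(levels >= 1L, "levels must be >= 1")
  known <- c("cdf53", names(wavelet_filters))
  if (!wavelet_name %in% known) {
    stopf("unknown wavelet '%s' (available: %s)", wavelet_name,
          paste(known, collapse = ", "))
  }
  h <- wavelet_filters[[wavelet_name]]   # NULL selects the lifting path
  max_depth <- floor(log2(min(dim(m))))
  if (min(dim(m)) < 2^levels) {
    stopf("image %dx%d too small for %d levels; maximum feasible depth is %d",
          nrow(m), ncol(m), levels, max_depth)
  }
  orig <- dim(m)
  block <- 2L^levels
  padr <- (block - nrow(m) %% block) %% block
  padc <- (block - ncol(m) %% block) %% block
  if (padr > 0) m <- m[reflect_index(seq_len(nrow(m) + padr), nrow(m)), ,
                       drop = FALSE]
  if (padc > 0) m <- m[, reflect_index(seq_len(ncol(m) + padc), ncol(m)),
                       drop = FALSE]
  details <- vector("list", levels)
  cur <- m
  for (l in seq_len(levels)) {
    st <- dwt2_step(cur, h)
    details[[l]] <- st[c("H", "V", "D")]
    cur <- st$LL
  }
  structure(list(low = cur, details = details, wavelet_name = wavelet_name,
                 levels = levels, orig_dim = orig),
            class = "wavelet_pyramid")
}

#' Inverse 2D wavelet transform
#'
#' Reconstructs the image from a (possibly modified) pyramid and clips the
#' result to `[0, 1]`.
#'
#' @param pyr A `wavelet_pyramid` from [wavelet_decompose()].
#' @return A `gray_image`.
#' @export
wavelet_reconstruct <- function(pyr) {
  stopifnot(inherits(pyr, "wavelet_pyramid"))
  h <- wavelet_filters[[pyr$wavelet_name]]
  cur <- pyr$low
  for (l in rev(seq_len(pyr$levels))) {
    d <- pyr$details[[l]]
    assert_that(all(dim(d$H) == dim(cur)) && all(dim(d$V) == dim(cur)) &&
                  all(dim(d$D) == dim(cur)),
                "pyramid shape mismatch at level %d", l)
    cur <- idwt2_step(list(LL = cur, H = d$H, V = d$V, D = d$D), h)
  }
  cur <- cur[seq_len(pyr$orig_dim[1]), seq_len(pyr$orig_dim[2]), drop = FALSE]
  as_gray_image(clamp01(cur), normalize = FALSE)
}

#' Wavelet band modification schedule
#'
#' Parameters of the injection-site background-suppression step: detail
#' bands at fine scales are removed outright; at the remaining scales,
#' large-magnitude diagonal details are amplified (injection blobs produce
#' strong diagonal energy at coarse scales) while small-magnitude
#' horizontal/vertical details (fiber-scale texture) are dampened; the
#' deepest low-pass band is dampened and Gaussian smoothed. Magnitude
#' thresholds are quantile based, so the schedule is scale free across
#' exposure settings.
#'
#' @param zero_detail_levels Levels whose detail bands are zeroed
#'   (default 1-3, the fine scales).
#' @param diag_gain Multiplicative gain (> 1) for large-magnitude diagonal
#'   coefficients at the remaining levels.
#' @param diag_large_quantile Quantile of `|D|` above which coefficients
#'   count as large (default 0.9, the top 10 percent).
#' @param hv_damp Multiplicative factor (< 1) for small-magnitude
#'   horizontal/vertical coefficients.
#' @param hv_small_quantile Quantile of `|H|`, `|V|` below which
#'   coefficients count as small (default 0.5).
#' @param low_damp Multiplicative factor applied to the deepest low-pass
#'   band.
#' @param low_smooth_sigma Gaussian sigma (in coefficient pixels) used to
#'   smooth the dampened low-pass band.
#' @return A `band_modification` object.
#' @export
band_modification <- function(zero_detail_levels = 1:3, diag_gain = 2,
                              diag_large_quantile = 0.9, hv_damp = 0.5,
                              hv_small_quantile = 0.5, low_damp = 0.5,
                              low_smooth_sigma = 2) {
  assert_that(diag_gain > 0 && hv_damp > 0 && low_damp > 0,
              "gains must be positive")
  assert_that(diag_large_quantile >= 0 && diag_large_quantile <= 1 &&
                hv_small_quantile >= 0 && hv_small_quantile <= 1,
              "quantiles must be in [0,1]")
  structure(list(zero_detail_levels = as.integer(zero_detail_levels),
                 diag_gain = diag_gain,
                 diag_large_quantile = diag_large_quantile,
                 hv_damp = hv_damp, hv_small_quantile = hv_small_quantile,
                 low_damp = low_damp, low_smooth_sigma = low_smooth_sigma),
            class = "band_modification")
}

#' Modify wavelet bands for background suppression
#'
#' Applies a [band_modification()] schedule to a pyramid: zeroes the detail
#' triples at the listed fine levels; at every remaining level amplifies
#' diagonal coefficients whose magnitude exceeds the large-magnitude
#' quantile and dampens horizontal/vertical coefficients below the
#' small-magnitude quantile; dampens the deepest low-pass band and smooths
#' it with a Gaussian kernel.
#'
#' @param pyr A `wavelet_pyramid`.
#' @param mod A [band_modification()].
#' @return A modified `wavelet_pyramid`.
#' @export
modify_bands <- function(pyr, mod = band_modification()) {
  stopifnot(inherits(pyr, "wavelet_pyramid"),
            inherits(mod, "band_modification"))
  assert_that(all(mod$zero_detail_levels %in% seq_len(pyr$levels)),
              "zero_detail_levels outside pyramid depth %d", pyr$levels)
  for (l in seq_len(pyr$levels)) {
    d <- pyr$details[[l]]
    if (l %in% mod$zero_detail_levels) {
      pyr$details[[l]] <- lapply(d, function(b) b * 0)
      next
    }
    if (mod$diag_gain != 1) {
      thr <- quantile(abs(d$D), mod$diag_large_quantile, names = FALSE)
      d$D[abs(d$D) > thr] <- d$D[abs(d$D) > thr] * mod$diag_gain
    }
    if (mod$hv_damp != 1) {
      for (b in c("H", "V")) {
        thr <- quantile(abs(d[[b]]), mod$hv_small_quantile, names = FALSE)
        small <- abs(d[[b]]) < thr
        d[[b]][small] <- d[[b]][small] * mod$hv_damp
      }
    }
    pyr$details[[l]] <- d
  }
  low <- pyr$low * mod$low_damp
  if (mod$low_smooth_sigma > 0) low <- gauss_blur(low, mod$low_smooth_sigma)
  pyr$low <- low
  pyr
}
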