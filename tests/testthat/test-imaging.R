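test_that("wavelet decomposition structure and round trip", {
  set.seed(21)
  m <- matrix(runif(128 * 96), 96, 128)
  for (w in c("cdf53", "haar", "db2", "db4")) {
    pyr <- wavelet_decompose(m, 4, w)
    expect_length(pyr$details, 4)
    rec <- wavelet_reconstruct(pyr)
    expect_lt(max(abs(rec - m)), 1e-6)
  }
  # constant image has no detail energy
  pyr <- wavelet_decompose(matrix(0.4, 64, 64), 3)
  expect_true(all(vapply(pyr$details, function(d) {
    max(abs(d$H), abs(d$V), abs(d$D))
  }, numeric(1)) < 1e-12))
  # a 512x512 image supports the 5-level decomposition used in production
  big <- matrix(runif(512 * 512), 512, 512)
  expect_length(wavelet_decompose(big, 5)$details, 5)
})

test_that("images too small for the requested depth name the feasible depth", {
  expect_error(wavelet_decompose(matrix(0.5, 16, 300), 5), "depth is 4")
})

test_that("band modification zeroes fine levels and leaves identity settings alone", {
  set.seed(3)
  m <- matrix(runif(64 * 64), 64, 64)
  pyr <- wavelet_decompose(m, 5)
  ident <- modify_bands(pyr, band_modification(
    zero_detail_levels = integer(0), diag_gain = 1, hv_damp = 1,
    low_damp = 1, low_smooth_sigma = 0))
  expect_equal(ident, pyr)
  mod <- modify_bands(pyr, band_modification())
  for (l in 1:3) {
    expect_true(all(mod$details[[l]]$H == 0))
    expect_true(all(mod$details[[l]]$D == 0))
  }
  expect_gt(max(abs(mod$details[[4]]$D)), 0)
})

test_that("band suppression removes fiber-scale energy and blob halo intensity", {
  sp <- section_spec(seed = 31, fiber_density = 0.04, noise_sd = 0.03)
  g <- gen_section_image(sp)
  pyr <- wavelet_decompose(g$image, 5)
  rec <- wavelet_reconstruct(modify_bands(pyr, band_modification()))
  # fine-scale (levels 1-3) energy of the cleaned image collapses
  e_in <- sum(vapply(wavelet_decompose(g$image, 3)$details, function(d) {
    sum(d$H^2) + sum(d$V^2) + sum(d$D^2)
  }, numeric(1)))
  e_out <- sum(vapply(wavelet_decompose(rec, 3)$details, function(d) {
    sum(d$H^2) + sum(d$V^2) + sum(d$D^2)
  }, numeric(1)))
  expect_lt(e_out / e_in, 0.2)
  # mean intensity in the background halo around the blob decreases
  halo <- !g$mask
  expect_lt(mean(rec[halo]), mean(g$image[halo]))
  # fully zeroed pyramid reconstructs to a constant
  zeroed <- pyr
  zeroed$low <- zeroed$low * 0
  zeroed$details <- lapply(zeroed$details, lapply, function(b) b * 0)
  expect_equal(max(wavelet_reconstruct(zeroed)) -
                 min(wavelet_reconstruct(zeroed)), 0)
})

test_that("sinusoidal intensity mapping and its Taylor form agree where expected", {
  expect_equal(contrast_map_initial(1, 2), 1)
  expect_equal(contrast_map_initial(0, 0.7), 0)
  expect_equal(contrast_map_initial(0.1, 1), 0.02447, tolerance = 1e-4)
  expect_equal(contrast_map_taylor(1, 3), pi^2 / 4)
  expect_equal(contrast_map_taylor(0, 2), 0)
  expect_equal(contrast_map_taylor(0.1, 2), pi^2 / 4 * 0.01, tolerance = 1e-12)
  expect_error(contrast_map_initial(0.5, -1), "positive")
  # small-angle regime on a grid of (f, p): the first-order expansion
  # sin(u) ~ u errs by u^2/6, under 2% wherever f^p <= 0.2; the squared
  # mappings consequently agree to twice that (u^2/3, under 3.5%)
  grid <- expand.grid(f = seq(0.01, 0.99, by = 0.02),
                      p = c(0.5, 1, 2, 4))
  grid <- grid[grid$f^grid$p <= 0.2, ]
  u <- (pi / 2) * grid$f^grid$p
  expect_lt(max(abs(u - sin(u)) / sin(u)), 0.02)
  t3 <- contrast_map_initial(grid$f, grid$p)
  t4 <- contrast_map_taylor(grid$f, 2 * grid$p)
  expect_lt(max(abs(t4 - t3) / t3), 0.035)
})

test_that("adaptive enhancement follows the expansion and sharpens blobs", {
  # identity kernel: second term vanishes, output is the normalized mapping
  ramp <- matrix(rep(seq(0, 1, length.out = 64), 64), 64, 64, byrow = TRUE)
  e <- adaptive_enhance(ramp, contrast_params(c1 = 1, c2 = 1,
                                              gauss_sigma = 0),
                        clip_quantile = 1)
  f <- ramp
  cc <- 1 * (f + 1e-6) / ((1 - f) + 1e-6) + 1
  tt <- (pi^2 / 4) * f^cc
  expect_equal(unclass(e), tt / max(tt), tolerance = 1e-6)
  # constant image maps to a constant
  e2 <- adaptive_enhance(matrix(0.6, 32, 32))
  expect_equal(max(e2) - min(e2), 0)
  # monotone along a gentle ramp when the neighborhood is nearly fixed
  gentle <- matrix(rep(seq(0.4, 0.6, length.out = 128), 128), 128, 128,
                   byrow = TRUE)
  e3 <- adaptive_enhance(gentle, contrast_params(gauss_sigma = 60),
                         clip_quantile = 1)
  mid <- e3[64, 20:108]
  expect_true(all(diff(mid) > -1e-9))
  # blob-to-halo contrast increases from the enhancement input to its output
  g <- gen_section_image(section_spec(seed = 12))
  pyr <- wavelet_decompose(g$image, 5)
  rec <- wavelet_reconstruct(modify_bands(pyr, band_modification()))
  enh <- adaptive_enhance(rec)
  ratio_in <- mean(rec[g$mask]) / mean(rec[!g$mask])
  ratio_out <- mean(enh[g$mask]) / mean(enh[!g$mask])
  expect_gt(ratio_out, ratio_in)
})

test_that("MSER recovers disk blobs and handles degenerate images", {
  # noiseless disk on dark background, no enhancement needed
  m <- matrix(0.05, 96, 96)
  xs <- matrix(rep(seq_len(96) - 0.5, each = 96), 96, 96)
  ys <- matrix(rep(seq_len(96) - 0.5, times = 96), 96, 96)
  disk <- sqrt((xs - 48)^2 + (ys - 40)^2) <= 10
  m[disk] <- 0.9
  blob <- extract_injection_site(as_gray_image(m, normalize = FALSE))
  expect_equal(blob$status, "ok")
  expect_lt(abs(blob$area - pi * 100) / (pi * 100), 0.15)
  expect_lt(sqrt(sum((blob$centroid - c(48, 40))^2)), 1)

  expect_warning(b0 <- extract_injection_site(
    as_gray_image(matrix(0, 64, 64), normalize = FALSE)), "blank")
  expect_equal(b0$area, 0L)

  # two blobs, the smaller carrying the global maximum: the returned blob
  # must contain the intensity maximum
  m2 <- matrix(0.05, 96, 96)
  big <- sqrt((xs - 30)^2 + (ys - 30)^2) <= 20
  small <- sqrt((xs - 70)^2 + (ys - 70)^2) <= 10
  m2[big] <- 0.7
  m2[small] <- 0.95
  b2 <- extract_injection_site(as_gray_image(m2, normalize = FALSE))
  expect_true(b2$mask[71, 71])
  expect_false(any(b2$mask & big))
})

test_that("blob annotation reports region overlaps with deterministic primaries", {
  m <- matrix(0.05, 60, 60)
  m[20:29, 21:30] <- 0.95             # 100-px square blob
  blob <- extract_injection_site(as_gray_image(m, normalize = FALSE),
                                 mser_params(min_area = 20))
  atlas <- matrix(0L, 60, 60)
  atlas[, 1:26] <- 1L                  # region A: 60 columns of the blob
  atlas[, 27:60] <- 2L                 # region B
  rt <- data.frame(id = c(1, 2), name = c("A", "B"))
  rep1 <- annotate_injection(blob, atlas, rt)
  expect_equal(rep1$fraction[rep1$region == "A"], 0.6)
  expect_equal(rep1$fraction[rep1$region == "B"], 0.4)
  expect_equal(attr(rep1, "primary"), "A")

  atlas_a <- matrix(1L, 60, 60)
  rep2 <- annotate_injection(blob, atlas_a, rt)
  expect_equal(rep2$fraction, 1)
  expect_equal(attr(rep2, "primary"), "A")

  expect_warning(rep3 <- annotate_injection(blob, matrix(0L, 60, 60), rt),
                 "outside")
  expect_true(is.na(attr(rep3, "primary")))
})

test_that("gray images survive PNG and TIFF round trips", {
  skip_if_not_installed("png")
  skip_if_not_installed("tiff")
  g <- gen_section_image(section_spec(height = 48, width = 40, seed = 2,
                                      blob_radius = 8,
                                      blob_center = c(20, 24)))$image
  for (ext in c(".png", ".tiff")) {
    path <- tempfile(fileext = ext)
    write_gray_image(g, path)
    back <- read_gray_image(path)
    expect_equal(dim(back), dim(g))
    expect_lt(max(abs(back - g)), 1 / 255)
    unlink(path)
  }
})
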