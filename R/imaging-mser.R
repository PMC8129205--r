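# 8-connected labeling: EBImage::bwlabel (4-connected) plus union-find
# merging of labels that touch diagonally
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  if (inherits(lab, "Image")) lab <- EBImage::imageData(lab)
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    r1 <- seq_len(nr - 1L); c1 <- if (sh[2] == 1L) seq_len(nc - 1L) else 2:nc
    a <- lab[r1, c1]
    b <- lab[r1 + 1L, c1 + sh[2]]
    sel <- a > 0 & b > 0 & a != b
    if (!any(sel)) next
    prs <- unique(cbind(a[sel], b[sel]))
    for (k in seq_len(nrow(prs))) {
      ra <- find(prs[k, 1]); rb <- find(prs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' MSER detector parameters
#'
#' @param delta Stability window on the 8-bit threshold axis: a region's
#'   stability at threshold `t` compares its areas at `t - delta` and
#'   `t + delta`.
#' @param min_area Minimum region area in pixels.
#' @param max_area_frac Maximum region area as a fraction of the raster.
#' @return An `mser_params` object.
#' @export
mser_params <- function(delta = 5L, min_area = 50L, max_area_frac = 0.25) {
  assert_that(delta >= 1, "delta must be >= 1")
  assert_that(min_area >= 1, "min_area must be >= 1")
  assert_that(max_area_frac > 0 && max_area_frac <= 1,
              "max_area_frac must be in (0,1]")
  structure(list(delta = as.integer(delta), min_area = as.integer(min_area),
                 max_area_frac = max_area_frac), class = "mser_params")
}

#' Extract the injection-site blob by MSER
#'
#' Quantizes the enhanced image to 8 bits and sweeps bright extremal
#' regions: for every threshold `t`, the 8-connected component of
#' `{image >= t}` containing the global intensity maximum is tracked, and
#' its relative area change rate over a `delta` window measures stability.
#' The returned blob is the component at the most stable threshold whose
#' area passes the size constraints (ties resolved toward the larger
#' region). A blank image, or one with no stable region within the size
#' bounds, yields an empty blob with a `"no-stable-region"` status.
#'
#' @param img Enhanced `gray_image` (output of the wavelet +
#'   contrast-enhancement front end).
#' @param params An [mser_params()].
#' @return An `injection_blob`: list with `pixels` (two-column matrix of
#'   `(x, y)` pixel coordinates), `mask` (logical matrix), `centroid`,
#'   `area`, `threshold` (selected 8-bit level) and `status`
#'   (`"ok"` or `"no-stable-region"`).
#' @export
extract_injection_site <- function(img, params = mser_params()) {
  stopifnot(inherits(params, "mser_params"))
  m <- unclass(as_gray_image(img))
  q <- round(m * 255)
  empty <- function() structure(
    list(pixels = matrix(numeric(0), 0, 2,
                         dimnames = list(NULL, c("x", "y"))),
         mask = matrix(FALSE, nrow(m), ncol(m)), centroid = c(NA_real_, NA_real_),
         area = 0L, threshold = NA_integer_, status = "no-stable-region"),
    class = "injection_blob")
  tmax <- max(q)
  if (tmax <= 0) { warnf("blank image: no injection blob found"); return(empty()) }
  # the intensity maximum is located on a lightly smoothed copy: under a
  # saturated core many pixels tie at the top, and smoothing places the
  # seed inside the largest bright mass rather than on a stray bright pixel
  sm <- gauss_blur(m, 2)
  seed <- which.max(ifelse(q == tmax, sm, -Inf))

  # area of the seed component at every threshold 1..tmax
  areas <- rep(NA_real_, tmax + 1L)   # index t+1 for threshold t
  masks <- vector("list", tmax + 1L)
  for (t in 0:tmax) {
    lab <- label8(q >= t)
    sl <- lab[seed]
    comp <- lab == sl
    areas[t + 1L] <- sum(comp)
    masks[[t + 1L]] <- comp
  }
  d <- params$delta
  max_area <- params$max_area_frac * length(m)
  # stability needs the full +-delta window: thresholds at the ends of the
  # quantization range would otherwise look spuriously stable
  stab <- rep(Inf, tmax + 1L)
  for (t in seq.int(d, tmax - d)) {
    stab[t + 1L] <- (areas[t - d + 1L] - areas[t + d + 1L]) / areas[t + 1L]
  }
  ok <- areas >= params$min_area & areas <= max_area & is.finite(stab)
  if (!any(ok)) { warnf("no stable region within area bounds"); return(empty()) }
  # maximally stable thresholds = local minima of the instability curve;
  # among them the largest-area region wins (the full blob rather than its
  # saturated core), with residual ties resolved toward higher stability
  n_t <- length(stab)
  local_min <- vapply(seq_len(n_t), function(i) {
    is.finite(stab[i]) &&
      stab[i] <= (if (i > 1) stab[i - 1] else Inf) &&
      stab[i] <= (if (i < n_t) stab[i + 1] else Inf)
  }, logical(1))
  cand <- which(ok & local_min)
  if (length(cand) == 0) cand <- which(ok)
  best <- cand[order(-areas[cand], stab[cand])][1]
  comp <- masks[[best]]
  ij <- which(comp, arr.ind = TRUE)
  pixels <- cbind(x = ij[, 2] - 0.5, y = ij[, 1] - 0.5)
  structure(list(pixels = pixels, mask = comp,
                 centroid = colMeans(pixels), area = nrow(pixels),
                 threshold = best - 1L, status = "ok"),
            class = "injection_blob")
}

#' Annotate an injection blob against an atlas raster
#'
#' Overlays the blob's pixel set on a labeled atlas raster and reports
#' per-region pixel counts and fractions of blob area. The primary region
#' is the one with the largest count; ties break by lexicographic region
#' name. Atlas label 0 means "outside all annotated regions" and is
#' reported only through the fraction remainder.
#'
#' @param blob An `injection_blob` from [extract_injection_site()].
#' @param atlas Integer matrix of region ids, same shape as the source
#'   image (0 = unannotated).
#' @param region_table Optional data frame with columns `id`, `name`
#'   mapping region ids to names; ids without names are named `region_<id>`.
#' @return A data frame (`region`, `pixels`, `fraction`) sorted by count,
#'   with attributes `primary` (region name or `NA`) and `area`.
#' @export
annotate_injection <- function(blob, atlas, region_table = NULL) {
  stopifnot(inherits(blob, "injection_blob"))
  if (blob$area == 0L) {
    out <- data.frame(region = character(0), pixels = integer(0),
                      fraction = numeric(0))
    attr(out, "primary") <- NA_character_; attr(out, "area") <- 0L
    return(out)
  }
  assert_that(all(dim(atlas) == dim(blob$mask)),
              "atlas raster shape must match the image")
  ids <- atlas[blob$mask]
  ids <- ids[ids != 0]
  name_of <- function(id) {
    if (!is.null(region_table)) {
      hit <- match(id, region_table$id)
      ifelse(is.na(hit), paste0("region_", id),
             as.character(region_table$name[hit]))
    } else paste0("region_", id)
  }
  if (length(ids) == 0) {
    warnf("blob lies outside all annotated regions; primary undefined")
    out <- data.frame(region = character(0), pixels = integer(0),
                      fraction = numeric(0))
    attr(out, "primary") <- NA_character_; attr(out, "area") <- blob$area
    return(out)
  }
  tab <- table(ids)
  out <- data.frame(region = name_of(as.integer(names(tab))),
                    pixels = as.integer(tab),
                    fraction = as.integer(tab) / blob$area)
  out <- out[order(-out$pixels, out$region), , drop = FALSE]
  rownames(out) <- NULL
  top <- out[out$pixels == max(out$pixels), "region"]
  attr(out, "primary") <- sort(top)[1]
  attr(out, "area") <- blob$area
  out
}
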