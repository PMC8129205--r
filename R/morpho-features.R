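# sample skewness; 0 for degenerate spread
skewness0 <- function(v) {
  s <- sd(v)
  if (!is.finite(s) || s < 1e-12) return(0)
  mean((v - mean(v))^3) / s^3
}

# box-counting fractal dimension of the dendritic polyline: slope of
# log N(s) vs log(1/s) over dyadic box sizes, on points resampled densely
# along every segment
fractal_dimension <- function(n) {
  segs <- segment_rows(n)
  if (nrow(segs) == 0) return(NA_real_)
  a <- cbind(n$x[segs[, 1]], n$y[segs[, 1]], n$z[segs[, 1]])
  b <- cbind(n$x[segs[, 2]], n$y[segs[, 2]], n$z[segs[, 2]])
  len <- sqrt(rowSums((b - a)^2))
  npts <- pmax(2L, ceiling(len) + 1L)
  seg_id <- rep.int(seq_len(nrow(segs)), npts)
  tt <- (sequence(npts) - 1) / (rep.int(npts, npts) - 1)
  pts <- a[seg_id, , drop = FALSE] +
    tt * (b[seg_id, , drop = FALSE] - a[seg_id, , drop = FALSE])
  ext <- max(apply(pts, 2, function(v) diff(range(v))))
  if (ext < 1e-9) return(NA_real_)
  sizes <- ext / 2^(1:6)
  counts <- vapply(sizes, function(s) {
    nrow(unique(floor(sweep(pts, 2, apply(pts, 2, min)) / s)))
  }, numeric(1))
  fit <- lm(log(counts) ~ log(1 / sizes))
  unname(coef(fit)[2])
}

# angle (degrees) between two 3D vectors
vec_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) return(NA_real_)
  acos(pmin(1, pmax(-1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Extract morphometric features from a neuron
#'
#' Computes the standard soma and dendrite measurements used for group
#' comparison. Soma features come from the type-1 contour nodes, modeled
#' as an ellipsoid: height/width/depth are the y/x/z extents, volume is the
#' ellipsoid volume of those semi-axes, surface area uses the Thomsen
#' approximation, sphericity is `pi^(1/3) (6V)^(2/3) / A`, spherical
#' diameter is the diameter of the volume-equivalent sphere, and skewness
#' is the coordinate-wise third standardized moment of the contour nodes
#' about the soma center (Euclidean skewness is the norm of the three).
#' Dendritic features follow common morphometric conventions: tortuosity is
#' the mean branch path/chord ratio; local bifurcation angle is between the
#' first child segments, remote bifurcation angle between the vectors to
#' the next topological nodes; partition asymmetry averages
#' `|L - R| / (L + R - 2)` over bifurcations (0 where both subtrees are
#' single tips); Rall's ratio averages `(r1^1.5 + r2^1.5) / r0^1.5`; the
#' fractal dimension is box-counting on the resampled polyline.
#'
#' @param n A [neuron()] (typically trimmed and smoothed).
#' @return A one-row data frame of soma and dendritic features.
#' @export
extract_features <- function(n) {
  stopifnot(inherits(n, "neuron"))
  ctr <- soma_center(n)
  soma <- n[n$type == 1L, , drop = FALSE]
  feats <- list()

  if (nrow(soma) >= 3 &&
      all(c(diff(range(soma$x)), diff(range(soma$y))) > 1e-9)) {
    a <- diff(range(soma$x)) / 2; b <- diff(range(soma$y)) / 2
    cz <- max(diff(range(soma$z)) / 2, 1e-9)
    vol <- 4 / 3 * pi * a * b * cz
    pexp <- 1.6075
    surf <- 4 * pi * ((a^pexp * b^pexp + a^pexp * cz^pexp +
                         b^pexp * cz^pexp) / 3)^(1 / pexp)
    feats$soma_volume <- vol
    feats$soma_sphericity <- min(1, pi^(1 / 3) * (6 * vol)^(2 / 3) / surf)
    feats$soma_spherical_diameter <- (6 * vol / pi)^(1 / 3)
    feats$soma_skew_x <- skewness0(soma$x - ctr[1])
    feats$soma_skew_y <- skewness0(soma$y - ctr[2])
    feats$soma_skew_z <- skewness0(soma$z - ctr[3])
    feats$soma_skew_euclidean <- sqrt(feats$soma_skew_x^2 +
                                        feats$soma_skew_y^2 +
                                        feats$soma_skew_z^2)
    feats$soma_height <- diff(range(soma$y))
    feats$soma_width <- diff(range(soma$x))
    feats$soma_depth <- diff(range(soma$z))
    feats$soma_surface_to_volume <- surf / vol
  } else {
    warnf("degenerate soma (fewer than 3 contour nodes or zero extent); soma features set to NA")
    for (f in c("soma_volume", "soma_sphericity", "soma_spherical_diameter",
                "soma_skew_x", "soma_skew_y", "soma_skew_z",
                "soma_skew_euclidean", "soma_height", "soma_width",
                "soma_depth", "soma_surface_to_volume")) feats[[f]] <- NA_real_
  }

  idx <- match(n$parent, n$id)
  is_soma <- n$type == 1L
  dend <- which(!is_soma)
  # dendritic child counts (soma contour children of the root don't count)
  nk_dend <- tabulate(idx[!is_soma & !is.na(idx)], nbins = nrow(n))

  stems <- which(!is_soma & (is.na(idx) | is_soma[idx]))
  bifs <- which(nk_dend >= 2L & !is_soma)
  # a multifurcating root-attached trunk still bifurcates the dendrite field
  tips <- which(!is_soma & nk_dend == 0L)
  paths <- branch_paths(n)

  feats$n_primary_dendrites <- length(stems)
  feats$n_branches <- length(paths)
  feats$n_bifurcations <- length(bifs)
  feats$n_terminal_tips <- length(tips)
  feats$n_nodes <- length(dend)
  feats$fractal_dimension <- fractal_dimension(n)
  tort <- branch_tortuosity(n)
  feats$tortuosity <- if (length(tort)) mean(tort) else NA_real_

  # precomputed dendritic children per node, subtree tip counts (one
  # post-order pass), and single-child successor pointers
  dend_rows <- which(!is_soma & !is.na(idx))
  kids_full <- split(dend_rows, factor(idx[dend_rows], levels = seq_len(nrow(n))))
  kids_of <- function(i) kids_full[[i]]
  pdist <- path_distance(n)
  ordv <- order(pdist)
  tips_sub <- rep(0L, nrow(n))
  for (i in rev(ordv)) {
    if (is_soma[i]) next
    kk <- kids_of(i)
    tips_sub[i] <- if (length(kk) == 0) 1L else sum(tips_sub[kk])
  }

  # bifurcation angles and Rall's ratio
  loc_ang <- rem_ang <- rall <- pa <- numeric(0)
  if (length(bifs) > 0) {
    for (bf in bifs) {
      kids <- kids_of(bf)[1:2]
      pb <- c(n$x[bf], n$y[bf], n$z[bf])
      u <- c(n$x[kids[1]], n$y[kids[1]], n$z[kids[1]]) - pb
      v <- c(n$x[kids[2]], n$y[kids[2]], n$z[kids[2]]) - pb
      loc_ang <- c(loc_ang, vec_angle(u, v))
      remote_end <- function(k) {
        cur <- k
        while (nk_dend[cur] == 1L) cur <- kids_of(cur)
        c(n$x[cur], n$y[cur], n$z[cur]) - pb
      }
      rem_ang <- c(rem_ang, vec_angle(remote_end(kids[1]), remote_end(kids[2])))
      rall <- c(rall, (n$radius[kids[1]]^1.5 + n$radius[kids[2]]^1.5) /
                  n$radius[bf]^1.5)
      l <- tips_sub[kids[1]]; r <- tips_sub[kids[2]]
      pa <- c(pa, if (l + r > 2) abs(l - r) / (l + r - 2) else 0)
    }
  }
  feats$local_bifurcation_angle <- if (length(loc_ang)) mean(loc_ang, na.rm = TRUE) else NA_real_
  feats$remote_bifurcation_angle <- if (length(rem_ang)) mean(rem_ang, na.rm = TRUE) else NA_real_
  feats$partition_asymmetry <- if (length(pa)) mean(pa) else 0
  feats$tips_to_dendrite_ratio <- if (length(stems)) length(tips) / length(stems) else NA_real_
  # branch generation: maximum number of bifurcations crossed root-to-tip
  gen <- rep(0L, nrow(n))
  for (i in ordv) {   # parents precede children along paths
    if (is_soma[i] || is.na(idx[i])) next
    gen[i] <- gen[idx[i]] + as.integer(nk_dend[idx[i]] >= 2L)
  }
  feats$branch_generation <- if (length(dend)) max(gen[dend]) else 0L
  feats$ralls_ratio <- if (length(rall)) mean(rall) else NA_real_

  as.data.frame(feats)
}
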