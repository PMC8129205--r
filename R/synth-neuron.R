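#' Specification of a synthetic neuron morphology
#'
#' Describes a rooted dendritic tree grown as a branching random walk with
#' von Mises-Fisher (vMF) direction persistence. Branch tortuosity is
#' controlled through the vMF concentration, calibrated numerically so the
#' realized mean branch tortuosity (path length / Euclidean chord) matches
#' `tortuosity_target`. Branching approximates a Poisson process along the
#' cable: after each segment of mean length `mean_branch_len` a branch
#' bifurcates with probability `min(1, bifurcation_rate * mean_branch_len)`
#' and otherwise keeps elongating; branches terminate only at `max_extent`
#' (or the branch-order cap), the way dendritic arbors fill their target
#' field rather than dying at random branch points. This keeps per-cell
#' bifurcation counts concentrated around their expectation instead of the
#' heavy-tailed counts a terminate-or-bifurcate process produces.
#'
#' @param soma_dims Length-3 numeric, soma (height, width, depth) in length
#'   units; the soma is rendered as an ellipsoid contour of type-1 nodes.
#' @param n_stems Number of primary dendrites leaving the soma.
#' @param bifurcation_rate Bifurcation intensity per unit branch length.
#' @param tortuosity_target Target mean branch tortuosity (>= 1);
#'   1 grows perfectly straight branches.
#' @param mean_branch_len Mean inter-bifurcation branch length (Gamma
#'   distributed, shape 4).
#' @param max_extent Maximum Euclidean distance from the soma; growth stops
#'   beyond it.
#' @param max_generation Maximum branch order (default 12, a realistic
#'   dendritic bound); capping the order keeps the branching process from
#'   the heavy-tailed excursions of a near-critical Galton-Watson tree.
#' @param seed Integer seed.
#' @return An object of class `neuron_spec`.
#' @export
neuron_spec <- function(soma_dims = c(12, 10, 9), n_stems = 3L,
                        bifurcation_rate = 0.01, tortuosity_target = 1.1,
                        mean_branch_len = 40, max_extent = 400,
                        max_generation = 12L, seed = 1L) {
  assert_that(length(soma_dims) == 3 && all(soma_dims > 0),
              "soma_dims must be 3 positive lengths")
  assert_that(n_stems >= 1, "need at least one stem")
  assert_that(bifurcation_rate >= 0, "bifurcation_rate must be >= 0")
  assert_that(tortuosity_target >= 1, "tortuosity_target must be >= 1")
  assert_that(mean_branch_len > 0 && max_extent > 0,
              "lengths must be positive")
  p <- min(bifurcation_rate * mean_branch_len, 1)
  # size guard: ~S segments per root-to-tip path, ~p*S bifurcations along
  # it, hence ~2^min(G, p*S) paths of ~10*S nodes each
  s_per_path <- ceiling(1.2 * max_extent / mean_branch_len)
  depth <- min(max_generation, p * s_per_path)
  exp_nodes <- n_stems * 2^depth * 10 * s_per_path
  if (exp_nodes > 1e5) {
    stopf("bifurcation_rate * mean_branch_len = %.3f with max_extent %.0f implies ~%.2g nodes (> 1e5); reduce the branching rate, extent, or max_generation",
          p, max_extent, exp_nodes)
  }
  structure(list(soma_dims = as.numeric(soma_dims),
                 n_stems = as.integer(n_stems),
                 bifurcation_rate = bifurcation_rate,
                 tortuosity_target = tortuosity_target,
                 mean_branch_len = mean_branch_len,
                 max_extent = max_extent,
                 max_generation = as.integer(max_generation),
                 seed = as.integer(seed)),
            class = "neuron_spec")
}

# sample n unit vectors from vMF(mu, kappa) in 3D
rvmf <- function(n, mu, kappa) {
  mu <- mu / sqrt(sum(mu^2))
  if (!is.finite(kappa)) return(matrix(mu, n, 3, byrow = TRUE))
  u <- runif(n)
  # inverse-CDF for the cosine, numerically stable for large kappa
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  ang <- runif(n, 0, 2 * pi)
  # orthonormal basis perpendicular to mu
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * mu) * mu; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  s <- sqrt(pmax(0, 1 - w^2))
  sweep(outer(w, mu), 2, 0, "+") + outer(s * cos(ang), e1) +
    outer(s * sin(ang), e2)
}

# one vMF step for every row of a direction matrix (vectorized)
rvmf_step <- function(mu, kappa) {
  n <- nrow(mu)
  if (!is.finite(kappa)) return(mu)
  u <- runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  phi <- runif(n, 0, 2 * pi)
  a <- ifelse(abs(mu[, 1]) < 0.9, 1, 0)
  aux <- cbind(a, 1 - a, 0)                  # (1,0,0) or (0,1,0) per row
  dt <- rowSums(aux * mu)
  e1 <- aux - dt * mu
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(mu[, 2] * e1[, 3] - mu[, 3] * e1[, 2],
              mu[, 3] * e1[, 1] - mu[, 1] * e1[, 3],
              mu[, 1] * e1[, 2] - mu[, 2] * e1[, 1])
  s <- sqrt(pmax(1 - w^2, 0))
  w * mu + s * cos(phi) * e1 + s * sin(phi) * e2
}

# mean tortuosity of a vMF walk at concentration kappa, estimated on a
# fixed-seed pilot sample (deterministic in its arguments). A branch runs
# for a Geometric(p_bif) number of segments (it elongates until it
# bifurcates), each of Gamma(shape 4, mean 10) steps, truncated at
# cap_steps (the extent bound); the path/chord ratio is heavy tailed, so
# the pilot uses a few thousand replicates (vectorized across walks).
pilot_tortuosity <- function(kappa, p_bif = 1, cap_steps = 1000L,
                             n_rep = 2000L) {
  withr::with_seed(20240301L, {
    n_seg <- if (p_bif >= 1) rep(1L, n_rep) else rgeom(n_rep, max(p_bif, 1e-3)) + 1L
    n_steps <- vapply(n_seg, function(k) {
      sum(pmax(2L, round(rgamma(min(k, 200L), shape = 4, rate = 4 / 10))))
    }, numeric(1))
    n_steps <- pmin(pmax(n_steps, 2L), max(cap_steps, 2L))
    horizon <- max(n_steps)
    d <- matrix(rep(c(0, 0, 1), each = n_rep), n_rep, 3L)
    pos <- matrix(0, n_rep, 3L)
    chord <- numeric(n_rep)
    for (s in seq_len(horizon)) {
      d <- rvmf_step(d, kappa)
      pos <- pos + d
      done <- n_steps == s
      if (any(done)) chord[done] <- sqrt(rowSums(pos[done, , drop = FALSE]^2))
    }
    mean(n_steps / pmax(chord, 1e-9))
  })
}

.kappa_cache <- new.env(parent = emptyenv())

# solve vMF concentration for a target mean branch tortuosity (memoized;
# the pilot is deterministic, so the root is a pure function of its
# arguments)
calibrate_kappa <- function(target, p_bif = 1, cap_steps = 1000L) {
  if (target <= 1 + 1e-9) return(Inf)
  key <- sprintf("%.6g|%.4g|%d", target, p_bif, as.integer(cap_steps))
  if (!is.null(.kappa_cache[[key]])) return(.kappa_cache[[key]])
  f <- function(lk) pilot_tortuosity(10^lk, p_bif, cap_steps) - target
  res <- if (f(0) < 0) 1 else 10^uniroot(f, c(0, 4), tol = 0.005)$root
  .kappa_cache[[key]] <- res
  res
}

#' Generate a synthetic neuron morphology
#'
#' Grows the tree described by a [neuron_spec()]: an ellipsoid soma contour,
#' `n_stems` primary dendrites leaving the soma in dispersed directions, and
#' branches elongating as persistent vMF random walks that bifurcate at
#' branch ends. Radii taper geometrically with branch order.
#'
#' @param spec A [neuron_spec()].
#' @return A [neuron()] object; the spec and the realized bifurcation count
#'   are attached as attributes `spec` and `truth`.
#' @export
gen_neuron <- function(spec) {
  stopifnot(inherits(spec, "neuron_spec"))
  withr::local_seed(spec$seed)
  step0 <- spec$mean_branch_len / 10
  kappa <- calibrate_kappa(
    spec$tortuosity_target,
    p_bif = min(1, spec$bifurcation_rate * spec$mean_branch_len),
    cap_steps = round(spec$tortuosity_target * spec$max_extent / step0))
  sd2 <- spec$soma_dims / 2           # (height y, width x, depth z) / 2
  ax <- c(sd2[2], sd2[1], sd2[3])     # semi-axes along x, y, z

  # node storage: per-segment blocks appended in bulk
  blocks <- list()
  nid <- 0L
  add_block <- function(type, xyz, radius, parents) {
    k <- nrow(xyz)
    ids <- nid + seq_len(k)
    blocks[[length(blocks) + 1L]] <<- data.frame(
      id = ids, type = type, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      radius = radius, parent = parents)
    nid <<- ids[k]
    ids
  }
  root <- add_block(1L, matrix(0, 1, 3), mean(ax), -1L)
  # soma contour ring (type 1) on the ellipsoid surface
  ring <- seq(0, 2 * pi, length.out = 9L)[-9L]
  contour <- rbind(cbind(ax[1] * cos(ring), ax[2] * sin(ring), 0),
                   c(0, 0, ax[3]), c(0, 0, -ax[3]))
  add_block(1L, contour, 0.5, root)

  p_bif <- min(1, spec$bifurcation_rate * spec$mean_branch_len)
  step <- spec$mean_branch_len / 10
  # total node budget: a dendritic arbor has finite cable; this bounds the
  # rare explosive excursions of the branching process
  max_nodes <- 2e4
  n_bif <- 0L

  draw_seg_steps <- function(k) {
    pmax(2L, round(rgamma(k, shape = 4, rate = 4 / spec$mean_branch_len) / step))
  }
  # all active lines advance one step per iteration (single vectorized vMF
  # draw); a line ends at max_extent, and at segment ends it either
  # bifurcates (two bent children) or keeps elongating
  dirs <- rvmf(spec$n_stems, c(0, 0, 1), 0.01)
  pos <- dirs * (ax[1] * 0.9)
  par <- rep(root, spec$n_stems)
  ord <- rep(1L, spec$n_stems)
  left <- draw_seg_steps(spec$n_stems)
  cable <- rep(0, spec$n_stems)
  # a root-to-tip line whose cable much exceeds what its tortuosity needs
  # to span the arbor is wandering pathologically and is terminated; this
  # also bounds the bifurcation opportunities any one line can accumulate
  cable_cap <- 1.5 * spec$tortuosity_target * spec$max_extent

  while (length(par) > 0 && nid < max_nodes) {
    dirs <- rvmf_step(dirs, kappa)
    pos2 <- pos + step * dirs
    alive <- sqrt(rowSums(pos2^2)) <= spec$max_extent &
      cable + step <= cable_cap
    if (!any(alive)) break
    dirs <- dirs[alive, , drop = FALSE]; pos <- pos2[alive, , drop = FALSE]
    par_old <- par[alive]; ord <- ord[alive]
    left <- left[alive] - 1L; cable <- cable[alive] + step
    rad <- pmax(0.05, 0.5 * 0.8^(ord - 1L))
    ids <- add_block(3L, pos, rad, par_old)
    par <- ids

    ends <- which(left == 0L)
    if (length(ends) > 0) {
      splits <- ends[ord[ends] < spec$max_generation &
                       runif(length(ends)) < p_bif]
      n_bif <- n_bif + length(splits)
      if (length(splits) > 0) {
        # children bent +-30 degrees away from the parent direction
        d0 <- dirs[splits, , drop = FALSE]
        perp <- rvmf_step(d0, 0.01)
        perp <- perp - rowSums(perp * d0) * d0
        nv <- sqrt(rowSums(perp^2))
        fix <- nv < 1e-8
        perp[fix, ] <- cbind(d0[fix, 2], -d0[fix, 1], 0)
        perp <- perp / pmax(sqrt(rowSums(perp^2)), 1e-12)
        kid1 <- cos(pi / 6) * d0 + sin(pi / 6) * perp
        kid2 <- cos(pi / 6) * d0 - sin(pi / 6) * perp
        dirs <- rbind(dirs[-splits, , drop = FALSE], kid1, kid2)
        pos <- rbind(pos[-splits, , drop = FALSE],
                     pos[splits, , drop = FALSE], pos[splits, , drop = FALSE])
        par <- c(par[-splits], par[splits], par[splits])
        cable <- c(cable[-splits], cable[splits], cable[splits])
        ord <- c(ord[-splits], rep(ord[splits] + 1L, 2))
        left <- c(left[-splits], draw_seg_steps(2L * length(splits)))
      }
      # non-splitting segment ends simply start a fresh segment
      cont <- left == 0L
      if (any(cont)) left[cont] <- draw_seg_steps(sum(cont))
    }
  }

  tab <- do.call(rbind, blocks)
  out <- neuron(tab)
  attr(out, "spec") <- spec
  attr(out, "truth") <- list(n_bifurcations = n_bif, kappa = kappa,
                             p_bif = p_bif)
  out
}
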