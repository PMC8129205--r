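#' Persistence diagram of a neuron under the path-distance filtration
#'
#' Branch decomposition of the dendritic tree filtered by path distance
#' from the soma, with the elder rule at merges: every leaf opens a branch
#' born at the leaf's path distance; when two branches meet at a
#' bifurcation, the one descending from the farther tip survives and the
#' other dies at the merge's path distance. The eldest branch dies at the
#' soma (0). The diagram therefore has exactly one point per leaf, with
#' `birth >= death` under this distal-to-proximal orientation.
#'
#' @param n A [neuron()].
#' @return A `persistence_diagram`: data frame with columns `birth`,
#'   `death`.
#' @export
persistence_diagram <- function(n) {
  stopifnot(inherits(n, "neuron"))
  pd <- path_distance(n)
  idx <- match(n$parent, n$id)
  is_soma <- n$type == 1L
  kids_of <- function(i) which(idx == i & !is_soma)
  points <- list()
  # returns the birth value (max descendant leaf distance) of the
  # surviving branch through node i; emits a diagram point for every
  # branch that dies at node i
  descend <- function(i) {
    kids <- kids_of(i)
    if (length(kids) == 0) return(pd[i])
    births <- vapply(kids, descend, numeric(1))
    eldest <- which.max(births)
    for (k in seq_along(births)[-eldest]) {
      points[[length(points) + 1L]] <<- c(birth = births[k], death = pd[i])
    }
    births[eldest]
  }
  root <- which(n$parent == -1L)
  stems <- which(!is_soma & (is.na(idx) | is_soma[idx]))
  for (s in stems) {
    b <- descend(s)
    points[[length(points) + 1L]] <- c(birth = b, death = 0)
  }
  out <- as.data.frame(do.call(rbind, points) %||% matrix(numeric(0), 0, 2,
    dimnames = list(NULL, c("birth", "death"))))
  class(out) <- c("persistence_diagram", "data.frame")
  out
}

# exact min-cost perfect matching (Hungarian algorithm with potentials,
# O(n^3)); cost is an n x n matrix (Inf allowed), returns the assigned
# column per row
solve_assignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1)      # column potentials, index j+1 (column 0 virtual)
  p <- integer(n + 1)      # p[j+1] = row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

#' Wasserstein distance between persistence diagrams
#'
#' Order-q Wasserstein distance with the L-infinity ground metric on the
#' plane and the diagonal as a partial-matching sink: each diagram point
#' may match a point of the other diagram or project to the diagonal at
#' cost `|birth - death| / 2`. The optimal matching is solved exactly as a
#' linear assignment over the augmented point sets.
#'
#' @param a,b `persistence_diagram` objects (or 2-column matrices).
#' @param q Matching cost order (default 1).
#' @return Non-negative distance.
#' @export
wasserstein_dist <- function(a, b, q = 1) {
  assert_that(q >= 1, "q must be >= 1")
  pa <- as.matrix(as.data.frame(a)); pb <- as.matrix(as.data.frame(b))
  na <- nrow(pa); nb <- nrow(pb)
  if (na == 0 && nb == 0) return(0)
  diag_cost <- function(p) abs(p[, 1] - p[, 2]) / 2
  n <- na + nb
  cost <- matrix(0, n, n)
  if (na > 0 && nb > 0) {
    for (i in seq_len(na)) {
      cost[i, seq_len(nb)] <- pmax(abs(pa[i, 1] - pb[, 1]),
                                   abs(pa[i, 2] - pb[, 2]))^q
    }
  }
  # any a-point may take any diagonal slot at its own projection cost
  # (rows: a-points then nb ghosts; columns: b-points then na ghosts)
  if (na > 0) cost[seq_len(na), nb + seq_len(na)] <- diag_cost(pa)^q
  if (nb > 0) cost[na + seq_len(nb), seq_len(nb)] <-
    matrix(diag_cost(pb)^q, nb, nb, byrow = TRUE)
  # ghost-to-ghost matches cost 0 (already 0)
  asg <- solve_assignment(cost)
  total <- sum(cost[cbind(seq_len(n), asg)])
  total^(1 / q)
}

#' Pairwise persistence distances within and between groups
#'
#' Computes the full pairwise Wasserstein distance matrix over a cohort of
#' neurons and summarizes it as mean distances per group pair (within-group
#' pairs on the diagonal).
#'
#' @param neurons List of [neuron()] objects (or precomputed
#'   `persistence_diagram`s).
#' @param groups Group label per neuron.
#' @param q Wasserstein order (default 1).
#' @return List with `distances` (symmetric matrix, zero diagonal) and
#'   `group_means` (matrix of mean distances per group pair).
#' @export
group_distance_summary <- function(neurons, groups, q = 1) {
  assert_that(length(neurons) >= 2, "need at least two neurons")
  groups <- factor(groups)
  assert_that(length(groups) == length(neurons),
              "groups must label every neuron")
  diagrams <- lapply(neurons, function(x) {
    if (inherits(x, "persistence_diagram")) x else persistence_diagram(x)
  })
  m <- length(diagrams)
  d <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      d[i, j] <- d[j, i] <- wasserstein_dist(diagrams[[i]], diagrams[[j]], q)
    }
  }
  gl <- levels(groups)
  gm <- matrix(NA_real_, length(gl), length(gl), dimnames = list(gl, gl))
  for (gi in seq_along(gl)) {
    for (gj in gi:length(gl)) {
      ii <- which(groups == gl[gi]); jj <- which(groups == gl[gj])
      if (gi == gj) {
        if (length(ii) > 1) {
          pairs <- utils::combn(ii, 2)
          gm[gi, gj] <- mean(d[cbind(pairs[1, ], pairs[2, ])])
        }
      } else {
        gm[gi, gj] <- gm[gj, gi] <- mean(d[ii, jj, drop = FALSE])
      }
    }
  }
  list(distances = d, group_means = gm)
}
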