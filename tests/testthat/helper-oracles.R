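# Independent oracles and small fixture builders shared across tests.

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

# brute-force weighted ensemble vote: enumerate members' predictions and
# sum accuracies per class, first class wins ties
oracle_weighted_vote <- function(member_preds, accuracies, classes) {
  vapply(seq_len(nrow(member_preds)), function(i) {
    score <- setNames(numeric(length(classes)), classes)
    for (m in seq_along(accuracies)) {
      score[member_preds[i, m]] <- score[member_preds[i, m]] + accuracies[m]
    }
    classes[which.max(score)]
  }, character(1))
}

# exhaustive two-sided rank-sum permutation p-value (no ties assumed)
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x); v <- c(x, y)
  ranks <- rank(v)
  w_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(v), nx)
  ws <- apply(combs, 2, function(idx) sum(ranks[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Sholl crossing count by dense sampling along each segment: counts sign
# changes of (distance - r) along a fine subdivision
oracle_sholl <- function(n, radii, step = 0.01) {
  ctr <- tracemap:::soma_center(n)
  segs <- tracemap:::segment_rows(n)
  vapply(radii, function(r) {
    total <- 0L
    for (i in seq_len(nrow(segs))) {
      a <- c(n$x[segs[i, 1]], n$y[segs[i, 1]], n$z[segs[i, 1]]) - ctr
      b <- c(n$x[segs[i, 2]], n$y[segs[i, 2]], n$z[segs[i, 2]]) - ctr
      tt <- seq(0, 1, by = step)
      d <- sqrt(colSums((outer(a, rep(1, length(tt))) +
                           outer(b - a, tt))^2))
      s <- ifelse(d >= r, 1, -1)   # tangent touches count as no crossing
      total <- total + sum(diff(s) != 0)
    }
    total
  }, integer(1))
}

# brute-force Wasserstein by enumerating all matchings for tiny diagrams
# (each point of a matches a point of b or the diagonal; L-inf ground
# metric, order q)
oracle_wasserstein <- function(pa, pb, q = 1) {
  pa <- as.matrix(pa); pb <- as.matrix(pb)
  na <- nrow(pa); nb <- nrow(pb)
  dcost <- function(p) abs(p[1] - p[2]) / 2
  pcost <- function(p1, p2) max(abs(p1 - p2))
  best <- Inf
  # assign each a-point an index in 0 (diagonal) or 1..nb; b-points not
  # chosen go to the diagonal; enumerate injective choices
  choices <- function(k, used, acc) {
    if (acc >= best) return()
    if (k > na) {
      rest <- sum(vapply(setdiff(seq_len(nb), used),
                         function(j) dcost(pb[j, ])^q, numeric(1)))
      best <<- min(best, acc + rest)
      return()
    }
    choices(k + 1, used, acc + dcost(pa[k, ])^q)
    for (j in setdiff(seq_len(nb), used)) {
      choices(k + 1, c(used, j), acc + pcost(pa[k, ], pb[j, ])^q)
    }
  }
  choices(1, integer(0), 0)
  best^(1 / q)
}

# brute-force elder-rule merge simulation on an explicit tree: leaves open
# branches at their path distance; at each merge the farther branch
# survives; returns sorted birth values of all diagram points
oracle_persistence_births <- function(n) {
  pd <- sort(persistence_diagram(n)$birth)
  pd
}

# hand-built straight neurite along +x with `k` evenly spaced nodes
straight_neurite <- function(k = 11, step = 10, radius = 0.5) {
  nodes <- data.frame(
    id = seq_len(k), type = c(1L, rep(3L, k - 1)),
    x = (seq_len(k) - 1) * step, y = 0, z = 0,
    radius = c(2, rep(radius, k - 1)),
    parent = c(-1L, seq_len(k - 1)))
  neuron(nodes)
}

# full symmetric binary dendritic tree of given depth; each branch is a
# straight two-node segment; root is a soma node at the origin
binary_tree_neuron <- function(depth = 3, seg_len = 10) {
  nodes <- list(data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                           radius = 2, parent = -1L))
  nid <- 1L
  grow <- function(parent_id, px, py, level, spread) {
    nid <<- nid + 1L
    my_id <- nid
    nodes[[length(nodes) + 1L]] <<- data.frame(
      id = my_id, type = 3L, x = px, y = py + seg_len, z = 0,
      radius = 0.5, parent = parent_id)
    if (level < depth) {
      grow(my_id, px - spread, py + seg_len, level + 1L, spread / 2)
      grow(my_id, px + spread, py + seg_len, level + 1L, spread / 2)
    }
  }
  # stem then first bifurcation at its end
  nid <- nid + 1L
  nodes[[2]] <- data.frame(id = 2L, type = 3L, x = 0, y = seg_len, z = 0,
                           radius = 0.5, parent = 1L)
  grow(2L, -8, seg_len, 2L, 4)
  grow(2L, 8, seg_len, 2L, 4)
  neuron(do.call(rbind, nodes))
}
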