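test_that("trimming cuts at the first out-of-radius node and removes re-entrant parts", {
  n <- straight_neurite(k = 11, step = 35)   # tips at x = 350
  expect_identical(trim_neuron(n, 1000), n)
  tr <- trim_neuron(n, 300)
  expect_equal(max(tr$x), 280)               # last node at distance <= 300
  expect_true(all(tr$id %in% n$id))

  # path that exits to 320 then re-enters to 250: distal part must go
  xs <- c(0, 100, 200, 320, 250, 220)
  reent <- neuron(data.frame(id = 1:6, type = c(1L, rep(3L, 5)),
                             x = xs, y = 0, z = 0, radius = 1,
                             parent = c(-1L, 1:5)))
  tr2 <- trim_neuron(reent, 300)
  expect_equal(nrow(tr2), 3)
  expect_equal(max(tr2$x), 200)
})

test_that("LOESS smoothing is exact on collinear branches and fixes topology", {
  n <- straight_neurite(k = 15, step = 7)
  sm <- loess_smooth_neuron(n)
  expect_lt(max(abs(sm$x - n$x), abs(sm$y - n$y), abs(sm$z - n$z)), 1e-9)

  # zig-zag branch: endpoints and bifurcations bit-identical, tortuosity drops
  k <- 21
  zig <- neuron(data.frame(id = 1:k, type = c(1L, rep(3L, k - 1)),
                           x = (0:(k - 1)) * 5,
                           y = rep(c(1, -1), length.out = k), z = 0,
                           radius = 1, parent = c(-1L, 1:(k - 1))))
  smz <- loess_smooth_neuron(zig)
  expect_identical(smz$x[c(1, k)], zig$x[c(1, k)])
  expect_identical(smz$y[c(1, k)], zig$y[c(1, k)])
  expect_lt(mean(tracemap:::branch_tortuosity(smz)),
            mean(tracemap:::branch_tortuosity(zig)))
  expect_identical(smz$id, zig$id)
  expect_identical(smz$parent, zig$parent)

  bt <- binary_tree_neuron(4)
  smb <- loess_smooth_neuron(bt)
  topo <- tracemap:::n_children(bt) >= 2 | tracemap:::n_children(bt) == 0
  expect_identical(smb$x[topo], bt$x[topo])
  expect_identical(smb$y[topo], bt$y[topo])
})

test_that("classic Sholl counts match segment-sphere enumeration", {
  n <- straight_neurite(k = 11, step = 10)   # length 100 from soma
  sh <- sholl_classic(n, c(25, 55, 95, 150))
  expect_equal(sh$crossings, c(1L, 1L, 1L, 0L))
  # neuron entirely inside the smallest radius
  expect_equal(sholl_classic(n, c(150, 200))$crossings, c(0L, 0L))

  bt <- binary_tree_neuron(4)
  radii <- c(5.5, 15.5, 25.5, 35.5, 45.5)
  expect_equal(sholl_classic(bt, radii)$crossings,
               oracle_sholl(bt, radii, step = 0.002))

  for (s in 1:5) {
    rn <- gen_neuron(neuron_spec(seed = s, bifurcation_rate = 0.008,
                                 mean_branch_len = 30, max_extent = 200))
    radii <- c(20.3, 50.7, 90.1, 130.9)
    expect_equal(sholl_classic(rn, radii)$crossings,
                 oracle_sholl(rn, radii, step = 0.002))
  }
})

test_that("surface-area Sholl conserves total area and localizes mass", {
  n <- straight_neurite(k = 41, step = 5, radius = 0.8)
  n$radius[] <- 1   # uniform cable: every bin holds the same area
  ss <- sholl_surface(n, 10)
  expect_equal(ss$fraction, rep(0.1, 10), tolerance = 1e-9)
  segs <- tracemap:::segment_rows(n)
  len <- tracemap:::segment_lengths(n, segs)
  total <- sum(pi * (n$radius[segs[, 1]] + n$radius[segs[, 2]]) *
                 sqrt(len^2 + (n$radius[segs[, 1]] - n$radius[segs[, 2]])^2))
  expect_equal(sum(ss$area), total, tolerance = 1e-9)

  # fat mid-path segment dominates its bin
  k <- 21
  fat <- neuron(data.frame(id = 1:k, type = c(1L, rep(3L, k - 1)),
                           x = (0:(k - 1)) * 10, y = 0, z = 0,
                           radius = c(2, ifelse(abs((1:(k - 1)) - 10) <= 1,
                                                4, 0.2)),
                           parent = c(-1L, 1:(k - 1))))
  sf <- sholl_surface(fat, 10)
  peak <- sf$bin_center[which.max(sf$area)]
  expect_gte(peak, 0.4)
  expect_lte(peak, 0.6)
})

test_that("morphometric features match hand counts on canonical trees", {
  n <- straight_neurite(k = 11, step = 10)
  expect_warning(f <- extract_features(n), "degenerate soma")
  expect_equal(f$n_bifurcations, 0)
  expect_equal(f$n_terminal_tips, 1)
  expect_equal(f$n_primary_dendrites, 1)
  expect_equal(f$partition_asymmetry, 0)
  expect_equal(f$tortuosity, 1, tolerance = 1e-9)

  bt <- binary_tree_neuron(4)
  fb <- suppressWarnings(extract_features(bt))
  expect_equal(fb$n_bifurcations, 7)
  expect_equal(fb$n_terminal_tips, 8)
  expect_equal(fb$branch_generation, 3)
  expect_equal(fb$partition_asymmetry, 0)
  expect_equal(fb$n_branches, 15)

  # generated soma: ellipsoid contour reproduces requested dimensions
  g <- gen_neuron(neuron_spec(soma_dims = c(12, 10, 8), seed = 3))
  fg <- extract_features(g)
  expect_equal(fg$soma_width, 10, tolerance = 1e-6)
  expect_equal(fg$soma_height, 12, tolerance = 1e-6)
  expect_equal(fg$soma_depth, 8, tolerance = 1e-6)
  expect_true(fg$soma_sphericity > 0 && fg$soma_sphericity <= 1)
  expect_equal(fg$soma_volume, 4 / 3 * pi * 5 * 6 * 4, tolerance = 1e-6)
})

test_that("PCA embedding standardizes, drops constants, and separates planted groups", {
  withr::with_seed(10, {
    g1 <- matrix(rnorm(30, 0, 1), 10, 3)
    g2 <- matrix(rnorm(30, 8, 1), 10, 3)
    feats <- as.data.frame(rbind(g1, g2))
    feats$const <- 5
  })
  expect_warning(emb <- pca_embed(feats), "constant")
  expect_equal(emb$dropped, "const")
  # duplicated rows embed identically
  dup <- feats[c(1, 1, 2, 5, 9, 12, 15, 18), 1:3]
  emb2 <- pca_embed(dup)
  expect_equal(emb2$scores[1, ], emb2$scores[2, ])
  # perfectly correlated pair: PC1 captures everything
  two <- data.frame(a = 1:10, b = 2 * (1:10) + 3)
  expect_gt(pca_embed(two, 2)$explained[1], 0.999)
  # planted separation: silhouette of groups in PC space
  lab <- rep(1:2, each = 10)
  sc <- emb$scores
  sil <- vapply(seq_len(nrow(sc)), function(i) {
    d <- sqrt(rowSums((sc - matrix(sc[i, ], nrow(sc), ncol(sc),
                                   byrow = TRUE))^2))
    a <- mean(d[lab == lab[i]][d[lab == lab[i]] > 0])
    b <- mean(d[lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("rank-sum tests match exhaustive permutation and BH hand computation", {
  res <- pairwise_wilcoxon_fdr(data.frame(v = c(1, 2, 3, 4)),
                               c("a", "a", "b", "b"))
  expect_equal(res$W, 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)

  same <- pairwise_wilcoxon_fdr(data.frame(v = rep(2, 6)),
                                rep(c("a", "b"), each = 3))
  expect_equal(same$p, 1)
  expect_equal(same$p_adj, 1)

  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))

  # exhaustive permutation oracle, n1 = n2 <= 6, no ties
  withr::with_seed(33, {
    for (rep_i in 1:6) {
      x <- sample(100, 5); y <- sample(200, 6) + 300
      y <- sample(c(x + 0.5, y))[1:6]  # interleave without ties
      p_pkg <- pairwise_wilcoxon_fdr(
        data.frame(v = c(x, y)), rep(c("a", "b"), c(5, 6)))$p
      expect_equal(p_pkg, oracle_wilcoxon_p(x, y), tolerance = 1e-12)
    }
  })
  # adjusted p never drops below raw p across a synthetic family
  withr::with_seed(8, {
    feats <- as.data.frame(matrix(rnorm(60), 12, 5))
    res2 <- pairwise_wilcoxon_fdr(feats, rep(c("a", "b", "c"), each = 4))
  })
  expect_true(all(res2$p_adj >= res2$p - 1e-12))
  expect_true(all(res2$p_adj <= 1))
})

test_that("persistence diagrams follow the elder rule with one point per leaf", {
  n <- straight_neurite(k = 11, step = 10)
  pd <- persistence_diagram(n)
  expect_equal(nrow(pd), 1)
  expect_equal(pd$birth, 100)
  expect_equal(pd$death, 0)

  bt <- binary_tree_neuron(4, seg_len = 10)
  pdb <- persistence_diagram(bt)
  expect_equal(nrow(pdb), 8)
  expect_equal(sum(pdb$death == 0), 1)
  expect_true(all(pdb$birth >= pdb$death))
  # merge distances follow the tree geometry: first bifurcation at path
  # distance 10, second tier at 10 + sqrt(8^2 + 10^2), third tier one
  # sqrt(4^2 + 10^2) segment further; elder rule kills one branch per merge
  d1 <- 10; d2 <- d1 + sqrt(164); d3 <- d2 + sqrt(116)
  expect_equal(sort(pdb$death), sort(c(0, d1, rep(d2, 2), rep(d3, 4))),
               tolerance = 1e-9)
  # all tips equidistant: every birth equals d3 + sqrt(2^2 + 10^2)
  expect_equal(pdb$birth, rep(d3 + sqrt(104), 8), tolerance = 1e-9)

  for (s in 1:10) {
    rn <- gen_neuron(neuron_spec(seed = s, bifurcation_rate = 0.009,
                                 mean_branch_len = 30))
    expect_equal(nrow(persistence_diagram(rn)),
                 extract_features(rn)$n_terminal_tips)
  }
})

test_that("Wasserstein distance matches brute force and satisfies metric axioms", {
  d1 <- data.frame(birth = c(1), death = c(0))
  empty <- data.frame(birth = numeric(0), death = numeric(0))
  expect_equal(wasserstein_dist(d1, empty), 0.5)
  expect_equal(wasserstein_dist(d1, d1), 0)

  withr::with_seed(14, {
    rand_diag <- function(k) {
      b <- runif(k, 0, 10); d <- b * runif(k)
      data.frame(birth = b, death = d)
    }
    for (rep_i in 1:8) {
      a <- rand_diag(sample(0:4, 1)); b <- rand_diag(sample(0:4, 1))
      expect_equal(wasserstein_dist(a, b), oracle_wasserstein(a, b),
                   tolerance = 1e-9)
      expect_equal(wasserstein_dist(a, b), wasserstein_dist(b, a),
                   tolerance = 1e-9)
    }
    for (rep_i in 1:5) {
      a <- rand_diag(3); b <- rand_diag(4); cc <- rand_diag(2)
      expect_lte(wasserstein_dist(a, cc),
                 wasserstein_dist(a, b) + wasserstein_dist(b, cc) + 1e-9)
    }
  })
})

test_that("group distance summaries separate structurally different cohorts", {
  shallow <- lapply(1:4, function(s) gen_neuron(neuron_spec(
    seed = s, bifurcation_rate = 0.002, mean_branch_len = 25,
    max_extent = 150)))
  deep <- lapply(5:8, function(s) gen_neuron(neuron_spec(
    seed = s, bifurcation_rate = 0.012, mean_branch_len = 25,
    max_extent = 280)))
  gs <- group_distance_summary(c(shallow, deep), rep(c("sh", "dp"), each = 4))
  expect_true(isSymmetric(gs$distances))
  expect_true(all(diag(gs$distances) == 0))
  expect_gt(gs$group_means["sh", "dp"],
            min(gs$group_means["sh", "sh"], gs$group_means["dp", "dp"]))

  same <- rep(list(gen_neuron(neuron_spec(seed = 1))), 3)
  gsame <- group_distance_summary(same, rep("g", 3))
  expect_true(all(gsame$distances == 0))
})
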