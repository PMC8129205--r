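make_case <- function(inj, tgts, vals, kind = "anterograde") {
  data.frame(injection_id = inj, target_id = tgts, value = vals,
             tracer_kind = kind)
}

test_that("aggregation builds one row per injection and sums duplicates", {
  one <- aggregate_annotations(list(make_case("i1", c("a", "b"), c(1, 2))))
  expect_equal(dim(one), c(1L, 2L))
  expect_equal(unclass(one)["i1", c("a", "b")], c(a = 1, b = 2))

  two <- aggregate_annotations(list(
    make_case("i1", c("a", "b"), c(1, 2)),
    make_case("i2", c("c", "d"), c(3, 4))))
  expect_equal(unclass(two)["i1", c("c", "d")], c(c = 0, d = 0))
  expect_equal(unclass(two)["i2", c("c", "d")], c(c = 3, d = 4))

  dup <- aggregate_annotations(list(
    make_case("i1", c("a", "a", "b"), c(1, 5, 2))))
  expect_equal(unclass(dup)["i1", "a"], 6)

  expect_error(aggregate_annotations(list(
    make_case("i1", "a", 1, "anterograde"),
    make_case("i1", "b", 1, "retrograde"))), "conflicting tracer_kind")
})

test_that("thresholding keeps entries at threshold and zeroes the rest", {
  m <- annotation_matrix(rbind(i1 = c(0.0045, 0.0044),
                               i2 = c(8, 7)),
                         tracer_kind = c("anterograde", "retrograde"))
  thr <- apply_thresholds(m)
  expect_equal(unname(unclass(thr)[1, ]), c(0.0045, 0))
  expect_equal(unname(unclass(thr)[2, ]), c(8, 0))
  z <- annotation_matrix(matrix(0, 2, 3))
  expect_equal(unclass(apply_thresholds(z)), unclass(z))
})

test_that("thresholding never increases entries; normalization preserves proportions", {
  withr::with_seed(4, {
    m <- annotation_matrix(matrix(rexp(60, 200), 5, 12),
                           tracer_kind = rep(c("anterograde", "retrograde"),
                                             length.out = 5))
  })
  thr <- apply_thresholds(m)
  expect_true(all(unclass(thr) <= unclass(m)))
  thr <- annotation_matrix(unclass(thr) + 0.001)  # ensure positive rows
  nm <- normalize_rows(thr)
  totals <- rowSums(nm)
  expect_equal(max(abs(totals - max(rowSums(thr)))), 0, tolerance = 1e-12)
  # within-row proportions unchanged
  p_before <- unclass(thr) / rowSums(thr)
  p_after <- unclass(nm) / rowSums(nm)
  expect_equal(p_after, p_before, tolerance = 1e-12)
  # the max-total row is bit-for-bit unchanged
  imax <- which.max(rowSums(thr))
  expect_identical(unclass(nm)[imax, ], unclass(thr)[imax, ])
})

test_that("row normalization equalizes totals and flags zero rows", {
  m <- annotation_matrix(rbind(a = c(4, 6), b = c(12, 8), c = c(2, 3)))
  nm <- normalize_rows(m)
  expect_equal(unname(rowSums(nm)), c(20, 20, 20))
  one <- annotation_matrix(matrix(c(1, 2), 1, 2))
  expect_identical(unclass(normalize_rows(one)), unclass(one))
  withz <- annotation_matrix(rbind(a = c(1, 1), b = c(0, 0)))
  expect_warning(nz <- normalize_rows(withz), "zero total")
  expect_equal(unname(unclass(nz)["b", ]), c(0, 0))
  allz <- annotation_matrix(matrix(0, 2, 2))
  expect_error(normalize_rows(allz), "all rows")
})

test_that("Louvain separates disconnected blocks and is reproducible", {
  blocks <- list(list(injections = 1:3, targets = 1:15, mean = 2),
                 list(injections = 4:6, targets = 16:30, mean = 2))
  gen <- gen_annotation_matrix(planted_matrix_spec(6, 30, blocks, seed = 2))
  runs <- louvain_runs(gen$matrix, n_runs = 10, seed = 5)
  for (p in runs) {
    expect_equal(length(unique(p)), 2)
    expect_equal(ari(p[names(gen$partition)], gen$partition), 1)
  }
  r1 <- louvain_runs(gen$matrix, n_runs = 1, seed = 42)[[1]]
  r2 <- louvain_runs(gen$matrix, n_runs = 1, seed = 42)[[1]]
  expect_identical(r1, r2)
})

test_that("single-run modularity beats the trivial one-community partition", {
  blocks <- list(list(injections = 1:4, targets = 1:20, mean = 2),
                 list(injections = 5:8, targets = 21:40, mean = 2))
  gen <- gen_annotation_matrix(planted_matrix_spec(8, 40, blocks,
                                                   noise_rate = 0.05,
                                                   seed = 6))
  g <- tracemap:::bipartite_graph(gen$matrix)
  p <- louvain_runs(gen$matrix, n_runs = 1, seed = 1)[[1]]
  mod_p <- igraph::modularity(g, p[igraph::V(g)$name] + 1,
                              weights = igraph::E(g)$weight)
  mod_triv <- igraph::modularity(g, rep(1, igraph::vcount(g)),
                                 weights = igraph::E(g)$weight)
  expect_gt(mod_p, mod_triv)
})

test_that("consensus of identical partitions is that partition and is idempotent", {
  p <- structure(setNames(c(0L, 0L, 1L, 1L), c("a", "b", "c", "d")),
                 class = "community_partition")
  cons <- consensus_partition(rep(list(p), 100), seed = 1)
  expect_equal(unclass(cons)[names(p)], unclass(p)[names(p)])
  cons2 <- consensus_partition(list(cons), seed = 1)
  expect_equal(unclass(cons2)[names(p)], unclass(cons)[names(p)])
})

test_that("consensus assigns a wavering node to its majority block", {
  base <- setNames(c(0L, 0L, 0L, 1L, 1L, 1L, 0L),
                   c(paste0("a", 1:3), paste0("b", 1:3), "w"))
  alt <- base; alt["w"] <- 1L
  # 60% of runs put w with block a, 40% with block b
  parts <- c(rep(list(structure(base, class = "community_partition")), 60),
             rep(list(structure(alt, class = "community_partition")), 40))
  cons <- consensus_partition(parts, seed = 3)
  expect_equal(unname(cons["w"]), unname(cons["a1"]))
  expect_equal(length(unique(cons)), 2)
})

test_that("consensus recovers planted partitions exactly on clean blocks", {
  blocks <- list(list(injections = 1:4, targets = 1:25, mean = 2),
                 list(injections = 5:8, targets = 26:50, mean = 2))
  gen <- gen_annotation_matrix(planted_matrix_spec(8, 50, blocks, seed = 11))
  runs <- louvain_runs(normalize_rows(gen$matrix), n_runs = 25, seed = 11)
  cons <- consensus_partition(runs, seed = 11)
  expect_equal(ari(cons[names(gen$partition)], gen$partition), 1)
})

test_that("community reordering makes planted blocks contiguous", {
  blocks <- list(list(injections = 1:3, targets = 1:12, mean = 2),
                 list(injections = 4:6, targets = 13:24, mean = 2))
  gen <- gen_annotation_matrix(planted_matrix_spec(6, 24, blocks, seed = 8))
  # shuffle rows and columns, then ask the partition to restore blocks
  withr::with_seed(1, {
    m <- unclass(gen$matrix)[sample(6), sample(24)]
  })
  ms <- annotation_matrix(m)
  ro <- reorder_for_matrix(ms, gen$partition)
  com_rows <- gen$partition[ro$rows]
  com_cols <- gen$partition[ro$cols]
  expect_equal(com_rows, sort(com_rows))
  expect_equal(com_cols, sort(com_cols))
  # single community: ordering is by strength
  one <- annotation_matrix(rbind(i1 = c(5, 1), i2 = c(9, 2)))
  part <- setNames(rep(0L, 4), c("i1", "i2", colnames(one)))
  ro1 <- reorder_for_matrix(one, part)
  expect_equal(ro1$rows, c("i2", "i1"))
})

test_that("community color coding paints pixels by strongest in-community injection", {
  vals <- rbind(A = c(0.9, 0), B = c(0.1, 0.8))
  colnames(vals) <- c("L1_r0_c0", "L1_r0_c1")
  m <- annotation_matrix(vals, colors = c("#FF0000", "#0000FF"))
  part <- setNames(c(0L, 0L, 0L, 0L), c("A", "B", colnames(vals)))
  class(part) <- "community_partition"
  seg <- matrix(FALSE, 10, 350)
  seg[2, c(5, 200)] <- TRUE
  maps <- color_code(part, m, list(L1 = seg))
  # grid cell 0 (columns 1-175): A wins 0.9 vs 0.1 -> red
  expect_equal(maps$L1$rgb[2, 5, ], c(1, 0, 0))
  # grid cell 1: B wins 0.8 vs 0 -> blue
  expect_equal(maps$L1$rgb[2, 200, ], c(0, 0, 1))
  expect_lte(length(maps$L1$legend), nrow(m))

  # single injection: every segmented pixel gets its color
  m1 <- annotation_matrix(matrix(c(1, 2), 1, 2,
                                 dimnames = list("A", colnames(vals))),
                          colors = "#00FF00")
  p1 <- setNames(rep(0L, 3), c("A", colnames(vals)))
  maps1 <- color_code(p1, m1, list(L1 = seg))
  expect_equal(maps1$L1$rgb[2, 5, ], c(0, 1, 0))
  expect_equal(maps1$L1$rgb[2, 200, ], c(0, 1, 0))
})

test_that("stacked-bar fractions and top ROIs match brute-force sums", {
  vals <- rbind(i1 = c(2, 0, 0, 0), i2 = c(1, 1, 1, 1))
  colnames(vals) <- paste0("g", 1:4)
  cm <- data.frame(level = c("L1", "L1", "L2", "L2"),
                   roi = c("ACB", "CP", "ACB", "OT"))
  m <- annotation_matrix(vals, col_meta = cm)
  sb <- stacked_bar_data(m)
  f <- sb$fractions
  expect_equal(f$fraction[f$injection == "i1" & f$level == "L1"], 1)
  expect_equal(f$fraction[f$injection == "i1" & f$level == "L2"], 0)
  expect_equal(f$fraction[f$injection == "i2" & f$level == "L1"], 0.5)
  # top-2 ROIs per level by summed label
  t1 <- sb$top_rois[sb$top_rois$level == "L1", ]
  expect_equal(t1$roi[t1$rank == 1], "ACB")  # 3 vs 1
  t2 <- sb$top_rois[sb$top_rois$level == "L2", ]
  expect_equal(sort(t2$roi), c("ACB", "OT"))
})

test_that("projection-vector clustering recovers planted groups under cosine distance", {
  # two identical vectors merge at distance 0
  two <- rbind(a = c(1, 2, 3), b = c(2, 4, 6))
  cl2 <- cluster_projection_vectors(two)
  expect_equal(as.numeric(cl2$distances), 0, tolerance = 1e-12)
  # orthogonal vectors sit at distance 1
  orth <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(as.numeric(cluster_projection_vectors(orth)$distances), 1)
  expect_error(cluster_projection_vectors(rbind(a = c(0, 0), b = c(1, 1))),
               "zero projection")
  # three planted groups of direction-coherent vectors
  withr::with_seed(6, {
    base <- diag(3)[rep(1:3, each = 5), ]
    noise <- matrix(runif(45, 0, 0.12), 15, 3)
    vecs <- base + noise
    rownames(vecs) <- paste0(rep(c("am", "al", "ac"), each = 5), 1:5)
  })
  cl <- cluster_projection_vectors(vecs, k = 3)
  expect_equal(ari(cl$groups, rep(1:3, each = 5)), 1)
})

test_that("tertile binning follows the stated tie rules", {
  b <- tertile_bins(1:9)
  expect_equal(as.character(b[7:9]), rep("strong", 3))
  expect_equal(as.character(b[1:3]), rep("weak", 3))
  expect_equal(as.character(tertile_bins(rep(2, 5))), rep("strong", 5))
  expect_error(tertile_bins(c(1, 2)), "at least 3")
  withr::with_seed(2, u <- runif(100))
  sizes <- sort(as.vector(table(tertile_bins(u))))
  expect_true(all(abs(sizes - c(33, 33, 34)) <= 1))
})
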