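#' Injection-by-target annotation matrix
#'
#' Weighted matrix of tracer annotation values: one row per injection
#' (pixel densities for anterograde tracers, cell counts for retrograde),
#' one column per target (an atlas grid cell or a named ROI). Row metadata
#' carry the tracer kind and a display color per injection; column metadata
#' may carry the atlas level and ROI of each target.
#'
#' @param m Non-negative numeric matrix with unique row and column names.
#' @param tracer_kind Character per row, `"anterograde"` or `"retrograde"`
#'   (recycled).
#' @param colors Optional display color per row (recycled).
#' @param col_meta Optional data frame of per-column metadata (e.g.
#'   `level`, `roi`), one row per matrix column.
#' @return An `annotation_matrix`.
#' @export
annotation_matrix <- function(m, tracer_kind = "anterograde", colors = NULL,
                              col_meta = NULL) {
  m <- as.matrix(m)
  assert_that(all(is.finite(m)) && all(m >= 0),
              "annotation values must be finite and non-negative")
  if (is.null(rownames(m))) rownames(m) <- paste0("inj", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("tgt", seq_len(ncol(m)))
  assert_that(!anyDuplicated(colnames(m)) && !anyDuplicated(rownames(m)),
              "row and column ids must be unique")
  tracer_kind <- rep_len(tracer_kind, nrow(m))
  assert_that(all(tracer_kind %in% c("anterograde", "retrograde")),
              "tracer_kind must be 'anterograde' or 'retrograde'")
  names(tracer_kind) <- rownames(m)
  if (is.null(colors)) {
    colors <- grDevices::hcl.colors(max(nrow(m), 2L), "Dark 3")[seq_len(nrow(m))]
  }
  colors <- setNames(rep_len(colors, nrow(m)), rownames(m))
  if (!is.null(col_meta)) {
    assert_that(nrow(col_meta) == ncol(m),
                "col_meta must have one row per matrix column")
    rownames(col_meta) <- colnames(m)
  }
  structure(m, tracer_kind = tracer_kind, colors = colors,
            col_meta = col_meta, class = c("annotation_matrix", "matrix", "array"))
}

# rebuild attributes after matrix surgery
rewrap_annotation <- function(m, template, rows = rownames(m)) {
  annotation_matrix(m, tracer_kind = attr(template, "tracer_kind")[rows],
                    colors = attr(template, "colors")[rows],
                    col_meta = {
                      cm <- attr(template, "col_meta")
                      if (is.null(cm)) NULL else cm[colnames(m), , drop = FALSE]
                    })
}

#' Aggregate per-case annotations into a single matrix
#'
#' Combines a list of per-case annotation records into one
#' injections-by-targets matrix. Cases are data frames with columns
#' `injection_id`, `target_id`, `value` and `tracer_kind`; repeated
#' (injection, target) entries (e.g. duplicated target columns across
#' cases) are summed, and missing cells are 0.
#'
#' @param cases List of per-case data frames.
#' @return An [annotation_matrix()].
#' @export
aggregate_annotations <- function(cases) {
  assert_that(length(cases) >= 1, "need at least one case")
  d <- do.call(rbind, lapply(cases, function(x) {
    as.data.frame(x)[, c("injection_id", "target_id", "value", "tracer_kind")]
  }))
  kinds <- unique(d[, c("injection_id", "tracer_kind")])
  dup <- kinds$injection_id[duplicated(kinds$injection_id)]
  assert_that(length(dup) == 0,
              "conflicting tracer_kind for injection(s): %s",
              paste(unique(dup), collapse = ", "))
  inj <- unique(d$injection_id); tgt <- unique(d$target_id)
  m <- matrix(0, length(inj), length(tgt), dimnames = list(inj, tgt))
  agg <- aggregate(value ~ injection_id + target_id, data = d, FUN = sum)
  m[cbind(match(agg$injection_id, inj), match(agg$target_id, tgt))] <- agg$value
  annotation_matrix(m, tracer_kind = kinds$tracer_kind[match(inj, kinds$injection_id)])
}

#' Remove sub-threshold annotation entries
#'
#' Entries that do not meet the minimum are set to zero; entries at or
#' above it are kept. The threshold is chosen per row by tracer kind:
#' labeled-pixel density for anterograde rows, labeled-cell count for
#' retrograde rows. The defaults (0.0045 and 8) exclude likely false
#' positives and connections too light to interpret.
#'
#' @param m An [annotation_matrix()].
#' @param t_antero Minimum anterograde pixel density (default 0.0045).
#' @param t_retro Minimum retrograde cell count (default 8).
#' @return The thresholded [annotation_matrix()].
#' @export
apply_thresholds <- function(m, t_antero = 0.0045, t_retro = 8) {
  stopifnot(inherits(m, "annotation_matrix"))
  assert_that(t_antero >= 0 && t_retro >= 0, "thresholds must be >= 0")
  kind <- attr(m, "tracer_kind")
  thr <- ifelse(kind == "anterograde", t_antero, t_retro)
  out <- unclass(m)
  out[out < thr] <- 0
  rewrap_annotation(out, m)
}

#' Normalize rows to the maximum injection total
#'
#' Scales every nonzero row so its total labeling equals that of the
#' injection with maximum total labeling; all-zero rows are left untouched
#' with a warning. Within-row proportions are preserved exactly, and the
#' maximum-total row is returned bit-for-bit unchanged.
#'
#' @param m An [annotation_matrix()].
#' @return The normalized [annotation_matrix()].
#' @export
normalize_rows <- function(m) {
  stopifnot(inherits(m, "annotation_matrix"))
  totals <- rowSums(m)
  assert_that(any(totals > 0), "all rows are zero; nothing to normalize")
  if (any(totals == 0)) {
    warnf("row(s) %s have zero total and were left unnormalized",
          paste(rownames(m)[totals == 0], collapse = ", "))
  }
  target <- max(totals)
  out <- unclass(m)
  nz <- totals > 0
  out[nz, ] <- out[nz, , drop = FALSE] * (target / totals[nz])
  out[which.max(totals), ] <- unclass(m)[which.max(totals), ]  # bit-exact
  rewrap_annotation(out, m)
}

# weighted bipartite graph over injections (rows) then targets (columns)
bipartite_graph <- function(m) {
  nz <- which(unclass(m) > 0, arr.ind = TRUE)
  assert_that(nrow(nz) > 0, "matrix has no nonzero entries; graph is empty")
  edges <- cbind(rownames(m)[nz[, 1]], colnames(m)[nz[, 2]])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- unclass(m)[nz]
  g <- g + igraph::vertices(setdiff(c(rownames(m), colnames(m)),
                                    igraph::V(g)$name))
  g
}

# one Louvain run with a shuffled vertex order (the igraph implementation
# is deterministic in vertex order, so shuffling restores run-to-run
# variability); returns a membership vector named by node
louvain_once <- function(g, gamma) {
  perm <- sample(igraph::vcount(g))
  gp <- igraph::permute(g, perm)
  cl <- igraph::cluster_louvain(gp, resolution = gamma)
  mem <- igraph::membership(cl)
  mem <- mem[match(igraph::V(g)$name, igraph::V(gp)$name)]
  setNames(as.integer(factor(mem, levels = unique(mem))) - 1L,
           igraph::V(g)$name)
}

#' Repeated Louvain community detection on an annotation matrix
#'
#' Casts the thresholded, normalized injection-by-target matrix as a
#' weighted bipartite graph (nodes = injections and targets, edge weights =
#' annotation values) and maximizes Newman modularity with the Louvain
#' algorithm at resolution `gamma`. The greedy optimizer depends on node
#' visit order, so `n_runs` independent executions are performed with
#' shuffled orders.
#'
#' @param m An [annotation_matrix()].
#' @param gamma Resolution parameter (default 1.0, single scale).
#' @param n_runs Number of independent executions (default 100).
#' @param seed Integer seed for the order shuffles.
#' @return List of `community_partition` objects (named integer membership
#'   vectors with 0-based contiguous community ids, plus `gamma` and
#'   `provenance` attributes).
#' @export
louvain_runs <- function(m, gamma = 1.0, n_runs = 100L, seed = 1L) {
  stopifnot(inherits(m, "annotation_matrix"))
  g <- bipartite_graph(m)
  withr::local_seed(seed)
  lapply(seq_len(n_runs), function(r) {
    structure(louvain_once(g, gamma), gamma = gamma,
              provenance = "single-run", class = "community_partition")
  })
}

#' Consensus partition of repeated community-detection runs
#'
#' Iterated reclustering of the thresholded co-assignment matrix: entry
#' `(i, j)` of the co-assignment matrix is the fraction of runs placing
#' nodes `i` and `j` in one community; entries below `tau` are zeroed, the
#' resulting weighted graph is re-partitioned `n_runs` times, and the
#' procedure repeats until all runs agree. A consensus of identical
#' partitions returns immediately (idempotence).
#'
#' @param partitions List of `community_partition`s over one node set.
#' @param tau Co-assignment threshold in `[0, 1]` (default 0.5).
#' @param gamma Resolution used for the reclustering steps.
#' @param n_runs Reclustering executions per iteration.
#' @param seed Integer seed.
#' @return A single `community_partition` with
#'   `provenance = "consensus-of-N"`.
#' @export
consensus_partition <- function(partitions, tau = 0.5, gamma = 1.0,
                                n_runs = 100L, seed = 1L) {
  assert_that(length(partitions) >= 1, "need at least one partition")
  nodes <- names(partitions[[1]])
  same <- vapply(partitions, function(p) identical(names(p), nodes), logical(1))
  assert_that(all(same), "partitions cover different node sets")
  withr::local_seed(seed)
  current <- partitions
  for (iter in seq_len(50L)) {
    if (all_identical_partitions(current)) break
    co <- coassignment(current)
    co[co < tau] <- 0
    diag(co) <- 0
    g <- igraph::graph_from_adjacency_matrix(co, mode = "undirected",
                                             weighted = TRUE)
    current <- lapply(seq_len(n_runs), function(r) louvain_once(g, gamma))
  }
  out <- current[[1]]
  out <- setNames(as.integer(factor(out, levels = unique(out))) - 1L, nodes)
  structure(out, gamma = gamma,
            provenance = sprintf("consensus-of-%d", length(partitions)),
            class = "community_partition")
}

coassignment <- function(partitions) {
  nodes <- names(partitions[[1]])
  co <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (p in partitions) co <- co + outer(p, p, "==")
  co / length(partitions)
}

all_identical_partitions <- function(ps) {
  if (length(ps) == 1) return(TRUE)
  ref <- canonical_labels(ps[[1]])
  all(vapply(ps[-1], function(p) identical(canonical_labels(p), ref),
             logical(1)))
}

# relabel communities by first appearance so label permutations compare equal
canonical_labels <- function(p) as.integer(factor(p, levels = unique(p)))

#' Reorder matrix rows and columns by community
#'
#' Produces row and column orderings that arrange each community's
#' injections next to their grouped targets, so the strongest
#' within-community connections fall along the block diagonal. Communities
#' are ordered by id; within a community, rows and columns are sorted by
#' decreasing within-community strength.
#'
#' @param m An [annotation_matrix()].
#' @param p A `community_partition` covering all rows and columns of `m`.
#' @return List with `rows`, `cols` (name orderings) and `reordered`
#'   (the permuted matrix).
#' @export
reorder_for_matrix <- function(m, p) {
  stopifnot(inherits(m, "annotation_matrix"))
  assert_that(all(c(rownames(m), colnames(m)) %in% names(p)),
              "partition must cover every row and column of the matrix")
  row_com <- p[rownames(m)]; col_com <- p[colnames(m)]
  row_str <- vapply(rownames(m), function(r) {
    sum(m[r, col_com == row_com[r], drop = FALSE])
  }, numeric(1))
  col_str <- vapply(colnames(m), function(cl) {
    sum(m[row_com == col_com[cl], cl])
  }, numeric(1))
  rows <- rownames(m)[order(row_com, -row_str)]
  cols <- colnames(m)[order(col_com, -col_str)]
  list(rows = rows, cols = cols,
       reordered = unclass(m)[rows, cols, drop = FALSE])
}

#' Color segmented pixels by community-resolved injection
#'
#' For every segmented pixel, the containing 175 x 175 px grid cell is
#' looked up in the consensus partition; among the injections of that
#' cell's community, the one with the greatest annotation value at the cell
#' claims the pixel, which is painted in that injection's display color.
#' One aggregated RGB image is produced per atlas level; grid cells whose
#' community contains no injection are flagged and left uncolored.
#'
#' @param p A `community_partition` over injections and grid-cell targets
#'   named `"L<level>_r<row>_c<col>"`.
#' @param m An [annotation_matrix()] with those grid columns.
#' @param segmentation Named list (per atlas level) of logical matrices
#'   marking segmented pixels.
#' @param cell_px Grid cell size in pixels (default 175).
#' @return Named list per level: `rgb` (H x W x 3 array), `legend`
#'   (injection colors used), `uncolored_cells` (flagged cell names).
#' @export
color_code <- function(p, m, segmentation, cell_px = 175L) {
  stopifnot(inherits(m, "annotation_matrix"))
  colors <- attr(m, "colors")
  inj_ids <- rownames(m)
  out <- list()
  for (lev in names(segmentation)) {
    seg <- segmentation[[lev]]
    rgbimg <- array(0, c(nrow(seg), ncol(seg), 3L))
    used <- character(0); flagged <- character(0)
    ij <- which(seg, arr.ind = TRUE)
    if (nrow(ij) > 0) {
      gr <- (ij[, 1] - 1L) %/% cell_px
      gc <- (ij[, 2] - 1L) %/% cell_px
      cell <- sprintf("%s_r%d_c%d", lev, gr, gc)
      for (cn in unique(cell)) {
        if (!cn %in% names(p) || !cn %in% colnames(m)) next
        com <- p[cn]
        inj_in_com <- inj_ids[p[inj_ids] == com]
        if (length(inj_in_com) == 0) { flagged <- c(flagged, cn); next }
        vals <- unclass(m)[inj_in_com, cn]
        winner <- inj_in_com[order(-vals, inj_in_com)][1]
        rgbv <- grDevices::col2rgb(colors[winner]) / 255
        sel <- cell == cn
        for (ch in 1:3) {
          rgbimg[cbind(ij[sel, , drop = FALSE], ch)] <- rgbv[ch]
        }
        used <- union(used, winner)
      }
    }
    out[[lev]] <- list(rgb = rgbimg, legend = colors[used],
                       uncolored_cells = flagged)
  }
  out
}

#' Per-atlas-level stacked-bar summary of connectivity
#'
#' For each injection, the fraction of its total labeling falling on each
#' atlas level (the stacked-bar heights), plus, per level, the two ROIs
#' containing the most summed labeling (the bar annotations). Optionally
#' restricted to a subset of ROIs.
#'
#' @param m A grid- or ROI-resolved [annotation_matrix()] whose `col_meta`
#'   has columns `level` and `roi`.
#' @param roi_subset Optional character vector of ROIs to restrict to.
#' @return List with `fractions` (data frame: `injection`, `level`,
#'   `fraction`) and `top_rois` (data frame: `level`, `roi`, `total`,
#'   `rank` of the top two per level).
#' @export
stacked_bar_data <- function(m, roi_subset = NULL) {
  stopifnot(inherits(m, "annotation_matrix"))
  cm <- attr(m, "col_meta")
  assert_that(!is.null(cm) && all(c("level", "roi") %in% names(cm)),
              "matrix col_meta must provide 'level' and 'roi' per target")
  keep <- rep(TRUE, ncol(m))
  if (!is.null(roi_subset)) keep <- cm$roi %in% roi_subset
  mm <- unclass(m)[, keep, drop = FALSE]
  cmk <- cm[keep, , drop = FALSE]
  totals <- rowSums(mm)
  lev <- factor(cmk$level)
  by_lev <- t(apply(mm, 1, function(r) tapply(r, lev, sum)))
  frac <- by_lev / ifelse(totals > 0, totals, 1)
  fractions <- data.frame(
    injection = rep(rownames(mm), times = nlevels(lev)),
    level = rep(levels(lev), each = nrow(mm)),
    fraction = as.vector(frac))
  tops <- do.call(rbind, lapply(levels(lev), function(lv) {
    roi_sum <- tapply(colSums(mm[, lev == lv, drop = FALSE]),
                      cmk$roi[lev == lv], sum)
    roi_sum <- sort(roi_sum, decreasing = TRUE)
    n <- min(2L, length(roi_sum))
    data.frame(level = lv, roi = names(roi_sum)[seq_len(n)],
               total = as.numeric(roi_sum[seq_len(n)]), rank = seq_len(n))
  }))
  rownames(tops) <- NULL
  list(fractions = fractions, top_rois = tops)
}

#' Hierarchically cluster projection vectors
#'
#' Each case's region-summed projection vector is L1 normalized (fraction
#' of projection to each region) and cases are agglomeratively clustered
#' under the cosine distance.
#'
#' @param vectors Numeric matrix, one row per case, one column per region.
#' @param method Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @param k Optional number of groups to cut the tree into.
#' @return List with `linkage` (an `hclust`), `leaf_order` (case names in
#'   dendrogram order), `distances` (`dist` of cosine distances) and, if
#'   `k` is given, `groups` (named membership vector).
#' @export
cluster_projection_vectors <- function(vectors, method = "average", k = NULL) {
  vectors <- as.matrix(vectors)
  assert_that(nrow(vectors) >= 2, "need at least two cases")
  if (is.null(rownames(vectors))) rownames(vectors) <- paste0("case", seq_len(nrow(vectors)))
  tot <- rowSums(abs(vectors))
  zero <- rownames(vectors)[tot == 0]
  assert_that(length(zero) == 0, "zero projection vector(s): %s",
              paste(zero, collapse = ", "))
  l1 <- vectors / tot
  nrm <- sqrt(rowSums(l1^2))
  cossim <- (l1 %*% t(l1)) / outer(nrm, nrm)
  d <- stats::as.dist(pmax(1 - cossim, 0))
  hc <- hclust(d, method = method)
  out <- list(linkage = hc, leaf_order = rownames(vectors)[hc$order],
              distances = d)
  if (!is.null(k)) out$groups <- cutree(hc, k = k)
  out
}

#' Bin connection strengths into tertiles
#'
#' Upper, middle and lower tertiles map to strong, moderate and weak
#' connection classes; values tied with a tertile boundary go to the
#' stronger bin.
#'
#' @param strengths Positive connection strengths (length >= 3).
#' @return Factor with levels `weak < moderate < strong`.
#' @export
tertile_bins <- function(strengths) {
  assert_that(length(strengths) >= 3, "need at least 3 strength values")
  q <- quantile(strengths, c(1 / 3, 2 / 3), names = FALSE)
  lab <- ifelse(strengths >= q[2], "strong",
                ifelse(strengths >= q[1], "moderate", "weak"))
  factor(lab, levels = c("weak", "moderate", "strong"), ordered = TRUE)
}
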