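#' Neuron morphology container (SWC semantics)
#'
#' A rooted tree of 3D nodes with radii, following SWC conventions: columns
#' `id`, `type`, `x`, `y`, `z`, `radius`, `parent`, with the root's parent
#' equal to -1. Type 1 marks soma nodes. Exactly one root is required, ids
#' must be unique, radii positive, and parent pointers must form a single
#' acyclic tree.
#'
#' @param nodes Data frame with the seven SWC columns.
#' @param group_label Optional domain/group tag carried through analyses.
#' @return A `neuron` data frame.
#' @export
neuron <- function(nodes, group_label = NULL) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  assert_that(all(need %in% names(nodes)), "nodes must have SWC columns %s",
              paste(need, collapse = ", "))
  nodes <- as.data.frame(nodes)[, need]
  nodes$id <- as.integer(nodes$id); nodes$parent <- as.integer(nodes$parent)
  nodes$type <- as.integer(nodes$type)
  assert_that(!anyDuplicated(nodes$id), "node ids must be unique")
  assert_that(all(nodes$radius > 0), "radii must be positive")
  roots <- which(nodes$parent == -1L)
  assert_that(length(roots) == 1L, "exactly one root (parent = -1) required")
  assert_that(all(nodes$parent[-roots] %in% nodes$id),
              "every non-root parent id must exist")
  # acyclicity: walking parent pointers must terminate at the root
  ord <- match(nodes$parent, nodes$id)        # parent row per node (NA = root)
  depth <- rep(NA_integer_, nrow(nodes)); depth[roots] <- 0L
  pending <- which(is.na(depth))
  guard <- 0L
  while (length(pending) > 0) {
    ready <- pending[!is.na(depth[ord[pending]])]
    if (length(ready) == 0) stopf("parent pointers contain a cycle")
    depth[ready] <- depth[ord[ready]] + 1L
    pending <- setdiff(pending, ready)
    guard <- guard + 1L
    if (guard > nrow(nodes)) stopf("parent pointers contain a cycle")
  }
  attr(nodes, "group_label") <- group_label
  class(nodes) <- c("neuron", "data.frame")
  nodes
}

#' Read / write neuron morphologies in SWC format
#'
#' Standard 7-column whitespace-delimited SWC with `#` comment lines.
#'
#' @param path File path.
#' @param n A [neuron()].
#' @return `read_swc()` returns a [neuron()]; `write_swc()` returns `path`
#'   invisibly.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  assert_that(length(lines) > 0, "no data rows in %s", path)
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  assert_that(ncol(m) == 7, "SWC rows must have 7 columns")
  colnames(m) <- c("id", "type", "x", "y", "z", "radius", "parent")
  neuron(as.data.frame(m))
}

#' @rdname read_swc
#' @export
write_swc <- function(n, path) {
  stopifnot(inherits(n, "neuron"))
  header <- "# id type x y z radius parent"
  body <- sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                  n$id, n$type, n$x, n$y, n$z, n$radius, n$parent)
  writeLines(c(header, body), path)
  invisible(path)
}

# ---- internal tree helpers ------------------------------------------------

# soma center: centroid of type-1 nodes (falls back to root position)
soma_center <- function(n) {
  s <- n[n$type == 1L, , drop = FALSE]
  if (nrow(s) == 0) s <- n[n$parent == -1L, , drop = FALSE]
  c(mean(s$x), mean(s$y), mean(s$z))
}

root_id <- function(n) n$id[n$parent == -1L]

# rows of dendritic segments: parent row index, child row index.
# Segments internal to the soma contour (both endpoints type 1) are not
# dendritic cable and are excluded.
segment_rows <- function(n) {
  idx <- match(n$parent, n$id)
  child <- which(!is.na(idx))
  par <- idx[child]
  keep <- !(n$type[child] == 1L & n$type[par] == 1L)
  cbind(parent = par[keep], child = child[keep])
}

segment_lengths <- function(n, segs = segment_rows(n)) {
  sqrt((n$x[segs[, 1]] - n$x[segs[, 2]])^2 +
       (n$y[segs[, 1]] - n$y[segs[, 2]])^2 +
       (n$z[segs[, 1]] - n$z[segs[, 2]])^2)
}

# path distance from the root along the tree, per node (root = 0);
# soma contour nodes get their Euclidean offset, which is never used
# downstream for dendrite measures
path_distance <- function(n) {
  idx <- match(n$parent, n$id)
  elen <- sqrt((n$x - n$x[idx])^2 + (n$y - n$y[idx])^2 + (n$z - n$z[idx])^2)
  elen[is.na(elen)] <- 0
  d <- rep(NA_real_, nrow(n))
  d[n$parent == -1L] <- 0
  pending <- which(is.na(d))
  while (length(pending) > 0) {
    ready <- pending[!is.na(d[idx[pending]])]
    d[ready] <- d[idx[ready]] + elen[ready]
    pending <- setdiff(pending, ready)
  }
  d
}

# number of children per node (restricted to dendritic continuation)
n_children <- function(n) {
  tab <- table(factor(n$parent, levels = n$id))
  as.integer(tab)
}

# Decompose the dendritic tree into unbranched paths ("branches") running
# between topological nodes (root/stem attachment, bifurcations, tips).
# Returns a list of integer row-index vectors, each path ordered
# proximal -> distal and including both topological endpoints.
branch_paths <- function(n) {
  idx <- match(n$parent, n$id)
  is_soma <- n$type == 1L
  dend_rows <- which(!is_soma & !is.na(idx))
  kids_full <- split(dend_rows, factor(idx[dend_rows], levels = seq_len(nrow(n))))
  nk <- tabulate(idx[dend_rows], nbins = nrow(n))
  # branch starts: dendritic nodes whose parent is soma/root, and children
  # of bifurcation nodes
  starts <- which(!is_soma & (is.na(idx) | is_soma[idx] | nk[idx] >= 2L))
  paths <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    s <- starts[k]
    cur <- s
    line <- integer(0)
    while (nk[cur] == 1L) {
      cur <- kids_full[[cur]]
      line <- c(line, cur)
    }
    paths[[k]] <- if (!is.na(idx[s])) c(idx[s], s, line) else c(s, line)
  }
  paths
}

# branch tortuosity: path length / chord, one value per branch with
# positive chord
branch_tortuosity <- function(n) {
  paths <- branch_paths(n)
  vals <- vapply(paths, function(p) {
    if (length(p) < 2) return(NA_real_)
    xyz <- cbind(n$x[p], n$y[p], n$z[p])
    steps <- sqrt(rowSums(diff(xyz)^2))
    chord <- sqrt(sum((xyz[nrow(xyz), ] - xyz[1, ])^2))
    if (chord < 1e-9) return(NA_real_)
    sum(steps) / chord
  }, numeric(1))
  vals[!is.na(vals)]
}
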