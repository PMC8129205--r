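#' Specification of a planted block-structured annotation matrix
#'
#' Describes an injections-by-targets weighted matrix with planted community
#' structure: disjoint blocks of injections and targets carry high
#' within-block weights, while off-block cells are sparsely populated with
#' low-level noise. Used to test thresholding, normalization and community
#' detection with a known partition.
#'
#' @param n_injections,n_targets Matrix dimensions.
#' @param blocks List of blocks, each a list with `injections` (row indices),
#'   `targets` (column indices) and `mean` (mean within-block weight). Every
#'   row and column must belong to exactly one block.
#' @param noise_rate Probability that an off-block cell is nonzero.
#' @param noise_mean Mean weight of nonzero off-block cells (default one
#'   tenth of the smallest block mean).
#' @param tracer_kinds Character vector per injection, `"anterograde"` or
#'   `"retrograde"` (recycled).
#' @param seed Integer seed.
#' @return An object of class `planted_matrix_spec`.
#' @export
planted_matrix_spec <- function(n_injections, n_targets, blocks,
                                noise_rate = 0, noise_mean = NULL,
                                tracer_kinds = "anterograde", seed = 1L) {
  assert_that(n_injections >= 1 && n_targets >= 1, "matrix must be non-empty")
  assert_that(length(blocks) >= 1, "at least one block required")
  inj_all <- unlist(lapply(blocks, `[[`, "injections"))
  tgt_all <- unlist(lapply(blocks, `[[`, "targets"))
  if (anyDuplicated(inj_all) || anyDuplicated(tgt_all)) {
    stopf("blocks overlap: each injection and target must belong to exactly one block")
  }
  assert_that(setequal(inj_all, seq_len(n_injections)) &&
                setequal(tgt_all, seq_len(n_targets)),
              "blocks must cover every injection and target exactly once")
  means <- vapply(blocks, `[[`, numeric(1), "mean")
  assert_that(all(means > 0), "block mean weights must be positive")
  assert_that(noise_rate >= 0 && noise_rate < 1, "noise_rate must be in [0,1)")
  structure(list(n_injections = as.integer(n_injections),
                 n_targets = as.integer(n_targets), blocks = blocks,
                 noise_rate = noise_rate,
                 noise_mean = noise_mean %||% (0.1 * min(means)),
                 tracer_kinds = {
                   assert_that(all(tracer_kinds %in% c("anterograde", "retrograde")),
                               "tracer_kinds must be 'anterograde' or 'retrograde'")
                   rep_len(tracer_kinds, n_injections)
                 },
                 seed = as.integer(seed)),
            class = "planted_matrix_spec")
}

#' Generate an annotation matrix with a planted partition
#'
#' Within-block weights are Gamma distributed (shape 4) around the block
#' mean; off-block cells are nonzero with probability `noise_rate`, with
#' Gamma(1) weights around `noise_mean`. Returns the matrix together with
#' the planted community partition over the bipartite node set
#' (injections then targets).
#'
#' @param spec A [planted_matrix_spec()].
#' @return List with `matrix` (an [annotation_matrix()]) and `partition`
#'   (integer vector over nodes `inj:*` then `tgt:*`, one community per
#'   block).
#' @export
gen_annotation_matrix <- function(spec) {
  stopifnot(inherits(spec, "planted_matrix_spec"))
  withr::local_seed(spec$seed)
  m <- matrix(0, spec$n_injections, spec$n_targets,
              dimnames = list(paste0("inj", seq_len(spec$n_injections)),
                              paste0("tgt", seq_len(spec$n_targets))))
  for (b in spec$blocks) {
    nb <- length(b$injections) * length(b$targets)
    m[b$injections, b$targets] <- rgamma(nb, shape = 4, rate = 4 / b$mean)
  }
  if (spec$noise_rate > 0) {
    off <- matrix(TRUE, spec$n_injections, spec$n_targets)
    for (b in spec$blocks) off[b$injections, b$targets] <- FALSE
    hit <- off & matrix(runif(length(m)) < spec$noise_rate,
                        nrow(m), ncol(m))
    m[hit] <- rgamma(sum(hit), shape = 1, rate = 1 / spec$noise_mean)
  }
  part <- integer(spec$n_injections + spec$n_targets)
  for (k in seq_along(spec$blocks)) {
    b <- spec$blocks[[k]]
    part[b$injections] <- k
    part[spec$n_injections + b$targets] <- k
  }
  names(part) <- c(rownames(m), colnames(m))
  list(matrix = annotation_matrix(m, tracer_kind = spec$tracer_kinds),
       partition = part)
}
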