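#' PCA embedding of morphometric feature tables
#'
#' Z-score standardizes the features and returns principal-component
#' scores, loadings and explained-variance fractions. Constant features
#' (zero variance) are dropped with a warning; columns containing `NA` are
#' dropped likewise.
#'
#' @param features Numeric data frame or matrix, one row per neuron.
#' @param n_components Number of components to return (default 3).
#' @return List with `scores`, `loadings`, `explained` (variance
#'   fractions for the kept components) and `dropped` (feature names).
#' @export
pca_embed <- function(features, n_components = 3L) {
  x <- as.matrix(features)
  assert_that(nrow(x) >= 3, "need at least 3 neurons")
  bad_na <- colnames(x)[!complete.cases(t(x))]
  keep <- setdiff(colnames(x), bad_na)
  x <- x[, keep, drop = FALSE]
  vars <- apply(x, 2, var)
  const <- colnames(x)[vars < 1e-12]
  if (length(c(const, bad_na)) > 0) {
    warnf("dropping constant or incomplete feature(s): %s",
          paste(c(const, bad_na), collapse = ", "))
  }
  x <- x[, vars >= 1e-12, drop = FALSE]
  assert_that(ncol(x) >= 2, "fewer than 2 usable features")
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$x))
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)],
       dropped = c(const, bad_na))
}

#' Pairwise Wilcoxon rank-sum tests with FDR control
#'
#' For every feature and every pair of groups, runs a two-sided Wilcoxon
#' rank-sum (Mann-Whitney) test: `W` is the rank-sum statistic of the first
#' group minus its minimum, p-values are exact for small samples without
#' ties and use the normal approximation with continuity correction
#' otherwise, and the location shift is the Hodges-Lehmann estimate with
#' confidence interval. Benjamini-Hochberg adjustment is applied jointly
#' across the entire feature-by-pair family. Completely tied comparisons
#' return p = 1 exactly.
#'
#' @param features Data frame of features, one row per neuron.
#' @param groups Group label per neuron (at least 2 groups with 2+ members).
#' @param conf_level Confidence level for the shift interval (default 0.95).
#' @return A data frame (`feature`, `group1`, `group2`, `W`, `p`, `p_adj`,
#'   `shift`, `conf_low`, `conf_high`), sorted as computed, with
#'   `p_adj >= p` guaranteed by the BH construction.
#' @export
pairwise_wilcoxon_fdr <- function(features, groups, conf_level = 0.95) {
  features <- as.data.frame(features)
  groups <- factor(groups)
  assert_that(length(groups) == nrow(features),
              "groups must label every row of features")
  counts <- table(groups)
  assert_that(nlevels(groups) >= 2 && all(counts >= 2),
              "need at least 2 groups with at least 2 members each")
  pairs <- utils::combn(levels(groups), 2)
  rows <- list()
  for (f in names(features)) {
    v <- features[[f]]
    if (!is.numeric(v)) next
    for (k in seq_len(ncol(pairs))) {
      g1 <- pairs[1, k]; g2 <- pairs[2, k]
      x <- v[groups == g1]; y <- v[groups == g2]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) < 2 || length(y) < 2) next
      if (length(unique(c(x, y))) == 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, group1 = g1, group2 = g2,
          W = length(x) * length(y) / 2, p = 1,
          shift = 0, conf_low = NA_real_, conf_high = NA_real_)
        next
      }
      wt <- suppressWarnings(wilcox.test(x, y, conf.int = TRUE,
                                         conf.level = conf_level))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, group1 = g1, group2 = g2,
        W = unname(wt$statistic), p = wt$p.value,
        shift = unname(wt$estimate),
        conf_low = wt$conf.int[1], conf_high = wt$conf.int[2])
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[, c("feature", "group1", "group2", "W", "p", "p_adj",
          "shift", "conf_low", "conf_high")]
}
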