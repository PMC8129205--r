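#' Pool per-section labeled points into one per-level training set
#'
#' Concatenates the segmented tracer-pixel coordinate sets of all sections
#' registered to the same atlas level, with each point keeping its
#' section's domain label. Duplicate coordinates are retained.
#'
#' @param sections List of [labeled_points()] sharing one `level_id`.
#' @return A single [labeled_points()].
#' @export
build_training_set <- function(sections) {
  assert_that(length(sections) >= 1, "need at least one section")
  lv <- unique(vapply(sections, function(s) as.character(attr(s, "level_id")),
                      character(1)))
  assert_that(length(lv) == 1,
              "sections span multiple atlas levels (%s); pool one level at a time",
              paste(lv, collapse = ", "))
  x <- unlist(lapply(sections, `[[`, "x"))
  y <- unlist(lapply(sections, `[[`, "y"))
  lab <- unlist(lapply(sections, function(s) as.character(s$label)))
  labeled_points(x, y, lab, attr(sections[[1]], "level_id"))
}

default_c_grid <- function() 2^(-2:5)
default_gamma_grid <- function() 2^(-5:2)

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin, keeping every fold's class counts within 1 of proportional
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train an accuracy-weighted RBF-SVM ensemble
#'
#' Fits one soft-margin RBF-kernel SVM per `(C, gamma)` pair on the
#' power-of-two grids (8 x 8 = 64 members by default). Each member's weight
#' is its mean held-out accuracy over `cv_repeats` independent repetitions
#' of stratified `cv_folds`-fold cross-validation (30 held-out evaluations
#' under the defaults); after weighting, every member is refit on the full
#' data. Coordinates are z-score standardized per level before the RBF
#' kernel so the gamma grid has a scale-free meaning.
#'
#' @param data A [labeled_points()] with at least two classes.
#' @param c_grid,gamma_grid Hyperparameter grids (powers of two by default).
#' @param cv_folds Folds per cross-validation (default 3).
#' @param cv_repeats Independent CV repetitions (default 10).
#' @param seed Integer seed controlling fold shuffles.
#' @return An `svm_ensemble`: list with `members` (each holding `C`,
#'   `gamma`, `accuracy`, fitted model), `classes`, `level_id`, `scaling`.
#' @export
train_ensemble <- function(data, c_grid = default_c_grid(),
                           gamma_grid = default_gamma_grid(),
                           cv_folds = 3L, cv_repeats = 10L, seed = 1L) {
  stopifnot(inherits(data, "labeled_points"))
  labs <- droplevels(data$label)
  assert_that(nlevels(labs) >= 2, "training needs at least 2 distinct labels")
  counts <- table(labs)
  bad <- names(counts)[counts < cv_folds]
  assert_that(length(bad) == 0,
              "class(es) %s have fewer than cv_folds = %d points",
              paste(bad, collapse = ", "), cv_folds)

  ctr <- c(mean(data$x), mean(data$y))
  scl <- c(sd(data$x), sd(data$y))
  scl[scl == 0] <- 1
  xs <- cbind((data$x - ctr[1]) / scl[1], (data$y - ctr[2]) / scl[2])

  withr::local_seed(seed)
  n <- nrow(xs)
  folds <- lapply(seq_len(cv_repeats), function(r) stratified_folds(labs, cv_folds))

  grid <- expand.grid(C = c_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  members <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    accs <- numeric(0)
    for (r in seq_len(cv_repeats)) {
      f <- folds[[r]]
      for (k in seq_len(cv_folds)) {
        tr <- f != k
        fit <- e1071::svm(xs[tr, , drop = FALSE], labs[tr],
                          kernel = "radial", cost = grid$C[i],
                          gamma = grid$gamma[i], scale = FALSE)
        pred <- predict(fit, xs[!tr, , drop = FALSE])
        accs <- c(accs, mean(pred == labs[!tr]))
      }
    }
    fit_full <- e1071::svm(xs, labs, kernel = "radial", cost = grid$C[i],
                           gamma = grid$gamma[i], scale = FALSE)
    members[[i]] <- list(C = grid$C[i], gamma = grid$gamma[i],
                         accuracy = mean(accs), model = fit_full)
  }
  structure(list(members = members, classes = levels(labs),
                 level_id = attr(data, "level_id"),
                 scaling = list(center = ctr, scale = scl)),
            class = "svm_ensemble")
}

#' Accuracy-weighted ensemble prediction
#'
#' Each point's label is the class maximizing the accuracy-weighted vote
#' `sum_i a_i I(y_i(x) = y)` over ensemble members; ties resolve to the
#' first class in the ensemble's fixed class order
#' (medial < lateral < caudal for canonical domain labels).
#'
#' @param model An `svm_ensemble` from [train_ensemble()].
#' @param points Two-column matrix or data frame of `(x, y)` coordinates.
#' @return Factor of predicted labels.
#' @export
ensemble_predict <- function(model, points) {
  stopifnot(inherits(model, "svm_ensemble"))
  assert_that(length(model$members) >= 1, "ensemble has no trained members")
  p <- as.matrix(as.data.frame(points)[, 1:2])
  xs <- cbind((p[, 1] - model$scaling$center[1]) / model$scaling$scale[1],
              (p[, 2] - model$scaling$center[2]) / model$scaling$scale[2])
  votes <- matrix(0, nrow(xs), length(model$classes),
                  dimnames = list(NULL, model$classes))
  for (m in model$members) {
    pred <- as.character(predict(m$model, xs))
    votes[cbind(seq_len(nrow(xs)), match(pred, model$classes))] <-
      votes[cbind(seq_len(nrow(xs)), match(pred, model$classes))] + m$accuracy
  }
  win <- max.col(votes, ties.method = "first")
  factor(model$classes[win], levels = model$classes)
}

#' Dense domain classification over a mask
#'
#' Classifies every pixel of a mask with the weighted ensemble vote,
#' producing the demarcated domain map for the level.
#'
#' @param model An `svm_ensemble`.
#' @param mask Either a logical matrix (with optional `xs`/`ys` grid
#'   coordinate attributes) or a `boundary_map`-like list with `mask`,
#'   `xs`, `ys` (e.g. from [ground_truth_map()]).
#' @return A `boundary_map` (see [ground_truth_map()]) with per-domain
#'   pixel counts in attribute `counts`.
#' @export
demarcate <- function(model, mask) {
  stopifnot(inherits(model, "svm_ensemble"))
  if (is.list(mask) && !is.null(mask$mask)) {
    mk <- mask$mask; xs <- mask$xs; ys <- mask$ys
  } else {
    mk <- mask
    xs <- attr(mask, "xs") %||% (seq_len(ncol(mk)) - 0.5)
    ys <- attr(mask, "ys") %||% (seq_len(nrow(mk)) - 0.5)
  }
  assert_that(any(mk), "mask is empty")
  ij <- which(mk, arr.ind = TRUE)
  pts <- cbind(xs[ij[, 2]], ys[ij[, 1]])
  pred <- ensemble_predict(model, pts)
  labels <- matrix(NA_integer_, nrow(mk), ncol(mk))
  labels[ij] <- as.integer(pred)
  out <- structure(list(labels = labels, levels = model$classes, mask = mk,
                        xs = xs, ys = ys, level_id = model$level_id),
                   class = "boundary_map")
  attr(out, "counts") <- table(pred)
  out
}

#' Pixelwise agreement between two domain maps
#'
#' Fraction of shared mask pixels carrying identical domain labels, plus a
#' per-domain confusion table (reference in rows).
#'
#' @param auto,reference `boundary_map` objects over the same mask and
#'   level.
#' @return Agreement fraction in `[0, 1]` with attribute `confusion`.
#' @export
agreement <- function(auto, reference) {
  stopifnot(inherits(auto, "boundary_map"), inherits(reference, "boundary_map"))
  assert_that(identical(dim(auto$mask), dim(reference$mask)) &&
                all(auto$mask == reference$mask),
              "boundary maps must share one mask")
  assert_that(identical(as.character(auto$level_id),
                        as.character(reference$level_id)),
              "boundary maps must be from the same atlas level")
  a <- factor(auto$levels[auto$labels[auto$mask]], levels = reference$levels)
  r <- factor(reference$levels[reference$labels[reference$mask]],
              levels = reference$levels)
  frac <- mean(a == r)
  structure(frac, confusion = table(reference = r, automated = a))
}

#' Boundary-demarcation agreement study on synthetic atlas levels
#'
#' End-to-end benchmark of the demarcation pipeline: for each synthetic
#' atlas level, generates three partially overlapping domain point clouds,
#' trains the full power-of-two ensemble with repeated stratified
#' cross-validation, densely classifies the nucleus mask, and scores
#' pixelwise agreement against the generator's ground-truth domain surface.
#'
#' @param n_levels Number of synthetic atlas levels (default 7).
#' @param n_points Points per domain and level (default 500).
#' @param overlap_fraction Calibrated domain overlap (default 0.1).
#' @param resolution Pixel step of the dense classification grid.
#' @param seed Root seed; each level derives its own generation seed.
#' @param cv_repeats,cv_folds Cross-validation schedule per member.
#' @return Data frame with one row per level: `level`, `agreement`
#'   (fraction in `[0, 1]`), `n_mask_pixels`.
#' @export
demarcation_benchmark <- function(n_levels = 7L, n_points = 500L,
                                  overlap_fraction = 0.1, resolution = 1,
                                  seed = 1L, cv_repeats = 10L,
                                  cv_folds = 3L) {
  out <- lapply(seq_len(n_levels), function(lev) {
    lseed <- child_seed(seed, lev)
    spec <- domain_cloud_spec(level_id = lev, n_points = n_points,
                              overlap_fraction = overlap_fraction,
                              seed = lseed)
    pts <- gen_domain_points(spec)
    ens <- train_ensemble(pts, cv_repeats = cv_repeats,
                          cv_folds = cv_folds, seed = lseed)
    gt <- ground_truth_map(spec, resolution = resolution)
    auto <- demarcate(ens, gt)
    data.frame(level = lev, agreement = as.numeric(agreement(auto, gt)),
               n_mask_pixels = sum(gt$mask))
  })
  do.call(rbind, out)
}
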