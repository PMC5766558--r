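#' Class weights (classifier operating point)
#'
#' Nonnegative weights for the vessel, core, and ground-glass posterior
#' probabilities, summing to one. Scaling the posteriors by these weights
#' before the argmax shifts the operating point of the three-class decision.
#'
#' @param w_v,w_c,w_g weights for vessel, solid core, ground-glass.
#' @return A `class_weights` object (named numeric of length 3).
#' @export
class_weights <- function(w_v, w_c, w_g) {
  w <- c(vessel = unname(w_v), core = unname(w_c), ggo = unname(w_g))
  if (any(!is.finite(w)) || any(w < 0))
    stop("class weights must be finite and nonnegative")
  if (abs(sum(w) - 1) > 1e-9)
    stop(sprintf("class weights must sum to 1 (got %.12f)", sum(w)))
  structure(w, class = "class_weights")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(expr)
}

# Water-filling allocation of `target` samples over nodules with given
# capacities: quotas are as equal as possible, spare capacity of small
# nodules redistributed to the rest. Deterministic; returns allocation in
# the input order.
quota_allocate <- function(capacity, target) {
  stopifnot(target <= sum(capacity))
  n <- length(capacity)
  ord <- order(capacity, seq_len(n))
  alloc <- integer(n)
  rem <- target
  left <- n
  for (i in ord) {
    q <- rem %/% left
    extra <- rem %% left
    # later nodules (in processing order) absorb the indivisible remainder
    take <- min(capacity[i], q + (if (left <= extra) 1L else 0L))
    alloc[i] <- take
    rem <- rem - take
    left <- left - 1L
  }
  alloc
}

#' Balance training classes to the minority-class size
#'
#' Downsamples each class, without replacement, to the size of the smallest
#' class. Selection is stratified over nodules so that each nodule
#' contributes an approximately equal number of samples per class
#' (water-filling quotas: nodules with fewer samples than their fair share
#' contribute everything, the shortfall is spread over the rest).
#'
#' @param features samples-by-features matrix (or data.frame).
#' @param labels integer class labels (1 vessel, 2 core, 3 ground-glass).
#' @param nodule_id per-row nodule identifier.
#' @param seed RNG seed for the within-nodule subsampling.
#' @return A list with `features`, `labels`, `nodule_id` (row-subset of the
#'   input, original row order preserved) and `rows` (the kept row indices).
#' @export
balance_classes <- function(features, labels, nodule_id, seed = NULL) {
  labels <- as.integer(labels)
  if (length(labels) != nrow(features) || length(nodule_id) != nrow(features))
    stop("`labels` and `nodule_id` must have one entry per feature row")
  counts <- tabulate(labels, nbins = 3L)
  if (any(counts == 0L))
    stop(sprintf("class '%s' has no samples; cannot balance",
                 CLASS_NAMES[which(counts == 0L)[1L]]))
  target <- min(counts)
  keep <- with_seed(seed, {
    sel <- integer(0)
    for (cls in 1:3) {
      rows <- which(labels == cls)
      if (length(rows) == target) {
        sel <- c(sel, rows)
        next
      }
      nod <- as.character(nodule_id[rows])
      ids <- unique(nod)
      cap <- as.integer(table(factor(nod, levels = ids)))
      alloc <- quota_allocate(cap, target)
      for (j in seq_along(ids)) {
        pool <- rows[nod == ids[j]]
        sel <- c(sel, if (alloc[j] == length(pool)) pool
                 else sort(sample(pool, alloc[j])))
      }
    }
    sort(sel)
  })
  list(features = features[keep, , drop = FALSE], labels = labels[keep],
       nodule_id = nodule_id[keep], rows = keep)
}

#' Train the kNN voxel classifier
#'
#' Features are standardized to zero mean and unit variance using training
#' statistics (HU and eigenvalue scales differ by orders of magnitude, so
#' unstandardized Euclidean distance would be degenerate); the posterior for
#' a query voxel is the class fraction among its `k` nearest training
#' samples in Euclidean distance.
#'
#' @param features training matrix (samples x features).
#' @param labels integer class labels in 1..3.
#' @param k number of neighbours (default 150).
#' @return An `ssn_classifier` object.
#' @export
train_classifier <- function(features, labels, k = 150L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  n <- nrow(features)
  if (k > n)
    stop(sprintf("k = %d exceeds the number of training samples (%d)", k, n))
  if (k < 1L) stop("k must be >= 1")
  if (length(unique(labels)) < 3L)
    stop("training data must contain all three classes")
  ctr <- colMeans(features)
  scl <- apply(features, 2L, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  x <- sweep(sweep(features, 2L, ctr), 2L, scl, "/")
  structure(list(x = x, labels = labels, k = as.integer(k),
                 center = ctr, scale = scl,
                 feature_spec = attr(features, "feature_spec")),
            class = "ssn_classifier")
}

#' Posterior probabilities for new samples
#' @param object an `ssn_classifier`.
#' @param newdata matrix on the same feature columns (unstandardized).
#' @param ... unused.
#' @return Matrix (samples x 3) of class posteriors, columns vessel, core,
#'   ggo; rows sum to 1.
#' @export
predict.ssn_classifier <- function(object, newdata, ...) {
  q <- sweep(sweep(as.matrix(newdata), 2L, object$center), 2L, object$scale,
             "/")
  post <- .knn_posteriors(object$x, object$labels, q, object$k, 3L)
  colnames(post) <- CLASS_NAMES
  post
}

# Weighted argmax over class scores with the fixed tie priority
# ground-glass > vessel > core. P: n x 3 (vessel, core, ggo); w length 3.
weighted_argmax <- function(P, w) {
  L <- sweep(P, 2L, as.numeric(w), "*")
  # evaluate in priority order; max.col("first") then honours the priority
  pr <- max.col(L[, TIE_ORDER, drop = FALSE], ties.method = "first")
  TIE_ORDER[pr]
}

# All weight triples on the simplex lattice with the given step.
weight_grid <- function(grid_step = 0.01) {
  N <- round(1 / grid_step)
  if (abs(N * grid_step - 1) > 1e-9)
    stop("`grid_step` must divide 1")
  g <- expand.grid(i = 0:N, j = 0:N)
  g <- g[g$i + g$j <= N, ]
  cbind(w_v = g$i / N, w_c = g$j / N, w_g = (N - g$i - g$j) / N)
}

#' Optimize the class-weight operating point
#'
#' Exhaustive search over the simplex lattice of weight triples (step
#' `grid_step`, weights summing to one) minimizing the number of hard-label
#' disagreements between the weighted-argmax classification of the supplied
#' (out-of-fold) posteriors and the reference labels. Ties are broken by
#' smallest distance to the uniform triple, then lexicographically.
#'
#' @param posteriors samples x 3 matrix (vessel, core, ggo), e.g. from
#'   [cv_posteriors()].
#' @param labels reference labels in 1..3.
#' @param grid_step lattice step, default 0.01.
#' @return A [class_weights()] object with attribute `disagreement` (the
#'   minimized count).
#' @export
optimize_weights <- function(posteriors, labels, grid_step = 0.01) {
  posteriors <- as.matrix(posteriors)
  labels <- as.integer(labels)
  if (nrow(posteriors) == 0L) stop("no validation posteriors supplied")
  grid <- weight_grid(grid_step)
  dis <- integer(nrow(grid))
  for (g in seq_len(nrow(grid)))
    dis[g] <- sum(weighted_argmax(posteriors, grid[g, ]) != labels)
  best <- which(dis == min(dis))
  if (length(best) > 1L) {
    d_unif <- rowSums(sweep(grid[best, , drop = FALSE], 2L, 1 / 3)^2)
    best <- best[d_unif == min(d_unif)]
    if (length(best) > 1L) {
      ord <- do.call(order, as.data.frame(grid[best, , drop = FALSE]))
      best <- best[ord[1L]]
    }
  }
  w <- class_weights(grid[best, 1L], grid[best, 2L], grid[best, 3L])
  attr(w, "disagreement") <- min(dis)
  w
}

#' Out-of-fold posteriors by patient
#'
#' Leave-one-patient-out cross-validation (grouped K-fold when there are
#' more than `max_lopo` patients; fold assignment is seeded) producing, for
#' every sample, the posterior from a classifier trained without that
#' sample's patient. `k` is clipped to the smallest training-fold size minus
#' one, with a warning.
#'
#' @param features,labels,patient_id training rows with a patient identifier
#'   per row.
#' @param k neighbours, as in [train_classifier()].
#' @param max_lopo above this patient count, grouped `max_lopo`-fold CV is
#'   used instead of leave-one-patient-out.
#' @param seed fold-assignment seed.
#' @return Matrix (samples x 3) of out-of-fold posteriors.
#' @export
cv_posteriors <- function(features, labels, patient_id, k = 150L,
                          max_lopo = 20L, seed = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  pats <- unique(patient_id)
  if (length(pats) < 2L) stop("need at least two patients for cross-validation")
  fold_of <- if (length(pats) <= max_lopo) {
    setNames(seq_along(pats), pats)
  } else {
    setNames(with_seed(seed, sample(rep_len(seq_len(max_lopo), length(pats)))),
             pats)
  }
  folds <- fold_of[as.character(patient_id)]
  post <- matrix(NA_real_, nrow(features), 3L,
                 dimnames = list(NULL, CLASS_NAMES))
  min_train <- min(vapply(unique(folds), function(f) sum(folds != f),
                          integer(1L)))
  if (k >= min_train) {
    warning(sprintf("k = %d clipped to %d (smallest training fold - 1)",
                    k, min_train - 1L))
    k <- min_train - 1L
  }
  for (f in unique(folds)) {
    tr <- folds != f
    model <- train_classifier(features[tr, , drop = FALSE], labels[tr], k)
    post[!tr, ] <- predict(model, features[!tr, , drop = FALSE])
  }
  post
}

#' Posterior stack over the nodule
#'
#' Three aligned probability maps (vessel, core, ground-glass) over a nodule
#' mask; inside the mask each voxel's probabilities sum to one.
#'
#' @param p_v,p_c,p_g 3D probability arrays.
#' @param mask logical array: voxels where the stack is defined.
#' @param spacing,origin grid metadata, as in [ct_volume()].
#' @return A `posterior_stack`.
#' @export
posterior_stack <- function(p_v, p_c, p_g, mask, spacing = c(1, 1, 1),
                            origin = c(0, 0, 0)) {
  stopifnot(identical(dim(p_v), dim(p_c)), identical(dim(p_v), dim(p_g)),
            identical(dim(p_v), dim(mask)))
  m <- which(mask)
  vals <- cbind(p_v[m], p_c[m], p_g[m])
  if (any(vals < -1e-9) || any(vals > 1 + 1e-9))
    stop("posterior probabilities must lie in [0, 1]")
  if (any(abs(rowSums(vals) - 1) > 1e-6))
    stop("posteriors must sum to 1 at every masked voxel")
  structure(list(p_v = p_v, p_c = p_c, p_g = p_g, mask = mask,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "posterior_stack")
}

#' Predict posterior maps for a nodule
#'
#' Computes class posteriors on the standardized grid and, when a source
#' grid is supplied, interpolates them back to the source resolution with
#' trilinear interpolation, renormalizing to sum to one afterwards. Source
#' mask voxels with no interpolation support (no masked standardized voxel
#' within reach, a rare boundary case) receive uniform posteriors.
#'
#' @param model an `ssn_classifier`.
#' @param vol_std standardized [ct_volume()].
#' @param mask_std nodule mask on the standardized grid.
#' @param source optional source-grid [ct_volume()] to interpolate back to.
#' @param source_mask nodule mask on the source grid (required with
#'   `source`).
#' @param spec [feature_spec()] used at training time.
#' @return A [posterior_stack()] on the standardized (or source) grid.
#' @export
predict_posteriors <- function(model, vol_std, mask_std, source = NULL,
                               source_mask = NULL, spec = NULL) {
  if (is.null(spec)) spec <- model$feature_spec
  if (is.null(spec)) spec <- feature_spec()
  fm <- assemble_features(vol_std, mask_std, spec)
  post <- predict(model, fm)
  d <- vol_dim(vol_std)
  idx <- attr(fm, "voxel_index")
  maps <- lapply(1:3, function(cls) {
    a <- array(0, d)
    a[idx] <- post[, cls]
    a
  })
  msk_std <- as_logical_mask(mask_std)
  if (is.null(source)) {
    return(posterior_stack(maps[[1L]], maps[[2L]], maps[[3L]], msk_std,
                           vol_std$spacing, vol_std$origin))
  }
  if (is.null(source_mask))
    stop("`source_mask` is required when interpolating to a source grid")
  src_msk <- as_logical_mask(source_mask)
  # physical bounds check: every masked source voxel must map inside the
  # standardized grid (within half a voxel)
  offs <- (source$origin - vol_std$origin) / vol_std$spacing
  step <- source$spacing / vol_std$spacing
  mi <- which(src_msk, arr.ind = TRUE)
  ci <- sweep(sweep(mi - 1, 2L, step, "*"), 2L, offs, "+")
  if (any(ci < -0.5) || any(sweep(ci, 2L, d - 0.5) > 0))
    stop("nodule mask voxels map outside the standardized grid")
  interp <- lapply(maps, function(a)
    .resample_grid(a, d, vol_dim(source), offs, step, 0L))
  s <- interp[[1L]] + interp[[2L]] + interp[[3L]]
  inside <- src_msk & s > 1e-12
  out <- lapply(interp, function(a) {
    a[inside] <- a[inside] / s[inside]
    a[!inside] <- 0
    a[src_msk & !inside] <- 1 / 3
    a
  })
  posterior_stack(out[[1L]], out[[2L]], out[[3L]], src_msk,
                  source$spacing, source$origin)
}

#' Initial three-class segmentation (weighted argmax)
#'
#' Each masked voxel receives the class maximizing the likelihood
#' `L_m = w_m * P_m`; ties follow the fixed priority ground-glass > vessel >
#' core. Solitary voxels are then replaced by the majority label of their
#' neighbours (see [smooth_solitary()]), unless `smooth = FALSE`.
#'
#' @param post a [posterior_stack()].
#' @param weights a [class_weights()] triple.
#' @param smooth apply the solitary-voxel majority pass (default `TRUE`).
#' @return A [label_volume()]; 0 outside the mask.
#' @export
initial_segmentation <- function(post, weights, smooth = TRUE) {
  stopifnot(inherits(post, "posterior_stack"))
  w <- as.numeric(weights)
  idx <- which(post$mask)
  P <- cbind(post$p_v[idx], post$p_c[idx], post$p_g[idx])
  lab <- array(0L, dim(post$mask))
  lab[idx] <- weighted_argmax(P, w)
  labels <- label_volume(lab, post$spacing, post$origin)
  if (smooth) {
    L <- lapply(1:3, function(cls) {
      a <- array(0, dim(post$mask))
      a[idx] <- P[, cls] * w[cls]
      a
    })
    labels <- smooth_solitary(labels, likelihood = L)
  }
  labels
}

#' Replace solitary voxels by their neighbourhood majority
#'
#' A labelled voxel with no same-label voxel among its masked 26-neighbours
#' is relabelled with the majority label of those neighbours, in a single
#' pass over a snapshot of the input (no cascade). Majority ties are broken
#' by the largest class likelihood at the voxel when likelihood maps are
#' supplied, otherwise by the fixed class priority.
#'
#' @param labels a [label_volume()] (0 outside the nodule).
#' @param likelihood optional list of 3 arrays (`L_v`, `L_c`, `L_g`).
#' @return A [label_volume()].
#' @export
smooth_solitary <- function(labels, likelihood = NULL) {
  stopifnot(inherits(labels, "ct_volume"))
  lab <- labels$data
  storage.mode(lab) <- "integer"
  info <- .solitary_info(lab, dim(lab), 3L)
  if (nrow(info) == 0L) return(labels)
  out <- lab
  for (r in seq_len(nrow(info))) {
    i <- info[r, 1L]
    cnt <- info[r, 3:5]
    if (sum(cnt) == 0L) next  # isolated masked voxel: keep its label
    mx <- which(cnt == max(cnt))
    if (length(mx) > 1L) {
      if (!is.null(likelihood)) {
        lv <- vapply(mx, function(cls) likelihood[[cls]][i], numeric(1L))
        mx <- mx[lv == max(lv)]
      }
      if (length(mx) > 1L) mx <- TIE_ORDER[TIE_ORDER %in% mx][1L]
    }
    out[i] <- as.integer(mx[1L])
  }
  label_volume(out, labels$spacing, labels$origin)
}
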