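#' Feature specification for the voxel classifier
#'
#' The default descriptor has 17 dimensions: for each scale sigma = 1, 2, 4
#' mm the three Hessian eigenvalues (sorted by decreasing `|lambda|`, sign
#' retained) and the gradient magnitude (12 columns), the raw HU value (1),
#' Gaussian-smoothed HU at each scale (3), and the standard deviation over
#' the 26-neighbourhood including the centre voxel (1).
#'
#' @param scales Gaussian scales in mm, strictly positive.
#' @param eigenvalues,gradient,smoothed,raw,neighborhood_sd logical flags
#'   enabling each feature block.
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(scales = c(1, 2, 4), eigenvalues = TRUE,
                         gradient = TRUE, smoothed = TRUE, raw = TRUE,
                         neighborhood_sd = TRUE) {
  scales <- as.numeric(scales)
  if (length(scales) < 1L || any(!is.finite(scales)) || any(scales <= 0))
    stop("`scales` must be strictly positive (mm)")
  if (!any(eigenvalues, gradient, smoothed, raw, neighborhood_sd))
    stop("at least one feature block must be enabled")
  structure(list(scales = scales, eigenvalues = eigenvalues,
                 gradient = gradient, smoothed = smoothed, raw = raw,
                 neighborhood_sd = neighborhood_sd),
            class = "feature_spec")
}

feature_names <- function(spec) {
  nm <- character(0)
  if (spec$eigenvalues || spec$gradient) {
    for (s in spec$scales) {
      if (spec$eigenvalues)
        nm <- c(nm, sprintf(c("l1_s%g", "l2_s%g", "l3_s%g"), s))
      if (spec$gradient) nm <- c(nm, sprintf("grad_s%g", s))
    }
  }
  if (spec$raw) nm <- c(nm, "hu")
  if (spec$smoothed) nm <- c(nm, sprintf("smooth_s%g", spec$scales))
  if (spec$neighborhood_sd) nm <- c(nm, "nsd")
  nm
}

#' Gaussian-smoothed volume
#' @param vol an isotropic [ct_volume()].
#' @param sigma Gaussian scale (mm).
#' @return A [ct_volume()].
#' @export
gaussian_smooth <- function(vol, sigma) {
  assert_isotropic(vol)
  ct_volume(filter_gaussian(vol$data, sigma, vol$spacing), vol$spacing,
            vol$origin)
}

#' Hessian eigenvalue maps
#'
#' Eigenvalues of the 3x3 matrix of Gaussian second derivatives at physical
#' scale `sigma`, sorted per voxel by decreasing absolute value
#' (`|l1| >= |l2| >= |l3|`); the sign is retained, so a bright tube has
#' `l1, l2 << 0` and `|l3|` small, and a bright blob has three similar
#' negative eigenvalues.
#'
#' @param vol an isotropic [ct_volume()]; anisotropic input is an error
#'   (resample first).
#' @param sigma derivative scale (mm).
#' @return A list of three [ct_volume()]s: `l1`, `l2`, `l3`.
#' @export
hessian_eigenvalues <- function(vol, sigma) {
  assert_isotropic(vol)
  h2 <- function(ox, oy, oz)
    filter_gaussian(vol$data, sigma, vol$spacing, orders = c(ox, oy, oz))
  e <- .eig3_sorted(h2(2L, 0L, 0L), h2(0L, 2L, 0L), h2(0L, 0L, 2L),
                    h2(1L, 1L, 0L), h2(1L, 0L, 1L), h2(0L, 1L, 1L))
  d <- vol_dim(vol)
  lapply(e, function(v) {
    dim(v) <- d
    ct_volume(v, vol$spacing, vol$origin)
  })
}

#' Gradient magnitude map
#'
#' Euclidean norm of the Gaussian first-derivative vector at scale `sigma`.
#'
#' @inheritParams hessian_eigenvalues
#' @return A [ct_volume()].
#' @export
gradient_magnitude <- function(vol, sigma) {
  assert_isotropic(vol)
  g1 <- function(ox, oy, oz)
    filter_gaussian(vol$data, sigma, vol$spacing, orders = c(ox, oy, oz))
  gm <- sqrt(g1(1L, 0L, 0L)^2 + g1(0L, 1L, 0L)^2 + g1(0L, 0L, 1L)^2)
  ct_volume(gm, vol$spacing, vol$origin)
}

#' 26-neighbourhood standard deviation
#'
#' Population standard deviation over the 3x3x3 neighbourhood (26 neighbours
#' plus the centre voxel, 27 values); edge voxels use the neighbours that
#' exist.
#'
#' @param vol a [ct_volume()].
#' @return A [ct_volume()].
#' @export
neighborhood_sd <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  arr <- as.numeric(vol$data)
  dim(arr) <- vol_dim(vol)
  ct_volume(.neighborhood_sd(arr, vol_dim(vol)), vol$spacing, vol$origin)
}

#' Assemble the per-voxel feature matrix
#'
#' One row per masked voxel, in increasing linear (column-major, x fastest)
#' voxel order — a fixed deterministic ordering. Columns follow the block
#' layout of [feature_spec()]; with the default spec there are 17.
#'
#' @param vol a standardized (isotropic) [ct_volume()].
#' @param mask a [label_volume()] or logical array on the same grid; rows are
#'   produced for voxels where `mask > 0`.
#' @param spec a [feature_spec()].
#' @return A numeric matrix with column names and a `voxel_index` attribute
#'   (1-based linear indices into the grid).
#' @export
assemble_features <- function(vol, mask, spec = feature_spec()) {
  stopifnot(inherits(vol, "ct_volume"), inherits(spec, "feature_spec"))
  if (inherits(mask, "ct_volume")) stop_if_misaligned(vol, mask, "vol/mask")
  msk <- as_logical_mask(mask) & TRUE
  idx <- which(msk)
  if (length(idx) == 0L)
    stop("mask is empty; no voxels to extract features for")
  cols <- list()
  if (spec$eigenvalues || spec$gradient) {
    for (s in spec$scales) {
      if (spec$eigenvalues) {
        ev <- hessian_eigenvalues(vol, s)
        cols[[length(cols) + 1L]] <- ev$l1$data[idx]
        cols[[length(cols) + 1L]] <- ev$l2$data[idx]
        cols[[length(cols) + 1L]] <- ev$l3$data[idx]
      }
      if (spec$gradient)
        cols[[length(cols) + 1L]] <- gradient_magnitude(vol, s)$data[idx]
    }
  }
  if (spec$raw) cols[[length(cols) + 1L]] <- as.numeric(vol$data[idx])
  if (spec$smoothed) {
    for (s in spec$scales)
      cols[[length(cols) + 1L]] <- gaussian_smooth(vol, s)$data[idx]
  }
  if (spec$neighborhood_sd)
    cols[[length(cols) + 1L]] <- neighborhood_sd(vol)$data[idx]
  fm <- do.call(cbind, cols)
  colnames(fm) <- feature_names(spec)
  bad <- which(!is.finite(fm), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite feature '%s' at voxel %d",
                 colnames(fm)[bad[1L, 2L]], idx[bad[1L, 1L]]))
  attr(fm, "voxel_index") <- idx
  attr(fm, "feature_spec") <- spec
  fm
}
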