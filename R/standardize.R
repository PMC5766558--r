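#' Resample a volume to an isotropic grid
#'
#' Trilinear resampling to `target_spacing` mm in all three directions. The
#' output grid keeps the input origin (first voxel centre unchanged) and its
#' shape is `round(dim * spacing / target_spacing)` per axis, so the physical
#' extent is preserved to within one output voxel; the rounding rule is
#' recorded in the result's `resample_rule` attribute. Sampling outside the
#' source grid uses edge clamping.
#'
#' @param vol a [ct_volume()].
#' @param target_spacing isotropic target voxel size (mm), default 0.5.
#' @return A [ct_volume()] with spacing `c(t, t, t)`.
#' @export
resample_isotropic <- function(vol, target_spacing = 0.5) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!is.finite(target_spacing) || target_spacing <= 0)
    stop("`target_spacing` must be a positive number (mm)")
  d <- vol_dim(vol)
  degen <- which(d == 1L & abs(vol$spacing - target_spacing) > 1e-9)
  if (length(degen))
    stop(sprintf("cannot resample along degenerate single-slice axis %s",
                 paste(c("x", "y", "z")[degen], collapse = ", ")))
  if (all(abs(vol$spacing - target_spacing) < 1e-9)) {
    out <- vol
    attr(out, "resample_rule") <- "identity"
    return(out)
  }
  out_dim <- pmax(1L, as.integer(round(d * vol$spacing / target_spacing)))
  step <- rep(target_spacing, 3) / vol$spacing
  arr <- .resample_grid(as.numeric(vol$data), d, out_dim,
                        offset = c(0, 0, 0), step = step, mode = 0L)
  out <- ct_volume(arr, spacing = rep(target_spacing, 3), origin = vol$origin)
  attr(out, "resample_rule") <- "round(dim*spacing/target); origin preserved"
  out
}

#' Resample a label map onto a reference grid
#'
#' Nearest-neighbour interpolation in physical coordinates; never invents new
#' labels.
#'
#' @param labels a [label_volume()].
#' @param reference a [ct_volume()] defining the output grid.
#' @return A [label_volume()] on the reference grid.
#' @export
resample_labels <- function(labels, reference) {
  stopifnot(inherits(labels, "ct_volume"), inherits(reference, "ct_volume"))
  if (same_grid(labels, reference)) {
    return(label_volume(labels$data, labels$spacing, labels$origin))
  }
  d <- vol_dim(labels)
  offset <- (reference$origin - labels$origin) / labels$spacing
  step <- reference$spacing / labels$spacing
  arr <- .resample_grid(as.numeric(labels$data), d, vol_dim(reference),
                        offset = offset, step = step, mode = 1L)
  label_volume(arr, reference$spacing, reference$origin)
}

#' Reconstruction-kernel band profile
#'
#' Difference-of-Gaussians band decomposition used to match the frequency
#' content of a sharp-kernel reconstruction to a soft reference kernel. Band
#' `b` is `G[sigma_{b-1}] - G[sigma_b]` (with `sigma_0 = 0`, i.e. the
#' identity); the residual is the final low-pass `G[sigma_B]`. With all gains
#' at 1 the decomposition reconstructs the input exactly.
#'
#' @param band_sigmas strictly increasing Gaussian scales (mm); default
#'   `c(0.5, 1, 2, 4)`, spanning the feature scales used downstream.
#' @param gain_per_band multiplicative energy-correction factor per band.
#' @param residual_gain factor for the low-pass residual.
#' @return A `band_profile` object.
#' @export
band_profile <- function(band_sigmas = c(0.5, 1, 2, 4),
                         gain_per_band = rep(1, length(band_sigmas)),
                         residual_gain = 1) {
  band_sigmas <- as.numeric(band_sigmas)
  if (length(band_sigmas) == 0L)
    stop("band profile needs at least one band scale")
  if (any(diff(band_sigmas) <= 0) || any(band_sigmas <= 0))
    stop("`band_sigmas` must be strictly increasing and positive")
  gain_per_band <- as.numeric(gain_per_band)
  if (length(gain_per_band) != length(band_sigmas) ||
      any(!is.finite(gain_per_band)) || any(gain_per_band <= 0))
    stop("`gain_per_band` must be positive and match `band_sigmas`")
  if (!is.finite(residual_gain) || residual_gain <= 0)
    stop("`residual_gain` must be positive")
  structure(list(band_sigmas = band_sigmas, gain_per_band = gain_per_band,
                 residual_gain = residual_gain), class = "band_profile")
}

# Decompose an isotropic volume into difference-of-Gaussians bands plus the
# low-pass residual. Returns list of arrays: bands[[1..B]], residual.
decompose_bands <- function(vol, band_sigmas) {
  h <- assert_isotropic(vol)
  smoothed <- lapply(band_sigmas, function(s)
    filter_gaussian(vol$data, s, vol$spacing))
  bands <- vector("list", length(band_sigmas))
  prev <- as.numeric(vol$data)
  dim(prev) <- vol_dim(vol)
  for (b in seq_along(band_sigmas)) {
    bands[[b]] <- prev - smoothed[[b]]
    prev <- smoothed[[b]]
  }
  list(bands = bands, residual = prev)
}

#' Normalize a volume to a reference reconstruction kernel
#'
#' Decomposes the (isotropic) volume into frequency bands, rescales each
#' band's amplitude by the profile gain, and recombines with the low-pass
#' residual. An identity profile returns the input unchanged up to numerical
#' tolerance.
#'
#' @param vol an isotropic [ct_volume()].
#' @param profile a [band_profile()].
#' @return A [ct_volume()] with adjusted frequency content.
#' @export
kernel_normalize <- function(vol, profile) {
  stopifnot(inherits(vol, "ct_volume"), inherits(profile, "band_profile"))
  dec <- decompose_bands(vol, profile$band_sigmas)
  out <- profile$residual_gain * dec$residual
  for (b in seq_along(dec$bands))
    out <- out + profile$gain_per_band[b] * dec$bands[[b]]
  ct_volume(out, vol$spacing, vol$origin)
}

#' Estimate a band profile from sharp- and soft-kernel reconstructions
#'
#' Finds the per-band gains such that the normalized sharp-kernel volumes
#' match the mean band energies (sum of squared band values, optionally
#' restricted to a body mask so that air outside the patient does not
#' distort the estimate) of the soft-kernel reference group. Because the
#' difference-of-Gaussians bands overlap spectrally, a gain applied to one
#' band changes the measured energy of its neighbours; the gains are
#' therefore solved by fixed-point iteration — rescale each gain by
#' `sqrt(E_ref / E_current)`, re-normalize, repeat — which converges in a
#' few iterations and exactly recovers gains that were applied with the
#' same band definition. The residual gain is estimated from the mean-free
#' low-pass residual.
#'
#' @param sharp_vols,soft_vols lists of isotropic [ct_volume()]s
#'   reconstructed with the sharp (to be corrected) and soft (reference)
#'   kernels.
#' @param band_sigmas band scales (mm), as in [band_profile()].
#' @param masks optional list of body masks (one per volume, sharp then
#'   soft) restricting the energy computation.
#' @param max_iter,tol fixed-point iteration controls (stop when the
#'   largest relative gain update falls below `tol`).
#' @return A [band_profile()].
#' @export
estimate_band_profile <- function(sharp_vols, soft_vols,
                                  band_sigmas = c(0.5, 1, 2, 4),
                                  masks = NULL, max_iter = 25L, tol = 1e-4) {
  if (length(sharp_vols) < 1L || length(soft_vols) < 1L)
    stop("need at least one volume per kernel group")
  nb <- length(band_sigmas)
  mask_for <- function(i) {
    if (!is.null(masks)) as_logical_mask(masks[[i]]) else TRUE
  }
  group_energy <- function(vols, first_index) {
    e <- matrix(NA_real_, nrow = length(vols), ncol = nb + 1L)
    for (i in seq_along(vols)) {
      dec <- decompose_bands(vols[[i]], band_sigmas)
      sel <- mask_for(first_index + i - 1L)
      for (b in seq_len(nb)) e[i, b] <- sum(dec$bands[[b]][sel]^2)
      res <- dec$residual - mean(dec$residual[sel])
      e[i, nb + 1L] <- sum(res[sel]^2)
    }
    colMeans(e)
  }
  e_soft <- group_energy(soft_vols, length(sharp_vols) + 1L)
  e_sharp0 <- group_energy(sharp_vols, 1L)
  zero <- which(e_sharp0[seq_len(nb)] <= 0)
  if (length(zero))
    stop(sprintf("zero band energy in sharp group for band(s) %s (sigma %s mm)",
                 paste(zero, collapse = ", "),
                 paste(band_sigmas[zero], collapse = ", ")))
  gains <- rep(1, nb)
  res_gain <- if (e_sharp0[nb + 1L] > 0 && e_soft[nb + 1L] > 0)
    sqrt(e_soft[nb + 1L] / e_sharp0[nb + 1L]) else 1
  for (it in seq_len(max_iter)) {
    prof <- band_profile(band_sigmas, gains, res_gain)
    normed <- lapply(sharp_vols, kernel_normalize, profile = prof)
    e_cur <- group_energy(normed, 1L)
    upd <- sqrt(e_soft[seq_len(nb)] / e_cur[seq_len(nb)])
    gains <- gains * upd
    if (max(abs(upd - 1)) < tol) break
  }
  band_profile(band_sigmas, gains, res_gain)
}

#' Standardize a CT volume
#'
#' Resampling to an isotropic grid followed by reconstruction-kernel band
#' normalization — the preprocessing every scan receives before feature
#' extraction so that training and test data share resolution and kernel
#' appearance.
#'
#' @param vol input [ct_volume()] in HU.
#' @param target_spacing isotropic voxel size (mm), default 0.5.
#' @param profile a [band_profile()]; the default identity profile leaves the
#'   frequency content untouched.
#' @return An isotropic, kernel-normalized [ct_volume()].
#' @export
standardize_volume <- function(vol, target_spacing = 0.5,
                               profile = band_profile()) {
  kernel_normalize(resample_isotropic(vol, target_spacing), profile)
}
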