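#' Vascular continuity weight
#'
#' Piecewise-linear penalty on the vessel likelihood based on the ratio of
#' the local vessel diameter inside the nodule (`d_in`) to the mean diameter
#' of the vessel entering the nodule (`d_out`): 1 when `d_in <= d_out`, 0
#' when `d_in >= a * d_out`, and the linear interpolation
#' `1 - (d_in/d_out - 1)/(a - 1)` in between. Continuous at both
#' breakpoints. The cutoff `a` defaults to 3: an inside vessel three times
#' as thick as its entering vessel is not anatomically plausible.
#'
#' @param d_in local diameter(s) inside the nodule (mm); vectorized.
#' @param d_out mean entering-vessel diameter (mm), > 0.
#' @param a cutoff ratio, > 1.
#' @return Weight(s) in `[0, 1]`.
#' @export
continuity_weight <- function(d_in, d_out, a = 3) {
  if (!is.finite(d_out) || d_out <= 0) stop("`d_out` must be > 0")
  if (!is.finite(a) || a <= 1) stop("`a` must be > 1")
  r <- d_in / d_out
  w <- 1 - (r - 1) / (a - 1)
  w[r <= 1] <- 1
  w[r >= a] <- 0
  w
}

#' Split a binary vessel set into 6-connected components
#'
#' @param mask logical array or [label_volume()] (nonzero = vessel).
#' @param connectivity 6 (default, the convention for splitting the inside
#'   vessel set) or 26.
#' @return A list of components, each with `id` and `voxels` (1-based linear
#'   indices); ids are ordered by each component's smallest linear voxel
#'   index.
#' @export
split_components <- function(mask, connectivity = 6L) {
  dims <- if (inherits(mask, "ct_volume")) vol_dim(mask) else dim(mask)
  m <- as_logical_mask(mask)
  lab <- .cc_label(as.logical(m), dims, as.integer(connectivity))
  nc <- max(lab)
  if (nc == 0L) return(list())
  vox <- split(which(lab > 0L), lab[lab > 0L])
  lapply(seq_len(nc), function(i)
    list(id = i, voxels = as.integer(vox[[as.character(i)]])))
}

#' Per-voxel vessel diameter by local thickness
#'
#' Diameter of the largest sphere inscribed in the vessel mask that covers
#' each voxel, computed from the Euclidean distance transform (the digital
#' distance to the nearest background voxel centre is reduced by half a
#' voxel so that a structure `n` voxels across measures `n` voxel widths).
#' Spacing may be anisotropic; distances are physical (mm).
#'
#' @param mask binary vessel mask (logical array or [label_volume()]).
#' @param spacing voxel spacing (mm); taken from `mask` if it is a volume.
#' @return Array of diameters (mm), 0 outside the mask.
#' @export
estimate_diameters <- function(mask, spacing = NULL) {
  if (inherits(mask, "ct_volume")) {
    if (is.null(spacing)) spacing <- mask$spacing
    dims <- vol_dim(mask)
  } else {
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    dims <- dim(mask)
  }
  m <- as_logical_mask(mask)
  if (!any(m)) stop("vessel mask is empty")
  e2 <- .edt_squared(as.logical(m), dims, spacing)
  h <- mean(spacing)
  r <- sqrt(e2)
  r[m] <- pmax(r[m] - h / 2, h / 4)
  r[!m] <- 0
  .local_thickness(as.logical(m), dims, spacing, r^2)
}

#' Default outside-vessel segmentation
#'
#' Pluggable stand-in producing a binary mask of vessels in the lung outside
#' the nodule: a multi-scale tubularity measure from the Hessian eigenvalues
#' (bright tubes have two large negative eigenvalues) gated by a soft-tissue
#' HU threshold, keeping 26-connected structures. An externally supplied
#' mask bypasses the filter untouched.
#'
#' @param vol standardized (isotropic) [ct_volume()] in HU.
#' @param roi region to search (logical array or [label_volume()]); must be
#'   nonempty.
#' @param nodule nodule mask; removed from the result.
#' @param external optional precomputed vessel mask, returned as-is (minus
#'   the nodule).
#' @param scales tubularity scales (mm).
#' @param hu_threshold minimum HU for vessel candidates.
#' @param min_voxels discard components smaller than this.
#' @return A [label_volume()] with 1 = outside vessel.
#' @export
outer_vessel_mask <- function(vol, roi = NULL, nodule = NULL, external = NULL,
                              scales = c(1, 2), hu_threshold = -450,
                              min_voxels = 2L) {
  stopifnot(inherits(vol, "ct_volume"))
  d <- vol_dim(vol)
  nod <- if (is.null(nodule)) array(FALSE, d) else as_logical_mask(nodule)
  if (!is.null(external)) {
    m <- as_logical_mask(external)
    m[nod] <- FALSE
    return(label_volume(m, vol$spacing, vol$origin))
  }
  r <- if (is.null(roi)) array(TRUE, d) else as_logical_mask(roi)
  if (!any(r)) stop("empty ROI for vessel segmentation")
  tub <- array(0, d)
  for (s in scales) {
    ev <- hessian_eigenvalues(vol, s)
    t_s <- ifelse(ev$l1$data < 0 & ev$l2$data < 0,
                  abs(ev$l2$data) - abs(ev$l3$data), 0)
    tub <- pmax(tub, t_s)
  }
  cand <- r & !nod & vol$data > hu_threshold & tub > 0
  if (any(cand)) {
    lab <- .cc_label(as.logical(cand), d, 26L)
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < min_voxels)
    if (length(drop)) cand[lab %in% drop] <- FALSE
  }
  label_volume(cand, vol$spacing, vol$origin)
}

#' Entering vessels and continuity weights for an initial segmentation
#'
#' For each 6-connected component of the initial inside-vessel set, the
#' entering vessel is the outside-vessel component that (1) is attached to
#' the component — within `attach_mm` of it, a physical tolerance covering
#' diagonal contact and the sub-voxel gap that boundary partial-volume
#' voxels can open between the inside segmentation and the outside vessel —
#' (2) is at least as large as any other attached outside vessel, and (3)
#' belongs to the vascular tree (outside components within `tree_fraction` of the largest
#' one; the default keeps only the largest, so segmentation noise cannot
#' anchor a continuity weight). Among qualifying components the one with the
#' largest diameter near the nodule border wins; ties go to the larger
#' voxel count, then the smaller component id. `d_out` is that component's
#' calibre — the largest inscribed-sphere diameter — within
#' `border_band_mm` of the nodule surface.
#' Components with no entering vessel are anatomically implausible as
#' vessels and get weight 0 (configurable via `unattached_weight`).
#'
#' @param initial_labels [label_volume()] from [initial_segmentation()].
#' @param outer [label_volume()] of vessels outside the nodule.
#' @param nodule nodule mask.
#' @param a continuity cutoff, see [continuity_weight()].
#' @param border_band_mm width of the band next to the nodule surface over
#'   which `d_out` is averaged (default 2 mm).
#' @param attach_mm attachment tolerance between inside components and
#'   outside vessels (default 2 mm, about one diagonal voxel at screening
#'   resolution plus the boundary shell).
#' @param tree_fraction outside components with at least this fraction of
#'   the largest component's voxels count as vascular tree (default 0.1).
#'   In a whole-lung vessel segmentation every real branch connects to the
#'   tree; in a cropped sub-volume the two sides of a crossing vessel are
#'   separate components, so tree membership is approximated by size —
#'   sizable components are vessels, specks are segmentation noise.
#' @param unattached_weight `w_vc` for inside components with no entering
#'   vessel (default 0).
#' @return A `continuity_field`: list with `w_vc` (array, 1 outside the
#'   initial vessel set), `d_in` (array, mm), and `components` (per-component
#'   bookkeeping: entering vessel id and `d_out`).
#' @export
continuity_field <- function(initial_labels, outer, nodule, a = 3,
                             border_band_mm = 2, attach_mm = 2,
                             tree_fraction = 0.1, unattached_weight = 0) {
  stopifnot(inherits(initial_labels, "ct_volume"))
  d <- vol_dim(initial_labels)
  spacing <- initial_labels$spacing
  inner <- initial_labels$data == LBL_VESSEL
  nod <- as_logical_mask(nodule)
  out_msk <- as_logical_mask(outer)
  out_msk[nod] <- FALSE
  w_vc <- array(1, d)
  d_in <- array(0, d)
  comps <- split_components(inner, 6L)
  if (length(comps) == 0L)
    return(structure(list(w_vc = w_vc, d_in = d_in, components = list(),
                          a = a), class = "continuity_field"))
  # local thickness over the full vessel structure (inside set + outside
  # vessels), so a tube keeps its calibre across the nodule boundary
  full <- inner | out_msk
  thick <- estimate_diameters(full, spacing)
  d_in[inner] <- thick[inner]

  out_lab <- .cc_label(as.logical(out_msk), d, 26L)
  n_out <- max(out_lab)
  tree_ids <- integer(0)
  border_sel <- NULL
  if (n_out > 0L) {
    sizes <- tabulate(out_lab[out_lab > 0L], nbins = n_out)
    tree_ids <- which(sizes >= tree_fraction * max(sizes))
    # distance from outside voxels to the nodule surface
    dist_nod2 <- .edt_squared(as.logical(!nod), d, spacing)
    border_sel <- out_lab > 0L & dist_nod2 <= border_band_mm^2
  }
  for (ci in seq_along(comps)) {
    comp <- comps[[ci]]
    comp_mask <- array(TRUE, d)
    comp_mask[comp$voxels] <- FALSE
    dist2 <- .edt_squared(as.logical(comp_mask), d, spacing)
    attached <- sort(unique(out_lab[out_lab > 0L & dist2 <= attach_mm^2]))
    qualifying <- intersect(attached, tree_ids)
    if (length(qualifying) == 0L) {
      comps[[ci]]$entering_vessel_id <- NA_integer_
      comps[[ci]]$d_out <- NA_real_
      w_vc[comp$voxels] <- unattached_weight
      next
    }
    d_out_cand <- vapply(qualifying, function(id) {
      sel <- which(border_sel & out_lab == id)
      if (length(sel) == 0L) sel <- which(out_lab == id)
      # the calibre of the entering vessel near the border: the largest
      # inscribed-sphere diameter there (the voxel-wise thickness field
      # carries shell voxels whose values reflect digitization, not calibre)
      max(thick[sel])
    }, numeric(1L))
    best <- which(d_out_cand == max(d_out_cand))
    if (length(best) > 1L) {
      szs <- tabulate(out_lab[out_lab > 0L])[qualifying[best]]
      best <- best[szs == max(szs)]
      best <- best[which.min(qualifying[best])]
    }
    id <- qualifying[best[1L]]
    d_out <- d_out_cand[best[1L]]
    comps[[ci]]$entering_vessel_id <- id
    comps[[ci]]$d_out <- d_out
    w_vc[comp$voxels] <- continuity_weight(thick[comp$voxels], d_out, a)
  }
  structure(list(w_vc = w_vc, d_in = d_in, components = comps, a = a),
            class = "continuity_field")
}

#' Final segmentation with vascular-continuity regularization
#'
#' Re-runs the weighted argmax with the vessel likelihood redefined as
#' `L_v = w_v * w_vc(x) * P_v(x)` (core and ground-glass likelihoods
#' unchanged), then reapplies the solitary-voxel majority pass. Since the
#' vessel likelihood can only shrink, the final vessel set (before
#' smoothing) is a subset of the initial one.
#'
#' @param post the [posterior_stack()] used for the initial segmentation.
#' @param weights the [class_weights()] triple.
#' @param field a `continuity_field` from [continuity_field()].
#' @param smooth reapply the solitary-voxel pass (default `TRUE`).
#' @return A [label_volume()] with the final labels.
#' @export
apply_continuity <- function(post, weights, field, smooth = TRUE) {
  stopifnot(inherits(post, "posterior_stack"),
            inherits(field, "continuity_field"))
  if (!identical(dim(field$w_vc), dim(post$mask)))
    stop("continuity field and posterior stack are on different grids")
  w <- as.numeric(weights)
  idx <- which(post$mask)
  L <- cbind(post$p_v[idx] * w[1L] * field$w_vc[idx],
             post$p_c[idx] * w[2L],
             post$p_g[idx] * w[3L])
  pr <- max.col(L[, TIE_ORDER, drop = FALSE], ties.method = "first")
  lab <- array(0L, dim(post$mask))
  lab[idx] <- TIE_ORDER[pr]
  labels <- label_volume(lab, post$spacing, post$origin)
  if (smooth) {
    Llist <- lapply(1:3, function(cls) {
      a <- array(0, dim(post$mask))
      a[idx] <- L[, cls]
      a
    })
    labels <- smooth_solitary(labels, likelihood = Llist)
  }
  labels
}
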