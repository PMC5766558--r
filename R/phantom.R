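#' Specification of a synthetic subsolid-nodule phantom
#'
#' Describes a CT sub-volume containing lung parenchyma (~ -900 HU), an
#' ellipsoidal ground-glass nodule, optionally a solid core blob, and
#' tubular vessels at soft-tissue attenuation crossing the nodule with a
#' tapering diameter. The rendered volume receives a partial-volume Gaussian
#' blur and additive Gaussian noise; ground-truth labels are assigned on the
#' pre-blur geometry (core > vessel > ground-glass precedence inside the
#' nodule), mirroring how an annotator outlines structures.
#'
#' @param shape grid size (voxels), default `c(56, 56, 40)`.
#' @param spacing voxel spacing (mm); the default `c(0.7, 0.7, 1)` is an
#'   anisotropic screening-CT resolution.
#' @param background_hu parenchyma attenuation, default -900.
#' @param nodule list with `center` (mm), `radii` (mm, length 3), `hu`
#'   (default -600, ground-glass).
#' @param core optional list with `center` (mm), `radius` (mm), `hu`
#'   (default +50, soft tissue); must lie inside the nodule.
#' @param vessels list of vessels, each a list with `points` (n x 3 matrix
#'   of path control points, mm), `diameter` (mm; scalar or one value per
#'   control point, linearly interpolated along the path), `hu` (default
#'   +50).
#' @param blur_sigma partial-volume blur (mm), default 0.6.
#' @param noise_sigma additive Gaussian noise (HU), default 20.
#' @param seed RNG seed for the noise.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(56L, 56L, 40L), spacing = c(0.7, 0.7, 1),
                         background_hu = -900,
                         nodule = list(center = NULL, radii = c(7, 7, 6),
                                       hu = -600),
                         core = NULL, vessels = list(),
                         blur_sigma = 0.6, noise_sigma = 20, seed = 1L) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, all(shape > 0), all(spacing > 0))
  extent <- (shape - 1L) * spacing
  if (is.null(nodule$center)) nodule$center <- extent / 2
  if (is.null(nodule$hu)) nodule$hu <- -600
  if (nodule$hu <= background_hu)
    stop("ground-glass HU must be above the background HU")
  if (!is.null(core)) {
    if (is.null(core$hu)) core$hu <- 50
    if (core$hu <= nodule$hu)
      stop("core HU must be above the ground-glass HU")
    if (any(abs(core$center - nodule$center) + core$radius >
            nodule$radii + 1e-9))
      stop("solid core must lie inside the nodule ellipsoid")
  }
  vessels <- lapply(vessels, function(v) {
    if (is.null(v$hu)) v$hu <- 50
    if (v$hu <= nodule$hu)
      stop("vessel HU must be above the ground-glass HU")
    v$points <- as.matrix(v$points)
    if (ncol(v$points) != 3L || nrow(v$points) < 2L)
      stop("vessel `points` must be an n x 3 matrix with n >= 2")
    v$diameter <- rep_len(as.numeric(v$diameter), nrow(v$points))
    if (any(v$diameter <= 0)) stop("vessel diameters must be positive")
    v
  })
  structure(list(shape = shape, spacing = spacing,
                 background_hu = background_hu, nodule = nodule, core = core,
                 vessels = vessels, blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# physical coordinates (mm) of all voxel centres: three arrays
grid_coords <- function(shape, spacing) {
  list(x = array(rep((0:(shape[1L] - 1L)) * spacing[1L], times = shape[2L] *
                       shape[3L]), shape),
       y = array(rep(rep((0:(shape[2L] - 1L)) * spacing[2L],
                         each = shape[1L]), times = shape[3L]), shape),
       z = array(rep((0:(shape[3L] - 1L)) * spacing[3L],
                     each = shape[1L] * shape[2L]), shape))
}

# Rasterize one tube swept along a polyline with per-control-point diameter.
rasterize_tube <- function(coords, points, diameter) {
  seg_len <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                             points[-nrow(points), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg_len))
  inside <- array(FALSE, dim(coords$x))
  px <- as.numeric(coords$x); py <- as.numeric(coords$y)
  pz <- as.numeric(coords$z)
  for (s in seq_len(nrow(points) - 1L)) {
    p0 <- points[s, ]; p1 <- points[s + 1L, ]
    v <- p1 - p0
    vv <- sum(v^2)
    if (vv == 0) next
    t <- ((px - p0[1L]) * v[1L] + (py - p0[2L]) * v[2L] +
            (pz - p0[3L]) * v[3L]) / vv
    t <- pmin(pmax(t, 0), 1)
    dx <- px - (p0[1L] + t * v[1L])
    dy <- py - (p0[2L] + t * v[2L])
    dz <- pz - (p0[3L] + t * v[3L])
    dist2 <- dx * dx + dy * dy + dz * dz
    rad <- (diameter[s] + t * (diameter[s + 1L] - diameter[s])) / 2
    inside <- inside | array(dist2 <= rad^2, dim(inside))
  }
  inside
}

#' Generate a synthetic subsolid-nodule phantom
#'
#' Rasterizes the geometry of a [phantom_spec()] (background, ground-glass
#' ellipsoid, swept vessel tubes, core blob), applies the partial-volume
#' blur and seeded additive noise, and returns the volume together with the
#' nodule mask, the ground-truth class labels inside the nodule, and the
#' binary mask of vessel voxels outside the nodule. Deterministic for a
#' fixed spec (the seed lives in the spec).
#'
#' @param spec a [phantom_spec()].
#' @return A list: `volume` ([ct_volume()]), `nodule` ([label_volume()],
#'   binary), `truth` ([label_volume()], 1 vessel / 2 core / 3 ground-glass
#'   inside the nodule), `outer_vessels` ([label_volume()], binary),
#'   `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  co <- grid_coords(spec$shape, spec$spacing)
  nod <- ((co$x - spec$nodule$center[1L]) / spec$nodule$radii[1L])^2 +
    ((co$y - spec$nodule$center[2L]) / spec$nodule$radii[2L])^2 +
    ((co$z - spec$nodule$center[3L]) / spec$nodule$radii[3L])^2 <= 1
  vess <- array(FALSE, spec$shape)
  for (v in spec$vessels)
    vess <- vess | rasterize_tube(co, v$points, v$diameter)
  core <- if (!is.null(spec$core)) {
    (co$x - spec$core$center[1L])^2 + (co$y - spec$core$center[2L])^2 +
      (co$z - spec$core$center[3L])^2 <= spec$core$radius^2
  } else array(FALSE, spec$shape)

  hu <- array(spec$background_hu, spec$shape)
  hu[nod] <- spec$nodule$hu
  for (v in spec$vessels) {
    m <- rasterize_tube(co, v$points, v$diameter)
    hu[m] <- v$hu
  }
  if (!is.null(spec$core)) hu[core] <- spec$core$hu

  if (spec$blur_sigma > 0)
    hu <- filter_gaussian(hu, spec$blur_sigma, spec$spacing)
  if (spec$noise_sigma > 0)
    hu <- hu + with_seed(spec$seed,
                         array(rnorm(prod(spec$shape), 0, spec$noise_sigma),
                               spec$shape))

  truth <- array(0L, spec$shape)
  truth[nod] <- LBL_GGO
  truth[nod & vess] <- LBL_VESSEL
  truth[nod & core] <- LBL_CORE
  outer <- vess & !nod

  list(volume = ct_volume(hu, spec$spacing),
       nodule = label_volume(nod, spec$spacing),
       truth = label_volume(truth, spec$spacing),
       outer_vessels = label_volume(outer, spec$spacing),
       spec = spec)
}

# Distance from `origin` to the bounding box [0, extent] along `dir`
# (positive direction); the ray is assumed to start inside the box.
ray_box_t <- function(origin, dir, extent) {
  tt <- Inf
  for (ax in 1:3) {
    if (dir[ax] > 1e-12) tt <- min(tt, (extent[ax] - origin[ax]) / dir[ax])
    if (dir[ax] < -1e-12) tt <- min(tt, (0 - origin[ax]) / dir[ax])
  }
  tt
}

# A random crossing-vessel path: a straight chord through a target point
# near the nodule centre, running boundary to boundary along a fixed
# direction (ray-box intersection keeps the path straight, so branches
# placed on the centerline are guaranteed to touch it), with a mild linear
# taper along the direction of travel.
sample_crossing_vessel <- function(target, extent, diameter, taper = 0.8) {
  dir <- rnorm(3)
  dir[3] <- dir[3] * 0.5  # mostly in-plane, as pulmonary vessels near nodules
  dir <- dir / sqrt(sum(dir^2))
  t_fwd <- ray_box_t(target, dir, extent)
  t_bwd <- ray_box_t(target, -dir, extent)
  pts <- rbind(target - dir * t_bwd, target, target + dir * t_fwd)
  list(points = pts, diameter = c(diameter, diameter * (taper + 1) / 2,
                                  diameter * taper), hu = 50, dir = dir,
       t_fwd = t_fwd, t_bwd = t_bwd)
}

# A side branch leaving the parent vessel at a point on its centerline
# outside the nodule and crossing the nodule at a lateral offset, so that
# all vessels of a phantom form one connected tree, as pulmonary vessels do.
sample_branch_vessel <- function(parent, center, offset, r_max, extent,
                                 diameter, taper = 0.8) {
  t_branch <- min(runif(1L, 1.3, 1.6) * r_max, 0.9 * parent$t_fwd)
  branch_at <- center + parent$dir * t_branch
  target <- center + offset
  dir <- target - branch_at
  dir <- dir / sqrt(sum(dir^2))
  t_fwd <- ray_box_t(target, dir, extent)
  pts <- rbind(branch_at, target, target + dir * t_fwd)
  list(points = pts, diameter = c(diameter, diameter * (taper + 1) / 2,
                                  diameter * taper), hu = 50, dir = dir)
}

#' Generate a seeded phantom cohort
#'
#' Samples phantom specifications from uniform parameter ranges. With the
#' default `composition = "evaluation"` the cohort is stratified round-robin
#' over the four nodule strata used for 3D evaluation — non-solid and
#' part-solid, each with and without crossing vessels — so `n = 16` gives 4
#' per stratum. `composition = "training"` instead mirrors a training set
#' for this task, in which nearly every nodule contains vessels and most
#' have a solid core (vessels in every phantom, a core in four of five):
#' the classifier and its operating point need vessel examples from every
#' cross-validation fold. The manifest records every sampled parameter.
#'
#' @param n number of phantoms.
#' @param seed cohort seed; phantom `i` uses `seed + i` for its noise.
#' @param nodule_radius_mm range of the in-plane nodule semi-axis (mm).
#' @param core_radius_mm range of the solid-core radius (mm); part-solid
#'   nodules with a solid component under ~5 mm across are below the
#'   clinically relevant size, so the default starts at 2.5 mm. The radius
#'   is capped at 80% of the smallest nodule semi-axis so the core stays
#'   inside the nodule.
#' @param vessel_diameter_mm range of vessel diameters at the nodule (mm).
#' @param n_vessels range (min, max) of crossing vessels per vesselized
#'   phantom; additional vessels branch off the first one outside the
#'   nodule, so each phantom's vessels form a single connected tree.
#' @param noise_sigma,blur_sigma acquisition noise (HU) and partial-volume
#'   blur (mm).
#' @param shape,spacing grid geometry passed to [phantom_spec()].
#' @param composition `"evaluation"` (strata-balanced, default) or
#'   `"training"` (vessel-rich, as a training set for this task is).
#' @return A list with `bundles` (list of [generate_phantom()] outputs) and
#'   `manifest` (data.frame, one row per phantom).
#' @export
generate_cohort <- function(n, seed = 1L, nodule_radius_mm = c(5, 8),
                            core_radius_mm = c(2.5, 4),
                            vessel_diameter_mm = c(2, 3.5),
                            n_vessels = c(1L, 2L), noise_sigma = 20,
                            blur_sigma = 0.6, shape = c(56L, 56L, 40L),
                            spacing = c(0.7, 0.7, 1),
                            composition = c("evaluation", "training")) {
  stopifnot(n >= 1L)
  composition <- match.arg(composition)
  strata <- expand.grid(solid = c(FALSE, TRUE), vessels = c(FALSE, TRUE))
  rows <- list()
  bundles <- vector("list", n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      st <- if (composition == "training") {
        data.frame(solid = (i %% 5L) != 0L, vessels = TRUE)
      } else {
        strata[((i - 1L) %% 4L) + 1L, ]
      }
      extent <- (shape - 1L) * spacing
      center <- extent / 2
      r_xy <- runif(1L, nodule_radius_mm[1L], nodule_radius_mm[2L])
      radii <- c(r_xy, r_xy * runif(1L, 0.85, 1), r_xy * runif(1L, 0.7, 0.9))
      core <- NULL
      core_r <- NA_real_
      if (st$solid) {
        core_r <- min(runif(1L, core_radius_mm[1L], core_radius_mm[2L]),
                      0.8 * min(radii))
        core <- list(center = center, radius = core_r, hu = 50)
      }
      vessels <- list()
      nv <- 0L
      vd <- NA_real_
      if (st$vessels) {
        nv <- sample(seq(n_vessels[1L], n_vessels[2L]), 1L)
        vd <- sort(runif(nv, vessel_diameter_mm[1L], vessel_diameter_mm[2L]),
                   decreasing = TRUE)
        trunk <- sample_crossing_vessel(center, extent, vd[1L])
        vessels <- list(trunk)
        for (j in seq_len(nv - 1L)) {
          off_dir <- rnorm(3)
          off_dir[3L] <- off_dir[3L] * 0.5
          # keep the branch target away from the trunk axis
          off_dir <- off_dir - sum(off_dir * trunk$dir) * trunk$dir
          off_dir <- off_dir / sqrt(sum(off_dir^2))
          offset <- off_dir * runif(1L, 0.35, 0.55) * min(radii)
          vessels[[j + 1L]] <- sample_branch_vessel(trunk, center, offset,
                                                    max(radii), extent, vd[j + 1L])
        }
      }
      sp <- phantom_spec(shape = shape, spacing = spacing,
                         nodule = list(center = center, radii = radii,
                                       hu = -600),
                         core = core, vessels = vessels,
                         blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                         seed = seed + i)
      bundles[[i]] <- generate_phantom(sp)
      rows[[i]] <- data.frame(
        id = sprintf("phantom%03d", i),
        stratum = sprintf("%s_%s", if (st$solid) "part_solid" else "non_solid",
                          if (st$vessels) "vessels" else "no_vessels"),
        diameter_mm = 2 * max(radii),
        radius_x = radii[1L], radius_y = radii[2L], radius_z = radii[3L],
        core_radius_mm = core_r, n_vessels = nv,
        mean_vessel_diameter_mm = if (nv > 0L) mean(vd) else NA_real_,
        noise_sigma = noise_sigma, blur_sigma = blur_sigma,
        complex = FALSE, seed = seed + i,
        stringsAsFactors = FALSE)
    }
  })
  list(bundles = bundles, manifest = do.call(rbind, rows))
}

#' Apply the standard cohort exclusions to a manifest
#'
#' Screening analyses exclude nodules below a minimum diameter (small
#' nodules are very likely benign) and nodules flagged as complex (large
#' irregular lesions that may contain bubbles, outside the three-class
#' model). Returns the manifest rows that survive both filters.
#'
#' @param manifest data.frame with columns `diameter_mm` and `complex`.
#' @param min_diameter_mm exclusion threshold (default 6 mm).
#' @return The filtered manifest.
#' @export
filter_cohort <- function(manifest, min_diameter_mm = 6) {
  stopifnot(is.data.frame(manifest),
            all(c("diameter_mm", "complex") %in% names(manifest)))
  manifest[manifest$diameter_mm >= min_diameter_mm & !manifest$complex, ,
           drop = FALSE]
}

#' Sparse training annotations from a truth label map
#'
#' Emulates an expert freely annotating voxels of each class: up to
#' `per_class` voxels per class are sampled without replacement from the
#' truth, stratified over the 26-connected components of the class so that
#' structures of all sizes contribute (quota allocation as in
#' [balance_classes()]). Vessel and core annotations are depth-biased: within
#' each structure only voxels at or above the component's median interior
#' depth (Euclidean distance to the structure boundary) are eligible, the
#' way an annotator clicks towards the centre of a structure and leaves its
#' partial-volume shell alone. Ground-glass is annotated freely throughout
#' the nodule, including voxels adjacent to vessels and cores. A class
#' absent from the truth is skipped with a warning.
#'
#' @param truth a [label_volume()] of ground-truth classes.
#' @param per_class maximum annotated voxels per class.
#' @param seed RNG seed.
#' @return A sparse [label_volume()] (0 = unlabeled) with attribute
#'   `skipped` naming absent classes.
#' @export
sparse_annotations <- function(truth, per_class, seed = NULL) {
  stopifnot(inherits(truth, "ct_volume"), per_class >= 1L)
  out <- array(0L, vol_dim(truth))
  skipped <- character(0)
  d <- vol_dim(truth)
  # interior depth of the vessel/core structures: distance from each voxel
  # of the class to the class boundary
  depth <- list()
  for (cls in c(LBL_VESSEL, LBL_CORE)) {
    m <- truth$data == cls
    depth[[cls]] <- if (any(m))
      sqrt(.edt_squared(as.logical(m), d, truth$spacing)) else NULL
  }
  with_seed(seed, {
    for (cls in 1:3) {
      comps <- split_components(truth$data == cls, 26L)
      if (length(comps) == 0L) {
        warning(sprintf("class '%s' absent from truth; skipped",
                        CLASS_NAMES[cls]))
        skipped <- c(skipped, CLASS_NAMES[cls])
        next
      }
      pools <- lapply(comps, function(cp) {
        if (cls == LBL_GGO) return(cp$voxels)
        dp <- depth[[cls]][cp$voxels]
        cp$voxels[dp >= stats::median(dp)]
      })
      cap <- lengths(pools)
      total <- min(per_class, sum(cap))
      alloc <- quota_allocate(cap, total)
      for (j in seq_along(pools)) {
        vx <- pools[[j]]
        pick <- if (alloc[j] >= length(vx)) vx else sort(sample(vx, alloc[j]))
        out[pick] <- cls
      }
    }
  })
  ann <- label_volume(out, truth$spacing, truth$origin)
  attr(ann, "skipped") <- skipped
  ann
}
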