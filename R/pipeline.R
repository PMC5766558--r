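#' Pipeline configuration
#'
#' Every tunable convention of the pipeline in one place: target spacing,
#' feature scales, classifier and weight-grid settings, continuity
#' parameters, connectivity conventions (fixed: 26 for detection, 6 for
#' inside-vessel splitting) and seeds. Round-trips losslessly through JSON.
#'
#' @param target_spacing standardized voxel size (mm), default 0.5.
#' @param scales feature scales (mm).
#' @param k kNN neighbours.
#' @param grid_step weight-grid step.
#' @param a continuity cutoff ratio.
#' @param border_band_mm entering-vessel diameter band (mm).
#' @param seed default seed for stochastic steps.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(target_spacing = 0.5, scales = c(1, 2, 4),
                            k = 150L, grid_step = 0.01, a = 3,
                            border_band_mm = 2, seed = 1L) {
  structure(list(target_spacing = target_spacing, scales = scales,
                 k = as.integer(k), grid_step = grid_step, a = a,
                 border_band_mm = border_band_mm,
                 detection_connectivity = 26L, splitting_connectivity = 6L,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Segment vessels and solid core in a nodule
#'
#' Runs the full method on one scan: standardization, posterior prediction
#' (interpolated back to the source grid), initial weighted-argmax
#' segmentation, and vascular-continuity regularization. A supplied
#' `vessel_mask` (source grid) bypasses the built-in outside-vessel filter.
#'
#' @param model an `ssn_model` from [train_model()] / [load_model()].
#' @param scan source [ct_volume()] in HU.
#' @param nodule_mask nodule mask on the source grid.
#' @param vessel_mask optional binary mask of vessels outside the nodule on
#'   the source grid.
#' @param lung_roi optional search region for the built-in vessel filter
#'   (source grid); defaults to the whole volume.
#' @param a,border_band_mm continuity parameters (see [continuity_field()]).
#' @param skip_continuity if `TRUE`, stop after the initial segmentation.
#' @return A list: `labels` (final [label_volume()]), `initial`, `w_vc`
#'   (array), `posteriors` ([posterior_stack()]), `field`
#'   (`continuity_field` or `NULL`).
#' @export
segment_nodule <- function(model, scan, nodule_mask, vessel_mask = NULL,
                           lung_roi = NULL, a = 3, border_band_mm = 2,
                           skip_continuity = FALSE) {
  stopifnot(inherits(model, "ssn_model"), inherits(scan, "ct_volume"))
  std <- standardize_volume(scan, model$target_spacing, model$profile)
  mask_std <- resample_labels(as_label(nodule_mask, scan), std)
  post <- predict_posteriors(model$classifier, std, mask_std$data > 0L,
                             source = scan,
                             source_mask = nodule_mask, spec = model$spec)
  initial <- initial_segmentation(post, model$weights)
  if (skip_continuity) {
    return(list(labels = initial, initial = initial, w_vc = NULL,
                posteriors = post, field = NULL))
  }
  outer_src <- if (!is.null(vessel_mask)) {
    outer_vessel_mask(scan, nodule = nodule_mask, external = vessel_mask)
  } else {
    outer_std <- outer_vessel_mask(std, roi = lung_roi_std(lung_roi, std),
                                   nodule = mask_std$data > 0L)
    resample_labels(outer_std, scan)
  }
  field <- continuity_field(initial, outer_src, nodule_mask, a = a,
                            border_band_mm = border_band_mm)
  final <- apply_continuity(post, model$weights, field)
  list(labels = final, initial = initial, w_vc = field$w_vc,
       posteriors = post, field = field)
}

as_label <- function(mask, ref) {
  if (inherits(mask, "ct_volume"))
    label_volume(mask$data, mask$spacing, mask$origin)
  else label_volume(mask, ref$spacing, ref$origin)
}

lung_roi_std <- function(lung_roi, std) {
  if (is.null(lung_roi)) return(NULL)
  resample_labels(as_label(lung_roi, std), std)$data > 0L
}

#' Run the pipeline with provenance
#'
#' Thin wrapper over [segment_nodule()] that threads a [pipeline_config()]
#' and attaches a machine-readable provenance record (configuration, model
#' settings, package version) sufficient to reproduce the output.
#'
#' @inheritParams segment_nodule
#' @param config a [pipeline_config()].
#' @return As [segment_nodule()], plus `provenance`.
#' @export
run_pipeline <- function(model, scan, nodule_mask, vessel_mask = NULL,
                         config = pipeline_config(),
                         skip_continuity = FALSE) {
  res <- segment_nodule(model, scan, nodule_mask, vessel_mask = vessel_mask,
                        a = config$a, border_band_mm = config$border_band_mm,
                        skip_continuity = skip_continuity)
  res$provenance <- list(
    config = unclass(config),
    model = list(k = model$k, weights = as.numeric(model$weights),
                 target_spacing = model$target_spacing, seed = model$seed),
    package_version = as.character(utils::packageVersion("subsolidseg")))
  res
}
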