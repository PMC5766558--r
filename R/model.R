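#' Train the full segmentation model from annotated cases
#'
#' Runs the complete training procedure: every case is standardized
#' (isotropic resampling plus kernel normalization), features are extracted
#' at the annotated voxels, classes are balanced to the minority class with
#' per-nodule stratification, the class-weight operating point is optimized
#' by leave-one-patient-out cross-validation on the simplex lattice, and the
#' final kNN classifier is trained on the balanced set. When `k` exceeds the
#' balanced sample count it is clipped to `n - 1` with a warning (small
#' training sets).
#'
#' @param cases list of cases; each a list with `volume` ([ct_volume()]),
#'   `annotations` (sparse [label_volume()]; 0 = unlabeled), and optionally
#'   `nodule_id` and `patient_id` (default: case index; patients default to
#'   nodules).
#' @param k neighbours for the kNN classifier (default 150).
#' @param seed seed for balancing and fold assignment.
#' @param target_spacing standardized voxel size (mm).
#' @param profile [band_profile()] for kernel normalization; stored with the
#'   model so training and test standardization stay symmetric.
#' @param spec [feature_spec()].
#' @param grid_step weight-grid step (default 0.01).
#' @return An `ssn_model`: classifier, optimized weights, feature spec, band
#'   profile and standardization parameters.
#' @export
train_model <- function(cases, k = 150L, seed = 1L, target_spacing = 0.5,
                        profile = band_profile(), spec = feature_spec(),
                        grid_step = 0.01) {
  feats <- list()
  labs <- list()
  nods <- list()
  pats <- list()
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    nodule_id <- if (!is.null(cs$nodule_id)) cs$nodule_id else sprintf("n%03d", i)
    patient_id <- if (!is.null(cs$patient_id)) cs$patient_id else nodule_id
    std <- standardize_volume(cs$volume, target_spacing, profile)
    ann <- resample_labels(cs$annotations, std)
    if (!any(ann$data > 0L))
      stop(sprintf("case %d has no annotated voxels after resampling", i))
    fm <- assemble_features(std, ann$data > 0L, spec)
    feats[[i]] <- fm
    labs[[i]] <- ann$data[attr(fm, "voxel_index")]
    nods[[i]] <- rep(nodule_id, nrow(fm))
    pats[[i]] <- rep(patient_id, nrow(fm))
  }
  features <- do.call(rbind, feats)
  labels <- unlist(labs)
  nodule_id <- unlist(nods)
  patient_id <- unlist(pats)
  bal <- balance_classes(features, labels, nodule_id, seed = seed)
  bal_pat <- patient_id[bal$rows]
  kk <- as.integer(k)
  if (kk > nrow(bal$features)) {
    warning(sprintf("k = %d clipped to %d (balanced sample count - 1)",
                    kk, nrow(bal$features) - 1L))
    kk <- nrow(bal$features) - 1L
  }
  post <- cv_posteriors(bal$features, bal$labels, bal_pat, k = kk,
                        seed = seed)
  weights <- optimize_weights(post, bal$labels, grid_step)
  classifier <- train_classifier(bal$features, bal$labels, kk)
  classifier$feature_spec <- spec
  structure(list(classifier = classifier, weights = weights, spec = spec,
                 profile = profile, target_spacing = target_spacing,
                 k = kk, seed = seed),
            class = "ssn_model")
}

#' @export
print.ssn_model <- function(x, ...) {
  cat(sprintf("<ssn_model> kNN k=%d, %d training samples, weights (v=%.2f, c=%.2f, g=%.2f)\n",
              x$k, nrow(x$classifier$x), x$weights[1L], x$weights[2L],
              x$weights[3L]))
  invisible(x)
}

#' Save a trained model as a text directory
#'
#' The model directory holds the standardized training matrix and labels
#' (CSV), the feature standardization parameters, the class weights, the
#' feature spec and the band profile (JSON) — everything needed to
#' reproduce predictions, with a versioned format tag.
#'
#' @param model an `ssn_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "ssn_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cl <- model$classifier
  write.csv(data.frame(label = cl$labels, cl$x, check.names = FALSE),
            file.path(dir, "training.csv"), row.names = FALSE)
  meta <- list(
    format = "ssn_model/1",
    k = cl$k,
    center = as.list(setNames(cl$center, colnames(cl$x))),
    scale = as.list(setNames(cl$scale, colnames(cl$x))),
    weights = as.list(setNames(as.numeric(model$weights), names(model$weights))),
    feature_spec = unclass(model$spec),
    band_profile = unclass(model$profile),
    target_spacing = model$target_spacing,
    seed = model$seed)
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load a model saved by [save_model()]
#' @param dir model directory.
#' @return An `ssn_model`.
#' @export
load_model <- function(dir) {
  meta_path <- file.path(dir, "model.json")
  if (!file.exists(meta_path))
    stop(sprintf("not a model directory (missing model.json): %s", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "ssn_model/1"))
    stop(sprintf("unsupported model format '%s'", meta$format))
  tr <- read.csv(file.path(dir, "training.csv"), check.names = FALSE)
  x <- as.matrix(tr[, -1L, drop = FALSE])
  spec <- do.call(feature_spec, meta$feature_spec)
  classifier <- structure(list(
    x = x, labels = as.integer(tr$label), k = as.integer(meta$k),
    center = unlist(meta$center), scale = unlist(meta$scale),
    feature_spec = spec), class = "ssn_classifier")
  weights <- class_weights(meta$weights$vessel, meta$weights$core,
                           meta$weights$ggo)
  profile <- band_profile(meta$band_profile$band_sigmas,
                          meta$band_profile$gain_per_band,
                          meta$band_profile$residual_gain)
  structure(list(classifier = classifier, weights = weights, spec = spec,
                 profile = profile, target_spacing = meta$target_spacing,
                 k = as.integer(meta$k), seed = meta$seed),
            class = "ssn_model")
}
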