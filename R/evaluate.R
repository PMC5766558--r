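#' Detect vessels and solid cores in a label map
#'
#' A class counts as detected when the label map contains at least one
#' 26-connected component of two or more voxels of that class;
#' single-voxel components are ignored.
#'
#' @param labels a [label_volume()].
#' @param nodule_id identifier carried into the record.
#' @param min_voxels detection size threshold (default 2).
#' @return A one-row data.frame: per class, `present` and `n_components`.
#' @export
detect_classes <- function(labels, nodule_id = NA_character_,
                           min_voxels = 2L) {
  stopifnot(inherits(labels, "ct_volume"))
  res <- lapply(1:3, function(cls) {
    comps <- split_components(labels$data == cls, 26L)
    sizes <- vapply(comps, function(cp) length(cp$voxels), integer(1L))
    n <- sum(sizes >= min_voxels)
    data.frame(n_components = n, present = n >= 1L)
  })
  data.frame(nodule_id = nodule_id,
             vessel_present = res[[1L]]$present,
             core_present = res[[2L]]$present,
             ggo_present = res[[3L]]$present,
             vessel_components = res[[1L]]$n_components,
             core_components = res[[2L]]$n_components,
             ggo_components = res[[3L]]$n_components,
             stringsAsFactors = FALSE)
}

#' Agreement metrics for a 2x2 detection table
#'
#' Accuracy, sensitivity, specificity, precision, and Cohen's kappa with a
#' 95% confidence interval from the asymptotic standard error
#' `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))` with a normal approximation.
#'
#' @param tp,fp,fn,tn cell counts; the reference rater defines positives
#'   (fp = predicted positive, reference negative).
#' @return A list of metrics; `kappa_ci` is the 95% interval.
#' @export
agreement_metrics <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  if (n == 0L) stop("empty agreement table")
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) 1 else (po - pe) / (1 - pe)
  se <- if (abs(1 - pe) < 1e-12) 0 else sqrt(po * (1 - po) / (n * (1 - pe)^2))
  list(kappa = kappa,
       kappa_ci = c(kappa - 1.96 * se, kappa + 1.96 * se),
       accuracy = po,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Pairwise detection agreement between two raters
#'
#' Builds the per-class 2x2 table from matched detection records (rater `a`
#' is the reference for sensitivity/specificity/precision) and computes
#' [agreement_metrics()] per class.
#'
#' @param a,b data.frames from [detect_classes()], one row per nodule, same
#'   nodule set.
#' @param classes which classes to report (default vessel and core, the two
#'   detection endpoints).
#' @return A data.frame, one row per class.
#' @export
pairwise_agreement <- function(a, b, classes = c("vessel", "core")) {
  if (!identical(sort(a$nodule_id), sort(b$nodule_id)))
    stop("detection records cover different nodule sets")
  b <- b[match(a$nodule_id, b$nodule_id), ]
  rows <- lapply(classes, function(cls) {
    col <- paste0(cls, "_present")
    ref <- a[[col]]
    prd <- b[[col]]
    m <- agreement_metrics(tp = sum(prd & ref), fp = sum(prd & !ref),
                           fn = sum(!prd & ref), tn = sum(!prd & !ref))
    data.frame(class = cls, kappa = m$kappa, kappa_lo = m$kappa_ci[1L],
               kappa_hi = m$kappa_ci[2L], accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               precision = m$precision, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Voxel-overlap scores between a predicted and a reference label map
#'
#' Per class: sensitivity `|pred & ref| / |ref|`, precision
#' `|pred & ref| / |pred|`, Dice `2 |pred & ref| / (|pred| + |ref|)`. When
#' exactly one of the two maps contains the class (presence disagreement)
#' all three scores are 0; when neither does, the row is flagged
#' unscoreable (`scoreable = FALSE`, scores `NA`) so aggregates can exclude
#' it. With `slice` given, scoring is restricted to that axial plane.
#'
#' @param pred,ref aligned [label_volume()]s.
#' @param slice optional axial (third-axis) index.
#' @param nodule_id identifier carried into the rows.
#' @return A data.frame, one row per class.
#' @export
voxel_scores <- function(pred, ref, slice = NULL, nodule_id = NA_character_) {
  stop_if_misaligned(pred, ref, "pred/ref label maps")
  p <- pred$data
  r <- ref$data
  if (!is.null(slice)) {
    p <- p[, , slice, drop = FALSE]
    r <- r[, , slice, drop = FALSE]
  }
  rows <- lapply(1:3, function(cls) {
    np <- sum(p == cls)
    nr <- sum(r == cls)
    if (np == 0L && nr == 0L)
      return(data.frame(nodule_id = nodule_id, class = CLASS_NAMES[cls],
                        sensitivity = NA_real_, precision = NA_real_,
                        dsc = NA_real_, scoreable = FALSE,
                        presence_agreement = TRUE, stringsAsFactors = FALSE))
    if (np == 0L || nr == 0L)
      return(data.frame(nodule_id = nodule_id, class = CLASS_NAMES[cls],
                        sensitivity = 0, precision = 0, dsc = 0,
                        scoreable = TRUE, presence_agreement = FALSE,
                        stringsAsFactors = FALSE))
    ov <- sum(p == cls & r == cls)
    data.frame(nodule_id = nodule_id, class = CLASS_NAMES[cls],
               sensitivity = ov / nr, precision = ov / np,
               dsc = 2 * ov / (np + nr), scoreable = TRUE,
               presence_agreement = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Consensus label map by intersection
#'
#' Voxels labelled the same class by both raters keep that class; nodule
#' voxels with no agreed class fall back to ground-glass.
#'
#' @param a,b aligned [label_volume()]s.
#' @param nodule nodule mask (defaults to the union of labelled voxels).
#' @return A [label_volume()].
#' @export
consensus_intersection <- function(a, b, nodule = NULL) {
  stop_if_misaligned(a, b, "label maps")
  nod <- if (is.null(nodule)) (a$data > 0L | b$data > 0L)
         else as_logical_mask(nodule)
  out <- array(0L, vol_dim(a))
  out[nod] <- LBL_GGO
  agree <- a$data == b$data & a$data > 0L & nod
  out[agree] <- a$data[agree]
  label_volume(out, a$spacing, a$origin)
}

#' Axial slice with the largest nodule cross-section
#'
#' @param nodule a nodule mask ([label_volume()] or logical array).
#' @return 1-based axial (third-axis) index; ties go to the smallest index.
#' @export
largest_area_slice <- function(nodule) {
  m <- as_logical_mask(nodule)
  if (!any(m)) stop("empty nodule mask")
  areas <- apply(m, 3L, sum)
  which.max(areas)
}

#' Stratified summary of voxel scores
#'
#' Means and sample standard deviations (n - 1) per class and metric,
#' computed twice: over all scoreable rows, and over the stratum of rows
#' with agreement on the presence of the class. Empty cells are reported as
#' `NA` with `n = 0`, never as zero.
#'
#' @param rows data.frame of [voxel_scores()] rows.
#' @return A data.frame: class, stratum, metric, n, mean, sd.
#' @export
stratified_summary <- function(rows) {
  metrics <- c("sensitivity", "precision", "dsc")
  out <- list()
  for (cls in unique(rows$class)) {
    for (stratum in c("all", "presence_agreement")) {
      sel <- rows$class == cls & rows$scoreable
      if (stratum == "presence_agreement") sel <- sel & rows$presence_agreement
      for (met in metrics) {
        v <- rows[[met]][sel]
        out[[length(out) + 1L]] <- data.frame(
          class = cls, stratum = stratum, metric = met, n = length(v),
          mean = if (length(v)) mean(v) else NA_real_,
          sd = if (length(v) > 1L) sd(v) else if (length(v)) 0 else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
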