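#' CT volume container
#'
#' A minimal 3D scalar grid with physical metadata: a column-major array of
#' values (Hounsfield Units for CT images, integer codes for label maps),
#' per-axis voxel spacing in mm, and the physical position of the first voxel
#' centre in mm.
#'
#' @param data 3D array of finite values.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, physical coordinates (mm) of voxel
#'   `(1, 1, 1)`.
#' @return An object of class `ct_volume`.
#' @examples
#' v <- ct_volume(array(-900, c(4, 4, 4)), spacing = c(0.7, 0.7, 1))
#' v$spacing
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  if (any(!is.finite(data)))
    stop("volume data contains non-finite values")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' Label map aligned to a CT grid
#'
#' Same container as [ct_volume()] but with integer-coded data. Legend:
#' 0 background, 1 vessel, 2 solid core, 3 ground-glass.
#'
#' @inheritParams ct_volume
#' @return A `label_volume` (also a `ct_volume`).
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "integer"
  v <- ct_volume(data, spacing, origin)
  class(v) <- c("label_volume", class(v))
  v
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1L], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  if (inherits(x, "label_volume")) {
    tab <- table(factor(x$data, levels = 0:3,
                        labels = c("background", CLASS_NAMES)))
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  } else {
    cat(sprintf("  range [%.1f, %.1f]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

vol_dim <- function(vol) dim(vol$data)

#' Check two volumes share a grid
#' @param a,b `ct_volume` objects.
#' @param tol metadata tolerance (mm).
#' @return `TRUE` or `FALSE`.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(vol_dim(a), vol_dim(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_misaligned <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on the same grid (dims %s vs %s)", what,
                 paste(vol_dim(a), collapse = "x"),
                 paste(vol_dim(b), collapse = "x")))
  invisible(TRUE)
}

assert_isotropic <- function(vol, tol = 1e-6) {
  if (diff(range(vol$spacing)) > tol)
    stop("volume must be isotropic; resample with resample_isotropic() first",
         call. = FALSE)
  invisible(vol$spacing[1L])
}

as_logical_mask <- function(x) {
  if (inherits(x, "ct_volume")) x <- x$data
  storage.mode(x) <- "logical"
  x
}
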