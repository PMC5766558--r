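#' Read a CT volume or label map
#'
#' Supports NIfTI (`.nii`, `.nii.gz`; via the RNifti package) and
#' uncompressed MetaImage (`.mha`, or `.mhd` with a sidecar `.raw`).
#' Spacing and origin metadata are preserved through a read-write-read
#' round trip.
#'
#' @param path file path.
#' @param labels logical; if `TRUE` return a [label_volume()] (values rounded
#'   to integer).
#' @return A [ct_volume()] (or [label_volume()]).
#' @export
read_volume <- function(path, labels = FALSE) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  ext <- tolower(sub(".*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  vol <- if (ext %in% c(".nii", ".nii.gz")) {
    read_nifti_volume(path)
  } else if (ext %in% c(".mha", ".mhd")) {
    read_metaimage(path)
  } else {
    stop(sprintf("unsupported volume format '%s' for %s", ext, path))
  }
  if (labels) label_volume(round(vol$data), vol$spacing, vol$origin) else vol
}

#' Write a CT volume or label map
#'
#' @param vol a [ct_volume()].
#' @param path output path; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.mha`, `.mhd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  ext <- tolower(sub(".*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    write_nifti_volume(vol, path)
  } else if (ext %in% c(".mha", ".mhd")) {
    write_metaimage(vol, path)
  } else {
    stop(sprintf("unsupported volume format '%s' for %s", ext, path))
  }
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop(sprintf("expected a 3D image in %s, got %dD", path, length(dim(arr))))
  ct_volume(arr, spacing = RNifti::pixdim(img)[1:3], origin = xf[1:3, 4])
}

write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  xf <- diag(c(vol$spacing, 1))
  xf[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
}

# --- MetaImage ---------------------------------------------------------------
# Minimal MetaImage support: 3D, uncompressed, little-endian,
# MET_UCHAR/MET_SHORT/MET_USHORT/MET_INT/MET_FLOAT/MET_DOUBLE.

met_types <- data.frame(
  name = c("MET_UCHAR", "MET_CHAR", "MET_SHORT", "MET_USHORT", "MET_INT",
           "MET_FLOAT", "MET_DOUBLE"),
  what = c("integer", "integer", "integer", "integer", "integer",
           "double", "double"),
  size = c(1L, 1L, 2L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop(sprintf("corrupt MetaImage header (no ElementDataFile): %s", path))
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1L]]
    if (length(kv) != 3L)
      stop(sprintf("corrupt MetaImage header line in %s: '%s'", path, line))
    hdr[[kv[2L]]] <- trimws(kv[3L])
    if (kv[2L] == "ElementDataFile") break
  }
  if (identical(hdr$CompressedData, "True"))
    stop(sprintf("compressed MetaImage not supported: %s", path))
  if (identical(hdr$BinaryDataByteOrderMSB, "True"))
    stop(sprintf("big-endian MetaImage not supported: %s", path))
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1L]])
  if (length(dims) != 3L)
    stop(sprintf("expected 3D MetaImage in %s", path))
  tp <- met_types[met_types$name == hdr$ElementType, ]
  if (nrow(tp) != 1L)
    stop(sprintf("unsupported ElementType '%s' in %s", hdr$ElementType, path))
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw_data <- readBin(con, tp$what, n = n, size = tp$size,
                        signed = tp$signed, endian = "little")
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path))
      stop(sprintf("MetaImage data file not found: %s", raw_path))
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    raw_data <- readBin(rcon, tp$what, n = n, size = tp$size,
                        signed = tp$signed, endian = "little")
  }
  if (length(raw_data) != n)
    stop(sprintf("truncated MetaImage data in %s", path))
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1L]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1L]]) else c(0, 0, 0)
  ct_volume(array(as.numeric(raw_data), dim = dims), spacing, origin)
}

write_metaimage <- function(vol, path) {
  is_mhd <- grepl("\\.mhd$", path, ignore.case = TRUE)
  int_ok <- inherits(vol, "label_volume") ||
    (all(vol$data == round(vol$data)) && max(abs(vol$data)) < 32767)
  etype <- if (int_ok) "MET_SHORT" else "MET_FLOAT"
  data_file <- if (is_mhd) sub("\\.mhd$", ".raw", basename(path),
                               ignore.case = TRUE) else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %s", paste(format(vol$origin, trim = TRUE), collapse = " ")),
    sprintf("ElementSpacing = %s",
            paste(format(vol$spacing, trim = TRUE), collapse = " ")),
    sprintf("DimSize = %s", paste(dim(vol$data), collapse = " ")),
    sprintf("ElementType = %s", etype),
    sprintf("ElementDataFile = %s", data_file)
  )
  write_payload <- function(con) {
    if (etype == "MET_SHORT")
      writeBin(as.integer(vol$data), con, size = 2L, endian = "little")
    else
      writeBin(as.numeric(vol$data), con, size = 4L, endian = "little")
  }
  if (is_mhd) {
    writeLines(hdr, path)
    rcon <- file(file.path(dirname(path), data_file), "wb")
    on.exit(close(rcon))
    write_payload(rcon)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    write_payload(con)
  }
  invisible(path)
}
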