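#' Voxel volume containers
#'
#' A `vox_volume` wraps a 3D array with its isotropic voxel size in
#' micrometers. Subclasses mark the interpretation of voxel values:
#' `gray_volume` (intensity), `binary_volume` (logical foreground),
#' `label_volume` (non-negative integer tile ids, 0 = background/gap) and
#' `distance_volume` (micrometers; signed or unsigned).
#'
#' The voxel convention used throughout the package is 0-based indices with
#' world coordinate `(index + 0.5) * voxel_size(x)` at voxel centers.
#'
#' @param data 3D array (logical for binary, integer for labels).
#' @param voxel voxel edge length in micrometers (isotropic, > 0).
#' @param signed for distance volumes, whether values are signed
#'   (negative inside the foreground).
#' @return An object of class `vox_volume` (with the subclass named above).
#' @name vox-volumes
NULL

new_vox_volume <- function(data, voxel, subclass, extra = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!is.numeric(voxel) || length(voxel) != 1 || voxel <= 0)
    stop("`voxel` must be a single positive length in micrometers",
         call. = FALSE)
  structure(c(list(data = data, voxel = as.numeric(voxel)), extra),
            class = c(subclass, "vox_volume"))
}

#' @rdname vox-volumes
#' @export
gray_volume <- function(data, voxel) {
  storage.mode(data) <- "double"
  new_vox_volume(data, voxel, "gray_volume")
}

#' @rdname vox-volumes
#' @export
binary_volume <- function(data, voxel) {
  storage.mode(data) <- "logical"
  new_vox_volume(data, voxel, "binary_volume")
}

#' @rdname vox-volumes
#' @export
label_volume <- function(data, voxel) {
  storage.mode(data) <- "integer"
  if (any(data < 0, na.rm = TRUE))
    stop("label values must be non-negative (0 = background)", call. = FALSE)
  new_vox_volume(data, voxel, "label_volume",
                 extra = list(log = empty_edit_log()))
}

#' @rdname vox-volumes
#' @export
distance_volume <- function(data, voxel, signed = FALSE) {
  storage.mode(data) <- "double"
  new_vox_volume(data, voxel, "distance_volume",
                 extra = list(signed = isTRUE(signed)))
}

empty_edit_log <- function() {
  tibble::tibble(op = character(), a = integer(), b = integer(),
                 detail = character())
}

#' @export
dim.vox_volume <- function(x) dim(x$data)

#' Voxel size of a volume (micrometers)
#' @param x a `vox_volume`.
#' @export
voxel_size <- function(x) UseMethod("voxel_size")

#' @export
voxel_size.vox_volume <- function(x) x$voxel

#' @export
print.vox_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<%s> %d x %d x %d voxels, %.3g um/voxel\n",
              class(x)[1], d[1], d[2], d[3], x$voxel))
  if (inherits(x, "label_volume")) {
    cat(sprintf("  labels: %d (max id %d)\n",
                length(setdiff(unique(as.vector(x$data)), 0L)),
                max(x$data)))
  }
  invisible(x)
}

#' Voxel-center world coordinates (micrometers)
#'
#' Converts 1-based array indices to world coordinates under the package
#' voxel convention: world = (index0 + 0.5) * voxel.
#'
#' @param idx matrix of 1-based (i, j, k) indices.
#' @param voxel voxel size in micrometers.
#' @export
voxel_to_world <- function(idx, voxel) {
  (as.matrix(idx) - 1 + 0.5) * voxel
}

#' Write / read a volume as a multi-page TIFF stack
#'
#' Grayscale values are stored as 32-bit floats; labels are stored as floats
#' too (lossless for ids below 2^24). The voxel size (micrometers) is kept
#' in the TIFF description tag.
#'
#' @param vol a `vox_volume`.
#' @param path file path ending in `.tif`/`.tiff`.
#' @export
write_volume_tiff <- function(vol, path) {
  d <- dim(vol)
  slices <- lapply(seq_len(d[3]), function(k) {
    m <- vol$data[, , k]
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(slices, path, bits.per.sample = 32L, reduce = FALSE,
                  description = sprintf("voxel_um=%.9g", vol$voxel))
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param kind one of "gray", "binary", "label", "distance".
#' @param voxel voxel size override; if `NULL` it is parsed from the TIFF
#'   description tag.
#' @export
read_volume_tiff <- function(path, kind = "gray", voxel = NULL) {
  slices <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (!is.list(slices)) slices <- list(slices)
  if (is.null(voxel)) {
    desc <- attr(slices[[1]], "description")
    if (!is.null(desc) && grepl("voxel_um=", desc))
      voxel <- as.numeric(sub(".*voxel_um=([0-9.eE+-]+).*", "\\1", desc))
    if (is.null(voxel) || is.na(voxel))
      stop("voxel size not found in TIFF metadata; pass `voxel`",
           call. = FALSE)
  }
  arr <- array(0, c(dim(slices[[1]])[1:2], length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
  switch(kind,
         gray = gray_volume(arr, voxel),
         binary = binary_volume(arr > 0.5, voxel),
         label = label_volume(array(as.integer(round(arr)), dim(arr)), voxel),
         distance = distance_volume(arr, voxel),
         stop("unknown kind: ", kind, call. = FALSE))
}
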