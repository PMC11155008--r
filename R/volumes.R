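#' Image volumes and binary masks
#'
#' `image_volume()` wraps a 3D numeric array together with its voxel spacing
#' and physical origin (both in mm); `binary_mask()` is the same container
#' restricted to values in \{0, 1\}, used for the tumor region (GTV).
#' Arrays use R's native (x, y, z) axis order and 1-based voxel indices,
#' matching how \pkg{RNifti} presents NIfTI data.
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param origin Numeric length-3, position of the first voxel in mm.
#' @return An object of class `image_volume` (and additionally
#'   `binary_mask` for masks): a list with elements `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- image_volume(array(0, c(8, 8, 8)), spacing = c(1, 1, 1))
#' dim(v$data)
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (any(!is.finite(data))) stop("`data` must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive values (mm)", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin)),
    class = "image_volume"
  )
}

#' @rdname image_volume
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!all(data %in% c(0, 1))) {
    stop("mask `data` must contain only 0 and 1", call. = FALSE)
  }
  v <- image_volume(data, spacing, origin)
  class(v) <- c("binary_mask", class(v))
  v
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf(
    "<%s> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
    class(x)[1L], paste(dim(x$data), collapse = "x"),
    paste(format(x$spacing, trim = TRUE), collapse = "x"),
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} that carry voxel spacing through the
#' NIfTI header (`pixdim`). `read_volume()` returns an [image_volume()];
#' `read_mask()` additionally binarizes at 0.5 and returns a
#' [binary_mask()].
#'
#' @param vol An [image_volume()] or [binary_mask()].
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @return `write_volume()` returns `path` invisibly; the readers return
#'   the corresponding container.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing = spacing)
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask((v$data >= 0.5) + 0, spacing = v$spacing, origin = v$origin)
}
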