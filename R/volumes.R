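# Lightweight containers for 4D BOLD data and 3D maps/masks. All grids are
# voxel-indexed 1-based in R; world (mm) coordinates use 0-based indices times
# voxel size unless an affine is attached (NIfTI I/O honours the affine).

#' Construct a BOLD time series object
#'
#' Bundles a 4D array (x, y, z, t) with its voxel spacing and repetition
#' time. Values must be finite and at least three frames are required for
#' any autoregressive analysis downstream.
#'
#' @param data 4D numeric array, dimensions (x, y, z, t).
#' @param voxel_size numeric length-3, voxel edge lengths in mm (all > 0).
#' @param tr repetition time in seconds (> 0).
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, voxel_size = c(3, 3, 3), tr = 2) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 3L)
    stop("a BOLD series needs at least 3 frames")
  if (!all(is.finite(data)))
    stop("BOLD data contain non-finite values")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive mm values")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("`tr` must be a positive scalar (seconds)")
  structure(list(data = data, voxel_size = voxel_size, tr = tr,
                 frame_count = dim(data)[4]),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %d x %d x %d voxels, %d frames, TR %.3g s, voxel %s mm\n",
              d[1], d[2], d[3], d[4], x$tr,
              paste(format(x$voxel_size), collapse = " x ")))
  invisible(x)
}

#' Construct a spatial map
#'
#' A 3D scalar grid (e.g. a z-scored ICA component, a network template, or a
#' Granger-causality z-map) aligned to a BOLD or anatomical grid.
#'
#' @param values 3D numeric array.
#' @param voxel_size numeric length-3 voxel spacing in mm.
#' @return An object of class `spatial_map`.
#' @export
spatial_map <- function(values, voxel_size = c(3, 3, 3)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  structure(list(values = values, voxel_size = as.numeric(voxel_size)),
            class = "spatial_map")
}

#' Construct a voxel mask
#'
#' @param values 3D logical array (or numeric, nonzero treated as TRUE).
#' @param label optional region label, e.g. "lMFG", "rAI_sphere", "brain",
#'   "WM", "CSF".
#' @param voxel_size numeric length-3 voxel spacing in mm.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(values, label = NULL, voxel_size = c(3, 3, 3)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  v <- array(as.logical(values != 0), dim = dim(values))
  structure(list(values = v, label = label, voxel_size = as.numeric(voxel_size)),
            class = "voxel_mask")
}

# Accept either a container or a bare array; return the array.
.map_values <- function(x) {
  if (inherits(x, c("spatial_map", "voxel_mask"))) x$values else x
}
.mask_values <- function(x) {
  v <- .map_values(x)
  array(as.logical(v != 0), dim = dim(v))
}

#' Spherical region-of-interest mask
#'
#' Marks every voxel whose centre lies within `radius_mm` of a centre point,
#' e.g. the 6 mm right-anterior-insula seed sphere.
#'
#' @param dim3 integer length-3 grid dimensions.
#' @param center_vox numeric length-3 centre in 1-based voxel indices.
#' @param radius_mm sphere radius in mm.
#' @param voxel_size voxel spacing in mm.
#' @param label optional region label.
#' @return A `voxel_mask`.
#' @export
sphere_mask <- function(dim3, center_vox, radius_mm = 6,
                        voxel_size = c(3, 3, 3), label = "rAI_sphere") {
  stopifnot(length(dim3) == 3L, length(center_vox) == 3L, radius_mm > 0)
  ix <- (seq_len(dim3[1]) - center_vox[1]) * voxel_size[1]
  iy <- (seq_len(dim3[2]) - center_vox[2]) * voxel_size[2]
  iz <- (seq_len(dim3[3]) - center_vox[3]) * voxel_size[3]
  d2 <- outer(outer(ix^2, iy^2, "+"), iz^2, "+")
  voxel_mask(d2 <= radius_mm^2, label = label, voxel_size = voxel_size)
}

#' Read a NIfTI volume as a spatial map or mask
#'
#' @param path path to a NIfTI file.
#' @param as one of "map", "mask" or "bold".
#' @param tr repetition time override in seconds for `as = "bold"`; if `NULL`
#'   the NIfTI header pixdim is used.
#' @return A `spatial_map`, `voxel_mask` or `bold_series`.
#' @export
read_volume <- function(path, as = c("map", "mask", "bold"), tr = NULL) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)
  arr <- as.array(img)
  arr[!is.finite(arr)] <- 0
  if (as == "bold") {
    if (is.null(tr)) tr <- if (length(pix) >= 4 && pix[4] > 0) pix[4] else 2
    out <- bold_series(arr, voxel_size = pix[1:3], tr = tr)
  } else if (as == "mask") {
    out <- voxel_mask(arr, voxel_size = pix[1:3])
  } else {
    out <- spatial_map(arr, voxel_size = pix[1:3])
  }
  attr(out, "affine") <- structure(RNifti::xform(img), code = NULL)
  out
}

#' Write a volume container to NIfTI
#'
#' @param x a `bold_series`, `spatial_map`, `voxel_mask`, or bare array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size voxel spacing used when `x` is a bare array.
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path, voxel_size = c(3, 3, 3)) {
  if (inherits(x, "bold_series")) {
    arr <- x$data; vs <- x$voxel_size; tdim <- x$tr
  } else if (inherits(x, c("spatial_map", "voxel_mask"))) {
    arr <- x$values * 1; vs <- x$voxel_size; tdim <- 1
  } else {
    arr <- x * 1; vs <- voxel_size; tdim <- 1
  }
  img <- RNifti::asNifti(arr)
  pd <- c(vs, tdim)[seq_along(dim(arr))]
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert a voxel index to world mm coordinates
#'
#' Indices are reported 0-based in world space (mm = (index - 1) * voxel
#' size), matching the package's plan exports.
#'
#' @param voxel_index 1-based integer triple.
#' @param voxel_size mm spacing triple.
#' @return numeric length-3 mm coordinates.
#' @export
voxel_to_mm <- function(voxel_index, voxel_size) {
  (as.numeric(voxel_index) - 1) * as.numeric(voxel_size)
}
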