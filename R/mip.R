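#' Maximum-intensity projection along one anatomical axis
#'
#' Per-pixel maximum over the slab of slices `[center - d, center + d]`
#' (clipped to the volume bounds) along the chosen axis. Under the package's
#' `(z, y, x)` voxel order, axis `"z"` gives the axial view (a y-x image),
#' `"y"` the coronal view (z-x), and `"x"` the sagittal view (z-y).
#'
#' @param vol a `normalized_volume` (or any list with a 3D `voxels` array).
#' @param axis `"z"`, `"y"`, or `"x"`.
#' @param center_index slice index along `axis`, 1-based.
#' @param slab_half_depth slices included on each side (>= 0).
#' @return 2D matrix: the projection.
#' @export
mip_project <- function(vol, axis = c("z", "y", "x"), center_index,
                        slab_half_depth = 0L) {
  axis <- match.arg(axis)
  vox <- if (is.list(vol)) vol$voxels else vol
  d <- dim(vox)
  ax <- match(axis, c("z", "y", "x"))
  center_index <- as.integer(center_index)
  if (center_index < 1L || center_index > d[ax])
    stop("center_index outside axis bounds")
  if (slab_half_depth < 0L) stop("slab_half_depth must be >= 0")
  lo <- max(1L, center_index - as.integer(slab_half_depth))
  hi <- min(d[ax], center_index + as.integer(slab_half_depth))
  slab <- switch(axis,
    z = vox[lo:hi, , , drop = FALSE],
    y = vox[, lo:hi, , drop = FALSE],
    x = vox[, , lo:hi, drop = FALSE])
  apply(slab, setdiff(1:3, ax), max)
}

#' Tri-planar maximum-intensity projection around a nodule
#'
#' The three [mip_project()] views centred on a voxel: axial (`z`), coronal
#' (`y`), sagittal (`x`). Spiculation perpendicular to any single projection
#' plane stays visible in at least one of the other two.
#'
#' @param vol a `normalized_volume`.
#' @param center voxel index `(z, y, x)`, 1-based, inside the volume.
#' @param slab_half_depth slices per side; defaults should cover the nodule
#'   radius.
#' @return A `mip_triplet`: list with `axial`, `coronal`, `sagittal`
#'   matrices plus the `center` and `slab_half_depth` used.
#' @export
triplanar_mip <- function(vol, center, slab_half_depth) {
  vox <- if (is.list(vol)) vol$voxels else vol
  d <- dim(vox)
  center <- as.integer(center)
  if (length(center) != 3L || any(center < 1L) || any(center > d))
    stop("center must lie inside the volume")
  structure(list(
    axial    = mip_project(vol, "z", center[1], slab_half_depth),
    coronal  = mip_project(vol, "y", center[2], slab_half_depth),
    sagittal = mip_project(vol, "x", center[3], slab_half_depth),
    center = center, slab_half_depth = as.integer(slab_half_depth)),
    class = "mip_triplet")
}
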