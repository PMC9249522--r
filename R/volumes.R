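#' Construct a CT volume
#'
#' A `ct_volume` holds a 3D scalar field of Hounsfield units with axis order
#' `(z, y, x)`: the first array index walks axial slices, the second image
#' rows (y), the third image columns (x).
#'
#' @param voxels 3D numeric array of HU values, axis order (z, y, x).
#' @param spacing numeric length-3 vector `(dz, dy, dx)` in mm.
#' @param origin free-text provenance label (file path, "phantom", ...).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = "unknown") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array (z, y, x)")
  if (any(dim(voxels) < 1L))
    stop("all three volume dimensions must be >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers (dz, dy, dx)")
  if (any(!is.finite(voxels)))
    stop("HU voxel values must all be finite")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.character(origin)[1]),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume %d x %d x %d (z,y,x), spacing %s mm, HU range [%g, %g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Read a CT volume from disk
#'
#' Supports NIfTI files (`.nii` / `.nii.gz`) and directories of equally sized
#' 2D TIFF or PNG slices whose lexicographic file order is the z (axial)
#' order. NIfTI voxel data arrive in (x, y, z) order and are transposed to
#' the package's (z, y, x) convention.
#'
#' @param path file (NIfTI) or directory (slice stack).
#' @param format `"nifti"` or `"slice_stack"`; `"auto"` picks by path type.
#' @param spacing optional spacing override `(dz, dy, dx)` in mm.
#' @return A [ct_volume()].
#' @export
load_volume <- function(path, format = c("auto", "nifti", "slice_stack"),
                        spacing = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "auto")
    format <- if (dir.exists(path)) "slice_stack" else "nifti"
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
      arr <- array(arr, dim(arr)[1:3])
    if (length(dim(arr)) != 3L)
      stop("not a 3D NIfTI volume: ", path)
    pix <- tryCatch(RNifti::pixdim(img), error = function(e) c(1, 1, 1))
    if (length(pix) < 3) pix <- c(pix, rep(1, 3 - length(pix)))
    # NIfTI (x,y,z) -> package (z,y,x)
    vox <- aperm(arr, c(3, 2, 1))
    sp <- if (is.null(spacing)) rev(pix[1:3]) else spacing
    ct_volume(vox, spacing = sp, origin = path)
  } else {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 1L) stop("no TIFF/PNG slices found in ", path)
    slices <- lapply(files, read_slice_2d)
    shp <- dim(slices[[1]])
    for (i in seq_along(slices)) {
      if (!identical(dim(slices[[i]]), shp))
        stop(sprintf("slice shape mismatch: '%s' is %s, expected %s",
                     basename(files[i]), paste(dim(slices[[i]]), collapse = "x"),
                     paste(shp, collapse = "x")))
    }
    vox <- array(0, dim = c(length(slices), shp[1], shp[2]))
    for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]
    sp <- if (is.null(spacing)) c(1, 1, 1) else spacing
    ct_volume(vox, spacing = sp, origin = path)
  }
}

read_slice_2d <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(f, as.is = TRUE)
         else png::readPNG(f)
  if (length(dim(img)) == 3L) img <- img[, , 1]   # drop colour channels
  if (length(dim(img)) != 2L) stop("unreadable 2D slice: ", f)
  img
}

#' Write a volume as NIfTI
#'
#' Inverse of [load_volume()]'s NIfTI branch: (z,y,x) voxels are written in
#' (x,y,z) order so a save-then-load round trip is voxel-identical.
#'
#' @param vol a [ct_volume()] or [normalized_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  vox <- vol$voxels
  sp <- if (!is.null(vol$spacing)) vol$spacing else c(1, 1, 1)
  img <- RNifti::asNifti(aperm(vox, c(3, 2, 1)))
  RNifti::pixdim(img) <- rev(sp)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Hounsfield windowing configuration
#'
#' An explicit `[lo, hi]` HU interval mapped affinely to `[0, 1]` with
#' clamping. The default is a standard lung window of width 1600 HU centred
#' at -550 HU.
#'
#' @param lo lower HU bound. @param hi upper HU bound (`lo < hi`).
#' @return An object of class `window_config`.
#' @export
window_config <- function(lo = -1350, hi = 250) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("window bounds must satisfy lo < hi")
  structure(list(lo = lo, hi = hi), class = "window_config")
}

#' Window and normalize a CT volume
#'
#' Maps HU value `v` to `clamp((v - lo)/(hi - lo), 0, 1)` and resamples each
#' axial slice to `out_size` by bilinear interpolation. The map is monotone
#' non-decreasing in HU.
#'
#' @param vol a [ct_volume()].
#' @param window a [window_config()].
#' @param out_size target `(H, W)` of each axial slice, or `NULL` to keep
#'   the native in-plane size.
#' @return A `normalized_volume`: voxels in `[0, 1]`, plus the window and
#'   spacing used.
#' @export
window_normalize <- function(vol, window = window_config(), out_size = NULL) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!inherits(window, "window_config")) window <- do.call(window_config, window)
  v <- (vol$voxels - window$lo) / (window$hi - window$lo)
  v[v < 0] <- 0; v[v > 1] <- 1
  d <- dim(v)
  if (!is.null(out_size)) {
    out_size <- as.integer(out_size)
    if (length(out_size) != 2L || any(out_size < 8L))
      stop("out_size must be (H, W) with both >= 8")
    if (!identical(out_size, as.integer(d[2:3]))) {
      out <- array(0, dim = c(d[1], out_size[1], out_size[2]))
      for (k in seq_len(d[1]))
        out[k, , ] <- resize_bilinear(v[k, , ], out_size[1], out_size[2])
      v <- out
    }
  }
  normalized_volume(v, window = window, spacing = vol$spacing,
                    origin = vol$origin)
}

#' Construct a normalized volume
#'
#' Container for voxels already scaled to `[0, 1]`.
#'
#' @param voxels 3D array in `[0,1]`, axis order (z, y, x).
#' @param window the [window_config()] that produced it (or `NULL`).
#' @param spacing voxel spacing `(dz, dy, dx)` in mm.
#' @param origin provenance label.
#' @param offset voxel offset `(z, y, x)` of this (sub)volume's first voxel
#'   inside its parent volume, 1-based; `c(1,1,1)` for a full volume.
#' @return An object of class `normalized_volume`.
#' @export
normalized_volume <- function(voxels, window = NULL, spacing = c(1, 1, 1),
                              origin = "unknown", offset = c(1L, 1L, 1L)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array (z, y, x)")
  if (any(!is.finite(voxels)) || min(voxels) < 0 || max(voxels) > 1)
    stop("normalized voxels must lie in [0, 1]")
  structure(list(voxels = voxels, window = window,
                 spacing = as.numeric(spacing), origin = origin,
                 offset = as.integer(offset)),
            class = "normalized_volume")
}

#' @export
print.normalized_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("normalized_volume %d x %d x %d (z,y,x), range [%.3f, %.3f]\n",
              d[1], d[2], d[3], min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Extract a nodule-centred region of interest
#'
#' Crops the axis-aligned box `center +/- half_extent`, clipped to the volume
#' bounds (no padding). The crop offset is recorded so ROI coordinates can be
#' mapped back with [roi_to_parent()].
#'
#' @param vol a `normalized_volume`.
#' @param center voxel index `(z, y, x)`, 1-based; must lie inside `vol`.
#' @param half_extent `(rz, ry, rx)` half sizes in voxels (>= 0).
#' @return A `normalized_volume` with `offset` recording the crop position.
#' @export
extract_roi <- function(vol, center, half_extent) {
  stopifnot(inherits(vol, "normalized_volume"))
  d <- dim(vol$voxels)
  center <- as.integer(center); half_extent <- as.integer(half_extent)
  if (length(center) != 3L || any(center < 1L) || any(center > d))
    stop("ROI center lies outside the volume")
  if (length(half_extent) != 3L || any(half_extent < 0L))
    stop("half_extent components must be >= 0")
  lo <- pmax(center - half_extent, 1L)
  hi <- pmin(center + half_extent, d)
  sub <- vol$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  normalized_volume(sub, window = vol$window, spacing = vol$spacing,
                    origin = vol$origin,
                    offset = vol$offset + lo - 1L)
}

#' Map ROI voxel indices back to the parent volume
#'
#' @param roi a `normalized_volume` produced by [extract_roi()].
#' @param idx matrix (n x 3) or length-3 vector of 1-based (z, y, x) indices
#'   within the ROI.
#' @return Indices in the parent volume's coordinates, same shape as `idx`.
#' @export
roi_to_parent <- function(roi, idx) {
  stopifnot(inherits(roi, "normalized_volume"))
  if (is.null(dim(idx))) return(as.integer(idx) + roi$offset - 1L)
  sweep(idx, 2L, roi$offset - 1L, `+`)
}

# bilinear resize of a 2D matrix to (h2, w2); edge-clamped sampling on the
# pixel-centre grid
resize_bilinear <- function(m, h2, w2) {
  h1 <- nrow(m); w1 <- ncol(m)
  ry <- if (h2 == 1L) rep(1, 1) else seq(1, h1, length.out = h2)
  rx <- if (w2 == 1L) rep(1, 1) else seq(1, w1, length.out = w2)
  y0 <- pmin(floor(ry), h1 - 1L); y0[h1 == 1L] <- 1L
  x0 <- pmin(floor(rx), w1 - 1L); x0[w1 == 1L] <- 1L
  if (h1 == 1L) { y0 <- rep(1L, h2); fy <- rep(0, h2) } else fy <- ry - y0
  if (w1 == 1L) { x0 <- rep(1L, w2); fx <- rep(0, w2) } else fx <- rx - x0
  y1 <- pmin(y0 + 1L, h1); x1 <- pmin(x0 + 1L, w1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d_ <- m[y1, x1, drop = FALSE]
  Fy <- matrix(fy, h2, w2); Fx <- matrix(fx, h2, w2, byrow = TRUE)
  (1 - Fy) * ((1 - Fx) * a + Fx * b) + Fy * ((1 - Fx) * c_ + Fx * d_)
}
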