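#' Sparse dictionaries for morphological component analysis
#'
#' Two linear analysis/synthesis operator pairs, both Parseval frames so that
#' synthesis is exactly the adjoint of analysis *and* a left inverse
#' (`synthesize(analyze(x)) == x` to machine precision):
#'
#' * `dict_uwt()` — an undecimated (shift-invariant, a-trous) separable Haar
#'   wavelet cascade with per-level filter normalisation `H'H + G'G = I` and
#'   circular boundaries. Detail planes are sparse on piecewise-smooth
#'   "cartoon" content (the nodule body); this is the cartoon dictionary.
#' * `dict_ldct()` — overlapped blockwise orthonormal DCT-II with per-pixel
#'   weights `1/sqrt(cover count)`. Sparse on oscillatory texture such as
#'   parenchymal striping; this is the texture dictionary.
#'
#' @param levels number of wavelet scales.
#' @param block LDCT block size in pixels.
#' @param overlap fraction of block overlap (0 = tiling, 0.5 = half-step).
#' @return A dictionary operator object for [analyze()] / [synthesize()].
#' @name dictionaries
NULL

#' @rdname dictionaries
#' @export
dict_uwt <- function(levels = 4L) {
  stopifnot(levels >= 1L)
  structure(list(name = "uwt", levels = as.integer(levels)),
            class = c("dict_uwt", "spic_dict"))
}

#' @rdname dictionaries
#' @export
dict_ldct <- function(block = 16L, overlap = 0.5) {
  stopifnot(block >= 4L, overlap >= 0, overlap < 1)
  structure(list(name = "ldct", block = as.integer(block), overlap = overlap),
            class = c("dict_ldct", "spic_dict"))
}

#' Analyze an image into dictionary coefficients
#'
#' @param image 2D numeric matrix with finite entries.
#' @param dict a dictionary from [dict_uwt()] or [dict_ldct()].
#' @return A coefficient set (class `spic_coeffs`) accepted by
#'   [synthesize()]; `synthesize(analyze(x, d), d)` reproduces `x` to within
#'   1e-6 relative error.
#' @export
analyze <- function(image, dict) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a 2D numeric matrix")
  if (any(!is.finite(image))) stop("`image` must be finite")
  UseMethod("analyze", dict)
}

#' Synthesize an image from dictionary coefficients
#'
#' Linear in the coefficients; the adjoint of [analyze()].
#'
#' @param coeffs a `spic_coeffs` coefficient set.
#' @param dict the dictionary that produced the shape of `coeffs`.
#' @return A 2D numeric matrix.
#' @export
synthesize <- function(coeffs, dict) {
  if (!inherits(coeffs, "spic_coeffs")) stop("`coeffs` must be a spic_coeffs set")
  if (!identical(coeffs$dict_name, dict$name))
    stop("coefficient set was produced by dictionary '", coeffs$dict_name,
         "', not '", dict$name, "'")
  UseMethod("synthesize", dict)
}

## ---- undecimated Haar frame -------------------------------------------------

# circular convolution of matrix columns (dim=1) or rows (dim=2) with a
# sparse two-tap kernel at offsets 0 and `gap`; adjoint uses negated offsets
conv2tap <- function(m, v0, v1, gap, dim, adjoint = FALSE) {
  n <- dim(m)[dim]
  g <- gap %% n
  shift <- function(m, k, dim) {     # row/col circular shift by +k
    if (k %% n == 0) return(m)
    idx <- ((seq_len(n) - 1 + k) %% n) + 1
    if (dim == 1L) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
  }
  if (!adjoint) v0 * m + v1 * shift(m, g, dim)
  else          v0 * m + v1 * shift(m, -g, dim)
}

#' @export
analyze.dict_uwt <- function(image, dict) {
  J <- dict$levels
  h0 <- 0.5; h1 <- 0.5; g0 <- 0.5; g1 <- -0.5
  planes <- list()
  c_ <- image
  for (j in seq_len(J)) {
    gap <- 2^(j - 1)
    Hy <- conv2tap(c_, h0, h1, gap, 1L); Gy <- conv2tap(c_, g0, g1, gap, 1L)
    planes[[paste0("LH", j)]] <- conv2tap(Hy, g0, g1, gap, 2L)
    planes[[paste0("HL", j)]] <- conv2tap(Gy, h0, h1, gap, 2L)
    planes[[paste0("HH", j)]] <- conv2tap(Gy, g0, g1, gap, 2L)
    c_ <- conv2tap(Hy, h0, h1, gap, 2L)
  }
  planes[["LL"]] <- c_
  structure(list(dict_name = "uwt", levels = J, planes = planes,
                 shape = dim(image)),
            class = "spic_coeffs")
}

#' @export
synthesize.dict_uwt <- function(coeffs, dict) {
  J <- coeffs$levels
  h0 <- 0.5; h1 <- 0.5; g0 <- 0.5; g1 <- -0.5
  p <- coeffs$planes
  c_ <- p[["LL"]]
  for (j in rev(seq_len(J))) {
    gap <- 2^(j - 1)
    # adjoint of the level-j analysis: sum of subband adjoints
    c_ <- conv2tap(conv2tap(c_, h0, h1, gap, 2L, adjoint = TRUE),
                   h0, h1, gap, 1L, adjoint = TRUE) +
      conv2tap(conv2tap(p[[paste0("LH", j)]], g0, g1, gap, 2L, adjoint = TRUE),
               h0, h1, gap, 1L, adjoint = TRUE) +
      conv2tap(conv2tap(p[[paste0("HL", j)]], h0, h1, gap, 2L, adjoint = TRUE),
               g0, g1, gap, 1L, adjoint = TRUE) +
      conv2tap(conv2tap(p[[paste0("HH", j)]], g0, g1, gap, 2L, adjoint = TRUE),
               g0, g1, gap, 1L, adjoint = TRUE)
  }
  c_
}

## ---- overlapped local DCT ---------------------------------------------------

dct_matrix <- function(B) {
  k <- 0:(B - 1)
  C <- sqrt(2 / B) * cos(outer(k, k + 0.5) * pi / B)
  C[1, ] <- C[1, ] / sqrt(2)
  C          # orthonormal DCT-II: C %*% t(C) = I
}

ldct_geometry <- function(shape, block, overlap) {
  stride <- max(1L, as.integer(round(block * (1 - overlap))))
  starts <- function(n) {
    if (n <= block) return(1L)
    s <- seq(1L, n - block + 1L, by = stride)
    if (s[length(s)] + block - 1L < n) s <- c(s, n - block + 1L)
    s
  }
  sy <- starts(shape[1]); sx <- starts(shape[2])
  cover <- matrix(0, shape[1], shape[2])
  B1 <- min(block, shape[1]); B2 <- min(block, shape[2])
  for (y in sy) for (x in sx)
    cover[y:(y + B1 - 1L), x:(x + B2 - 1L)] <-
      cover[y:(y + B1 - 1L), x:(x + B2 - 1L)] + 1
  list(sy = sy, sx = sx, B1 = B1, B2 = B2, w = 1 / sqrt(cover))
}

#' @export
analyze.dict_ldct <- function(image, dict) {
  geo <- ldct_geometry(dim(image), dict$block, dict$overlap)
  Cy <- dct_matrix(geo$B1); Cx <- dct_matrix(geo$B2)
  wi <- geo$w * image
  co <- array(0, c(geo$B1, geo$B2, length(geo$sy), length(geo$sx)))
  for (iy in seq_along(geo$sy)) for (ix in seq_along(geo$sx)) {
    y <- geo$sy[iy]; x <- geo$sx[ix]
    blk <- wi[y:(y + geo$B1 - 1L), x:(x + geo$B2 - 1L)]
    co[, , iy, ix] <- Cy %*% blk %*% t(Cx)
  }
  structure(list(dict_name = "ldct", blocks = co, shape = dim(image),
                 block = dict$block, overlap = dict$overlap),
            class = "spic_coeffs")
}

#' @export
synthesize.dict_ldct <- function(coeffs, dict) {
  geo <- ldct_geometry(coeffs$shape, dict$block, dict$overlap)
  Cy <- dct_matrix(geo$B1); Cx <- dct_matrix(geo$B2)
  out <- matrix(0, coeffs$shape[1], coeffs$shape[2])
  for (iy in seq_along(geo$sy)) for (ix in seq_along(geo$sx)) {
    y <- geo$sy[iy]; x <- geo$sx[ix]
    out[y:(y + geo$B1 - 1L), x:(x + geo$B2 - 1L)] <-
      out[y:(y + geo$B1 - 1L), x:(x + geo$B2 - 1L)] +
      t(Cy) %*% coeffs$blocks[, , iy, ix] %*% Cx
  }
  out * geo$w
}

## ---- coefficient-set utilities ---------------------------------------------

coeff_values <- function(coeffs) {
  if (coeffs$dict_name == "uwt") unlist(coeffs$planes, use.names = FALSE)
  else as.vector(coeffs$blocks)
}

# elementwise map over all coefficients; `protect_coarse` exempts the
# wavelet coarse (LL) plane, which carries the cartoon's plateau content
coeff_map <- function(coeffs, f, protect_coarse = FALSE) {
  if (coeffs$dict_name == "uwt") {
    for (nm in names(coeffs$planes)) {
      if (protect_coarse && nm == "LL") next
      coeffs$planes[[nm]] <- f(coeffs$planes[[nm]])
    }
  } else {
    coeffs$blocks <- f(coeffs$blocks)
  }
  coeffs
}

coeff_detail_max <- function(coeffs) {
  if (coeffs$dict_name == "uwt") {
    nm <- setdiff(names(coeffs$planes), "LL")
    max(vapply(nm, function(n) max(abs(coeffs$planes[[n]])), 0))
  } else {
    b <- coeffs$blocks
    b[1, 1, , ] <- 0                     # block DC is not texture detail
    max(abs(b))
  }
}

# hard thresholding; the wavelet coarse plane is optionally protected and
# the LDCT per-block DC is always suppressed (blockwise-constant content is
# cartoon, not texture)
hard_threshold <- function(coeffs, thr, protect_coarse = TRUE) {
  out <- coeff_map(coeffs, function(v) { v[abs(v) < thr] <- 0; v },
                   protect_coarse = protect_coarse)
  if (out$dict_name == "ldct") out$blocks[1, 1, , ] <- 0
  out
}

zero_coeffs <- function(coeffs) coeff_map(coeffs, function(v) v * 0)
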