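#' Unfold a nodule boundary into a polar pseudo-time series
#'
#' Takes the centroid `(x0, y0)` of the single foreground component as the
#' circle centre and, for each of `n_samples` uniformly spaced clockwise
#' angles (theta = 0 toward +x; under the image convention of y growing
#' downward, increasing theta traces the boundary clockwise on screen),
#' records `rho` = the distance to the *farthest* boundary crossing along
#' that ray (so spicule tips are captured, not hidden behind the body).
#' The mask is sampled bilinearly at 0.25-pixel radial steps and the 0.5
#' level crossing is located by linear interpolation. The series is rotated
#' so its global minimum — the boundary point closest to the centre — sits
#' at index 1, making series from rotated masks comparable.
#'
#' @param mask 2D 0/1 matrix with exactly one connected foreground
#'   component of at least 5 pixels.
#' @param n_samples number of angular samples over `[0, 2*pi)`.
#' @return A `polar_series`: `rho` (length `n_samples`), `center`
#'   `(x0, y0)`, `theta` (the angles), and `rotation` (the index of the
#'   original minimum).
#' @export
unfold_boundary <- function(mask, n_samples = 360L) {
  if (!is.matrix(mask)) stop("`mask` must be a 2D matrix")
  m <- (mask > 0) + 0
  lab <- label_components(m)
  ncomp <- max(lab)
  if (ncomp == 0L) stop("mask is empty")
  if (ncomp > 1L) stop("mask must have exactly one connected component, found ",
                       ncomp)
  if (sum(m) < 5) stop("foreground component must contain at least 5 pixels")
  n_samples <- as.integer(n_samples)
  idx <- which(m == 1, arr.ind = TRUE)
  y0 <- mean(idx[, 1]); x0 <- mean(idx[, 2])

  theta <- 2 * pi * (seq_len(n_samples) - 1) / n_samples
  step <- 0.25
  rmax <- sqrt(nrow(m)^2 + ncol(m)^2)
  r <- seq(0, rmax, by = step)
  # sample grid: rows = angles, cols = radii
  px <- outer(cos(theta), r) + x0
  py <- outer(sin(theta), r) + y0
  v <- matrix(bilinear_at(m, py, px), n_samples, length(r))
  inside <- v >= 0.5
  rho <- numeric(n_samples)
  for (a in seq_len(n_samples)) {
    hit <- which(inside[a, ])
    if (!length(hit)) { rho[a] <- 0; next }
    i <- hit[length(hit)]
    if (i < ncol(v) && v[a, i] > v[a, i + 1]) {
      frac <- (v[a, i] - 0.5) / (v[a, i] - v[a, i + 1])
      rho[a] <- r[i] + step * min(max(frac, 0), 1)
    } else rho[a] <- r[i]
  }
  rot <- which.min(rho)
  rho <- c(rho[rot:n_samples], rho[seq_len(rot - 1L)])
  structure(list(rho = rho, center = c(x0 = x0, y0 = y0),
                 theta = theta, rotation = rot),
            class = "polar_series")
}

# bilinear sampling of matrix m (rows = y, cols = x) at real-valued points;
# outside the grid -> 0
bilinear_at <- function(m, y, x) {
  h <- nrow(m); w <- ncol(m)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  val <- function(yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    out <- numeric(length(yy)); out[ok] <- m[cbind(yy[ok], xx[ok])]
    out
  }
  (1 - fy) * (1 - fx) * val(y0, x0) + (1 - fy) * fx * val(y0, x0 + 1) +
    fy * (1 - fx) * val(y0 + 1, x0) + fy * fx * val(y0 + 1, x0 + 1)
}

#' Extract protuberant excursions from a polar series
#'
#' The series minimum is the baseline ("the lowest point is the benchmark
#' for removal"); maximal contiguous runs above the baseline — circular
#' adjacency honoured — whose peak height reaches `min_prominence` are kept,
#' sorted by descending peak prominence, and their values concatenated into
#' a new series. Smooth nodules leave (almost) nothing; spicules leave one
#' excursion each.
#'
#' @param series a [unfold_boundary()] result, or a bare numeric vector.
#' @param min_prominence minimal peak height above baseline, in pixels.
#' @param baseline_tolerance radial jitter (pixels) treated as part of the
#'   flat baseline rather than as elevation; a digital circle's boundary
#'   radius wobbles by up to about one pixel, so separate excursions are
#'   runs exceeding the baseline by more than this, while their stored
#'   values remain the full height above the baseline.
#' @return A `protuberance_series`: `segments` (list of
#'   `(start, values, prominence)`), `values` (the concatenation), and the
#'   `baseline` used. Empty when no run qualifies.
#' @export
extract_protuberances <- function(series, min_prominence = 2,
                                  baseline_tolerance = 1) {
  rho <- if (inherits(series, "polar_series")) series$rho else as.numeric(series)
  n <- length(rho)
  if (n < 1L) stop("series must be nonempty")
  baseline <- min(rho)
  ex <- rho - baseline
  up <- ex > baseline_tolerance
  segs <- list()
  if (any(up)) {
    rle_ <- rle(up)
    ends <- cumsum(rle_$lengths)
    starts <- ends - rle_$lengths + 1L
    runs <- data.frame(start = starts[rle_$values], end = ends[rle_$values])
    # circular: merge a run ending at n with one starting at 1
    if (nrow(runs) > 1L && runs$start[1] == 1L && runs$end[nrow(runs)] == n) {
      runs$start[1] <- runs$start[nrow(runs)]
      runs <- runs[-nrow(runs), , drop = FALSE]
    }
    for (i in seq_len(nrow(runs))) {
      ix <- if (runs$start[i] <= runs$end[i]) runs$start[i]:runs$end[i]
            else c(runs$start[i]:n, 1L:runs$end[i])
      vals <- ex[ix]
      if (max(vals) >= min_prominence)
        segs[[length(segs) + 1L]] <- list(start = runs$start[i], values = vals,
                                          prominence = max(vals))
    }
  }
  if (length(segs)) {
    ord <- order(vapply(segs, `[[`, 0, "prominence"), decreasing = TRUE)
    segs <- segs[ord]
  }
  structure(list(segments = segs,
                 values = unlist(lapply(segs, `[[`, "values")),
                 baseline = baseline, n_samples = n),
            class = "protuberance_series")
}

#' Dynamic time warping distance between two value sequences
#'
#' Classic dynamic program `f(i,j) = d(P_i, Q_j) + min(f(i,j-1), f(i-1,j),
#' f(i-1,j-1))` with Euclidean local cost `d` on scalar values,
#' `f(0,0) = 0` and infinite first row/column; returns `f(n,m)`, the
#' minimal cumulative cost over all monotone warping paths.
#'
#' @param P,Q nonempty numeric vectors.
#' @return Non-negative warping distance; 0 iff a zero-cost alignment exists.
#' @export
dtw_distance <- function(P, Q) {
  P <- as.numeric(P); Q <- as.numeric(Q)
  n <- length(P); m <- length(Q)
  if (n < 1L || m < 1L) stop("sequences must be nonempty")
  f <- matrix(Inf, n + 1L, m + 1L)
  f[1, 1] <- 0
  for (i in seq_len(n)) {
    pi_ <- P[i]
    for (j in seq_len(m)) {
      f[i + 1L, j + 1L] <- abs(pi_ - Q[j]) +
        min(f[i + 1L, j], f[i, j + 1L], f[i, j])
    }
  }
  f[n + 1L, m + 1L]
}

#' Reference database of labelled protuberance series
#'
#' @param series list of numeric vectors (concatenated protuberance values;
#'   may be empty vectors).
#' @param labels character vector, `"spiculated"` / `"non-spiculated"`.
#' @param ids optional sample identifiers.
#' @return An object of class `reference_db`.
#' @export
reference_db <- function(series, labels, ids = NULL) {
  stopifnot(length(series) == length(labels), length(series) >= 1L)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("spiculated", "non-spiculated"))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  if (is.null(ids)) ids <- sprintf("s%03d", seq_along(series))
  structure(list(series = lapply(series, as.numeric), labels = labels,
                 ids = as.character(ids)),
            class = "reference_db")
}

#' Write / read a reference database as CSV
#'
#' Long format with columns `sample_id, label, index, value`; empty series
#' are stored as a single row with `index = 0` and no value.
#'
#' @param db a [reference_db()].
#' @param path CSV path.
#' @return `path` (write) or a `reference_db` (read).
#' @export
write_reference_db <- function(db, path) {
  stopifnot(inherits(db, "reference_db"))
  rows <- do.call(rbind, lapply(seq_along(db$series), function(i) {
    v <- db$series[[i]]
    if (!length(v))
      data.frame(sample_id = db$ids[i], label = db$labels[i],
                 index = 0L, value = NA_real_)
    else
      data.frame(sample_id = db$ids[i], label = db$labels[i],
                 index = seq_along(v), value = v)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_db
#' @export
read_reference_db <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "label", "index", "value")
  if (!all(need %in% names(d)))
    stop("reference CSV must have columns ", paste(need, collapse = ", "))
  ids <- unique(d$sample_id)
  series <- lapply(ids, function(id) {
    rows <- d[d$sample_id == id & d$index > 0, , drop = FALSE]
    rows$value[order(rows$index)]
  })
  labels <- vapply(ids, function(id) d$label[d$sample_id == id][1], "")
  reference_db(series, labels, ids)
}

#' Classify a protuberance series by DTW nearest neighbours
#'
#' k-nearest-neighbour majority vote under [dtw_distance()] against the
#' reference database; the score is the mean distance to the winning
#' label's members among the k neighbours. An empty sample series — no
#' protuberance anywhere — is non-spiculated by convention, with infinite
#' score.
#'
#' @param sample a `protuberance_series` or numeric vector.
#' @param db a [reference_db()].
#' @param k odd neighbour count.
#' @return List `(label, score, distances)`.
#' @export
dtw_classify <- function(sample, db, k = 3L) {
  stopifnot(inherits(db, "reference_db"))
  if (length(db$series) < 1L) stop("reference database is empty")
  if (k < 1L || k %% 2L == 0L) stop("k must be odd and >= 1")
  v <- if (inherits(sample, "protuberance_series")) sample$values
       else as.numeric(sample)
  if (!length(v))
    return(list(label = "non-spiculated", score = Inf, distances = numeric(0)))
  dists <- vapply(db$series, function(q) {
    if (!length(q)) dtw_distance(v, 0) else dtw_distance(v, q)
  }, 0)
  k <- min(k, length(dists))
  nn <- order(dists)[seq_len(k)]
  votes <- table(db$labels[nn])
  label <- names(votes)[which.max(votes)]
  win <- nn[db$labels[nn] == label]
  list(label = label, score = mean(dists[win]), distances = dists)
}

#' Resample a value series to a fixed length
#'
#' Linear interpolation onto `len` equally spaced positions; empty input
#' yields all zeros. Used to turn variable-length concatenated protuberance
#' series into fixed-length classifier features.
#'
#' @param values numeric vector (possibly empty).
#' @param len output length.
#' @return Numeric vector of length `len`.
#' @export
resample_series <- function(values, len = 64L) {
  values <- as.numeric(values)
  if (!length(values)) return(numeric(len))
  if (length(values) == 1L) return(rep(values, len))
  stats::approx(seq_along(values), values, n = len)$y
}
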