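#' Marker policy for the two-pass watershed
#'
#' @param brush_radius radius (pixels) of the disc structuring element used
#'   for the grayscale opening + closing that removes spurious local minima
#'   before marker extraction; small radii preserve the thin gradient
#'   ridge at the nodule edge.
#' @param marker_quantile only regional minima whose gradient value lies
#'   below this quantile of the cleaned gradient seed a basin; shallow
#'   ripple minima are flooded from the deep markers instead of spawning
#'   their own region.
#' @param merge whether to run the second watershed pass that merges
#'   over-segmented first-pass regions across weak boundaries.
#' @param connectivity pixel adjacency, 4 or 8.
#' @return An object of class `markers_config`.
#' @export
markers_config <- function(brush_radius = 1L, marker_quantile = 0.3,
                           merge = TRUE, connectivity = 8L) {
  stopifnot(brush_radius >= 0L, connectivity %in% c(4L, 8L),
            marker_quantile > 0, marker_quantile <= 1)
  structure(list(brush_radius = as.integer(brush_radius),
                 marker_quantile = marker_quantile,
                 merge = isTRUE(merge),
                 connectivity = as.integer(connectivity)),
            class = "markers_config")
}

#' Two-pass marker-driven watershed of a gradient image
#'
#' Pass 1: the gradient is smoothed by grayscale morphological opening then
#' closing, its regional minima become markers, and a priority-flood
#' watershed grows them into catchment basins. Pass 2 re-examines the
#' gradient along the first-pass basin boundaries: adjacent basin pairs
#' whose shared boundary has below-median gradient saliency are merged,
#' which collapses over-segmentation while keeping salient edges.
#'
#' @param gradient non-negative 2D matrix (e.g. [gradient_magnitude()]).
#' @param config a [markers_config()].
#' @return Integer label matrix; 0 marks watershed lines, labels `1..n`
#'   catchment basins. A flat gradient yields a single region.
#' @export
double_watershed <- function(gradient, config = markers_config()) {
  if (!is.matrix(gradient)) stop("`gradient` must be a 2D matrix")
  if (min(gradient) < 0) stop("`gradient` must be non-negative")
  g <- gradient
  if (config$brush_radius > 0L) {
    b <- EBImage::makeBrush(2L * config$brush_radius + 1L, shape = "disc")
    g <- EBImage::closing(EBImage::opening(g, b), b)
  }
  if (diff(range(g)) == 0)
    return(matrix(1L, nrow(g), ncol(g)))
  minima <- regional_minima(g, config$connectivity)
  if (config$marker_quantile < 1) {
    deep <- g <= stats::quantile(g, config$marker_quantile)
    if (any(minima & deep)) minima <- minima & deep
  }
  markers <- label_components(minima + 0L, config$connectivity)
  lab <- flood_watershed(g, markers, config$connectivity)
  if (config$merge && max(lab) > 1L)
    lab <- merge_weak_boundaries(lab, g, config$connectivity)
  lab
}

# pixels whose value equals the minimum over their neighbourhood and whose
# plateau has no strictly lower neighbour
regional_minima <- function(g, connectivity = 8L) {
  h <- nrow(g); w <- ncol(g)
  pad <- matrix(Inf, h + 2L, w + 2L); pad[2:(h + 1), 2:(w + 1)] <- g
  offs <- neighbour_offsets(connectivity)
  nmin <- matrix(Inf, h, w)
  for (k in seq_len(nrow(offs)))
    nmin <- pmin(nmin, pad[2:(h + 1) + offs[k, 1], 2:(w + 1) + offs[k, 2]])
  g <= nmin
}

# connected-component labeling of a binary matrix (8-connected foreground,
# the usual convention for object masks)
label_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  offs <- neighbour_offsets(connectivity)
  lab <- matrix(0L, h, w)
  cur <- 0L
  todo <- which(mask > 0)
  for (p in todo) {
    if (lab[p] > 0L) next
    cur <- cur + 1L
    queue <- p; lab[p] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]; queue <- queue[-length(queue)]
      i <- ((q - 1L) %% h) + 1L; j <- ((q - 1L) %/% h) + 1L
      ii <- i + offs[, 1]; jj <- j + offs[, 2]
      ok <- ii >= 1L & ii <= h & jj >= 1L & jj <= w
      nb <- (jj[ok] - 1L) * h + ii[ok]
      nb <- nb[mask[nb] > 0 & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

neighbour_offsets <- function(connectivity) {
  if (connectivity == 4L)
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  else
    cbind(rep(c(-1L, 0L, 1L), each = 3L), rep(c(-1L, 0L, 1L), 3L))[-5L, ]
}

# Meyer-style priority flood: grow markers in order of increasing gradient;
# a pixel reached by two different labels becomes a watershed line (0)
flood_watershed <- function(g, markers, connectivity = 8L) {
  h <- nrow(g); w <- ncol(g); n <- h * w
  offs <- neighbour_offsets(connectivity)
  lab <- as.integer(markers)          # 0 = unassigned
  state <- integer(n)                 # 0 unvisited, 1 frontier, 2 settled
  state[lab > 0L] <- 2L
  prio <- rep(Inf, n)
  gx <- as.numeric(g)
  neighbours <- function(p) {
    i <- ((p - 1L) %% h) + 1L; j <- ((p - 1L) %/% h) + 1L
    ii <- i + offs[, 1]; jj <- j + offs[, 2]
    ok <- ii >= 1L & ii <= h & jj >= 1L & jj <= w
    (jj[ok] - 1L) * h + ii[ok]
  }
  seeds <- which(lab > 0L)
  for (p in seeds) for (q in neighbours(p)) if (state[q] == 0L) {
    state[q] <- 1L; prio[q] <- gx[q]
  }
  line <- logical(n)
  while (TRUE) {
    p <- which.min(prio)
    if (!is.finite(prio[p])) break
    prio[p] <- Inf
    nb <- neighbours(p)
    nl <- unique(lab[nb][state[nb] == 2L & !line[nb]])
    nl <- nl[nl > 0L]
    if (length(nl) == 1L) lab[p] <- nl
    else line[p] <- TRUE               # touched by >= 2 basins (or none)
    state[p] <- 2L
    if (!line[p]) for (q in nb) if (state[q] == 0L) {
      state[q] <- 1L; prio[q] <- gx[q]
    }
  }
  lab[line] <- 0L
  matrix(lab, h, w)
}

# second pass: merge adjacent basins whose shared boundary saliency (mean
# smoothed gradient over the boundary's pixels) is below the median saliency
merge_weak_boundaries <- function(lab, g, connectivity = 8L) {
  h <- nrow(lab); w <- ncol(lab)
  offs <- neighbour_offsets(connectivity)
  lines <- which(lab == 0L)
  if (!length(lines)) return(lab)
  pair_key <- character(0); pair_val <- list()
  touching <- vector("list", length(lines))
  for (t in seq_along(lines)) {
    p <- lines[t]
    i <- ((p - 1L) %% h) + 1L; j <- ((p - 1L) %/% h) + 1L
    ii <- i + offs[, 1]; jj <- j + offs[, 2]
    ok <- ii >= 1L & ii <= h & jj >= 1L & jj <= w
    ls <- unique(lab[(jj[ok] - 1L) * h + ii[ok]])
    ls <- sort(ls[ls > 0L])
    touching[[t]] <- ls
    if (length(ls) >= 2L)
      for (a in seq_len(length(ls) - 1L)) for (b in (a + 1L):length(ls)) {
        k <- paste0(ls[a], "-", ls[b])
        pair_val[[k]] <- c(pair_val[[k]], g[p])
      }
  }
  if (!length(pair_val)) return(lab)
  sal <- vapply(pair_val, mean, 0)
  cut <- stats::median(sal)
  # union-find over labels
  parent <- seq_len(max(lab))
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (k in names(sal)[sal < cut]) {
    ab <- as.integer(strsplit(k, "-", fixed = TRUE)[[1]])
    ra <- find(ab[1]); rb <- find(ab[2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_along(parent), find, 0L)
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  # former line pixels interior to a merged basin join it
  for (t in seq_along(lines)) {
    ls <- touching[[t]]
    if (length(ls) >= 1L) {
      m <- unique(dense[ls])
      if (length(m) == 1L) out[lines[t]] <- m
    }
  }
  out
}

#' Segment a nodule from a nodule-centred 2D image
#'
#' Full sparse-decomposition segmentation chain: [mca_decompose()] into
#' cartoon + texture, [extract_nodule_component()] to reconstruct the
#' nodule component from the dominant cartoon coefficients, threshold
#' segmentation of that component, then [gradient_magnitude()] and the
#' two-pass [double_watershed()] to refine: only catchment basins whose
#' pixels are predominantly above the threshold are kept (which cuts
#' adherent structures at their gradient ridge), watershed-line pixels
#' adjacent to kept basins are included, the result is intersected with
#' the threshold mask, and the connected component containing the image
#' centre is the final mask. Deterministic: no randomness in the chain.
#'
#' The intensity threshold sits `threshold_frac` of the way from the
#' background level (the median of the nodule component) to its peak
#' (99th percentile).
#'
#' A detection-failure flag (empty mask, `detected = FALSE`) is returned
#' instead of an error when no centre component exists, when the
#' reconstructed component lacks contrast between mask and surroundings
#' (`min_contrast`), or when the "nodule" swallows most of the frame.
#'
#' @param image 2D matrix in `[0, 1]`, nodule at the centre.
#' @param config an [mca_config()].
#' @param markers a [markers_config()].
#' @param threshold_frac relative height of the intensity threshold.
#' @param min_contrast minimal mean contrast (nodule component, inside vs
#'   outside the mask) for a detection to count.
#' @param refine_iter iterations of the final geodesic refinement that
#'   grows the mask inside the original image's threshold set (recovers
#'   thin spicules the sparse reconstruction attenuates); 0 disables.
#' @return A `segmentation_result`: `mask` (0/1 matrix), `detected` flag,
#'   `components` (the MCA split), `nodule_image`, `gradient`, `labels`
#'   (watershed label image), and the configs used.
#' @export
segment_nodule <- function(image, config = mca_config(),
                           markers = markers_config(),
                           threshold_frac = 0.3, min_contrast = 0.1,
                           refine_iter = 10L) {
  refine_brush <- EBImage::makeBrush(3L, shape = "box")
  comps <- mca_decompose(image, config)
  io <- extract_nodule_component(comps, config)
  grad <- gradient_magnitude(io)
  lab <- double_watershed(grad, markers)
  bg <- stats::median(io)
  pk <- stats::quantile(io, 0.99, names = FALSE)
  cand <- (io >= bg + threshold_frac * (pk - bg)) + 0L
  mask <- matrix(0L, nrow(image), ncol(image))
  detected <- FALSE
  if (any(cand > 0)) {
    # watershed lines act as cuts through the threshold mask: adherent
    # bright structures separate from the nodule at their gradient ridge
    cut <- cand
    cut[lab == 0L] <- 0L
    cc <- label_components(cut)
    ci <- (nrow(image) + 1L) %/% 2L; cj <- (ncol(image) + 1L) %/% 2L
    sel <- cc[ci, cj]
    if (sel == 0L) {                    # centre just off the component
      nb <- cc[max(1, ci - 1):min(nrow(cc), ci + 1),
               max(1, cj - 1):min(ncol(cc), cj + 1)]
      nb <- nb[nb > 0L]
      sel <- if (length(nb)) as.integer(names(which.max(table(nb)))) else 0L
    }
    if (sel > 0L) {
      mask[cc == sel] <- 1L
      # line pixels that are themselves above threshold and adjacent to
      # the selected component belong to its rim
      rim <- include_adjacent_lines(mask, lab)
      mask[rim == 1L & cand == 1L] <- 1L
      # boundary refinement on the original intensities: the sparse
      # reconstruction attenuates thin spicules, so grow the mask
      # geodesically inside the image's own threshold set
      if (refine_iter > 0L) {
        ibg <- stats::median(image)
        ipk <- stats::quantile(image, 0.99, names = FALSE)
        cand_img <- image >= ibg + threshold_frac * (ipk - ibg)
        for (i in seq_len(refine_iter)) {
          grown <- (EBImage::dilate(mask, refine_brush) > 0) & cand_img
          new_mask <- (mask | grown) + 0L
          if (identical(new_mask, mask + 0L)) break
          mask <- new_mask
        }
        # and trim the rim the smoothed reconstruction added: every final
        # mask pixel must itself clear the image-level threshold
        trimmed <- (mask > 0) & cand_img
        if (any(trimmed)) mask <- trimmed
        mask <- matrix(as.integer(mask > 0), nrow(image), ncol(image))
      }
      inside <- mask == 1L
      if (sum(inside) >= 5L && !all(inside)) {
        contrast <- mean(io[inside]) - mean(io[!inside])
        detected <- contrast >= min_contrast && mean(inside) < 0.6
      }
    }
  }
  if (!detected) mask[] <- 0L
  structure(list(mask = mask, detected = detected, components = comps,
                 nodule_image = io, gradient = grad, labels = lab,
                 config = config, markers = markers),
            class = "segmentation_result")
}

# add watershed-line pixels that touch the selected region
include_adjacent_lines <- function(mask, lab) {
  h <- nrow(mask); w <- ncol(mask)
  offs <- neighbour_offsets(8L)
  pad <- matrix(0L, h + 2L, w + 2L); pad[2:(h + 1), 2:(w + 1)] <- mask
  touch <- matrix(0L, h, w)
  for (k in seq_len(nrow(offs)))
    touch <- pmax(touch, pad[2:(h + 1) + offs[k, 1], 2:(w + 1) + offs[k, 2]])
  mask[lab == 0L & touch == 1L] <- 1L
  mask
}
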