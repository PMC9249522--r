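#' Specification of a synthetic CT nodule phantom
#'
#' Describes a quasi-spherical bright nodule on noisy parenchyma, optionally
#' with radiating spicules (the positive class) and/or an adherent vessel
#' tube. Intensities are on the normalized `[0, 1]` scale, i.e. the phantom
#' emulates a lung-windowed CT region, not raw HU.
#'
#' @param shape volume shape `(z, y, x)` in voxels.
#' @param center nodule centre `(z, y, x)`; default volume centre.
#' @param radius nodule radius in voxels (>= 2).
#' @param intensity nodule body intensity in `(0, 1]`.
#' @param n_spicules number of radiating spicules (0 = smooth nodule).
#' @param spicule_length,spicule_width spicule size range in voxels; each
#'   spicule draws a length uniformly from `spicule_length` and tapers from
#'   `spicule_width` at its base to a point.
#' @param spicule_elev_deg maximal elevation (degrees) of spicule directions
#'   out of the axial plane; 0 keeps every spicule in the nodule's mid-axial
#'   plane.
#' @param vessel if `TRUE`, attach a straight vessel-like tube of radius
#'   `vessel_radius` running from the nodule to the volume face.
#' @param vessel_radius vessel tube radius in voxels.
#' @param background parenchyma plateau intensity.
#' @param texture_amp amplitude of the low-frequency cosine texture added to
#'   the background (gives the texture dictionary real work).
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param seed integer RNG seed; all stochasticity flows from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 48L), center = NULL,
                         radius = 10, intensity = 0.8,
                         n_spicules = 0L,
                         spicule_length = c(4, 8), spicule_width = 2,
                         spicule_elev_deg = 15,
                         vessel = FALSE, vessel_radius = 1.5,
                         background = 0.15, texture_amp = 0.04,
                         noise_sigma = 0.04, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) stop("shape must be 3 ints >= 8")
  if (is.null(center)) center <- (shape + 1) / 2
  if (radius < 2) stop("nodule radius must be >= 2 voxels")
  n_spicules <- as.integer(n_spicules)
  if (n_spicules < 0L) stop("n_spicules must be >= 0")
  reach <- radius + if (n_spicules > 0L) max(spicule_length) else 0
  if (any(center - reach < 1) || any(center + reach > shape))
    stop("nodule plus spicules would exceed the volume bounds")
  if (intensity <= 0 || intensity > 1) stop("intensity must be in (0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (noise_sigma > 0 && intensity - background < 3 * noise_sigma)
    stop("nodule/background contrast must be >= 3 x noise_sigma")
  structure(list(shape = shape, center = as.numeric(center), radius = radius,
                 intensity = intensity, n_spicules = n_spicules,
                 spicule_length = spicule_length, spicule_width = spicule_width,
                 spicule_elev_deg = spicule_elev_deg,
                 vessel = isTRUE(vessel), vessel_radius = vessel_radius,
                 background = background, texture_amp = texture_amp,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one synthetic nodule phantom
#'
#' Deterministic given `spec$seed`. The volume is the background plateau plus
#' low-frequency cosine texture plus Gaussian noise, with the nodule body
#' (a digital ball) and any spicules (tapered radial cones of the same
#' intensity) painted on top. The ground-truth mask covers body and spicules.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_sample`: list with `volume` (a `normalized_volume`),
#'   `mask` (3D 0/1 array), `label` (`"spiculated"` / `"non-spiculated"`),
#'   and `spec`.
#' @export
make_nodule_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  rng <- local_rng(spec$seed)
  d <- spec$shape
  zc <- spec$center[1]; yc <- spec$center[2]; xc <- spec$center[3]

  z <- slice.index(array(0, d), 1); y <- slice.index(array(0, d), 2)
  x <- slice.index(array(0, d), 3)
  dist2 <- (z - zc)^2 + (y - yc)^2 + (x - xc)^2
  mask <- dist2 <= spec$radius^2

  # spicules: tapered cones attached to the nodule surface, directions from
  # the seeded RNG (azimuth uniform, elevation limited to spicule_elev_deg)
  if (spec$n_spicules > 0L) {
    az <- rng$runif(spec$n_spicules, 0, 2 * pi)
    elmax <- spec$spicule_elev_deg * pi / 180
    el <- rng$runif(spec$n_spicules, -elmax, elmax)
    len <- rng$runif(spec$n_spicules, min(spec$spicule_length),
                     max(spec$spicule_length))
    for (s in seq_len(spec$n_spicules)) {
      u <- c(sin(el[s]),                       # z component
             sin(az[s]) * cos(el[s]),          # y
             cos(az[s]) * cos(el[s]))          # x
      # distance along the spicule axis from the centre
      t_ <- (z - zc) * u[1] + (y - yc) * u[2] + (x - xc) * u[3]
      perp2 <- dist2 - t_^2
      tip <- spec$radius + len[s]
      frac <- (tip - t_) / len[s]               # 1 at base, 0 at tip
      # taper to a point but keep >= ~1 voxel of flesh so the digital
      # spicule stays 8-connected to the body
      w <- pmax(spec$spicule_width / 2 * pmin(pmax(frac, 0), 1), 0.75)
      mask <- mask | (t_ > 0 & t_ <= tip & perp2 <= w^2 + 0.25)
    }
  }

  if (spec$vessel) {
    az <- rng$runif(1, 0, 2 * pi)
    u <- c(0, sin(az), cos(az))                 # axial-plane tube
    t_ <- (z - zc) * u[2] * 0 + (y - yc) * u[2] + (x - xc) * u[3]
    perp2 <- dist2 - t_^2
    vessel_vox <- t_ > 0 & perp2 <= spec$vessel_radius^2
    vol_extra <- vessel_vox
  } else vol_extra <- NULL

  vox <- array(spec$background, d)
  if (spec$texture_amp > 0) {
    ph <- rng$runif(4, 0, 2 * pi)
    tex <- spec$texture_amp *
      (cos(2 * pi * y / 11 + ph[1]) * cos(2 * pi * x / 13 + ph[2]) +
       cos(2 * pi * (x + y) / 17 + ph[3])) / 2
    vox <- vox + tex
  }
  if (spec$noise_sigma > 0)
    vox <- vox + array(rng$rnorm(prod(d), 0, spec$noise_sigma), d)
  vox[mask] <- spec$intensity
  if (!is.null(vol_extra)) vox[vol_extra & !mask] <- spec$intensity * 0.9
  vox[vox < 0] <- 0; vox[vox > 1] <- 1

  structure(list(
    volume = normalized_volume(vox, spacing = c(1, 1, 1), origin = "phantom"),
    mask = array(as.integer(mask), d),
    label = if (spec$n_spicules > 0L) "spiculated" else "non-spiculated",
    spec = spec), class = "phantom_sample")
}

#' Generate a labelled phantom dataset
#'
#' `n_pos` spiculated plus `n_neg` smooth samples, with per-sample jitter of
#' the nodule radius, intensity, and (for positives) spicule count, all drawn
#' from a single seeded RNG stream so two runs with the same seed produce
#' identical data.
#'
#' @param n_pos,n_neg class counts (>= 0).
#' @param base_spec the [phantom_spec()] that jitter is applied around.
#' @param seed integer seed for the dataset-level RNG.
#' @return List of `phantom_sample`s, positives first.
#' @export
make_phantom_dataset <- function(n_pos, n_neg, base_spec = phantom_spec(),
                                 seed = 1L) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  rng <- local_rng(seed)
  n <- n_pos + n_neg
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- i <= n_pos
    sp <- base_spec
    sp$radius <- max(2, base_spec$radius + rng$runif(1, -2, 2))
    sp$intensity <- min(1, max(0.3, base_spec$intensity + rng$runif(1, -0.1, 0.1)))
    sp$n_spicules <- if (pos) rng$sample_int(6, 1) + 2L else 0L  # 3..8
    sp$seed <- rng$sample_int(.Machine$integer.max - 1L, 1)
    out[[i]] <- make_nodule_phantom(sp)
  }
  out
}

# Self-contained RNG stream: isolates phantom randomness from the global
# .Random.seed so generation is reproducible regardless of caller state.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  with_state <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f(...)
  }
  list(runif = with_state(stats::runif),
       rnorm = with_state(stats::rnorm),
       sample_int = with_state(function(n, size) sample.int(n, size, replace = TRUE)))
}
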