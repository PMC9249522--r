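#' Configuration for morphological component analysis
#'
#' Parameters of the block-coordinate iterative-thresholding solver that
#' splits a nodule-centred image into a cartoon component (sparse in the
#' undecimated wavelet frame) and a texture component (sparse in the local
#' DCT dictionary), minimising the sparsity-penalised data-fidelity
#' objective with an optional total-variation term on the cartoon.
#'
#' @param lambda data-fidelity weight used when reporting the objective.
#' @param gamma_tv total-variation weight on the cartoon component
#'   (implemented as soft-thresholding of the cartoon's finest undecimated
#'   Haar details by `gamma_tv * threshold`, the standard light-weight TV
#'   surrogate in MCA solvers); 0 disables it.
#' @param n_iterations outer iterations of the solver (>= 1).
#' @param threshold_start,threshold_stop threshold schedule as fractions of
#'   the largest initial detail coefficient; must decay strictly.
#' @param tolerance stop early once the residual L2 norm falls below
#'   `tolerance * ||image||`.
#' @param keep_quantile fraction of largest-magnitude cartoon coefficients
#'   kept by [extract_nodule_component()] (0 keeps all, 1 drops all).
#' @param dicts list of the two dictionaries `(cartoon, texture)`.
#' @return An object of class `mca_config`.
#' @export
mca_config <- function(lambda = 1, gamma_tv = 0.1 * lambda,
                       n_iterations = 50L,
                       threshold_start = 1, threshold_stop = 0.01,
                       tolerance = 1e-4, keep_quantile = 0.80,
                       dicts = list(cartoon = dict_uwt(4L),
                                    texture = dict_ldct(16L, 0.5))) {
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (threshold_start <= threshold_stop)
    stop("threshold schedule must be strictly decreasing")
  if (gamma_tv < 0) stop("gamma_tv must be >= 0")
  structure(list(lambda = lambda, gamma_tv = gamma_tv,
                 n_iterations = n_iterations,
                 threshold_start = threshold_start,
                 threshold_stop = threshold_stop,
                 tolerance = tolerance, keep_quantile = keep_quantile,
                 dicts = dicts),
            class = "mca_config")
}

#' Decompose an image into cartoon + texture morphological components
#'
#' Block-coordinate relaxation with a linearly decaying hard threshold: at
#' each outer iteration the residual with respect to the other component is
#' analysed in each dictionary, thresholded, and re-synthesised. The wavelet
#' coarse plane is never thresholded (plateau content belongs to the
#' cartoon). The residual is defined by subtraction, so
#' `cartoon + texture + residual == image` holds exactly at all times.
#'
#' @param image 2D matrix with values in `[0, 1]`.
#' @param config an [mca_config()].
#' @return An `mca_components` object: `cartoon`, `texture`, `residual`
#'   matrices, the per-iteration data-fidelity trace, and `converged`
#'   (`TRUE` if the residual tolerance was reached before the iteration cap).
#' @export
mca_decompose <- function(image, config = mca_config()) {
  if (!is.matrix(image)) stop("`image` must be a 2D matrix")
  if (any(!is.finite(image)) || min(image) < 0 - 1e-9 || max(image) > 1 + 1e-9)
    stop("`image` values must lie in [0, 1]")
  dc <- config$dicts$cartoon; dt <- config$dicts$texture
  n <- config$n_iterations
  img_norm <- sqrt(sum(image^2))

  cartoon <- matrix(0, nrow(image), ncol(image))
  texture <- matrix(0, nrow(image), ncol(image))
  # threshold scale: largest detail coefficient over both dictionaries
  base <- max(coeff_detail_max(analyze(image, dc)),
              coeff_detail_max(analyze(image, dt)))
  if (base == 0)   # zero (or constant-free) image: nothing to separate
    base <- 1
  thr_seq <- base * seq(config$threshold_start, config$threshold_stop,
                        length.out = n)
  fidelity <- numeric(0)
  f_prev <- Inf
  grow <- 0L
  converged <- FALSE
  for (it in seq_len(n)) {
    thr <- thr_seq[it]
    # cartoon update against the texture-free residual
    co <- hard_threshold(analyze(image - texture, dc), thr,
                         protect_coarse = TRUE)
    cand_cartoon <- synthesize(co, dc)
    if (config$gamma_tv > 0)
      cand_cartoon <- tv_soften(cand_cartoon, config$gamma_tv * thr)
    # texture update against the cartoon-free residual
    ct <- hard_threshold(analyze(image - cand_cartoon, dt), thr,
                         protect_coarse = FALSE)
    cand_texture <- synthesize(ct, dt)

    f <- sqrt(sum((image - cand_cartoon - cand_texture)^2))
    if (f <= f_prev + 1e-12) {
      cartoon <- cand_cartoon; texture <- cand_texture
      f_prev <- min(f, f_prev)
      grow <- 0L
    } else {
      # monotone safeguard: near convergence the alternating updates can
      # wobble; keep the best iterate so the fidelity trace never increases
      if (f > 1.1 * f_prev) {
        grow <- grow + 1L
        if (grow >= 3L)
          stop("MCA diverged: data fidelity grew over 3 consecutive ",
               "iterations (trace: ",
               paste(signif(c(fidelity, f), 5), collapse = ", "), ")")
      } else grow <- 0L
      f <- f_prev
    }
    fidelity <- c(fidelity, f)
    if (f <= config$tolerance * img_norm) { converged <- TRUE; break }
  }
  structure(list(cartoon = cartoon, texture = texture,
                 residual = image - cartoon - texture,
                 fidelity = fidelity, converged = converged,
                 config = config),
            class = "mca_components")
}

# TV surrogate: soft-threshold the finest-scale undecimated Haar details
tv_soften <- function(img, t) {
  d <- dict_uwt(1L)
  co <- analyze(img, d)
  soft <- function(v) sign(v) * pmax(abs(v) - t, 0)
  for (nm in c("LH1", "HL1", "HH1")) co$planes[[nm]] <- soft(co$planes[[nm]])
  synthesize(co, d)
}

#' Reconstruct the nodule component from the sparsest cartoon coefficients
#'
#' Re-analyses the cartoon component in the cartoon dictionary, keeps only
#' the top `keep_quantile` fraction of coefficients by magnitude (the
#' nodule's compact support concentrates there), and re-synthesises.
#'
#' @param components an `mca_components` from [mca_decompose()].
#' @param config an [mca_config()]; `config$keep_quantile` is the fraction
#'   of coefficients *dropped*, i.e. the default 0.8 keeps the top 20%.
#' @return 2D matrix: the reconstructed nodule image.
#' @export
extract_nodule_component <- function(components, config = mca_config()) {
  stopifnot(inherits(components, "mca_components"))
  dc <- config$dicts$cartoon
  co <- analyze(components$cartoon, dc)
  q <- config$keep_quantile
  if (q <= 0) return(synthesize(co, dc))      # keep everything: identity
  vals <- abs(coeff_values(co))
  if (q >= 1) {
    warning("keep_quantile >= 1 drops every coefficient; returning zero image")
    return(synthesize(zero_coeffs(co), dc))
  }
  cut <- stats::quantile(vals, q, names = FALSE)
  coeff_map(co, function(v) { v[abs(v) < cut] <- 0; v }) |>
    synthesize(dc)
}

#' Gradient magnitude of a 2D image
#'
#' Central differences in the interior, one-sided at the borders:
#' `G = sqrt((dI/dx)^2 + (dI/dy)^2)`.
#'
#' @param image 2D matrix.
#' @return Non-negative 2D matrix of the same shape.
#' @export
gradient_magnitude <- function(image) {
  if (!is.matrix(image)) stop("`image` must be a 2D matrix")
  h <- nrow(image); w <- ncol(image)
  gy <- image; gx <- image
  gy[2:(h - 1), ] <- (image[3:h, ] - image[1:(h - 2), ]) / 2
  gy[1, ] <- image[2, ] - image[1, ]; gy[h, ] <- image[h, ] - image[h - 1, ]
  gx[, 2:(w - 1)] <- (image[, 3:w] - image[, 1:(w - 2)]) / 2
  gx[, 1] <- image[, 2] - image[, 1]; gx[, w] <- image[, w] - image[, w - 1]
  sqrt(gx^2 + gy^2)
}
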