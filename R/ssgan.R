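#' Configuration of the semi-supervised adversarial classifier
#'
#' The discriminator doubles as a K-class classifier; its loss is the
#' convex combination `alpha * L1 + beta * L2 + gamma * Psi` of the
#' supervised cross-entropy `L1`, the real/fake adversarial term `L2`
#' (with the discriminator probability computed from the mean class
#' activation early in training and from the log-sum form once the
#' classifier has matured), and the manifold regulariser `Psi` penalising
#' classifier-output change under small perturbations along the generator
#' manifold. The generator is trained by mean + standard-deviation feature
#' matching of the classifier output between real and generated batches.
#'
#' @param alpha,beta,gamma non-negative loss weights summing to 1.
#' @param epsilon manifold perturbation scale applied to the unit-normalised
#'   latent disturbance.
#' @param z_dim latent dimension of the generator.
#' @param gen_hidden,clf_hidden hidden-layer widths of the two MLPs.
#' @param feature which classifier layer feeds the feature-matching and
#'   manifold terms: `"softmax"` (output probabilities) or `"hidden"`.
#' @param lr Adam learning rate (the manifold step size is folded into the
#'   optimiser's handling of the `gamma * Psi` gradient).
#' @param batch_size,epochs training schedule.
#' @param mode_switch_frac fraction of epochs after which the discriminator
#'   probability switches from `mean_activation` to `logsum`.
#' @param seed integer seed driving parameter init, shuffling, latent
#'   sampling, and the manifold disturbances.
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(alpha = 0.5, beta = 0.3, gamma = 0.2,
                       epsilon = 0.1, z_dim = 16L,
                       gen_hidden = 64L, clf_hidden = 64L,
                       feature = c("softmax", "hidden"),
                       lr = 2e-3, batch_size = 32L, epochs = 100L,
                       mode_switch_frac = 0.3, seed = 1L) {
  if (alpha < 0 || beta < 0 || gamma < 0 ||
      abs(alpha + beta + gamma - 1) > 1e-9)
    stop("alpha, beta, gamma must be >= 0 and sum to 1")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 epsilon = epsilon, z_dim = as.integer(z_dim),
                 gen_hidden = as.integer(gen_hidden),
                 clf_hidden = as.integer(clf_hidden),
                 feature = match.arg(feature), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 mode_switch_frac = mode_switch_frac,
                 seed = as.integer(seed)),
            class = "gan_config")
}

## ---- numerically stable primitives -----------------------------------------

logsumexp_rows <- function(l) {
  m <- apply(l, 1L, max)
  m + log(rowSums(exp(l - m)))
}

# log(1 + e^x) without overflow: exactly linear for large x
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

sigmoid <- function(x) 1 / (1 + exp(-x))

as_logit_matrix <- function(l) {
  if (is.null(dim(l))) matrix(l, nrow = 1L) else as.matrix(l)
}

#' Class probabilities from classifier logits
#'
#' Softmax `P(y = i | x) = exp(l_i) / sum_k exp(l_k)`, computed with
#' max-subtraction so logits of magnitude 1e3 neither overflow nor lose
#' the normalisation (each row sums to exactly 1).
#'
#' @param logits K-vector, or n x K matrix of per-sample logits.
#' @return Probabilities of the same shape.
#' @export
class_probabilities <- function(logits) {
  vec <- is.null(dim(logits))
  l <- as_logit_matrix(logits)
  e <- exp(l - apply(l, 1L, max))
  p <- e / rowSums(e)
  if (vec) drop(p) else p
}

#' Discriminator probability that a sample is real
#'
#' Two forms share the classifier logits: `"logsum"` uses
#' `B = Z / (1 + Z)` with `Z = sum_k exp(l_k)` (equivalently
#' `sigmoid(logsumexp(l))`), appropriate once the classifier is mature;
#' `"mean_activation"` uses `B* = sigmoid(mean_k l_k)`, which does not
#' depend on the immature classifier's class preferences and is used early
#' in training. Both are evaluated in log space.
#'
#' @param logits K-vector or n x K matrix.
#' @param mode `"logsum"` or `"mean_activation"`.
#' @return Probability in (0, 1), one per row.
#' @export
disc_prob <- function(logits, mode = c("logsum", "mean_activation")) {
  mode <- match.arg(mode)
  l <- as_logit_matrix(logits)
  s <- if (mode == "logsum") logsumexp_rows(l) else rowMeans(l)
  drop(sigmoid(s))
}

#' Unsupervised real/fake loss on classifier logits
#'
#' `L = E_fake[log(1 + Z(x_g))] - E_real[log Z(x) - log(1 + Z(x))]` with
#' `Z = sum_k exp(l_k)`; log-sum-exp stabilised. Driving `L` down pushes
#' real samples toward high total activation and generated samples toward
#' low total activation.
#'
#' @param logits_real,logits_fake n x K logit matrices (nonempty).
#' @return Scalar loss.
#' @export
unsupervised_loss <- function(logits_real, logits_fake) {
  lr_ <- as_logit_matrix(logits_real); lf <- as_logit_matrix(logits_fake)
  sr <- logsumexp_rows(lr_); sf <- logsumexp_rows(lf)
  mean(softplus(sf)) - mean(sr - softplus(sr))
}

# gradients of unsupervised_loss wrt each logit matrix
unsupervised_loss_grad <- function(logits_real, logits_fake) {
  lr_ <- as_logit_matrix(logits_real); lf <- as_logit_matrix(logits_fake)
  pr <- class_probabilities(lr_); pf <- class_probabilities(lf)
  br <- sigmoid(logsumexp_rows(lr_)); bf <- sigmoid(logsumexp_rows(lf))
  list(real = -pr * (1 - br) / nrow(lr_),
       fake = pf * bf / nrow(lf))
}

#' Supervised cross-entropy loss
#'
#' Mean negative log of [class_probabilities()] at the true label.
#'
#' @param logits n x K matrix.
#' @param labels integer class indices in `1..K`.
#' @return Scalar loss.
#' @export
supervised_loss <- function(logits, labels) {
  l <- as_logit_matrix(logits)
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > ncol(l)))
    stop("labels must be class indices in 1..K")
  s <- logsumexp_rows(l)
  mean(s - l[cbind(seq_len(nrow(l)), labels)])
}

supervised_loss_grad <- function(logits, labels) {
  l <- as_logit_matrix(logits)
  p <- class_probabilities(l)
  p[cbind(seq_len(nrow(l)), as.integer(labels))] <-
    p[cbind(seq_len(nrow(l)), as.integer(labels))] - 1
  p / nrow(l)
}

#' Adversarial discriminator loss
#'
#' `L2 = E[-log B(x)] + E[-log(1 - B(x_g))]` with `B` given by
#' [disc_prob()] in the requested mode; computed via softplus so extreme
#' logits stay finite.
#'
#' @param logits_real,logits_fake n x K logit matrices.
#' @param mode passed to [disc_prob()].
#' @return Scalar loss.
#' @export
adversarial_b_loss <- function(logits_real, logits_fake,
                               mode = c("logsum", "mean_activation")) {
  mode <- match.arg(mode)
  lr_ <- as_logit_matrix(logits_real); lf <- as_logit_matrix(logits_fake)
  sr <- if (mode == "logsum") logsumexp_rows(lr_) else rowMeans(lr_)
  sf <- if (mode == "logsum") logsumexp_rows(lf) else rowMeans(lf)
  mean(softplus(-sr)) + mean(softplus(sf))
}

adversarial_b_loss_grad <- function(logits_real, logits_fake,
                                    mode = c("logsum", "mean_activation")) {
  mode <- match.arg(mode)
  lr_ <- as_logit_matrix(logits_real); lf <- as_logit_matrix(logits_fake)
  if (mode == "logsum") {
    wr <- class_probabilities(lr_); wf <- class_probabilities(lf)
    sr <- logsumexp_rows(lr_); sf <- logsumexp_rows(lf)
  } else {
    wr <- matrix(1 / ncol(lr_), nrow(lr_), ncol(lr_))
    wf <- matrix(1 / ncol(lf), nrow(lf), ncol(lf))
    sr <- rowMeans(lr_); sf <- rowMeans(lf)
  }
  list(real = -wr * (1 - sigmoid(sr)) / nrow(lr_),
       fake = wf * sigmoid(sf) / nrow(lf))
}

#' Mean and standard-deviation feature-matching loss
#'
#' `||mu_real - mu_fake||^2 + ||sigma_real - sigma_fake||^2` with
#' per-dimension batch mean and (n-1) standard deviation; the generator
#' objective.
#'
#' @param features_real,features_fake n x d feature matrices, each with at
#'   least 2 rows (the standard deviation is undefined otherwise).
#' @return Scalar loss; 0 for identical batches.
#' @export
feature_matching_loss <- function(features_real, features_fake) {
  fr <- as.matrix(features_real); ff <- as.matrix(features_fake)
  if (nrow(fr) < 2L || nrow(ff) < 2L)
    stop("feature matching needs batches of >= 2 samples")
  mu_r <- colMeans(fr); mu_f <- colMeans(ff)
  sd_r <- apply(fr, 2L, stats::sd); sd_f <- apply(ff, 2L, stats::sd)
  sum((mu_r - mu_f)^2) + sum((sd_r - sd_f)^2)
}

# gradient wrt the fake feature matrix
feature_matching_grad_fake <- function(features_real, features_fake) {
  fr <- as.matrix(features_real); ff <- as.matrix(features_fake)
  n <- nrow(ff)
  mu_r <- colMeans(fr); mu_f <- colMeans(ff)
  sd_r <- apply(fr, 2L, stats::sd); sd_f <- apply(ff, 2L, stats::sd)
  g_mu <- -2 * (mu_r - mu_f) / n
  dsd <- -2 * (sd_r - sd_f)
  centred <- sweep(ff, 2L, mu_f)
  denom <- (n - 1) * sd_f
  dsd_dx <- sweep(centred, 2L, ifelse(denom > 0, denom, Inf), `/`)
  sweep(dsd_dx, 2L, dsd, `*`) + matrix(g_mu, n, ncol(ff), byrow = TRUE)
}

#' Manifold regularisation penalty
#'
#' `Psi = (1/n) sum_i || phi(G(z_i + eps * dbar_i)) - phi(G(z_i)) ||^2`
#' where `dbar` is a unit-normalised Gaussian disturbance per sample and
#' `phi` is the classifier feature map ([gan_config()]'s `feature`).
#' Exactly 0 when `epsilon = 0` or the generator ignores its input.
#'
#' @param generator,classifier MLP parameter sets (see [train_ssgan()]).
#' @param z_batch n x z_dim latent matrix.
#' @param epsilon perturbation scale (>= 0).
#' @param delta optional pre-drawn disturbance matrix (else drawn from the
#'   current RNG stream).
#' @param feature `"softmax"` or `"hidden"`.
#' @return Scalar penalty >= 0.
#' @export
manifold_penalty <- function(generator, classifier, z_batch, epsilon,
                             delta = NULL, feature = "softmax") {
  z <- as.matrix(z_batch)
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (epsilon == 0) return(0)
  if (is.null(delta))
    delta <- matrix(stats::rnorm(length(z)), nrow(z), ncol(z))
  dbar <- delta / pmax(sqrt(rowSums(delta^2)), 1e-12)
  x0 <- mlp_forward(generator, z)$out
  x1 <- mlp_forward(generator, z + epsilon * dbar)$out
  f0 <- classifier_features(classifier, x0, feature)$phi
  f1 <- classifier_features(classifier, x1, feature)$phi
  mean(rowSums((f1 - f0)^2))
}

#' Combined discriminator loss
#'
#' `alpha * L1 + beta * L2 + gamma * Psi` per the configured weights;
#' degenerate weights reduce it to the corresponding single term.
#'
#' @param L1,L2,Psi the three loss components (see [supervised_loss()],
#'   [adversarial_b_loss()], [manifold_penalty()]).
#' @param config a [gan_config()] supplying the weights.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(L1, L2, Psi, config) {
  stopifnot(inherits(config, "gan_config"))
  config$alpha * L1 + config$beta * L2 + config$gamma * Psi
}

## ---- small MLP machinery ----------------------------------------------------

mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (i in seq_len(L)) {
    W[[i]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1L], 0,
                                  sqrt(1 / sizes[i])),
                     sizes[i], sizes[i + 1L])
    b[[i]] <- numeric(sizes[i + 1L])
  }
  list(W = W, b = b, sizes = sizes)
}

# forward pass; tanh on hidden layers, linear output
mlp_forward <- function(par, X) {
  X <- as.matrix(X)
  L <- length(par$W)
  h <- vector("list", L + 1L)
  h[[1L]] <- X
  for (i in seq_len(L)) {
    a <- h[[i]] %*% par$W[[i]]
    a <- sweep(a, 2L, par$b[[i]], `+`)
    h[[i + 1L]] <- if (i < L) tanh(a) else a
  }
  list(out = h[[L + 1L]], h = h)
}

# backward pass given dL/d(out); returns parameter grads and dL/dX
mlp_backward <- function(par, cache, dout) {
  L <- length(par$W)
  dW <- vector("list", L); db <- vector("list", L)
  d <- as.matrix(dout)
  for (i in rev(seq_len(L))) {
    if (i < L) d <- d * (1 - cache$h[[i + 1L]]^2)   # through tanh
    dW[[i]] <- crossprod(cache$h[[i]], d)
    db[[i]] <- colSums(d)
    d <- d %*% t(par$W[[i]])
  }
  list(dW = dW, db = db, dX = d)
}

classifier_features <- function(clf, X, feature) {
  fw <- mlp_forward(clf, X)
  phi <- if (feature == "softmax") class_probabilities(fw$out)
         else cache_hidden(fw)
  list(phi = phi, fw = fw)
}

cache_hidden <- function(fw) fw$h[[length(fw$h) - 1L]]

# backprop d(loss)/d(phi) through the feature map to params and input
features_backward <- function(clf, fw, dphi, feature) {
  if (feature == "softmax") {
    p <- class_probabilities(fw$out)
    dlog <- p * (dphi - rowSums(dphi * p))
    mlp_backward(clf, fw, dlog)
  } else {
    # phi is the post-tanh hidden layer: the last linear layer gets no
    # gradient, everything below does
    L <- length(clf$W)
    dW <- vector("list", L); db <- vector("list", L)
    dW[[L]] <- matrix(0, nrow(clf$W[[L]]), ncol(clf$W[[L]]))
    db[[L]] <- numeric(length(clf$b[[L]]))
    d <- dphi * (1 - fw$h[[L]]^2)
    for (i in rev(seq_len(L - 1L))) {
      dW[[i]] <- crossprod(fw$h[[i]], d)
      db[[i]] <- colSums(d)
      d <- d %*% t(clf$W[[i]])
      if (i > 1L) d <- d * (1 - fw$h[[i]]^2)
    }
    list(dW = dW, db = db, dX = d)
  }
}

adam_init <- function(par) {
  zero <- function(x) lapply(x, function(v) v * 0)
  list(mW = zero(par$W), vW = zero(par$W),
       mb = zero(par$b), vb = zero(par$b), t = 0L)
}

adam_step <- function(par, grads, opt, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (i in seq_along(par$W)) {
    opt$mW[[i]] <- b1 * opt$mW[[i]] + (1 - b1) * grads$dW[[i]]
    opt$vW[[i]] <- b2 * opt$vW[[i]] + (1 - b2) * grads$dW[[i]]^2
    opt$mb[[i]] <- b1 * opt$mb[[i]] + (1 - b1) * grads$db[[i]]
    opt$vb[[i]] <- b2 * opt$vb[[i]] + (1 - b2) * grads$db[[i]]^2
    mhW <- opt$mW[[i]] / (1 - b1^opt$t); vhW <- opt$vW[[i]] / (1 - b2^opt$t)
    mhb <- opt$mb[[i]] / (1 - b1^opt$t); vhb <- opt$vb[[i]] / (1 - b2^opt$t)
    par$W[[i]] <- par$W[[i]] - lr * mhW / (sqrt(vhW) + eps)
    par$b[[i]] <- par$b[[i]] - lr * mhb / (sqrt(vhb) + eps)
  }
  list(par = par, opt = opt)
}

add_grads <- function(...) {
  gs <- list(...)
  gs <- Filter(Negate(is.null), gs)
  out <- gs[[1L]]
  if (length(gs) > 1L) for (g in gs[-1L]) {
    for (i in seq_along(out$dW)) {
      out$dW[[i]] <- out$dW[[i]] + g$dW[[i]]
      out$db[[i]] <- out$db[[i]] + g$db[[i]]
    }
  }
  out
}

scale_grads <- function(g, s) {
  g$dW <- lapply(g$dW, `*`, s); g$db <- lapply(g$db, `*`, s); g
}

zero_grads <- function(par) {
  list(dW = lapply(par$W, function(w) w * 0),
       db = lapply(par$b, function(b) b * 0))
}

## ---- training ---------------------------------------------------------------

#' Train the semi-supervised adversarial classifier
#'
#' Alternates one discriminator update (the weighted sum of supervised,
#' adversarial, and manifold gradients) and one generator update
#' (feature-matching gradient) per mini-batch. Epochs before
#' `mode_switch_frac * epochs` use the `mean_activation` discriminator
#' probability, later epochs the `logsum` form. Deterministic for a fixed
#' seed: the seed drives parameter init, shuffling, latent draws, and the
#' manifold disturbances, and the caller's RNG state is restored on exit.
#'
#' @param x n x d numeric matrix of feature vectors.
#' @param labels length-n labels; `NA` marks unlabelled samples. At least
#'   one labelled sample of each class is required.
#' @param config a [gan_config()].
#' @return A `train_state`: `generator` and `classifier` parameter sets,
#'   `classes` (label levels in index order), per-epoch `trace` of L1, L2,
#'   Psi and the feature-matching loss, and the `config` (with its seed)
#'   for exact reload.
#' @export
train_ssgan <- function(x, labels, config = gan_config()) {
  stopifnot(inherits(config, "gan_config"))
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  lab_chr <- as.character(labels)
  classes <- sort(unique(lab_chr[!is.na(lab_chr)]))
  if (length(classes) < 2L) stop("need labelled samples from >= 2 classes")
  y <- match(lab_chr, classes)            # NA for unlabelled
  K <- length(classes)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  gen <- mlp_init(c(config$z_dim, config$gen_hidden, d))
  clf <- mlp_init(c(d, config$clf_hidden, K))
  opt_g <- adam_init(gen); opt_c <- adam_init(clf)
  switch_epoch <- ceiling(config$mode_switch_frac * config$epochs)
  trace <- matrix(NA_real_, config$epochs, 4L,
                  dimnames = list(NULL, c("L1", "L2", "Psi", "FM")))

  for (ep in seq_len(config$epochs)) {
    mode <- if (ep <= switch_epoch) "mean_activation" else "logsum"
    ord <- sample.int(n)
    nb <- max(1L, floor(n / config$batch_size))
    splits <- split(ord, rep(seq_len(nb), length.out = n))
    ep_loss <- c(L1 = 0, L2 = 0, Psi = 0, FM = 0)
    for (batch in splits) {
      xb <- x[batch, , drop = FALSE]
      yb <- y[batch]
      m <- length(batch)
      ## ---- discriminator step
      z <- matrix(stats::rnorm(m * config$z_dim), m, config$z_dim)
      gfw <- mlp_forward(gen, z)
      xg <- gfw$out
      fw_real <- mlp_forward(clf, xb)
      fw_fake <- mlp_forward(clf, xg)
      grads <- zero_grads(clf)
      L1 <- 0
      lab_idx <- which(!is.na(yb))
      if (length(lab_idx)) {
        fw_lab <- list(out = fw_real$out[lab_idx, , drop = FALSE],
                       h = lapply(fw_real$h, function(h) h[lab_idx, , drop = FALSE]))
        L1 <- supervised_loss(fw_lab$out, yb[lab_idx])
        g1 <- mlp_backward(clf, fw_lab, supervised_loss_grad(fw_lab$out, yb[lab_idx]))
        grads <- add_grads(grads, scale_grads(g1, config$alpha))
      }
      L2 <- adversarial_b_loss(fw_real$out, fw_fake$out, mode)
      g2g <- adversarial_b_loss_grad(fw_real$out, fw_fake$out, mode)
      g2 <- add_grads(mlp_backward(clf, fw_real, g2g$real),
                      mlp_backward(clf, fw_fake, g2g$fake))
      grads <- add_grads(grads, scale_grads(g2, config$beta))
      Psi <- 0
      if (config$gamma > 0 && config$epsilon > 0) {
        delta <- matrix(stats::rnorm(m * config$z_dim), m, config$z_dim)
        dbar <- delta / pmax(sqrt(rowSums(delta^2)), 1e-12)
        x1 <- mlp_forward(gen, z + config$epsilon * dbar)$out
        cf0 <- classifier_features(clf, xg, config$feature)
        cf1 <- classifier_features(clf, x1, config$feature)
        diff <- cf1$phi - cf0$phi
        Psi <- mean(rowSums(diff^2))
        g3 <- add_grads(
          features_backward(clf, cf1$fw, 2 * diff / m, config$feature),
          features_backward(clf, cf0$fw, -2 * diff / m, config$feature))
        grads <- add_grads(grads, scale_grads(g3, config$gamma))
      }
      st <- adam_step(clf, grads, opt_c, config$lr)
      clf <- st$par; opt_c <- st$opt
      ## ---- generator step (feature matching)
      FM <- 0
      if (m >= 2L) {
        z2 <- matrix(stats::rnorm(m * config$z_dim), m, config$z_dim)
        gfw2 <- mlp_forward(gen, z2)
        cr <- classifier_features(clf, xb, config$feature)
        cf <- classifier_features(clf, gfw2$out, config$feature)
        FM <- feature_matching_loss(cr$phi, cf$phi)
        dphi <- feature_matching_grad_fake(cr$phi, cf$phi)
        dxg <- features_backward(clf, cf$fw, dphi, config$feature)$dX
        gg <- mlp_backward(gen, gfw2, dxg)
        st <- adam_step(gen, gg, opt_g, config$lr)
        gen <- st$par; opt_g <- st$opt
      }
      ep_loss <- ep_loss + c(L1, L2, Psi, FM)
    }
    trace[ep, ] <- ep_loss / length(splits)
    if (any(!is.finite(trace[ep, ])))
      stop("non-finite loss at epoch ", ep, ": ",
           paste(sprintf("%s=%g", colnames(trace), trace[ep, ]), collapse = ", "))
  }
  structure(list(generator = gen, classifier = clf, classes = classes,
                 trace = as.data.frame(trace), config = config,
                 feature_dim = d),
            class = "train_state")
}

#' Predict class labels and probabilities
#'
#' Softmax argmax of the trained classifier; ties break toward the lower
#' class index.
#'
#' @param state a `train_state` from [train_ssgan()].
#' @param x n x d matrix with `d` matching the training features.
#' @return List with `labels` (character), `index` (class indices), and
#'   `probabilities` (n x K matrix, rows summing to 1).
#' @export
predict_spiculation <- function(state, x) {
  stopifnot(inherits(state, "train_state"))
  x <- as.matrix(x)
  if (ncol(x) != state$feature_dim)
    stop("input has ", ncol(x), " features; the model was trained with ",
         state$feature_dim)
  p <- class_probabilities(mlp_forward(state$classifier, x)$out)
  idx <- apply(p, 1L, function(r) which(r == max(r))[1L])
  list(labels = state$classes[idx], index = idx, probabilities = p)
}

#' Serialize / load a trained model as JSON
#'
#' Plain-text round trip of the `train_state` (parameters, classes,
#' config incl. seed) for exact reload.
#'
#' @param state a `train_state`. @param path JSON file path.
#' @return `path` (save) or the restored `train_state` (load).
#' @export
save_train_state <- function(state, path) {
  stopifnot(inherits(state, "train_state"))
  ser <- list(generator = lapply(state$generator[c("W", "b")], lapply, as.vector),
              gen_sizes = state$generator$sizes,
              classifier = lapply(state$classifier[c("W", "b")], lapply, as.vector),
              clf_sizes = state$classifier$sizes,
              classes = state$classes, feature_dim = state$feature_dim,
              config = unclass(state$config), trace = state$trace)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_train_state
#' @export
load_train_state <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = FALSE)
  rebuild <- function(p, sizes) {
    sizes <- as.integer(unlist(sizes))
    L <- length(sizes) - 1L
    W <- vector("list", L); b <- vector("list", L)
    for (i in seq_len(L)) {
      W[[i]] <- matrix(as.numeric(unlist(p$W[[i]])), sizes[i], sizes[i + 1L])
      b[[i]] <- as.numeric(unlist(p$b[[i]]))
    }
    list(W = W, b = b, sizes = sizes)
  }
  cfg <- do.call(gan_config, lapply(s$config, function(v)
    if (length(v) == 1L) v[[1]] else unlist(v)))
  trace <- as.data.frame(lapply(s$trace, unlist))
  structure(list(generator = rebuild(s$generator, s$gen_sizes),
                 classifier = rebuild(s$classifier, s$clf_sizes),
                 classes = unlist(s$classes), trace = trace,
                 config = cfg, feature_dim = as.integer(s$feature_dim)),
            class = "train_state")
}
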