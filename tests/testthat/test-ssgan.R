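test_that("softmax probabilities match closed forms and stay normalised", {
  expect_equal(class_probabilities(c(0, 0)), c(0.5, 0.5))
  expect_equal(class_probabilities(c(log(2), 0)), c(2/3, 1/3))
  set.seed(1)
  l <- matrix(rnorm(40, 0, 2), 10, 4)
  p <- class_probabilities(l)
  naive <- exp(l) / rowSums(exp(l))      # safe at low magnitude
  expect_equal(p, naive, tolerance = 1e-12)
  expect_equal(rowSums(p), rep(1, 10))
  # stability at magnitude 1e3
  big <- matrix(c(1000, -1000, 980, 990), 2, 2)
  pb <- class_probabilities(big)
  expect_true(all(is.finite(pb)))
  expect_equal(rowSums(pb), c(1, 1))
})

test_that("discriminator probabilities follow their two closed forms", {
  expect_equal(disc_prob(c(0, 0), "logsum"), 2/3)          # Z = 2
  expect_equal(disc_prob(c(0, 0), "mean_activation"), 0.5)
  expect_lt(disc_prob(c(-50, -50), "logsum"), 1e-6)
  expect_lt(disc_prob(c(-50, -50), "mean_activation"), 1e-6)
  # logsum identity computed two independent ways
  set.seed(2)
  l <- matrix(rnorm(30), 10, 3)
  Z <- rowSums(exp(l))
  expect_equal(disc_prob(l, "logsum"), Z / (1 + Z), tolerance = 1e-9)
  expect_true(all(disc_prob(matrix(rnorm(10) * 1000, 5, 2), "logsum") >= 0))
})

test_that("unsupervised and supervised losses match spot values and oracles", {
  z1 <- matrix(0, 4, 1)
  expect_equal(unsupervised_loss(z1, z1), 2 * log(2), tolerance = 1e-12)
  # perfect-discrimination limit
  expect_lt(unsupervised_loss(matrix(50, 3, 1), matrix(-50, 3, 1)), 1e-6)
  # naive-formula oracle at moderate magnitude
  set.seed(3)
  lr_ <- matrix(rnorm(12), 4, 3); lf <- matrix(rnorm(12), 4, 3)
  naive <- mean(log(1 + rowSums(exp(lf)))) -
    mean(log(rowSums(exp(lr_))) - log(1 + rowSums(exp(lr_))))
  expect_equal(unsupervised_loss(lr_, lf), naive, tolerance = 1e-9)

  expect_equal(supervised_loss(matrix(0, 1, 2), 1), log(2))
  conf <- matrix(c(20, -20), 1, 2)
  expect_lt(supervised_loss(conf, 1), 1e-3)
  # batch mean equals mean of per-sample losses
  l <- matrix(rnorm(10), 5, 2); y <- sample(1:2, 5, TRUE)
  per <- vapply(1:5, function(i) supervised_loss(l[i, , drop = FALSE], y[i]), 0)
  expect_equal(supervised_loss(l, y), mean(per))
  expect_error(supervised_loss(l, c(1, 2, 3, 1, 1) * 3L), "1..K")
})

test_that("adversarial loss hits its closed form and its gradient checks out", {
  z <- matrix(0, 3, 2)
  expect_equal(adversarial_b_loss(z, z, "mean_activation"), 2 * log(2))
  # perfect real/fake separation drives the loss to zero
  expect_lt(adversarial_b_loss(matrix(60, 2, 2), matrix(-60, 2, 2), "logsum"),
            1e-6)
  set.seed(4)
  for (mode in c("logsum", "mean_activation")) {
    lr_ <- matrix(rnorm(8), 4, 2); lf <- matrix(rnorm(8), 4, 2)
    g <- spicnet:::adversarial_b_loss_grad(lr_, lf, mode)
    eps <- 1e-6
    for (k in 1:5) {
      i <- sample(length(lr_), 1)
      lp <- lr_; lp[i] <- lp[i] + eps; lm <- lr_; lm[i] <- lm[i] - eps
      num <- (adversarial_b_loss(lp, lf, mode) -
              adversarial_b_loss(lm, lf, mode)) / (2 * eps)
      expect_lt(abs(num - g$real[i]) / max(abs(num), 1e-8), 1e-5)
      i <- sample(length(lf), 1)
      fp <- lf; fp[i] <- fp[i] + eps; fm <- lf; fm[i] <- fm[i] - eps
      num <- (adversarial_b_loss(lr_, fp, mode) -
              adversarial_b_loss(lr_, fm, mode)) / (2 * eps)
      expect_lt(abs(num - g$fake[i]) / max(abs(num), 1e-8), 1e-5)
    }
  }
})

test_that("supervised and unsupervised gradients match finite differences", {
  set.seed(5)
  l <- matrix(rnorm(12), 4, 3); y <- sample(1:3, 4, TRUE)
  g <- spicnet:::supervised_loss_grad(l, y)
  eps <- 1e-6
  for (k in 1:6) {
    i <- sample(length(l), 1)
    lp <- l; lp[i] <- lp[i] + eps; lm <- l; lm[i] <- lm[i] - eps
    num <- (supervised_loss(lp, y) - supervised_loss(lm, y)) / (2 * eps)
    expect_lt(abs(num - g[i]) / max(abs(num), 1e-8), 1e-5)
  }
  lr_ <- matrix(rnorm(12), 4, 3); lf <- matrix(rnorm(12), 4, 3)
  gu <- spicnet:::unsupervised_loss_grad(lr_, lf)
  for (k in 1:6) {
    i <- sample(length(lr_), 1)
    lp <- lr_; lp[i] <- lp[i] + eps; lm <- lr_; lm[i] <- lm[i] - eps
    num <- (unsupervised_loss(lp, lf) - unsupervised_loss(lm, lf)) / (2 * eps)
    expect_lt(abs(num - gu$real[i]) / max(abs(num), 1e-8), 1e-5)
  }
})

test_that("feature matching matches a direct two-pass computation", {
  set.seed(6)
  fr <- matrix(rnorm(20), 5, 4); ff <- matrix(rnorm(20), 5, 4)
  expect_equal(feature_matching_loss(fr, fr), 0)
  shift <- sweep(fr, 2, c(1, -2, 0.5, 3), `+`)
  expect_equal(feature_matching_loss(fr, shift), sum(c(1, -2, 0.5, 3)^2),
               tolerance = 1e-10)
  direct <- sum((colMeans(fr) - colMeans(ff))^2) +
    sum((apply(fr, 2, sd) - apply(ff, 2, sd))^2)
  expect_equal(feature_matching_loss(fr, ff), direct, tolerance = 1e-10)
  expect_error(feature_matching_loss(fr[1, , drop = FALSE], ff), ">= 2")
})

test_that("the manifold penalty vanishes when it must and matches a linear oracle", {
  set.seed(7)
  gen <- spicnet:::mlp_init(c(2, 4, 3))
  clf <- spicnet:::mlp_init(c(3, 4, 2))
  z <- matrix(rnorm(10), 5, 2)
  expect_equal(manifold_penalty(gen, clf, z, epsilon = 0), 0)
  # constant generator: weights zero, so G ignores z entirely
  cgen <- gen
  cgen$W <- lapply(cgen$W, function(w) w * 0)
  expect_equal(manifold_penalty(cgen, clf, z, epsilon = 0.5), 0)

  # linear generator + linear classifier: Psi ~ eps^2 * mean ||J dbar||^2
  A <- matrix(rnorm(6), 2, 3)                 # generator matrix
  C <- matrix(rnorm(6), 3, 2)                 # classifier logit matrix
  glin <- list(W = list(A), b = list(numeric(3)), sizes = c(2, 3))
  clin <- list(W = list(C), b = list(numeric(2)), sizes = c(3, 2))
  zl <- matrix(rnorm(200), 100, 2)
  dl <- matrix(rnorm(200), 100, 2)
  eps <- 1e-3
  got <- manifold_penalty(glin, clin, zl, eps, delta = dl)
  dbar <- dl / sqrt(rowSums(dl^2))
  # analytic Jacobian of softmax(z A C) wrt z, applied to eps*dbar
  pred <- mean(vapply(seq_len(nrow(zl)), function(i) {
    p <- drop(class_probabilities(zl[i, ] %*% A %*% C))
    Js <- diag(p) - tcrossprod(p)             # softmax Jacobian
    sum((eps * drop(dbar[i, ] %*% A %*% C) %*% Js)^2)
  }, 0))
  expect_lt(abs(got - pred) / pred, 0.05)
})

test_that("the combined discriminator loss is the stated convex combination", {
  cfg <- gan_config(alpha = 0.5, beta = 0.3, gamma = 0.2)
  expect_equal(discriminator_loss(1.2, 0.6, 3, cfg),
               0.5 * 1.2 + 0.3 * 0.6 + 0.2 * 3, tolerance = 1e-12)
  expect_equal(discriminator_loss(0, 0, 0, cfg), 0)
  cfg1 <- gan_config(alpha = 1, beta = 0, gamma = 0)
  expect_equal(discriminator_loss(0.77, 5, 9, cfg1), 0.77)
  expect_error(gan_config(alpha = 0.5, beta = 0.5, gamma = 0.2), "sum to 1")
})

test_that("discriminator parameter gradients agree with finite differences", {
  set.seed(8)
  d <- 3; n <- 6
  clf <- spicnet:::mlp_init(c(d, 4, 2))
  gen <- spicnet:::mlp_init(c(2, 4, d))
  xb <- matrix(rnorm(n * d), n, d); yb <- sample(1:2, n, TRUE)
  z <- matrix(rnorm(n * 2), n, 2); delta <- matrix(rnorm(n * 2), n, 2)
  cfg <- gan_config()
  loss_at <- function(cl) {
    fr <- spicnet:::mlp_forward(cl, xb)
    xg <- spicnet:::mlp_forward(gen, z)$out
    ff <- spicnet:::mlp_forward(cl, xg)
    discriminator_loss(
      supervised_loss(fr$out, yb),
      adversarial_b_loss(fr$out, ff$out, "mean_activation"),
      manifold_penalty(gen, cl, z, cfg$epsilon, delta), cfg)
  }
  fr <- spicnet:::mlp_forward(clf, xb)
  xg <- spicnet:::mlp_forward(gen, z)$out
  ff <- spicnet:::mlp_forward(clf, xg)
  g1 <- spicnet:::mlp_backward(clf, fr, spicnet:::supervised_loss_grad(fr$out, yb))
  ag <- spicnet:::adversarial_b_loss_grad(fr$out, ff$out, "mean_activation")
  g2 <- spicnet:::add_grads(spicnet:::mlp_backward(clf, fr, ag$real),
                            spicnet:::mlp_backward(clf, ff, ag$fake))
  dbar <- delta / sqrt(rowSums(delta^2))
  x1 <- spicnet:::mlp_forward(gen, z + cfg$epsilon * dbar)$out
  cf0 <- spicnet:::classifier_features(clf, xg, "softmax")
  cf1 <- spicnet:::classifier_features(clf, x1, "softmax")
  df <- cf1$phi - cf0$phi
  g3 <- spicnet:::add_grads(
    spicnet:::features_backward(clf, cf1$fw, 2 * df / n, "softmax"),
    spicnet:::features_backward(clf, cf0$fw, -2 * df / n, "softmax"))
  G <- spicnet:::add_grads(spicnet:::scale_grads(g1, cfg$alpha),
                           spicnet:::scale_grads(g2, cfg$beta),
                           spicnet:::scale_grads(g3, cfg$gamma))
  eps <- 1e-6
  for (li in 1:2) for (k in 1:5) {
    i <- sample(length(clf$W[[li]]), 1)
    cp <- clf; cp$W[[li]][i] <- cp$W[[li]][i] + eps
    cm <- clf; cm$W[[li]][i] <- cm$W[[li]][i] - eps
    num <- (loss_at(cp) - loss_at(cm)) / (2 * eps)
    expect_lt(abs(num - G$dW[[li]][i]) / max(abs(num), 1e-7), 1e-5)
  }
})

test_that("semi-supervised training separates a toy problem and is deterministic", {
  set.seed(0)
  n <- 200
  x <- rbind(matrix(rnorm(n, 2, 0.7), n / 2, 2),
             matrix(rnorm(n, -2, 0.7), n / 2, 2))
  truth <- rep(c("spiculated", "non-spiculated"), each = n / 2)
  lab <- truth
  keep <- c(sample(1:100, 10), sample(101:200, 10))   # 10% labelled
  lab[setdiff(1:n, keep)] <- NA
  st <- train_ssgan(x, lab, gan_config(epochs = 200, seed = 0))
  expect_true(all(is.finite(as.matrix(st$trace))))

  set.seed(99)
  xt <- rbind(matrix(rnorm(100, 2, 0.7), 50, 2),
              matrix(rnorm(100, -2, 0.7), 50, 2))
  tt <- rep(c("spiculated", "non-spiculated"), each = 50)
  acc <- mean(predict_spiculation(st, xt)$labels == tt)
  expect_gte(acc, 0.95)

  # gamma = beta = 0 reduces to supervised training; accuracy within 2 pts
  st_sup <- train_ssgan(x, lab, gan_config(alpha = 1, beta = 0, gamma = 0,
                                           epochs = 200, seed = 0))
  acc_sup <- mean(predict_spiculation(st_sup, xt)$labels == tt)
  expect_lte(abs(acc - acc_sup), 0.02 + 1e-9)

  # identical seed, identical loss traces
  s1 <- train_ssgan(x, lab, gan_config(epochs = 40, seed = 123))
  s2 <- train_ssgan(x, lab, gan_config(epochs = 40, seed = 123))
  expect_identical(s1$trace, s2$trace)

  expect_error(train_ssgan(x, rep(NA, n), gan_config()), "2 classes")
})

test_that("prediction is batch-invariant, normalised, and reloads exactly", {
  set.seed(10)
  x <- matrix(rnorm(60), 30, 2)
  lab <- rep(c("spiculated", "non-spiculated"), 15)
  st <- train_ssgan(x, lab, gan_config(epochs = 30, seed = 1, batch_size = 8))
  pr <- predict_spiculation(st, x)
  expect_equal(rowSums(pr$probabilities), rep(1, 30))
  one <- predict_spiculation(st, x[7, , drop = FALSE])
  expect_equal(one$labels, pr$labels[7])

  path <- withr::local_tempfile(fileext = ".json")
  save_train_state(st, path)
  back <- load_train_state(path)
  expect_equal(predict_spiculation(back, x)$probabilities,
               pr$probabilities, tolerance = 1e-12)
  expect_error(predict_spiculation(st, matrix(0, 2, 5)), "features")
})
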