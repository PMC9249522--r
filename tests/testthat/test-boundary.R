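test_that("a centred disk unfolds to a near-constant series starting at its minimum", {
  m <- disk_mask(41, 10)
  s <- unfold_boundary(m, 360)
  expect_length(s$rho, 360L)
  expect_true(all(abs(s$rho - 10) <= 0.5))
  expect_equal(which.min(s$rho), 1L)
  expect_true(all(s$rho >= 0))
})

test_that("a radial spike shows up at the right angle with the right height", {
  m <- disk_mask(41, 10)
  # single-pixel-wide spike of length 5 toward angle 90 degrees (+y)
  for (k in 1:5) m[21 + 10 + k, 21] <- 1
  s <- unfold_boundary(m, 360)
  excess <- max(s$rho) - stats::median(s$rho)
  expect_gte(excess, 4); expect_lte(excess, 6)
  # argmax angle: index in the unrotated frame should be near 90 degrees
  orig_idx <- (which.max(s$rho) - 1 + (s$rotation - 1)) %% 360 + 1
  ang <- (orig_idx - 1)                       # degrees, clockwise from +x
  expect_lte(min(abs(ang - 90), 360 - abs(ang - 90)), 2)
})

test_that("an ellipse unfolds to its analytic polar radius", {
  a <- 14; b <- 8
  m <- ellipse_mask(41, a, b)
  s <- unfold_boundary(m, 360)
  th <- 2 * pi * (0:359) / 360
  r_true <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  r_true <- r_true[c(s$rotation:360, seq_len(s$rotation - 1))]
  expect_lt(max(abs(s$rho - r_true)), 0.75)
})

test_that("unfolding rejects empty, fragmented, or tiny masks", {
  expect_error(unfold_boundary(matrix(0, 10, 10)), "empty")
  frag <- matrix(0, 20, 20); frag[3:6, 3:6] <- 1; frag[15:18, 15:18] <- 1
  expect_error(unfold_boundary(frag), "exactly one")
  tiny <- matrix(0, 10, 10); tiny[5, 5:7] <- 1
  expect_error(unfold_boundary(tiny), "at least 5")
})

test_that("rotating the mask only rotates the unfolded series", {
  sp <- clean_spec(seed = 5, radius = 8, n_spicules = 3)
  m <- make_nodule_phantom(sp)$mask[21, , ]
  s1 <- unfold_boundary(m, 360)
  # 90 degree rotation of the image grid
  m90 <- t(m)[, rev(seq_len(nrow(m)))]
  s2 <- unfold_boundary(m90, 360)
  # start-point normalisation should re-align the two series up to
  # interpolation noise; compare sorted values
  expect_lt(max(abs(sort(s1$rho) - sort(s2$rho))), 0.75)
})

test_that("protuberance extraction filters, orders, and concatenates runs", {
  expect_length(extract_protuberances(rep(5, 100), 2)$segments, 0L)

  bump <- c(rep(0, 40), rep(5, 10), rep(0, 50))
  p <- extract_protuberances(bump, 2)
  expect_length(p$segments, 1L)
  expect_true(all(p$segments[[1]]$values == 5))
  expect_equal(p$values, rep(5, 10))

  four <- rep(0, 120)
  four[11:14] <- 8; four[41:44] <- 6; four[71:74] <- 4; four[101:104] <- 2
  p4 <- extract_protuberances(four, 3)
  expect_length(p4$segments, 3L)
  expect_equal(vapply(p4$segments, `[[`, 0, "prominence"), c(8, 6, 4))

  # circular adjacency: an excursion wrapping the end joins up
  wrap <- rep(0, 60); wrap[58:60] <- 7; wrap[1:3] <- 7
  pw <- extract_protuberances(wrap, 2)
  expect_length(pw$segments, 1L)
  expect_length(pw$segments[[1]]$values, 6L)
})

test_that("DTW equals the brute-force warping-path minimum on small cases", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtw_distance(0, 3), 3)
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 3)),
               dtw_brute(c(1, 2, 3), c(1, 3)))
  set.seed(404)
  for (i in 1:50) {
    P <- round(stats::runif(sample(1:6, 1), 0, 10), 1)
    Q <- round(stats::runif(sample(1:6, 1), 0, 10), 1)
    expect_equal(dtw_distance(P, Q), dtw_brute(P, Q))
    expect_equal(dtw_distance(P, Q), dtw_distance(Q, P))  # symmetry
    expect_gte(dtw_distance(P, Q), 0)
  }
  expect_error(dtw_distance(numeric(0), 1), "nonempty")
})

test_that("DTW k-NN classification on phantom boundary series separates classes", {
  # reference database from ground-truth mid-axial masks (20 entries)
  series_of <- function(sample) {
    extract_protuberances(unfold_boundary(sample$mask[21, , ], 360), 2)$values
  }
  base <- clean_spec(seed = 1)
  db_samples <- make_phantom_dataset(10, 10, base, seed = 31)
  db <- reference_db(lapply(db_samples, series_of),
                     vapply(db_samples, `[[`, "", "label"))

  expect_error(dtw_classify(1:3, db, k = 2), "odd")

  # self-match: an entry classified against a db containing it, k = 1
  self <- dtw_classify(db$series[[1]], db, k = 1)
  expect_equal(self$label, db$labels[1])
  expect_equal(self$score, 0)

  # empty sample series is non-spiculated by convention
  empty <- extract_protuberances(rep(3, 60), 2)
  res <- dtw_classify(empty, db, k = 3)
  expect_equal(res$label, "non-spiculated")
  expect_equal(res$score, Inf)

  # held-out phantoms, k = 3
  held <- make_phantom_dataset(5, 5, base, seed = 77)
  pred <- vapply(held, function(s) dtw_classify(series_of(s), db, 3)$label, "")
  truth <- vapply(held, `[[`, "", "label")
  expect_gte(sum(pred == truth), 8L)
})

test_that("reference databases round-trip through CSV", {
  db <- reference_db(list(c(1.5, 2, 0.5), numeric(0), 4),
                     c("spiculated", "non-spiculated", "spiculated"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_db(db, path)
  back <- read_reference_db(path)
  expect_equal(back$labels, db$labels)
  expect_equal(back$series, db$series)
})

test_that("series resampling yields fixed-length features", {
  expect_equal(resample_series(numeric(0), 8), rep(0, 8))
  expect_equal(resample_series(5, 4), rep(5, 4))
  v <- resample_series(c(0, 10), 11)
  expect_equal(v, seq(0, 10, by = 1))
  expect_length(resample_series(stats::runif(100), 64), 64L)
})
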