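# Independent oracles and small programmatic fixtures shared across tests.

# exhaustive DTW: enumerate every monotone warping path (steps right, down,
# diagonal) and take the minimal cumulative |P_i - Q_j|; tractable for
# lengths <= 6
dtw_brute <- function(P, Q) {
  n <- length(P); m <- length(Q)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + abs(P[i] - Q[j])
    if (acc >= best) return(invisible())
    if (i == n && j == m) { best <<- acc; return(invisible()) }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
    invisible()
  }
  walk(1, 1, 0)
  best
}

# filled digital disk mask (rows = y, cols = x), 1-based centre
disk_mask <- function(n, r, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  yy <- row(matrix(0, n, n)); xx <- col(matrix(0, n, n))
  ((yy - cy)^2 + (xx - cx)^2 <= r^2) + 0
}

# filled digital ellipse with semi-axes a (along x) and b (along y)
ellipse_mask <- function(n, a, b, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  yy <- row(matrix(0, n, n)); xx <- col(matrix(0, n, n))
  (((xx - cx) / a)^2 + ((yy - cy) / b)^2 <= 1) + 0
}

# noiseless, texture-free phantom spec at a small odd-sized grid so the
# mid-axial slice passes exactly through the nodule centre
clean_spec <- function(seed, radius = 9, n_spicules = 0) {
  phantom_spec(shape = c(41L, 41L, 41L), radius = radius,
               n_spicules = n_spicules, spicule_elev_deg = 0,
               noise_sigma = 0, texture_amp = 0, seed = seed)
}

# concordance-count AUC: fraction of (positive, negative) pairs ranked
# correctly, ties counted half
auc_concordance <- function(scores, labels) {
  pos <- scores[labels > 0]; neg <- scores[labels <= 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}
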