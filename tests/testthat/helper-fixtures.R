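# Shared fixtures and independent oracles for the test suite.

# one deterministic subject with a size-7 foot
tiny_profile <- function(seed = 2) {
  generate_cohort(1, c("7" = 1), seed = seed)[[1]]
}

# hand-built pressure sequence around an arbitrary frame stack
make_seq <- function(frames, subject_id = 1, condition = "I",
                     round_id = 1) {
  storage.mode(frames) <- "integer"
  structure(list(frames = frames, subject_id = subject_id,
                 trial_id = "T", condition = condition, load_g = 0,
                 round_id = round_id, geometry = mat_geometry(),
                 truth = NULL),
            class = "pressure_seq")
}

# quadrant maps: class k has its hot block in quadrant k (linearly separable)
toy_quadrant_maps <- function(n_per_class, n_classes = 2, seed = 1) {
  stopifnot(n_classes <= 4)
  qs <- list(list(1:16, 1:16), list(17:32, 17:32),
             list(1:16, 17:32), list(17:32, 1:16))
  n <- n_per_class * n_classes
  x <- array(0, c(n, 32, 32))
  y <- rep(seq_len(n_classes), each = n_per_class)
  set.seed(seed)
  for (i in seq_len(n)) {
    q <- qs[[y[i]]]
    x[i, q[[1]], q[[2]]] <- matrix(runif(256, 50, 150), 16, 16)
  }
  list(x = x, y = y)
}

# brute-force 8-connected components of a logical mask (BFS; independent of
# the EBImage-based path in extract_rois)
brute_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r < 1 || c < 1 || r > nrow(mask) || c > ncol(mask)) next
        if (mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# dense-grid brute-force EER oracle: FAR/FRR evaluated on a dense threshold
# grid by explicit comparison, crossing interpolated linearly
brute_eer <- function(genuine, impostor, n_grid = 1e5) {
  lo <- min(genuine, impostor) - 0.01
  hi <- max(genuine, impostor) + 0.01
  grid <- seq(lo, hi, length.out = n_grid)
  far_c <- rowMeans(outer(grid, impostor, FUN = function(t, s) s >= t))
  frr_c <- rowMeans(outer(grid, genuine, FUN = function(t, s) s < t))
  d <- far_c - frr_c
  k <- which(d[-length(d)] > 0 & d[-1] <= 0)[1]
  lam <- d[k] / (d[k] - d[k + 1])
  far_c[k] + lam * (far_c[k + 1] - far_c[k])
}

# pairwise Mann-Whitney AUC estimator (ties count one half)
pairwise_auc <- function(genuine, impostor) {
  cmp <- outer(genuine, impostor, FUN = function(g, i) (g > i) + 0.5 * (g == i))
  mean(cmp)
}
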