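# Shared fixtures, all generated in code.

# Desk-scale phantom for VAE and quick pipeline checks.
small_phantom_spec <- function(seed = 1L, noise_sigma = 5) {
  phantom_spec(
    height = 32, width = 32, brain_axes = c(12, 10), skull_thickness = 2,
    core_center = c(19, 18), core_radius = 3, rim_width = 1.5,
    noise_sigma = noise_sigma, seed = seed
  )
}

# O(H*W) brute-force GLCM pair enumerator, independent of compute_glcm.
glcm_oracle <- function(img, levels, d, symmetric = FALSE) {
  q <- floor(img * levels / 256)
  q[q > levels - 1] <- levels - 1
  counts <- matrix(0L, levels, levels)
  for (r in seq_len(nrow(img))) {
    for (cc in seq_len(ncol(img))) {
      r2 <- r + d[1]
      c2 <- cc + d[2]
      if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img)) {
        a <- q[r, cc] + 1L
        b <- q[r2, c2] + 1L
        counts[a, b] <- counts[a, b] + 1L
      }
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts
}

# Random normalized 256-bin histogram with a few occupied levels.
random_histogram <- function(seed, n_levels = 12) {
  set.seed(seed)
  h <- numeric(256)
  idx <- sample(0:255, n_levels) + 1
  h[idx] <- stats::runif(n_levels)
  h / sum(h)
}

# Exhaustive within-class-variance minimizer (Otsu dual form).
within_class_oracle <- function(hist) {
  lv <- 0:255
  best_t <- NA
  best_w <- Inf
  for (t in 1:255) {
    lo <- lv < t
    w1 <- sum(hist[lo]); w2 <- sum(hist[!lo])
    if (w1 <= 0 || w2 <= 0) next
    m1 <- sum(hist[lo] * lv[lo]) / w1
    m2 <- sum(hist[!lo] * lv[!lo]) / w2
    wc <- sum(hist[lo] * (lv[lo] - m1)^2) + sum(hist[!lo] * (lv[!lo] - m2)^2)
    if (wc < best_w - 1e-12) {
      best_w <- wc
      best_t <- t
    }
  }
  best_t
}
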