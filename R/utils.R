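# Internal numeric helpers shared across modules.

# Derive a reproducible child seed from a master seed and a stage offset.
# Offsets are fixed per stage so any stage can be re-run in isolation.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1009L %% 2147483647L + as.integer(offset)
}

stage_seed_offsets <- c(
  phantom = 11L, denoise = 23L, texture = 37L, haris = 53L,
  vae = 71L, classifier = 89L, impact = 101L, benchmark = 127L
)

# Reflect-pad a matrix by `k` pixels on every side.
pad_reflect <- function(m, k) {
  if (k == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (k >= nr || k >= nc) stop("padding window exceeds image size")
  ri <- c(rev(seq_len(k) + 1L), seq_len(nr), nr - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(nc), nc - seq_len(k))
  m[ri, ci, drop = FALSE]
}

# 2-D convolution with an odd-sized kernel and reflect padding.
# Implemented as a sum of shifted submatrices: O(K^2) vectorized adds.
conv2_reflect <- function(m, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  k <- max(kh, kw) %/% 2
  p <- pad_reflect(m, k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (di in seq_len(kh)) {
    for (dj in seq_len(kw)) {
      w <- kernel[di, dj]
      if (w == 0) next
      r0 <- k + di - (kh %/% 2)   # top-left of the shifted window
      c0 <- k + dj - (kw %/% 2)
      out <- out + w * p[r0:(r0 + nr - 1L), c0:(c0 + nc - 1L)]
    }
  }
  out
}

# Normalized 2-D Gaussian kernel, half-width `half` (so (2*half+1)^2 taps).
gaussian_kernel <- function(sigma, half = 2L) {
  x <- seq.int(-half, half)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Sliding-window box mean with reflect padding (uniform kernel).
box_mean <- function(m, half) {
  n <- 2L * half + 1L
  conv2_reflect(m, matrix(1 / n^2, n, n))
}

clamp255 <- function(m) pmin(pmax(m, 0), 255)

# Largest connected component of a logical matrix (4-connectivity),
# used when cleaning probability-map regions. Flood fill via label
# propagation; fine at slice scale.
connected_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1L]; cc2 <- cc + d[2L]
        if (rr < 1L || rr > nr || cc2 < 1L || cc2 > nc) next
        q <- (cc2 - 1L) * nr + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Binary dilation by a disk of radius r (pixels), reflect-free (zeros
# outside). Used for the enhancement band in impact reporting.
dilate_disk <- function(mask, r) {
  if (r <= 0) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= r^2, ]
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    rs <- max(1L, 1L - di):min(nr, nr - di)
    cs <- max(1L, 1L - dj):min(nc, nc - dj)
    out[rs + di, cs + dj] <- out[rs + di, cs + dj] | mask[rs, cs]
  }
  out
}
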