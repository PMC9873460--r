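#' GLCM configuration
#'
#' @param levels number of grey levels `G >= 2` after uniform
#'   quantization of `[0, 255]`. Default 32 keeps the matrix
#'   well-populated on single 228x228 slices.
#' @param displacement integer `(d_row, d_col)` pixel offset, not `(0,0)`.
#' @param symmetric count each pair in both orderings.
#' @return list of class `glcm_config`.
#' @export
glcm_config <- function(levels = 32L, displacement = c(0L, 1L),
                        symmetric = FALSE) {
  levels <- as.integer(levels)
  displacement <- as.integer(displacement)
  if (levels < 2) stop("levels must be >= 2")
  if (all(displacement == 0L)) stop("displacement must be nonzero")
  structure(list(
    levels = levels, displacement = displacement, symmetric = symmetric
  ), class = "glcm_config")
}

#' Uniform grey-level quantization
#'
#' Bins `[0, 255]` into `levels` equal-width bins: level index
#' `floor(v * levels / 256)`, clipped to `levels - 1` for `v = 255` ...
#' in fact for any `v >= 255 * levels / 256`.
#'
#' @param img image matrix with values in `[0, 255]`.
#' @param levels number of levels, `>= 2`.
#' @return integer matrix with values in `0:(levels - 1)`.
#' @export
quantize <- function(img, levels) {
  levels <- as.integer(levels)
  if (levels < 2) stop("levels must be >= 2")
  m <- unclass(img)
  q <- pmin(floor(m * levels / 256), levels - 1L)
  storage.mode(q) <- "integer"
  q
}

#' Grey-level co-occurrence matrix
#'
#' Counts pixel pairs `(p, q), (p + d_row, q + d_col)` with quantized
#' values `(x, y)`; out-of-bounds pairs are skipped. `probs` is the
#' count matrix normalized to sum 1. With `symmetric = TRUE` both
#' orderings of every pair are counted.
#'
#' @param img image matrix with values in `[0, 255]`.
#' @param cfg a [glcm_config()].
#' @return object of class `glcm` with fields `counts` (GxG integer
#'   matrix), `probs` (GxG, sums to 1), `config`.
#' @export
compute_glcm <- function(img, cfg = glcm_config()) {
  m <- unclass(img)
  d <- cfg$displacement
  nr <- nrow(m); nc <- ncol(m)
  if (abs(d[1]) >= nr || abs(d[2]) >= nc) {
    stop("displacement must be smaller than the image in both axes")
  }
  q <- quantize(m, cfg$levels)
  rs <- seq_len(nr - abs(d[1]))
  cs <- seq_len(nc - abs(d[2]))
  if (d[1] < 0) rs <- rs + abs(d[1])
  if (d[2] < 0) cs <- cs + abs(d[2])
  a <- q[rs, cs, drop = FALSE]
  b <- q[rs + d[1], cs + d[2], drop = FALSE]
  counts <- matrix(0L, cfg$levels, cfg$levels)
  tab <- table(factor(a, levels = 0:(cfg$levels - 1L)),
               factor(b, levels = 0:(cfg$levels - 1L)))
  counts <- matrix(as.integer(tab), cfg$levels, cfg$levels)
  if (cfg$symmetric) counts <- counts + t(counts)
  total <- sum(counts)
  probs <- if (total > 0) counts / total else counts * 0
  structure(list(counts = counts, probs = probs, config = cfg),
            class = "glcm")
}

#' Haralick-style texture statistics
#'
#' Computes contrast `sum p_ij (i - j)^2`, energy `sum p_ij^2`,
#' homogeneity `sum p_ij / (1 + (i - j)^2)` and entropy
#' `-sum p_ij ln p_ij` (natural log, `0 log 0 := 0`) from the normalized
#' co-occurrence matrix.
#'
#' @param glcm a `glcm` object (or a probability matrix).
#' @return named list with `contrast`, `energy`, `homogeneity`, `entropy`.
#' @export
texture_stats <- function(glcm) {
  p <- if (inherits(glcm, "glcm")) glcm$probs else glcm
  if (sum(p) == 0) stop("all-zero co-occurrence matrix")
  g <- nrow(p)
  i <- matrix(seq_len(g), g, g)
  j <- matrix(seq_len(g), g, g, byrow = TRUE)
  d2 <- (i - j)^2
  nz <- p > 0
  list(
    contrast = sum(p * d2),
    energy = sum(p^2),
    homogeneity = sum(p / (1 + d2)),
    entropy = -sum(p[nz] * log(p[nz]))
  )
}

#' Sliding-window texture feature maps
#'
#' Per-pixel GLCM contrast and homogeneity over a square window, for the
#' horizontal unit displacement. Exploits the fact that for a uniformly
#' normalized window GLCM, contrast is the window mean of the squared
#' quantized-level difference of adjacent pixels (and homogeneity the
#' window mean of its inverse-quadratic transform), so both reduce to box
#' filters over pairwise difference images — exact and fast.
#'
#' @param img image matrix in `[0, 255]`.
#' @param levels quantization levels.
#' @param half window half-width (4 gives the 9x9 window).
#' @return list of two matrices, `contrast` and `homogeneity`, shaped
#'   like `img`.
#' @export
texture_maps <- function(img, levels = 32L, half = 4L) {
  q <- quantize(img, levels)
  nr <- nrow(q); nc <- ncol(q)
  dq <- q[, -1L, drop = FALSE] - q[, -nc, drop = FALSE]
  # pad the pair image back to full width (replicate last column)
  d2 <- cbind(dq^2, dq[, nc - 1L]^2)
  hom <- 1 / (1 + d2)
  list(
    contrast = box_mean(d2, half),
    homogeneity = box_mean(hom, half)
  )
}
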