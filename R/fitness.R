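#' Between-class (interclass) variance at a threshold
#'
#' Otsu's criterion for the two-class split of a 256-bin intensity
#' histogram at level `C_theta`: `w1 * w2 * (mu1 - mu2)^2` with class 1
#' the bins below the threshold and class 2 the rest. Returns 0 when
#' either class is empty. Maximizing this over thresholds is equivalent
#' to minimizing the within-class variance (the total-variance
#' decomposition), which tests exploit as a cross-check.
#'
#' @param hist probability vector over grey levels `0:(length(hist)-1)`,
#'   summing to 1 (tolerance 1e-6).
#' @param c_theta threshold level: class 1 is levels `< c_theta`.
#' @return nonnegative between-class variance.
#' @export
interclass_variance <- function(hist, c_theta) {
  if (abs(sum(hist) - 1) > 1e-6) stop("histogram is not normalized")
  n <- length(hist)
  if (c_theta < 0 || c_theta >= n) stop("threshold outside histogram range")
  lv <- 0:(n - 1)
  lo <- lv < c_theta
  w1 <- sum(hist[lo]); w2 <- sum(hist[!lo])
  if (w1 <= 0 || w2 <= 0) return(0)
  mu1 <- sum(hist[lo] * lv[lo]) / w1
  mu2 <- sum(hist[!lo] * lv[!lo]) / w2
  w1 * w2 * (mu1 - mu2)^2
}

#' Total histogram variance
#'
#' @param hist normalized probability vector over grey levels.
#' @return variance of the level distribution.
#' @export
histogram_variance <- function(hist) {
  lv <- 0:(length(hist) - 1)
  mu <- sum(hist * lv)
  sum(hist * (lv - mu)^2)
}

#' Otsu threshold via exhaustive between-class-variance maximization
#'
#' @param hist normalized probability vector.
#' @return the smallest level maximizing [interclass_variance()].
#' @export
otsu_threshold <- function(hist) {
  v <- vapply(seq_len(length(hist) - 1), function(t) {
    interclass_variance(hist, t)
  }, numeric(1))
  which.max(v)  # smallest-index tie-break is which.max's behavior
}

#' Fuzzy-entropy threshold selection
#'
#' Scans every candidate threshold `t`; grey levels get an S-shaped
#' membership in the bright class (logistic in the distance from `t`,
#' bandwidth half the inter-mode distance of the smoothed histogram,
#' fallback 32) and the complementary membership in the dark class. The
#' score is the histogram-weighted fuzzy entropy of the membership
#' assignment (the binary Shannon entropy, base 2, of each level's
#' membership pair); the smallest `t` maximizing it wins. The score
#' peaks where the intensity mass is most ambiguous between the two
#' classes, which brackets the threshold between separated modes.
#'
#' @param hist probability vector over levels `0:255` (any length `>= 2`
#'   works); rescaling by a positive constant is neutral because the
#'   histogram is re-normalized internally.
#' @param bandwidth membership bandwidth in grey levels, or `NULL` for
#'   the inter-mode heuristic.
#' @return list of class `fuzzy_threshold` with `c_theta`, `entropy`
#'   (bits, `>= 0`), `memberships` (data frame with per-level `mu_dark`,
#'   `mu_bright`) and `bandwidth`.
#' @export
fuzzy_entropy_threshold <- function(hist, bandwidth = NULL) {
  s <- sum(hist)
  if (s <= 0) stop("histogram has no mass")
  hist <- hist / s
  if (sum(hist > 0) < 2) stop("degenerate single-bin histogram")
  n <- length(hist)
  lv <- 0:(n - 1)
  if (is.null(bandwidth)) bandwidth <- intermode_bandwidth(hist)
  ent2 <- function(mu) {
    out <- numeric(length(mu))
    ok <- mu > 0 & mu < 1
    out[ok] <- -mu[ok] * log2(mu[ok]) - (1 - mu[ok]) * log2(1 - mu[ok])
    out
  }
  best_t <- NA_integer_
  best_theta <- -Inf
  for (t in 0:(n - 2)) {
    mu_bright <- stats::plogis((lv - t) / bandwidth)
    theta <- sum(hist * ent2(mu_bright))
    if (theta > best_theta + 1e-12) {
      best_theta <- theta
      best_t <- t
    }
  }
  mu_bright <- stats::plogis((lv - best_t) / bandwidth)
  structure(list(
    c_theta = best_t,
    entropy = best_theta,
    memberships = data.frame(
      level = lv,
      mu_dark = 1 - mu_bright,
      mu_bright = mu_bright
    ),
    bandwidth = bandwidth
  ), class = "fuzzy_threshold")
}

# Half the distance between the two dominant modes of the smoothed
# histogram; 32 when fewer than two modes stand out.
intermode_bandwidth <- function(hist, fallback = 32) {
  k <- stats::filter(hist, rep(1 / 9, 9), sides = 2)
  k[is.na(k)] <- 0
  n <- length(k)
  is_peak <- k > c(-Inf, k[-n]) & k >= c(k[-1], -Inf) & k > 0
  peaks <- which(is_peak)
  if (length(peaks) < 2) return(fallback)
  top2 <- peaks[order(k[peaks], decreasing = TRUE)][1:2]
  bw <- abs(diff(top2)) / 2
  if (bw < 1) fallback else bw
}

#' Intraclass correlation of a segment
#'
#' `sigma_seg^2 / (sigma_seg^2 + sigma_img^2)` where the segment variance
#' is computed locally on the member pixels and the image variance
#' globally (population variances). Defined as 0 (with a `degenerate`
#' attribute) when both variances vanish.
#'
#' @param seg_values intensities of the segment's pixels (non-empty).
#' @param img_values intensities of the whole image.
#' @return value in `[0, 1]`.
#' @export
intraclass_correlation <- function(seg_values, img_values) {
  if (length(seg_values) == 0) stop("segment is empty")
  pvar <- function(x) mean((x - mean(x))^2)
  vs <- pvar(seg_values)
  vi <- pvar(img_values)
  if (vs + vi == 0) {
    return(structure(0, degenerate = TRUE))
  }
  vs / (vs + vi)
}

#' Segment-partition fitness
#'
#' The two-term fitness used both for segment scoring (coefficients
#' `p`, `q`) and inside the HARIS pixel-allotment objective (coefficients
#' `alpha`, `beta`): coefficient-1 times `total pixels / segment count`
#' plus coefficient-2 times the sum over segments of
#' `seed-point count / segment size`.
#'
#' @param total_pixels pixels in the whole image.
#' @param seg_sizes integer vector of per-segment pixel counts (all
#'   `> 0`).
#' @param total_sp total number of seed points (defaults to the segment
#'   count, i.e. one seed per segment centroid).
#' @param p,q nonnegative coefficients.
#' @return scalar fitness.
#' @export
segment_fitness <- function(total_pixels, seg_sizes,
                            total_sp = length(seg_sizes), p = 1, q = 1) {
  if (length(seg_sizes) < 1) stop("at least one segment required")
  empty <- which(seg_sizes <= 0)
  if (length(empty)) {
    stop("empty segment(s): ", paste(empty, collapse = ", "))
  }
  if (p < 0 || q < 0) stop("coefficients must be >= 0")
  p * total_pixels / length(seg_sizes) + q * sum(total_sp / seg_sizes)
}

#' Update self-learning class weights from labeled samples
#'
#' Estimates class-conditional densities of a scalar classifier feature
#' from histograms of the labeled samples, then sets the non-tumor weight
#' `W_p` to the mean likelihood ratio (non-tumor density over tumor
#' density) evaluated at the non-tumor samples — exactly 1 when the two
#' class distributions coincide, large when they separate — and the tumor
#' weight `W_q` to the mean tumor-class probability mass at the tumor
#' samples. Both are strictly positive. With a class missing, weights are
#' left unchanged and a warning is raised.
#'
#' @param memory a [new_memory()] state.
#' @param features numeric feature vector, one value per sample.
#' @param labels logical or 0/1 vector, `TRUE`/1 for tumor.
#' @param bins histogram bins for the density estimates.
#' @return updated memory.
#' @export
update_class_weights <- function(memory, features, labels, bins = 32L) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    warning("one class absent; class weights unchanged")
    return(memory)
  }
  rng <- range(features)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(features, breaks, all.inside = TRUE), 1L), bins)
  eps <- 0.5  # additive smoothing, in counts
  p_t <- tabulate(idx[labels], bins) + eps
  p_n <- tabulate(idx[!labels], bins) + eps
  p_t <- p_t / sum(p_t)
  p_n <- p_n / sum(p_n)
  w_p <- mean(p_n[idx[!labels]] / p_t[idx[!labels]])
  w_q <- mean(p_t[idx[labels]])
  memory$class_weights <- list(W_p = w_p, W_q = w_q)
  memory$run_log <- c(memory$run_log, list(list(
    run_id = length(memory$run_log) + 1L,
    event = "class_weights",
    n_samples = length(features),
    W_p = w_p, W_q = w_q
  )))
  memory
}
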