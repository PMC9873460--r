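#' Denoising parameters for the hybrid fuzzy-Gaussian kernel
#'
#' The noise-normalization operator combines a 5x5 Gaussian smoothing
#' response with a fuzzy-weighted high-frequency correction. Each pixel's
#' correction is scaled by its fuzzy membership (an inverse-power bell
#' around `fuzz_t_max` with bandwidth `fuzz_k_max` and exponent
#' `2 * fuzz_u_max`) and by `correction_gain`.
#'
#' `fuzz_t_max` and `fuzz_k_max` default to `NULL`, meaning
#' scale-adaptive values computed per image: the median intensity and the
#' intensity IQR (floored at 1). These adapt the membership to the actual
#' intensity distribution and can be overridden with fixed values.
#'
#' @param sigma Gaussian kernel standard deviation in pixels, `> 0`.
#' @param window neighborhood half-width (2 gives the 5x5 stencil).
#' @param fuzz_t_max membership center intensity, or `NULL` for the image
#'   median.
#' @param fuzz_k_max membership bandwidth, or `NULL` for the image IQR
#'   (floored at 1); must be nonzero when given.
#' @param fuzz_u_max membership exponent (shape), `>= 0.5`.
#' @param correction_gain gain on the fuzzy correction term, `>= 0`. The
#'   operator's nominal gain is 4, but an effective removal coefficient
#'   (`fuzziness * gain`) above 1 over-subtracts the residual band and
#'   amplifies noise; the default 0.5 keeps the coefficient below 1 for
#'   every pixel and denoises at all noise levels.
#' @param leading `"smoothed"` applies the correction to the Gaussian
#'   response; `"raw"` applies it to the raw pixel instead.
#' @return list of class `denoise_params`.
#' @export
denoise_params <- function(sigma = 0.8, window = 2L,
                           fuzz_t_max = NULL, fuzz_k_max = NULL,
                           fuzz_u_max = 1, correction_gain = 0.5,
                           leading = c("smoothed", "raw")) {
  leading <- match.arg(leading)
  if (sigma <= 0) stop("sigma must be > 0")
  if (!is.null(fuzz_k_max) && fuzz_k_max == 0) stop("fuzz_k_max must be nonzero")
  if (correction_gain < 0) stop("correction_gain must be >= 0")
  if (window < 1) stop("window must be >= 1")
  structure(list(
    sigma = sigma, window = as.integer(window),
    fuzz_t_max = fuzz_t_max, fuzz_k_max = fuzz_k_max,
    fuzz_u_max = fuzz_u_max, correction_gain = correction_gain,
    leading = leading
  ), class = "denoise_params")
}

#' Fuzzy membership of a pixel intensity
#'
#' `1 / (1 + ((pix - t_max) / k_max)^(2 u_max))`: equals 1 at the center
#' intensity and decays symmetrically with distance from it.
#'
#' @param pix intensity value(s) in `[0, 255]`.
#' @param params a [denoise_params()] with `fuzz_t_max` and `fuzz_k_max`
#'   resolved (non-`NULL`).
#' @return membership value(s) in `(0, 1]`.
#' @export
fuzziness <- function(pix, params) {
  if (any(!is.finite(pix))) stop("pix must be finite")
  t_max <- params$fuzz_t_max
  k_max <- params$fuzz_k_max
  if (is.null(t_max) || is.null(k_max)) {
    stop("fuzz_t_max/fuzz_k_max must be resolved before calling fuzziness()")
  }
  1 / (1 + abs((pix - t_max) / k_max)^(2 * params$fuzz_u_max))
}

resolve_fuzz <- function(img, params) {
  if (is.null(params$fuzz_t_max)) {
    params$fuzz_t_max <- stats::median(img)
  }
  if (is.null(params$fuzz_k_max)) {
    params$fuzz_k_max <- max(1, stats::IQR(img))
  }
  params
}

#' Hybrid fuzzy-Gaussian noise normalization
#'
#' Each output pixel is the Gaussian smoothing response `G` minus a
#' fuzzy-weighted correction: the pixel's membership `f_z` times the gain
#' times the high-frequency residual of the smoothed image (the response
#' minus its own neighborhood average under the same normalized Gaussian
#' weights). With `correction_gain = 0` the operator reduces to plain
#' Gaussian filtering; constant images pass through unchanged. Output is
#' clamped to `[0, 255]`.
#'
#' @param img an [mri_image()] or numeric matrix.
#' @param params a [denoise_params()].
#' @return denoised [mri_image()]; metadata records the resolved fuzzifier
#'   parameters and a variance-of-Laplacian noise flag.
#' @export
denoise_image <- function(img, params = denoise_params()) {
  m <- unclass(img)
  if (!is.matrix(m)) stop("img must be a 2-D image")
  if (2L * params$window + 1L > min(dim(m))) stop("window exceeds image size")
  params <- resolve_fuzz(m, params)
  kern <- gaussian_kernel(params$sigma, params$window)
  g <- conv2_reflect(m, kern)
  base <- if (params$leading == "smoothed") g else m
  if (params$correction_gain > 0) {
    residual <- g - conv2_reflect(g, kern)
    fz <- fuzziness(m, params)
    out <- base - fz * params$correction_gain * residual
  } else {
    out <- base
  }
  meta <- image_meta(img)
  meta$denoise <- list(
    sigma = params$sigma, gain = params$correction_gain,
    fuzz_t_max = params$fuzz_t_max, fuzz_k_max = params$fuzz_k_max,
    fuzz_u_max = params$fuzz_u_max, leading = params$leading
  )
  meta$noisy_flag <- noise_flag(m)
  mri_image(clamp255(out), meta = meta)
}

#' Binary noisy/noise-free flag
#'
#' Flags an image as noisy when the variance of its Laplacian response
#' exceeds a threshold; recorded in metadata by [denoise_image()].
#'
#' @param img image matrix.
#' @param threshold variance-of-Laplacian threshold.
#' @return logical scalar.
#' @export
noise_flag <- function(img, threshold = 25) {
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  stats::var(as.vector(conv2_reflect(unclass(img), lap))) > threshold
}
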