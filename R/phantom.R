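#' Synthetic brain-MRI phantom specification
#'
#' Describes a 2-D brain-like slice: an elliptical brain surrounded by a
#' skull ring, containing a circular tumor core wrapped in an enhancement
#' rim. Default intensity means mimic a contrast-enhanced T1-weighted
#' appearance (dark background and bone, mid-grey parenchyma, brighter
#' core, bright enhancing rim); all regions are separated by at least 10
#' intensity units so segmentation stages have a documented separability
#' contract to rely on.
#'
#' @param height,width image size in pixels.
#' @param brain_axes numeric length-2, ellipse semi-axes (row, col) in
#'   pixels; the brain is centered on the image center.
#' @param skull_thickness thickness of the skull ring in pixels.
#' @param core_center tumor-core center as 0-based (row, col) pixels.
#' @param core_radius tumor-core radius in pixels.
#' @param rim_width enhancement-rim width in pixels.
#' @param intensity_means named numeric vector with entries `background`,
#'   `skull`, `brain`, `core`, `rim`, each in `[0, 255]` and pairwise at
#'   least 10 units apart.
#' @param noise_model `"rician"` (magnitude of a complex Gaussian
#'   perturbation, the standard MRI noise model) or `"gaussian"`.
#' @param noise_sigma noise scale in intensity units, `>= 0`.
#' @param seed integer RNG seed.
#' @return validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 228L, width = 228L,
                         brain_axes = c(88, 72),
                         skull_thickness = 6,
                         core_center = c(140, 132),
                         core_radius = 18,
                         rim_width = 5,
                         intensity_means = c(
                           background = 5, skull = 40, brain = 110,
                           core = 160, rim = 210
                         ),
                         noise_model = c("rician", "gaussian"),
                         noise_sigma = 5,
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  spec <- list(
    height = as.integer(height), width = as.integer(width),
    brain_axes = as.numeric(brain_axes),
    skull_thickness = as.numeric(skull_thickness),
    core_center = as.numeric(core_center),
    core_radius = as.numeric(core_radius),
    rim_width = as.numeric(rim_width),
    intensity_means = intensity_means,
    noise_model = noise_model,
    noise_sigma = as.numeric(noise_sigma),
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  req <- c("background", "skull", "brain", "core", "rim")
  mu <- spec$intensity_means
  if (!all(req %in% names(mu))) {
    stop("intensity_means: missing region(s) ",
         paste(setdiff(req, names(mu)), collapse = ", "))
  }
  if (any(mu < 0 | mu > 255)) stop("intensity_means: values must lie in [0, 255]")
  d <- abs(outer(as.numeric(mu), as.numeric(mu), "-"))
  if (min(d[upper.tri(d)]) < 10) {
    stop("intensity_means: region means must be pairwise >= 10 units apart")
  }
  if (spec$noise_sigma < 0) stop("noise_sigma: must be >= 0")
  if (length(spec$brain_axes) != 2 || any(spec$brain_axes <= 0)) {
    stop("brain_axes: two positive semi-axes required")
  }
  if (spec$skull_thickness <= 0) stop("skull_thickness: must be positive")
  if (spec$core_radius <= 0) stop("core_radius: must be positive")
  if (spec$rim_width < 0) stop("rim_width: must be >= 0")
  ctr <- c((spec$height - 1) / 2, (spec$width - 1) / 2)
  # Conservative containment: the core+rim disk must fit inside the brain
  # ellipse shrunk by the disk radius on both axes.
  R <- spec$core_radius + spec$rim_width
  shrink <- spec$brain_axes - R
  if (any(shrink <= 0)) {
    stop("core_radius: core plus rim does not fit inside brain_axes")
  }
  dd <- (spec$core_center - ctr) / shrink
  if (sum(dd^2) > 1) {
    stop("core_center: core plus rim extends outside the brain ellipse")
  }
  outer_ax <- spec$brain_axes + spec$skull_thickness
  if (outer_ax[1] >= (spec$height - 1) / 2 || outer_ax[2] >= (spec$width - 1) / 2) {
    stop("brain_axes: skull ring does not fit inside the image")
  }
  invisible(spec)
}

phantom_labels <- function(spec) {
  ctr <- c((spec$height - 1) / 2, (spec$width - 1) / 2)
  r <- matrix(0:(spec$height - 1), spec$height, spec$width)
  c_ <- matrix(0:(spec$width - 1), spec$height, spec$width, byrow = TRUE)
  e_in <- ((r - ctr[1]) / spec$brain_axes[1])^2 +
    ((c_ - ctr[2]) / spec$brain_axes[2])^2 <= 1
  oa <- spec$brain_axes + spec$skull_thickness
  e_out <- ((r - ctr[1]) / oa[1])^2 + ((c_ - ctr[2]) / oa[2])^2 <= 1
  d2 <- (r - spec$core_center[1])^2 + (c_ - spec$core_center[2])^2
  core <- d2 <= spec$core_radius^2
  rim <- !core & d2 <= (spec$core_radius + spec$rim_width)^2
  lab <- matrix(0L, spec$height, spec$width)
  lab[e_out] <- 1L
  lab[e_in] <- 2L
  lab[rim & e_in] <- 4L
  lab[core & e_in] <- 3L
  lab
}

#' Generate one phantom slice with exact ground truth
#'
#' Paints the piecewise-constant region image defined by the spec, then
#' adds Gaussian or Rician noise and clamps to `[0, 255]` (the clamping
#' rate is recorded in the image metadata). Identical `(spec, seed)`
#' yields bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `image` ([mri_image()]) and `mask`
#'   ([label_mask()]).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  lab <- phantom_labels(spec)
  mu <- spec$intensity_means
  clean <- matrix(mu[["background"]], spec$height, spec$width)
  for (region in c("skull", "brain", "core", "rim")) {
    clean[lab == mask_legend()[[region]]] <- mu[[region]]
  }
  set.seed(spec$seed)
  n <- length(clean)
  if (spec$noise_sigma > 0) {
    if (spec$noise_model == "gaussian") {
      noisy <- clean + stats::rnorm(n, 0, spec$noise_sigma)
    } else {
      noisy <- sqrt((clean + stats::rnorm(n, 0, spec$noise_sigma))^2 +
                      stats::rnorm(n, 0, spec$noise_sigma)^2)
    }
    noisy <- matrix(noisy, spec$height, spec$width)
  } else {
    noisy <- clean
  }
  clamp_rate <- mean(noisy < 0 | noisy > 255)
  img <- mri_image(clamp255(noisy), meta = list(
    source = "phantom", synthetic = TRUE, seed = spec$seed,
    noise_model = spec$noise_model, noise_sigma = spec$noise_sigma,
    clamp_rate = clamp_rate
  ))
  list(image = img, mask = label_mask(lab, meta = list(seed = spec$seed)))
}

#' Generate a jittered phantom dataset
#'
#' Draws `n` phantoms whose geometry and intensity means are perturbed by
#' up to `jitter` (relative, uniform) around the base spec; per-sample
#' seeds are derived deterministically from the master seed. Samples whose
#' jittered geometry violates the containment contract are re-drawn
#' (bounded retries).
#'
#' @param spec base [phantom_spec()].
#' @param n number of phantoms, `>= 1`.
#' @param jitter relative perturbation in `[0, 0.5)`.
#' @param seed master seed.
#' @return list of `n` `list(image, mask)` pairs.
#' @export
generate_dataset <- function(spec, n, jitter = 0, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (jitter < 0 || jitter >= 0.5) stop("jitter must lie in [0, 0.5)")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sample_seed <- derive_seed(seed, 1000L + i)
    ok <- FALSE
    for (try in 0:19) {
      sp <- jitter_spec(spec, jitter, sample_seed + 100000L * try)
      valid <- tryCatch({
        validate_phantom_spec(sp)
        TRUE
      }, error = function(e) FALSE)
      if (valid) {
        out[[i]] <- generate_phantom(sp)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not draw a valid jittered phantom for sample ", i)
  }
  out
}

jitter_spec <- function(spec, jitter, seed) {
  if (jitter == 0) {
    sp <- spec
    sp$seed <- as.integer(seed %% 2147483647)
    return(sp)
  }
  set.seed(seed %% 2147483647)
  u <- function(k) stats::runif(k, 1 - jitter, 1 + jitter)
  sp <- spec
  sp$brain_axes <- spec$brain_axes * u(2)
  sp$core_radius <- spec$core_radius * u(1)
  sp$rim_width <- spec$rim_width * u(1)
  ctr <- c((spec$height - 1) / 2, (spec$width - 1) / 2)
  sp$core_center <- ctr + (spec$core_center - ctr) * u(2)
  mu <- spec$intensity_means
  mu[c("brain", "core", "rim")] <-
    pmin(255, mu[c("brain", "core", "rim")] * u(3))
  sp$intensity_means <- mu
  sp$seed <- as.integer(seed %% 2147483647)
  sp
}

#' Generate a concentric multi-region phantom
#'
#' A simpler phantom of `k` nested elliptical regions with well-separated
#' intensity means, used to exercise cluster-count estimation for a known
#' number of intensity classes.
#'
#' @param k number of regions (including background), `>= 2`.
#' @param side image side in pixels.
#' @param noise_sigma Gaussian noise scale.
#' @param seed RNG seed.
#' @return list with `image` ([mri_image()]) and `regions` (integer matrix
#'   of region ids `0:(k-1)`).
#' @export
generate_kregion_phantom <- function(k, side = 96L, noise_sigma = 5, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  side <- as.integer(side)
  ctr <- (side - 1) / 2
  r <- matrix(0:(side - 1), side, side)
  c_ <- matrix(0:(side - 1), side, side, byrow = TRUE)
  rad <- sqrt((r - ctr)^2 + (c_ - ctr)^2)
  # k-1 nested disks inside background; radii evenly spaced.
  radii <- seq(0.45 * side, 0.45 * side / (k - 1), length.out = k - 1)
  regions <- matrix(0L, side, side)
  for (i in seq_len(k - 1)) regions[rad <= radii[i]] <- i
  means <- seq(20, 230, length.out = k)
  clean <- matrix(means[regions + 1L], side, side)
  set.seed(as.integer(seed %% 2147483647))
  img <- clamp255(clean + stats::rnorm(length(clean), 0, noise_sigma))
  list(
    image = mri_image(matrix(img, side, side), meta = list(
      source = "kregion-phantom", synthetic = TRUE, k = k, seed = seed
    )),
    regions = regions
  )
}
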