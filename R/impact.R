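#' Derive tumor core / enhanced / whole masks
#'
#' From a probability map: the core is the high-confidence region
#' (probability at or above `core_threshold`), the enhanced region is a
#' morphological band of width `band` around the core restricted to the
#' tumor-positive region (probability at or above `positive_threshold`),
#' and the whole tumor is their union; core and enhanced are disjoint by
#' construction. A [label_mask()] passes its labels 3 and 4 through
#' exactly.
#'
#' @param x probability matrix in `[0, 1]`, or a [label_mask()].
#' @param core_threshold,positive_threshold probability cutoffs.
#' @param band enhancement band width in pixels.
#' @return list of logical matrices `core`, `enhanced`, `whole`, plus
#'   `empty` flag (TRUE when no tumor-positive pixels were found).
#' @export
derive_regions <- function(x, core_threshold = 0.7,
                           positive_threshold = 0.5, band = 3L) {
  if (inherits(x, "label_mask")) {
    m <- unclass(x)
    core <- m == 3L
    enhanced <- m == 4L
    return(list(core = core, enhanced = enhanced,
                whole = core | enhanced, empty = !any(core | enhanced)))
  }
  p <- unclass(x)
  positive <- p >= positive_threshold
  if (!any(positive)) {
    z <- matrix(FALSE, nrow(p), ncol(p))
    return(list(core = z, enhanced = z, whole = z, empty = TRUE))
  }
  core <- p >= core_threshold
  enhanced <- dilate_disk(core, band) & positive & !core
  list(core = core, enhanced = enhanced, whole = core | enhanced,
       empty = FALSE)
}

#' Texture-weighted damage index of a region
#'
#' `index = ln(1 + area) * (1 + GLCM contrast of the masked region)`,
#' with the contrast computed over horizontally adjacent pixel pairs
#' lying entirely inside the mask. The erroneous index is the half-width
#' of the 95% bootstrap interval of the index over `n_boot` resamples of
#' those pairs; deterministic under the seed. An empty mask yields
#' `(0, 0)`.
#'
#' @param mask logical matrix.
#' @param image intensity matrix in `[0, 255]`.
#' @param levels GLCM quantization levels.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @return list with `index`, `erroneous_index`, `area` (pixel count),
#'   `contrast`.
#' @export
damage_index <- function(mask, image, levels = 32L, n_boot = 200L, seed = 1L) {
  area <- sum(mask)
  if (area == 0) {
    return(list(index = 0, erroneous_index = 0, area = 0, contrast = 0))
  }
  q <- quantize(unclass(image), levels)
  nc <- ncol(q)
  pair_ok <- mask[, -nc, drop = FALSE] & mask[, -1L, drop = FALSE]
  d2 <- (q[, -nc, drop = FALSE] - q[, -1L, drop = FALSE])^2
  dvals <- d2[pair_ok]
  contrast <- if (length(dvals)) mean(dvals) else 0
  index <- log1p(area) * (1 + contrast)
  err <- 0
  if (length(dvals) > 1) {
    set.seed(as.integer(seed))
    boot <- vapply(seq_len(n_boot), function(b) {
      log1p(area) * (1 + mean(sample(dvals, replace = TRUE)))
    }, numeric(1))
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
    err <- (ci[2] - ci[1]) / 2
  }
  list(index = index, erroneous_index = err, area = area,
       contrast = contrast)
}

#' Build an impact report
#'
#' Areas (pixels, and mm^2 when a pixel spacing is given) and
#' texture-weighted damage indices with bootstrap erroneous indices for
#' the tumor core, enhanced region and whole tumor.
#'
#' @param regions output of [derive_regions()].
#' @param image intensity matrix.
#' @param pixel_spacing optional pixel side length in mm.
#' @param seed bootstrap seed.
#' @param run_id free-form run identifier.
#' @return list of class `impact_report`.
#' @export
impact_report <- function(regions, image, pixel_spacing = NULL, seed = 1L,
                          run_id = NULL) {
  di <- function(mask, off) damage_index(mask, image, seed = seed + off)
  core <- di(regions$core, 0L)
  enh <- di(regions$enhanced, 1L)
  whole <- di(regions$whole, 2L)
  rep_ <- list(
    core_area = core$area, enhanced_area = enh$area,
    whole_area = whole$area,
    core_index = core$index, enhanced_index = enh$index,
    whole_index = whole$index,
    erroneous_core = core$erroneous_index,
    erroneous_enhanced = enh$erroneous_index,
    erroneous_whole = whole$erroneous_index,
    pixel_spacing = pixel_spacing,
    run_id = run_id %||% format(Sys.time(), "%Y%m%d%H%M%S"),
    empty = isTRUE(regions$empty)
  )
  if (!is.null(pixel_spacing)) {
    rep_$core_area_mm2 <- core$area * pixel_spacing^2
    rep_$enhanced_area_mm2 <- enh$area * pixel_spacing^2
    rep_$whole_area_mm2 <- whole$area * pixel_spacing^2
  }
  structure(rep_, class = "impact_report")
}

#' @export
print.impact_report <- function(x, ...) {
  cat(sprintf(
    paste0("<impact_report: core %d px (index %.3f +/- %.3f), ",
           "enhanced %d px (index %.3f +/- %.3f), ",
           "whole %d px (index %.3f +/- %.3f)>\n"),
    x$core_area, x$core_index, x$erroneous_core,
    x$enhanced_area, x$enhanced_index, x$erroneous_enhanced,
    x$whole_area, x$whole_index, x$erroneous_whole
  ))
  invisible(x)
}

#' Longitudinal tumor progression between two reports
#'
#' Absolute and relative deltas for the three areas and indices; growth
#' is flagged when the whole-tumor index increase exceeds the sum of the
#' two reports' whole-tumor erroneous indices (i.e. the change clears
#' the combined uncertainty bands).
#'
#' @param prev,curr [impact_report()]s with the same pixel spacing.
#' @return list with `deltas` (data frame: quantity, previous, current,
#'   absolute, relative) and `growth` flag.
#' @export
progression <- function(prev, curr) {
  if (!identical(prev$pixel_spacing, curr$pixel_spacing)) {
    stop("pixel spacing mismatch between reports")
  }
  qty <- c("core_area", "enhanced_area", "whole_area",
           "core_index", "enhanced_index", "whole_index")
  deltas <- do.call(rbind, lapply(qty, function(q) {
    a <- prev[[q]]; b <- curr[[q]]
    data.frame(
      quantity = q, previous = a, current = b,
      absolute = b - a,
      relative = if (a != 0) (b - a) / a else ifelse(b == 0, 0, Inf)
    )
  }))
  growth <- (curr$whole_index - prev$whole_index) >
    (prev$erroneous_whole + curr$erroneous_whole)
  list(deltas = deltas, growth = growth)
}

#' Render a colormap overlay of tumor regions
#'
#' Grayscale base with the tumor core in red and the enhanced region in
#' yellow (the whole tumor is their union). Colors are fixed; the legend
#' is attached as the `legend` attribute (and written as sidecar JSON by
#' [save_overlay()]).
#'
#' @param image intensity matrix in `[0, 255]`.
#' @param regions output of [derive_regions()].
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
overlay_regions <- function(image, regions) {
  m <- unclass(image)
  if (!all(dim(m) == dim(regions$core))) stop("shape mismatch")
  g <- m / 255
  rgb_ <- array(rep(g, 3), c(nrow(m), ncol(m), 3))
  colors <- list(core = c(1, 0, 0), enhanced = c(1, 1, 0))
  for (nm in names(colors)) {
    msk <- regions[[nm]]
    for (ch in 1:3) {
      plane <- rgb_[, , ch]
      plane[msk] <- colors[[nm]][ch]
      rgb_[, , ch] <- plane
    }
  }
  attr(rgb_, "legend") <- list(core = "#FF0000", enhanced = "#FFFF00",
                               whole = "core + enhanced")
  rgb_
}

#' Write an overlay PNG with its legend sidecar
#'
#' @param overlay array from [overlay_regions()].
#' @param path output PNG path; the legend goes to `<path>.json`.
#' @export
save_overlay <- function(overlay, path) {
  png::writePNG(overlay, path)
  jsonlite::write_json(attr(overlay, "legend"), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}
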