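#' MRI image container
#'
#' A 2-D grayscale intensity grid on the 0--255 scale with provenance
#' metadata. Coordinates are 0-based, row-major `(row, col)` throughout the
#' package; R matrices are 1-indexed so accessors translate where needed.
#'
#' @param data numeric matrix of intensities in `[0, 255]`.
#' @param meta named list of provenance metadata (seed, source, pixel
#'   spacing in mm, synthetic flag, ...). Free-form; merged, never dropped.
#' @return object of class `mri_image` (a numeric matrix with a `meta`
#'   attribute).
#' @export
mri_image <- function(data, meta = list()) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix")
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("image intensities must be finite")
  }
  structure(data, meta = meta, class = c("mri_image", "matrix", "array"))
}

#' @export
print.mri_image <- function(x, ...) {
  cat(sprintf(
    "<mri_image %d x %d, range [%.1f, %.1f]>\n",
    nrow(x), ncol(x), min(x), max(x)
  ))
  meta <- attr(x, "meta")
  if (length(meta)) {
    cat("  meta:", paste(names(meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname mri_image
#' @param x object to query.
#' @export
image_meta <- function(x) attr(x, "meta") %||% list()

#' Label mask container
#'
#' Integer label grid aligned with an [mri_image()]. The legend is fixed:
#' 0 background, 1 skull/non-brain, 2 brain (non-tumor), 3 tumor core,
#' 4 enhancement rim. "Whole tumor" is the union of labels 3 and 4.
#'
#' @param labels integer matrix with values in `0:4`.
#' @param meta named list of metadata.
#' @return object of class `label_mask`.
#' @export
label_mask <- function(labels, meta = list()) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  if (anyNA(labels)) stop("labels must not contain NA")
  bad <- setdiff(unique(as.vector(labels)), 0:4)
  if (length(bad)) {
    stop("unknown label values: ", paste(bad, collapse = ", "))
  }
  structure(labels, meta = meta, class = c("label_mask", "matrix", "array"))
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(as.vector(x), levels = 0:4))
  cat(sprintf("<label_mask %d x %d>\n", nrow(x), ncol(x)))
  cat("  counts:", paste(sprintf("%s=%d", mask_legend(), tab), collapse = " "), "\n")
  invisible(x)
}

#' Mask legend
#'
#' @return named integer vector mapping region names to label values.
#' @export
mask_legend <- function() {
  c(background = 0L, skull = 1L, brain = 2L, core = 3L, rim = 4L)
}

#' Binary tumor masks from a label mask
#'
#' @param mask a [label_mask()].
#' @return list with logical matrices `core` (label 3), `rim` (label 4),
#'   `whole` (labels 3 or 4) and `brain` (labels >= 2).
#' @export
tumor_masks <- function(mask) {
  m <- unclass(mask)
  list(
    core  = m == 3L,
    rim   = m == 4L,
    whole = m == 3L | m == 4L,
    brain = m >= 2L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
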