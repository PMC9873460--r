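#' Read a grayscale image (PNG or NIfTI)
#'
#' 8-bit grayscale PNG or a single-slice NIfTI volume; intensities are
#' normalized to the package's `[0, 255]` contract. Multi-channel PNGs
#' are collapsed to luminance; 16-bit PNGs are rejected with a
#' conversion hint. NIfTI affines are preserved in metadata.
#'
#' @param path file path ending in `.png`, `.nii` or `.nii.gz`.
#' @return an [mri_image()].
#' @export
load_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path, info = TRUE)
    info <- attr(a, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8) {
      stop("16-bit PNG unsupported; convert to 8-bit grayscale first")
    }
    if (length(dim(a)) == 3) {
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    }
    mri_image(a * 255, meta = list(source = path, format = "png"))
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- RNifti::readNifti(path)
    m <- as.array(v)
    if (length(dim(m)) == 3 && dim(m)[3] == 1) m <- m[, , 1]
    if (length(dim(m)) != 2) stop("only single-slice NIfTI supported")
    rng <- range(m)
    if (rng[2] > 255 || rng[1] < 0) {
      m <- (m - rng[1]) / max(rng[2] - rng[1], 1e-12) * 255
    }
    mri_image(m, meta = list(source = path, format = "nifti",
                             affine = RNifti::xform(v),
                             pixdim = RNifti::pixdim(v)))
  } else {
    stop("unsupported format (use .png, .nii or .nii.gz): ", path)
  }
}

#' Write an image as 8-bit grayscale PNG or NIfTI
#'
#' @param img an [mri_image()] or matrix in `[0, 255]`.
#' @param path destination ending in `.png`, `.nii` or `.nii.gz`.
#' @export
save_image <- function(img, path) {
  m <- clamp255(unclass(img))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(round(m) / 255, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(m), path)
  } else {
    stop("unsupported format: ", path)
  }
  invisible(path)
}

#' Write a label mask losslessly
#'
#' PNG stores label values directly in an 8-bit grayscale channel
#' (`label / 255` on disk); NIfTI stores the integer grid.
#'
#' @param mask a [label_mask()] or integer matrix.
#' @param path destination path.
#' @export
save_mask <- function(mask, path) {
  m <- unclass(mask)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(m / 255, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(m), path)
  } else {
    stop("unsupported format: ", path)
  }
  invisible(path)
}

#' Read a label mask written by [save_mask()]
#'
#' @param path file path.
#' @return a [label_mask()].
#' @export
load_mask <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- a[, , 1]
    label_mask(matrix(as.integer(round(a * 255)), nrow(a), ncol(a)))
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    m <- as.array(RNifti::readNifti(path))
    if (length(dim(m)) == 3 && dim(m)[3] == 1) m <- m[, , 1]
    label_mask(matrix(as.integer(round(m)), nrow(m), ncol(m)))
  } else {
    stop("unsupported format: ", path)
  }
}
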