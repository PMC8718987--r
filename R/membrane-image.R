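#' Membrane image objects
#'
#' A `membrane_image` is the universal substrate of all NRP quantification: a
#' dense 2D field of pixel values in `[0, 1]`. Straight off a scanner the
#' values are luminance (white membrane high, dark MnO2 deposit low); after
#' [to_reductive_scale()] they are *reductive intensity*, where larger values
#' mean more MnO2 deposit, i.e. more reduction by the applied sample.
#'
#' Pixels are indexed `(row, column)`, 1-based, origin at the top-left of the
#' scanned membrane. Dorsoventral profiles in the spatial analysis run along
#' increasing row index. The canonical working scale is floating point
#' `[0, 1]`; integer code spaces (8/16-bit) exist only at file boundaries.
#'
#' @param pixels Numeric matrix of pixel values in `[0, 1]`.
#' @param is_reductive_scale Logical; `TRUE` once the image has been inverted
#'   so intensity encodes reductive capacity.
#' @param scale_note Free-text provenance (bit depth, source file).
#'
#' @return A `membrane_image`: a list with elements `pixels` (matrix),
#'   `height_px`, `width_px`, `is_reductive_scale` and `scale_note`.
#' @examples
#' img <- membrane_image(matrix(c(0, 1, 0.5, 0.5), 2, 2))
#' img$height_px
#' @export
membrane_image <- function(pixels, is_reductive_scale = FALSE,
                           scale_note = "constructed") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("zero-sized image: need at least one row and one column", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("pixel values must be finite", call. = FALSE)
  }
  if (any(pixels < 0) || any(pixels > 1)) {
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      pixels = unname(pixels),
      height_px = nrow(pixels),
      width_px = ncol(pixels),
      is_reductive_scale = isTRUE(is_reductive_scale),
      scale_note = as.character(scale_note)[1]
    ),
    class = "membrane_image"
  )
}

#' @export
print.membrane_image <- function(x, ...) {
  cat(sprintf(
    "<membrane_image> %d x %d px, %s scale\n  range [%.4f, %.4f]  (%s)\n",
    x$height_px, x$width_px,
    if (x$is_reductive_scale) "reductive" else "luminance",
    min(x$pixels), max(x$pixels), x$scale_note
  ))
  invisible(x)
}

#' @export
dim.membrane_image <- function(x) dim(x$pixels)

is_membrane_image <- function(x) inherits(x, "membrane_image")

assert_reductive <- function(img, what) {
  if (!is_membrane_image(img)) {
    stop("`img` must be a membrane_image", call. = FALSE)
  }
  if (!img$is_reductive_scale) {
    stop(what, " requires a reductive-scale image; call to_reductive_scale() first",
         call. = FALSE)
  }
  invisible(img)
}

#' Invert an image to the reductive-intensity scale
#'
#' Dark deposits on a digitized membrane have *low* luminance; NRP reads
#' darkness as signal. This replaces every pixel `v` by `1 - v` so that larger
#' values mean more MnO2 deposit (more reductive capacity), the convention
#' used by every downstream quantification function. Double inversion is
#' refused so a membrane cannot silently end up back on the luminance scale.
#'
#' @param img A `membrane_image` on the luminance scale.
#' @return The inverted `membrane_image` with `is_reductive_scale = TRUE`.
#' @examples
#' img <- membrane_image(matrix(0.25, 2, 2))
#' to_reductive_scale(img)$pixels[1, 1] # 0.75
#' @export
to_reductive_scale <- function(img) {
  if (!is_membrane_image(img)) stop("`img` must be a membrane_image", call. = FALSE)
  if (img$is_reductive_scale) {
    stop("image is already on the reductive scale (double inversion refused)",
         call. = FALSE)
  }
  membrane_image(1 - img$pixels, is_reductive_scale = TRUE,
                 scale_note = paste0(img$scale_note, "; inverted"))
}
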