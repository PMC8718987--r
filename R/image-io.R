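#' Read a digitized membrane from a TIFF or PNG file
#'
#' Reads an 8- or 16-bit grayscale or RGB raster and normalizes it linearly to
#' `[0, 1]` (full-scale code maps to 1). RGB is collapsed to luminance with the
#' fixed ITU-R BT.601 weights 0.299/0.587/0.114 — membranes are scanned without
#' a declared colorspace, and a fixed convention keeps results reproducible
#' across scanners. The result is on the *luminance* scale
#' (`is_reductive_scale = FALSE`); pass it through [to_reductive_scale()]
#' before quantification.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return A `membrane_image` with pixel values in `[0, 1]` and the source
#'   file and bit depth recorded in `scale_note`.
#' @seealso [save_membrane()] for the lossless-within-quantization inverse.
#' @export
load_membrane <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    "tif" = ,
    "tiff" = tryCatch(tiff::readTIFF(path, info = FALSE),
                      error = function(e) stop("unreadable TIFF: ", path, " (",
                                               conditionMessage(e), ")", call. = FALSE)),
    "png" = tryCatch(png::readPNG(path),
                     error = function(e) stop("unreadable PNG: ", path, " (",
                                              conditionMessage(e), ")", call. = FALSE)),
    stop("unsupported format '", ext, "': expected TIFF or PNG", call. = FALSE)
  )
  # readTIFF/readPNG already scale integer codes linearly to [0, 1]
  px <- collapse_luminance(arr)
  if (nrow(px) < 1L || ncol(px) < 1L) stop("zero-sized image: ", path, call. = FALSE)
  membrane_image(pmin(pmax(px, 0), 1),
                 is_reductive_scale = FALSE,
                 scale_note = sprintf("loaded %s", basename(path)))
}

# BT.601 luminance; alpha channel ignored
collapse_luminance <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3L) {
    nr <- dim(arr)[1]; ncol_px <- dim(arr)[2]
    slice <- function(k) matrix(arr[, , k], nr, ncol_px)
    nc <- dim(arr)[3]
    if (nc %in% c(1L, 2L)) return(slice(1))   # gray (+alpha)
    return(0.299 * slice(1) + 0.587 * slice(2) + 0.114 * slice(3))
  }
  stop("unsupported image array layout", call. = FALSE)
}

#' Write a membrane image to disk
#'
#' Quantizes the `[0, 1]` field to the requested bit depth and writes
#' grayscale TIFF or PNG (chosen by file extension). Round trips through
#' [load_membrane()] are exact to within one quantization step of the chosen
#' depth (1/255 or 1/65535). The reductive/luminance state is *not* stored in
#' the file; record it externally (the CLI manifest does).
#'
#' @param img A `membrane_image`.
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @param bit_depth 8 or 16. 16-bit output is available for TIFF; PNG output
#'   is 8-bit.
#' @return `path`, invisibly.
#' @export
save_membrane <- function(img, path, bit_depth = 16) {
  if (!is_membrane_image(img)) stop("`img` must be a membrane_image", call. = FALSE)
  if (!bit_depth %in% c(8, 16)) stop("`bit_depth` must be 8 or 16", call. = FALSE)
  if (!is.character(path) || length(path) != 1L || !nzchar(path)) {
    stop("cannot write image: invalid path", call. = FALSE)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write image: no such directory: ", dir, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff", "png")) {
    stop("unsupported output format '", ext, "': expected TIFF or PNG", call. = FALSE)
  }
  if (ext == "png" && bit_depth == 16) {
    stop("16-bit output requires TIFF; PNG output is 8-bit", call. = FALSE)
  }
  tryCatch({
    if (ext == "png") png::writePNG(img$pixels, path)
    else tiff::writeTIFF(img$pixels, path, bits.per.sample = bit_depth)
  }, error = function(e) stop("cannot write image to ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}
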