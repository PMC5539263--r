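#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

# Validate an image matrix: integer gray levels 0..255, optionally with
# negative mask sentinels. Returns the matrix in integer storage.
check_image <- function(img, allow_sentinel = TRUE,
                        arg = deparse(substitute(img))) {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("'%s' must be a numeric matrix of gray levels", arg))
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(sprintf("'%s' must have at least one row and one column", arg))
  if (anyNA(img) || any(!is.finite(img)))
    stop(sprintf("'%s' contains missing or non-finite values", arg))
  if (any(img != floor(img)))
    stop(sprintf("'%s' must contain integer gray levels (0..255)", arg))
  if (any(img > 255))
    stop(sprintf("'%s' contains levels above 255", arg))
  if (!allow_sentinel && any(img < 0))
    stop(sprintf("'%s' contains masked (sentinel) pixels; this operation needs an unmasked image", arg))
  storage.mode(img) <- "integer"
  img
}

#' Convert RGB channel levels to a gray level
#'
#' ITU-R BT.601 luminance, `0.299 R + 0.587 G + 0.114 B`, rounded half-up to
#' the nearest integer level. This is the most common still-image convention;
#' it is applied channel-wise when [read_image()] meets a color input.
#'
#' @param red,green,blue integer levels in 0..255 (vectorized).
#' @return Integer gray level(s) in 0..255.
#' @examples
#' rgb_to_gray(255, 0, 0)   # 76
#' rgb_to_gray(128, 128, 128)
#' @export
rgb_to_gray <- function(red, green, blue) {
  for (ch in list(red, green, blue)) {
    if (any(ch < 0 | ch > 255 | ch != floor(ch)))
      stop("channel levels must be integers in 0..255")
  }
  as.integer(round_half_up(0.299 * red + 0.587 * green + 0.114 * blue))
}

#' Read an image as an 8-bit grayscale level matrix
#'
#' Decodes a PNG or JPEG file and returns an integer matrix of gray levels
#' 0..255, the representation all comparison algorithms consume. Color images
#' are converted with [rgb_to_gray()]; an alpha channel is dropped with a
#' warning; images with more than 8 bits per channel are rescaled to 8 bits
#' with rounding. JPEG input is accepted but triggers a warning, because JPEG
#' compression is lossy and perturbs the exact pixel identities the counting
#' algorithms rely on -- lossless PNG is preferred.
#'
#' The file format is recognized from the file's magic bytes, not its
#' extension.
#'
#' @param path path to a PNG or JPEG file.
#' @return Integer matrix of gray levels (rows x columns of the image).
#' @seealso [write_image()], [mask_monochrome()]
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("'path' must be a single file path")
  if (!file.exists(path))
    stop(sprintf("cannot read image: file '%s' does not exist", path))
  magic <- readBin(path, "raw", n = 4L)
  is_png <- length(magic) >= 4L &&
    identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47)))
  is_jpg <- length(magic) >= 3L &&
    identical(magic[1:3], as.raw(c(0xff, 0xd8, 0xff)))
  if (!is_png && !is_jpg)
    stop(sprintf("unsupported or corrupt image format in '%s' (PNG and JPEG are supported)", path))
  x <- tryCatch(
    if (is_png) png::readPNG(path) else jpeg::readJPEG(path),
    error = function(e)
      stop(sprintf("cannot decode image '%s': %s", path, conditionMessage(e)))
  )
  if (is_jpg)
    warning(sprintf("'%s' is JPEG: lossy compression may have altered pixel values; prefer lossless PNG", path))
  if (length(dim(x)) == 3L) {
    nch <- dim(x)[3L]
    if (nch %in% c(2L, 4L)) {
      warning(sprintf("'%s' has an alpha channel; it is dropped", path))
      x <- x[, , -nch, drop = FALSE]
      nch <- dim(x)[3L]
    }
    if (nch == 1L) {
      x <- x[, , 1L]
    } else if (nch == 3L) {
      # quantize channels to 8-bit first, then take luminance
      r <- round_half_up(x[, , 1L] * 255)
      g <- round_half_up(x[, , 2L] * 255)
      b <- round_half_up(x[, , 3L] * 255)
      out <- matrix(rgb_to_gray(as.vector(r), as.vector(g), as.vector(b)),
                    nrow = nrow(r))
      return(check_image(out, arg = path))
    } else {
      stop(sprintf("'%s': unsupported channel count (%d)", path, nch))
    }
  }
  # grayscale: values in [0,1]; for bit depth > 8 the rescale rounds to 8 bit
  out <- round_half_up(x * 255)
  check_image(out, arg = path)
}

#' Write a gray-level matrix as an 8-bit grayscale PNG
#'
#' PNG only: lossless, so [read_image()] recovers the levels bit-exactly.
#' Masked images cannot be written (sentinels have no gray value).
#'
#' @param img integer matrix of gray levels 0..255.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- check_image(img, allow_sentinel = FALSE)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' Replace monochrome pixels with unmatchable sentinels
#'
#' Large monochrome areas (typically pure black 0 and pure white 255) produce
#' overwhelming false-positive matches in the counting algorithms, because
#' every such pixel is identical to every other. Each pixel whose level is in
#' `mono_levels` is replaced with a unique sentinel value that never matches
#' anything -- not even itself -- so masked areas contribute zero to every
#' shift score. Sentinels are consecutive negative integers assigned in
#' row-major order.
#'
#' The variance algorithm cannot run on masked images; use the pixel-wise or
#' nearest-neighbor algorithm there.
#'
#' @param img integer matrix of gray levels 0..255.
#' @param mono_levels levels to mask; default `c(0, 255)`.
#' @return The image matrix with sentinel values, class `"masked_image"`,
#'   with attribute `sentinel_count`.
#' @export
mask_monochrome <- function(img, mono_levels = c(0L, 255L)) {
  img <- check_image(img, allow_sentinel = FALSE)
  if (length(mono_levels) > 0 &&
      any(mono_levels < 0 | mono_levels > 255 | mono_levels != floor(mono_levels)))
    stop("'mono_levels' must be integer levels in 0..255")
  out <- img
  if (length(mono_levels) > 0) {
    hit <- which(matrix(img %in% as.integer(mono_levels), nrow(img)), arr.ind = TRUE)
    if (nrow(hit) > 0) {
      ord <- order(hit[, 1L], hit[, 2L])  # row-major sentinel numbering
      out[hit[ord, , drop = FALSE]] <- -seq_len(nrow(hit))
    }
    n_masked <- nrow(hit)
  } else {
    n_masked <- 0L
  }
  structure(out, class = c("masked_image", class(out)),
            sentinel_count = as.integer(n_masked))
}

#' Number of sentinel (masked) pixels in an image
#' @param img an image matrix, masked or not.
#' @return Integer count of sentinel pixels.
#' @export
sentinel_count <- function(img) {
  sc <- attr(img, "sentinel_count")
  if (!is.null(sc)) return(sc)
  sum(img < 0)
}

#' @export
print.masked_image <- function(x, ...) {
  cat(sprintf("masked image: %d x %d pixels, %d masked\n",
              nrow(x), ncol(x), sentinel_count(x)))
  invisible(x)
}
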