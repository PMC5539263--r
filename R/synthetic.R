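# Seeded fixtures with known ground truth, emulating the screening scenarios:
# a noisy micrograph/blot-like background in which rectangles are copied and
# pasted (possibly brightness-shifted), and duplicated crops across a pair of
# images. Backgrounds are i.i.d. uniform integer noise: the simplest model of
# the "weak background noise" that makes copied areas detectable at all.
# Every generator is a pure function of its arguments including the seed.

#' Generate a noisy background image
#'
#' I.i.d. uniform integer gray levels on `[level_low, level_high]`. A spread
#' of 64 or more distinct levels keeps chance pixel collisions per shift an
#' order of magnitude below the signal of a planted copy of 100+ pixels.
#'
#' @param rows,cols image extent in pixels.
#' @param level_low,level_high inclusive gray-level range, within 0..255.
#' @param seed integer seed; the same seed reproduces the image bit-exactly.
#' @return Integer gray-level matrix.
#' @export
gen_background <- function(rows, cols, level_low = 96L, level_high = 159L,
                           seed = 1L) {
  if (rows < 1 || cols < 1) stop("'rows' and 'cols' must be at least 1")
  if (level_low < 0 || level_high > 255 || level_low > level_high)
    stop("need 0 <= level_low <= level_high <= 255")
  lv <- seq.int(level_low, level_high)
  withr::with_seed(as.integer(seed), {
    matrix(lv[sample.int(length(lv), rows * cols, replace = TRUE)],
           nrow = rows, ncol = cols)
  })
}

#' Plant a copied rectangle with known ground truth
#'
#' Copies the `source_rect` block onto `dest_origin`, adding `offset_levels`
#' to every copied pixel (a brightness-shifted copy, the case the variance
#' algorithm exists for). The offset must not push any level outside 0..255;
#' clipping would break the exact level arithmetic the detectors rely on, so
#' it is an error rather than silently saturated.
#'
#' @param img integer gray-level matrix.
#' @param source_rect `c(row, col, height, width)`, 1-based.
#' @param dest_origin `c(row, col)` of the pasted block's top-left, 1-based.
#' @param offset_levels integer brightness offset added to the copy.
#' @return List: `image` (the manipulated matrix) and `shift`, the 0-based
#'   ground-truth cyclic shift `c(di, dj)` at which the comparison algorithms
#'   superimpose the pasted block on its source.
#' @export
plant_copy <- function(img, source_rect, dest_origin, offset_levels = 0L) {
  img <- check_image(img, allow_sentinel = FALSE)
  if (length(source_rect) != 4L || length(dest_origin) != 2L)
    stop("'source_rect' must be c(row, col, height, width) and 'dest_origin' c(row, col)")
  sr <- as.integer(source_rect); dor <- as.integer(dest_origin)
  h <- sr[3L]; w <- sr[4L]
  if (h < 1 || w < 1) stop("copy extent must be at least 1 x 1")
  if (sr[1L] < 1 || sr[2L] < 1 || sr[1L] + h - 1L > nrow(img) ||
      sr[2L] + w - 1L > ncol(img))
    stop("'source_rect' must lie inside the image")
  if (dor[1L] < 1 || dor[2L] < 1 || dor[1L] + h - 1L > nrow(img) ||
      dor[2L] + w - 1L > ncol(img))
    stop("destination rectangle must lie inside the image")
  block <- img[sr[1L]:(sr[1L] + h - 1L), sr[2L]:(sr[2L] + w - 1L), drop = FALSE] +
    as.integer(offset_levels)
  if (any(block < 0L | block > 255L))
    stop("'offset_levels' pushes copied levels outside 0..255 (clipping not allowed)")
  img[dor[1L]:(dor[1L] + h - 1L), dor[2L]:(dor[2L] + w - 1L)] <- block
  shift <- c((dor[1L] - sr[1L]) %% nrow(img), (dor[2L] - sr[2L]) %% ncol(img))
  list(image = img, shift = as.integer(shift))
}

#' Build a duplicated-crop image pair
#'
#' Returns the original image together with a cropped detail of it -- the
#' duplicated-figure scenario, where a published panel turns out to be a
#' detail of another. The ground-truth shift is the crop origin: comparing
#' the pair, the comparison window is the crop extent and the crop is
#' superimposed on its source region at exactly that shift.
#'
#' @param img integer gray-level matrix.
#' @param crop_rect `c(row, col, height, width)`, 1-based, inside `img`.
#' @return List: `a` (the original), `b` (the crop) and `shift`, the 0-based
#'   ground-truth `c(di, dj)`.
#' @export
gen_duplicate_pair <- function(img, crop_rect) {
  img <- check_image(img, allow_sentinel = FALSE)
  if (length(crop_rect) != 4L) stop("'crop_rect' must be c(row, col, height, width)")
  cr <- as.integer(crop_rect)
  if (cr[3L] < 1 || cr[4L] < 1) stop("crop extent must be at least 1 x 1")
  if (cr[1L] < 1 || cr[2L] < 1 || cr[1L] + cr[3L] - 1L > nrow(img) ||
      cr[2L] + cr[4L] - 1L > ncol(img))
    stop("'crop_rect' must lie inside the image")
  crop <- img[cr[1L]:(cr[1L] + cr[3L] - 1L), cr[2L]:(cr[2L] + cr[4L] - 1L),
              drop = FALSE]
  list(a = img, b = crop, shift = c(cr[1L] - 1L, cr[2L] - 1L))
}

#' Write a fixture image with a ground-truth sidecar
#'
#' Saves the image as lossless PNG plus a JSON sidecar (`<path>.json`)
#' recording the generator parameters and ground truth, so a scan of the
#' fixture can be checked against what was planted.
#'
#' @param img integer gray-level matrix.
#' @param path output PNG path.
#' @param spec list of generator parameters and ground truth to record.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(img, path, spec = list()) {
  write_image(img, path)
  jsonlite::write_json(spec, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
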