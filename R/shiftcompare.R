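# Shift conventions
# -----------------
# A shift (di, dj) slides one image over the other by di rows and dj columns;
# rows/columns pushed past the edge wrap around to the opposite side (cyclic
# shift), so for equal sizes every pixel pair meets at exactly one shift.
# Shifts are 0-based; grid entry [di + 1, dj + 1] scores shift (di, dj).
# The comparison window is min(rows) x min(cols) and the shift space
# max(rows) x max(cols). In each dimension the larger image (the first on
# ties) is indexed cyclically by the shift and the other directly: window
# position i pairs wrapped[(i + d) mod n] with direct[i]. Hence a shift by
# one row pairs the first row of the first image with the last row of the
# second, and a cropped detail is superimposed on its source region at the
# shift equal to its crop origin, whichever argument order is used.

overlay_frames <- function(A, B, shift, w) {
  wrapA <- c(nrow(A) >= nrow(B), ncol(A) >= ncol(B))
  wn <- c(if (wrapA[1]) nrow(A) else nrow(B), if (wrapA[2]) ncol(A) else ncol(B))
  idx <- function(k) {
    direct <- seq_len(w[k])
    wrapped <- ((direct - 1L + shift[k]) %% wn[k]) + 1L
    if (wrapA[k]) list(a = wrapped, b = direct) else list(a = direct, b = wrapped)
  }
  list(rows = idx(1L), cols = idx(2L), wrapA = wrapA, wn = wn)
}

new_shift_grid <- function(m, algorithm, window) {
  structure(m, class = c("shift_grid", class(m)),
            algorithm = algorithm, window = as.integer(window))
}

#' @export
print.shift_grid <- function(x, ...) {
  cat(sprintf("shift grid (%s): %d x %d shifts, window %d x %d\n",
              attr(x, "algorithm"), nrow(x), ncol(x),
              attr(x, "window")[1], attr(x, "window")[2]))
  cat(sprintf("  scores: min %g, max %g\n", min(x), max(x)))
  invisible(x)
}

#' @export
as.matrix.shift_grid <- function(x, ...) {
  attributes(x) <- list(dim = dim(x))
  x
}

window_dims <- function(A, B) c(min(nrow(A), nrow(B)), min(ncol(A), ncol(B)))
shift_dims  <- function(A, B) c(max(nrow(A), nrow(B)), max(ncol(A), ncol(B)))

#' Superimpose two images at one cyclic shift
#'
#' Slides one image over the other by `shift = c(di, dj)` and returns the
#' paired pixel values over the comparison window (the smaller of the two
#' extents in each dimension). In each dimension the larger image -- the
#' first one on ties -- is indexed cyclically, so pixels pushed past its edge
#' wrap to the opposite side: for equal sizes a shift by one row pairs the
#' first row of `A` with the last row of `B`.
#'
#' @param A,B gray-level matrices (masked or not).
#' @param shift integer vector `c(di, dj)`, 0-based, `di` in `[0, M)` and
#'   `dj` in `[0, N)` where `M x N` is the shift space.
#' @return List with matrices `a` and `b`: the paired pixel values over the
#'   comparison window (`a[i, j]` is superimposed on `b[i, j]`).
#' @export
cyclic_overlay <- function(A, B, shift) {
  A <- check_image(A); B <- check_image(B)
  sd <- shift_dims(A, B)
  if (length(shift) != 2L || any(shift != floor(shift)))
    stop("'shift' must be two integers c(di, dj)")
  if (shift[1] < 0 || shift[1] >= sd[1] || shift[2] < 0 || shift[2] >= sd[2])
    stop(sprintf("shift (%d, %d) outside the shift space %d x %d",
                 shift[1], shift[2], sd[1], sd[2]))
  w <- window_dims(A, B)
  fr <- overlay_frames(A, B, shift, w)
  list(a = A[fr$rows$a, fr$cols$a, drop = FALSE],
       b = B[fr$rows$b, fr$cols$b, drop = FALSE])
}

#' Identical-pixel count for every cyclic shift
#'
#' For each shift `(di, dj)` counts the superimposed pixel pairs whose gray
#' levels are exactly equal. Equality is exact integer equality on 0..255;
#' sentinel (masked) pixels never match. The self-comparison at shift (0, 0)
#' scores the full window area for an unmasked image.
#'
#' @param A,B gray-level matrices; `B` defaults to `A` (self-scan).
#' @return A `shift_grid` of integer counts, one per shift, indexed
#'   `[di + 1, dj + 1]`.
#' @seealso [nn_shift_counts()], [variance_shift_sums()], [match_mask()]
#' @export
pixelwise_shift_counts <- function(A, B = A) {
  A <- check_image(A); B <- check_image(B)
  new_shift_grid(cpp_pixelwise_grid(A, B), "pixelwise", window_dims(A, B))
}

#' Identical 3x3-neighborhood count for every cyclic shift
#'
#' Counts, per shift, the anchor positions whose full 3x3 pixel block is
#' identical in both superimposed images. The count is recorded at the
#' position of the block's top-left pixel; blocks do not wrap across the
#' window edge. Far fewer chance matches than single pixels, so small copied
#' areas stand out, but a single changed pixel in a block destroys the match.
#'
#' @inheritParams pixelwise_shift_counts
#' @return A `shift_grid` of integer counts in `[0, (m-2)(n-2)]` for an
#'   `m x n` window.
#' @export
nn_shift_counts <- function(A, B = A) {
  A <- check_image(A); B <- check_image(B)
  new_shift_grid(cpp_nn_grid(A, B), "nearest_neighbor", window_dims(A, B))
}

#' Accumulated 3x3-block variance of the difference image, per shift
#'
#' At each shift the two windows are subtracted and, for every 3x3 block,
#' the population variance (divide by 9) of the nine differences is
#' computed; the per-shift score is the sum over all blocks. Regions that
#' are identical up to a constant brightness offset have zero difference
#' variance, so low scores flag similarity that exact-equality counting
#' misses. The score at shift (0, 0) of a self-comparison is exactly 0.
#'
#' Blocks that would cross the cyclic seam of either image are skipped: a
#' seam-crossing block juxtaposes opposite image edges, so its variance is
#' pure noise, and dropping it makes the statistic exactly symmetric under
#' mirroring a shift (`grid(A,B)[i,j] == grid(B,A)[(M-i) mod M, (N-j) mod N]`).
#' The counting algorithms keep seam-crossing blocks, where a spurious exact
#' match is essentially impossible.
#'
#' Masked images are rejected: a sentinel has no gray value to subtract, so
#' the variance algorithm does not work for images with monochrome areas.
#'
#' @inheritParams pixelwise_shift_counts
#' @return A `shift_grid` of non-negative numeric sums; low values are the
#'   conspicuous ones.
#' @export
variance_shift_sums <- function(A, B = A) {
  A <- check_image(A); B <- check_image(B)
  new_shift_grid(cpp_variance_grid(A, B), "variance", window_dims(A, B))
}

#' Per-pixel match map at a single shift
#'
#' Marks, over the comparison window, where the superimposed pixels (or the
#' full 3x3 block anchored there, for the nearest-neighbor algorithm) are
#' identical at one given shift. This is the map used to visualize and
#' reconstruct the duplicated regions behind a conspicuous shift. The
#' variance algorithm has no per-pixel identity notion and is not supported.
#'
#' @inheritParams cyclic_overlay
#' @param algorithm `"pixelwise"` or `"nearest_neighbor"`.
#' @return Logical matrix over the comparison window; for
#'   `"nearest_neighbor"`, `TRUE` only at block anchor positions. The number
#'   of `TRUE` entries equals the corresponding shift-grid score.
#' @export
match_mask <- function(A, B = A, shift,
                       algorithm = c("pixelwise", "nearest_neighbor")) {
  algorithm <- match.arg(algorithm)
  ov <- cyclic_overlay(A, B, shift)
  eq <- ov$a == ov$b & ov$a >= 0L & ov$b >= 0L
  if (algorithm == "pixelwise") return(eq)
  m <- nrow(eq); n <- ncol(eq)
  if (m < 3L || n < 3L)
    stop("comparison window must be at least 3x3 for the nearest-neighbor algorithm")
  blk <- function(dr, dc) eq[seq_len(m - 2L) + dr, seq_len(n - 2L) + dc, drop = FALSE]
  anchors <- blk(0L, 0L) & blk(1L, 0L) & blk(2L, 0L) &
             blk(0L, 1L) & blk(1L, 1L) & blk(2L, 1L) &
             blk(0L, 2L) & blk(1L, 2L) & blk(2L, 2L)
  out <- matrix(FALSE, m, n)
  out[seq_len(m - 2L), seq_len(n - 2L)] <- anchors
  out
}

#' Find every exact recurrence of a rectangular block
#'
#' Compares the `height x width` block anchored at `anchor` (its top-left
#' pixel, 1-based) with every possible placement in the image and returns all
#' top-left positions where the block recurs exactly, including the anchor
#' itself. Useful when a suspicious area is already known and its origin is
#' sought.
#'
#' @param img gray-level matrix.
#' @param anchor `c(row, col)` of the block's top-left pixel, 1-based.
#' @param height,width block extent in pixels.
#' @return Two-column integer matrix of 1-based `(row, col)` positions in
#'   row-major order.
#' @export
block_template_search <- function(img, anchor, height, width) {
  img <- check_image(img)
  if (length(anchor) != 2L || any(anchor != floor(anchor)))
    stop("'anchor' must be two integers c(row, col)")
  if (height < 1 || width < 1)
    stop("'height' and 'width' must be at least 1")
  if (anchor[1] < 1 || anchor[2] < 1 ||
      anchor[1] + height - 1 > nrow(img) || anchor[2] + width - 1 > ncol(img))
    stop("the block must lie inside the image")
  hits <- cpp_block_search(img, as.integer(anchor[1]) - 1L,
                           as.integer(anchor[2]) - 1L,
                           as.integer(height), as.integer(width))
  hits <- hits + 1L
  colnames(hits) <- c("row", "col")
  hits
}

#' Reference shift grids by direct enumeration
#'
#' Recomputes any of the three per-shift statistics with plain R loops over
#' shifts, window positions and block pixels, sharing no code with the
#' optimized routines. Intended as an independent cross-check on small inputs
#' (about 16x16 or less); it is orders of magnitude slower than the
#' production functions.
#'
#' @inheritParams pixelwise_shift_counts
#' @param algorithm which statistic to enumerate.
#' @return A `shift_grid` with the same contract as the corresponding
#'   optimized function.
#' @export
brute_force_oracle <- function(A, B = A,
                               algorithm = c("pixelwise", "nearest_neighbor",
                                             "variance")) {
  algorithm <- match.arg(algorithm)
  A <- check_image(A); B <- check_image(B)
  if (algorithm == "variance" && (any(A < 0) || any(B < 0)))
    stop("variance oracle: masked (sentinel) pixels present")
  w <- window_dims(A, B); sd <- shift_dims(A, B)
  mw <- w[1]; nw <- w[2]
  if (algorithm != "pixelwise" && (mw < 3 || nw < 3))
    stop("comparison window must be at least 3x3")
  # per-element index arithmetic, written out independently of the optimized
  # code: the larger image (first on ties) wraps by the shift, the other is
  # indexed directly (1-based here)
  arow <- function(i, di) if (nrow(A) >= nrow(B)) ((i - 1L + di) %% nrow(A)) + 1L else i
  brow <- function(i, di) if (nrow(A) >= nrow(B)) i else ((i - 1L + di) %% nrow(B)) + 1L
  acol <- function(j, dj) if (ncol(A) >= ncol(B)) ((j - 1L + dj) %% ncol(A)) + 1L else j
  bcol <- function(j, dj) if (ncol(A) >= ncol(B)) j else ((j - 1L + dj) %% ncol(B)) + 1L
  wrap_r <- max(nrow(A), nrow(B)); wrap_c <- max(ncol(A), ncol(B))
  out <- matrix(if (algorithm == "variance") 0 else 0L, sd[1], sd[2])
  for (di in 0:(sd[1] - 1L)) {
    for (dj in 0:(sd[2] - 1L)) {
      acc <- if (algorithm == "variance") 0 else 0L
      if (algorithm == "pixelwise") {
        for (i in seq_len(mw)) for (j in seq_len(nw)) {
          a <- A[arow(i, di), acol(j, dj)]
          b <- B[brow(i, di), bcol(j, dj)]
          if (a == b && a >= 0L) acc <- acc + 1L
        }
      } else {
        for (i in seq_len(mw - 2L)) for (j in seq_len(nw - 2L)) {
          ab <- bb <- matrix(0L, 3L, 3L)
          for (u in 0:2) for (v in 0:2) {
            ab[u + 1L, v + 1L] <- A[arow(i + u, di), acol(j + v, dj)]
            bb[u + 1L, v + 1L] <- B[brow(i + u, di), bcol(j + v, dj)]
          }
          if (algorithm == "nearest_neighbor") {
            if (all(ab == bb) && all(ab >= 0L)) acc <- acc + 1L
          } else {
            # seam rule: the block must be contiguous in the wrapped frame
            wr <- ((i + 0:2 - 1L + di) %% wrap_r)
            wc <- ((j + 0:2 - 1L + dj) %% wrap_c)
            if (all(diff(wr) == 1L) && all(diff(wc) == 1L)) {
              d <- as.numeric(ab) - as.numeric(bb)
              acc <- acc + mean((d - mean(d))^2)
            }
          }
        }
      }
      out[di + 1L, dj + 1L] <- acc
    }
  }
  alg_name <- c(pixelwise = "pixelwise", nearest_neighbor = "nearest_neighbor",
                variance = "variance")[[algorithm]]
  new_shift_grid(out, alg_name, w)
}

#' Write a shift grid (or any matrix) as CSV
#'
#' Row and column names record the 0-based shift each entry scores.
#'
#' @param grid a `shift_grid` or plain matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  m <- as.matrix(grid)
  dimnames(m) <- list(0:(nrow(m) - 1L), 0:(ncol(m) - 1L))
  write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' Write a matrix as a grayscale PNG heatmap
#'
#' Values are min-max scaled to the full 8-bit range for visual inspection
#' (a constant matrix maps to mid-gray). For the variance algorithm pass
#' `invert = TRUE` so that the conspicuous (low) scores appear bright.
#'
#' @param grid a `shift_grid`, localization grid or plain matrix.
#' @param path output file path.
#' @param invert flip the scale so low values are bright.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(grid, path, invert = FALSE) {
  m <- as.matrix(grid)
  rng <- range(m)
  v <- if (rng[1] == rng[2]) matrix(0.5, nrow(m), ncol(m)) else (m - rng[1]) / (rng[2] - rng[1])
  if (invert) v <- 1 - v
  png::writePNG(v, target = path)
  invisible(path)
}
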