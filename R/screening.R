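# From raw shift grids to ranked findings: exclude the trivial small shifts
# (neighborhood autocorrelation, not manipulation), threshold and rank the
# rest, localize where in the image the duplicated material sits, and report.

toroidal_dist <- function(idx0, extent) pmin(idx0, extent - idx0)

#' Flag trivial shifts near the origin
#'
#' Very small displacements score highly on any natural image simply because
#' neighboring pixels are similar to each other; those shifts are not
#' evidence of manipulation. All shifts within toroidal Chebyshev distance
#' `radius` of shift (0, 0) are flagged ineligible (the distance is toroidal
#' because a shift of `M - 1` rows is a shift of one row in the other
#' direction). Radius 0 removes only the identity shift (0, 0).
#'
#' @param grid a `shift_grid`.
#' @param radius exclusion radius in pixels (default 5).
#' @return The grid with excluded entries set to `NA` and a logical
#'   `excluded` attribute marking them.
#' @export
exclude_trivial_shifts <- function(grid, radius = 5L) {
  if (radius < 0 || radius != floor(radius))
    stop("'radius' must be a non-negative integer")
  M <- nrow(grid); N <- ncol(grid)
  dr <- toroidal_dist(0:(M - 1L), M)
  dc <- toroidal_dist(0:(N - 1L), N)
  excluded <- outer(dr, dc, pmax) <= radius
  if (all(excluded))
    stop(sprintf("empty candidate space: exclusion radius %d removes all %d x %d shifts",
                 radius, M, N))
  out <- grid
  out[excluded] <- NA
  attr(out, "excluded") <- excluded
  attr(out, "radius") <- as.integer(radius)
  out
}

#' Canonical representative of a self-comparison shift pair
#'
#' On a self-scan every shift `(di, dj)` and its mirror
#' `((M - di) mod M, (N - dj) mod N)` superimpose the same pixel pairs and
#' score identically -- they are the same move seen from either end. The
#' canonical representative is the row-major smaller of the two.
#'
#' @param shift integer `c(di, dj)`, 0-based.
#' @param dims shift-space extent `c(M, N)`.
#' @return The canonical `c(di, dj)`.
#' @export
canonical_shift <- function(shift, dims) {
  mirror <- c((dims[1] - shift[1]) %% dims[1], (dims[2] - shift[2]) %% dims[2])
  as.integer(
    if (mirror[1] < shift[1] || (mirror[1] == shift[1] && mirror[2] < shift[2]))
      mirror else shift)
}

#' Rank conspicuous shifts
#'
#' Applies the trivial-shift exclusion, then keeps the eligible shifts whose
#' score passes the threshold: strictly above it for the counting algorithms
#' (`direction = "high"`), strictly below for the variance algorithm
#' (`direction = "low"`). Candidates are ordered by score (descending for
#' high, ascending for low); ties are broken row-major by `(di, dj)` so the
#' ranking is deterministic.
#'
#' When no absolute threshold is given it defaults to a grid quantile of the
#' eligible scores -- the top 0.05% for `"high"`, the bottom 0.1% for
#' `"low"` -- because absolute counts depend on image size and level spread.
#' What matters is a score conspicuous relative to the other shifts, not its
#' absolute value.
#'
#' With `collapse_mirror = TRUE` the mirror folding happens *before*
#' thresholding and ranking: on a self-scan every non-trivial shift scores
#' identically to its mirror, so leaving both in would make the default
#' quantile threshold sit exactly on such a tied maximum and discard it.
#'
#' @param grid a `shift_grid`.
#' @param threshold absolute score cut, or `NULL` for the quantile default.
#' @param direction `"high"` (counting algorithms) or `"low"` (variance).
#' @param radius trivial-shift exclusion radius, passed to
#'   [exclude_trivial_shifts()].
#' @param collapse_mirror on a self-scan, fold each shift with its mirror
#'   (see [canonical_shift()]) and keep one candidate per pair.
#' @return Data frame with columns `di`, `dj` (0-based shift), `score`,
#'   `rank` and `algorithm`.
#' @export
find_candidate_shifts <- function(grid, threshold = NULL,
                                  direction = c("high", "low"),
                                  radius = 5L, collapse_mirror = FALSE) {
  direction <- match.arg(direction)
  algorithm <- attr(grid, "algorithm")
  if (is.null(algorithm)) algorithm <- "unknown"
  g <- exclude_trivial_shifts(grid, radius)
  eligible <- !attr(g, "excluded")
  scores <- as.matrix(g)
  idx <- which(eligible, arr.ind = TRUE)
  cand <- data.frame(di = idx[, 1L] - 1L, dj = idx[, 2L] - 1L,
                     score = scores[eligible])
  if (collapse_mirror) {
    # the mirror of a non-trivial shift is non-trivial, so folding keeps
    # exactly one eligible representative per pair
    dims <- dim(scores)
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      identical(canonical_shift(c(cand$di[i], cand$dj[i]), dims),
                c(cand$di[i], cand$dj[i]))
    }, TRUE)
    cand <- cand[keep, , drop = FALSE]
  }
  if (is.null(threshold)) {
    p <- if (direction == "high") 1 - 0.0005 else 0.001
    threshold <- as.numeric(quantile(cand$score, p, names = FALSE))
  }
  cand <- cand[if (direction == "high") cand$score > threshold
               else cand$score < threshold, , drop = FALSE]
  ord <- order(if (direction == "high") -cand$score else cand$score,
               cand$di, cand$dj)
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  cand$rank <- seq_len(nrow(cand))
  cand$algorithm <- rep(algorithm, nrow(cand))
  attr(cand, "threshold") <- threshold
  attr(cand, "radius") <- as.integer(radius)
  cand
}

#' Localization matrix for the nearest-neighbor algorithm
#'
#' Entry `(r, c)` counts, over all shifts, how often the 3x3 block anchored
#' at `(r, c)` is identical in both superimposed images. Duplicated material
#' accumulates counts at its own location across the shifts that reproduce
#' it, so high-count areas show *where* in the image the copied regions lie,
#' complementing the shift grid which only says by *how much* they are
#' displaced.
#'
#' @inheritParams pixelwise_shift_counts
#' @return Integer matrix over the comparison window (counts at block anchor
#'   positions; the two last rows/columns hold no anchors and stay 0). Its
#'   total equals the total of the nearest-neighbor shift grid.
#' @export
localization_nn <- function(A, B = A) {
  A <- check_image(A); B <- check_image(B)
  cpp_localization_nn(A, B)
}

#' Localization matrix for the variance algorithm
#'
#' Entry `(r, c)` counts, over all shifts, how often the difference variance
#' of the 3x3 block anchored at `(r, c)` falls strictly below `cutpoint`.
#'
#' @inheritParams variance_shift_sums
#' @param cutpoint positive variance threshold (gray levels squared).
#' @return Integer matrix over the comparison window.
#' @export
localization_variance <- function(A, B = A, cutpoint) {
  A <- check_image(A); B <- check_image(B)
  if (!is.numeric(cutpoint) || length(cutpoint) != 1L || cutpoint <= 0)
    stop("'cutpoint' must be a single positive number")
  cpp_localization_variance(A, B, cutpoint)
}

# Largest all-TRUE axis-aligned rectangle in a logical matrix, by the
# histogram method. Ties: smallest top row, then smallest left column, then
# largest height. Returns c(row, col, height, width, area) or NULL.
largest_rectangle <- function(mask) {
  m <- nrow(mask); n <- ncol(mask)
  heights <- integer(n)
  best <- NULL
  for (r in seq_len(m)) {
    heights <- ifelse(mask[r, ], heights + 1L, 0L)
    # largest rectangle in histogram via stack
    stack_pos <- integer(0); stack_h <- integer(0)
    for (c in seq_len(n + 1L)) {
      h <- if (c <= n) heights[c] else 0L
      start <- c
      while (length(stack_h) > 0 && stack_h[length(stack_h)] > h) {
        ph <- stack_h[length(stack_h)]; pp <- stack_pos[length(stack_pos)]
        stack_h <- stack_h[-length(stack_h)]; stack_pos <- stack_pos[-length(stack_pos)]
        area <- ph * (c - pp)
        cand <- c(r - ph + 1L, pp, ph, c - pp, area)
        if (is.null(best) || area > best[5L] ||
            (area == best[5L] && (cand[1L] < best[1L] ||
              (cand[1L] == best[1L] && cand[2L] < best[2L]) ||
              (cand[1L] == best[1L] && cand[2L] == best[2L] && cand[3L] > best[3L]))))
          best <- cand
        start <- pp
      }
      if (h > 0 && (length(stack_h) == 0 || stack_h[length(stack_h)] < h)) {
        stack_pos <- c(stack_pos, start); stack_h <- c(stack_h, h)
      }
    }
  }
  best
}

#' Reconstruct the copied rectangles behind a conspicuous shift
#'
#' Given the per-pixel match map of one shift, greedily extracts the largest
#' all-matching axis-aligned rectangle, removes it, and repeats while
#' rectangles of at least `min_area` pixels remain. Each rectangle is
#' reported together with the origin of its shift-displaced partner region,
#' reconstructing the copy-and-paste moves: on a self-scan of a planted copy
#' the rectangle lies on one duplicated region and the partner origin on the
#' other. Isolated chance matches that fit no rectangle are counted as
#' residual pixels; rectangle areas plus the residual always account for
#' every matching pixel.
#'
#' @param mask logical match map from [match_mask()].
#' @param shift the `c(di, dj)` shift the mask belongs to.
#' @param min_area smallest rectangle worth reporting (default 4 pixels);
#'   below this, matches are indistinguishable from chance.
#' @param partner_dims extent of the cyclically indexed image, for the
#'   modular partner coordinates; defaults to the mask extent (self-scan on
#'   equal sizes).
#' @return Data frame with 1-based rectangle (`row`, `col`, `height`,
#'   `width`, `area`) in window coordinates and the partner origin
#'   (`partner_row`, `partner_col`; may wrap), plus attributes `residual`
#'   (count) and `residual_mask`.
#' @export
reconstruct_moves <- function(mask, shift, min_area = 4L, partner_dims = dim(mask)) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("'mask' must be a logical matrix")
  rects <- list()
  work <- mask
  repeat {
    if (!any(work)) break
    r <- largest_rectangle(work)
    if (is.null(r) || r[5L] < min_area) break
    rects[[length(rects) + 1L]] <- r
    work[r[1L]:(r[1L] + r[3L] - 1L), r[2L]:(r[2L] + r[4L] - 1L)] <- FALSE
  }
  if (length(rects) > 0) {
    rm_ <- do.call(rbind, rects)
    out <- data.frame(row = rm_[, 1L], col = rm_[, 2L], height = rm_[, 3L],
                      width = rm_[, 4L], area = rm_[, 5L])
    out$partner_row <- ((out$row - 1L + shift[1]) %% partner_dims[1]) + 1L
    out$partner_col <- ((out$col - 1L + shift[2]) %% partner_dims[2]) + 1L
  } else {
    out <- data.frame(row = integer(0), col = integer(0), height = integer(0),
                      width = integer(0), area = integer(0),
                      partner_row = integer(0), partner_col = integer(0))
  }
  attr(out, "residual") <- sum(work)
  attr(out, "residual_mask") <- work
  attr(out, "shift") <- as.integer(shift)
  out
}

#' Assemble a machine-readable screening report
#'
#' Collects the candidate tables of one scan (one image or one pair) into a
#' single deterministic structure suitable for JSON serialization. Field
#' order is fixed so identical inputs yield byte-identical reports.
#'
#' @param candidates named list of candidate data frames (one per algorithm)
#'   from [find_candidate_shifts()].
#' @param localizations named list of localization summaries (may be empty).
#' @param metadata list with at least `images` (character vector of the image
#'   identifiers the scan used) and `config`; every candidate table must come
#'   from the same scan.
#' @return A list of class `"screening_report"`.
#' @export
screening_report <- function(candidates, localizations = list(), metadata) {
  if (is.null(metadata$images))
    stop("metadata must carry the image identifier(s) in 'images'")
  for (nm in names(candidates)) {
    src <- attr(candidates[[nm]], "images")
    if (!is.null(src) && !identical(unname(src), unname(metadata$images)))
      stop(sprintf("candidate table '%s' comes from images %s, report is for %s",
                   nm, paste(src, collapse = " vs "),
                   paste(metadata$images, collapse = " vs ")))
  }
  cand_out <- lapply(candidates[order(names(candidates))], function(df) {
    list(threshold = attr(df, "threshold"),
         exclusion_radius = attr(df, "radius"),
         n_candidates = nrow(df),
         candidates = df[, c("di", "dj", "score", "rank")])
  })
  structure(list(images = metadata$images,
                 config = metadata$config,
                 algorithms = cand_out,
                 localization = localizations,
                 artifacts = metadata$artifacts),
            class = "screening_report")
}

#' Write a screening report as JSON
#' @param report a `screening_report` (or list of them, for batch runs).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) {
    attr(x, "threshold") <- NULL; attr(x, "radius") <- NULL
    attr(x, "images") <- NULL
    return(x)
  }
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

#' @export
print.screening_report <- function(x, ...) {
  cat("screening report:", paste(x$images, collapse = " vs "), "\n")
  for (nm in names(x$algorithms)) {
    a <- x$algorithms[[nm]]
    cat(sprintf("  %-17s %d candidate shift(s) past threshold %.6g\n",
                paste0(nm, ":"), a$n_candidates, a$threshold))
    if (a$n_candidates > 0) {
      top <- a$candidates[1L, ]
      cat(sprintf("    rank 1: shift (%d, %d), score %.6g\n",
                  top$di, top$dj, top$score))
    }
  }
  invisible(x)
}
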