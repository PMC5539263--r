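# Fixtures are built in code; seeds are fixed so every run sees the same
# images.

rand_img <- function(rows, cols, levels = 0:255, seed = 1L) {
  withr::with_seed(seed, {
    matrix(as.integer(sample(levels, rows * cols, replace = TRUE)), rows, cols)
  })
}

# A noisy background with one planted copy; returns image + canonical shift.
planted_fixture <- function(seed, rows = 100L, cols = 100L, h = 20L, w = 15L,
                            offset = 0L) {
  bg <- gen_background(rows, cols, 96L, 159L, seed = seed)
  withr::with_seed(seed + 1000L, {
    src <- c(sample(seq_len(rows - h + 1L), 1L), sample(seq_len(cols - w + 1L), 1L))
    repeat {  # redraw until the planted shift is outside the trivial zone
      dst <- c(sample(seq_len(rows - h + 1L), 1L), sample(seq_len(cols - w + 1L), 1L))
      d <- c((dst[1] - src[1]) %% rows, (dst[2] - src[2]) %% cols)
      if (max(pmin(d, c(rows, cols) - d)) > 6L) break
    }
  })
  pc <- plant_copy(bg, c(src, h, w), dst, offset_levels = offset)
  list(image = pc$image, shift = pc$shift,
       canonical = canonical_shift(pc$shift, c(rows, cols)),
       src = src, dst = dst)
}

# gray-level histogram over 0..255
level_hist <- function(img) tabulate(as.vector(img) + 1L, nbins = 256L)

mirror_grid <- function(g) {
  m <- as.matrix(g)
  M <- nrow(m); N <- ncol(m)
  m[c(1L, M:2), c(1L, N:2)]
}
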