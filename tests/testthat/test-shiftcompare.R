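test_that("cyclic_overlay pairs pixels with wrap-around", {
  A <- matrix(as.integer(c(0, 2, 1, 3)), 2, 2)  # [[0,1],[2,3]]
  # identity shift pairs each pixel with itself
  ov <- cyclic_overlay(A, A, c(0, 0))
  expect_identical(ov$a, ov$b)
  # full wrap: (0,3),(1,2),(2,1),(3,0) as unordered pairs
  ov <- cyclic_overlay(A, A, c(1, 1))
  pairs <- sort(paste(pmin(ov$a, ov$b), pmax(ov$a, ov$b)))
  expect_identical(pairs, sort(c("0 3", "1 2", "1 2", "0 3")))
  # a shift by one row pairs the first row of A with the last row of B
  B <- matrix(as.integer(10:18), 3, 3)
  A3 <- matrix(as.integer(1:9), 3, 3)
  ov <- cyclic_overlay(A3, B, c(1, 0))
  i <- which(ov$a == A3[1, 1], arr.ind = TRUE)
  expect_identical(ov$b[i], B[3, 1])
  expect_error(cyclic_overlay(A, A, c(2, 0)), "outside the shift space")
})

test_that("cyclic_overlay handles unequal sizes with the min window", {
  A <- rand_img(3, 3, seed = 1)
  B <- rand_img(5, 5, seed = 2)
  ov <- cyclic_overlay(A, B, c(4, 4))
  expect_identical(dim(ov$a), c(3L, 3L))
  expect_identical(dim(ov$b), c(3L, 3L))
  # the larger image wraps: window rows 4,5,1 of B (0-based 4 -> rows 5,1,2)
  expect_identical(ov$b, B[c(5, 1, 2), c(5, 1, 2)])
  expect_identical(ov$a, A)
})

test_that("pixelwise counts match the hand-worked examples", {
  # constant image: every pixel matches at every shift
  C <- matrix(7L, 2, 2)
  expect_true(all(as.matrix(pixelwise_shift_counts(C)) == 4L))
  # all-distinct image: only the identity shift matches
  D <- matrix(as.integer(c(0, 2, 1, 3)), 2, 2)
  expect_identical(as.matrix(pixelwise_shift_counts(D)),
                   matrix(c(4L, 0L, 0L, 0L), 2, 2))
  # histogram identity: two 4x4 images of eight 5s and eight 9s
  A <- matrix(as.integer(rep(c(5, 9), 8)), 4, 4)
  B <- matrix(as.integer(rep(c(9, 5), 8)), 4, 4)
  expect_identical(sum(as.matrix(pixelwise_shift_counts(A, B))), 8L * 8L + 8L * 8L)
})

test_that("nearest-neighbor counts match the hand-worked examples", {
  C <- matrix(7L, 4, 4)
  expect_true(all(as.matrix(nn_shift_counts(C)) == 4L))  # (4-2)^2 anchors
  D <- matrix(as.integer(0:15), 4, 4)
  g <- as.matrix(nn_shift_counts(D))
  expect_identical(g[1, 1], 4L)
  expect_true(all(g[-1] == 0L) && sum(g) == 4L)
  expect_error(nn_shift_counts(matrix(1L, 2, 2)), "at least 3x3")
})

test_that("a planted copy yields at least the interior anchor count", {
  img <- rand_img(50, 50, levels = 0:255, seed = 11)
  pc <- plant_copy(img, c(5, 10, 10, 10), c(25, 15))  # shift (20, 5)
  expect_identical(pc$shift, c(20L, 5L))
  g <- as.matrix(nn_shift_counts(pc$image))
  expect_gte(g[21, 6], (10 - 2) * (10 - 2))
})

test_that("variance sums match the hand-worked examples", {
  A <- rand_img(8, 8, levels = 0:200, seed = 5)
  expect_identical(as.matrix(variance_shift_sums(A, A))[1, 1], 0)
  expect_identical(as.matrix(variance_shift_sums(A, A + 10L))[1, 1], 0)
  # single 3x3 block, one pixel differs by 9: population variance 8
  A3 <- matrix(0L, 3, 3); B3 <- A3; B3[2, 2] <- 9L
  expect_equal(as.matrix(variance_shift_sums(A3, B3))[1, 1], 8)
})

test_that("variance rejects masked images", {
  m <- mask_monochrome(matrix(c(0L, 10L, 20L, 30L, 40L, 50L, 60L, 70L, 80L), 3, 3))
  expect_error(variance_shift_sums(m, m), "monochrome")
  expect_error(localization_variance(m, m, cutpoint = 1), "monochrome")
})

test_that("brightness offsets leave the variance grid unchanged entry-wise", {
  A <- rand_img(12, 12, levels = 60:140, seed = 6)
  g0 <- as.matrix(variance_shift_sums(A, A))
  for (cc in c(1L, 10L, 50L)) {
    expect_equal(as.matrix(variance_shift_sums(A, A + cc)), g0, tolerance = 1e-12)
  }
})

test_that("optimized grids agree with the brute-force oracle", {
  withr::with_seed(99, {
    for (k in 1:8) {
      dims <- sample(3:12, 4, replace = TRUE)
      A <- matrix(as.integer(sample(0:63, dims[1] * dims[2], TRUE)), dims[1], dims[2])
      B <- matrix(as.integer(sample(0:63, dims[3] * dims[4], TRUE)), dims[3], dims[4])
      expect_identical(as.matrix(pixelwise_shift_counts(A, B)),
                       as.matrix(brute_force_oracle(A, B, "pixelwise")))
      expect_identical(as.matrix(nn_shift_counts(A, B)),
                       as.matrix(brute_force_oracle(A, B, "nearest_neighbor")))
      expect_equal(as.matrix(variance_shift_sums(A, B)),
                   as.matrix(brute_force_oracle(A, B, "variance")),
                   tolerance = 1e-9)
    }
  })
})

test_that("oracle agreement holds on masked input too", {
  A <- rand_img(8, 8, levels = c(0L, 255L, 17L, 34L), seed = 12)
  m <- mask_monochrome(A)
  expect_identical(as.matrix(pixelwise_shift_counts(m, m)),
                   as.matrix(brute_force_oracle(m, m, "pixelwise")))
  expect_identical(as.matrix(nn_shift_counts(m, m)),
                   as.matrix(brute_force_oracle(m, m, "nearest_neighbor")))
})

test_that("self-comparison identities hold", {
  for (seed in 1:3) {
    A <- rand_img(9, 7, seed = seed)
    expect_identical(as.matrix(pixelwise_shift_counts(A))[1, 1], 9L * 7L)
    expect_identical(as.matrix(nn_shift_counts(A))[1, 1], 7L * 5L)
    expect_identical(as.matrix(variance_shift_sums(A))[1, 1], 0)
  }
})

test_that("an identical 3x3 block implies at least nine identical pixels", {
  for (seed in 1:5) {
    A <- rand_img(10, 10, levels = 0:15, seed = seed)
    B <- rand_img(10, 10, levels = 0:15, seed = seed + 50)
    gn <- as.matrix(nn_shift_counts(A, B))
    gp <- as.matrix(pixelwise_shift_counts(A, B))
    expect_true(all(gp[gn > 0] >= 9L))
  }
})

test_that("shift grids are mirror-symmetric between argument orders", {
  A <- rand_img(10, 10, levels = 0:31, seed = 21)
  B <- rand_img(10, 10, levels = 0:31, seed = 22)
  expect_identical(as.matrix(pixelwise_shift_counts(A, B)),
                   mirror_grid(pixelwise_shift_counts(B, A)))
  expect_identical(as.matrix(nn_shift_counts(A, B)),
                   mirror_grid(nn_shift_counts(B, A)))
  expect_equal(as.matrix(variance_shift_sums(A, B)),
               mirror_grid(variance_shift_sums(B, A)), tolerance = 1e-9)
})

test_that("match_mask counts agree with the shift grid", {
  A <- rand_img(12, 12, levels = 0:7, seed = 31)
  B <- rand_img(12, 12, levels = 0:7, seed = 32)
  gp <- as.matrix(pixelwise_shift_counts(A, B))
  gn <- as.matrix(nn_shift_counts(A, B))
  for (sh in list(c(0L, 0L), c(3L, 7L), c(11L, 1L))) {
    expect_identical(sum(match_mask(A, B, sh, "pixelwise")), gp[sh[1] + 1, sh[2] + 1])
    expect_identical(sum(match_mask(A, B, sh, "nearest_neighbor")), gn[sh[1] + 1, sh[2] + 1])
  }
  expect_identical(match_mask(A, A, c(0, 0), "pixelwise"), matrix(TRUE, 12, 12))
  expect_error(match_mask(A, B, c(0, 0), "variance"))
})

test_that("match_mask at the planted shift covers the copied rectangle", {
  fx <- planted_fixture(seed = 4)
  mm <- match_mask(fx$image, fx$image, fx$shift, "pixelwise")
  expect_gte(sum(mm), 20L * 15L)
  # the source rectangle itself is fully matched
  expect_true(all(mm[fx$src[1]:(fx$src[1] + 19L), fx$src[2]:(fx$src[2] + 14L)]))
})

test_that("block_template_search finds exactly the recurrences", {
  img <- rand_img(20, 20, levels = 0:255, seed = 41)
  # the whole image recurs only at itself
  expect_identical(unname(block_template_search(img, c(1, 1), 20, 20)),
                   matrix(c(1L, 1L), 1, 2))
  # a planted 5x4 copy from (3,3) to (11,8)
  pc <- plant_copy(img, c(3, 3, 5, 4), c(11, 8))
  hits <- block_template_search(pc$image, c(3, 3), 5, 4)
  expect_identical(unname(hits), matrix(c(3L, 11L, 3L, 8L), 2, 2))
  # brute-force cross-check of the same search
  ref <- list()
  for (r in 1:16) for (c in 1:17) {
    if (identical(pc$image[r:(r + 4), c:(c + 3)], pc$image[3:7, 3:6]))
      ref[[length(ref) + 1L]] <- c(r, c)
  }
  expect_identical(unname(hits), matrix(as.integer(unlist(ref)), ncol = 2, byrow = TRUE))
  expect_error(block_template_search(img, c(18, 18), 5, 5), "inside the image")
})

test_that("grid CSV and heatmap exports round-trip / write files", {
  g <- pixelwise_shift_counts(rand_img(5, 5, seed = 51))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".png")
  write_grid_csv(g, f1)
  got <- as.matrix(utils::read.csv(f1, row.names = 1))
  expect_identical(unname(got), unname(as.matrix(g)))
  write_heatmap(g, f2)
  expect_true(file.exists(f2))
})
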