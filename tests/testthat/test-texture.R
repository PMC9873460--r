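test_that("quantization: identity at 256 levels, binary split, brute force", {
  img <- matrix(0:255, 16, 16)
  expect_identical(quantize(img, 256), matrix(0:255, 16, 16))
  q2 <- quantize(img, 2)
  expect_true(all(q2[img < 128] == 0L) && all(q2[img >= 128] == 1L))
  set.seed(1)
  r <- matrix(floor(stats::runif(100, 0, 256)), 10, 10)
  q8 <- quantize(r, 8)
  expect_identical(q8, matrix(as.integer(floor(r * 8 / 256)), 10, 10))
  expect_error(quantize(img, 1), "levels")
})

test_that("hand-enumerated 2x2 co-occurrence counts", {
  img <- rbind(c(0, 0), c(255, 255))
  g <- compute_glcm(img, glcm_config(levels = 2, displacement = c(0, 1)))
  expect_identical(g$counts, matrix(c(1L, 0L, 0L, 1L), 2, 2))
  gs <- compute_glcm(img, glcm_config(levels = 2, displacement = c(0, 1),
                                      symmetric = TRUE))
  expect_identical(gs$counts, matrix(c(2L, 0L, 0L, 2L), 2, 2))
})

test_that("constant image concentrates all probability in one cell", {
  g <- compute_glcm(matrix(90, 8, 8), glcm_config(levels = 4))
  expect_identical(sum(g$counts > 0), 1L)
  expect_equal(max(g$probs), 1)
  expect_equal(sum(g$probs), 1)
})

test_that("counts equal the brute-force pair enumerator for all displacements", {
  set.seed(2)
  for (rep in 1:10) {
    img <- matrix(floor(stats::runif(144, 0, 256)), 12, 12)
    for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      g <- compute_glcm(img, glcm_config(levels = 8, displacement = d))
      expect_identical(g$counts, glcm_oracle(img, 8, d), info = paste(d, collapse = ","))
      expect_equal(sum(g$probs), 1)
    }
  }
})

test_that("symmetric mode yields a symmetric matrix; transpose duality holds", {
  set.seed(3)
  img <- matrix(floor(stats::runif(400, 0, 256)), 20, 20)
  gs <- compute_glcm(img, glcm_config(levels = 16, displacement = c(1, 1),
                                      symmetric = TRUE))
  expect_identical(gs$counts, t(gs$counts))
  g01 <- compute_glcm(t(img), glcm_config(levels = 16, displacement = c(0, 1)))
  g10 <- compute_glcm(img, glcm_config(levels = 16, displacement = c(1, 0)))
  expect_identical(g01$counts, g10$counts)
})

test_that("displacement larger than the image is rejected", {
  expect_error(compute_glcm(matrix(1, 4, 4),
                            glcm_config(displacement = c(0, 4))), "displacement")
  expect_error(glcm_config(displacement = c(0, 0)), "nonzero")
})

test_that("texture statistics: closed forms and double-loop oracle", {
  g_const <- compute_glcm(matrix(10, 6, 6), glcm_config(levels = 4))
  st <- texture_stats(g_const)
  expect_equal(st$contrast, 0)
  expect_equal(st$energy, 1)
  expect_equal(st$entropy, 0)
  G <- 5
  uni <- matrix(1 / G^2, G, G)
  expect_equal(texture_stats(uni)$entropy, 2 * log(G))
  set.seed(4)
  p <- matrix(stats::runif(16), 4, 4)
  p <- p / sum(p)
  st <- texture_stats(p)
  co <- en <- ho <- ent <- 0
  for (i in 1:4) {
    for (j in 1:4) {
      co <- co + p[i, j] * (i - j)^2
      en <- en + p[i, j]^2
      ho <- ho + p[i, j] / (1 + (i - j)^2)
      if (p[i, j] > 0) ent <- ent - p[i, j] * log(p[i, j])
    }
  }
  expect_equal(st$contrast, co, tolerance = 1e-12)
  expect_equal(st$energy, en, tolerance = 1e-12)
  expect_equal(st$homogeneity, ho, tolerance = 1e-12)
  expect_equal(st$entropy, ent, tolerance = 1e-12)
  expect_error(texture_stats(matrix(0, 4, 4)), "zero")
})

test_that("sliding texture maps: flat zero, edges raise contrast", {
  tm_flat <- texture_maps(matrix(100, 20, 20))
  expect_equal(max(abs(tm_flat$contrast)), 0, tolerance = 1e-12)
  expect_equal(range(tm_flat$homogeneity), c(1, 1), tolerance = 1e-12)
  edge <- cbind(matrix(0, 20, 10), matrix(255, 20, 10))
  tm <- texture_maps(edge, levels = 32, half = 2)
  expect_gt(max(tm$contrast[, 8:12]), 0)
  expect_equal(max(tm$contrast[, 1:5]), 0)
})
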