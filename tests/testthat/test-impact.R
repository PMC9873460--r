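test_that("region derivation: empty input, truth pass-through, set algebra", {
  z <- matrix(0, 20, 20)
  r0 <- derive_regions(z)
  expect_true(r0$empty)
  expect_false(any(r0$core) || any(r0$enhanced) || any(r0$whole))
  ph <- generate_phantom(phantom_spec(seed = 3))
  r <- derive_regions(ph$mask)
  tm <- tumor_masks(ph$mask)
  expect_identical(r$core, tm$core)
  expect_identical(r$enhanced, tm$rim)
  set.seed(4)
  for (i in 1:50) {
    p <- matrix(stats::runif(400), 20, 20)
    rr <- derive_regions(p)
    expect_identical(rr$whole, rr$core | rr$enhanced)
    expect_false(any(rr$core & rr$enhanced))
  }
})

test_that("damage index: degenerate cases and area monotonicity", {
  img <- matrix(100, 30, 30)
  empty <- damage_index(matrix(FALSE, 30, 30), img)
  expect_equal(empty$index, 0)
  expect_equal(empty$erroneous_index, 0)
  m1 <- matrix(FALSE, 30, 30)
  m1[10:15, 10:15] <- TRUE
  di <- damage_index(m1, img)
  expect_equal(di$contrast, 0)
  expect_equal(di$index, log1p(sum(m1)))   # constant region: pure area term
  m2 <- m1
  m2[5:20, 5:20] <- TRUE   # nested, larger
  expect_gt(damage_index(m2, img)$index, di$index)
  # deterministic under seed
  set.seed(5)
  noisy <- matrix(stats::runif(900, 0, 255), 30, 30)
  a <- damage_index(m2, noisy, seed = 7)
  b <- damage_index(m2, noisy, seed = 7)
  expect_identical(a, b)
})

test_that("bootstrap uncertainty shrinks with region size", {
  set.seed(6)
  img <- matrix(stats::runif(120 * 120, 0, 255), 120, 120)
  small <- matrix(FALSE, 120, 120)
  small[1:12, 1:12] <- TRUE
  large <- matrix(FALSE, 120, 120)
  large[1:96, 1:96] <- TRUE
  es <- damage_index(small, img, seed = 1)$erroneous_index /
    damage_index(small, img, seed = 1)$index
  el <- damage_index(large, img, seed = 1)$erroneous_index /
    damage_index(large, img, seed = 1)$index
  expect_lt(el, es)   # relative half-width shrinks with n
})

test_that("impact report conserves areas and attaches spacing", {
  ph <- generate_phantom(phantom_spec(seed = 8))
  r <- derive_regions(ph$mask)
  rep_ <- impact_report(r, unclass(ph$image), pixel_spacing = 0.9, seed = 1)
  expect_equal(rep_$whole_area, rep_$core_area + rep_$enhanced_area)
  expect_equal(rep_$whole_area_mm2, rep_$whole_area * 0.81)
  expect_gte(rep_$erroneous_whole, 0)
})

test_that("progression: zero deltas, growth flag, uncertainty overlap", {
  ph <- generate_phantom(phantom_spec(seed = 9))
  r <- derive_regions(ph$mask)
  a <- impact_report(r, unclass(ph$image), seed = 1)
  pr <- progression(a, a)
  expect_true(all(pr$deltas$absolute == 0))
  expect_false(pr$growth)
  b <- a
  b$whole_area <- round(a$whole_area * 1.5)
  b$whole_index <- a$whole_index * 1.5
  b$erroneous_whole <- 1e-6
  a2 <- a
  a2$erroneous_whole <- 1e-6
  pr2 <- progression(a2, b)
  whole_row <- pr2$deltas[pr2$deltas$quantity == "whole_area", ]
  expect_equal(whole_row$relative, 0.5, tolerance = 1e-3)
  expect_true(pr2$growth)
  # growth within the combined error bars is not flagged
  c_ <- a
  c_$whole_index <- a$whole_index + 0.1
  c_$erroneous_whole <- 1
  a3 <- a
  a3$erroneous_whole <- 1
  expect_false(progression(a3, c_)$growth)
  d <- a
  d$pixel_spacing <- 2
  expect_error(progression(a, d), "spacing")
})

test_that("overlays color exactly the masked pixels, deterministically", {
  ph <- generate_phantom(phantom_spec(seed = 10))
  img <- unclass(ph$image)
  r0 <- derive_regions(matrix(0, 228, 228))
  ov0 <- overlay_regions(img, r0)
  expect_equal(matrix(ov0[, , 1], 228, 228), matrix(img / 255, 228, 228),
               tolerance = 1e-12)
  expect_equal(ov0[, , 1], ov0[, , 2])
  r <- derive_regions(ph$mask)
  ov <- overlay_regions(img, r)
  red <- ov[, , 1] == 1 & ov[, , 2] == 0 & ov[, , 3] == 0
  yellow <- ov[, , 1] == 1 & ov[, , 2] == 1 & ov[, , 3] == 0
  expect_identical(sum(red), sum(r$core))
  expect_gte(sum(yellow), sum(r$enhanced))  # grayscale 255 pixels could match
  ov2 <- overlay_regions(img, r)
  expect_identical(ov, ov2)
  expect_error(overlay_regions(img[1:10, ], r), "shape")
})
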