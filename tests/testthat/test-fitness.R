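test_that("between-class variance: closed forms and guards", {
  h <- numeric(256)
  h[101] <- 1   # all mass at level 100
  for (t in c(1, 100, 200)) expect_equal(interclass_variance(h, t), 0)
  h2 <- numeric(256)
  h2[51] <- 0.5
  h2[201] <- 0.5  # two spikes at 50 and 200
  expect_equal(interclass_variance(h2, 128), 0.25 * 150^2)
  expect_error(interclass_variance(h2 * 2, 128), "normalized")
})

test_that("maximizing between-class variance minimizes within-class variance", {
  for (s in 1:100) {
    h <- random_histogram(s)
    expect_identical(otsu_threshold(h), within_class_oracle(h), info = s)
  }
})

test_that("between-class variance never exceeds the total variance", {
  for (s in 1:20) {
    h <- random_histogram(400 + s)
    tot <- histogram_variance(h)
    bc <- vapply(1:255, function(t) interclass_variance(h, t), numeric(1))
    expect_true(all(bc <= tot + 1e-9))
    # decomposition: within + between = total at the argmax
    t_star <- otsu_threshold(h)
    lv <- 0:255
    lo <- lv < t_star
    w1 <- sum(h[lo]); w2 <- sum(h[!lo])
    m1 <- sum(h[lo] * lv[lo]) / w1
    m2 <- sum(h[!lo] * lv[!lo]) / w2
    wc <- sum(h[lo] * (lv[lo] - m1)^2) + sum(h[!lo] * (lv[!lo] - m2)^2)
    expect_equal(wc + interclass_variance(h, t_star), tot, tolerance = 1e-9)
  }
})

test_that("fuzzy-entropy threshold: bimodal bracketing, symmetry, invariances", {
  h <- numeric(256)
  h[65] <- 0.5
  h[193] <- 0.5   # modes at levels 64 and 192
  ft <- fuzzy_entropy_threshold(h)
  expect_gt(ft$c_theta, 64)
  expect_lt(ft$c_theta, 192)
  expect_gte(ft$entropy, 0)
  # mirror image maps the threshold to its reflection (+/- 1)
  hm <- rev(h)
  ftm <- fuzzy_entropy_threshold(hm)
  expect_lte(abs((255 - ft$c_theta) - ftm$c_theta), 1)
  # rescaling by a positive constant before normalization is neutral
  ft2 <- fuzzy_entropy_threshold(h * 37)
  expect_identical(ft2$c_theta, ft$c_theta)
  expect_error(fuzzy_entropy_threshold(c(rep(0, 255), 1)), "degenerate")
})

test_that("fuzzy-entropy score is nonnegative on random histograms", {
  for (s in 1:20) {
    ft <- fuzzy_entropy_threshold(random_histogram(500 + s))
    expect_gte(ft$entropy, 0)
    expect_true(all(ft$memberships$mu_dark >= 0 & ft$memberships$mu_dark <= 1))
  }
})

test_that("intraclass correlation: symmetry point, degenerate cases, oracle", {
  set.seed(6)
  x <- stats::rnorm(500)
  expect_equal(as.numeric(intraclass_correlation(x, x)), 0.5)
  img <- c(rep(1, 50), stats::rnorm(200))
  expect_equal(as.numeric(intraclass_correlation(rep(1, 50), img)), 0)
  flat <- intraclass_correlation(rep(2, 10), rep(2, 100))
  expect_equal(as.numeric(flat), 0)
  expect_true(attr(flat, "degenerate"))
  seg <- stats::runif(120)
  whole <- c(seg, stats::runif(400))
  pv <- function(v) mean((v - mean(v))^2)
  expect_equal(as.numeric(intraclass_correlation(seg, whole)),
               pv(seg) / (pv(seg) + pv(whole)), tolerance = 1e-12)
})

test_that("segment fitness: arithmetic, linearity, empty-segment guard", {
  expect_equal(segment_fitness(228^2, rep(228^2 / 4, 4), p = 1, q = 0), 12996)
  sizes <- c(100, 250, 400)
  f1 <- segment_fitness(750, sizes, total_sp = 3, p = 1, q = 1)
  f2 <- segment_fitness(750, sizes, total_sp = 3, p = 2, q = 1)
  expect_equal(f2 - f1, 750 / 3)   # doubling p doubles the first term
  k <- 4
  n <- 1600
  f <- segment_fitness(n, rep(n / k, k), total_sp = k, p = 0, q = 1)
  expect_equal(f, k * k / (n / k))
  expect_error(segment_fitness(100, c(50, 0, 50)), "2")
})

test_that("class weights: neutrality, separation, missing class", {
  mem <- new_memory()
  x <- rep(seq(0, 1, length.out = 50), 2)
  lab <- rep(c(TRUE, FALSE), each = 50)
  m1 <- update_class_weights(mem, x, lab)
  expect_equal(m1$class_weights$W_p, 1, tolerance = 1e-12)
  # disjoint supports: tumor low, non-tumor high
  x2 <- c(stats::runif(60, 0, 0.3), stats::runif(60, 0.7, 1))
  lab2 <- rep(c(TRUE, FALSE), each = 60)
  m2 <- update_class_weights(mem, x2, lab2)
  expect_gt(m2$class_weights$W_p, 5)
  expect_gt(m2$class_weights$W_q, 0)
  expect_warning(m3 <- update_class_weights(mem, x2, rep(TRUE, 120)), "absent")
  expect_identical(m3$class_weights, mem$class_weights)
})
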