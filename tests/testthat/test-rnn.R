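test_that("zero weights give activations of exactly 0.5 everywhere", {
  w <- rnn_init(3, 4, seed = 1)
  for (nm in c("Wi_ff", "W_ff", "b_ff", "Wi_fb", "W_fb", "b_fb")) {
    w[[nm]] <- w[[nm]] * 0
  }
  out <- rnn_forward(matrix(stats::rnorm(15), 5, 3), w)
  expect_true(all(out$ff == 0.5))
  expect_true(all(out$fb == 0.5))
})

test_that("recurrences match a hand-unrolled oracle", {
  w <- rnn_init(1, 1, seed = 2)
  x <- matrix(c(0.3, -0.5, 0.9), 3, 1)
  out <- rnn_forward(x, w)
  sig <- function(z) 1 / (1 + exp(-z))
  ff <- numeric(3)
  h <- 0
  for (t in 1:3) {
    h <- sig(w$Wi_ff[1, 1] * x[t, 1] + w$W_ff[1, 1] * h + w$b_ff)
    ff[t] <- h
  }
  fb <- numeric(3)
  h <- 0
  for (t in 3:1) {
    h <- sig(w$Wi_fb[1, 1] * x[t, 1] + w$W_fb[1, 1] * h + w$b_fb)
    fb[t] <- h
  }
  expect_equal(out$ff[, 1], ff, tolerance = 1e-12)
  expect_equal(out$fb[, 1], fb, tolerance = 1e-12)
})

test_that("reversing the sequence and swapping directions mirrors the outputs", {
  w <- rnn_init(2, 3, seed = 3)
  x <- matrix(stats::rnorm(12), 6, 2)
  out <- rnn_forward(x, w)
  w_swap <- w
  w_swap$Wi_ff <- w$Wi_fb; w_swap$W_ff <- w$W_fb; w_swap$b_ff <- w$b_fb
  w_swap$Wi_fb <- w$Wi_ff; w_swap$W_fb <- w$W_ff; w_swap$b_fb <- w$b_ff
  out_rev <- rnn_forward(x[6:1, ], w_swap)
  expect_equal(out_rev$fb[6:1, ], out$ff, tolerance = 1e-12)
  expect_equal(out_rev$ff[6:1, ], out$fb, tolerance = 1e-12)
})

test_that("activations stay strictly inside (0, 1)", {
  w <- rnn_init(4, 8, seed = 4)
  x <- matrix(stats::rnorm(40, 0, 10), 10, 4)
  out <- rnn_forward(x, w)
  expect_true(all(out$ff > 0 & out$ff < 1))
  expect_true(all(out$fb > 0 & out$fb < 1))
})

test_that("softmax head: symmetric weights and unit-sum probabilities", {
  w <- rnn_init(2, 3, seed = 5)
  w$W_out <- cbind(rep(0.3, 6), rep(0.3, 6))
  w$b_out <- c(0, 0)
  p <- rnn_classify(matrix(stats::rnorm(8), 4, 2), w)
  expect_equal(unname(p), c(0.5, 0.5))
  w2 <- rnn_init(2, 3, seed = 6)
  for (i in 1:100) {
    p <- rnn_classify(matrix(stats::rnorm(8), 4, 2), w2)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("patch grid arithmetic and labeling", {
  img <- matrix(100, 228, 228)
  patches <- encode_patches(img, NULL, patch_size = 12, stride = 12)
  expect_identical(length(patches), 361L)   # 19 x 19 positions
  expect_identical(patches[[1]]$row, 0L)
  sp <- phantom_spec(seed = 6)
  ph <- generate_phantom(sp)
  all_tumor <- label_mask(matrix(3L, 228, 228))
  pt <- encode_patches(ph$image, all_tumor, 12, 12)
  expect_true(all(vapply(pt, function(p) p$label, character(1)) == "tumor"))
  bal <- encode_patches(ph$image, ph$mask, 12, 6, balanced = TRUE, seed = 2)
  labs <- vapply(bal, function(p) p$label, character(1))
  expect_lte(abs(sum(labs == "tumor") - sum(labs == "nontumor")), 1)
  empty_brain <- label_mask(matrix(0L, 228, 228))
  expect_error(encode_patches(ph$image, empty_brain, 12, 12), "brain")
  expect_error(encode_patches(matrix(1, 8, 8), NULL, 12, 12), "patch_size")
})

test_that("training: schedule, loss, determinism, and class guard", {
  set.seed(7)
  mkseq <- function(mu) list(
    features = matrix(stats::rnorm(18, mu, 1), 6, 3),
    label = if (mu > 0) "tumor" else "nontumor"
  )
  train <- c(lapply(1:40, function(i) mkseq(3)),
             lapply(1:40, function(i) mkseq(-3)))
  fit <- rnn_train(train, rnn_train_config(epochs = 40, lr0 = 0.5, seed = 1))
  expect_true(all(diff(fit$trace$lr) <= 0))
  expect_lt(fit$trace$loss[40], fit$trace$loss[1])
  fit2 <- rnn_train(train, rnn_train_config(epochs = 40, lr0 = 0.5, seed = 1))
  expect_identical(fit$weights, fit2$weights)
  expect_error(rnn_train(train[1:40]), "both classes")
  # learning factor reaches the expected scale by epoch 38
  cfg <- rnn_train_config(epochs = 40)
  lr38 <- cfg$lr0 / (1 + cfg$decay * 37)
  expect_lte(lr38, 0.08)
})

test_that("held-out accuracy on separable Gaussian classes is high", {
  set.seed(8)
  mkseq <- function(mu) list(
    features = matrix(stats::rnorm(18, mu, 1), 6, 3),
    label = if (mu > 0) "tumor" else "nontumor"
  )
  train <- c(lapply(1:100, function(i) mkseq(3)),
             lapply(1:100, function(i) mkseq(-3)))
  test <- c(lapply(1:50, function(i) mkseq(3)),
            lapply(1:50, function(i) mkseq(-3)))
  fit <- rnn_train(train, rnn_train_config(epochs = 100, lr0 = 0.5,
                                           hidden_dim = 8, seed = 1))
  p <- vapply(test, function(s) rnn_classify(s$features, fit$weights)[["tumor"]],
              numeric(1))
  truth <- vapply(test, function(s) s$label == "tumor", logical(1))
  expect_gte(mean((p >= 0.5) == truth), 0.95)
})

test_that("probability maps are covered votes in [0, 1]", {
  ph <- generate_phantom(phantom_spec(seed = 9))
  patches <- encode_patches(ph$image, ph$mask, 12, 12, balanced = TRUE, seed = 1)
  fit <- rnn_train(patches, rnn_train_config(epochs = 30, lr0 = 0.5, seed = 2))
  prob <- classify_image(ph$image, fit$weights, ph$mask, 12, 6)
  expect_true(all(prob >= 0 & prob <= 1))
  expect_identical(dim(prob), c(228L, 228L))
  # refinement keeps the range and zeroes non-brain pixels
  seg <- run_haris(ph$image, haris_config(seed = 2),
                   brain_mask = tumor_masks(ph$mask)$brain)
  ref <- refine_probability(prob, seg)
  expect_true(all(ref >= 0 & ref <= 1))
  expect_true(all(ref[is.na(seg$labels)] == 0))
})
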