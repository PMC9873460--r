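#' Initialize a variational autoencoder
#'
#' A dense Gaussian-posterior VAE for square grayscale images: encoder
#' `x -> tanh -> (mu, logvar)`, standard-normal prior on the latent,
#' decoder `z -> tanh -> sigmoid` with a Bernoulli per-pixel likelihood
#' on `[0, 1]` intensities (a Gaussian likelihood is available via
#' `likelihood`). Sized for desk-scale training (32x32 inputs, latent 8)
#' on one CPU.
#'
#' @param image_side input side length in pixels.
#' @param latent_dim latent dimensionality.
#' @param hidden hidden-layer width.
#' @param likelihood `"bernoulli"` or `"gaussian"`.
#' @param seed RNG seed for the initialization.
#' @return list of class `vae_model` holding the weight matrices.
#' @export
vae_init <- function(image_side = 32L, latent_dim = 8L, hidden = 64L,
                     likelihood = c("bernoulli", "gaussian"), seed = 1L) {
  likelihood <- match.arg(likelihood)
  D <- as.integer(image_side)^2
  H <- as.integer(hidden)
  L <- as.integer(latent_dim)
  set.seed(as.integer(seed))
  xav <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
  }
  structure(list(
    image_side = as.integer(image_side), latent_dim = L, hidden = H,
    likelihood = likelihood, trained = FALSE,
    W1 = xav(D, H), b1 = rep(0, H),
    W_mu = xav(H, L), b_mu = rep(0, L),
    W_lv = xav(H, L), b_lv = rep(0, L),
    W2 = xav(L, H), b2 = rep(0, H),
    W_out = xav(H, D), b_out = rep(0, D)
  ), class = "vae_model")
}

vae_encode <- function(model, X) {
  h1 <- tanh(sweep(X %*% model$W1, 2, model$b1, "+"))
  list(
    h1 = h1,
    mu = sweep(h1 %*% model$W_mu, 2, model$b_mu, "+"),
    lv = sweep(h1 %*% model$W_lv, 2, model$b_lv, "+")
  )
}

vae_decode <- function(model, Z) {
  h2 <- tanh(sweep(Z %*% model$W2, 2, model$b2, "+"))
  logits <- sweep(h2 %*% model$W_out, 2, model$b_out, "+")
  list(h2 = h2, logits = logits, xhat = stats::plogis(logits))
}

#' Closed-form Gaussian KL divergence to the standard normal prior
#'
#' `KL(N(mu, diag(exp(logvar))) || N(0, I)) =
#' 0.5 * sum(mu^2 + exp(logvar) - 1 - logvar)`, always nonnegative.
#'
#' @param mu matrix (rows = samples) or vector of posterior means.
#' @param logvar matching log-variances.
#' @return per-sample KL values.
#' @export
gaussian_kl <- function(mu, logvar) {
  if (is.null(dim(mu))) {
    mu <- matrix(mu, 1)
    logvar <- matrix(logvar, 1)
  }
  0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
}

#' Evidence lower bound of a batch
#'
#' Reconstruction term (expected log-likelihood under the posterior,
#' estimated with one reparameterized sample, or evaluated at the
#' posterior mean when `sample = FALSE`) minus `kl_weight` times the
#' closed-form Gaussian KL.
#'
#' @param model a [vae_model][vae_init()].
#' @param images numeric matrix, one flattened image per row, values in
#'   `[0, 1]`.
#' @param kl_weight weight on the KL term.
#' @param sample draw a reparameterized latent sample (seeded by the
#'   caller) instead of using the posterior mean.
#' @return list with `total`, `reconstruction`, `kl` (batch means).
#' @export
vae_elbo <- function(model, images, kl_weight = 1, sample = FALSE) {
  enc <- vae_encode(model, images)
  z <- if (sample) {
    enc$mu + exp(enc$lv / 2) * matrix(stats::rnorm(length(enc$mu)),
                                      nrow(enc$mu), ncol(enc$mu))
  } else enc$mu
  dec <- vae_decode(model, z)
  if (any(!is.finite(dec$logits))) stop("non-finite decoder activations")
  recon <- mean(bernoulli_ll(images, dec$logits))
  kl <- mean(gaussian_kl(enc$mu, enc$lv))
  list(total = recon - kl_weight * kl, reconstruction = recon, kl = kl)
}

# Row sums of the Bernoulli log-likelihood, computed from logits for
# numerical stability: x*l - log(1 + exp(l)).
bernoulli_ll <- function(X, logits) {
  rowSums(X * logits - log1p(exp(-abs(logits))) - pmax(logits, 0))
}

#' VAE training configuration
#'
#' @param epochs,batch_size,learning_rate,kl_weight,seed the usual
#'   suspects; all positive, `seed` fixes initialization and shuffling.
#' @return list of class `vae_train_config`.
#' @export
vae_train_config <- function(epochs = 200L, batch_size = 32L,
                             learning_rate = 1e-3, kl_weight = 1,
                             seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, kl_weight > 0)
  structure(list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, kl_weight = kl_weight,
    seed = as.integer(seed)
  ), class = "vae_train_config")
}

#' Train the VAE
#'
#' Minibatch Adam on the negative ELBO with the reparameterization
#' trick; aborts on divergence, returning the last finite checkpoint.
#'
#' @param model a [vae_model][vae_init()].
#' @param images matrix of flattened images in `[0, 1]` (>= 16 rows) or
#'   a list of [mri_image()]s (rescaled internally).
#' @param cfg a [vae_train_config()].
#' @return list with `model` (trained) and `trace` (per-epoch data frame
#'   of loss, reconstruction, KL).
#' @export
vae_train <- function(model, images, cfg = vae_train_config()) {
  X <- as_image_matrix(images, model$image_side)
  if (nrow(X) < 16) stop("at least 16 training images required")
  set.seed(cfg$seed)
  par_names <- c("W1", "b1", "W_mu", "b_mu", "W_lv", "b_lv",
                 "W2", "b2", "W_out", "b_out")
  adam_m <- lapply(par_names, function(p) model[[p]] * 0)
  adam_v <- adam_m
  names(adam_m) <- names(adam_v) <- par_names
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  trace <- vector("list", cfg$epochs)
  last_good <- model
  for (epoch in seq_len(cfg$epochs)) {
    idx <- sample(nrow(X))
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    ep_loss <- ep_rec <- ep_kl <- 0
    for (bi in batches) {
      g <- vae_grad(model, X[bi, , drop = FALSE], cfg$kl_weight)
      if (!is.finite(g$loss)) {
        warning("divergence at epoch ", epoch, "; returning last checkpoint")
        return(list(model = last_good,
                    trace = do.call(rbind, trace[seq_len(epoch - 1)])))
      }
      step <- step + 1
      for (p in par_names) {
        adam_m[[p]] <- b1 * adam_m[[p]] + (1 - b1) * g$grads[[p]]
        adam_v[[p]] <- b2 * adam_v[[p]] + (1 - b2) * g$grads[[p]]^2
        mhat <- adam_m[[p]] / (1 - b1^step)
        vhat <- adam_v[[p]] / (1 - b2^step)
        model[[p]] <- model[[p]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
      }
      w <- length(bi) / nrow(X)
      ep_loss <- ep_loss + w * g$loss
      ep_rec <- ep_rec + w * g$recon
      ep_kl <- ep_kl + w * g$kl
    }
    last_good <- model
    trace[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss,
                                 reconstruction = ep_rec, kl = ep_kl)
  }
  model$trained <- TRUE
  list(model = model, trace = do.call(rbind, trace))
}

# One-sample reparameterized gradient of the negative ELBO (batch mean).
vae_grad <- function(model, X, kl_weight) {
  n <- nrow(X)
  enc <- vae_encode(model, X)
  epsn <- matrix(stats::rnorm(length(enc$mu)), n, ncol(enc$mu))
  sd_ <- exp(enc$lv / 2)
  z <- enc$mu + sd_ * epsn
  dec <- vae_decode(model, z)
  recon <- mean(bernoulli_ll(X, dec$logits))
  kl <- mean(gaussian_kl(enc$mu, enc$lv))
  loss <- -(recon - kl_weight * kl)

  dlogits <- (dec$xhat - X) / n
  gW_out <- crossprod(dec$h2, dlogits)
  gb_out <- colSums(dlogits)
  dh2 <- dlogits %*% t(model$W_out)
  da2 <- dh2 * (1 - dec$h2^2)
  gW2 <- crossprod(z, da2)
  gb2 <- colSums(da2)
  dz <- da2 %*% t(model$W2)
  dmu <- dz + kl_weight * enc$mu / n
  dlv <- dz * epsn * sd_ / 2 + kl_weight * (exp(enc$lv) - 1) / (2 * n)
  gW_mu <- crossprod(enc$h1, dmu)
  gb_mu <- colSums(dmu)
  gW_lv <- crossprod(enc$h1, dlv)
  gb_lv <- colSums(dlv)
  dh1 <- dmu %*% t(model$W_mu) + dlv %*% t(model$W_lv)
  da1 <- dh1 * (1 - enc$h1^2)
  gW1 <- crossprod(X, da1)
  gb1 <- colSums(da1)
  list(
    loss = loss, recon = recon, kl = kl,
    grads = list(W1 = gW1, b1 = gb1, W_mu = gW_mu, b_mu = gb_mu,
                 W_lv = gW_lv, b_lv = gb_lv, W2 = gW2, b2 = gb2,
                 W_out = gW_out, b_out = gb_out)
  )
}

#' Sample images from the prior
#'
#' Draws latent vectors from the standard-normal prior and decodes them;
#' outputs are rescaled to the `[0, 255]` intensity contract.
#'
#' @param model a trained [vae_model][vae_init()] (an untrained model
#'   samples too, with a warning).
#' @param n number of images (0 gives an empty list).
#' @param seed RNG seed.
#' @return list of [mri_image()]s flagged `synthetic` in metadata.
#' @export
vae_sample <- function(model, n, seed = 1L) {
  if (!isTRUE(model$trained)) warning("sampling from an untrained model")
  if (n == 0) return(list())
  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(n * model$latent_dim), n, model$latent_dim)
  dec <- vae_decode(model, Z)
  lapply(seq_len(n), function(i) {
    mri_image(matrix(dec$xhat[i, ] * 255, model$image_side, model$image_side),
              meta = list(source = "vae", synthetic = TRUE, seed = seed,
                          index = i))
  })
}

#' Augment a dataset with generated images
#'
#' @param dataset list of [mri_image()]s.
#' @param model trained [vae_model][vae_init()].
#' @param n_new number of generated images to append.
#' @param seed RNG seed for sampling.
#' @return list of images: originals then generated; each generated
#'   image's metadata carries `synthetic = TRUE` and the overall
#'   `generated_fraction`.
#' @export
vae_augment <- function(dataset, model, n_new, seed = 1L) {
  if (n_new == 0) return(dataset)
  gen <- vae_sample(model, n_new, seed)
  frac <- n_new / (length(dataset) + n_new)
  gen <- lapply(gen, function(im) {
    meta <- image_meta(im)
    meta$generated_fraction <- frac
    mri_image(unclass(im), meta = meta)
  })
  c(dataset, gen)
}

# Coerce a list of images (or a matrix) to rows of [0,1] pixels.
as_image_matrix <- function(images, side) {
  if (is.matrix(images) && !inherits(images, "mri_image")) {
    if (max(images) > 1 + 1e-9) images <- images / 255
    return(images)
  }
  if (inherits(images, "mri_image")) images <- list(images)
  do.call(rbind, lapply(images, function(im) {
    m <- unclass(im)
    if (nrow(m) != side || ncol(m) != side) {
      stop("image size ", nrow(m), "x", ncol(m),
           " does not match model image_side ", side)
    }
    as.vector(m) / 255
  }))
}
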