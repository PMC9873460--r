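#' Initialize the bidirectional recurrent classifier
#'
#' The printed recurrences are a sigmoid Elman-style pair — a forward
#' pass `ff_i = sigmoid(W_i ff * pix_i + W_ff * ff_(i-1) + bias)` and a
#' mirror-image backward pass — rather than a gated cell; this
#' implements them literally. The readout is a softmax over
#' tumor/non-tumor on the concatenated final forward and first backward
#' states.
#'
#' @param input_dim per-timestep feature dimension.
#' @param hidden_dim hidden state width.
#' @param seed initialization seed.
#' @return list of class `rnn_weights`.
#' @export
rnn_init <- function(input_dim, hidden_dim = 16L, seed = 1L) {
  set.seed(as.integer(seed))
  H <- as.integer(hidden_dim)
  d <- as.integer(input_dim)
  sc <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, 1 / sqrt(nin)),
                                   nin, nout)
  structure(list(
    input_dim = d, hidden_dim = H,
    Wi_ff = sc(d, H), W_ff = sc(H, H) * 0.5, b_ff = rep(0, H),
    Wi_fb = sc(d, H), W_fb = sc(H, H) * 0.5, b_fb = rep(0, H),
    W_out = sc(2L * H, 2L), b_out = rep(0, 2)
  ), class = "rnn_weights")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Batched forward over a list of T input matrices (n x d each).
# Returns lists FF, FB of T hidden-state matrices (n x H).
rnn_forward_batch <- function(X_list, w) {
  T_ <- length(X_list)
  n <- nrow(X_list[[1]])
  H <- w$hidden_dim
  FF <- FB <- vector("list", T_)
  h <- matrix(0, n, H)
  for (t in seq_len(T_)) {
    h <- sigmoid(sweep(X_list[[t]] %*% w$Wi_ff + h %*% w$W_ff, 2, w$b_ff, "+"))
    if (any(is.na(h))) stop("NaN activation at forward step ", t)
    FF[[t]] <- h
  }
  h <- matrix(0, n, H)
  for (t in rev(seq_len(T_))) {
    h <- sigmoid(sweep(X_list[[t]] %*% w$Wi_fb + h %*% w$W_fb, 2, w$b_fb, "+"))
    if (any(is.na(h))) stop("NaN activation at backward step ", t)
    FB[[t]] <- h
  }
  list(FF = FF, FB = FB)
}

#' Forward and backward recurrent passes over one sequence
#'
#' @param features `T x d` matrix, one feature vector per timestep.
#' @param weights an [rnn_weights][rnn_init()].
#' @return list with `ff` and `fb`, each a `T x hidden_dim` matrix of
#'   activations in `(0, 1)`.
#' @export
rnn_forward <- function(features, weights) {
  if (ncol(features) != weights$input_dim) stop("feature dimension mismatch")
  X_list <- lapply(seq_len(nrow(features)), function(t) features[t, , drop = FALSE])
  out <- rnn_forward_batch(X_list, weights)
  list(
    ff = do.call(rbind, out$FF),
    fb = do.call(rbind, out$FB)
  )
}

#' Classify one patch sequence
#'
#' @param features `T x d` matrix.
#' @param weights an [rnn_weights][rnn_init()].
#' @return named numeric `c(tumor = p, nontumor = 1 - p)`.
#' @export
rnn_classify <- function(features, weights) {
  p <- rnn_classify_batch(list(features), weights)
  c(tumor = p[1], nontumor = 1 - p[1])
}

# Tumor probability for a list of sequences (all same length).
rnn_classify_batch <- function(seq_list, w) {
  T_ <- nrow(seq_list[[1]])
  X_list <- lapply(seq_len(T_), function(t) {
    do.call(rbind, lapply(seq_list, function(s) s[t, ]))
  })
  out <- rnn_forward_batch(X_list, w)
  C <- cbind(out$FF[[T_]], out$FB[[1]])
  logits <- sweep(C %*% w$W_out, 2, w$b_out, "+")
  lm_ <- logits - apply(logits, 1, max)
  e <- exp(lm_)
  (e / rowSums(e))[, 1]
}

#' Training configuration for the recurrent classifier
#'
#' The learning rate decays monotonically, `lr0 / (1 + decay * (epoch -
#' 1))`; the defaults start at 0.1 and fall below 0.08 by epoch 38.
#'
#' @param epochs training epochs.
#' @param lr0 initial learning rate.
#' @param decay hyperbolic decay coefficient.
#' @param hidden_dim hidden width.
#' @param seed seed for initialization and shuffling.
#' @return list of class `rnn_train_config`.
#' @export
rnn_train_config <- function(epochs = 80L, lr0 = 0.1, decay = 0.007,
                             hidden_dim = 16L, seed = 1L) {
  stopifnot(epochs >= 1, lr0 > 0, decay >= 0)
  structure(list(
    epochs = as.integer(epochs), lr0 = lr0, decay = decay,
    hidden_dim = as.integer(hidden_dim), seed = as.integer(seed)
  ), class = "rnn_train_config")
}

#' Train the patch classifier
#'
#' Full-batch gradient descent (backpropagation through time) on the
#' softmax cross-entropy, with per-class loss weights taken from the
#' self-learning memory (`W_p` for non-tumor, `W_q` for tumor,
#' normalized to unit mean over the batch). The memory's run log is
#' appended with the final loss and learning factor.
#'
#' @param patches list of patch sequences, each with `features`
#'   (`T x d`) and `label` (`"tumor"`/`"nontumor"`).
#' @param cfg an [rnn_train_config()].
#' @param memory a [new_memory()] state (class weights are read from
#'   it and the run is logged into it).
#' @return list with `weights`, `trace` (per-epoch loss, accuracy,
#'   learning rate), `memory`.
#' @export
rnn_train <- function(patches, cfg = rnn_train_config(), memory = new_memory()) {
  labels <- vapply(patches, function(p) identical(p$label, "tumor") ||
                     isTRUE(p$label), logical(1))
  if (!any(labels) || all(labels)) stop("both classes must be present")
  T_ <- nrow(patches[[1]]$features)
  d <- ncol(patches[[1]]$features)
  n <- length(patches)
  X_list <- lapply(seq_len(T_), function(t) {
    do.call(rbind, lapply(patches, function(p) p$features[t, ]))
  })
  Y <- cbind(as.numeric(labels), as.numeric(!labels))
  # The stored class weights are a likelihood ratio (W_p) and a density
  # mass (W_q) on different scales; normalize to unit geometric mean and
  # bound their influence so a highly separable history cannot collapse
  # training onto one class.
  cw <- c(memory$class_weights$W_q, memory$class_weights$W_p)
  cw <- cw / sqrt(prod(cw))
  cw <- pmin(pmax(cw, 0.8), 1.25)
  wts <- ifelse(labels, cw[1], cw[2])
  wts <- wts / mean(wts)
  w <- rnn_init(d, cfg$hidden_dim, seed = cfg$seed)
  trace <- vector("list", cfg$epochs)
  lr <- NA
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$lr0 / (1 + cfg$decay * (epoch - 1))
    fw <- rnn_forward_batch(X_list, w)
    C <- cbind(fw$FF[[T_]], fw$FB[[1]])
    logits <- sweep(C %*% w$W_out, 2, w$b_out, "+")
    lm_ <- logits - apply(logits, 1, max)
    P <- exp(lm_) / rowSums(exp(lm_))
    loss <- -mean(wts * log(pmax(rowSums(P * Y), 1e-12)))
    acc <- mean((P[, 1] >= 0.5) == labels)
    trace[[epoch]] <- data.frame(epoch = epoch, loss = loss,
                                 accuracy = acc, lr = lr)
    g <- rnn_grad(X_list, fw, P, Y, wts, w)
    for (p in names(g)) w[[p]] <- w[[p]] - lr * g[[p]]
  }
  final <- trace[[cfg$epochs]]
  memory <- memory_log_run(memory, segments = NA,
                           fitness = -final$loss, learning_factor = lr)
  list(weights = w, trace = do.call(rbind, trace), memory = memory)
}

# BPTT gradient of the weighted cross-entropy (batch mean).
rnn_grad <- function(X_list, fw, P, Y, wts, w) {
  T_ <- length(X_list)
  n <- nrow(P)
  H <- w$hidden_dim
  C <- cbind(fw$FF[[T_]], fw$FB[[1]])
  dlogits <- (P - Y) * wts / n
  gW_out <- crossprod(C, dlogits)
  gb_out <- colSums(dlogits)
  dC <- dlogits %*% t(w$W_out)
  gWi_ff <- w$Wi_ff * 0; gW_ff <- w$W_ff * 0; gb_ff <- w$b_ff * 0
  gWi_fb <- w$Wi_fb * 0; gW_fb <- w$W_fb * 0; gb_fb <- w$b_fb * 0
  dff <- dC[, seq_len(H), drop = FALSE]
  for (t in rev(seq_len(T_))) {
    a <- fw$FF[[t]]
    da <- dff * a * (1 - a)
    gWi_ff <- gWi_ff + crossprod(X_list[[t]], da)
    prev <- if (t > 1) fw$FF[[t - 1]] else matrix(0, n, H)
    gW_ff <- gW_ff + crossprod(prev, da)
    gb_ff <- gb_ff + colSums(da)
    dff <- da %*% t(w$W_ff)
  }
  dfb <- dC[, H + seq_len(H), drop = FALSE]
  for (t in seq_len(T_)) {
    a <- fw$FB[[t]]
    da <- dfb * a * (1 - a)
    gWi_fb <- gWi_fb + crossprod(X_list[[t]], da)
    nxt <- if (t < T_) fw$FB[[t + 1]] else matrix(0, n, H)
    gW_fb <- gW_fb + crossprod(nxt, da)
    gb_fb <- gb_fb + colSums(da)
    dfb <- da %*% t(w$W_fb)
  }
  list(Wi_ff = gWi_ff, W_ff = gW_ff, b_ff = gb_ff,
       Wi_fb = gWi_fb, W_fb = gW_fb, b_fb = gb_fb,
       W_out = gW_out, b_out = gb_out)
}

#' Extract labeled patch sequences from an image
#'
#' Patches are taken on a regular top-left grid; with a label mask, only
#' patches with at least half their pixels inside the brain (labels >= 2)
#' are kept, and each is labeled tumor when the majority of its pixels
#' carry tumor labels (3 or 4). Each patch row becomes one timestep whose
#' features are the row's intensities (scaled to `[0, 1]`) plus four
#' patch-level GLCM statistics (constant across timesteps).
#'
#' @param img an [mri_image()] or matrix.
#' @param mask optional [label_mask()] for brain restriction + labels.
#' @param patch_size square patch side in pixels.
#' @param stride grid step in pixels.
#' @param balanced subsample the majority class to the minority count
#'   (seeded).
#' @param seed seed for balancing.
#' @return list of patch sequences: `features` (`patch_size x
#'   (patch_size + 4)`), `label`, `row`, `col`, `size` (0-based
#'   top-left coordinates).
#' @export
encode_patches <- function(img, mask = NULL, patch_size = 12L, stride = 12L,
                           balanced = FALSE, seed = 1L) {
  m <- unclass(img)
  ps <- as.integer(patch_size)
  if (ps > min(dim(m))) stop("patch_size exceeds image side")
  brain <- NULL
  if (!is.null(mask)) {
    lm <- unclass(mask)
    brain <- lm >= 2L
    if (!any(brain)) stop("no brain pixels in mask")
  }
  stride <- as.integer(stride)
  r0s <- seq.int(1L, nrow(m) - ps + 1L, by = stride)
  c0s <- seq.int(1L, ncol(m) - ps + 1L, by = stride)
  patches <- list()
  for (r0 in r0s) {
    for (c0 in c0s) {
      rows <- r0:(r0 + ps - 1L)
      cols <- c0:(c0 + ps - 1L)
      if (!is.null(brain) && mean(brain[rows, cols]) < 0.5) next
      lab <- NA
      if (!is.null(mask)) {
        lm_sub <- unclass(mask)[rows, cols]
        lab <- if (mean(lm_sub == 3L | lm_sub == 4L) > 0.5) "tumor" else "nontumor"
      }
      patches[[length(patches) + 1L]] <- list(
        features = patch_features(m[rows, cols]),
        label = lab, row = as.integer(r0) - 1L,
        col = as.integer(c0) - 1L, size = ps
      )
    }
  }
  if (balanced && !is.null(mask) && length(patches)) {
    labs <- vapply(patches, function(p) p$label, character(1))
    n_t <- sum(labs == "tumor"); n_n <- sum(labs == "nontumor")
    k <- min(n_t, n_n)
    if (k > 0) {
      set.seed(as.integer(seed))
      keep <- c(sample(which(labs == "tumor"), k),
                sample(which(labs == "nontumor"), k))
      patches <- patches[sort(keep)]
    }
  }
  patches
}

# Per-timestep feature matrix of one patch: scaled row intensities plus
# four patch-level GLCM statistics, normalized to O(1) scales.
patch_features <- function(patch) {
  g <- compute_glcm(patch, glcm_config(levels = 8L, displacement = c(0L, 1L)))
  st <- texture_stats(g)
  glob <- c(st$contrast / 49, st$energy, st$homogeneity, st$entropy / log(64))
  t(vapply(seq_len(nrow(patch)), function(r) {
    c(patch[r, ] / 255, glob)
  }, numeric(ncol(patch) + 4L)))
}

#' Per-pixel tumor-probability map from overlapping patch votes
#'
#' Classifies every admissible patch on a (usually overlapping) grid and
#' averages the tumor probabilities over the patches covering each
#' pixel. Pixels covered by no patch get probability 0.
#'
#' @param img an [mri_image()] or matrix.
#' @param weights trained [rnn_weights][rnn_init()].
#' @param mask optional [label_mask()] restricting patches to the brain.
#' @param patch_size,stride patch grid geometry (an overlapping stride
#'   smooths the vote map).
#' @return numeric matrix of tumor probabilities in `[0, 1]`.
#' @export
classify_image <- function(img, weights, mask = NULL, patch_size = 12L,
                           stride = 6L) {
  m <- unclass(img)
  patches <- encode_patches(m, mask, patch_size, stride)
  prob <- matrix(0, nrow(m), ncol(m))
  cnt <- matrix(0, nrow(m), ncol(m))
  if (!length(patches)) return(prob)
  p_t <- rnn_classify_batch(lapply(patches, `[[`, "features"), weights)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    rows <- (p$row + 1L):(p$row + p$size)
    cols <- (p$col + 1L):(p$col + p$size)
    prob[rows, cols] <- prob[rows, cols] + p_t[i]
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  covered <- cnt > 0
  prob[covered] <- prob[covered] / cnt[covered]
  prob
}

#' Refine a probability map with segmentation boundaries
#'
#' Blends each pixel's patch-vote tumor probability with the mean
#' probability of its segment, so the decision boundary is pulled toward
#' the intensity-accurate segment edges instead of the coarse patch grid
#' while thin structures keep their local votes. `blend = 1` snaps fully
#' to segment means; `blend = 0` returns the raw votes. Pixels outside
#' the segmentation (NA labels) get probability 0.
#'
#' @param prob probability matrix from [classify_image()].
#' @param segmentation a [run_haris()] result (its `labels` are used).
#' @param blend weight on the segment-mean component, in `[0, 1]`.
#' @return refined probability matrix.
#' @export
refine_probability <- function(prob, segmentation, blend = 0.5) {
  labels <- segmentation$labels
  snap <- matrix(0, nrow(prob), ncol(prob))
  ids <- sort(unique(labels[!is.na(labels)]))
  for (id in ids) {
    sel <- !is.na(labels) & labels == id
    snap[sel] <- mean(prob[sel])
  }
  out <- (1 - blend) * prob + blend * snap
  out[is.na(labels)] <- 0
  out
}
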