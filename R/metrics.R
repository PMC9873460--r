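#' Confusion counts and benchmark metrics
#'
#' Pixel- (or patch-) level confusion of a binary prediction against a
#' binary truth, with sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, accuracy `(TP+TN)/total`, F1 (harmonic mean of
#' precision and sensitivity) and Dice `2TP/(2TP+FP+FN)`.
#' Zero-denominator ratios are reported as 0 with the `zero_division`
#' flag set.
#'
#' @param pred,truth logical matrices/vectors of equal shape.
#' @param level `"pixel"` or `"patch"` (bookkeeping only).
#' @return list of class `eval_report`.
#' @export
confusion_eval <- function(pred, truth, level = "pixel") {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    stop("prediction and truth shapes differ")
  }
  pred <- as.logical(pred)
  truth <- as.logical(truth)
  tp <- sum(pred & truth)
  tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  zero <- FALSE
  ratio <- function(num, den) {
    if (den == 0) {
      zero <<- TRUE
      0
    } else num / den
  }
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  acc <- ratio(tp + tn, tp + tn + fp + fn)
  prec <- ratio(tp, tp + fp)
  f1 <- if (prec + sens == 0) {
    zero <- TRUE
    0
  } else 2 * prec * sens / (prec + sens)
  dice <- ratio(2 * tp, 2 * tp + fp + fn)
  structure(list(
    TP = tp, TN = tn, FP = fp, FN = fn,
    sensitivity = sens, specificity = spec, accuracy = acc,
    precision = prec, f1 = f1, dice = dice,
    level = level, zero_division = zero
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report (%s): sens %.3f spec %.3f acc %.3f f1 %.3f dice %.3f>\n",
    x$level, x$sensitivity, x$specificity, x$accuracy, x$f1, x$dice
  ))
  invisible(x)
}

#' Dice coefficient of the best-matching segment
#'
#' For unsupervised segmentations, the predicted region for a truth mask
#' is the single segment with the highest Dice overlap.
#'
#' @param labels integer segment-label matrix (NA allowed).
#' @param truth logical truth mask.
#' @return list with `dice` and `segment` (the matched 0-based id).
#' @export
best_segment_dice <- function(labels, truth) {
  ids <- sort(unique(labels[!is.na(labels)]))
  best <- list(dice = 0, segment = NA_integer_)
  for (id in ids) {
    pred <- !is.na(labels) & labels == id
    d <- confusion_eval(pred, truth)$dice
    if (d > best$dice) best <- list(dice = d, segment = id)
  }
  best
}

#' Phantom benchmark of the full identification pipeline
#'
#' Trains the patch classifier on `n_train` jittered phantoms, then for
#' each of `n` seeded test phantoms runs denoising, HARIS segmentation,
#' patch classification into a tumor-probability map, and region
#' derivation, and scores the predicted whole tumor against the ground
#' truth at pixel level. Metrics are micro-averaged (confusion counts
#' pooled over all images). Fully reproducible from the seed; per-image
#' failures are recorded and skipped.
#'
#' @param n number of test phantoms.
#' @param spec base [phantom_spec()].
#' @param seed master seed.
#' @param n_train training phantoms for the classifier.
#' @param jitter geometric/intensity jitter for both sets.
#' @param patch_size,stride classifier patch grid.
#' @param rnn_cfg an [rnn_train_config()] (seed is overridden).
#' @param haris_cfg a [haris_config()] (seed is overridden per image).
#' @param memory optional [new_memory()] carried through training and
#'   segmentation runs.
#' @return list with `aggregate` ([confusion_eval()] over pooled
#'   pixels), `per_image` data frame, `failures`, `memory`, `weights`.
#' @export
benchmark_phantoms <- function(n = 50L, spec = phantom_spec(), seed = 1L,
                               n_train = 16L, jitter = 0.1,
                               patch_size = 12L, stride = 6L,
                               rnn_cfg = rnn_train_config(epochs = 150L,
                                                          lr0 = 0.5),
                               haris_cfg = haris_config(),
                               memory = new_memory()) {
  if (n < 1) stop("n must be >= 1")
  train_set <- generate_dataset(spec, n_train, jitter,
                                seed = derive_seed(seed, 301L))
  patches <- list()
  for (tr in train_set) {
    patches <- c(patches, encode_patches(tr$image, tr$mask,
                                         patch_size, patch_size,
                                         balanced = TRUE,
                                         seed = derive_seed(seed, 303L)))
  }
  feats <- vapply(patches, function(p) mean(p$features[, seq_len(patch_size)]),
                  numeric(1))
  labs <- vapply(patches, function(p) p$label == "tumor", logical(1))
  memory <- update_class_weights(memory, feats, labs)
  rnn_cfg$seed <- derive_seed(seed, 307L)
  fit <- rnn_train(patches, rnn_cfg, memory)
  memory <- fit$memory

  test_set <- generate_dataset(spec, n, jitter,
                               seed = derive_seed(seed, 311L))
  pooled <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  rows <- list()
  failures <- 0L
  for (i in seq_len(n)) {
    res <- tryCatch({
      img <- test_set[[i]]$image
      truth_mask <- test_set[[i]]$mask
      tm <- tumor_masks(truth_mask)
      den <- denoise_image(img)
      hc <- haris_cfg
      hc$seed <- derive_seed(seed, 1000L + i)
      seg <- run_haris(img, hc, brain_mask = tm$brain, memory = memory)
      prob <- classify_image(den, fit$weights, truth_mask,
                             patch_size, stride)
      prob <- refine_probability(prob, seg)
      regions <- derive_regions(prob)
      ev <- confusion_eval(regions$whole, tm$whole)
      list(ev = ev, k = length(seg$segments), mem = seg$memory)
    }, error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
      next
    }
    memory <- res$mem
    ev <- res$ev
    pooled <- pooled + c(TP = ev$TP, TN = ev$TN, FP = ev$FP, FN = ev$FN)
    rows[[length(rows) + 1L]] <- data.frame(
      image = i, segments = res$k,
      sensitivity = ev$sensitivity, specificity = ev$specificity,
      accuracy = ev$accuracy, f1 = ev$f1, dice = ev$dice
    )
  }
  if (!length(rows)) stop("pipeline failed on every image")
  agg_pred <- c(rep(TRUE, pooled["TP"]), rep(FALSE, pooled["TN"]),
                rep(TRUE, pooled["FP"]), rep(FALSE, pooled["FN"]))
  agg_truth <- c(rep(TRUE, pooled["TP"]), rep(FALSE, pooled["TN"]),
                 rep(FALSE, pooled["FP"]), rep(TRUE, pooled["FN"]))
  list(
    aggregate = confusion_eval(agg_pred, agg_truth),
    per_image = do.call(rbind, rows),
    failures = failures,
    memory = memory,
    weights = fit$weights
  )
}
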