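#' Pipeline configuration
#'
#' A strict nested configuration for the end-to-end run: unknown keys
#' are rejected, every stage is runnable from the config alone, and the
#' serialized YAML form round-trips. One global seed derives per-stage
#' seeds by fixed offsets so stages can be re-run in isolation.
#'
#' @param path YAML file, or `NULL` to build the default config.
#' @param overrides named list merged over the defaults (nested lists
#'   merge by key).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user, "config")
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides, "overrides")
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

default_pipeline_config <- function() {
  list(
    schema_version = 1L,
    seed = 1L,
    paths = list(state_file = "slns_memory.json", out_dir = "slns_out"),
    phantom = list(n = 1L, jitter = 0, height = 228L, width = 228L,
                   noise_model = "rician", noise_sigma = 5),
    denoise = list(sigma = 0.8, gain = 0.5),
    texture = list(levels = 32L, d_row = 0L, d_col = 1L),
    haris = list(max_iters = 50L, plateau_tol = 1e-4, initial_j = 23L,
                 feature_set = "intensity+texture"),
    vae = list(enabled = FALSE, image_side = 32L, latent_dim = 8L,
               epochs = 200L, n_generate = 0L),
    classifier = list(patch_size = 12L, stride = 6L, epochs = 120L,
                      lr0 = 0.5, hidden_dim = 16L, n_train_images = 8L),
    impact = list(core_threshold = 0.7, positive_threshold = 0.5,
                  band = 3L, pixel_spacing = NULL)
  )
}

merge_config <- function(base, user, where) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(where, "$", k))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_pipeline_config <- function(cfg) {
  required <- c("schema_version", "seed", "paths", "phantom", "denoise",
                "texture", "haris", "classifier", "impact")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("missing required section(s): ", paste(missing, collapse = ", "))
  }
  invisible(cfg)
}

#' Run the end-to-end pipeline
#'
#' Generates (or loads) the input slice, then executes denoise, texture
#' summary, HARIS segmentation, patch classification and impact
#' reporting in order, writing every artifact with provenance (config,
#' seed) into the output directory and updating the self-learning memory
#' state once. Two runs from the same config and seed produce identical
#' masks and reports.
#'
#' @param cfg a [pipeline_config()].
#' @param image optional [mri_image()] input; by default a phantom is
#'   generated from the config.
#' @param mask optional [label_mask()] with ground truth (enables the
#'   brain pre-mask, classifier training and evaluation).
#' @return invisible list with the stage outputs and the output
#'   directory.
#' @export
run_pipeline <- function(cfg, image = NULL, mask = NULL) {
  validate_pipeline_config(cfg)
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  memory <- load_memory(cfg$paths$state_file)
  starting_weights <- memory$class_weights
  starting_gb <- memory$gb_fitness

  if (is.null(image)) {
    spec <- phantom_spec(
      height = cfg$phantom$height, width = cfg$phantom$width,
      noise_model = cfg$phantom$noise_model,
      noise_sigma = cfg$phantom$noise_sigma,
      seed = derive_seed(seed, stage_seed_offsets[["phantom"]])
    )
    ph <- generate_phantom(spec)
    image <- ph$image
    mask <- mask %||% ph$mask
  }
  save_image(image, file.path(out_dir, "input.png"))

  den <- denoise_image(image, denoise_params(
    sigma = cfg$denoise$sigma, correction_gain = cfg$denoise$gain
  ))
  save_image(den, file.path(out_dir, "denoised.png"))

  gl <- compute_glcm(den, glcm_config(
    levels = cfg$texture$levels,
    displacement = c(cfg$texture$d_row, cfg$texture$d_col)
  ))
  stats_ <- texture_stats(gl)
  jsonlite::write_json(stats_, file.path(out_dir, "texture.json"),
                       auto_unbox = TRUE, digits = NA)

  brain <- if (!is.null(mask)) tumor_masks(mask)$brain else NULL
  hc <- haris_config(
    max_iters = cfg$haris$max_iters, plateau_tol = cfg$haris$plateau_tol,
    initial_j = cfg$haris$initial_j, feature_set = cfg$haris$feature_set,
    seed = derive_seed(seed, stage_seed_offsets[["haris"]])
  )
  seg <- run_haris(image, hc, brain_mask = brain, memory = memory)
  memory <- seg$memory %||% memory
  seg_labels <- seg$labels
  seg_labels[is.na(seg_labels)] <- 0L
  save_mask(seg_labels, file.path(out_dir, "segments.png"))
  utils::write.csv(seg$trace, file.path(out_dir, "haris_trace.csv"),
                   row.names = FALSE)

  prob <- NULL
  regions <- NULL
  if (!is.null(mask)) {
    train <- generate_dataset(
      phantom_spec(seed = derive_seed(seed, stage_seed_offsets[["phantom"]] + 1L)),
      cfg$classifier$n_train_images, jitter = 0.1,
      seed = derive_seed(seed, stage_seed_offsets[["classifier"]])
    )
    patches <- list()
    for (tr in train) {
      patches <- c(patches, encode_patches(
        tr$image, tr$mask, cfg$classifier$patch_size,
        cfg$classifier$patch_size, balanced = TRUE,
        seed = derive_seed(seed, stage_seed_offsets[["classifier"]] + 1L)
      ))
    }
    feats <- vapply(patches, function(p) mean(p$features), numeric(1))
    labs <- vapply(patches, function(p) p$label == "tumor", logical(1))
    memory <- update_class_weights(memory, feats, labs)
    fit <- rnn_train(patches, rnn_train_config(
      epochs = cfg$classifier$epochs, lr0 = cfg$classifier$lr0,
      hidden_dim = cfg$classifier$hidden_dim,
      seed = derive_seed(seed, stage_seed_offsets[["classifier"]] + 2L)
    ), memory)
    memory <- fit$memory
    prob <- classify_image(den, fit$weights, mask,
                           cfg$classifier$patch_size, cfg$classifier$stride)
    prob <- refine_probability(prob, seg)
    save_image(prob * 255, file.path(out_dir, "tumor_probability.png"))
    regions <- derive_regions(prob, cfg$impact$core_threshold,
                              cfg$impact$positive_threshold, cfg$impact$band)
  } else {
    regions <- derive_regions(seg_to_probability(seg, den))
  }
  report <- impact_report(regions, unclass(den),
                          pixel_spacing = cfg$impact$pixel_spacing,
                          seed = derive_seed(seed, stage_seed_offsets[["impact"]]),
                          run_id = sprintf("run-%d", seed))
  jsonlite::write_json(unclass(report), file.path(out_dir, "impact.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  save_overlay(overlay_regions(unclass(den), regions),
               file.path(out_dir, "overlay.png"))

  metrics <- NULL
  if (!is.null(mask) && !is.null(regions)) {
    metrics <- confusion_eval(regions$whole, tumor_masks(mask)$whole)
    jsonlite::write_json(unclass(metrics), file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  provenance <- list(
    schema_version = cfg$schema_version, seed = seed,
    config = unclass(cfg), package_version = as.character(utils::packageVersion("slns")),
    starting_class_weights = starting_weights,
    starting_gb_fitness = starting_gb
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  save_memory(memory, cfg$paths$state_file)
  invisible(list(
    out_dir = out_dir, image = image, denoised = den, segmentation = seg,
    probability = prob, regions = regions, report = report,
    metrics = metrics, memory = memory,
    starting_class_weights = starting_weights,
    starting_gb_fitness = starting_gb
  ))
}

# Fallback tumor probability from an unsupervised segmentation: the
# brightest segment (by centroid intensity) is treated as tumor-like.
seg_to_probability <- function(seg, img) {
  prob <- matrix(0, nrow(seg$labels), ncol(seg$labels))
  if (!length(seg$segments)) return(prob)
  mus <- vapply(seg$segments, function(s) s$centroid[1], numeric(1))
  tumor_id <- which.max(mus) - 1L
  prob[!is.na(seg$labels) & seg$labels == tumor_id] <- 1
  prob
}
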