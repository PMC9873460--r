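#' Self-learning memory state
#'
#' A persisted cross-run record: the class weights used to balance the
#' classifier loss, the best seed-point fitness ever observed
#' (`gb_fitness`, the global best that seed-point refinement chases),
#' and an append-only run log. The state round-trips losslessly through
#' its JSON file representation.
#'
#' @return list of class `slns_memory`.
#' @export
new_memory <- function() {
  structure(list(
    schema_version = 1L,
    class_weights = list(W_p = 1, W_q = 1),
    gb_fitness = NULL,
    run_log = list()
  ), class = "slns_memory")
}

#' Append a segmentation/training run to memory
#'
#' Updates `gb_fitness` to the running maximum over logged fitness
#' values.
#'
#' @param memory a [new_memory()] state.
#' @param segments segment count of the run.
#' @param fitness final fitness of the run.
#' @param learning_factor final learning rate (classifier runs), or `NA`.
#' @return updated memory.
#' @export
memory_log_run <- function(memory, segments, fitness, learning_factor = NA) {
  memory$run_log <- c(memory$run_log, list(list(
    run_id = length(memory$run_log) + 1L,
    event = "run",
    segments = segments,
    fitness = fitness,
    learning_factor = learning_factor
  )))
  fits <- vapply(memory$run_log, function(e) {
    if (!is.null(e$fitness) && is.finite(e$fitness)) e$fitness else -Inf
  }, numeric(1))
  if (any(is.finite(fits))) memory$gb_fitness <- max(fits)
  memory
}

#' Persist memory to JSON
#'
#' @param memory a [new_memory()] state.
#' @param path file path.
#' @export
save_memory <- function(memory, path) {
  jsonlite::write_json(unclass(memory), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Load memory from JSON
#'
#' @param path file path; a missing file yields a fresh state.
#' @return `slns_memory`.
#' @export
load_memory <- function(path) {
  if (!file.exists(path)) return(new_memory())
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  mem <- new_memory()
  mem$schema_version <- as.integer(raw$schema_version %||% 1L)
  if (!is.null(raw$class_weights)) {
    mem$class_weights <- list(
      W_p = as.numeric(raw$class_weights$W_p),
      W_q = as.numeric(raw$class_weights$W_q)
    )
  }
  mem$gb_fitness <- if (is.null(raw$gb_fitness)) NULL else as.numeric(raw$gb_fitness)
  mem$run_log <- lapply(raw$run_log %||% list(), function(e) {
    lapply(e, function(v) if (is.null(v)) NA else v)
  })
  mem
}

#' @export
print.slns_memory <- function(x, ...) {
  cat(sprintf(
    "<slns_memory v%d: W_p=%.4g W_q=%.4g gb_fitness=%s, %d log entries>\n",
    x$schema_version, x$class_weights$W_p, x$class_weights$W_q,
    if (is.null(x$gb_fitness)) "none" else format(x$gb_fitness),
    length(x$run_log)
  ))
  invisible(x)
}
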