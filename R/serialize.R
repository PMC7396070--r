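#' Save a trained model as JSON
#'
#' Single-archive JSON with a format-version field; weight field names match
#' the parameter bundle (`Wxi`, `Whi`, `wci`, ... `Wy`, `by`), stored at full
#' double precision alongside the standardisation statistics and channel
#' manifest needed for prediction.
#'
#' @param model A `gait_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    format = "gaitsynergy-model",
    version = 1L,
    n_in = attr(model$params, "n_in"),
    n_hidden = attr(model$params, "n_hidden"),
    n_out = attr(model$params, "n_out"),
    peephole_output = model$peephole_output,
    clamp_output = model$clamp_output,
    window_len = model$window_len,
    lead = model$lead,
    input_channels = model$input_channels,
    target_channels = model$target_channels,
    stats = model$stats,
    params = lapply(unclass(model$params), identity),
    loss_history = model$loss_history)
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a model saved by [write_model()]
#'
#' @param path JSON model file.
#' @return A `gait_model` (without the original training config).
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "gaitsynergy-model")) {
    stop("not a gaitsynergy model file: ", path, call. = FALSE)
  }
  params <- p$params
  for (nm in c("Wxi", "Wxf", "Wxc", "Wxo", "Whi", "Whf", "Whc", "Who", "Wy")) {
    params[[nm]] <- as.matrix(params[[nm]])
    dimnames(params[[nm]]) <- NULL
  }
  for (nm in c("wci", "wcf", "wco", "bi", "bf", "bc", "bo", "by")) {
    params[[nm]] <- as.numeric(params[[nm]])
  }
  params <- structure(params, n_in = p$n_in, n_hidden = p$n_hidden,
                      n_out = p$n_out, class = "lstm_params")
  stats <- lapply(p$stats, function(v) {
    out <- as.numeric(v)
    names(out) <- names(v)
    out
  })
  structure(list(params = params, stats = stats,
                 input_channels = p$input_channels,
                 target_channels = p$target_channels,
                 window_len = p$window_len, lead = p$lead,
                 peephole_output = p$peephole_output,
                 clamp_output = p$clamp_output,
                 loss_history = as.numeric(p$loss_history),
                 config = NULL),
            class = "gait_model")
}
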