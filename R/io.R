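#' Write / read a trace set as CSV
#'
#' The documented tabular layout: a long-format values file with columns
#' `neuron_id`, `frame`, `time_s`, `F`, plus a companion metadata file (one
#' row per neuron).
#'
#' @param t a `trace_set`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_trace_set <- function(t, dir, prefix = "traces") {
  stopifnot(inherits(t, "trace_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_frames <- ncol(t$values)
  long <- data.frame(
    neuron_id = rep(t$neuron_meta$neuron_id, each = n_frames),
    frame = rep(seq_len(n_frames), nrow(t$values)),
    time_s = rep(t$frame_times, nrow(t$values)),
    F = as.vector(t(t$values))
  )
  p_values <- file.path(dir, paste0(prefix, "_values.csv"))
  p_meta <- file.path(dir, paste0(prefix, "_neurons.csv"))
  utils::write.csv(long, p_values, row.names = FALSE)
  meta <- t$neuron_meta
  meta$units <- t$units
  utils::write.csv(meta, p_meta, row.names = FALSE)
  invisible(c(values = p_values, meta = p_meta))
}

#' @rdname write_trace_set
#' @param dir directory holding the pair of CSV files.
#' @export
read_trace_set <- function(dir, prefix = "traces") {
  long <- utils::read.csv(file.path(dir, paste0(prefix, "_values.csv")))
  meta <- utils::read.csv(file.path(dir, paste0(prefix, "_neurons.csv")),
                          stringsAsFactors = FALSE)
  units <- meta$units[1]
  meta$units <- NULL
  ids <- meta$neuron_id
  times <- sort(unique(long$time_s))
  vals <- matrix(NA_real_, length(ids), length(times),
                 dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    sub <- long[long$neuron_id == ids[i], ]
    vals[i, ] <- sub$F[order(sub$time_s)]
  }
  trace_set(vals, times, meta, units = units)
}

#' Write / read a stimulus schedule as CSV
#' @param schedule a [stimulus_schedule()].
#' @param path CSV path.
#' @export
write_schedule <- function(schedule, path) {
  df <- as.data.frame(schedule)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @param control control label (for reading).
#' @export
read_schedule <- function(path, control = "water") {
  stimulus_schedule(utils::read.csv(path, stringsAsFactors = FALSE),
                    control = control)
}

#' Write / read a generator configuration as YAML
#' @param config a [generator_config()].
#' @param path YAML path.
#' @export
write_generator_config <- function(config, path) {
  yaml::write_yaml(config_as_yaml_list(config), path)
  invisible(path)
}

config_as_yaml_list <- function(config) {
  out <- unclass(config)
  for (nm in c("class_mixture", "mod_cue_mixture", "mod_uv_mixture")) {
    if (!is.null(out[[nm]])) out[[nm]] <- as.list(out[[nm]])
  }
  out
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("class_mixture", "mod_cue_mixture", "mod_uv_mixture")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(generator_config, raw)
}
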