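#' Build a stimulus schedule from a generator configuration
#'
#' Events alternate the control label (first element of `cue_labels`) with
#' each test cue in turn, starting at `first_onset` and spaced by `isi`.
#' When `uv_after_cue` is set, every cue pulse is followed by a 100-ms
#' `uv_trpa1` pulse that many seconds after the cue onset.
#'
#' @param config a [generator_config()].
#' @return a `stimulus_schedule`: a data frame with columns `onset_s`,
#'   `duration_s`, `label`, sorted by onset, with the control label stored
#'   in `attr(, "control")`.
#' @examples
#' sched <- make_schedule(generator_config(isi = 300, duration = 1300))
#' sched$onset_s   # 60 360 660 960
#' @export
make_schedule <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  labels <- config$cue_labels
  onsets <- seq(config$first_onset, config$duration, by = config$isi)
  onsets <- onsets[onsets + config$isi <= config$duration]
  if (length(onsets) < 2 * length(labels)) {
    stop("duration too short: need at least two presentations per cue")
  }
  ev <- data.frame(
    onset_s = onsets,
    duration_s = config$pulse_duration,
    label = rep(labels, length.out = length(onsets)),
    stringsAsFactors = FALSE
  )
  if (!is.null(config$uv_after_cue)) {
    uv <- data.frame(
      onset_s = ev$onset_s + config$uv_after_cue,
      duration_s = 0.1,
      label = "uv_trpa1",
      stringsAsFactors = FALSE
    )
    ev <- rbind(ev, uv)
  }
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  if (any(diff(ev$onset_s) < utils::head(ev$duration_s, -1))) {
    stop("schedule events overlap; reduce pulse_duration or uv_after_cue")
  }
  stimulus_schedule(ev, control = labels[1])
}

#' Construct/validate a stimulus schedule
#'
#' @param events data frame with `onset_s`, `duration_s`, `label`.
#' @param control control event label (defaults to `"water"`).
#' @return a `stimulus_schedule`.
#' @export
stimulus_schedule <- function(events, control = "water") {
  stopifnot(all(c("onset_s", "duration_s", "label") %in% names(events)))
  events <- events[order(events$onset_s), , drop = FALSE]
  stopifnot(!is.unsorted(events$onset_s, strictly = TRUE))
  structure(events, class = c("stimulus_schedule", "data.frame"),
            control = control)
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat("<stimulus_schedule> ", nrow(x), " events, control = '",
      attr(x, "control"), "'\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

# Event labels excluding UV pulses.
cue_events <- function(schedule) {
  schedule[schedule$label != "uv_trpa1", , drop = FALSE]
}

# For every uv_trpa1 event, the label of the most recent preceding cue
# ("trial label"): TRPA1 trials inherit the identity of the cue they follow.
uv_trial_labels <- function(schedule) {
  uv <- schedule[schedule$label == "uv_trpa1", , drop = FALSE]
  cues <- cue_events(schedule)
  vapply(uv$onset_s, function(on) {
    prior <- cues$label[cues$onset_s < on]
    if (!length(prior)) NA_character_ else prior[length(prior)]
  }, character(1))
}

#' Specify an integration/alignment epoch
#'
#' An epoch is a time window relative to a reference event: `reference =
#' "cue"` anchors on events carrying the label passed at use time,
#' `reference = "uv_trpa1"` anchors on UV pulses whose trial label (the cue
#' they follow) matches.
#'
#' @param reference `"cue"` or `"uv_trpa1"`.
#' @param offset_start,offset_end window bounds in seconds relative to the
#'   anchor onset (`offset_end > offset_start`).
#' @param name optional label carried into result tables.
#' @return an `epoch_spec`.
#' @export
epoch_spec <- function(reference = c("cue", "uv_trpa1"),
                       offset_start, offset_end, name = NULL) {
  reference <- match.arg(reference)
  stopifnot(is.numeric(offset_start), is.numeric(offset_end),
            offset_end > offset_start)
  structure(list(reference = reference,
                 offset_start = offset_start,
                 offset_end = offset_end,
                 name = name %||% sprintf("%s[%g,%g]", reference,
                                          offset_start, offset_end)),
            class = "epoch_spec")
}

#' Named epoch presets
#'
#' `post_cue_60s` is the standard 60-s post-stimulus integration window;
#' `post_trpa1_5s` and `pre_trpa1_30s` are the 5-s post-UV and 30-s pre-UV
#' (post-cue) windows of the TRPA1 paradigm; `opto_10s`/`opto_30s` split a
#' 40-s post-stimulus window into its first 10 s and subsequent 30 s;
#' `precue_90s` is the 90-s pre-cue behavioral baseline.
#'
#' @param name preset name.
#' @return an [epoch_spec()].
#' @export
epoch_preset <- function(name = c("post_cue_60s", "post_trpa1_5s",
                                  "pre_trpa1_30s", "opto_10s", "opto_30s",
                                  "precue_90s")) {
  name <- match.arg(name)
  switch(name,
    post_cue_60s  = epoch_spec("cue", 0, 60, name = name),
    post_trpa1_5s = epoch_spec("uv_trpa1", 0, 5, name = name),
    pre_trpa1_30s = epoch_spec("uv_trpa1", -30, 0, name = name),
    opto_10s      = epoch_spec("cue", 0, 10, name = name),
    opto_30s      = epoch_spec("cue", 10, 40, name = name),
    precue_90s    = epoch_spec("cue", -90, 0, name = name)
  )
}

# Anchor onsets for (label, epoch): cue-referenced epochs use events with
# that label; UV-referenced epochs use UV pulses on trials of that label.
anchor_onsets <- function(schedule, label, window) {
  if (window$reference == "uv_trpa1" && label != "uv_trpa1") {
    uv <- schedule[schedule$label == "uv_trpa1", , drop = FALSE]
    on <- uv$onset_s[uv_trial_labels(schedule) == label]
  } else {
    on <- schedule$onset_s[schedule$label == label]
  }
  if (!length(on)) stop("no events for label '", label, "'", call. = FALSE)
  on
}
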