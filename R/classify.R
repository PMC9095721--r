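#' Classify neurons as suppressed / enhanced / no-change by a cue
#'
#' For every neuron, the calcium signal is averaged over the epoch window
#' for cue trials and for control trials ([integrate_epoch()]), trial means
#' are averaged per label, and the difference `delta = mean(cue) -
#' mean(control)` is thresholded: `enhanced` if `delta > threshold`,
#' `suppressed` if `delta < -threshold`, otherwise `no_change`.  The
#' boundary `|delta| == threshold` is `no_change` (the rule is a strict
#' "more than").
#'
#' For UV-referenced windows, trials are UV pulses grouped by the cue they
#' follow, so `cue` vs `control` compares TRPA1 responses on cue trials with
#' those on the alternating water trials.
#'
#' @param t a `trace_set` in delta-f/f units (typically smoothed).
#' @param schedule a [stimulus_schedule()].
#' @param cue test cue label.
#' @param control control label (default `"water"`).
#' @param window an [epoch_spec()] (default: 60-s post-stimulus window).
#' @param threshold classification threshold in delta-f/f units
#'   (default 0.05).
#' @return a `response_table` data frame: `neuron_id`, `cue`,
#'   `mean_integrated_cue`, `mean_integrated_control`, `delta`, `call`,
#'   `threshold`, `window`.
#' @export
classify_responses <- function(t, schedule, cue, control = "water",
                               window = epoch_preset("post_cue_60s"),
                               threshold = 0.05) {
  stopifnot(inherits(t, "trace_set"), threshold >= 0)
  if (t$units != "dff") stop("classification requires dff traces")
  ic <- integrate_epoch(t, schedule, cue, window)
  i0 <- tryCatch(integrate_epoch(t, schedule, control, window),
                 error = function(e) stop("missing control events ('",
                                          control, "'): ",
                                          conditionMessage(e), call. = FALSE))
  delta <- ic$per_neuron - i0$per_neuron
  rt <- data.frame(
    neuron_id = t$neuron_meta$neuron_id,
    cue = cue,
    mean_integrated_cue = ic$per_neuron,
    mean_integrated_control = i0$per_neuron,
    delta = delta,
    call = response_call(delta, threshold),
    threshold = threshold,
    window = window$name,
    stringsAsFactors = FALSE
  )
  rownames(rt) <- NULL
  class(rt) <- c("response_table", "data.frame")
  rt
}

response_call <- function(delta, threshold) {
  factor(ifelse(delta > threshold, "enhanced",
                ifelse(delta < -threshold, "suppressed", "no_change")),
         levels = c("suppressed", "no_change", "enhanced"))
}

#' Fractions of suppressed/enhanced/no-change calls across thresholds
#'
#' The per-neuron deltas are computed once and re-thresholded, so the
#' suppressed + enhanced fraction is non-increasing in the threshold by
#' construction.
#'
#' @inheritParams classify_responses
#' @param thresholds strictly increasing non-negative thresholds.
#' @return data frame with one row per threshold: fractions of each call
#'   and the neuron count `n`.
#' @export
threshold_sweep <- function(t, schedule, cue, control = "water",
                            window = epoch_preset("post_cue_60s"),
                            thresholds = seq(0.01, 0.15, by = 0.01)) {
  stopifnot(all(thresholds >= 0), !is.unsorted(thresholds, strictly = TRUE))
  rt <- classify_responses(t, schedule, cue, control, window, threshold = 0)
  out <- do.call(rbind, lapply(thresholds, function(thr) {
    call <- response_call(rt$delta, thr)
    data.frame(threshold = thr,
               frac_suppressed = mean(call == "suppressed"),
               frac_enhanced = mean(call == "enhanced"),
               frac_no_change = mean(call == "no_change"),
               n = length(call))
  }))
  rownames(out) <- NULL
  out
}

#' Population fractions of response calls
#'
#' @param rt a `response_table` (or any data frame with a `call` column).
#' @param by optional grouping column name in `rt`.
#' @return data frame of counts and fractions per call (and group);
#'   fractions sum to 1 within each group.
#' @export
population_fractions <- function(rt, by = NULL) {
  stopifnot("call" %in% names(rt))
  groups <- if (is.null(by)) rep("all", nrow(rt)) else rt[[by]]
  tab <- table(group = groups, call = rt$call)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("group", "call", "count")
  tot <- tapply(out$count, out$group, sum)
  out$fraction <- out$count / as.numeric(tot[out$group])
  if (is.null(by)) out$group <- NULL
  out
}

#' Cross-tabulate response calls to two cues
#'
#' Overlap matrix between two response tables on the same neurons (e.g. how
#' kin-water calls distribute across adult-water calls).
#'
#' @param rt_a,rt_b `response_table`s over identical neurons.
#' @return 3 x 3 contingency table (rows: `rt_a` calls).
#' @export
response_overlap <- function(rt_a, rt_b) {
  stopifnot(identical(rt_a$neuron_id, rt_b$neuron_id))
  table(rt_a$call, rt_b$call, dnn = c(rt_a$cue[1], rt_b$cue[1]))
}

#' Two-stage random subsampling of neurons
#'
#' Stage 1 samples up to `per_fish` neurons per fish without replacement
#' (defaults to 25); stage 2 samples exactly `per_group` neurons per
#' treatment group from the pooled stage-1 sample (default 200).  Ensures
#' even representation of fish and groups before pooled comparisons.
#'
#' @param t a `trace_set` whose metadata has `fish_id` (and optionally a
#'   `group` column).
#' @param per_fish neurons kept per fish in stage 1.
#' @param per_group neurons kept per group in stage 2 (`NULL` skips
#'   stage 2).
#' @param seed RNG seed; the selection is deterministic given the seed.
#' @return the subsampled `trace_set`.
#' @export
subsample_neurons <- function(t, per_fish = 25, per_group = 200, seed = 0) {
  stopifnot(inherits(t, "trace_set"))
  idx <- two_stage_sample(t$neuron_meta, per_fish, per_group,
                          fish_col = "fish_id", group_col = "group",
                          seed = seed)
  t[idx]
}
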