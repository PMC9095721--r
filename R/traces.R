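#' Construct a trace set
#'
#' The central container: a neurons x frames matrix of fluorescence (raw
#' arbitrary units or delta-f/f, tracked by a units flag), strictly
#' increasing frame times, and per-neuron metadata.
#'
#' @param values neurons x frames numeric matrix.
#' @param frame_times frame timestamps, seconds, strictly increasing.
#' @param neuron_meta data frame with one row per neuron; a `neuron_id`
#'   column is added when missing.  Conventional columns: `fish_id`,
#'   `region` (PO/PT/OB/aSPa/pSPa/other/background), `ap_um`, `x_um`,
#'   `y_um`, `z_um`.
#' @param units `"raw"` (values must be > 0) or `"dff"`.
#' @return a `trace_set`.
#' @export
trace_set <- function(values, frame_times, neuron_meta = NULL,
                      units = c("raw", "dff")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  stopifnot(is.numeric(values), length(frame_times) == ncol(values))
  if (is.unsorted(frame_times, strictly = TRUE)) {
    stop("frame_times must be strictly increasing")
  }
  if (is.null(neuron_meta)) {
    neuron_meta <- data.frame(neuron_id = paste0("n", seq_len(nrow(values))),
                              stringsAsFactors = FALSE)
  }
  if (!"neuron_id" %in% names(neuron_meta)) {
    neuron_meta$neuron_id <- paste0("n", seq_len(nrow(values)))
  }
  stopifnot(nrow(neuron_meta) == nrow(values))
  if (units == "raw" && any(values <= 0)) {
    stop("raw fluorescence must be strictly positive")
  }
  structure(list(values = values, frame_times = as.numeric(frame_times),
                 neuron_meta = neuron_meta, units = units),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set> ", nrow(x$values), " neurons x ", ncol(x$values),
      " frames (", x$units, "), ",
      sprintf("%.3g", diff(x$frame_times[1:2])), " s/frame\n", sep = "")
  invisible(x)
}

#' Subset a trace set by neuron
#' @param x a `trace_set`.
#' @param i neuron index (logical, integer or neuron_id character).
#' @param ... ignored.
#' @export
`[.trace_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$neuron_meta$neuron_id)
  out <- x
  out$values <- x$values[i, , drop = FALSE]
  out$neuron_meta <- x$neuron_meta[i, , drop = FALSE]
  rownames(out$neuron_meta) <- NULL
  f0 <- attr(x, "baseline_f0")
  if (!is.null(f0)) attr(out, "baseline_f0") <- f0[i]
  out
}

#' Compute delta-f/f against the pre-stimulus baseline
#'
#' For each neuron, the baseline F0 is the mean fluorescence over all frames
#' strictly before the first scheduled event (overridable via
#' `baseline_end`), and delta-f/f = (F - F0) / F0.
#'
#' @param raw a `trace_set` in raw units.
#' @param schedule a [stimulus_schedule()]; its earliest onset ends the
#'   baseline period.
#' @param baseline_end optional explicit end of the baseline period,
#'   seconds.
#' @return a `trace_set` in `dff` units with per-neuron `F0` stored in
#'   `attr(, "baseline_f0")`.
#' @export
compute_dff <- function(raw, schedule = NULL, baseline_end = NULL) {
  stopifnot(inherits(raw, "trace_set"))
  if (raw$units != "raw") stop("traces are already in dff units")
  t_end <- baseline_end %||% min(schedule$onset_s)
  idx <- which(raw$frame_times < t_end)
  if (!length(idx)) stop("no frames before the first stimulus")
  f0 <- rowMeans(raw$values[, idx, drop = FALSE])
  if (any(f0 <= 0)) {
    stop("nonpositive baseline for neuron(s): ",
         paste(raw$neuron_meta$neuron_id[f0 <= 0], collapse = ", "))
  }
  out <- raw
  out$values <- sweep(sweep(raw$values, 1, f0), 1, f0, "/")
  out$units <- "dff"
  attr(out, "baseline_f0") <- f0
  out
}

#' Zero-phase moving-average smoothing
#'
#' A `window`-frame moving average applied forward then backward (classic
#' zero-phase filtering), with reflect padding at the trace ends so the
#' baseline is not biased.  Peak positions of symmetric inputs are
#' preserved.
#'
#' @param t a `trace_set`.
#' @param window odd window length in frames (default 3).
#' @return a smoothed `trace_set` of identical dimensions.
#' @export
smooth_zero_phase <- function(t, window = 3) {
  stopifnot(inherits(t, "trace_set"), window >= 1, window %% 2 == 1)
  n <- ncol(t$values)
  if (window > n) stop("window longer than trace")
  if (window == 1) return(t)
  out <- t
  out$values <- t(apply(t$values, 1, zero_phase_ma, window = window))
  out
}

# Forward-backward causal moving average with reflect padding.
zero_phase_ma <- function(x, window) {
  n <- length(x)
  pad <- window
  xp <- c(x[pad:1], x, x[n:(n - pad + 1)])
  causal <- function(v) {
    f <- stats::filter(v, rep(1 / window, window), method = "convolution",
                       sides = 1)
    as.numeric(f)
  }
  fwd <- causal(xp)
  bwd <- rev(causal(rev(fwd)))
  bwd[(pad + 1):(pad + n)]
}

#' Subtract a fitted linear background drift
#'
#' A least-squares line is fitted to a signal-free background ROI trace and
#' its drift component (slope times elapsed time) is subtracted from every
#' neuron's raw trace, restoring a flat baseline before delta-f/f
#' computation.  Intended for the dye-absorption artifact in which a colored
#' compound produces a linear rise in background fluorescence.
#'
#' @param t a `trace_set` in raw units.
#' @param background_trace numeric vector on the same timebase.
#' @return the corrected `trace_set`; the fit is stored in
#'   `attr(, "background_fit")` (`intercept`, `slope`).
#' @export
subtract_background <- function(t, background_trace) {
  stopifnot(inherits(t, "trace_set"))
  if (t$units != "raw") stop("background subtraction applies to raw traces")
  stopifnot(length(background_trace) == ncol(t$values))
  tt <- t$frame_times
  if (length(tt) < 2 || stats::sd(tt) == 0) {
    stop("degenerate timebase: constant frame times")
  }
  fit <- stats::lm(background_trace ~ tt)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  out <- t
  out$values <- sweep(t$values, 2, slope * (tt - tt[1]))
  attr(out, "background_fit") <- c(intercept = intercept, slope = slope)
  out
}

# Frame indices for one anchored window: frames at or after onset+start and
# strictly before onset+end (nearest-frame-at-or-after alignment).
window_frames <- function(frame_times, onset, window) {
  which(frame_times >= onset + window$offset_start &
          frame_times < onset + window$offset_end)
}

#' Stimulus-triggered average
#'
#' Aligns every presentation of `label` on a common relative timebase
#' (nearest frame at or after each onset) and averages across repeats per
#' neuron.
#'
#' @param t a `trace_set`.
#' @param schedule a [stimulus_schedule()].
#' @param label event label to align on.
#' @param window an [epoch_spec()] defining the alignment window.
#' @return list with `rel_time`, `sta` (neurons x relative frames, mean
#'   across repeats), `mean` and `sem` (across neurons), and `n_events`.
#' @export
stimulus_triggered_average <- function(t, schedule, label,
                                       window = epoch_preset("post_cue_60s")) {
  stopifnot(inherits(t, "trace_set"))
  onsets <- anchor_onsets(schedule, label, window)
  idx <- lapply(onsets, window_frames, frame_times = t$frame_times,
                window = window)
  if (any(lengths(idx) == 0)) stop("window outside recording for some event")
  n_rel <- min(lengths(idx))
  slabs <- lapply(seq_along(onsets), function(i) {
    t$values[, idx[[i]][seq_len(n_rel)], drop = FALSE]
  })
  sta <- Reduce(`+`, slabs) / length(slabs)
  rel_time <- t$frame_times[idx[[1]][seq_len(n_rel)]] - onsets[1]
  grand <- colMeans(sta)
  sem <- apply(sta, 2, stats::sd) / sqrt(nrow(sta))
  list(rel_time = rel_time, sta = sta, mean = grand, sem = sem,
       n_events = length(onsets))
}

#' Integrate (average) traces over an epoch
#'
#' Per-neuron, per-event mean delta-f/f over the window (a mean, not a sum,
#' so the 0.05 classification threshold stays in delta-f/f units), plus the
#' per-neuron average across events of the same label.
#'
#' @param t a `trace_set`.
#' @param schedule a [stimulus_schedule()].
#' @param label event label (for UV-referenced windows: the trial label).
#' @param window an [epoch_spec()].
#' @param normalize_to optional label; per-neuron values are divided by that
#'   neuron's mean response to `normalize_to` in the same window (e.g. each
#'   neuron's cue response normalized to its own mean water-flow response).
#' @return list with `per_event` (neurons x events), `per_neuron`, `onsets`.
#' @export
integrate_epoch <- function(t, schedule, label, window,
                            normalize_to = NULL) {
  stopifnot(inherits(t, "trace_set"))
  onsets <- anchor_onsets(schedule, label, window)
  per_event <- vapply(onsets, function(on) {
    idx <- window_frames(t$frame_times, on, window)
    if (!length(idx)) stop("empty window after frame alignment at onset ", on)
    rowMeans(t$values[, idx, drop = FALSE])
  }, numeric(nrow(t$values)))
  per_event <- matrix(per_event, nrow = nrow(t$values))
  rownames(per_event) <- t$neuron_meta$neuron_id
  per_neuron <- rowMeans(per_event)
  if (!is.null(normalize_to)) {
    ref <- integrate_epoch(t, schedule, normalize_to, window)$per_neuron
    per_neuron <- per_neuron / ref
    per_event <- sweep(per_event, 1, ref, "/")
  }
  list(per_event = per_event, per_neuron = per_neuron, onsets = onsets)
}

#' Resample traces onto a new timebase by linear interpolation
#'
#' Planes keep their own frame times by default; this explicit resampling
#' op supports cross-plane alignment when requested.
#'
#' @param t a `trace_set`.
#' @param new_times strictly increasing times within the recorded range.
#' @return a `trace_set` on `new_times`.
#' @export
resample_traces <- function(t, new_times) {
  stopifnot(inherits(t, "trace_set"),
            !is.unsorted(new_times, strictly = TRUE))
  vals <- t(apply(t$values, 1, function(x) {
    stats::approx(t$frame_times, x, xout = new_times, rule = 2)$y
  }))
  out <- t
  out$values <- vals
  out$frame_times <- as.numeric(new_times)
  out
}
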