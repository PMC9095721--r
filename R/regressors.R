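#' GCaMP6s kernel parameters
#'
#' The indicator impulse response is modeled as a delayed single exponential:
#' zero before the response delay, then `exp(-(t - delay)/tau_decay)`, with
#' unit peak at the delay.  Defaults are the measured GCaMP6s response delay
#' (0.48 s) and decay time (3 s).
#'
#' @param delay response delay in seconds (>= 0).
#' @param tau_decay decay time constant in seconds (> 0).
#' @param normalization only `"unit_peak"` is defined.
#' @return a `kernel_params` list.
#' @export
kernel_params <- function(delay = 0.48, tau_decay = 3,
                          normalization = "unit_peak") {
  stopifnot(delay >= 0, tau_decay > 0, normalization == "unit_peak")
  structure(list(delay = delay, tau_decay = tau_decay,
                 normalization = normalization),
            class = "kernel_params")
}

#' Sample the GCaMP6s kernel
#'
#' @param params a [kernel_params()].
#' @param dt sample spacing, seconds (> 0).
#' @param length kernel support, seconds; at least `delay + 5 * tau_decay`
#'   is recommended so the tail is captured.
#' @return list with `time` and `h`; `h(t) = 0` for `t < delay`,
#'   `exp(-(t - delay)/tau_decay)` otherwise (unit peak at the delay).
#' @examples
#' k <- gcamp_kernel(kernel_params(), dt = 0.12, length = 6)
#' k$h[k$time == 0.48]        # 1
#' k$h[k$time == 0.48 + 3]    # exp(-1)
#' @export
gcamp_kernel <- function(params = kernel_params(), dt, length) {
  stopifnot(dt > 0, length > 0)
  time <- seq(0, length, by = dt)
  h <- ifelse(time < params$delay, 0,
              exp(-(time - params$delay) / params$tau_decay))
  list(time = time, h = h)
}

# Full (open) discrete convolution of x with kernel y.
conv_open <- function(x, y) {
  stats::convolve(x, rev(y), type = "open")
}

# Kernel-convolved response of a train of events on a frame timebase.
# Each event is a boxcar of `duration` seconds (an impulse when `duration
# <= impulse_below`), and the series is scaled so a single isolated event
# peaks at 1.  Built on a fine grid anchored at the first frame time (so the
# construction is invariant to shifting all times by a constant), then
# linearly interpolated onto the timebase.
response_series <- function(onsets, duration, timebase,
                            params = kernel_params(), dt = 0.05,
                            impulse_below = 0.25) {
  t0 <- timebase[1]
  rel <- onsets - t0
  rel <- rel[rel >= 0 & rel <= (timebase[length(timebase)] - t0)]
  n_fine <- ceiling((timebase[length(timebase)] - t0) / dt) + 2L
  drive <- numeric(n_fine)
  box_len <- if (duration <= impulse_below) 1L else max(1L, round(duration / dt))
  for (on in rel) {
    i0 <- floor(on / dt) + 1L
    i1 <- min(n_fine, i0 + box_len - 1L)
    if (i0 <= n_fine) drive[i0:i1] <- drive[i0:i1] + 1
  }
  ker <- gcamp_kernel(params, dt = dt,
                      length = params$delay + 6 * params$tau_decay)
  conv <- conv_open(drive, ker$h)[seq_len(n_fine)]
  peak <- max(conv_open(rep(1, box_len), ker$h))
  y <- if (peak > 0) conv / peak else conv
  stats::approx(x = t0 + (seq_len(n_fine) - 1L) * dt, y = y,
                xout = timebase, rule = 2)$y
}

#' Build a kernel-convolved stimulus regressor
#'
#' A unit boxcar spanning each event of `label` (UV pulses, being shorter
#' than any frame, are modeled as impulses) is convolved with the GCaMP6s
#' kernel, resampled to the frame timebase and renormalized to unit peak.
#'
#' @param schedule a [stimulus_schedule()].
#' @param label event label.
#' @param timebase frame times, seconds.
#' @param params [kernel_params()].
#' @param allow_empty if `TRUE`, a label without events yields an all-zero
#'   regressor (flagged via `attr(, "empty")`) instead of an error.
#' @return numeric vector on `timebase` with unit peak.
#' @export
build_stimulus_regressor <- function(schedule, label, timebase,
                                     params = kernel_params(),
                                     allow_empty = FALSE) {
  ev <- schedule[schedule$label == label, , drop = FALSE]
  if (!nrow(ev)) {
    if (allow_empty) {
      return(structure(numeric(length(timebase)), empty = TRUE))
    }
    stop("no events with label '", label, "'")
  }
  y <- response_series(ev$onset_s, ev$duration_s[1], timebase, params)
  m <- max(abs(y))
  structure(if (m > 0) y / m else y, empty = m == 0)
}

#' Build motor regressors from a bout table
#'
#' Bout onsets are split into `motor_stim` (onset within `stim_window`
#' seconds after any UV pulse) and spontaneous bouts, with the latter
#' further split at `angle_cut` degrees into small (`motor_spon_S`, peak
#' angle <= cut) and large (`motor_spon_L`, > cut).  Each impulse train is
#' convolved with the kernel and renormalized to unit peak; an empty
#' category yields a zero regressor flagged unusable for correlation.
#'
#' @param bouts a bout table with `onset` and `peak_angle` columns.
#' @param schedule a [stimulus_schedule()] (UV pulses define the stimulus
#'   window).
#' @param timebase frame times, seconds.
#' @param params [kernel_params()].
#' @param stim_window seconds after UV within which a bout counts as
#'   stimulus-associated (default 5).
#' @param angle_cut small/large boundary in degrees (default 50; large
#'   is strictly greater).
#' @return named list of regressors (`motor_stim`, `motor_spon_S`,
#'   `motor_spon_L`), each with an `empty` attribute.
#' @export
build_motor_regressors <- function(bouts, schedule, timebase,
                                   params = kernel_params(),
                                   stim_window = 5, angle_cut = 50) {
  uv <- schedule$onset_s[schedule$label == "uv_trpa1"]
  is_stim <- if (length(uv) && nrow(bouts)) {
    vapply(bouts$onset, function(on) any(on > uv & on <= uv + stim_window),
           logical(1))
  } else {
    rep(FALSE, nrow(bouts))
  }
  spon <- bouts[!is_stim, , drop = FALSE]
  sets <- list(
    motor_stim   = bouts$onset[is_stim],
    motor_spon_S = spon$onset[spon$peak_angle <= angle_cut],
    motor_spon_L = spon$onset[spon$peak_angle > angle_cut]
  )
  lapply(sets, function(on) {
    if (!length(on)) {
      return(structure(numeric(length(timebase)), empty = TRUE))
    }
    y <- response_series(on, 0, timebase, params)
    m <- max(abs(y))
    structure(if (m > 0) y / m else y, empty = m == 0)
  })
}

#' Assemble a regressor bank
#'
#' Convenience wrapper building one stimulus regressor per scheduled label
#' plus, when a bout table is supplied, the three motor regressors.
#'
#' @param schedule a [stimulus_schedule()].
#' @param timebase frame times, seconds.
#' @param params [kernel_params()].
#' @param bouts optional bout table for [build_motor_regressors()].
#' @param labels labels to include (default: all labels in the schedule).
#' @param ... passed to [build_motor_regressors()].
#' @return a `regressor_bank`: list with `regressors` (frames x regressors
#'   matrix), `timebase`, `params` and logical `empty` flags.
#' @export
regressor_bank <- function(schedule, timebase, params = kernel_params(),
                           bouts = NULL, labels = NULL, ...) {
  labels <- labels %||% unique(schedule$label)
  regs <- lapply(labels, function(l) {
    build_stimulus_regressor(schedule, l, timebase, params)
  })
  names(regs) <- labels
  if (!is.null(bouts)) {
    regs <- c(regs, build_motor_regressors(bouts, schedule, timebase,
                                           params, ...))
  }
  mat <- do.call(cbind, lapply(regs, as.numeric))
  colnames(mat) <- names(regs)
  structure(list(regressors = mat, timebase = timebase, params = params,
                 empty = vapply(regs, function(r) isTRUE(attr(r, "empty")),
                                logical(1))),
            class = "regressor_bank")
}

#' Correlate traces with a regressor bank
#'
#' Zero-lag Pearson correlation of every (smoothed, delta-f/f) trace with
#' every regressor.  The kernel already encodes the indicator lag, so no lag
#' search is performed.  Constant traces or empty regressors yield a
#' correlation of 0 and are flagged in `attr(, "degenerate")`.
#'
#' @param t a `trace_set` in delta-f/f units.
#' @param bank a [regressor_bank()] on the same timebase.
#' @return neurons x regressors correlation matrix.
#' @export
correlate_traces <- function(t, bank) {
  stopifnot(inherits(t, "trace_set"), inherits(bank, "regressor_bank"))
  if (t$units != "dff") stop("traces must be in dff units; run compute_dff()")
  if (length(bank$timebase) != length(t$frame_times) ||
      max(abs(bank$timebase - t$frame_times)) > 1e-8) {
    stop("timebase mismatch between traces and regressor bank")
  }
  X <- t(t$values)                       # frames x neurons
  R <- bank$regressors                   # frames x regressors
  sd_x <- apply(X, 2, stats::sd)
  sd_r <- apply(R, 2, stats::sd)
  corr <- matrix(0, ncol(X), ncol(R),
                 dimnames = list(t$neuron_meta$neuron_id, colnames(R)))
  ok_x <- sd_x > 0
  ok_r <- sd_r > 0 & !bank$empty
  if (any(ok_x) && any(ok_r)) {
    corr[ok_x, ok_r] <- stats::cor(X[, ok_x, drop = FALSE],
                                   R[, ok_r, drop = FALSE])
  }
  degenerate <- outer(!ok_x, rep(TRUE, ncol(R))) |
    outer(rep(TRUE, ncol(X)), !ok_r)
  dimnames(degenerate) <- dimnames(corr)
  structure(corr, degenerate = degenerate)
}
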