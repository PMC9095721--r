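#' Simulate a trace set with known ground truth
#'
#' Forward model: each neuron draws a tuning class from
#' `config$class_mixture` and (independently) cue-period / post-UV
#' modulation labels.  Its delta-f/f signal is a sum of kernel-convolved
#' event responses —
#'
#' * a sustained boxcar (length `response_duration`) at every flow pulse,
#'   with amplitude `flow_response` plus, on test-cue trials, the planted
#'   cue modulation (`+/- effect_size` or 0);
#' * an impulse response at every UV pulse with a class-specific amplitude
#'   (`effect_size` times the class UV gain; `trpa1_strong` has gain 1, so a
#'   noiseless strong neuron peaks exactly at `effect_size`) plus, on
#'   test-cue trials, the planted post-UV modulation;
#' * impulse responses at tail-bout onsets for motor-tuned classes (each
#'   fish carries its own simulated bout train).
#'
#' Suppression is planted as a negative-amplitude response, so delta-f/f can
#' dip below the tonic baseline.  Raw fluorescence is then
#' `baseline_f * (1 + signal) + drift_slope * t + noise`, with i.i.d.
#' Gaussian per-frame noise of `noise_sd` delta-f/f units.
#'
#' @param config a [generator_config()].
#' @param schedule a [stimulus_schedule()]; defaults to
#'   `make_schedule(config)`.
#' @return list of class `synth_traces` with elements `traces` (raw
#'   `trace_set`), `truth` (ground-truth data frame: per-neuron
#'   `tuning_class`, `mod_cue`, `mod_uv`, planted deltas), `bouts` (list of
#'   per-fish bout tables) and `schedule`.  The ground truth is never
#'   consulted by any analysis stage.
#' @export
make_traces <- function(config, schedule = make_schedule(config)) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_fish * config$neurons_per_fish
  fish <- rep(seq_len(config$n_fish), each = config$neurons_per_fish)
  timebase <- seq(0, config$duration, by = config$frame_interval)
  gains <- class_gain_table()

  truth <- local_seed(child_seed(config$seed, 1), {
    cls <- sample(names(config$class_mixture), n, replace = TRUE,
                  prob = config$class_mixture)
    mod_cue <- if (is.null(config$mod_cue_mixture)) {
      ifelse(cls == "cue_suppressed", "suppressed",
             ifelse(cls == "cue_enhanced", "enhanced", "none"))
    } else {
      m <- sample(names(config$mod_cue_mixture), n, replace = TRUE,
                  prob = config$mod_cue_mixture)
      # cue-tuned classes carry their own sign by construction
      m[cls == "cue_suppressed"] <- "suppressed"
      m[cls == "cue_enhanced"] <- "enhanced"
      m
    }
    mod_uv <- if (is.null(config$mod_uv_mixture)) {
      rep("none", n)
    } else {
      sample(names(config$mod_uv_mixture), n, replace = TRUE,
              prob = config$mod_uv_mixture)
    }
    ap <- runif(n, -100, 100)
    data.frame(
      neuron_id = sprintf("f%02d_n%03d", fish, seq_len(n)),
      fish_id = fish,
      tuning_class = cls,
      mod_cue = mod_cue,
      mod_uv = mod_uv,
      effect_size = config$effect_size,
      ap_um = ap,
      stringsAsFactors = FALSE
    )
  })
  sgn <- function(m) (m == "enhanced") - (m == "suppressed")
  delta_cue <- config$effect_size * sgn(truth$mod_cue)
  delta_uv <- config$effect_size * sgn(truth$mod_uv)
  gi <- match(truth$tuning_class, gains$class)
  uv_amp_class <- config$effect_size * gains$uv[gi]
  motor_amp <- config$effect_size * gains$motor[gi]

  # --- stimulus-driven signal: event unit responses x amplitude matrix ---
  cues <- cue_events(schedule)
  control <- attr(schedule, "control")
  E <- vapply(cues$onset_s, function(on) {
    response_series(on, config$response_duration, timebase)
  }, numeric(length(timebase)))
  A <- matrix(vapply(seq_len(nrow(cues)), function(e) {
    if (cues$label[e] == control) rep(config$flow_response, n)
    else config$flow_response + delta_cue
  }, numeric(n)), nrow = n)
  signal <- E %*% t(A)                       # frames x neurons
  uv <- schedule[schedule$label == "uv_trpa1", , drop = FALSE]
  if (nrow(uv)) {
    trial <- uv_trial_labels(schedule)
    Eu <- vapply(uv$onset_s, function(on) {
      response_series(on, 0, timebase)
    }, numeric(length(timebase)))
    Au <- matrix(vapply(seq_len(nrow(uv)), function(e) {
      if (trial[e] == control) uv_amp_class
      else uv_amp_class + delta_uv
    }, numeric(n)), nrow = n)
    signal <- signal + Eu %*% t(Au)
  }

  # --- motor-driven signal, per fish ---
  bouts <- vector("list", config$n_fish)
  need_motor <- any(motor_amp != 0)
  for (f in seq_len(config$n_fish)) {
    bouts[[f]] <- sample_bouts(config, schedule,
                               seed = child_seed(config$seed, 100 + f))
    if (need_motor) {
      b <- bouts[[f]]
      in_fish <- which(fish == f & motor_amp != 0)
      if (length(in_fish) && nrow(b)) {
        spon <- b[!b$stim_locked, , drop = FALSE]
        series <- list(
          S = response_series(spon$onset[spon$peak_angle <= 50], 0, timebase),
          L = response_series(spon$onset[spon$peak_angle > 50], 0, timebase),
          all = response_series(b$onset, 0, timebase)
        )
        for (j in in_fish) {
          src <- switch(truth$tuning_class[j],
                        motor_spon_S = series$S,
                        motor_spon_L = series$L,
                        series$all)
          signal[, j] <- signal[, j] + motor_amp[j] * src
        }
      }
    }
  }

  raw <- config$baseline_f * (1 + t(signal)) +
    matrix(config$drift_slope * timebase, n, length(timebase), byrow = TRUE)
  if (config$noise_sd > 0) {
    raw <- raw + local_seed(child_seed(config$seed, 2), {
      matrix(rnorm(length(raw), sd = config$noise_sd * config$baseline_f),
             nrow = n)
    })
  }
  meta <- data.frame(
    neuron_id = truth$neuron_id,
    fish_id = truth$fish_id,
    region = ifelse(truth$ap_um < 0, "PO", "PT"),
    ap_um = truth$ap_um,
    stringsAsFactors = FALSE
  )
  if (config$include_background) {
    bg <- matrix(config$baseline_f + config$drift_slope * timebase,
                 config$n_fish, length(timebase), byrow = TRUE)
    raw <- rbind(raw, bg)
    meta <- rbind(meta, data.frame(
      neuron_id = sprintf("f%02d_bg", seq_len(config$n_fish)),
      fish_id = seq_len(config$n_fish),
      region = "background", ap_um = NA_real_,
      stringsAsFactors = FALSE
    ))
  }
  traces <- trace_set(raw, timebase, meta, units = "raw")
  structure(list(traces = traces, truth = truth, bouts = bouts,
                 schedule = schedule),
            class = "synth_traces")
}

#' @export
print.synth_traces <- function(x, ...) {
  cat("<synth_traces> ", nrow(x$truth), " neurons, ",
      nrow(x$schedule), " scheduled events\n", sep = "")
  print(table(x$truth$tuning_class))
  invisible(x)
}

# Sample one fish's bout train: spontaneous bouts as a Poisson process with
# lognormal peak angles (excluded from the 5-s post-UV stimulus windows),
# plus optional large-angle stimulus-locked bouts after each UV pulse.
sample_bouts <- function(config, schedule, seed) {
  uv <- schedule$onset_s[schedule$label == "uv_trpa1"]
  local_seed(seed, {
    n_spon <- rpois(1, config$bout_rate * config$duration)
    onset <- sort(runif(n_spon, 1, config$duration - 1))
    if (length(uv)) {
      in_stim <- vapply(onset, function(on) any(on > uv & on <= uv + 5),
                        logical(1))
      onset <- onset[!in_stim]
    }
    if (length(onset) > 1) {
      keep <- c(TRUE, diff(onset) > max(1, 2 * config$bout_duration))
      onset <- onset[keep]
    }
    amp <- pmin(rlnorm(length(onset), config$bout_amp_meanlog,
                       config$bout_amp_sdlog), 120)
    stim_locked <- rep(FALSE, length(onset))
    if (length(uv)) {
      trig <- runif(length(uv)) < config$stim_bout_prob
      t_on <- uv[trig] + runif(sum(trig), 0.3, config$stim_bout_latency)
      onset <- c(onset, t_on)
      amp <- c(amp, runif(sum(trig), 55, 90))
      stim_locked <- c(stim_locked, rep(TRUE, sum(trig)))
    }
    o <- order(onset)
    data.frame(
      bout_id = seq_along(onset),
      onset = onset[o],
      peak_time = onset[o] + config$bout_duration / 2,
      peak_angle = amp[o],
      category = ifelse(amp[o] > 50, "large", "small"),
      stim_locked = stim_locked[o],
      sign = sample(c(-1, 1), length(onset), replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a tail-angle trace with ground-truth bouts
#'
#' Cumulative tail angle sampled at `tail_fps` (default 200 frames/s):
#' Gaussian tracking noise plus signed half-sine bouts of duration
#' `bout_duration`.  Spontaneous bouts follow a Poisson process with
#' lognormal peak angles straddling the 50-degree large/small boundary;
#' each UV pulse triggers a large-angle bout with probability
#' `stim_bout_prob` within the 5-s stimulus window.
#'
#' @param config a [generator_config()].
#' @param schedule a [stimulus_schedule()].
#' @param fish fish index; selects the per-fish random stream so tail
#'   traces are consistent with [make_traces()] bouts.
#' @return list with `tail` (`tail_trace` data frame: `time_s`,
#'   `angle_deg`) and `bouts` (ground-truth bout table).
#' @export
make_tail_trace <- function(config, schedule = make_schedule(config),
                            fish = 1) {
  stopifnot(inherits(config, "generator_config"))
  b <- sample_bouts(config, schedule, seed = child_seed(config$seed, 100 + fish))
  times <- seq(0, config$duration, by = 1 / config$tail_fps)
  angle <- if (config$tail_noise_sd > 0) {
    local_seed(child_seed(config$seed, 200 + fish),
               rnorm(length(times), sd = config$tail_noise_sd))
  } else {
    numeric(length(times))
  }
  for (i in seq_len(nrow(b))) {
    idx <- which(times >= b$onset[i] & times <= b$onset[i] + config$bout_duration)
    angle[idx] <- angle[idx] + b$sign[i] * b$peak_angle[i] *
      sin(pi * (times[idx] - b$onset[i]) / config$bout_duration)
  }
  tail <- structure(data.frame(time_s = times, angle_deg = angle),
                    class = c("tail_trace", "data.frame"))
  list(tail = tail, bouts = b)
}
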