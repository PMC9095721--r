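#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the forward model in one validated list.  Defaults
#' follow the tethered-imaging paradigm the generator emulates: ~474 ms
#' frames, 10-s cue pulses alternating control water with a conditioned-water
#' cue at a 5-min interstimulus interval, and Gaussian per-frame noise on a
#' positive fluorescence baseline.
#'
#' @param n_fish number of fish (neurons are grouped per fish).
#' @param neurons_per_fish neurons simulated per fish.
#' @param frame_interval seconds per frame (default 0.474, one two-plane
#'   volume at ~237 ms per plane).
#' @param duration recording length in seconds.  `NULL` sizes the recording
#'   to fit two presentations of every cue plus the pre-stimulus baseline.
#' @param cue_labels character vector of event labels.  The first label is
#'   the control (water); remaining labels are test cues.  `"uv_trpa1"`
#'   events are generated via `uv_after_cue`, not listed here.
#' @param isi interstimulus interval, seconds.
#' @param pulse_duration cue pulse length, seconds.
#' @param first_onset onset of the first event, seconds; everything before it
#'   is the delta-f/f baseline period.
#' @param uv_after_cue if non-`NULL`, a 100-ms `uv_trpa1` pulse follows every
#'   cue onset by this many seconds.
#' @param class_mixture named probabilities over tuning classes (must sum
#'   to 1); see [tuning_classes()].
#' @param mod_cue_mixture,mod_uv_mixture named probabilities over
#'   `c("suppressed", "enhanced", "none")` used to plant cue-period and
#'   post-UV modulation labels independently of the tuning class.  `NULL`
#'   derives labels from the tuning class (`cue_suppressed`/`cue_enhanced`
#'   classes carry their sign, everything else `"none"`).
#' @param effect_size planted modulation amplitude, delta-f/f units.
#' @param response_duration length of the sustained cue-period response
#'   boxcar, seconds.
#' @param flow_response amplitude of the unmodulated response to any flow
#'   pulse (mechanosensory component), delta-f/f units.
#' @param noise_sd per-frame Gaussian noise, delta-f/f units.
#' @param baseline_f baseline fluorescence, arbitrary units.
#' @param drift_slope linear background drift, fluorescence units/second
#'   (dye absorption artifact).
#' @param include_background add one signal-free background ROI per fish
#'   that carries only baseline + drift (for [subtract_background()]).
#' @param bout_rate spontaneous tail-bout rate, Hz.
#' @param bout_amp_meanlog,bout_amp_sdlog lognormal parameters of
#'   spontaneous peak cumulative tail angles (degrees); defaults straddle
#'   the 50-degree large-angle boundary.
#' @param bout_duration bout half-sine duration, seconds.
#' @param stim_bout_prob probability that a UV pulse triggers a large-angle
#'   bout within `stim_bout_latency` seconds.
#' @param stim_bout_latency latest stimulus-locked bout onset after UV,
#'   seconds (within the 5-s stimulus window).
#' @param tail_fps tail-trace sampling rate, frames/second.
#' @param tail_noise_sd tail-angle tracking noise, degrees.
#' @param perk settings for [make_perk_table()]: a list with `groups` (named
#'   list of `list(meanlog, sdlog, n_fish, cells_per_fish)`), `control`
#'   (control group label) and `ap_cutoff` (anterior-posterior split, um).
#' @param seed integer seed; all generator randomness derives from it.
#' @return an object of class `generator_config` (a validated list).
#' @seealso [generator_preset()] for ready-made study-condition presets.
#' @export
generator_config <- function(n_fish = 8,
                             neurons_per_fish = 25,
                             frame_interval = 0.474,
                             duration = NULL,
                             cue_labels = c("water", "kin"),
                             isi = 300,
                             pulse_duration = 10,
                             first_onset = 60,
                             uv_after_cue = NULL,
                             class_mixture = c(cue_suppressed = 0.3,
                                               cue_enhanced = 0.1,
                                               cue_neutral = 0.6),
                             mod_cue_mixture = NULL,
                             mod_uv_mixture = NULL,
                             effect_size = 0.2,
                             response_duration = 60,
                             flow_response = 0.1,
                             noise_sd = 0.025,
                             baseline_f = 100,
                             drift_slope = 0,
                             include_background = FALSE,
                             bout_rate = 0.05,
                             bout_amp_meanlog = log(35),
                             bout_amp_sdlog = 0.4,
                             bout_duration = 0.3,
                             stim_bout_prob = 0.8,
                             stim_bout_latency = 3,
                             tail_fps = 200,
                             tail_noise_sd = 1,
                             perk = NULL,
                             seed = 0) {
  cfg <- as.list(environment())
  if (is.null(cfg$duration)) {
    cfg$duration <- first_onset + 2 * length(cue_labels) * isi
  }
  if (is.null(cfg$perk)) {
    cfg$perk <- list(
      groups = list(
        group    = list(meanlog = log(200), sdlog = 0.4, n_fish = 12,
                        cells_per_fish = 70),
        isolated = list(meanlog = log(200) + log(1.3), sdlog = 0.4,
                        n_fish = 12, cells_per_fish = 70)
      ),
      control = "group",
      ap_cutoff = 0
    )
  }
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_fish >= 1, cfg$neurons_per_fish >= 1,
            cfg$frame_interval > 0, cfg$isi > 0,
            cfg$pulse_duration > 0, cfg$first_onset > 0,
            cfg$effect_size >= 0, cfg$response_duration > 0,
            cfg$tail_fps > 0, cfg$bout_duration > 0)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$pulse_duration >= cfg$isi) stop("pulse_duration must be < isi")
  if (abs(sum(cfg$class_mixture) - 1) > 1e-9) {
    stop("class_mixture probabilities must sum to 1")
  }
  unknown <- setdiff(names(cfg$class_mixture), tuning_classes())
  if (length(unknown)) {
    stop("unknown tuning classes: ", paste(unknown, collapse = ", "))
  }
  for (m in c("mod_cue_mixture", "mod_uv_mixture")) {
    if (!is.null(cfg[[m]])) {
      if (abs(sum(cfg[[m]]) - 1) > 1e-9) stop(m, " must sum to 1")
      if (!all(names(cfg[[m]]) %in% c("suppressed", "enhanced", "none"))) {
        stop(m, " labels must be suppressed/enhanced/none")
      }
    }
  }
  if (cfg$duration < cfg$first_onset + length(cfg$cue_labels) * cfg$isi) {
    stop("duration too short for one full stimulus cycle")
  }
  invisible(cfg)
}

#' Planted tuning classes
#'
#' The tuning class determines what drives a neuron's calcium signal:
#' cue-period flow responses, UV/TRPA1 pulses, spontaneous tail bouts of a
#' given size, a mixture of stimulus and motor drive, an anticorrelated
#' (post-UV dip) response, or nothing.
#'
#' @return character vector of valid class names.
#' @export
tuning_classes <- function() {
  c("cue_suppressed", "cue_enhanced", "cue_neutral",
    "trpa1_strong", "trpa1_moderate", "trpa1_weak",
    "motor_spon_L", "motor_spon_S", "mixed_stim_motor",
    "anticorrelated", "unresponsive")
}

# Per-class response gains, in units of `effect_size`.  `uv` scales the
# response to each UV pulse, `motor` the response to tail bouts.  The gains
# are calibrated so that, at the TRPA1 preset's noise level, planted classes
# land inside the default correlation rule bands of `default_class_rules()`
# (strong ~0.75, moderate ~0.35, weak ~0.15).
class_gain_table <- function() {
  data.frame(
    class = tuning_classes(),
    uv    = c(0, 0, 0, 1.0, 0.35, 0.15, 0, 0, 0.35, -0.5, 0),
    motor = c(0, 0, 0, 0,   0,    0,    1, 1, 0.20,  0,    0),
    stringsAsFactors = FALSE
  )
}

#' Study-condition generator presets
#'
#' Ready-made [generator_config()] objects whose planted mixtures mirror the
#' population structures the analyses are benchmarked against:
#'
#' * `"fig2-kin"`, `"fig2-nonkin"`, `"fig2-adult"` — a conditioned-water cue
#'   alternating with control water at a 5-min ISI; planted
#'   suppressed/enhanced fractions 27.5%/10%, 18%/23% and 14%/46%
#'   respectively (kin fractions are midpoints of the reported 25-30% and
#'   9-11% ranges).
#' * `"fig6-trpa1"` — alternating water/kin pulses each followed 30 s later
#'   by a 100-ms UV (TRPA1) pulse.  Tuning classes are planted at fractions
#'   3.2/25.2/8/31.2/12.8/12.8/6.8% (strong/moderate/weak TRPA1, mixed
#'   stimulus-motor, motor-only, unresponsive, anticorrelated; motor split
#'   evenly between large- and small-angle tuning).  Cue-period modulation
#'   labels are planted at 43% suppressed / 30% enhanced, post-UV modulation
#'   at 54% suppressed / 32% enhanced.
#'
#' All presets default to 40 fish x 25 neurons = 1000 neurons, effect size
#' 0.2 delta-f/f and per-frame noise 0.025 delta-f/f.
#'
#' @param name preset name.
#' @param ... overrides passed on to [generator_config()].
#' @return a `generator_config`.
#' @export
generator_preset <- function(name = c("fig2-kin", "fig2-nonkin",
                                      "fig2-adult", "fig6-trpa1"),
                             ...) {
  name <- match.arg(name)
  overrides <- list(...)
  base <- switch(
    name,
    "fig2-kin" = list(
      cue_labels = c("water", "kin"),
      class_mixture = c(cue_suppressed = 0.275, cue_enhanced = 0.10,
                        cue_neutral = 0.625)
    ),
    "fig2-nonkin" = list(
      cue_labels = c("water", "nonkin"),
      class_mixture = c(cue_suppressed = 0.18, cue_enhanced = 0.23,
                        cue_neutral = 0.59)
    ),
    "fig2-adult" = list(
      cue_labels = c("water", "adult"),
      class_mixture = c(cue_suppressed = 0.14, cue_enhanced = 0.46,
                        cue_neutral = 0.40)
    ),
    "fig6-trpa1" = list(
      cue_labels = c("water", "kin"),
      uv_after_cue = 30,
      response_duration = 20,
      flow_response = 0,
      class_mixture = c(trpa1_strong = 0.032, trpa1_moderate = 0.252,
                        trpa1_weak = 0.08, mixed_stim_motor = 0.312,
                        motor_spon_L = 0.064, motor_spon_S = 0.064,
                        unresponsive = 0.128, anticorrelated = 0.068),
      mod_cue_mixture = c(suppressed = 0.43, enhanced = 0.30, none = 0.27),
      mod_uv_mixture = c(suppressed = 0.54, enhanced = 0.32, none = 0.14)
    )
  )
  base$n_fish <- 40
  args <- utils::modifyList(base, overrides)
  do.call(generator_config, args)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat("  neurons:", x$n_fish, "fish x", x$neurons_per_fish, "\n")
  cat("  cues:", paste(x$cue_labels, collapse = ", "),
      if (!is.null(x$uv_after_cue)) sprintf("(+ uv_trpa1 at cue+%gs)",
                                            x$uv_after_cue) else "", "\n")
  cat("  isi:", x$isi, "s; pulse:", x$pulse_duration,
      "s; duration:", x$duration, "s; dt:", x$frame_interval, "s\n")
  cat("  effect:", x$effect_size, "dF/F; noise:", x$noise_sd,
      "dF/F; seed:", x$seed, "\n")
  cat("  mixture:", paste(sprintf("%s=%.3g", names(x$class_mixture),
                                  x$class_mixture), collapse = ", "), "\n")
  invisible(x)
}
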