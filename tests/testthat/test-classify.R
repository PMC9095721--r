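# A small deterministic dataset where per-neuron deltas are known exactly:
# constant response plateaus inside the integration windows.
delta_traces <- function(deltas, base = 0.1) {
  tt <- (0:199) * 0.5
  sch <- stimulus_schedule(data.frame(onset_s = c(20, 60), duration_s = 5,
                                      label = c("water", "kin")))
  vals <- t(sapply(deltas, function(d) {
    v <- numeric(length(tt))
    v[tt >= 20 & tt < 30] <- base
    v[tt >= 60 & tt < 70] <- base + d
    v
  }))
  list(t = trace_set(vals, tt, units = "dff"), sch = sch,
       win = epoch_spec("cue", 0, 10))
}

test_that("the 0.05 rule is a strict sign-dependent threshold", {
  # base 0 keeps the boundary deltas exact in floating point
  fx <- delta_traces(c(0.06, -0.06, 0.05, -0.05, 0), base = 0)
  rt <- classify_responses(fx$t, fx$sch, "kin", window = fx$win)
  expect_equal(as.character(rt$call),
               c("enhanced", "suppressed", "no_change", "no_change",
                 "no_change"))
  expect_equal(rt$delta, c(0.06, -0.06, 0.05, -0.05, 0), tolerance = 1e-12)
  expect_equal(rt$delta,
               rt$mean_integrated_cue - rt$mean_integrated_control)
  expect_error(classify_responses(fx$t, fx$sch, "kin", control = "adult",
                                  window = fx$win), "control")
})

test_that("classification matches an independent brute-force loop", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(3:6, 1)
    tt <- (0:79) * 0.5
    sch <- stimulus_schedule(data.frame(
      onset_s = c(5, 15, 25, 35), duration_s = 2,
      label = c("water", "kin", "water", "kin")))
    t <- trace_set(matrix(rnorm(n * 80, sd = 0.2), n), tt, units = "dff")
    win <- epoch_spec("cue", 0, sample(c(4, 6, 8), 1))
    thr <- runif(1, 0.01, 0.1)
    got <- classify_responses(t, sch, "kin", window = win, threshold = thr)
    ref <- classify_brute(t, sch, "kin", "water", win, thr)
    expect_equal(got$delta, ref$delta, tolerance = 1e-10)
    expect_equal(as.character(got$call), ref$call)
  }
})

test_that("calls are invariant to a common additive offset", {
  fx <- delta_traces(c(0.2, -0.2, 0.01))
  rt1 <- classify_responses(fx$t, fx$sch, "kin", window = fx$win)
  shifted <- fx$t
  shifted$values <- shifted$values + 5
  rt2 <- classify_responses(shifted, fx$sch, "kin", window = fx$win)
  expect_equal(rt1$delta, rt2$delta, tolerance = 1e-12)
  expect_identical(rt1$call, rt2$call)
})

test_that("UV-referenced windows compare trials by their preceding cue", {
  cfg <- small_config(uv_after_cue = 30, flow_response = 0, noise_sd = 0,
                      response_duration = 20,
                      class_mixture = c(trpa1_moderate = 1),
                      mod_uv_mixture = c(suppressed = 1),
                      bout_rate = 0, stim_bout_prob = 0)
  sched <- make_schedule(cfg)
  d <- compute_dff(make_traces(cfg, sched)$traces, sched)
  rt <- classify_responses(d, sched, "kin",
                           window = epoch_preset("post_trpa1_5s"))
  expect_true(all(rt$call == "suppressed"))
})

test_that("threshold sweeps are monotone with the documented limits", {
  fx <- delta_traces(runif(50, -0.3, 0.3))
  sw <- threshold_sweep(fx$t, fx$sch, "kin", window = fx$win,
                        thresholds = c(0.01, 0.05, 0.1, 0.2, 1))
  responsive <- sw$frac_suppressed + sw$frac_enhanced
  expect_true(all(diff(responsive) <= 1e-12))
  expect_equal(sw$frac_no_change[nrow(sw)], 1)   # threshold -> infinity
  # threshold 0 counts only exact ties as no_change
  sw0 <- threshold_sweep(fx$t, fx$sch, "kin", window = fx$win,
                         thresholds = c(0, 0.05))
  rt <- classify_responses(fx$t, fx$sch, "kin", window = fx$win,
                           threshold = 0)
  expect_equal(sw0$frac_no_change[1], mean(rt$delta == 0))
  expect_error(threshold_sweep(fx$t, fx$sch, "kin", window = fx$win,
                               thresholds = c(0.1, 0.05)))
})

test_that("planted mixture fractions are stable across thresholds", {
  cfg <- generator_config(n_fish = 10, neurons_per_fish = 100, isi = 120,
                          pulse_duration = 10, first_onset = 30,
                          duration = 510, response_duration = 60,
                          class_mixture = c(cue_suppressed = 0.3,
                                            cue_enhanced = 0.1,
                                            cue_neutral = 0.6),
                          effect_size = 0.3, noise_sd = 0.02, seed = 8)
  sched <- make_schedule(cfg)
  sim <- make_traces(cfg, sched)
  d <- smooth_zero_phase(compute_dff(sim$traces, sched))
  sw <- threshold_sweep(d, sched, "kin", window = epoch_preset("post_cue_60s"),
                        thresholds = c(0.02, 0.05, 0.1, 0.15))
  realized_sup <- mean(sim$truth$mod_cue == "suppressed")
  realized_enh <- mean(sim$truth$mod_cue == "enhanced")
  # every threshold in the range reports the planted fractions
  expect_true(all(abs(sw$frac_suppressed - realized_sup) < 0.01))
  expect_true(all(abs(sw$frac_enhanced - realized_enh) < 0.01))
  expect_true(all(abs(sw$frac_suppressed - 0.3) < 0.05))
  expect_true(all(abs(sw$frac_enhanced - 0.1) < 0.05))
})

test_that("population fractions partition the population", {
  fx <- delta_traces(c(-0.2))
  rt <- classify_responses(fx$t, fx$sch, "kin", window = fx$win)
  pf <- population_fractions(rt)
  expect_equal(pf$fraction[pf$call == "suppressed"], 1)
  expect_equal(sum(pf$fraction), 1, tolerance = 1e-12)
  # cross-tab of two cues partitions the neuron count
  fx2 <- delta_traces(runif(40, -0.2, 0.2))
  rt_a <- classify_responses(fx2$t, fx2$sch, "kin", window = fx2$win)
  rt_b <- classify_responses(fx2$t, fx2$sch, "kin", window = fx2$win,
                             threshold = 0.01)
  ov <- response_overlap(rt_a, rt_b)
  expect_equal(sum(ov), 40)
})

test_that("high-SNR calls recover planted labels at >= 99% accuracy", {
  accs <- sapply(1:10, function(s) {
    b <- run_figure_preset("fig2-kin", seed = s, n_fish = 80,
                           neurons_per_fish = 25, isi = 120,
                           duration = 60 + 4 * 120,
                           effect_size = 0.2, noise_sd = 0.025)
    b$accuracy$mod_cue
  })
  expect_true(all(accs >= 0.99))
})

test_that("two-stage subsampling honors its counts and seed", {
  cfg <- small_config()
  t <- make_traces(cfg)$traces    # 2 fish x 10 neurons
  s1 <- subsample_neurons(t, per_fish = 10, per_group = NULL)
  expect_equal(nrow(s1$values), 20)   # fish at the cap keep everything
  t$neuron_meta$group <- rep(c("a", "b"), each = 10)
  s2 <- subsample_neurons(t, per_fish = 8, per_group = 5, seed = 1)
  expect_equal(nrow(s2$values), 10)
  expect_equal(unname(table(s2$neuron_meta$group)), array(c(5L, 5L)))
  s3 <- subsample_neurons(t, per_fish = 8, per_group = 5, seed = 1)
  expect_identical(s2$neuron_meta, s3$neuron_meta)
  expect_error(subsample_neurons(t, per_fish = 8, per_group = 50, seed = 1),
               "exceeds")
})

test_that("12 fish x 25 sampled neurons pool to a 200-neuron selection", {
  meta <- data.frame(fish_id = rep(1:12, each = 40))
  tt <- trace_set(matrix(1.0, 480, 3) + runif(480 * 3), (0:2) * 0.5,
                  meta, units = "raw")
  out <- subsample_neurons(tt, per_fish = 25, per_group = 200, seed = 2)
  expect_equal(nrow(out$values), 200)
  expect_true(all(table(out$neuron_meta$fish_id) <= 25))
})
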