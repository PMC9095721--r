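make_raw <- function(values, dt = 0.5) {
  values <- as.matrix(values)
  trace_set(values, (seq_len(ncol(values)) - 1) * dt, units = "raw")
}
sched1 <- stimulus_schedule(data.frame(onset_s = c(10, 40),
                                       duration_s = 5,
                                       label = c("water", "kin")))

test_that("delta-f/f is (F - F0)/F0 with a pre-stimulus baseline", {
  t <- make_raw(matrix(100, 1, 100))
  d <- compute_dff(t, sched1)
  expect_equal(max(abs(d$values)), 0)
  t2 <- make_raw(rbind(c(rep(100, 20), 150, rep(100, 79))))
  d2 <- compute_dff(t2, sched1)
  expect_equal(d2$values[1, 21], 0.5)
  expect_equal(d2$units, "dff")
})

test_that("raw traces are exactly recoverable from dff and F0", {
  set.seed(1)
  t <- make_raw(matrix(100 + rnorm(500), 5, 100))
  d <- compute_dff(t, sched1)
  f0 <- attr(d, "baseline_f0")
  back <- sweep(sweep(d$values, 1, f0, "*"), 1, f0, "+")
  expect_equal(back, t$values, tolerance = 1e-12)
})

test_that("dff errors are informative", {
  t <- make_raw(matrix(100, 2, 100))
  early <- stimulus_schedule(data.frame(onset_s = 0, duration_s = 1,
                                        label = "kin"))
  expect_error(compute_dff(t, early), "no frames before")
  expect_error(compute_dff(compute_dff(t, sched1), sched1), "already")
})

test_that("forward/inverse consistency: planted amplitude is recovered", {
  cfg <- generator_config(n_fish = 1, neurons_per_fish = 1,
                          frame_interval = 0.05, isi = 100,
                          pulse_duration = 10, first_onset = 20,
                          duration = 430, response_duration = 30,
                          noise_sd = 0, flow_response = 0,
                          class_mixture = c(cue_enhanced = 1),
                          effect_size = 0.3)
  sched <- make_schedule(cfg)
  d <- compute_dff(make_traces(cfg, sched)$traces, sched)
  expect_equal(max(d$values), 0.3, tolerance = 1e-6)
})

test_that("zero-phase smoothing matches the forward-backward oracle", {
  x <- c(0, 0, 0, 1, 0, 0, 0, 0)   # unit impulse
  sm <- smooth_zero_phase(dff_traces(rbind(x)), 3)
  expect_equal(sm$values[1, ], zero_phase_brute(x, 3), tolerance = 1e-12)
  set.seed(2)
  y <- rnorm(60)
  sm5 <- smooth_zero_phase(dff_traces(rbind(y)), 5)
  expect_equal(sm5$values[1, ], zero_phase_brute(y, 5), tolerance = 1e-12)
})

test_that("smoothing is zero-phase and mass-conserving", {
  const <- smooth_zero_phase(dff_traces(rbind(rep(2, 30))), 3)
  expect_equal(const$values[1, ], rep(2, 30))
  tri <- c(rep(0, 10), 1:5, 4:0, rep(0, 10))   # symmetric pulse
  sm <- smooth_zero_phase(dff_traces(rbind(tri)), 3)
  expect_equal(which.max(sm$values[1, ]), which.max(tri))
  # interior mass conserved for constant-padded edges
  z <- c(rep(1, 5), 3, 5, 3, rep(1, 5))
  smz <- smooth_zero_phase(dff_traces(rbind(z)), 3)
  expect_equal(mean(smz$values[1, ]), mean(z), tolerance = 1e-9)
  expect_error(smooth_zero_phase(dff_traces(rbind(1:4)), 5), "window")
})

test_that("background drift is fitted and removed", {
  tt <- (0:199) * 0.5
  vals <- rbind(100 + 0 * tt, 80 + 0 * tt)
  drift <- 0.2 * tt
  t <- trace_set(sweep(vals, 2, -drift), tt, units = "raw")
  bg <- 50 + 0.2 * tt
  out <- subtract_background(t, bg)
  expect_equal(unname(attr(out, "background_fit")["slope"]), 0.2,
               tolerance = 1e-6)
  expect_equal(out$values, vals, tolerance = 1e-9)
  # no drift: output equals input
  t0 <- make_raw(matrix(100, 1, 100))
  expect_equal(subtract_background(t0, rep(7, 100))$values, t0$values,
               tolerance = 1e-9)
  bad <- trace_set(matrix(1, 1, 1), 0, units = "raw")
  expect_error(subtract_background(bad, 1), "degenerate")
})

test_that("a synthetic dye-drift run regains a flat baseline", {
  cfg <- small_config(drift_slope = 0.3, include_background = TRUE,
                      noise_sd = 0, flow_response = 0, effect_size = 0)
  sched <- make_schedule(cfg)
  sim <- make_traces(cfg, sched)
  bg_row <- which(sim$traces$neuron_meta$region == "background")[1]
  corrected <- subtract_background(sim$traces, sim$traces$values[bg_row, ])
  d <- compute_dff(corrected, sched)
  pre <- d$frame_times < min(sched$onset_s)
  expect_lt(max(abs(d$values[, pre])), 1e-3)
})

test_that("stimulus-triggered averages behave like trial means", {
  tt <- (0:99) * 0.5
  resp <- exp(-pmax(tt - 10, 0) / 3) * (tt >= 10) +
    exp(-pmax(tt - 30, 0) / 3) * (tt >= 30)
  t <- dff_traces(rbind(resp))
  sch <- stimulus_schedule(data.frame(onset_s = c(10, 30), duration_s = 1,
                                      label = "kin"))
  sta <- stimulus_triggered_average(t, sch, "kin", epoch_spec("cue", 0, 10))
  single <- resp[tt >= 10 & tt < 20]
  # identical repeats: STA equals the single-trial response (up to the
  # overlap of the second event's tail, negligible at this separation)
  expect_equal(as.numeric(sta$sta[1, ]), single, tolerance = 1e-2)
  # a response and its negation average to zero
  x <- c(rep(0, 10), 1, 2, 1, rep(0, 17), -1, -2, -1, rep(0, 17))
  t2 <- dff_traces(rbind(x), dt = 1)
  sch2 <- stimulus_schedule(data.frame(onset_s = c(10, 30), duration_s = 1,
                                       label = "kin"))
  sta2 <- stimulus_triggered_average(t2, sch2, "kin", epoch_spec("cue", 0, 5))
  expect_equal(max(abs(sta2$sta)), 0)
  expect_error(stimulus_triggered_average(t2, sch2, "adult",
                                          epoch_spec("cue", 0, 5)),
               "no events")
})

test_that("averaging across repeats shrinks noise as expected", {
  set.seed(3)
  dt <- 0.5
  tt <- seq(0, 400, by = dt)
  onsets <- seq(20, 370, by = 50)         # 8 repeats
  shape <- oxtrace:::response_series(onsets, 10, tt)
  one <- oxtrace:::response_series(onsets[1], 10, tt)
  noise_sd <- 0.1
  t <- trace_set(rbind(0.5 * shape + rnorm(length(tt), sd = noise_sd)),
                 tt, units = "dff")
  sch <- stimulus_schedule(data.frame(onset_s = onsets, duration_s = 10,
                                      label = "kin"))
  sta <- stimulus_triggered_average(t, sch, "kin", epoch_spec("cue", 0, 30))
  idx <- which(tt >= onsets[1] & tt < onsets[1] + 30)[seq_along(sta$rel_time)]
  rmse <- sqrt(mean((sta$sta[1, ] - 0.5 * one[idx])^2))
  expect_lt(rmse, noise_sd / sqrt(8) * 1.5)
})

test_that("epoch integration is a mean and is linear", {
  t <- dff_traces(rbind(rep(0.7, 100)))
  win <- epoch_spec("cue", 0, 10)
  expect_equal(unname(integrate_epoch(t, sched1, "kin", win)$per_neuron), 0.7)
  # closed-form: mean of exp(-t/3) over [0, 60]
  dt <- 0.001
  tt <- seq(0, 80, by = dt)
  tr <- dff_traces(rbind(exp(-tt / 3)), dt = dt)
  sch <- stimulus_schedule(data.frame(onset_s = 0, duration_s = 1,
                                      label = "kin"))
  got <- unname(integrate_epoch(tr, sch, "kin",
                                epoch_spec("cue", 0, 60))$per_neuron)
  expect_lt(abs(got - 3 / 60 * (1 - exp(-20))), 1e-4)
  # linearity
  set.seed(4)
  x <- rnorm(100); y <- rnorm(100)
  win2 <- epoch_spec("cue", 0, 20)
  ie <- function(v) unname(integrate_epoch(dff_traces(rbind(v)), sched1,
                                           "kin", win2)$per_neuron)
  expect_equal(ie(2 * x + 3 * y), 2 * ie(x) + 3 * ie(y), tolerance = 1e-12)
})

test_that("integration can normalize to the control response", {
  tt <- (0:99) * 0.5
  v <- numeric(100)
  v[tt >= 10 & tt < 20] <- 0.2    # water response
  v[tt >= 40 & tt < 50] <- 0.6    # kin response
  t <- dff_traces(rbind(v))
  sch <- stimulus_schedule(data.frame(onset_s = c(10, 40), duration_s = 5,
                                      label = c("water", "kin")))
  got <- integrate_epoch(t, sch, "kin", epoch_spec("cue", 0, 10),
                         normalize_to = "water")$per_neuron
  expect_equal(unname(got), 3)
})

test_that("resampling interpolates onto a new timebase", {
  tt <- 0:10
  t <- dff_traces(rbind(tt), dt = 1)
  out <- resample_traces(t, seq(0, 10, by = 0.5))
  expect_equal(out$values[1, ], seq(0, 10, by = 0.5))
})
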