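# Shared fixtures and independent oracles, built in code at test time.

# Small, fast generator configuration: two cues, short ISI, few frames.
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_fish = 2, neurons_per_fish = 10, isi = 60, pulse_duration = 5,
         first_onset = 20, duration = 20 + 4 * 60, response_duration = 30),
    list(...))
  do.call(generator_config, args)
}

# Trace set with arbitrary dff values (for oracle comparisons).
dff_traces <- function(values, dt = 0.5, meta = NULL) {
  values <- as.matrix(values)
  trace_set(values, frame_times = (seq_len(ncol(values)) - 1) * dt,
            neuron_meta = meta, units = "dff")
}

# Independent Pearson correlation: explicit sum formula.
pearson_brute <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Independent response classification: direct loops over events and frames.
classify_brute <- function(t, schedule, cue, control, window, threshold) {
  mean_for <- function(label) {
    ons <- schedule$onset_s[schedule$label == label]
    sapply(seq_len(nrow(t$values)), function(i) {
      per_event <- sapply(ons, function(on) {
        vals <- c()
        for (j in seq_along(t$frame_times)) {
          tf <- t$frame_times[j]
          if (tf >= on + window$offset_start && tf < on + window$offset_end) {
            vals <- c(vals, t$values[i, j])
          }
        }
        mean(vals)
      })
      mean(per_event)
    })
  }
  delta <- mean_for(cue) - mean_for(control)
  call <- ifelse(delta > threshold, "enhanced",
                 ifelse(delta < -threshold, "suppressed", "no_change"))
  list(delta = delta, call = call)
}

# Exhaustive k-means optimum by enumerating all assignments (tiny inputs).
kmeans_brute <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n <= 8, k <= 3)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    if (length(unique(assign)) == k) {
      inertia <- 0
      for (cl in unique(assign)) {
        sub <- x[assign == cl, , drop = FALSE]
        cen <- colMeans(sub)
        inertia <- inertia + sum(sweep(sub, 2, cen)^2)
      }
      best <- min(best, inertia)
    }
    i <- 1L
    while (i <= n && assign[i] == k) { assign[i] <- 1L; i <- i + 1L }
    if (i > n) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# Forward-then-reverse causal moving average with reflect padding (oracle
# for the zero-phase filter).
zero_phase_brute <- function(x, w) {
  n <- length(x)
  xp <- c(x[w:1], x, x[n:(n - w + 1)])
  fwd <- sapply(seq_along(xp), function(i) {
    if (i < w) NA_real_ else mean(xp[(i - w + 1):i])
  })
  rv <- rev(fwd)
  bwd <- sapply(seq_along(rv), function(i) {
    if (i < w) NA_real_ else mean(rv[(i - w + 1):i])
  })
  rev(bwd)[(w + 1):(w + n)]
}
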