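#' Extract tail bouts from a cumulative tail-angle trace
#'
#' Peak detection on the absolute (lightly smoothed) tail angle: local
#' maxima at least `prominence` degrees high and `min_separation` seconds
#' apart.  The bout onset is the last pre-peak crossing of the rest band
#' (`|angle| < rest_epsilon`), the bout end the first post-peak return into
#' it; the peak cumulative angle is taken from the unsmoothed trace inside
#' the bout span.  Bouts with peak angle strictly greater than 50 degrees
#' are `large`, otherwise `small`.
#'
#' @param tail a `tail_trace` data frame (`time_s`, `angle_deg`).
#' @param prominence minimum peak height above rest, degrees (default 10).
#' @param min_separation minimum peak separation, seconds (default 0.1).
#' @param rest_epsilon rest-band half-width, degrees (default 5).
#' @param angle_cut large/small boundary, degrees (default 50; `large` is
#'   strictly greater).
#' @param smooth_window odd moving-average window (samples) applied before
#'   peak detection to reject tracking noise (default 5).
#' @return a `bout_table` data frame: `bout_id`, `onset`, `peak_time`,
#'   `peak_angle`, `category`, `max_velocity`, `min_velocity` (deg/s).
#' @export
extract_bouts <- function(tail, prominence = 10, min_separation = 0.1,
                          rest_epsilon = 5, angle_cut = 50,
                          smooth_window = 5) {
  stopifnot(all(c("time_s", "angle_deg") %in% names(tail)))
  tt <- tail$time_s
  x <- tail$angle_deg
  dt <- stats::median(diff(tt))
  sm <- if (smooth_window > 1) zero_phase_ma(x, smooth_window) else x
  a <- abs(sm)
  empty <- data.frame(bout_id = integer(), onset = numeric(),
                      peak_time = numeric(), peak_angle = numeric(),
                      category = character(), max_velocity = numeric(),
                      min_velocity = numeric(), stringsAsFactors = FALSE)
  pk <- pracma::findpeaks(a, minpeakheight = prominence,
                          minpeakdistance = max(1L, round(min_separation / dt)))
  if (is.null(pk)) return(structure(empty, class = c("bout_table",
                                                     "data.frame")))
  pk <- pk[order(pk[, 2]), , drop = FALSE]
  rows <- lapply(seq_len(nrow(pk)), function(i) {
    ip <- pk[i, 2]
    pre <- which(a[seq_len(ip)] < rest_epsilon)
    i0 <- if (length(pre)) max(pre) else 1L
    post <- which(a[ip:length(a)] < rest_epsilon)
    i1 <- if (length(post)) ip + min(post) - 1L else length(a)
    span <- i0:i1
    ipk <- span[which.max(abs(x[span]))]
    v <- diff(x[span]) / diff(tt[span])
    data.frame(onset = tt[i0], peak_time = tt[ipk],
               peak_angle = abs(x[ipk]),
               max_velocity = max(v), min_velocity = min(v))
  })
  b <- do.call(rbind, rows)
  # merged rest-band spans can duplicate a bout; keep the larger peak
  keep <- !duplicated(b$onset)
  b <- b[keep, , drop = FALSE]
  b$category <- ifelse(b$peak_angle > angle_cut, "large", "small")
  b <- b[order(b$onset), , drop = FALSE]
  b$bout_id <- seq_len(nrow(b))
  b <- b[, c("bout_id", "onset", "peak_time", "peak_angle", "category",
             "max_velocity", "min_velocity")]
  rownames(b) <- NULL
  structure(b, class = c("bout_table", "data.frame"))
}

#' Bout counts and rates per stimulus epoch
#'
#' Counts bouts (per size category) in the 90 s before each cue (`precue`),
#' the 30 s from cue delivery (`post_cue`), and the 5 s from each UV pulse
#' (`post_trpa1`).  When windows from a dense schedule overlap, a bout is
#' assigned to at most one epoch with precedence post_trpa1 > post_cue >
#' precue (the most specific epoch wins) and a warning is raised.
#'
#' @param bouts a `bout_table`.
#' @param schedule a [stimulus_schedule()].
#' @param precue,post_cue,post_trpa1 window lengths in seconds.
#' @return data frame per epoch x category: bout `count` and `rate_per_min`
#'   (normalized by total epoch time).
#' @export
epoch_bout_frequency <- function(bouts, schedule, precue = 90,
                                 post_cue = 30, post_trpa1 = 5) {
  cues <- cue_events(schedule)
  uv <- schedule$onset_s[schedule$label == "uv_trpa1"]
  windows <- rbind(
    if (length(uv)) data.frame(epoch = "post_trpa1", lo = uv,
                               hi = uv + post_trpa1),
    data.frame(epoch = "post_cue", lo = cues$onset_s,
               hi = cues$onset_s + post_cue),
    data.frame(epoch = "precue", lo = cues$onset_s - precue,
               hi = cues$onset_s)
  )
  overlap <- FALSE
  assign_epoch <- function(on) {
    hit <- windows$epoch[on >= windows$lo & on < windows$hi]
    if (length(hit) > 1) overlap <<- TRUE
    if (length(hit)) hit[1] else NA_character_
  }
  epoch <- vapply(bouts$onset, assign_epoch, character(1))
  if (overlap) {
    warning("overlapping epochs; precedence post_trpa1 > post_cue > precue",
            call. = FALSE)
  }
  total_min <- c(post_trpa1 = length(uv) * post_trpa1,
                 post_cue = nrow(cues) * post_cue,
                 precue = nrow(cues) * precue) / 60
  grid <- expand.grid(epoch = c("precue", "post_cue", "post_trpa1"),
                      category = c("small", "large"),
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(e, cat) {
    sum(epoch == e & bouts$category == cat, na.rm = TRUE)
  }, grid$epoch, grid$category)
  grid$rate_per_min <- ifelse(total_min[grid$epoch] > 0,
                              grid$count / total_min[grid$epoch], 0)
  rownames(grid) <- NULL
  grid
}

#' Kinematic features per bout
#'
#' Finite-difference velocities over each bout span, peak cumulative angle,
#' and latency from the most recent prior scheduled event (absent when the
#' bout precedes all events).
#'
#' @param tail the `tail_trace` the bouts came from.
#' @param bouts a `bout_table`.
#' @param events event onsets in seconds (or a [stimulus_schedule()], whose
#'   onsets are used).
#' @return `bouts` with `max_velocity`, `min_velocity` recomputed and a
#'   `latency_s` column (NA when no prior event).
#' @export
bout_kinematics <- function(tail, bouts, events = numeric()) {
  if (inherits(events, "stimulus_schedule")) events <- events$onset_s
  tt <- tail$time_s
  x <- tail$angle_deg
  feats <- lapply(seq_len(nrow(bouts)), function(i) {
    span <- which(tt >= bouts$onset[i] &
                    tt <= bouts$onset[i] + 2 * (bouts$peak_time[i] -
                                                  bouts$onset[i]))
    if (length(span) < 2) span <- which.min(abs(tt - bouts$onset[i])) + 0:1
    v <- diff(x[span]) / diff(tt[span])
    prior <- events[events <= bouts$onset[i]]
    data.frame(max_velocity = max(v), min_velocity = min(v),
               peak_angle = max(abs(x[span])),
               latency_s = if (length(prior))
                 bouts$onset[i] - max(prior) else NA_real_)
  })
  f <- do.call(rbind, feats)
  out <- bouts
  out$max_velocity <- f$max_velocity
  out$min_velocity <- f$min_velocity
  out$latency_s <- f$latency_s
  out
}
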