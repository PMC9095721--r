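# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without clobbering the caller's
# random-number stream.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a master seed.  Offsets are small
# fixed integers per consumer; results stay inside the 32-bit integer range.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(offset)
}

# Two-stage sampling without replacement shared by `subsample_neurons()` and
# `stratified_sample()`: first up to `per_fish` rows per fish, then exactly
# `per_group` rows per group from the pooled stage-1 sample.
two_stage_sample <- function(meta, per_fish, per_group = NULL,
                             fish_col = "fish_id", group_col = NULL,
                             seed = 0) {
  stopifnot(fish_col %in% names(meta))
  idx_all <- seq_len(nrow(meta))
  local_seed(seed, {
    stage1 <- unlist(lapply(split(idx_all, meta[[fish_col]]), function(idx) {
      if (length(idx) < per_fish) {
        warning("fewer than ", per_fish, " neurons in a fish; keeping all ",
                length(idx), call. = FALSE)
        idx
      } else {
        sample(idx, per_fish)
      }
    }), use.names = FALSE)
    if (is.null(per_group)) return(sort(stage1))
    grp <- if (!is.null(group_col) && group_col %in% names(meta)) {
      meta[[group_col]][stage1]
    } else {
      rep("all", length(stage1))
    }
    stage2 <- unlist(lapply(split(stage1, grp), function(idx) {
      if (length(idx) < per_group) {
        stop("per_group (", per_group, ") exceeds pooled stage-1 sample (",
             length(idx), ")", call. = FALSE)
      }
      sample(idx, per_group)
    }), use.names = FALSE)
    sort(stage2)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
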