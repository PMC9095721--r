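#' Run an end-to-end analysis on a generator preset
#'
#' Generates a synthetic dataset from a [generator_preset()], preprocesses
#' it (delta-f/f, 3-frame zero-phase smoothing), and runs the analyses that
#' preset is meant to exercise:
#'
#' * `fig2-*` presets: classification of the test cue against water over
#'   the 60-s post-stimulus window, plus population fractions.
#' * `fig6-trpa1`: classification over both the 5-s post-UV and the 30-s
#'   pre-UV (post-cue) windows; per-fish regressor banks (stimulus + motor),
#'   the pooled correlation matrix, K-means (k = 12) and broad-class
#'   assignment.
#'
#' Ground truth is carried alongside so recovery can be scored, but no
#' analysis stage reads it.
#'
#' @param preset preset name (see [generator_preset()]).
#' @param seed master seed; every stochastic stage derives its own child
#'   seed from it, so the whole bundle is reproducible.
#' @param out_dir optional directory; when given, all result tables are
#'   written as CSV together with a YAML manifest (preset, seed, config
#'   echo, stage counts).
#' @param threshold classification threshold (default 0.05).
#' @param k cluster count for the TRPA1 preset (default 12).
#' @param ... overrides forwarded to [generator_preset()].
#' @return a result bundle (list) with the config echo, schedule, response
#'   tables, population fractions, recovery accuracies and — for the TRPA1
#'   preset — the correlation matrix, cluster model and class fractions.
#' @export
run_figure_preset <- function(preset, seed = 0, out_dir = NULL,
                              threshold = 0.05, k = 12, ...) {
  config <- generator_preset(preset, seed = seed, ...)
  schedule <- make_schedule(config)
  sim <- make_traces(config, schedule)
  dff <- smooth_zero_phase(compute_dff(sim$traces, schedule), 3)
  test_cue <- setdiff(config$cue_labels, attr(schedule, "control"))[1]
  log <- list(neurons_in = nrow(dff$values))
  bundle <- list(preset = preset, seed = seed, config = config,
                 schedule = schedule, truth = sim$truth)
  if (preset == "fig6-trpa1") {
    rt_post <- classify_responses(dff, schedule, test_cue,
                                  window = epoch_preset("post_trpa1_5s"),
                                  threshold = threshold)
    rt_pre <- classify_responses(dff, schedule, test_cue,
                                 window = epoch_preset("pre_trpa1_30s"),
                                 threshold = threshold)
    corr <- pooled_fish_correlations(dff, schedule, sim$bouts)
    km <- fit_kmeans(corr, k = k, seed = child_seed(seed, 7))
    classes <- assign_classes(km)
    bundle$response_tables <- list(post_trpa1 = rt_post, pre_trpa1 = rt_pre)
    bundle$fractions <- list(post_trpa1 = population_fractions(rt_post),
                             pre_trpa1 = population_fractions(rt_pre))
    bundle$correlations <- corr
    bundle$cluster <- km
    bundle$classes <- classes
    bundle$accuracy <- list(
      mod_uv = mean(as.character(rt_post$call) ==
                      modulation_as_call(sim$truth$mod_uv)),
      mod_cue = mean(as.character(rt_pre$call) ==
                       modulation_as_call(sim$truth$mod_cue))
    )
    log$clustered <- length(km$assignments)
  } else {
    rt <- classify_responses(dff, schedule, test_cue,
                             window = epoch_preset("post_cue_60s"),
                             threshold = threshold)
    bundle$response_tables <- list(post_cue = rt)
    bundle$fractions <- list(post_cue = population_fractions(rt))
    bundle$accuracy <- list(
      mod_cue = mean(as.character(rt$call) ==
                       modulation_as_call(sim$truth$mod_cue))
    )
  }
  log$classified <- nrow(bundle$response_tables[[1]])
  bundle$log <- log
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

modulation_as_call <- function(mod) {
  ifelse(mod == "suppressed", "suppressed",
         ifelse(mod == "enhanced", "enhanced", "no_change"))
}

# Per-fish regressor banks (motor regressors use that fish's bout train),
# correlated fish by fish and stacked into one pooled matrix.
pooled_fish_correlations <- function(dff, schedule, bouts,
                                     params = kernel_params()) {
  fish_ids <- unique(dff$neuron_meta$fish_id)
  labels <- unique(schedule$label)
  mats <- lapply(fish_ids, function(f) {
    sub <- dff[dff$neuron_meta$fish_id == f]
    bank <- regressor_bank(schedule, sub$frame_times, params,
                           bouts = bouts[[f]], labels = labels)
    correlate_traces(sub, bank)
  })
  do.call(rbind, mats)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$response_tables)) {
    utils::write.csv(bundle$response_tables[[nm]],
                     file.path(out_dir, paste0("responses_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(bundle$fractions[[nm]],
                     file.path(out_dir, paste0("fractions_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(bundle$truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$schedule),
                   file.path(out_dir, "schedule.csv"), row.names = FALSE)
  if (!is.null(bundle$correlations)) {
    utils::write.csv(data.frame(neuron_id = rownames(bundle$correlations),
                                bundle$correlations, check.names = FALSE),
                     file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$classes$map,
                     file.path(out_dir, "cluster_classes.csv"),
                     row.names = FALSE)
  }
  manifest <- list(preset = bundle$preset, seed = bundle$seed,
                   log = bundle$log,
                   config = config_as_yaml_list(bundle$config))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Nonparametric group comparison
#'
#' Wraps the standard nonparametric tests used throughout the pipeline:
#' Wilcoxon signed-rank for paired data, Wilcoxon rank-sum for independent
#' samples (one-sided when a directional hypothesis is declared), and
#' Kruskal-Wallis followed by Tukey-Kramer-corrected pairwise comparisons
#' on rank means for multi-group data.
#'
#' @param x numeric values (for the multi-group method: all values).
#' @param y second sample (two-sample methods) or `NULL`.
#' @param groups group labels parallel to `x` (multi-group method).
#' @param method test to run.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (two-sample
#'   methods).
#' @return list with `method`, `statistic`, `p_value`; the multi-group
#'   method adds `pairwise` (data frame of Tukey-Kramer adjusted p-values);
#'   paired data whose differences are all zero return a degenerate result
#'   (`p_value = NA`, `degenerate = TRUE`).
#' @export
compare_groups <- function(x, y = NULL, groups = NULL,
                           method = c("wilcoxon_rank_sum",
                                      "wilcoxon_signed_rank",
                                      "kruskal_wallis_tukey_kramer"),
                           alternative = "two.sided") {
  method <- match.arg(method)
  if (method == "kruskal_wallis_tukey_kramer") {
    stopifnot(!is.null(groups), length(groups) == length(x))
    kw <- stats::kruskal.test(x, factor(groups))
    return(list(method = method,
                statistic = unname(kw$statistic),
                p_value = kw$p.value,
                pairwise = tukey_kramer_ranks(x, factor(groups))))
  }
  stopifnot(!is.null(y))
  paired <- method == "wilcoxon_signed_rank"
  if (paired) {
    stopifnot(length(x) == length(y))
    if (all(x - y == 0)) {
      return(list(method = method, statistic = 0, p_value = NA_real_,
                  degenerate = TRUE))
    }
  }
  wt <- stats::wilcox.test(x, y, paired = paired, alternative = alternative,
                           exact = FALSE)
  list(method = method, statistic = unname(wt$statistic),
       p_value = wt$p.value)
}

# Tukey-Kramer pairwise comparison of mean ranks after Kruskal-Wallis,
# with tie correction; p-values from the studentized range distribution.
tukey_kramer_ranks <- function(x, g) {
  r <- rank(x)
  n <- length(x)
  ni <- tapply(r, g, length)
  mi <- tapply(r, g, mean)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  v <- n * (n + 1) / 12 * tie_corr
  lev <- names(ni)
  k <- length(lev)
  pairs <- utils::combn(lev, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(v / 2 * (1 / ni[[a]] + 1 / ni[[b]]))
    q <- abs(mi[[a]] - mi[[b]]) / se
    data.frame(group_a = a, group_b = b,
               mean_rank_diff = mi[[a]] - mi[[b]],
               p_adj = stats::ptukey(q, k, Inf, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
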