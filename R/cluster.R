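#' K-means clustering of a neuron x regressor correlation matrix
#'
#' Seeded, multi-restart K-means (best of `n_init` restarts by
#' within-cluster sum of squares, via [stats::kmeans()]).  `k = 12` is the
#' headline setting used across datasets; [select_k()] provides BIC/AIC
#' diagnostics.
#'
#' @param corr neurons x regressors correlation matrix (finite entries).
#' @param k number of clusters (`<=` rows).
#' @param seed RNG seed; the fit is deterministic given the seed.
#' @param n_init number of random restarts.
#' @return a `cluster_model`: list with `k`, `assignments` (named integer
#'   vector), `centroids` (k x regressors), `inertia` (total within-cluster
#'   sum of squares), `size`, `seed`, `n_init`.
#' @export
fit_kmeans <- function(corr, k = 12, seed = 0, n_init = 50) {
  corr <- as.matrix(corr)
  if (!all(is.finite(corr))) stop("correlation matrix has non-finite entries")
  if (k > nrow(corr)) stop("k exceeds the number of neurons")
  if (k == nrow(corr)) {
    # one point per cluster: the optimum is immediate (inertia 0)
    assignments <- seq_len(k)
    names(assignments) <- rownames(corr)
    return(structure(list(k = k, assignments = assignments,
                          centroids = corr, inertia = 0,
                          size = rep(1L, k), seed = seed, n_init = n_init),
                     class = "cluster_model"))
  }
  km <- local_seed(seed,
                   stats::kmeans(corr, centers = k, nstart = n_init,
                                 iter.max = 100))
  assignments <- km$cluster
  names(assignments) <- rownames(corr)
  empty <- setdiff(seq_len(k), unique(assignments))
  if (length(empty)) {
    message("empty cluster(s) after fitting: ", paste(empty, collapse = ", "))
  }
  structure(list(k = k, assignments = assignments,
                 centroids = km$centers, inertia = km$tot.withinss,
                 size = km$size, seed = seed, n_init = n_init),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k =", x$k, "; inertia =", signif(x$inertia, 6), "\n")
  cat("  sizes:", paste(x$size, collapse = ", "), "\n")
  invisible(x)
}

#' BIC/AIC model-order diagnostics for K-means
#'
#' For each `k`, the K-means solution is scored under a hard-assignment
#' spherical-Gaussian mixture approximation with shared variance
#' `sigma^2 = inertia / (n * d)` and empirical mixing proportions
#' `n_j / n`:
#' `logL = sum_j n_j log(n_j / n) - (n * d / 2) * (log(2 pi sigma^2) + 1)`,
#' with `p = k * d + 1` centroid-plus-variance parameters,
#' `BIC = -2 logL + p log(n)` and `AIC = -2 logL + 2 p`.  The
#' mixing-proportion term charges each extra cluster for the data it
#' claims, which keeps the criterion from endlessly rewarding blob
#' splitting.  The full table is returned; nothing is picked silently.
#'
#' @param corr neurons x regressors matrix.
#' @param k_range candidate cluster counts (within `2 .. rows - 1`).
#' @param seed RNG seed.
#' @param n_init restarts per fit.
#' @return data frame with `k`, `inertia`, `logL`, `BIC`, `AIC`, and
#'   attributes `k_bic` / `k_aic` holding the argmins.
#' @export
select_k <- function(corr, k_range = 2:12, seed = 0, n_init = 20) {
  corr <- as.matrix(corr)
  n <- nrow(corr); d <- ncol(corr)
  stopifnot(all(k_range >= 2), all(k_range <= n - 1))
  rows <- lapply(k_range, function(k) {
    fit <- fit_kmeans(corr, k, seed = child_seed(seed, k), n_init = n_init)
    sigma2 <- max(fit$inertia / (n * d), .Machine$double.eps)
    nj <- tabulate(fit$assignments, nbins = k)
    nj <- nj[nj > 0]
    logL <- sum(nj * log(nj / n)) - (n * d / 2) * (log(2 * pi * sigma2) + 1)
    p <- k * d + 1
    data.frame(k = k, inertia = fit$inertia, logL = logL,
               BIC = -2 * logL + p * log(n),
               AIC = -2 * logL + 2 * p)
  })
  out <- do.call(rbind, rows)
  attr(out, "k_bic") <- out$k[which.min(out$BIC)]
  attr(out, "k_aic") <- out$k[which.min(out$AIC)]
  out
}

#' Per-cluster counts, percentages and stimulus-triggered averages
#'
#' @param model a `cluster_model`.
#' @param t optional `trace_set` (dff) for per-cluster mean
#'   stimulus-triggered responses.
#' @param schedule,label,window passed to
#'   [stimulus_triggered_average()] when `t` is given.
#' @return list with `counts` (data frame: cluster, n, percent; percentages
#'   sum to 100 over nonempty clusters) and, when traces are supplied,
#'   `sta` (list per cluster: `rel_time`, `mean`).
#' @export
cluster_summary <- function(model, t = NULL, schedule = NULL, label = NULL,
                            window = epoch_preset("post_cue_60s")) {
  stopifnot(inherits(model, "cluster_model"))
  tab <- table(factor(model$assignments, levels = seq_len(model$k)))
  nonempty <- as.integer(names(tab))[tab > 0]
  counts <- data.frame(cluster = nonempty,
                       n = as.integer(tab[tab > 0]))
  counts$percent <- 100 * counts$n / sum(counts$n)
  out <- list(counts = counts)
  if (!is.null(t)) {
    stopifnot(!is.null(schedule), !is.null(label))
    sta_all <- stimulus_triggered_average(t, schedule, label, window)
    out$sta <- lapply(nonempty, function(cl) {
      rows <- which(model$assignments == cl)
      list(cluster = cl, rel_time = sta_all$rel_time,
           mean = colMeans(sta_all$sta[rows, , drop = FALSE]))
    })
  }
  out
}

#' Default broad-class rules for cluster centroids
#'
#' The grouping of clusters into broad activity classes is made explicit as
#' an ordered, mutually exclusive, exhaustive rule list over two centroid
#' summaries: `stim` (correlation with the UV/TRPA1 stimulus regressor) and
#' `spon` (maximum correlation over the spontaneous-motor regressors).
#' Bands: high >= 0.5, moderate 0.2-0.5, weak 0.05-0.2, anticorrelated
#' <= -0.2.  Classes:
#'
#' * `v`   — anticorrelated with the stimulus (`stim <= -0.2`);
#' * `ii_a`/`ii_b` — both stimulus-responsive and spontaneous-motor
#'   correlated (`stim >= 0.2 & spon >= 0.2`; `ii_a` stimulus-dominant);
#' * `i_a`/`i_b`/`i_c` — stimulus-selective at high/moderate/weak
#'   correlation;
#' * `iii` — primarily motor-correlated (`spon >= 0.2`);
#' * `iv`  — unresponsive (everything else).
#'
#' @return ordered list of rules (`class`, `test(stim, spon)`).
#' @export
default_class_rules <- function() {
  list(
    list(class = "v",    test = function(stim, spon) stim <= -0.2),
    list(class = "ii_a", test = function(stim, spon)
      stim >= 0.2 && spon >= 0.2 && stim >= spon),
    list(class = "ii_b", test = function(stim, spon)
      stim >= 0.2 && spon >= 0.2),
    list(class = "i_a",  test = function(stim, spon) stim >= 0.5),
    list(class = "i_b",  test = function(stim, spon) stim >= 0.2),
    list(class = "iii",  test = function(stim, spon) spon >= 0.2),
    list(class = "i_c",  test = function(stim, spon) stim >= 0.05),
    list(class = "iv",   test = function(stim, spon) TRUE)
  )
}

#' Map clusters to broad activity classes
#'
#' Each cluster centroid is summarized by its stimulus correlation and its
#' maximum spontaneous-motor correlation and passed through the ordered
#' rule list; the first matching rule assigns the class.  Rules must be
#' exhaustive (the default set ends in a catch-all).
#'
#' @param model a `cluster_model` fitted on a correlation matrix whose
#'   columns include the stimulus and motor regressors.
#' @param rules rule list as from [default_class_rules()].
#' @param stim_name column name of the stimulus regressor (default
#'   `"uv_trpa1"`).
#' @param spon_names column names of the spontaneous-motor regressors.
#' @return list with `map` (data frame: cluster, class, stim, spon, n) and
#'   `class_fractions` (data frame: class, n, fraction of neurons).
#' @export
assign_classes <- function(model, rules = default_class_rules(),
                           stim_name = "uv_trpa1",
                           spon_names = c("motor_spon_S", "motor_spon_L")) {
  stopifnot(inherits(model, "cluster_model"))
  cen <- model$centroids
  stopifnot(stim_name %in% colnames(cen), all(spon_names %in% colnames(cen)))
  tab <- table(factor(model$assignments, levels = seq_len(model$k)))
  map <- do.call(rbind, lapply(seq_len(nrow(cen)), function(cl) {
    stim <- cen[cl, stim_name]
    spon <- max(cen[cl, spon_names])
    hit <- NULL
    for (r in rules) if (isTRUE(r$test(stim, spon))) { hit <- r$class; break }
    if (is.null(hit)) {
      stop("centroid of cluster ", cl, " matches no rule; rules must be ",
           "exhaustive")
    }
    data.frame(cluster = cl, class = hit, stim = stim, spon = spon,
               n = as.integer(tab[cl]), stringsAsFactors = FALSE)
  }))
  rownames(map) <- NULL
  agg <- stats::aggregate(n ~ class, data = map, sum)
  agg$fraction <- agg$n / sum(agg$n)
  list(map = map, class_fractions = agg)
}
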