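test_that("k-means attains the enumeration optimum on tiny instances", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    k <- sample(2:3, 1)
    x <- matrix(rnorm(n * 2), n)
    fit <- fit_kmeans(x, k, seed = i, n_init = 100)
    expect_equal(fit$inertia, kmeans_brute(x, k), tolerance = 1e-8)
  }
})

test_that("degenerate clusterings behave as expected", {
  set.seed(10)
  x <- matrix(rnorm(12), 6)
  fit <- fit_kmeans(x, k = 6, seed = 1)
  expect_equal(fit$inertia, 0, tolerance = 1e-12)
  expect_error(fit_kmeans(x, k = 7), "exceeds")
  # duplicate rows are always co-assigned
  xd <- rbind(x, x[1, ], x[1, ])
  fit2 <- fit_kmeans(xd, k = 3, seed = 2)
  dup <- fit2$assignments[c(1, 7, 8)]
  expect_equal(length(unique(dup)), 1)
})

test_that("separated blobs are recovered exactly up to relabeling", {
  set.seed(11)
  x <- rbind(matrix(rnorm(40, 0, 0.2), 20),
             matrix(rnorm(40, 8, 0.2), 20))
  planted <- rep(1:2, each = 20)
  fit <- fit_kmeans(x, 2, seed = 3)
  expect_equal(length(unique(paste(planted, fit$assignments))), 2)
})

test_that("fits are deterministic under a seed and permutation-stable", {
  set.seed(12)
  x <- matrix(rnorm(200), 50)
  f1 <- fit_kmeans(x, 4, seed = 5)
  f2 <- fit_kmeans(x, 4, seed = 5)
  expect_identical(f1$assignments, f2$assignments)
  # inertia is invariant under row permutation of the data
  p <- sample(nrow(x))
  f3 <- fit_kmeans(x[p, ], 4, seed = 5, n_init = 100)
  f4 <- fit_kmeans(x, 4, seed = 6, n_init = 100)
  expect_equal(f3$inertia, f4$inertia, tolerance = 1e-8)
})

test_that("BIC and AIC share the likelihood and differ by the penalty", {
  set.seed(13)
  x <- matrix(rnorm(120), 40)
  tab <- select_k(x, 2:5, seed = 1)
  p <- tab$k * ncol(x) + 1
  expect_equal(tab$BIC - tab$AIC, p * (log(nrow(x)) - 2), tolerance = 1e-9)
  expect_equal(tab$BIC, -2 * tab$logL + p * log(nrow(x)), tolerance = 1e-9)
})

test_that("BIC recovers the planted order of separable mixtures", {
  hits <- sapply(1:5, function(s) {
    set.seed(s)
    x <- rbind(matrix(rnorm(100, 0, 0.5), 50),
               matrix(rnorm(100, 10, 0.5), 50),
               matrix(rnorm(100, -10, 0.5), 50))
    attr(select_k(x, 2:6, seed = s), "k_bic") == 3
  })
  expect_true(all(hits))
  # independent cross-check: a spherical Gaussian mixture fit agrees
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))   # Mclust needs its namespace attached
  set.seed(1)
  x <- rbind(matrix(rnorm(100, 0, 0.5), 50),
             matrix(rnorm(100, 10, 0.5), 50),
             matrix(rnorm(100, -10, 0.5), 50))
  mc <- mclust::Mclust(x, G = 2:6, modelNames = "EII", verbose = FALSE)
  expect_equal(mc$G, 3)
})

test_that("cluster summaries report counts, percentages and STAs", {
  set.seed(14)
  x <- matrix(rnorm(30), 15)
  fit <- fit_kmeans(x, 3, seed = 1)
  cs <- cluster_summary(fit)
  expect_equal(sum(cs$counts$percent), 100, tolerance = 1e-9)
  expect_equal(sum(cs$counts$n), 15)
  one <- fit_kmeans(x, 1, seed = 1)
  expect_equal(cluster_summary(one)$counts$percent, 100)
  # with traces: one STA per nonempty cluster
  tt <- (0:99) * 0.5
  tr <- trace_set(matrix(rnorm(15 * 100, sd = 0.1), 15), tt, units = "dff")
  sch <- stimulus_schedule(data.frame(onset_s = c(10, 40), duration_s = 5,
                                      label = c("water", "kin")))
  cs2 <- cluster_summary(fit, tr, sch, "kin", epoch_spec("cue", 0, 10))
  expect_equal(length(cs2$sta), nrow(cs$counts))
})

test_that("centroid rules assign the documented broad classes", {
  centroids <- rbind(
    c(uv_trpa1 = 0.8, motor_spon_S = 0.05, motor_spon_L = 0.02),
    c(uv_trpa1 = 0.5, motor_spon_S = 0.5, motor_spon_L = 0.1),
    c(uv_trpa1 = -0.4, motor_spon_S = 0.0, motor_spon_L = 0.0),
    c(uv_trpa1 = 0.3, motor_spon_S = 0.1, motor_spon_L = 0.05),
    c(uv_trpa1 = 0.1, motor_spon_S = 0.0, motor_spon_L = 0.0),
    c(uv_trpa1 = 0.0, motor_spon_S = 0.0, motor_spon_L = 0.9),
    c(uv_trpa1 = 0.0, motor_spon_S = 0.0, motor_spon_L = 0.0)
  )
  fake <- structure(list(k = nrow(centroids),
                         assignments = setNames(seq_len(nrow(centroids)),
                                                paste0("n", 1:7)),
                         centroids = centroids, inertia = 0,
                         size = rep(1, 7), seed = 0, n_init = 1),
                    class = "cluster_model")
  got <- assign_classes(fake)
  expect_equal(got$map$class,
               c("i_a", "ii_a", "v", "i_b", "i_c", "iii", "iv"))
  expect_equal(sum(got$class_fractions$fraction), 1, tolerance = 1e-12)
  # non-exhaustive rules are an error
  rules <- list(list(class = "i_a", test = function(stim, spon) stim >= 0.5))
  expect_error(assign_classes(fake, rules = rules), "exhaustive")
})

test_that("planted broad-class fractions are recovered on synthetic data", {
  planted <- c(i_a = 0.032, i_b = 0.252, i_c = 0.08, ii = 0.312,
               iii = 0.128, iv = 0.128, v = 0.068)
  for (s in c(21, 22)) {
    b <- run_figure_preset("fig6-trpa1", seed = s, n_fish = 20,
                           mod_cue_mixture = c(none = 1),
                           mod_uv_mixture = c(none = 1))
    cf <- b$classes$class_fractions
    cf$class[cf$class %in% c("ii_a", "ii_b")] <- "ii"
    got <- tapply(cf$fraction, cf$class, sum)
    n <- sum(cf$n)
    for (cl in names(planted)) {
      p <- planted[[cl]]
      ci <- 1.96 * sqrt(p * (1 - p) / n) + 0.01
      frac <- if (cl %in% names(got)) got[[cl]] else 0
      expect_lt(abs(frac - p), ci)
    }
  }
})

test_that("label permutation leaves inertia and class fractions unchanged", {
  b <- run_figure_preset("fig6-trpa1", seed = 23, n_fish = 6,
                         mod_cue_mixture = c(none = 1),
                         mod_uv_mixture = c(none = 1))
  fit <- b$cluster
  perm <- sample(fit$k)
  permuted <- fit
  permuted$assignments <- setNames(perm[fit$assignments],
                                   names(fit$assignments))
  permuted$centroids <- fit$centroids[order(perm), , drop = FALSE]
  a1 <- assign_classes(fit)$class_fractions
  a2 <- assign_classes(permuted)$class_fractions
  expect_equal(a1[order(a1$class), ], a2[order(a2$class), ],
               ignore_attr = TRUE)
})
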