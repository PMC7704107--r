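test_that("firing rate and presence ratio arithmetic", {
  s <- Sorting(list(u = (0:2999) * 3000, e = numeric(0)), 30000)  # 10 Hz for 300 s
  expect_equal(firing_rate(s, "u", 300), 10)
  expect_equal(firing_rate(s, "e", 300), 0)
  expect_equal(firing_rate(s, "u", 600), 5)
  expect_error(firing_rate(s, "u", 0), "positive")

  expect_equal(presence_ratio(s, "u", 300), 1)
  expect_equal(presence_ratio(s, "e", 300), 0)
  # spikes only in the first half of the recording
  expect_equal(presence_ratio(s, "u", 600), 0.5)
})

test_that("SNR is template peak over channel noise", {
  tpl <- structure(list(
    templates = list(u = matrix(c(0, -100, 20, 0), 1)),
    best_channel = c(u = "ch1"), undefined_units = character(0),
    nbefore = 1, nafter = 3, sampling_frequency = 30000,
    channel_ids = "ch1", channel_locations = cbind(0, 0)
  ), class = "TemplateSet")
  expect_equal(snr(tpl, c(ch1 = 10), "u"), 10)
  # scale invariance: scaling both template and noise leaves snr unchanged
  tpl2 <- tpl; tpl2$templates$u <- tpl$templates$u * 3
  expect_equal(snr(tpl2, c(ch1 = 30), "u"), 10)
})

test_that("SNR on a synthesized recording recovers the planted ratio", {
  gt <- generate_gt_sorting(n_units = 3, firing_rate = 8, duration = 10, seed = 14)
  rec <- synthesize_recording(gt, noise_sd = 10, amplitude_uv = 120, seed = 14)
  wf <- extract_waveforms(rec, gt, seed = 0)
  tps <- compute_templates(wf)
  nl <- estimate_noise_levels(rec, seed = 0)
  got <- snr(tps, nl)
  planted <- vapply(unit_ids(gt), function(u) {
    max(abs(rec$gt_templates[[u]])) / rec$noise_sd
  }, 1)
  expect_true(all(abs(got - planted) / planted < 0.15))
})

test_that("ISI violation ratio follows the stated normalization", {
  fs <- 30000
  # clean 2.5 ms spacing: no violations at the 1.5 ms threshold
  clean <- Sorting(list(u = seq(0, 2999) * 75), fs)
  expect_equal(isi_violation_ratio(clean, "u", 100), 0)

  # N = 1000 spikes over 100 s with exactly 3 violating intervals:
  # (3 / (2*1000*0.0015)) / (1000/100) = 0.1
  base <- seq(0, 999) * 3000  # 100 ms apart
  base[c(10, 500, 900)] <- base[c(9, 499, 899)] + 30  # 1 ms gaps
  viol <- Sorting(list(u = sort(base)), fs)
  expect_equal(isi_violation_ratio(viol, "u", 100), 0.1)

  single <- Sorting(list(u = c(5)), fs)
  expect_true(is.nan(isi_violation_ratio(single, "u", 100)))
})

test_that("ISI ratio of a Poisson train sits at the estimator's chance level", {
  # For a homogeneous Poisson train the adjacent-ISI violation count is
  # ~N*r*t while the normalization window is 2*N*t, so this (Hill-style)
  # estimator converges to 0.5, not 1, at chance.
  ratios <- vapply(1:10, function(seed) {
    s <- generate_gt_sorting(n_units = 1, firing_rate = 10, duration = 600,
                             refractory_ms = 0, seed = seed)
    isi_violation_ratio(s, "1", 600)
  }, 1)
  expect_gt(mean(ratios), 0.4)
  expect_lt(mean(ratios), 0.6)
})

test_that("amplitude cutoff estimates the truncated tail", {
  set.seed(123)
  full <- rnorm(10000, mean = 100, sd = 10)
  expect_lte(amplitude_cutoff(full), 0.02)

  truncated <- full[full > 100 - 10]  # planted miss fraction pnorm(-1) = 0.159
  est <- amplitude_cutoff(truncated)
  expect_lt(abs(est - pnorm(-1)), 0.06)

  expect_true(is.nan(amplitude_cutoff(rnorm(40))))
  # pathological bimodal input is capped at 0.5
  bimodal <- c(rnorm(5000, 0, 0.5), rnorm(5000, 10, 0.5))
  expect_lte(amplitude_cutoff(bimodal), 0.5)
})

# PCAScores stub with explicit per-channel PC1 scores and spike frames,
# used to plant known depths for the drift metrics
fake_drift_pca <- function(depths, times, fs = 30000, y = c(0, 100)) {
  n <- length(depths)
  arr <- array(0, dim = c(n, 2, 1))
  w <- depths / max(y)  # fraction of PC1 energy on the deep channel
  arr[, 1, 1] <- sqrt(1 - w)
  arr[, 2, 1] <- sqrt(w)
  structure(list(
    scores = list(u = arr), features = matrix(arr, n), labels = rep("u", n),
    spike_frames = list(u = round(times * fs)),
    basis = NULL, centers = NULL, sdev = NULL, n_comp = 1,
    channel_ids = c("a", "b"), channel_locations = cbind(0, y),
    sampling_frequency = fs
  ), class = "PCAScores")
}

test_that("drift metrics recover planted depth trajectories", {
  set.seed(4)
  t <- sort(runif(600, 0, 600))
  stationary <- fake_drift_pca(rep(50, 600), t)
  d0 <- drift_metrics(stationary, "u")
  expect_equal(d0$max_drift_um, 0)
  expect_equal(d0$cumulative_drift_um, 0)

  # linear 20 um drift end-to-end; interval medians sit at interval centres
  drifting <- fake_drift_pca(40 + 20 * t / 600, t)
  d1 <- drift_metrics(drifting, "u")
  expect_gt(d1$max_drift_um, 16)
  expect_lt(d1$max_drift_um, 24)
  # monotone drift: cumulative equals max
  expect_equal(d1$cumulative_drift_um, d1$max_drift_um, tolerance = 1e-9)

  short <- fake_drift_pca(rep(50, 5), sort(runif(5, 0, 30)))
  expect_true(is.nan(drift_metrics(short, "u")$max_drift_um))
})

two_cluster_features <- function(n1 = 200, n2 = 200, sep = 10, d = 3, seed = 1) {
  set.seed(seed)
  f <- rbind(matrix(rnorm(n1 * d), n1),
             matrix(rnorm(n2 * d), n2) + matrix(rep(c(sep, rep(0, d - 1)), each = n2), n2))
  pca_scores_from_matrix(f, c(rep("a", n1), rep("b", n2)))
}

test_that("isolation distance matches a naive recomputation", {
  pca <- two_cluster_features(sep = 10)
  got <- isolation_distance(pca, "a")
  # independent recomputation: mahalanobis by explicit solve
  mem <- pca$features[pca$labels == "a", ]
  oth <- pca$features[pca$labels == "b", ]
  mu <- colMeans(mem); S <- cov(mem)
  diffs <- sweep(oth, 2, mu)
  d2 <- rowSums((diffs %*% solve(S)) * diffs)
  expect_equal(got, sort(d2)[nrow(mem)], tolerance = 1e-9)
  expect_gt(got, 50)  # 10-sigma separation is far

  # all non-members at the cluster mean -> distance ~0
  mem_a <- matrix(rnorm(50 * 2), 50)
  at_mean <- pca_scores_from_matrix(
    rbind(mem_a, matrix(colMeans(mem_a), 100, 2, byrow = TRUE)),
    c(rep("a", 50), rep("b", 100)))
  expect_lt(isolation_distance(at_mean, "a"), 0.5)

  # more members than non-members -> NaN
  few <- pca_scores_from_matrix(rbind(matrix(rnorm(60), 30), matrix(rnorm(20), 10)),
                                c(rep("a", 30), rep("b", 10)))
  expect_true(is.nan(isolation_distance(few, "a")))
})

test_that("L-ratio separates far clusters and is ~0.5 for identical ones", {
  far <- two_cluster_features(sep = 12)
  expect_lte(l_ratio(far, "a"), 0.01)

  vals <- vapply(1:20, function(s) {
    same <- two_cluster_features(sep = 0, seed = s)
    l_ratio(same, "a")
  }, 1)
  expect_lt(abs(mean(vals) - 0.5), 0.1)

  lone <- pca_scores_from_matrix(matrix(rnorm(40), 20), rep("a", 20))
  expect_equal(l_ratio(lone, "a"), 0)
})

test_that("d-prime measures standardized separation and is affine-invariant", {
  same <- two_cluster_features(sep = 0, n1 = 500, n2 = 500, d = 2, seed = 2)
  expect_lte(d_prime(same, "a"), 0.2)

  two <- two_cluster_features(sep = 2, n1 = 2000, n2 = 2000, d = 1, seed = 3)
  expect_lt(abs(d_prime(two, "a") - 2), 0.15)

  scaled <- two
  scaled$features <- two$features * 7
  expect_equal(d_prime(scaled, "a"), d_prime(two, "a"), tolerance = 1e-9)
})

test_that("nearest-neighbour rates detect separation and overlap", {
  far <- two_cluster_features(sep = 12, seed = 4)
  nn <- nearest_neighbor_metrics(far, "a")
  expect_gte(nn$hit_rate, 0.95)
  expect_lte(nn$miss_rate, 0.05)

  mixed <- two_cluster_features(sep = 0, seed = 5)
  nnm <- nearest_neighbor_metrics(mixed, "a")
  expect_lt(abs(nnm$hit_rate - 0.5), 0.15)

  lone <- pca_scores_from_matrix(rbind(matrix(rnorm(20), 10), 5), c(rep("a", 10), "b"))
  expect_true(is.nan(nearest_neighbor_metrics(lone, "b")$hit_rate))
})

test_that("silhouette scores tight/far vs duplicated clusters", {
  far <- two_cluster_features(sep = 30, seed = 6)
  expect_gte(silhouette_score(far, "a"), 0.9)

  dup <- two_cluster_features(sep = 0, seed = 7)
  expect_lt(abs(silhouette_score(dup, "a")), 0.1)

  single <- pca_scores_from_matrix(matrix(rnorm(40), 20), rep("a", 20))
  expect_true(is.nan(silhouette_score(single, "a")))
})

test_that("compute_quality_metrics orchestrates dependencies and seeds", {
  gt <- generate_gt_sorting(n_units = 3, firing_rate = 10, duration = 8, seed = 31)
  # rate-only metrics need no recording
  t1 <- compute_quality_metrics(gt, metric_names = c("firing_rate", "presence_ratio"),
                                duration = 8)
  expect_identical(names(t1), c("unit_id", "firing_rate", "presence_ratio"))
  expect_error(compute_quality_metrics(gt, metric_names = "snr"), "require a recording")
  expect_error(compute_quality_metrics(gt, metric_names = "bogus"), "unknown metric")

  rec <- synthesize_recording(gt, noise_sd = 8, seed = 31)
  a <- compute_quality_metrics(gt, rec, seed = 7)
  b <- compute_quality_metrics(gt, rec, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(is.null(attr(a, "params")))

  p <- tempfile(fileext = ".csv")
  write_metric_table(a, p)
  expect_true(file.exists(p) && file.exists(paste0(p, ".params.json")))
})

test_that("metric table values respect their documented ranges", {
  set.seed(77)
  for (i in 1:5) {
    gt <- generate_gt_sorting(n_units = sample(2:4, 1), firing_rate = c(4, 12),
                              duration = 6, seed = 200 + i)
    rec <- synthesize_recording(gt, noise_sd = sample(5:15, 1), seed = 300 + i)
    tab <- compute_quality_metrics(gt, rec, seed = i)
    expect_true(all(tab$firing_rate >= 0))
    expect_true(all(tab$presence_ratio >= 0 & tab$presence_ratio <= 1))
    expect_true(all(is.nan(tab$amplitude_cutoff) |
                    (tab$amplitude_cutoff >= 0 & tab$amplitude_cutoff <= 0.5)))
    expect_true(all(is.nan(tab$isolation_distance) | tab$isolation_distance >= 0))
    expect_true(all(is.nan(tab$nn_hit_rate) |
                    (tab$nn_hit_rate >= 0 & tab$nn_hit_rate <= 1)))
    expect_true(all(is.nan(tab$silhouette) |
                    (tab$silhouette >= -1 & tab$silhouette <= 1)))
    expect_true(all(is.nan(tab$isi_violation_ratio) | tab$isi_violation_ratio >= 0))
  }
})

test_that("contamination increases the ISI violation ratio monotonically", {
  levels <- c(0, 0.05, 0.1, 0.15, 0.2)
  rhos <- vapply(1:8, function(seed) {
    gt <- generate_gt_sorting(n_units = 1, firing_rate = 10, duration = 300,
                              refractory_ms = 3, seed = seed)
    ratios <- vapply(levels, function(fp) {
      s <- corrupt_sorting(gt, fp_rate = fp * 10, duration = 300, seed = seed + 1)
      isi_violation_ratio(s, "1", 300)
    }, 1)
    cor(levels, ratios, method = "spearman")
  }, 1)
  expect_gt(mean(rhos), 0.9)
})

test_that("separation metrics are monotone in planted cluster distance", {
  seps <- c(0.5, 1, 2, 4, 8)
  vals <- lapply(seps, function(s) {
    pca <- two_cluster_features(n1 = 300, n2 = 300, sep = s, d = 2, seed = 11)
    list(dp = d_prime(pca, "a"), iso = isolation_distance(pca, "a"),
         nn = nearest_neighbor_metrics(pca, "a")$hit_rate,
         sil = silhouette_score(pca, "a"))
  })
  get <- function(k) vapply(vals, `[[`, 1, k)
  expect_true(all(diff(get("dp")) >= 0))
  expect_true(all(diff(get("iso")) >= 0))
  expect_true(all(diff(get("nn")) >= -1e-9))
  expect_true(all(diff(get("sil")) >= 0))
})
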