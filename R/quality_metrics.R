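# Per-unit quality metrics. All "undefined for this unit" cases return NaN,
# never an error, so a metric table can always be assembled; downstream
# curation treats NaN as failing any threshold (overridable).

#' Firing rate of a unit
#' @param sorting a `Sorting`.
#' @param unit unit id.
#' @param duration recording duration in seconds (> 0).
#' @return spikes per second (Hz).
#' @export
firing_rate <- function(sorting, unit, duration) {
  if (!is_scalar_num(duration) || duration <= 0) {
    sm_stop("duration must be positive", type = "parameter")
  }
  length(spike_train(sorting, unit)) / duration
}

#' Presence ratio of a unit
#'
#' Fraction of equal-width time bins spanning the recording that contain at
#' least one spike.
#'
#' @inheritParams firing_rate
#' @param num_bins number of bins (default 100).
#' @return fraction in `[0, 1]`.
#' @export
presence_ratio <- function(sorting, unit, duration, num_bins = 100L) {
  if (!is_scalar_num(duration) || duration <= 0) {
    sm_stop("duration must be positive", type = "parameter")
  }
  t <- spike_times(sorting, unit)
  if (length(t) == 0L) return(0)
  bins <- pmin(floor(t / (duration / num_bins)), num_bins - 1L)
  length(unique(bins)) / num_bins
}

#' Template signal-to-noise ratio
#'
#' Maximum absolute template amplitude on the unit's best channel divided by
#' the MAD-based noise level of that channel.
#'
#' @param templates a `TemplateSet`.
#' @param noise_levels named per-channel noise sigma in microvolts, from
#'   [estimate_noise_levels()].
#' @param unit unit id, or `NULL` for all units.
#' @return named numeric vector of SNR values (NaN for undefined templates).
#' @export
snr <- function(templates, noise_levels, unit = NULL) {
  stopifnot(inherits(templates, "TemplateSet"))
  units <- unit %||% names(templates$templates)
  out <- vapply(as.character(units), function(u) {
    bc <- templates$best_channel[[u]]
    if (is.na(bc)) return(NaN)
    sig <- noise_levels[[bc]]
    if (!is.finite(sig) || sig <= 0) return(NaN)
    max(abs(templates$templates[[u]][match(bc, templates$channel_ids), ])) / sig
  }, 1)
  if (!is.null(unit) && length(unit) == 1L) unname(out) else out
}

#' ISI refractory-period violation ratio
#'
#' The rate of inter-spike intervals shorter than `isi_threshold_ms`,
#' normalized by the unit's overall firing rate (Hill-style contamination
#' estimator): `[n_violations / (2 N (t_r - t_min))] / (N / T)`. A value
#' near 1 means the short-ISI rate equals that of a homogeneous Poisson
#' train of the same rate; a clean refractory unit scores 0.
#'
#' @inheritParams firing_rate
#' @param isi_threshold_ms refractory threshold in milliseconds (default 1.5).
#' @param min_isi_ms censored minimum ISI in milliseconds (default 0).
#' @return ratio >= 0, or NaN for units with fewer than 2 spikes.
#' @export
isi_violation_ratio <- function(sorting, unit, duration,
                                isi_threshold_ms = 1.5, min_isi_ms = 0) {
  t <- spike_times(sorting, unit)
  n <- length(t)
  if (n < 2L) return(NaN)
  isi <- diff(t)
  n_viol <- sum(isi < isi_threshold_ms / 1000)
  viol_window <- 2 * n * (isi_threshold_ms - min_isi_ms) / 1000
  (n_viol / viol_window) / (n / duration)
}

#' Amplitude-cutoff estimate of the missed-spike fraction
#'
#' Builds a smoothed histogram of the spike amplitudes, assumed truncated on
#' the low side when spikes were missed by the detector. The height of the
#' lowest-amplitude bin marks the truncation level; by symmetry, the
#' histogram mass beyond the mirrored point on the high side of the peak
#' equals the mass cut off below. The miss fraction is reported relative to
#' the reconstructed full distribution (observed mass plus the estimated
#' missing mass), and capped at 0.5 (a symmetric distribution cannot
#' indicate more than half missing).
#'
#' @param amplitudes numeric vector of spike amplitudes on a scale where
#'   weak spikes are small (pass magnitudes, or negate negative-going
#'   amplitudes).
#' @param num_bins histogram bins (default 500).
#' @param smoothing Gaussian smoothing sigma in bins (default 3).
#' @return estimated miss fraction in `[0, 0.5]`; NaN for fewer than 50
#'   spikes.
#' @export
amplitude_cutoff <- function(amplitudes, num_bins = 500L, smoothing = 3) {
  amplitudes <- amplitudes[is.finite(amplitudes)]
  if (length(amplitudes) < 50L) return(NaN)
  h <- graphics::hist(amplitudes, breaks = seq(min(amplitudes), max(amplitudes),
                                               length.out = num_bins + 1L),
                      plot = FALSE)
  pdf <- gaussian_smooth(h$counts, smoothing)
  peak <- which.max(pdf)
  tail_part <- pdf[peak:length(pdf)]
  g <- peak + which.min(abs(tail_part - pdf[1L])) - 1L
  t_obs <- sum(pdf[g:length(pdf)]) / sum(pdf)
  # t_obs is the mirrored tail relative to the *observed* mass; the missing
  # fraction of the full distribution is t/(1+t)
  min(t_obs / (1 + t_obs), 0.5)
}

gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- ceiling(4 * sigma)
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k <- k / sum(k)
  # reflect-pad so edge bins keep their mass scale
  xp <- c(rev(x[seq_len(r)]), x, rev(x[length(x) - seq_len(r) + 1L]))
  as.numeric(stats::filter(xp, k, sides = 2L))[(r + 1L):(r + length(x))]
}

# depth of each spike: centre of mass of the energy of the first
# principal-component score across channels, using the probe y-coordinate
spike_depths <- function(pca, unit) {
  arr <- pca$scores[[unit]]
  if (is.null(arr) || dim(arr)[1L] == 0L) return(numeric(0))
  pc1sq <- arr[, , 1L, drop = FALSE]^2
  pc1sq <- matrix(pc1sq, dim(arr)[1L], dim(arr)[2L])
  y <- pca$channel_locations[, 2L]
  num <- pc1sq %*% y
  den <- rowSums(pc1sq)
  as.numeric(num) / den
}

#' Drift metrics (maximum and cumulative)
#'
#' Estimates each spike's depth as the centre of mass of its first
#' principal-component energy across channels, takes the median depth per
#' time interval, and reports the range (max drift) and the summed absolute
#' change between successive intervals (cumulative drift).
#'
#' @param pca a `PCAScores` with channel locations and spike frames.
#' @param unit unit id.
#' @param interval_s interval length in seconds (default 60).
#' @param min_spikes_per_interval intervals with fewer spikes are skipped
#'   (default 10).
#' @return list `(max_drift_um, cumulative_drift_um)`; both NaN when fewer
#'   than 2 valid intervals exist.
#' @export
drift_metrics <- function(pca, unit, interval_s = 60, min_spikes_per_interval = 10L) {
  stopifnot(inherits(pca, "PCAScores"))
  if (is.null(pca$spike_frames) || is.null(pca$channel_locations)) {
    sm_stop("drift metrics need spike frames and channel locations", type = "parameter")
  }
  depths <- spike_depths(pca, unit)
  t <- pca$spike_frames[[unit]] / pca$sampling_frequency
  if (length(depths) == 0L) return(list(max_drift_um = NaN, cumulative_drift_um = NaN))
  iv <- floor(t / interval_s)
  med <- tapply(depths, iv, function(d) {
    if (length(d) >= min_spikes_per_interval) stats::median(d) else NA_real_
  })
  med <- med[!is.na(med)]
  if (length(med) < 2L) return(list(max_drift_um = NaN, cumulative_drift_um = NaN))
  list(max_drift_um = max(med) - min(med),
       cumulative_drift_um = sum(abs(diff(med))))
}

pca_members <- function(pca, unit) {
  which(pca$labels == as.character(unit))
}

#' Isolation distance of a unit
#'
#' Squared Mahalanobis distance (under the unit's own mean and covariance)
#' of the N-th closest non-member spike, N being the unit's spike count —
#' the radius of the smallest ellipsoid centred on the cluster that contains
#' as many non-member spikes as the cluster has members.
#'
#' @param pca a `PCAScores`.
#' @param unit unit id.
#' @return distance >= 0, or NaN when non-members are fewer than members or
#'   the covariance is singular.
#' @export
isolation_distance <- function(pca, unit) {
  stopifnot(inherits(pca, "PCAScores"))
  mem <- pca_members(pca, unit)
  oth <- setdiff(seq_len(nrow(pca$features)), mem)
  n <- length(mem)
  if (n < 2L || length(oth) < n) return(NaN)
  x <- pca$features[mem, , drop = FALSE]
  d2 <- tryCatch(
    stats::mahalanobis(pca$features[oth, , drop = FALSE], colMeans(x), stats::cov(x)),
    error = function(e) NULL
  )
  if (is.null(d2)) return(NaN)
  sort(d2)[n]
}

#' L-ratio of a unit
#'
#' Sum over non-member spikes of the chi-square tail probability of their
#' squared Mahalanobis distance from the cluster (df = feature dimension),
#' divided by the cluster's spike count.
#'
#' @inheritParams isolation_distance
#' @return ratio >= 0 (0 when there are no non-members), NaN when the
#'   covariance is singular or the cluster has fewer than 2 spikes.
#' @export
l_ratio <- function(pca, unit) {
  stopifnot(inherits(pca, "PCAScores"))
  mem <- pca_members(pca, unit)
  oth <- setdiff(seq_len(nrow(pca$features)), mem)
  if (length(mem) < 2L) return(NaN)
  if (length(oth) == 0L) return(0)
  x <- pca$features[mem, , drop = FALSE]
  d2 <- tryCatch(
    stats::mahalanobis(pca$features[oth, , drop = FALSE], colMeans(x), stats::cov(x)),
    error = function(e) NULL
  )
  if (is.null(d2)) return(NaN)
  sum(1 - stats::pchisq(d2, df = ncol(pca$features))) / length(mem)
}

#' d-prime separation of a unit
#'
#' Projects member and non-member spikes onto the Fisher linear discriminant
#' axis and reports the standardized mean separation
#' `|mu1 - mu2| / sqrt((s1^2 + s2^2)/2)`.
#'
#' @inheritParams isolation_distance
#' @return d' >= 0, or NaN when either class has fewer than 2 spikes or the
#'   pooled covariance is singular.
#' @export
d_prime <- function(pca, unit) {
  stopifnot(inherits(pca, "PCAScores"))
  mem <- pca_members(pca, unit)
  oth <- setdiff(seq_len(nrow(pca$features)), mem)
  if (length(mem) < 2L || length(oth) < 2L) return(NaN)
  x1 <- pca$features[mem, , drop = FALSE]
  x2 <- pca$features[oth, , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  sw <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) / (n1 + n2 - 2)
  w <- tryCatch(solve(sw, colMeans(x1) - colMeans(x2)), error = function(e) NULL)
  if (is.null(w)) return(NaN)
  p1 <- x1 %*% w
  p2 <- x2 %*% w
  abs(mean(p1) - mean(p2)) / sqrt((stats::var(as.numeric(p1)) +
                                   stats::var(as.numeric(p2))) / 2)
}

# squared euclidean cross-distances via the expansion trick
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Nearest-neighbour contamination metrics
#'
#' `hit_rate`: among the `n_neighbors` nearest neighbours (excluding self)
#' of each member spike, the average fraction that are themselves members.
#' `miss_rate`: the average fraction of member neighbours around non-member
#' spikes. A well-isolated unit has hit rate near 1 and miss rate near 0;
#' two fully interleaved equal clusters give both near 0.5.
#'
#' @inheritParams isolation_distance
#' @param n_neighbors neighbours per query (default 4).
#' @param max_spikes subsample cap on the total spikes considered, seeded.
#' @param seed RNG seed for the subsample.
#' @return list `(hit_rate, miss_rate)`, each in `[0, 1]` or NaN for
#'   degenerate clusters (fewer than 2 members or no non-members).
#' @export
nearest_neighbor_metrics <- function(pca, unit, n_neighbors = 4L,
                                     max_spikes = 10000L, seed = 0L) {
  stopifnot(inherits(pca, "PCAScores"))
  idx <- seq_len(nrow(pca$features))
  if (length(idx) > max_spikes) {
    idx <- with_seed(seed, sort(sample.int(length(idx), max_spikes)))
  }
  labels <- pca$labels[idx]
  is_mem <- labels == as.character(unit)
  if (sum(is_mem) < 2L || sum(!is_mem) == 0L) {
    return(list(hit_rate = NaN, miss_rate = NaN))
  }
  x <- pca$features[idx, , drop = FALSE]
  d2 <- cross_dist2(x, x)
  diag(d2) <- Inf
  k <- min(n_neighbors, nrow(x) - 1L)
  frac_member <- vapply(seq_len(nrow(x)), function(i) {
    nn <- order(d2[i, ])[seq_len(k)]
    mean(is_mem[nn])
  }, 1)
  list(hit_rate = mean(frac_member[is_mem]),
       miss_rate = mean(frac_member[!is_mem]))
}

#' Mean silhouette score of a unit
#'
#' For each member spike, cohesion `a` is its mean distance to the other
#' members and separation `b` its mean distance to the nearest other
#' cluster; the silhouette is `(b - a) / max(a, b)` and the unit score is
#' the mean over members.
#'
#' @inheritParams isolation_distance
#' @param max_spikes subsample cap (seeded) on spikes per computation.
#' @param seed RNG seed.
#' @return mean silhouette in `[-1, 1]`, NaN when there is no other cluster
#'   or fewer than 2 members.
#' @export
silhouette_score <- function(pca, unit, max_spikes = 5000L, seed = 0L) {
  stopifnot(inherits(pca, "PCAScores"))
  idx <- seq_len(nrow(pca$features))
  if (length(idx) > max_spikes) {
    idx <- with_seed(seed, sort(sample.int(length(idx), max_spikes)))
  }
  labels <- pca$labels[idx]
  mem <- idx[labels == as.character(unit)]
  others <- setdiff(unique(labels), as.character(unit))
  if (length(mem) < 2L || length(others) == 0L) return(NaN)
  xm <- pca$features[mem, , drop = FALSE]
  dmm <- sqrt(cross_dist2(xm, xm))
  a <- rowSums(dmm) / (nrow(xm) - 1L)
  bmat <- vapply(others, function(o) {
    xo <- pca$features[idx[labels == o], , drop = FALSE]
    if (nrow(xo) == 0L) return(rep(Inf, nrow(xm)))
    rowMeans(sqrt(cross_dist2(xm, xo)))
  }, numeric(nrow(xm)))
  b <- if (is.matrix(bmat)) apply(bmat, 1L, min) else bmat
  mean((b - a) / pmax(a, b))
}

QM_ALL <- c("firing_rate", "presence_ratio", "isi_violation_ratio", "snr",
            "amplitude_cutoff", "drift", "isolation_distance", "l_ratio",
            "d_prime", "nearest_neighbor", "silhouette")
QM_NEED_RECORDING <- c("snr", "amplitude_cutoff", "drift", "isolation_distance",
                       "l_ratio", "d_prime", "nearest_neighbor", "silhouette")

#' Compute a table of quality metrics
#'
#' Computes the requested metrics for every unit, internally deriving
#' waveforms, templates, PCA projections, amplitudes and noise levels as
#' needed. Deterministic for a fixed seed.
#'
#' @param sorting a `Sorting`.
#' @param recording a `Recording`; required for the metrics that consume
#'   traces (`snr`, `amplitude_cutoff`, `drift`, `isolation_distance`,
#'   `l_ratio`, `d_prime`, `nearest_neighbor`, `silhouette`).
#' @param metric_names character vector of metric names, or `"all"`.
#' @param duration recording duration in seconds; defaults to the
#'   recording's duration, or to the last spike time when no recording is
#'   given.
#' @param params named list overriding metric parameters (`num_bins`,
#'   `isi_threshold_ms`, `min_isi_ms`, `amp_num_bins`, `amp_smoothing`,
#'   `peak_sign`, `interval_s`, `min_spikes_per_interval`, `n_neighbors`,
#'   `max_spikes`, `n_comp`, `ms_before`, `ms_after`, `max_spikes_per_unit`).
#' @param seed RNG seed for every stochastic step.
#' @return a `MetricTable` data.frame (one row per unit, one column per
#'   metric) with the fully resolved parameter block in
#'   `attr(, "params")`.
#' @export
compute_quality_metrics <- function(sorting, recording = NULL,
                                    metric_names = "all", duration = NULL,
                                    params = list(), seed = 0L) {
  stopifnot(inherits(sorting, "Sorting"))
  if (identical(metric_names, "all")) metric_names <- QM_ALL
  unknown <- setdiff(metric_names, QM_ALL)
  if (length(unknown)) {
    sm_stop(sprintf("unknown metric name(s): %s", paste(unknown, collapse = ", ")),
            type = "parameter")
  }
  need_rec <- intersect(metric_names, QM_NEED_RECORDING)
  if (length(need_rec) && is.null(recording)) {
    sm_stop(sprintf("metric(s) %s require a recording",
                    paste(need_rec, collapse = ", ")), type = "validation")
  }
  p <- utils::modifyList(list(
    num_bins = 100L, isi_threshold_ms = 1.5, min_isi_ms = 0,
    amp_num_bins = 500L, amp_smoothing = 3, peak_sign = "neg",
    interval_s = 60, min_spikes_per_interval = 10L,
    n_neighbors = 4L, max_spikes = 10000L,
    n_comp = 3L, ms_before = 1, ms_after = 2, max_spikes_per_unit = 500L
  ), params)
  duration <- duration %||% if (!is.null(recording)) {
    recording_duration(recording)
  } else {
    (max(c(0, unlist(sorting$spike_trains))) + 1) / sorting$sampling_frequency
  }
  ids <- unit_ids(sorting)
  tab <- data.frame(unit_id = ids, stringsAsFactors = FALSE)

  templates <- NULL; pca <- NULL; amplitudes <- NULL; noise <- NULL
  if (length(need_rec)) {
    wf <- extract_waveforms(recording, sorting, ms_before = p$ms_before,
                            ms_after = p$ms_after,
                            max_spikes_per_unit = p$max_spikes_per_unit,
                            seed = seed)
    templates <- compute_templates(wf)
    if (any(c("drift", "isolation_distance", "l_ratio", "d_prime",
              "nearest_neighbor", "silhouette") %in% metric_names)) {
      pca <- compute_pca_scores(wf, n_comp = p$n_comp, seed = seed)
    }
    if ("snr" %in% metric_names) {
      noise <- estimate_noise_levels(recording, seed = seed)
    }
    if ("amplitude_cutoff" %in% metric_names) {
      amplitudes <- compute_spike_amplitudes(recording, sorting,
                                             peak_sign = p$peak_sign,
                                             templates = templates, seed = seed)
    }
  }
  for (m in metric_names) {
    switch(m,
      firing_rate = {
        tab$firing_rate <- vapply(ids, function(u) firing_rate(sorting, u, duration), 1)
      },
      presence_ratio = {
        tab$presence_ratio <- vapply(ids, function(u) {
          presence_ratio(sorting, u, duration, num_bins = p$num_bins)
        }, 1)
      },
      isi_violation_ratio = {
        tab$isi_violation_ratio <- vapply(ids, function(u) {
          isi_violation_ratio(sorting, u, duration,
                              isi_threshold_ms = p$isi_threshold_ms,
                              min_isi_ms = p$min_isi_ms)
        }, 1)
      },
      snr = {
        tab$snr <- unname(snr(templates, noise))
      },
      amplitude_cutoff = {
        tab$amplitude_cutoff <- vapply(ids, function(u) {
          a <- amplitudes[[u]]
          if (identical(p$peak_sign, "neg")) a <- -a
          amplitude_cutoff(a, num_bins = p$amp_num_bins, smoothing = p$amp_smoothing)
        }, 1)
      },
      drift = {
        dm <- lapply(ids, function(u) {
          drift_metrics(pca, u, interval_s = p$interval_s,
                        min_spikes_per_interval = p$min_spikes_per_interval)
        })
        tab$max_drift_um <- vapply(dm, `[[`, 1, "max_drift_um")
        tab$cumulative_drift_um <- vapply(dm, `[[`, 1, "cumulative_drift_um")
      },
      isolation_distance = {
        tab$isolation_distance <- vapply(ids, function(u) isolation_distance(pca, u), 1)
      },
      l_ratio = {
        tab$l_ratio <- vapply(ids, function(u) l_ratio(pca, u), 1)
      },
      d_prime = {
        tab$d_prime <- vapply(ids, function(u) d_prime(pca, u), 1)
      },
      nearest_neighbor = {
        nn <- lapply(ids, function(u) {
          nearest_neighbor_metrics(pca, u, n_neighbors = p$n_neighbors,
                                   max_spikes = p$max_spikes, seed = seed)
        })
        tab$nn_hit_rate <- vapply(nn, `[[`, 1, "hit_rate")
        tab$nn_miss_rate <- vapply(nn, `[[`, 1, "miss_rate")
      },
      silhouette = {
        tab$silhouette <- vapply(ids, function(u) {
          silhouette_score(pca, u, max_spikes = p$max_spikes, seed = seed)
        }, 1)
      }
    )
  }
  attr(tab, "params") <- c(p, list(seed = seed, duration = duration,
                                   metric_names = metric_names))
  class(tab) <- c("MetricTable", "data.frame")
  tab
}

#' Write a MetricTable to CSV plus a JSON parameter block
#' @param table a `MetricTable`.
#' @param path output CSV path; the parameter block goes to `path` +
#'   ".params.json".
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE,
                   eol = "\n")
  jsonlite::write_json(attr(table, "params"), paste0(path, ".params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
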