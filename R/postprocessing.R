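#' Extract spike-triggered waveforms
#'
#' Cuts a window of `ms_before` + `ms_after` around every spike of every
#' unit (the spike frame is the first sample of the `ms_after` part). Spikes
#' whose window crosses a recording edge are skipped and counted. Units with
#' more than `max_spikes_per_unit` spikes are subsampled without replacement
#' under the given seed.
#'
#' @param recording a `Recording`.
#' @param sorting a `Sorting` with the same sampling frequency.
#' @param ms_before,ms_after window extent in milliseconds (defaults 1 and 2).
#' @param max_spikes_per_unit cap on waveforms per unit (default 500).
#' @param seed RNG seed for the subsampling.
#' @return a `WaveformSet`: per-unit arrays of shape
#'   (spikes x channels x samples) in microvolts, plus the source spike
#'   frames retained for each unit.
#' @export
extract_waveforms <- function(recording, sorting, ms_before = 1, ms_after = 2,
                              max_spikes_per_unit = 500L, seed = 0L) {
  stopifnot(inherits(recording, "Recording"), inherits(sorting, "Sorting"))
  fs <- recording$sampling_frequency
  if (abs(fs - sorting$sampling_frequency) > 1e-9) {
    sm_stop("recording and sorting sampling frequencies differ")
  }
  nbefore <- round(ms_before * fs / 1000)
  nafter <- round(ms_after * fs / 1000)
  nsamples <- nbefore + nafter
  if (nsamples < 1L) sm_stop("waveform window is empty", type = "parameter")
  ids <- unit_ids(sorting)
  waveforms <- setNames(vector("list", length(ids)), ids)
  frames_used <- setNames(vector("list", length(ids)), ids)
  n_edge <- setNames(integer(length(ids)), ids)
  nch <- recording$num_channels
  with_seed(seed, {
    for (u in ids) {
      tr <- sorting$spike_trains[[u]]
      ok <- tr - nbefore >= 0 & tr + nafter <= recording$num_frames
      n_edge[[u]] <- sum(!ok)
      valid <- tr[ok]
      if (length(valid) > max_spikes_per_unit) {
        valid <- sort(valid[sample.int(length(valid), max_spikes_per_unit)])
      }
      if (length(valid) == 0L) {
        if (length(tr) > 0L) {
          warning(sprintf("unit '%s': all spikes at recording edges; empty waveform set", u))
        }
        waveforms[[u]] <- array(numeric(0), dim = c(0L, nch, nsamples))
        frames_used[[u]] <- numeric(0)
        next
      }
      arr <- array(NA_real_, dim = c(length(valid), nch, nsamples))
      for (s in seq_along(valid)) {
        arr[s, , ] <- get_traces(recording, start_frame = valid[s] - nbefore,
                                 end_frame = valid[s] + nafter)
      }
      waveforms[[u]] <- arr
      frames_used[[u]] <- valid
    }
  })
  structure(list(
    waveforms = waveforms,
    spike_frames = frames_used,
    n_edge_skipped = n_edge,
    ms_before = ms_before, ms_after = ms_after,
    nbefore = nbefore, nafter = nafter, nsamples = nsamples,
    sampling_frequency = fs,
    channel_ids = recording$channel_ids,
    channel_locations = recording$channel_locations,
    max_spikes_per_unit = max_spikes_per_unit,
    seed = seed
  ), class = "WaveformSet")
}

#' Per-unit mean templates
#'
#' @param waveforms a `WaveformSet`.
#' @return a `TemplateSet`: per-unit channels x samples mean waveform in
#'   microvolts and the channel of maximum peak-to-peak amplitude
#'   (`best_channel`). Units with no waveforms get an all-`NA` template and
#'   are listed in `undefined_units`.
#' @export
compute_templates <- function(waveforms) {
  stopifnot(inherits(waveforms, "WaveformSet"))
  ids <- names(waveforms$waveforms)
  templates <- setNames(vector("list", length(ids)), ids)
  best <- setNames(character(length(ids)), ids)
  undefined <- character(0)
  for (u in ids) {
    arr <- waveforms$waveforms[[u]]
    if (dim(arr)[1L] == 0L) {
      templates[[u]] <- matrix(NA_real_, length(waveforms$channel_ids),
                               waveforms$nsamples)
      best[[u]] <- NA_character_
      undefined <- c(undefined, u)
      next
    }
    tpl <- apply(arr, c(2L, 3L), mean)
    rownames(tpl) <- waveforms$channel_ids
    templates[[u]] <- tpl
    p2p <- apply(tpl, 1L, function(r) max(r) - min(r))
    best[[u]] <- waveforms$channel_ids[which.max(p2p)]
  }
  structure(list(
    templates = templates, best_channel = best, undefined_units = undefined,
    nbefore = waveforms$nbefore, nafter = waveforms$nafter,
    sampling_frequency = waveforms$sampling_frequency,
    channel_ids = waveforms$channel_ids,
    channel_locations = waveforms$channel_locations
  ), class = "TemplateSet")
}

#' Per-channel PCA projections of spike waveforms
#'
#' Fits, per channel, a PCA basis on spikes pooled across all units
#' (subsampled to `max_spikes_for_fit` under the seed) and projects every
#' spike of every unit onto the first `n_comp` components.
#'
#' @param waveforms a `WaveformSet`.
#' @param n_comp number of components per channel (default 3).
#' @param mode only `"by_channel"` is implemented.
#' @param max_spikes_for_fit cap on pooled spikes used to fit the basis.
#' @param seed RNG seed for the fit subsample.
#' @return a `PCAScores` object: per-unit arrays (spikes x channels x
#'   n_comp), a pooled feature matrix (spikes x channels*n_comp) with unit
#'   labels, the fitted orthonormal bases, and per-channel component
#'   standard deviations.
#' @export
compute_pca_scores <- function(waveforms, n_comp = 3L, mode = "by_channel",
                               max_spikes_for_fit = 10000L, seed = 0L) {
  stopifnot(inherits(waveforms, "WaveformSet"))
  mode <- match.arg(mode, "by_channel")
  if (n_comp > waveforms$nsamples) {
    sm_stop(sprintf("n_comp (%d) exceeds samples per waveform (%d)",
                    n_comp, waveforms$nsamples), type = "parameter")
  }
  ids <- names(waveforms$waveforms)
  counts <- vapply(ids, function(u) dim(waveforms$waveforms[[u]])[1L], 1L)
  total <- sum(counts)
  if (total < n_comp) sm_stop("fewer spikes than requested components", type = "parameter")
  nch <- length(waveforms$channel_ids)
  labels <- rep(ids, counts)
  fit_rows <- with_seed(seed, {
    if (total > max_spikes_for_fit) sort(sample.int(total, max_spikes_for_fit))
    else seq_len(total)
  })
  basis <- vector("list", nch)
  centers <- vector("list", nch)
  sdevs <- vector("list", nch)
  features <- matrix(NA_real_, total, nch * n_comp)
  per_channel <- vector("list", nch)
  for (c in seq_len(nch)) {
    mat <- do.call(rbind, lapply(ids, function(u) {
      arr <- waveforms$waveforms[[u]]
      if (dim(arr)[1L] == 0L) NULL else matrix(arr[, c, ], nrow = dim(arr)[1L])
    }))
    p <- stats::prcomp(mat[fit_rows, , drop = FALSE], center = TRUE, scale. = FALSE)
    k <- min(n_comp, ncol(p$rotation))
    rot <- p$rotation[, seq_len(k), drop = FALSE]
    sc <- sweep(mat, 2L, p$center, "-") %*% rot
    if (k < n_comp) sc <- cbind(sc, matrix(0, nrow(sc), n_comp - k))
    features[, ((c - 1L) * n_comp + 1L):(c * n_comp)] <- sc
    per_channel[[c]] <- sc
    basis[[c]] <- rot
    centers[[c]] <- p$center
    sdevs[[c]] <- p$sdev[seq_len(k)]
  }
  scores <- setNames(vector("list", length(ids)), ids)
  offset <- 0L
  for (u in ids) {
    n <- counts[[u]]
    arr <- array(NA_real_, dim = c(n, nch, n_comp))
    if (n > 0L) {
      rows <- (offset + 1L):(offset + n)
      for (c in seq_len(nch)) arr[, c, ] <- per_channel[[c]][rows, , drop = FALSE]
    }
    scores[[u]] <- arr
    offset <- offset + n
  }
  structure(list(
    scores = scores, features = features, labels = labels,
    spike_frames = waveforms$spike_frames,
    basis = basis, centers = centers, sdev = sdevs,
    n_comp = n_comp,
    channel_ids = waveforms$channel_ids,
    channel_locations = waveforms$channel_locations,
    sampling_frequency = waveforms$sampling_frequency,
    seed = seed
  ), class = "PCAScores")
}

#' Build a PCAScores object from a plain feature matrix
#'
#' Convenience constructor for computing the cluster-separation quality
#' metrics on externally supplied features (one row per spike).
#'
#' @param features numeric matrix, spikes x dimensions.
#' @param labels unit label per row.
#' @param spike_frames optional named list of spike frames per unit.
#' @param channel_locations,sampling_frequency optional geometry/timing
#'   needed only by the drift metrics.
#' @return a `PCAScores` object.
#' @export
pca_scores_from_matrix <- function(features, labels, spike_frames = NULL,
                                   channel_locations = NULL,
                                   sampling_frequency = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  structure(list(
    scores = NULL, features = features, labels = labels,
    spike_frames = spike_frames, basis = NULL, centers = NULL, sdev = NULL,
    n_comp = ncol(features), channel_ids = NULL,
    channel_locations = channel_locations,
    sampling_frequency = sampling_frequency
  ), class = "PCAScores")
}

#' Template shape features (peak-to-valley, FWHM)
#'
#' Computed on each unit's best channel. The trough is the extremum of
#' larger absolute amplitude (ties broken toward negative); for
#' positive-going templates the same logic applies with signs flipped.
#' `peak_to_valley_ms` is the time from the trough to the subsequent
#' opposite-sign extremum; `fwhm_ms` is the width of the trough at half its
#' amplitude, linearly interpolated between samples. Flat templates yield
#' `NA` features.
#'
#' @param templates a `TemplateSet`.
#' @return data.frame with columns `unit_id`, `peak_to_valley_ms`, `fwhm_ms`.
#' @export
compute_template_features <- function(templates) {
  stopifnot(inherits(templates, "TemplateSet"))
  fs <- templates$sampling_frequency
  ids <- names(templates$templates)
  out <- data.frame(unit_id = ids, peak_to_valley_ms = NA_real_,
                    fwhm_ms = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    u <- ids[i]
    bc <- templates$best_channel[[u]]
    if (is.na(bc)) next
    w <- templates$templates[[u]][match(bc, templates$channel_ids), ]
    if (max(w) - min(w) < .Machine$double.eps * 100) next  # flat: undefined
    cand <- which(abs(w) == max(abs(w)))
    i0 <- cand[order(w[cand])][1L]  # tie toward negative
    m <- w[i0]
    n <- length(w)
    if (i0 < n) {
      seg <- w[(i0 + 1L):n] * (-sign(m))
      i1 <- i0 + which.max(seg)
      out$peak_to_valley_ms[i] <- (i1 - i0) / fs * 1000
    }
    half <- m / 2
    # crossing of the half-amplitude level on each side of the trough,
    # linear interpolation between neighbouring samples
    rel <- w * sign(m) - half * sign(m)  # positive inside the trough lobe
    left <- i0
    while (left > 1L && rel[left - 1L] > 0) left <- left - 1L
    xl <- if (left == 1L) 1 else left - rel[left] / (rel[left - 1L] - rel[left])
    right <- i0
    while (right < n && rel[right + 1L] > 0) right <- right + 1L
    xr <- if (right == n) n else right + rel[right] / (rel[right + 1L] - rel[right])
    out$fwhm_ms[i] <- (xr - xl) / fs * 1000
  }
  out
}

#' Per-spike amplitudes at the unit's best channel
#'
#' The amplitude of a spike is the extremum of the trace on the unit's best
#' channel within +/- `search_ms` of the spike frame (window truncated at
#' recording edges).
#'
#' @param recording a `Recording`.
#' @param sorting a `Sorting`.
#' @param peak_sign `"neg"` (minimum, default), `"pos"` (maximum) or
#'   `"both"` (extremum of larger magnitude).
#' @param templates optional `TemplateSet` supplying each unit's best
#'   channel; computed internally when omitted.
#' @param search_ms half-width of the search window in milliseconds.
#' @param seed seed for the internal template computation.
#' @return named list: per unit, a numeric vector of amplitudes in
#'   microvolts, one per spike.
#' @export
compute_spike_amplitudes <- function(recording, sorting,
                                     peak_sign = c("neg", "pos", "both"),
                                     templates = NULL, search_ms = 0.1,
                                     seed = 0L) {
  peak_sign <- match.arg(peak_sign)
  if (is.null(templates)) {
    wf <- extract_waveforms(recording, sorting, max_spikes_per_unit = 100L,
                            seed = seed)
    templates <- compute_templates(wf)
  }
  fs <- recording$sampling_frequency
  sw <- round(search_ms * fs / 1000)
  out <- setNames(vector("list", n_units(sorting)), unit_ids(sorting))
  for (u in unit_ids(sorting)) {
    tr <- sorting$spike_trains[[u]]
    bc <- templates$best_channel[[u]]
    if (is.na(bc) || length(tr) == 0L) {
      out[[u]] <- numeric(length(tr)) * NA_real_
      next
    }
    amps <- numeric(length(tr))
    for (s in seq_along(tr)) {
      a <- max(0, tr[s] - sw)
      b <- min(recording$num_frames, tr[s] + sw + 1)
      x <- get_traces(recording, channel_ids = bc, start_frame = a, end_frame = b)
      amps[s] <- switch(peak_sign,
        neg = min(x),
        pos = max(x),
        both = x[which.max(abs(x))]
      )
    }
    out[[u]] <- amps
  }
  out
}

#' MAD-based per-channel noise levels
#'
#' Estimates the noise standard deviation of every channel as the median
#' absolute deviation scaled by 1/0.6745 (Gaussian consistency), computed on
#' seeded random chunks of the recording.
#'
#' @param recording a `Recording`.
#' @param method only `"mad"` is implemented.
#' @param chunk_seconds length of each sampled chunk (default 1 s).
#' @param num_chunks number of chunks (default 20; fewer if the recording is
#'   short).
#' @param seed RNG seed for chunk placement.
#' @return named numeric vector of per-channel sigma in microvolts.
#' @export
estimate_noise_levels <- function(recording, method = "mad", chunk_seconds = 1,
                                  num_chunks = 20L, seed = 0L) {
  stopifnot(inherits(recording, "Recording"))
  method <- match.arg(method, "mad")
  fs <- recording$sampling_frequency
  chunk_frames <- max(1, round(chunk_seconds * fs))
  nf <- recording$num_frames
  if (chunk_frames * num_chunks >= nf) {
    x <- get_traces(recording)
  } else {
    starts <- with_seed(seed, sort(sample.int(nf - chunk_frames, num_chunks)))
    x <- do.call(cbind, lapply(starts, function(s) {
      get_traces(recording, start_frame = s, end_frame = s + chunk_frames)
    }))
  }
  sig <- apply(x, 1L, function(row) stats::mad(row, constant = 1 / 0.6745))
  setNames(sig, recording$channel_ids)
}
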