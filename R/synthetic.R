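# Seeded synthetic benchmark generators: Poisson ground-truth sortings with
# refractory periods, template-plus-Gaussian-noise recordings on a grid
# probe, corrupted pseudo-sorter outputs with controlled failure modes, and
# a multi-sorter consensus scenario with a planted truth table. All
# generators are pure functions of their parameters (seed included).

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset * 7919) %% (2^31 - 1))
}

thin_refractory <- function(frames, refr_frames) {
  if (length(frames) < 2L || refr_frames <= 0) return(frames)
  keep <- logical(length(frames))
  last <- -Inf
  for (i in seq_along(frames)) {
    if (frames[i] - last >= refr_frames) {
      keep[i] <- TRUE
      last <- frames[i]
    }
  }
  frames[keep]
}

# strictly increasing trains: nudge exact collisions forward by one frame
dedupe_nudge <- function(frames) {
  frames <- sort(frames)
  repeat {
    d <- which(diff(frames) == 0)
    if (!length(d)) return(frames)
    frames[d + 1L] <- frames[d + 1L] + 1
    frames <- sort(frames)
  }
}

#' Generate a ground-truth sorting of independent Poisson units
#'
#' Each unit fires as an independent Poisson process of the given rate,
#' thinned so that no inter-spike interval is shorter than the refractory
#' period (the later spike of a violating pair is deleted).
#'
#' @param n_units number of units (default 10).
#' @param firing_rate Hz; a scalar (all units), a length-2 range (uniform
#'   per unit) or one value per unit. Default 5.
#' @param duration recording duration in seconds (default 300).
#' @param refractory_ms refractory period in milliseconds (default 2).
#' @param sampling_frequency Hz (default 30000).
#' @param seed RNG seed; the same seed reproduces the same sorting exactly.
#' @return a `Sorting` with units `"1".."n_units"`.
#' @export
generate_gt_sorting <- function(n_units = 10L, firing_rate = 5, duration = 300,
                                refractory_ms = 2, sampling_frequency = 30000,
                                seed = 0L) {
  if (!is_count(n_units)) sm_stop("n_units must be a positive integer", type = "parameter")
  if (any(firing_rate <= 0)) sm_stop("firing rates must be positive", type = "parameter")
  if (refractory_ms < 0) sm_stop("refractory period must be >= 0", type = "parameter")
  total_frames <- floor(duration * sampling_frequency)
  refr_frames <- round(refractory_ms * sampling_frequency / 1000)
  trains <- with_seed(seed, {
    rates <- if (length(firing_rate) == 1L) {
      rep(firing_rate, n_units)
    } else if (length(firing_rate) == 2L && n_units != 2L) {
      stats::runif(n_units, firing_rate[1L], firing_rate[2L])
    } else if (length(firing_rate) == n_units) {
      firing_rate
    } else {
      sm_stop("firing_rate must be scalar, a range, or one value per unit",
              type = "parameter")
    }
    lapply(seq_len(n_units), function(i) {
      n <- stats::rpois(1L, rates[i] * duration)
      n <- min(n, total_frames)
      fr <- sort(sample.int(total_frames, n)) - 1
      thin_refractory(fr, refr_frames)
    })
  })
  names(trains) <- as.character(seq_len(n_units))
  Sorting(trains, sampling_frequency,
          provenance = new_provenance(list(
            kind = "synthetic", generator = "generate_gt_sorting",
            params = list(n_units = n_units, firing_rate = firing_rate,
                          duration = duration, refractory_ms = refractory_ms,
                          sampling_frequency = sampling_frequency, seed = seed)
          )))
}

# biphasic template shape: Gaussian trough plus delayed repolarization bump,
# normalized so the trough equals exactly -amplitude at sample `nbefore + 1`
biphasic_shape <- function(fs, amplitude, nbefore, nafter,
                           trough_sd_ms = 0.1, bump_delay_ms = 0.5,
                           bump_sd_ms = 0.2, bump_frac = 0.3) {
  k <- seq_len(nbefore + nafter) - (nbefore + 1L)
  s1 <- trough_sd_ms * fs / 1000
  s2 <- bump_sd_ms * fs / 1000
  g <- bump_delay_ms * fs / 1000
  w <- -exp(-0.5 * (k / s1)^2) + bump_frac * exp(-0.5 * ((k - g) / s2)^2)
  w / max(abs(w)) * amplitude
}

#' Synthesize a recording from a ground-truth sorting
#'
#' Places each unit at a location on (or between) the electrodes of a grid
#' probe, injects a biphasic template at every spike frame with per-channel
#' amplitude decaying as `exp(-distance / decay_um)`, and adds white
#' Gaussian noise of standard deviation `noise_sd` (default 10 microvolts).
#' The planted templates, unit locations and noise level are retrievable
#' from the returned object (`$gt_templates`, `$unit_locations`,
#' `$noise_sd`).
#'
#' @param gt a ground-truth `Sorting`.
#' @param probe_rows,probe_cols grid probe layout (default 4 x 2).
#' @param pitch_um electrode pitch in micrometres (default 25).
#' @param amplitude_uv template trough amplitude in microvolts; scalar or a
#'   length-2 range sampled per unit (default 100).
#' @param decay_um spatial decay constant in micrometres (default 30).
#' @param noise_sd additive Gaussian noise sigma in microvolts (default 10).
#' @param duration_s recording length in seconds; default spans the last
#'   spike plus the template tail.
#' @param unit_locations optional n_units x 2 matrix of locations in
#'   micrometres; random within the probe bounds when omitted.
#' @param seed RNG seed.
#' @return an in-memory `Recording` in microvolts.
#' @export
synthesize_recording <- function(gt, probe_rows = 4L, probe_cols = 2L,
                                 pitch_um = 25, amplitude_uv = 100,
                                 decay_um = 30, noise_sd = 10,
                                 duration_s = NULL, unit_locations = NULL,
                                 seed = 0L) {
  stopifnot(inherits(gt, "Sorting"))
  if (any(amplitude_uv <= 0)) sm_stop("amplitude must be positive", type = "parameter")
  if (decay_um <= 0) sm_stop("decay constant must be positive", type = "parameter")
  if (noise_sd < 0) sm_stop("noise_sd must be >= 0", type = "parameter")
  fs <- gt$sampling_frequency
  nbefore <- round(0.5e-3 * fs)
  nafter <- round(1.5e-3 * fs)
  max_spike <- max(c(0, unlist(gt$spike_trains)))
  num_frames <- if (is.null(duration_s)) {
    max_spike + nafter + 1
  } else {
    floor(duration_s * fs)
  }
  nch <- probe_rows * probe_cols
  locs <- cbind(
    x = rep(seq_len(probe_cols) - 1L, each = probe_rows) * pitch_um,
    y = rep(seq_len(probe_rows) - 1L, times = probe_cols) * pitch_um
  )
  ids <- unit_ids(gt)
  if (!is.null(unit_locations) && is.list(unit_locations)) {
    unit_locations <- do.call(rbind, lapply(unit_locations, unlist))
  }
  params_for_prov <- list(
    probe_rows = probe_rows, probe_cols = probe_cols, pitch_um = pitch_um,
    amplitude_uv = amplitude_uv, decay_um = decay_um, noise_sd = noise_sd,
    duration_s = duration_s, unit_locations = unit_locations, seed = seed,
    gt_provenance = unclass(gt$provenance)
  )
  traces <- NULL
  gt_templates <- setNames(vector("list", length(ids)), ids)
  with_seed(seed, {
    amps <- if (length(amplitude_uv) == 2L) {
      stats::runif(length(ids), amplitude_uv[1L], amplitude_uv[2L])
    } else {
      rep(amplitude_uv, length.out = length(ids))
    }
    if (is.null(unit_locations)) {
      unit_locations <- cbind(
        stats::runif(length(ids), 0, max(locs[, 1])),
        stats::runif(length(ids), 0, max(locs[, 2]))
      )
    }
    traces <- matrix(stats::rnorm(nch * num_frames, 0, noise_sd), nch, num_frames)
    for (i in seq_along(ids)) {
      shape <- biphasic_shape(fs, amps[i], nbefore, nafter)
      dists <- sqrt((locs[, 1] - unit_locations[i, 1])^2 +
                    (locs[, 2] - unit_locations[i, 2])^2)
      scales <- exp(-dists / decay_um)
      tpl <- outer(scales, shape)
      gt_templates[[ids[i]]] <- tpl
      for (f in gt$spike_trains[[i]]) {
        a <- f - nbefore
        b <- f + nafter - 1
        sa <- max(0, a); sb <- min(num_frames - 1, b)
        if (sb < sa) next
        cols <- (sa + 1):(sb + 1)
        traces[, cols] <- traces[, cols] + tpl[, (sa - a + 1):(sb - a + 1), drop = FALSE]
      }
    }
  })
  rec <- matrix_recording(traces, fs, channel_locations = locs,
                          provenance = new_provenance(list(
                            kind = "synthetic", generator = "synthesize_recording",
                            params = params_for_prov
                          )))
  rec$gt_templates <- gt_templates
  rec$unit_locations <- unit_locations
  rec$noise_sd <- noise_sd
  rec$template_nbefore <- nbefore
  rec
}

#' Corrupt a ground-truth sorting with controlled sorter failure modes
#'
#' Applies, per unit and in order: i.i.d. spike deletion (`miss_prob`),
#' Gaussian timing jitter rounded to integer frames (`jitter_sd_ms`),
#' insertion of uniformly random false-positive spikes (`fp_rate` Hz); then
#' splits (alternate spikes of a unit into two new units), merges
#' (concatenation of unit pairs) and appended uniform-rate noise units.
#' Exact frame collisions after jitter are nudged forward by one frame so
#' trains stay strictly increasing.
#'
#' @param gt a ground-truth `Sorting`.
#' @param jitter_sd_ms timing jitter sigma in milliseconds (default 0).
#' @param miss_prob per-spike deletion probability in `[0, 1)` (default 0).
#' @param fp_rate rate of inserted false-positive spikes per unit, Hz
#'   (default 0).
#' @param n_noise_units number of appended pure-noise units (default 0).
#' @param noise_rate firing rate of noise units, Hz (default 5).
#' @param split_units unit ids to split in two (`<id>_split1/2`).
#' @param merge_unit_pairs list of unit id pairs to fuse (`<a>+<b>`).
#' @param duration duration in seconds used for inserted spikes; default
#'   spans the last ground-truth spike.
#' @param seed RNG seed.
#' @return a corrupted `Sorting`.
#' @export
corrupt_sorting <- function(gt, jitter_sd_ms = 0, miss_prob = 0, fp_rate = 0,
                            n_noise_units = 0L, noise_rate = 5,
                            split_units = NULL, merge_unit_pairs = NULL,
                            duration = NULL, seed = 0L) {
  stopifnot(inherits(gt, "Sorting"))
  if (miss_prob < 0 || miss_prob >= 1) sm_stop("miss_prob must be in [0, 1)", type = "parameter")
  if (fp_rate < 0 || jitter_sd_ms < 0) sm_stop("rates must be >= 0", type = "parameter")
  fs <- gt$sampling_frequency
  duration <- duration %||% ((max(c(0, unlist(gt$spike_trains))) + 1) / fs)
  total_frames <- floor(duration * fs)
  params <- list(jitter_sd_ms = jitter_sd_ms, miss_prob = miss_prob,
                 fp_rate = fp_rate, n_noise_units = n_noise_units,
                 noise_rate = noise_rate, split_units = split_units,
                 merge_unit_pairs = merge_unit_pairs, duration = duration,
                 seed = seed)
  trains <- with_seed(seed, {
    out <- lapply(unit_ids(gt), function(u) {
      tr <- gt$spike_trains[[u]]
      if (miss_prob > 0 && length(tr)) tr <- tr[stats::runif(length(tr)) >= miss_prob]
      if (jitter_sd_ms > 0 && length(tr)) {
        tr <- tr + round(stats::rnorm(length(tr), 0, jitter_sd_ms * fs / 1000))
        tr <- pmax(tr, 0)
      }
      if (fp_rate > 0) {
        n_fp <- stats::rpois(1L, fp_rate * duration)
        tr <- c(tr, sample.int(total_frames, min(n_fp, total_frames)) - 1)
      }
      dedupe_nudge(tr)
    })
    names(out) <- unit_ids(gt)
    for (u in as.character(split_units %||% character(0))) {
      if (!u %in% names(out)) sm_stop(sprintf("cannot split unknown unit '%s'", u))
      tr <- out[[u]]
      out[[u]] <- NULL
      out[[paste0(u, "_split1")]] <- tr[seq_along(tr) %% 2L == 1L]
      out[[paste0(u, "_split2")]] <- tr[seq_along(tr) %% 2L == 0L]
    }
    for (pair in merge_unit_pairs %||% list()) {
      pair <- as.character(pair)
      if (!all(pair %in% names(out))) sm_stop("cannot merge unknown units")
      merged <- dedupe_nudge(c(out[[pair[1L]]], out[[pair[2L]]]))
      out[[pair[1L]]] <- NULL
      out[[pair[2L]]] <- NULL
      out[[paste(pair, collapse = "+")]] <- merged
    }
    if (n_noise_units > 0) {
      for (i in seq_len(n_noise_units)) {
        n <- stats::rpois(1L, noise_rate * duration)
        out[[paste0("noise", i)]] <- sort(sample.int(total_frames, min(n, total_frames))) - 1
      }
    }
    out
  })
  Sorting(trains, fs, provenance = prov_append(gt$provenance, "corrupt_sorting", params))
}

#' Generate a planted multi-sorter comparison scenario
#'
#' Emulates an ensemble of imperfect sorters run on the same ground truth:
#' each pseudo-sorter detects a seeded random subset of the ground-truth
#' units (probability `detection_prob` per unit), reproduces each detected
#' train with misses and timing jitter, and adds its own private noise
#' units. The returned truth table marks every emitted unit as true or noise
#' and records its planted agreement count k (the number of sorters that
#' detected its ground-truth unit; 1 for noise units).
#'
#' @param n_sorters number of pseudo-sorters (default 6).
#' @param n_units ground-truth units (default 40).
#' @param duration seconds (default 300).
#' @param firing_rate Hz (default 5).
#' @param refractory_ms ground-truth refractory period (default 2 ms).
#' @param sampling_frequency Hz (default 30000).
#' @param detection_prob per-sorter probability of detecting each unit
#'   (default 0.8).
#' @param miss_prob per-spike miss probability in detected units (default 0.1).
#' @param jitter_sd_ms spike timing jitter sigma (default 0.1 ms).
#' @param n_noise_units private noise units per sorter (default 10).
#' @param noise_rate firing rate of noise units, Hz (default 5).
#' @param seed RNG seed.
#' @return list with `gt` (the ground truth `Sorting`), `sortings` (named
#'   list of pseudo-sorter `Sorting`s), `truth` (data.frame `sorter`,
#'   `unit`, `is_true`, `gt_unit`, `planted_k`) and `params`.
#' @export
generate_comparison_scenario <- function(n_sorters = 6L, n_units = 40L,
                                         duration = 300, firing_rate = 5,
                                         refractory_ms = 2,
                                         sampling_frequency = 30000,
                                         detection_prob = 0.8, miss_prob = 0.1,
                                         jitter_sd_ms = 0.1,
                                         n_noise_units = 10L, noise_rate = 5,
                                         seed = 0L) {
  if (n_sorters < 2L) sm_stop("need at least 2 sorters", type = "parameter")
  gt <- generate_gt_sorting(n_units = n_units, firing_rate = firing_rate,
                            duration = duration, refractory_ms = refractory_ms,
                            sampling_frequency = sampling_frequency, seed = seed)
  detected <- with_seed(derive_seed(seed, 1L), {
    matrix(stats::rbinom(n_sorters * n_units, 1L, detection_prob) == 1L,
           n_sorters, n_units)
  })
  planted_k <- colSums(detected)
  labels <- paste0("sorter", seq_len(n_sorters))
  sortings <- setNames(vector("list", n_sorters), labels)
  truth <- list()
  for (s in seq_len(n_sorters)) {
    det_units <- unit_ids(gt)[detected[s, ]]
    base <- select_units(gt, det_units)
    sortings[[s]] <- corrupt_sorting(base, jitter_sd_ms = jitter_sd_ms,
                                     miss_prob = miss_prob,
                                     n_noise_units = n_noise_units,
                                     noise_rate = noise_rate,
                                     duration = duration,
                                     seed = derive_seed(seed, 100L + s))
    ids <- unit_ids(sortings[[s]])
    is_true <- !grepl("^noise", ids)
    truth[[s]] <- data.frame(
      sorter = labels[s], unit = ids, is_true = is_true,
      gt_unit = ifelse(is_true, ids, NA_character_),
      planted_k = ifelse(is_true, planted_k[match(ids, unit_ids(gt))], 1L),
      stringsAsFactors = FALSE
    )
  }
  list(gt = gt, sortings = sortings, truth = do.call(rbind, truth),
       params = list(n_sorters = n_sorters, n_units = n_units,
                     duration = duration, firing_rate = firing_rate,
                     refractory_ms = refractory_ms,
                     sampling_frequency = sampling_frequency,
                     detection_prob = detection_prob, miss_prob = miss_prob,
                     jitter_sd_ms = jitter_sd_ms,
                     n_noise_units = n_noise_units, noise_rate = noise_rate,
                     seed = seed))
}
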