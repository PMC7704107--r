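# Lazy preprocessing stages. Each stage is itself a Recording (substitutable
# everywhere a Recording is accepted); trace computation happens only when
# get_traces() is called, and chaining N stages composes the transforms in
# order. Filter stages read an overlap margin around the requested range so
# chunked reads match an eager full-trace filter away from recording edges.

processed_recording <- function(parent, name, params, trace_fn,
                                channel_ids = parent$channel_ids,
                                channel_locations = parent$channel_locations) {
  rec <- new_recording(
    trace_fn = trace_fn,
    num_channels = length(channel_ids),
    num_frames = parent$num_frames,
    sampling_frequency = parent$sampling_frequency,
    channel_ids = channel_ids,
    channel_locations = channel_locations,
    provenance = prov_append(parent$provenance, name, params)
  )
  rec$parent <- parent
  rec$stage <- list(name = name, params = params)
  class(rec) <- c("ProcessedRecording", "Recording")
  rec
}

FILTER_MARGIN_FRAMES <- 1024L

filtered_recording <- function(recording, name, params, b, a) {
  trace_fn <- function(ch_idx, start, end) {
    if (end == start) return(matrix(numeric(0), length(ch_idx), 0))
    s0 <- max(0, start - FILTER_MARGIN_FRAMES)
    e0 <- min(recording$num_frames, end + FILTER_MARGIN_FRAMES)
    x <- get_traces(recording, channel_ids = recording$channel_ids[ch_idx],
                    start_frame = s0, end_frame = e0)
    y <- t(apply(x, 1L, function(row) signal::filtfilt(b, a, row)))
    if (nrow(x) == 1L) y <- matrix(y, nrow = 1L)
    y[, seq.int(start - s0 + 1L, length.out = end - start), drop = FALSE]
  }
  processed_recording(recording, name, params, trace_fn)
}

#' Zero-phase band-pass filter (lazy)
#'
#' Butterworth IIR band-pass of the given order, applied forward and backward
#' (`signal::filtfilt`) so spike timing is preserved. Output length equals
#' input length.
#'
#' @param recording a `Recording`.
#' @param freq_min,freq_max band edges in Hz; must satisfy
#'   `0 < freq_min < freq_max < sampling_frequency/2`.
#' @param order filter order before the forward-backward doubling (default 3).
#' @return a `ProcessedRecording`.
#' @export
bandpass_filter <- function(recording, freq_min = 300, freq_max = 6000, order = 3L) {
  stopifnot(inherits(recording, "Recording"))
  nyq <- recording$sampling_frequency / 2
  if (!(freq_min > 0 && freq_min < freq_max && freq_max < nyq)) {
    sm_stop(sprintf("band [%g, %g] Hz must lie strictly inside (0, %g) Hz",
                    freq_min, freq_max, nyq), type = "parameter")
  }
  bt <- signal::butter(order, c(freq_min, freq_max) / nyq, type = "pass")
  filtered_recording(recording, "bandpass_filter",
                     list(freq_min = freq_min, freq_max = freq_max, order = order),
                     bt$b, bt$a)
}

#' Zero-phase notch filter (lazy)
#'
#' Second-order biquad notch (centre frequency `freq`, quality factor `q`)
#' applied forward and backward. Attenuation is strong at `freq` and
#' negligible far from it.
#'
#' @param recording a `Recording`.
#' @param freq notch centre frequency in Hz, inside (0, Nyquist).
#' @param q dimensionless quality factor (bandwidth = freq/q), default 30.
#' @return a `ProcessedRecording`.
#' @export
notch_filter <- function(recording, freq = 50, q = 30) {
  stopifnot(inherits(recording, "Recording"))
  nyq <- recording$sampling_frequency / 2
  if (!(freq > 0 && freq < nyq)) {
    sm_stop(sprintf("notch frequency %g Hz outside (0, %g) Hz", freq, nyq),
            type = "parameter")
  }
  if (!is_scalar_num(q) || q <= 0) sm_stop("q must be positive", type = "parameter")
  w0 <- 2 * pi * freq / recording$sampling_frequency
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  filtered_recording(recording, "notch_filter", list(freq = freq, q = q), b, a)
}

#' Common reference subtraction (lazy)
#'
#' Subtracts, at every frame, the median (or mean) across all channels from
#' every channel — the standard global re-referencing step that removes
#' signal components common to the whole probe.
#'
#' @param recording a `Recording` with at least two channels.
#' @param mode `"median"` (default) or `"average"`.
#' @return a `ProcessedRecording`.
#' @export
common_reference <- function(recording, mode = c("median", "average")) {
  stopifnot(inherits(recording, "Recording"))
  mode <- match.arg(mode)
  if (recording$num_channels < 2L) {
    sm_stop("common reference requires at least 2 channels", type = "parameter")
  }
  trace_fn <- function(ch_idx, start, end) {
    x <- get_traces(recording, start_frame = start, end_frame = end)
    ref <- if (mode == "median") apply(x, 2L, stats::median) else colMeans(x)
    y <- sweep(x, 2L, ref, "-")
    y[ch_idx, , drop = FALSE]
  }
  processed_recording(recording, "common_reference", list(mode = mode), trace_fn)
}

#' Drop channels from a Recording (lazy)
#'
#' @param recording a `Recording`.
#' @param channel_ids_to_remove channel ids to drop. Removing every channel
#'   is an error; traces of the remaining channels are unchanged and their
#'   probe locations are carried over.
#' @return a `ProcessedRecording`.
#' @export
remove_channels <- function(recording, channel_ids_to_remove) {
  stopifnot(inherits(recording, "Recording"))
  channel_ids_to_remove <- as.character(channel_ids_to_remove)
  unknown <- setdiff(channel_ids_to_remove, recording$channel_ids)
  if (length(unknown)) {
    sm_stop(sprintf("unknown channel id(s): %s", paste(unknown, collapse = ", ")),
            type = "parameter")
  }
  keep <- setdiff(recording$channel_ids, channel_ids_to_remove)
  if (length(keep) == 0L) {
    sm_stop("removing all channels would leave an empty recording", type = "parameter")
  }
  trace_fn <- function(ch_idx, start, end) {
    get_traces(recording, channel_ids = keep[ch_idx],
               start_frame = start, end_frame = end)
  }
  processed_recording(recording, "remove_channels",
                      list(channel_ids = channel_ids_to_remove),
                      trace_fn,
                      channel_ids = keep,
                      channel_locations = recording$channel_locations[keep, , drop = FALSE])
}
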