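#' Construct a Recording from an arbitrary trace source
#'
#' Low-level constructor. `trace_fn(channel_indices, start_frame, end_frame)`
#' must return a |channels| x |frames| numeric matrix in microvolts for the
#' half-open frame range `[start_frame, end_frame)` (0-based). The function
#' is only invoked when traces are requested, so recordings backed by files
#' are lazy: construction reads no trace bytes.
#'
#' @param trace_fn trace accessor function, see above.
#' @param num_channels,num_frames dimensions of the trace source.
#' @param sampling_frequency sampling rate in Hz.
#' @param channel_ids unique channel identifiers (default `"1".."n"`).
#' @param channel_locations `num_channels` x 2 matrix of electrode
#'   coordinates in micrometres.
#' @param provenance internal provenance record.
#' @return an object of class `Recording`.
#' @export
new_recording <- function(trace_fn, num_channels, num_frames, sampling_frequency,
                          channel_ids = NULL, channel_locations = NULL,
                          provenance = NULL) {
  if (!is.function(trace_fn)) sm_stop("trace_fn must be a function")
  if (!is_count(num_channels)) sm_stop("num_channels must be a positive integer")
  if (!is_count(num_frames, positive = FALSE)) sm_stop("num_frames must be a non-negative integer")
  if (!is_scalar_num(sampling_frequency) || sampling_frequency <= 0) {
    sm_stop("sampling_frequency must be positive")
  }
  channel_ids <- as.character(channel_ids %||% seq_len(num_channels))
  if (length(channel_ids) != num_channels || anyDuplicated(channel_ids)) {
    sm_stop("channel_ids must be unique and match num_channels")
  }
  if (is.null(channel_locations)) {
    channel_locations <- cbind(0, seq_len(num_channels) * 20)
  }
  channel_locations <- as.matrix(channel_locations)
  if (nrow(channel_locations) != num_channels || ncol(channel_locations) != 2L) {
    sm_stop("channel_locations must be a num_channels x 2 matrix")
  }
  rownames(channel_locations) <- channel_ids
  structure(list(
    trace_fn = trace_fn,
    num_channels = as.integer(num_channels),
    num_frames = as.numeric(num_frames),
    sampling_frequency = as.numeric(sampling_frequency),
    channel_ids = channel_ids,
    channel_locations = channel_locations,
    provenance = provenance %||% new_provenance(list(kind = "memory"))
  ), class = "Recording")
}

#' Construct an in-memory Recording from a trace matrix
#'
#' @param traces channels x frames numeric matrix in microvolts.
#' @param sampling_frequency sampling rate in Hz.
#' @inheritParams new_recording
#' @return a `Recording`.
#' @export
matrix_recording <- function(traces, sampling_frequency, channel_ids = NULL,
                             channel_locations = NULL, provenance = NULL) {
  traces <- as.matrix(traces)
  new_recording(
    trace_fn = function(ch_idx, start, end) {
      traces[ch_idx, seq.int(start + 1L, length.out = end - start), drop = FALSE]
    },
    num_channels = nrow(traces), num_frames = ncol(traces),
    sampling_frequency = sampling_frequency,
    channel_ids = channel_ids, channel_locations = channel_locations,
    provenance = provenance
  )
}

#' Read traces from a Recording
#'
#' @param recording a `Recording`.
#' @param channel_ids channels to read, in the requested order (default all).
#' @param start_frame,end_frame half-open 0-based frame range
#'   `[start_frame, end_frame)`; defaults to the full recording.
#' @return a |channels| x |frames| numeric matrix in microvolts. Repeated
#'   reads of the same range return identical values.
#' @export
get_traces <- function(recording, channel_ids = NULL, start_frame = 0,
                       end_frame = NULL) {
  stopifnot(inherits(recording, "Recording"))
  end_frame <- end_frame %||% recording$num_frames
  if (start_frame < 0 || end_frame > recording$num_frames || start_frame > end_frame) {
    sm_stop(sprintf("frame range [%s, %s) out of bounds (num_frames = %s)",
                    start_frame, end_frame, recording$num_frames))
  }
  channel_ids <- as.character(channel_ids %||% recording$channel_ids)
  ch_idx <- match(channel_ids, recording$channel_ids)
  if (anyNA(ch_idx)) {
    sm_stop(sprintf("unknown channel id(s): %s",
                    paste(channel_ids[is.na(ch_idx)], collapse = ", ")))
  }
  out <- recording$trace_fn(ch_idx, start_frame, end_frame)
  out <- as.matrix(out)
  rownames(out) <- channel_ids
  out
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("%s: %d channels x %s frames @ %g Hz (%.1f s)\n",
              class(x)[1L], x$num_channels,
              format(x$num_frames, scientific = FALSE), x$sampling_frequency,
              x$num_frames / x$sampling_frequency))
  invisible(x)
}

#' Duration of a Recording in seconds
#' @param recording a `Recording`.
#' @export
recording_duration <- function(recording) {
  recording$num_frames / recording$sampling_frequency
}

DTYPE_INFO <- list(
  int16   = list(size = 2L, what = integer(),  signed = TRUE),
  uint16  = list(size = 2L, what = integer(),  signed = FALSE),
  int32   = list(size = 4L, what = integer(),  signed = TRUE),
  float32 = list(size = 4L, what = numeric(),  signed = TRUE),
  float64 = list(size = 8L, what = numeric(),  signed = TRUE)
)

#' Read a raw binary Recording with probe geometry
#'
#' The trace file is flat little-endian binary, frame-major (all channels of
#' frame 0, then frame 1, ...). A JSON sidecar supplies
#' `{dtype, num_channels, sampling_frequency, gain_to_uV, offset}` and a
#' probe CSV (`channel_id,x,y`, micrometres) supplies the geometry. The
#' returned Recording is lazy: construction reads no trace bytes, and
#' `get_traces()` seeks directly to the requested frame range.
#'
#' @param path path to the flat binary trace file.
#' @param probe_path path to the probe CSV.
#' @param header_path path to the JSON sidecar; defaults to `path` + ".json".
#' @return a `Recording` in microvolts (`gain_to_uV`/`offset` applied).
#' @export
read_recording <- function(path, probe_path, header_path = paste0(path, ".json")) {
  for (f in c(path, probe_path, header_path)) {
    if (!file.exists(f)) sm_stop(sprintf("file not found: %s", f), type = "io")
  }
  hdr <- jsonlite::read_json(header_path, simplifyVector = TRUE)
  info <- DTYPE_INFO[[hdr$dtype %||% ""]]
  if (is.null(info)) {
    sm_stop(sprintf("unknown dtype token '%s'", hdr$dtype %||% "<missing>"), type = "format")
  }
  nch <- as.integer(hdr$num_channels)
  probe <- utils::read.csv(probe_path, colClasses = c("character", "numeric", "numeric"))
  if (!all(c("channel_id", "x", "y") %in% names(probe))) {
    sm_stop("probe CSV must have header 'channel_id,x,y'", type = "format")
  }
  if (nrow(probe) != nch) {
    sm_stop(sprintf("probe lists %d channels but header declares %d",
                    nrow(probe), nch))
  }
  bytes <- file.size(path)
  frame_bytes <- info$size * nch
  if (bytes %% frame_bytes != 0) {
    sm_stop("binary file size is not a whole number of frames", type = "format")
  }
  num_frames <- bytes / frame_bytes
  gain <- as.numeric(hdr$gain_to_uV %||% 1)
  offset <- as.numeric(hdr$offset %||% 0)
  dtype <- hdr$dtype
  trace_fn <- function(ch_idx, start, end) {
    nfr <- end - start
    if (nfr == 0) return(matrix(numeric(0), nrow = length(ch_idx), ncol = 0))
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, where = start * frame_bytes)
    vals <- readBin(con, info$what, n = nfr * nch, size = info$size,
                    signed = info$signed, endian = "little")
    m <- matrix(as.numeric(vals), nrow = nch, ncol = nfr)
    m[ch_idx, , drop = FALSE] * gain + offset
  }
  new_recording(trace_fn, nch, num_frames, as.numeric(hdr$sampling_frequency),
                channel_ids = probe$channel_id,
                channel_locations = cbind(probe$x, probe$y),
                provenance = new_provenance(list(
                  kind = "file", format = "binary",
                  path = normalizePath(path),
                  header_path = normalizePath(header_path),
                  probe_path = normalizePath(probe_path)
                )))
}

#' Write a Recording to flat binary + sidecar header + probe CSV
#'
#' @param recording a `Recording`.
#' @param path output path for the binary traces.
#' @param probe_path output path for the probe CSV.
#' @param header_path output path for the JSON sidecar.
#' @param dtype on-disk sample type (default `"float64"`, lossless).
#' @param chunk_frames frames written per chunk.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, probe_path,
                            header_path = paste0(path, ".json"),
                            dtype = "float64", chunk_frames = 300000L) {
  stopifnot(inherits(recording, "Recording"))
  info <- DTYPE_INFO[[dtype]]
  if (is.null(info)) sm_stop(sprintf("unknown dtype token '%s'", dtype), type = "format")
  con <- file(path, "wb")
  start <- 0
  while (start < recording$num_frames) {
    end <- min(start + chunk_frames, recording$num_frames)
    tr <- get_traces(recording, start_frame = start, end_frame = end)
    if (dtype %in% c("float32", "float64")) {
      writeBin(as.numeric(tr), con, size = info$size, endian = "little")
    } else {
      writeBin(as.integer(round(tr)), con, size = info$size, endian = "little")
    }
    start <- end
  }
  close(con)
  jsonlite::write_json(list(dtype = dtype, num_channels = recording$num_channels,
                            sampling_frequency = recording$sampling_frequency,
                            gain_to_uV = 1, offset = 0),
                       header_path, auto_unbox = TRUE, digits = NA)
  probe <- data.frame(channel_id = recording$channel_ids,
                      x = recording$channel_locations[, 1],
                      y = recording$channel_locations[, 2])
  utils::write.csv(probe, probe_path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
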