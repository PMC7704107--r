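#' Construct a Sorting (per-unit spike trains)
#'
#' A `Sorting` holds the output of a spike sorter: one strictly increasing
#' train of integer sample frames (0-based) per unit, plus the sampling
#' frequency that converts frames to seconds. Unit identifiers are
#' coerced to character and must be unique. Duplicate frames within a unit
#' are invalid; unsorted trains are sorted with a warning so that all
#' downstream matching is deterministic.
#'
#' @param spike_trains named list of numeric vectors of spike frames
#'   (0-based integers); names are the unit ids.
#' @param sampling_frequency sampling rate in Hz (positive).
#' @param unit_properties optional named list (per unit) of key-value
#'   annotations.
#' @param spike_features optional named list (per unit) of named lists of
#'   per-spike arrays; each array must match the unit's spike count.
#' @param provenance internal provenance record; normally left `NULL`.
#' @return an object of class `Sorting`.
#' @export
Sorting <- function(spike_trains, sampling_frequency,
                    unit_properties = NULL, spike_features = NULL,
                    provenance = NULL) {
  if (!is.list(spike_trains)) sm_stop("spike_trains must be a named list")
  ids <- names(spike_trains)
  if (length(spike_trains) > 0L && (is.null(ids) || any(ids == ""))) {
    sm_stop("every spike train must be named with a unit id")
  }
  if (anyDuplicated(ids)) sm_stop("unit ids must be unique")
  if (!is_scalar_num(sampling_frequency) || sampling_frequency <= 0) {
    sm_stop("sampling_frequency must be a positive number")
  }
  spike_trains <- lapply(spike_trains, as.numeric)
  for (u in ids) {
    tr <- spike_trains[[u]]
    if (is.unsorted(tr, strictly = FALSE)) {
      warning(sprintf("unit '%s': spike frames were not sorted; sorting on construction", u))
      tr <- sort(tr)
      spike_trains[[u]] <- tr
    }
    check_frames(tr, unit = u)
    if (!is.null(spike_features) && !is.null(spike_features[[u]])) {
      for (fn in names(spike_features[[u]])) {
        if (length(spike_features[[u]][[fn]]) != length(tr)) {
          sm_stop(sprintf("unit '%s': feature '%s' length != spike count", u, fn))
        }
      }
    }
  }
  structure(list(
    spike_trains = spike_trains,
    sampling_frequency = as.numeric(sampling_frequency),
    unit_properties = unit_properties %||% setNames(vector("list", length(ids)), ids),
    spike_features = spike_features %||% setNames(vector("list", length(ids)), ids),
    provenance = provenance %||% new_provenance(list(kind = "memory"))
  ), class = "Sorting")
}

#' Unit identifiers of a Sorting
#' @param sorting a `Sorting`.
#' @return character vector of unit ids.
#' @export
unit_ids <- function(sorting) {
  stopifnot(inherits(sorting, "Sorting"))
  names(sorting$spike_trains) %||% character(0)
}

#' Number of units in a Sorting
#' @param sorting a `Sorting`.
#' @export
n_units <- function(sorting) length(unit_ids(sorting))

#' Spike train of one unit
#' @param sorting a `Sorting`.
#' @param unit a unit id.
#' @return numeric vector of 0-based integer sample frames, strictly
#'   increasing.
#' @export
spike_train <- function(sorting, unit) {
  stopifnot(inherits(sorting, "Sorting"))
  unit <- as.character(unit)
  if (!unit %in% unit_ids(sorting)) {
    sm_stop(sprintf("unknown unit id '%s'", unit))
  }
  sorting$spike_trains[[unit]]
}

#' Spike times of one unit in seconds
#' @inheritParams spike_train
#' @export
spike_times <- function(sorting, unit) {
  spike_train(sorting, unit) / sorting$sampling_frequency
}

#' @export
print.Sorting <- function(x, ...) {
  cat(sprintf("Sorting: %d units @ %g Hz, %d spikes total\n",
              n_units(x), x$sampling_frequency,
              sum(vapply(x$spike_trains, length, 1L))))
  invisible(x)
}

#' Keep a subset of units
#' @param sorting a `Sorting`.
#' @param units character vector of unit ids to retain (order preserved).
#' @return a `Sorting` containing only `units`, trains unchanged.
#' @export
select_units <- function(sorting, units) {
  units <- as.character(units)
  missing <- setdiff(units, unit_ids(sorting))
  if (length(missing)) sm_stop(sprintf("unknown unit id(s): %s", paste(missing, collapse = ", ")))
  Sorting(sorting$spike_trains[units], sorting$sampling_frequency,
          unit_properties = sorting$unit_properties[units],
          spike_features = sorting$spike_features[units],
          provenance = prov_append(sorting$provenance, "select_units",
                                   list(units = units)))
}

#' Write a Sorting to disk
#'
#' CSV files have header `unit_id,frame` with LF line endings; NPZ files
#' hold `unit_ids`, `spike_frames`, CSR-style `unit_index_ptr` offsets and
#' a scalar `sampling_frequency`. Output is byte-stable: writing the same
#' Sorting twice yields identical files.
#'
#' @param sorting a `Sorting`.
#' @param path output file path.
#' @param format `"csv"` or `"npz"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_sorting <- function(sorting, path, format = NULL) {
  stopifnot(inherits(sorting, "Sorting"))
  format <- format %||% infer_format(path)
  ids <- unit_ids(sorting)
  if (format == "csv") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(sprintf("# sampling_frequency=%s",
                       format(sorting$sampling_frequency, scientific = FALSE)),
               con, sep = "\n")
    writeLines("unit_id,frame", con, sep = "\n")
    for (u in ids) {
      tr <- sorting$spike_trains[[u]]
      if (length(tr)) {
        writeLines(paste0(u, ",", format(tr, scientific = FALSE, trim = TRUE)),
                   con, sep = "\n")
      }
    }
  } else if (format == "npz") {
    counts <- vapply(ids, function(u) length(sorting$spike_trains[[u]]), 1L)
    npz_write(path, list(
      unit_ids = list(value = if (length(ids)) ids else character(0)),
      spike_frames = list(value = as_int64(unlist(sorting$spike_trains, use.names = FALSE) %||% numeric(0))),
      unit_index_ptr = list(value = as_int64(cumsum(c(0, counts)))),
      sampling_frequency = list(value = sorting$sampling_frequency, scalar = TRUE)
    ))
  } else {
    sm_stop(sprintf("unknown sorting format '%s'", format), type = "parameter")
  }
  invisible(path)
}

#' Read a Sorting from disk
#'
#' Accepts the CSV and NPZ layouts produced by [write_sorting()]. Frames
#' that are not sorted within a unit are sorted with a warning; duplicate
#' frames within a unit raise a validation error naming the unit.
#'
#' @param path input file path.
#' @param format `"csv"` or `"npz"`; default inferred from the extension.
#' @return a `Sorting`.
#' @export
read_sorting <- function(path, format = NULL) {
  if (!file.exists(path)) sm_stop(sprintf("file not found: %s", path), type = "io")
  format <- format %||% infer_format(path)
  if (format == "csv") {
    first <- readLines(path, n = 1L)
    fs <- NA_real_
    skip <- 0L
    if (grepl("^#\\s*sampling_frequency=", first)) {
      fs <- as.numeric(sub("^#\\s*sampling_frequency=", "", first))
      skip <- 1L
    }
    df <- utils::read.csv(path, skip = skip, colClasses = c("character", "numeric"))
    if (!all(c("unit_id", "frame") %in% names(df))) {
      sm_stop("sorting CSV must have header 'unit_id,frame'", type = "format")
    }
    if (is.na(fs)) sm_stop("sorting CSV missing '# sampling_frequency=' line", type = "format")
    trains <- split(df$frame, factor(df$unit_id, levels = unique(df$unit_id)))
    sorting <- Sorting(as.list(trains), fs,
                       provenance = new_provenance(list(kind = "file", format = "csv",
                                                        path = normalizePath(path))))
  } else if (format == "npz") {
    arrs <- npz_read(path)
    need <- c("unit_ids", "spike_frames", "unit_index_ptr", "sampling_frequency")
    if (!all(need %in% names(arrs))) {
      sm_stop("sorting NPZ missing required arrays", type = "format")
    }
    ids <- as.character(arrs$unit_ids)
    ptr <- arrs$unit_index_ptr
    frames <- arrs$spike_frames
    trains <- lapply(seq_along(ids), function(i) {
      if (ptr[i + 1L] > ptr[i]) frames[(ptr[i] + 1L):ptr[i + 1L]] else numeric(0)
    })
    names(trains) <- ids
    sorting <- Sorting(trains, arrs$sampling_frequency[1L],
                       provenance = new_provenance(list(kind = "file", format = "npz",
                                                        path = normalizePath(path))))
  } else {
    sm_stop(sprintf("unknown sorting format '%s'", format), type = "parameter")
  }
  sorting
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "npz")) ext else
    sm_stop(sprintf("cannot infer format from extension '.%s'", ext), type = "parameter")
}
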