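# Provenance: every Recording/Sorting carries a serializable record of its
# source (file or synthetic generator) and the ordered operations applied to
# it, so any derived object can be dumped to JSON and rebuilt exactly.

PROVENANCE_SCHEMA_VERSION <- "1.0"

new_provenance <- function(source) {
  structure(list(
    schema_version = PROVENANCE_SCHEMA_VERSION,
    source = source,
    operations = list()
  ), class = "ProvenanceRecord")
}

prov_append <- function(prov, name, params) {
  prov$operations <- c(prov$operations, list(list(name = name, params = params)))
  prov
}

#' Dump the provenance record of a Recording or Sorting
#'
#' @param obj a `Recording` or `Sorting`.
#' @return a `ProvenanceRecord`: source descriptor, ordered operation list
#'   with full parameter sets and seeds, and a schema version.
#' @export
dump_provenance <- function(obj) {
  if (!inherits(obj, "Recording") && !inherits(obj, "Sorting")) {
    sm_stop("dump_provenance expects a Recording or Sorting")
  }
  obj$provenance
}

#' Serialize a provenance record to JSON
#' @param record a `ProvenanceRecord`.
#' @param path output path for the JSON document.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(record, path) {
  stopifnot(inherits(record, "ProvenanceRecord"))
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a provenance record from JSON
#' @param path path to a JSON document written by [write_provenance()].
#' @return a `ProvenanceRecord`.
#' @export
read_provenance <- function(path) {
  if (!file.exists(path)) sm_stop(sprintf("file not found: %s", path), type = "io")
  rec <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  structure(rec, class = "ProvenanceRecord")
}

# Replayable operations. Each entry rebuilds one pipeline stage from its
# recorded parameters.
prov_op_registry <- function() {
  list(
    bandpass_filter  = function(obj, p) bandpass_filter(obj, p$freq_min, p$freq_max, p$order),
    notch_filter     = function(obj, p) notch_filter(obj, p$freq, p$q),
    common_reference = function(obj, p) common_reference(obj, p$mode),
    remove_channels  = function(obj, p) remove_channels(obj, unlist(p$channel_ids)),
    select_units     = function(obj, p) select_units(obj, unlist(p$units)),
    corrupt_sorting  = function(obj, p) do.call(corrupt_sorting, c(list(gt = obj), p)),
    threshold_curation = function(obj, p) {
      do.call(threshold_curation, c(list(sorting = obj), p))
    }
  )
}

#' Rebuild a Recording or Sorting from its provenance record
#'
#' Re-reads the recorded source (a file path or a synthetic generator spec,
#' seeds included) and replays the recorded operations in order. The result
#' is element-wise equal to the object the record was dumped from.
#'
#' @param record a `ProvenanceRecord` (or path to its JSON serialization).
#' @return a `Recording` or `Sorting`.
#' @export
restore_provenance <- function(record) {
  if (is.character(record)) record <- read_provenance(record)
  stopifnot(inherits(record, "ProvenanceRecord"))
  if (!identical(record$schema_version, PROVENANCE_SCHEMA_VERSION)) {
    sm_stop(sprintf("unsupported provenance schema version '%s' (expected '%s')",
                    record$schema_version, PROVENANCE_SCHEMA_VERSION), type = "format")
  }
  src <- record$source
  obj <- switch(src$kind %||% "memory",
    file = {
      if (!file.exists(src$path)) {
        sm_stop(sprintf("provenance source file missing: %s", src$path), type = "io")
      }
      if (src$format %in% c("csv", "npz")) {
        read_sorting(src$path, format = src$format)
      } else if (src$format == "binary") {
        read_recording(src$path, probe_path = src$probe_path,
                       header_path = src$header_path)
      } else {
        sm_stop(sprintf("unknown source format '%s'", src$format), type = "format")
      }
    },
    synthetic = {
      gen <- switch(src$generator,
        generate_gt_sorting = generate_gt_sorting,
        synthesize_recording = function(...) {
          # gt sorting is itself restored from its embedded record
          gt <- restore_provenance(structure(src$params$gt_provenance,
                                             class = "ProvenanceRecord"))
          p <- src$params
          p$gt_provenance <- NULL
          do.call(synthesize_recording, c(list(gt = gt), p))
        },
        sm_stop(sprintf("unknown synthetic generator '%s'", src$generator),
                type = "format")
      )
      if (identical(src$generator, "synthesize_recording")) gen() else do.call(gen, src$params)
    },
    sm_stop("object was built in memory and is not restorable", type = "validation")
  )
  reg <- prov_op_registry()
  for (op in record$operations) {
    fn <- reg[[op$name]]
    if (is.null(fn)) sm_stop(sprintf("unknown operation '%s' in provenance", op$name),
                             type = "format")
    obj <- fn(obj, op$params)
  }
  obj
}
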