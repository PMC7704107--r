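# Curation: non-destructive unit exclusion. A curated sorting is itself a
# Sorting (chainable); the parent is untouched and every exclusion is logged
# (unit, metric, value, threshold, sign) so the operation is auditable and
# replayable.

curated_sorting <- function(parent, keep_units, log, op_name, op_params) {
  s <- Sorting(parent$spike_trains[keep_units], parent$sampling_frequency,
               unit_properties = parent$unit_properties[keep_units],
               spike_features = parent$spike_features[keep_units],
               provenance = prov_append(parent$provenance, op_name, op_params))
  s$parent <- parent
  s$exclusion_log <- log
  class(s) <- c("CuratedSorting", "Sorting")
  s
}

#' Exclude units by a quality-metric threshold
#'
#' Removes every unit whose metric value satisfies the exclusion predicate
#' (`sign = "less"` removes units with value < threshold, etc.). Curated
#' sortings are ordinary sortings, so thresholds on different metrics can be
#' chained. Units whose metric is NaN fail every threshold and are excluded
#' by default (`nan_policy = "exclude"`).
#'
#' @param sorting a `Sorting`.
#' @param metric metric name, see [compute_quality_metrics()] (for the drift
#'   and nearest-neighbour pairs, use the column name, e.g. `"nn_hit_rate"`).
#' @param threshold threshold value.
#' @param sign one of `"less"`, `"greater"`, `"less_or_equal"`,
#'   `"greater_or_equal"`: the condition under which a unit is excluded.
#' @param recording a `Recording`, required when the metric consumes traces.
#' @param duration,params,seed passed to [compute_quality_metrics()].
#' @param nan_policy `"exclude"` (default) or `"keep"` units with NaN
#'   metric values.
#' @return a `CuratedSorting` with the exclusion log in
#'   `$exclusion_log`.
#' @export
threshold_curation <- function(sorting, metric, threshold,
                               sign = c("less", "greater", "less_or_equal",
                                        "greater_or_equal"),
                               recording = NULL, duration = NULL,
                               params = list(), seed = 0L,
                               nan_policy = c("exclude", "keep")) {
  sign <- match.arg(sign)
  nan_policy <- match.arg(nan_policy)
  if (!is_scalar_num(threshold)) sm_stop("threshold must be a number", type = "parameter")
  col_to_metric <- c(max_drift_um = "drift", cumulative_drift_um = "drift",
                     nn_hit_rate = "nearest_neighbor", nn_miss_rate = "nearest_neighbor")
  metric_name <- if (metric %in% names(col_to_metric)) col_to_metric[[metric]] else metric
  tab <- compute_quality_metrics(sorting, recording = recording,
                                 metric_names = metric_name, duration = duration,
                                 params = params, seed = seed)
  col <- if (metric %in% names(tab)) metric else metric_name
  values <- setNames(tab[[col]], tab$unit_id)
  pred <- switch(sign,
    less = values < threshold,
    greater = values > threshold,
    less_or_equal = values <= threshold,
    greater_or_equal = values >= threshold
  )
  pred[is.na(pred)] <- nan_policy == "exclude"
  excluded <- names(values)[pred]
  keep <- setdiff(unit_ids(sorting), excluded)
  log <- data.frame(unit = excluded,
                    metric = rep(metric, length(excluded)),
                    value = unname(values[excluded]),
                    threshold = rep(threshold, length(excluded)),
                    sign = rep(sign, length(excluded)),
                    stringsAsFactors = FALSE)
  curated_sorting(sorting, keep, log, "threshold_curation",
                  list(metric = metric, threshold = threshold, sign = sign,
                       params = params, seed = seed, nan_policy = nan_policy))
}

#' Consensus-based curation of multiple sortings
#'
#' Compares all sortings pairwise, counts for each unit the number of
#' sorters agreeing on it (its k in the agreement graph) and, for every
#' sorter, retains only the units with `k >= min_k` — the ensemble strategy
#' of keeping units corroborated by at least one other sorter.
#'
#' @param sortings list of `Sorting` objects (>= 2).
#' @param labels unique sorter labels.
#' @param min_k minimum agreement count to retain a unit (default 2;
#'   `min_k = 1` retains everything).
#' @param delta_time matching window in milliseconds (default 0.4).
#' @param min_match_score minimum agreement score for an edge (default 0.5).
#' @return named list of `CuratedSorting` objects, one per sorter; each
#'   exclusion log cites the removed unit's k.
#' @export
consensus_curation <- function(sortings, labels = NULL, min_k = 2L,
                               delta_time = 0.4, min_match_score = 0.5) {
  graph <- compare_multiple(sortings, labels = labels, delta_time = delta_time,
                            min_match_score = min_match_score)
  if (min_k > length(graph$labels)) {
    sm_stop(sprintf("min_k (%d) exceeds the number of sorters (%d)",
                    min_k, length(graph$labels)), type = "parameter")
  }
  names(sortings) <- graph$labels
  out <- setNames(vector("list", length(graph$labels)), graph$labels)
  for (l in graph$labels) {
    nd <- graph$nodes[graph$nodes$sorter == l, , drop = FALSE]
    k <- setNames(nd$k, nd$unit)
    keep <- unit_ids(sortings[[l]])[k[unit_ids(sortings[[l]])] >= min_k]
    excluded <- setdiff(unit_ids(sortings[[l]]), keep)
    log <- data.frame(unit = excluded,
                      metric = rep("agreement_count_k", length(excluded)),
                      value = as.numeric(unname(k[excluded])),
                      threshold = rep(min_k, length(excluded)),
                      sign = rep("less", length(excluded)),
                      stringsAsFactors = FALSE)
    out[[l]] <- curated_sorting(sortings[[l]], keep, log, "consensus_curation",
                                list(min_k = min_k, delta_time = delta_time,
                                     min_match_score = min_match_score,
                                     labels = graph$labels, sorter = l))
  }
  out
}

#' Replay an exclusion log on a parent sorting
#'
#' Applies the logged exclusions to the parent and returns the retained unit
#' ids; used to audit that a curated sorting is exactly its log applied to
#' its parent.
#'
#' @param parent the parent `Sorting`.
#' @param log an exclusion log data.frame with a `unit` column.
#' @return character vector of retained unit ids.
#' @export
replay_exclusions <- function(parent, log) {
  setdiff(unit_ids(parent), log$unit)
}
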