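# Multi-sorter agreement graph and consensus construction.
#
# Pairwise Hungarian matchings between every pair of sorting outputs become
# the edges of an undirected graph whose nodes are (sorter, unit). A node's
# agreement count k is 1 plus the number of distinct other sorters it is
# directly matched with; k is deliberately based on direct neighbours rather
# than connected-component membership so transitive chains cannot inflate
# agreement.

#' Pairwise comparison of multiple sortings
#'
#' @param sortings list of `Sorting` objects (>= 2, equal sampling
#'   frequencies).
#' @param labels unique sorter labels; default `names(sortings)` or
#'   `"sorter1"..`.
#' @param delta_time matching window in milliseconds (default 0.4).
#' @param min_match_score minimum agreement for an edge (default 0.5).
#' @return a `MultiComparison`: `nodes` data.frame (`sorter`, `unit`, `k`),
#'   `edges` data.frame (`sorter_a`, `unit_a`, `sorter_b`, `unit_b`,
#'   `score`), the labels and parameters.
#' @export
compare_multiple <- function(sortings, labels = NULL, delta_time = 0.4,
                             min_match_score = 0.5) {
  if (!is.list(sortings) || length(sortings) < 2L) {
    sm_stop("need at least two sortings", type = "parameter")
  }
  lapply(sortings, function(s) stopifnot(inherits(s, "Sorting")))
  labels <- labels %||% names(sortings) %||% paste0("sorter", seq_along(sortings))
  labels <- as.character(labels)
  if (length(labels) != length(sortings) || anyDuplicated(labels)) {
    sm_stop("labels must be unique, one per sorting", type = "parameter")
  }
  names(sortings) <- labels
  nodes <- do.call(rbind, lapply(labels, function(l) {
    ids <- unit_ids(sortings[[l]])
    if (length(ids) == 0L) return(NULL)
    data.frame(sorter = l, unit = ids, stringsAsFactors = FALSE)
  }))
  if (is.null(nodes)) nodes <- data.frame(sorter = character(0), unit = character(0))
  edges <- list()
  for (i in seq_along(labels)) {
    for (j in seq_along(labels)) {
      if (j <= i) next
      agreement <- compute_agreement_matrix(sortings[[i]], sortings[[j]],
                                            delta_time = delta_time)
      mt <- hungarian_match(agreement, min_score = min_match_score)
      matched <- names(mt$a_to_b)[!is.na(mt$a_to_b)]
      if (length(matched)) {
        edges[[length(edges) + 1L]] <- data.frame(
          sorter_a = labels[i], unit_a = matched,
          sorter_b = labels[j], unit_b = unname(mt$a_to_b[matched]),
          score = unname(mt$scores_a[matched]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else {
    data.frame(sorter_a = character(0), unit_a = character(0),
               sorter_b = character(0), unit_b = character(0),
               score = numeric(0))
  }
  # k = 1 + number of distinct other sorters this node is matched with
  key <- function(sorter, unit) paste(sorter, unit, sep = "\r")
  neighbours <- new.env(parent = emptyenv())
  add <- function(k, s) {
    assign(k, union(get0(k, envir = neighbours, ifnotfound = character(0)), s),
           envir = neighbours)
  }
  for (r in seq_len(nrow(edges))) {
    add(key(edges$sorter_a[r], edges$unit_a[r]), edges$sorter_b[r])
    add(key(edges$sorter_b[r], edges$unit_b[r]), edges$sorter_a[r])
  }
  nodes$k <- vapply(seq_len(nrow(nodes)), function(r) {
    1L + length(get0(key(nodes$sorter[r], nodes$unit[r]),
                     envir = neighbours, ifnotfound = character(0)))
  }, 1L)
  structure(list(nodes = nodes, edges = edges, labels = labels,
                 sampling_frequency = sortings[[1L]]$sampling_frequency,
                 params = list(delta_time = delta_time,
                               min_match_score = min_match_score)),
            class = "MultiComparison")
}

#' @export
print.MultiComparison <- function(x, ...) {
  cat(sprintf("MultiComparison: %d sorters, %d units, %d agreement edges\n",
              length(x$labels), nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# connected components of the agreement graph; returns a list of
# data.frames of nodes, each with the component's distinct-sorter count
graph_components <- function(graph) {
  key <- paste(graph$nodes$sorter, graph$nodes$unit, sep = "\r")
  if (nrow(graph$edges) > 0) {
    ek_a <- paste(graph$edges$sorter_a, graph$edges$unit_a, sep = "\r")
    ek_b <- paste(graph$edges$sorter_b, graph$edges$unit_b, sep = "\r")
    g <- igraph::graph_from_data_frame(
      data.frame(from = ek_a, to = ek_b), directed = FALSE,
      vertices = data.frame(name = key)
    )
    comp <- igraph::components(g)$membership[key]
  } else {
    comp <- seq_along(key)
  }
  split(seq_len(nrow(graph$nodes)), comp)
}

#' Tabulate agreement counts
#'
#' Two views of "how many sorters agree": a group-level table where each
#' connected agreement group of units counts once (its k is the number of
#' distinct sorters in the group), and a per-sorter table counting each
#' sorter's units by their node-level k.
#'
#' @param graph a `MultiComparison`.
#' @return list with `groups` (`k`, `n_groups`) and `per_sorter`
#'   (`sorter`, `k`, `n_units`) data.frames, covering k = 1..M.
#' @export
agreement_counts <- function(graph) {
  stopifnot(inherits(graph, "MultiComparison"))
  M <- length(graph$labels)
  comps <- graph_components(graph)
  group_k <- vapply(comps, function(idx) {
    length(unique(graph$nodes$sorter[idx]))
  }, 1L)
  groups <- data.frame(k = seq_len(M),
                       n_groups = vapply(seq_len(M), function(k) sum(group_k == k), 1L))
  per <- expand.grid(sorter = graph$labels, k = seq_len(M),
                     stringsAsFactors = FALSE)
  per$n_units <- vapply(seq_len(nrow(per)), function(r) {
    sum(graph$nodes$sorter == per$sorter[r] & graph$nodes$k == per$k[r])
  }, 1L)
  per <- per[order(per$sorter, per$k), ]
  rownames(per) <- NULL
  list(groups = groups, per_sorter = per)
}

#' Build a consensus sorting from the agreement graph
#'
#' For every agreement group supported by at least `min_k` distinct sorters,
#' emits one consensus unit: the union of the spike trains of the two
#' closest-matching units in the group (the strongest edge), with spikes
#' matched within the tolerance window counted once (the earlier frame of a
#' matched pair is kept).
#'
#' @param graph a `MultiComparison`.
#' @param sortings the list of `Sorting` objects the graph was built from,
#'   in the same order/labels.
#' @param min_k minimum number of agreeing sorters to retain a group
#'   (default 2).
#' @param delta_time matching window in milliseconds used for the union
#'   (default: the graph's window).
#' @return a `Sorting` of consensus units; provenance records the two donor
#'   units of each.
#' @export
build_consensus_sorting <- function(graph, sortings, min_k = 2L,
                                    delta_time = NULL) {
  stopifnot(inherits(graph, "MultiComparison"))
  M <- length(graph$labels)
  if (min_k > M) {
    sm_stop(sprintf("min_k (%d) exceeds the number of sorters (%d)", min_k, M),
            type = "parameter")
  }
  labels <- graph$labels
  names(sortings) <- labels
  delta_time <- delta_time %||% graph$params$delta_time
  fs <- graph$sampling_frequency
  delta_frames <- round(delta_time * fs / 1000)
  comps <- graph_components(graph)
  trains <- list()
  donors <- list()
  for (idx in comps) {
    sorters <- unique(graph$nodes$sorter[idx])
    if (length(sorters) < min_k) next
    keys <- paste(graph$nodes$sorter[idx], graph$nodes$unit[idx], sep = "\r")
    in_comp <- paste(graph$edges$sorter_a, graph$edges$unit_a, sep = "\r") %in% keys
    e <- graph$edges[in_comp, , drop = FALSE]
    if (nrow(e) == 0L) {
      # isolated unit (only reachable when min_k = 1): pass it through
      trains[[length(trains) + 1L]] <-
        spike_train(sortings[[graph$nodes$sorter[idx[1L]]]], graph$nodes$unit[idx[1L]])
      donors[[length(donors) + 1L]] <- list(
        sorter_a = graph$nodes$sorter[idx[1L]], unit_a = graph$nodes$unit[idx[1L]],
        sorter_b = NULL, unit_b = NULL, score = NA,
        n_sorters_in_group = 1L
      )
      next
    }
    best <- e[which.max(e$score), , drop = FALSE]
    t1 <- spike_train(sortings[[best$sorter_a]], best$unit_a)
    t2 <- spike_train(sortings[[best$sorter_b]], best$unit_b)
    pairs <- .match_pairs_cpp(t1, t2, delta_frames)
    merged <- sort(c(
      if (nrow(pairs)) pmin(t1[pairs[, 1]], t2[pairs[, 2]]) else numeric(0),
      t1[setdiff(seq_along(t1), pairs[, 1])],
      t2[setdiff(seq_along(t2), pairs[, 2])]
    ))
    trains[[length(trains) + 1L]] <- merged
    donors[[length(donors) + 1L]] <- list(
      sorter_a = best$sorter_a, unit_a = best$unit_a,
      sorter_b = best$sorter_b, unit_b = best$unit_b,
      score = best$score, n_sorters_in_group = length(sorters)
    )
  }
  names(trains) <- if (length(trains)) paste0("consensus_", seq_along(trains)) else character(0)
  prov <- new_provenance(list(kind = "memory"))
  prov <- prov_append(prov, "build_consensus_sorting",
                      list(min_k = min_k, delta_time = delta_time, donors = donors))
  Sorting(trains, fs, provenance = prov)
}
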