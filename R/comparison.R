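# Spike-train and unit-level comparison.
#
# Two spikes from two different trains are "matched" when they fall within a
# tolerance window of each other (|t1 - t2| <= delta, inclusive). Matching is
# one-to-one: n_matches is the size of a maximum bipartite pairing, computed
# by a greedy two-pointer sweep over the sorted trains (optimal for this
# interval structure; ties resolve toward the earlier spike). The agreement
# score of two trains is
#
#     score = n_matches / (n1 + n2 - n_matches)
#
# i.e. matched spikes over the union size, in [0, 1].

#' Count matched spikes between two trains
#'
#' @param train1,train2 strictly increasing numeric vectors of spike frames.
#' @param delta_frames inclusive matching window in frames (>= 0).
#' @return a `MatchCounts` list: `n1`, `n2`, `n_matches`, `delta_frames`.
#' @export
count_matched_spikes <- function(train1, train2, delta_frames) {
  check_frames(train1)
  check_frames(train2)
  if (!is_scalar_num(delta_frames) || delta_frames < 0) {
    sm_stop("delta_frames must be a non-negative number", type = "parameter")
  }
  n <- .count_matches_cpp(as.numeric(train1), as.numeric(train2),
                          as.numeric(delta_frames))
  structure(list(n1 = length(train1), n2 = length(train2),
                 n_matches = n, delta_frames = delta_frames),
            class = "MatchCounts")
}

#' Matched spike index pairs between two trains
#'
#' Same maximum one-to-one pairing as [count_matched_spikes()], returning
#' the paired indices (1-based into each train).
#'
#' @inheritParams count_matched_spikes
#' @return two-column integer matrix of (index in train1, index in train2).
#' @export
matched_spike_pairs <- function(train1, train2, delta_frames) {
  check_frames(train1)
  check_frames(train2)
  .match_pairs_cpp(as.numeric(train1), as.numeric(train2), as.numeric(delta_frames))
}

#' Agreement score of two spike trains
#'
#' `n_matches / (n1 + n2 - n_matches)`: matched spikes over the union size.
#' Symmetric in the two trains; 1 iff the trains match perfectly, 0 iff no
#' spike matches. Two empty trains score 0 (an empty unit carries no
#' evidence of agreement).
#'
#' @param counts a `MatchCounts` from [count_matched_spikes()], or a list
#'   with fields `n1`, `n2`, `n_matches`.
#' @return score in `[0, 1]`.
#' @export
agreement_score <- function(counts) {
  n1 <- counts$n1; n2 <- counts$n2; nm <- counts$n_matches
  if (nm > min(n1, n2)) sm_stop("n_matches exceeds min(n1, n2)")
  if (n1 + n2 == 0) return(0)
  nm / (n1 + n2 - nm)
}

#' Agreement matrix between two sortings
#'
#' Computes the agreement score for every (unit of A, unit of B) pair,
#' matching spikes within `delta_time` milliseconds (default 0.4 ms,
#' converted to frames as `round(delta_time * fs / 1000)`).
#'
#' @param sorting_a,sorting_b `Sorting` objects with equal sampling
#'   frequencies.
#' @param delta_time matching window in milliseconds (default 0.4).
#' @return an `AgreementMatrix`: |units A| x |units B| matrix of scores in
#'   `[0, 1]`, with unit ids as dimnames and the window recorded in
#'   attributes.
#' @export
compute_agreement_matrix <- function(sorting_a, sorting_b, delta_time = 0.4) {
  stopifnot(inherits(sorting_a, "Sorting"), inherits(sorting_b, "Sorting"))
  if (abs(sorting_a$sampling_frequency - sorting_b$sampling_frequency) > 1e-9) {
    sm_stop("sampling frequencies of the two sortings differ")
  }
  fs <- sorting_a$sampling_frequency
  delta_frames <- round(delta_time * fs / 1000)
  ids_a <- unit_ids(sorting_a)
  ids_b <- unit_ids(sorting_b)
  m <- matrix(0, length(ids_a), length(ids_b), dimnames = list(ids_a, ids_b))
  for (i in seq_along(ids_a)) {
    t1 <- sorting_a$spike_trains[[i]]
    for (j in seq_along(ids_b)) {
      t2 <- sorting_b$spike_trains[[j]]
      nm <- .count_matches_cpp(t1, t2, delta_frames)
      denom <- length(t1) + length(t2) - nm
      m[i, j] <- if (denom == 0) 0 else nm / denom
    }
  }
  attr(m, "delta_time") <- delta_time
  attr(m, "delta_frames") <- delta_frames
  attr(m, "sampling_frequency") <- fs
  class(m) <- c("AgreementMatrix", class(m))
  m
}

#' Optimal one-to-one unit assignment (Hungarian method)
#'
#' Finds the injective assignment of row units to column units that
#' maximizes total agreement, then discards pairs scoring below
#' `min_score`.
#'
#' @param matrix an `AgreementMatrix` (or plain numeric matrix with
#'   dimnames) of scores in `[0, 1]`.
#' @param min_score matches below this score are reported `UNMATCHED`
#'   (`NA`); default 0.
#' @return a `MatchResult`: `a_to_b` and `b_to_a` named character vectors
#'   (`NA` = unmatched), `scores_a`/`scores_b` of the retained matches, and
#'   the method label.
#' @export
hungarian_match <- function(matrix, min_score = 0) {
  m <- unclass(matrix)
  attr(m, "delta_time") <- NULL; attr(m, "delta_frames") <- NULL
  attr(m, "sampling_frequency") <- NULL
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
  if (!is_scalar_num(min_score) || min_score < 0 || min_score > 1) {
    sm_stop("min_score must lie in [0, 1]", type = "parameter")
  }
  na <- nrow(m); nb <- ncol(m)
  a_to_b <- setNames(rep(NA_character_, na), rownames(m))
  b_to_a <- setNames(rep(NA_character_, nb), colnames(m))
  scores_a <- setNames(rep(NA_real_, na), rownames(m))
  if (na > 0 && nb > 0) {
    pos <- which(m > 0, arr.ind = TRUE)
    if (nrow(pos) > 0) {
      edges <- as.vector(t(cbind(pos[, 1], na + pos[, 2])))
      g <- igraph::make_bipartite_graph(c(rep(FALSE, na), rep(TRUE, nb)), edges)
      mt <- igraph::max_bipartite_match(g, weights = m[pos])$matching
      for (i in seq_len(na)) {
        j <- mt[i]
        if (!is.na(j)) {
          jj <- j - na
          if (m[i, jj] >= min_score && m[i, jj] > 0) {
            a_to_b[i] <- colnames(m)[jj]
            b_to_a[jj] <- rownames(m)[i]
            scores_a[i] <- m[i, jj]
          }
        }
      }
    }
  }
  scores_b <- setNames(rep(NA_real_, nb), colnames(m))
  matched_b <- !is.na(b_to_a)
  scores_b[matched_b] <- scores_a[b_to_a[matched_b]]
  structure(list(a_to_b = a_to_b, b_to_a = b_to_a,
                 scores_a = scores_a, scores_b = scores_b,
                 method = "hungarian", min_score = min_score),
            class = "MatchResult")
}

#' Thresholded best matches (possibly many-to-one)
#'
#' For every row unit, lists all column units whose agreement score is at
#' least `min_score`, in descending score order. No injectivity is imposed;
#' this is the matching mode used to analyse failure modes such as
#' oversplitting.
#'
#' @inheritParams hungarian_match
#' @param min_score minimum agreement to report a match (default 0.5).
#' @return named list (one entry per row unit) of data.frames with columns
#'   `unit` and `score`.
#' @export
best_match <- function(matrix, min_score = 0.5) {
  m <- unclass(matrix)
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
  out <- setNames(vector("list", nrow(m)), rownames(m))
  for (i in seq_len(nrow(m))) {
    keep <- which(m[i, ] >= min_score)
    keep <- keep[order(m[i, keep], decreasing = TRUE)]
    out[[i]] <- data.frame(unit = colnames(m)[keep], score = m[i, keep],
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}

#' Label spikes of a tested train against ground truth
#'
#' Spikes paired by the maximum one-to-one matching are true positives;
#' unpaired ground-truth spikes are false negatives; unpaired tested spikes
#' are false positives.
#'
#' @param gt_train,tested_train strictly increasing spike frames.
#' @param delta_frames inclusive matching window in frames.
#' @return a `SpikeLabelCounts` list: `tp`, `fn`, `fp`.
#' @export
label_spikes <- function(gt_train, tested_train, delta_frames) {
  counts <- count_matched_spikes(gt_train, tested_train, delta_frames)
  structure(list(tp = counts$n_matches,
                 fn = counts$n1 - counts$n_matches,
                 fp = counts$n2 - counts$n_matches),
            class = "SpikeLabelCounts")
}

#' Performance measures from spike label counts
#'
#' The five standard measures: accuracy `tp/(tp+fn+fp)`, recall
#' `tp/(tp+fn)`, precision `tp/(tp+fp)`, miss rate `fn/(tp+fn)` and false
#' discovery rate `fp/(tp+fp)`.
#'
#' @param counts a `SpikeLabelCounts` (or list with `tp`, `fn`, `fp`).
#' @return a `PerformanceSummary` list of the five measures, each in
#'   `[0, 1]`. All-zero counts are undefined and raise an error.
#' @export
performance_measures <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp
  if (any(c(tp, fn, fp) < 0)) sm_stop("counts must be non-negative")
  if (tp + fn + fp == 0) {
    sm_stop("performance undefined for all-zero counts", type = "parameter")
  }
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    accuracy = tp / (tp + fn + fp),
    recall = ratio(tp, tp + fn),
    precision = ratio(tp, tp + fp),
    miss_rate = ratio(fn, tp + fn),
    false_discovery_rate = ratio(fp, tp + fp)
  ), class = "PerformanceSummary")
}

#' Classify tested units against ground truth
#'
#' Applies the agreement-based unit categories, in precedence order:
#' \itemize{
#'   \item \emph{overmerged}: agreement above `false_positive_threshold`
#'     with two or more ground-truth units;
#'   \item \emph{well_detected}: the assigned match of a ground-truth unit
#'     with agreement above `well_detected_threshold`;
#'   \item \emph{redundant}: agreement above `false_positive_threshold` with
#'     exactly one ground-truth unit but not that unit's best-matched tested
#'     unit;
#'   \item \emph{false_positive}: unmatched, or matched below
#'     `false_positive_threshold`;
#'   \item \emph{weak_match}: anything else (intermediate agreement).
#' }
#'
#' @param agreement `AgreementMatrix` with ground-truth units as rows and
#'   tested units as columns.
#' @param match a `MatchResult` from [hungarian_match()] on that matrix.
#' @param well_detected_threshold agreement above which a matched unit is
#'   well detected (default 0.8).
#' @param false_positive_threshold agreement below which a unit is a false
#'   positive (default 0.2).
#' @return data.frame with one row per tested unit: `unit_id`, `category`,
#'   `matched_gt`, `score`; thresholds recorded in attributes.
#' @export
classify_units <- function(agreement, match,
                           well_detected_threshold = 0.8,
                           false_positive_threshold = 0.2) {
  m <- unclass(agreement)
  gt_ids <- rownames(m); tested_ids <- colnames(m)
  out <- data.frame(unit_id = tested_ids, category = NA_character_,
                    matched_gt = NA_character_, score = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(tested_ids)) {
    col <- m[, j]
    above <- gt_ids[col > false_positive_threshold]
    matched_gt <- match$b_to_a[[tested_ids[j]]]
    score <- if (is.na(matched_gt)) NA_real_ else m[matched_gt, j]
    out$matched_gt[j] <- matched_gt
    out$score[j] <- if (length(col)) max(col) else NA_real_
    out$category[j] <- if (length(above) >= 2L) {
      "overmerged"
    } else if (!is.na(matched_gt) && score > well_detected_threshold) {
      "well_detected"
    } else if (length(above) == 1L && {
      # the gt unit's best-matched tested unit: its assigned partner if
      # any, otherwise the argmax of its row
      best_for_gt <- match$a_to_b[[above]]
      if (is.na(best_for_gt)) best_for_gt <- tested_ids[which.max(m[above, ])]
      !identical(best_for_gt, tested_ids[j])
    }) {
      "redundant"
    } else if (is.na(matched_gt) || score < false_positive_threshold) {
      "false_positive"
    } else {
      "weak_match"
    }
  }
  attr(out, "well_detected_threshold") <- well_detected_threshold
  attr(out, "false_positive_threshold") <- false_positive_threshold
  out
}

#' Compare a sorting output with ground truth
#'
#' Runs the full ground-truth evaluation: agreement matrix, unit assignment
#' (Hungarian by default, or thresholded best-match), per-ground-truth-unit
#' spike label counts and performance measures, and the tested-unit
#' classification. Ground-truth units left unmatched get recall 0.
#'
#' @param gt ground-truth `Sorting`.
#' @param tested tested `Sorting` (same sampling frequency).
#' @param method `"hungarian"` (default) or `"best"`.
#' @param delta_time matching window in milliseconds (default 0.4).
#' @param min_score minimum agreement for a unit match (default 0.5).
#' @param well_detected_threshold,false_positive_threshold classification
#'   thresholds (defaults 0.8 and 0.2).
#' @return a `GroundTruthComparison`: list with `agreement`, `match`,
#'   `counts` (per-gt-unit tp/fn/fp), `performance` (per-gt-unit measures),
#'   `classification` (per tested unit) and the parameters used.
#' @export
compare_with_ground_truth <- function(gt, tested,
                                      method = c("hungarian", "best"),
                                      delta_time = 0.4, min_score = 0.5,
                                      well_detected_threshold = 0.8,
                                      false_positive_threshold = 0.2) {
  method <- match.arg(method)
  agreement <- compute_agreement_matrix(gt, tested, delta_time = delta_time)
  delta_frames <- attr(agreement, "delta_frames")
  hmatch <- hungarian_match(agreement, min_score = min_score)
  gt_ids <- unit_ids(gt)
  assigned <- if (method == "hungarian") {
    hmatch$a_to_b
  } else {
    bm <- best_match(agreement, min_score = min_score)
    vapply(gt_ids, function(g) {
      if (nrow(bm[[g]]) > 0) bm[[g]]$unit[1L] else NA_character_
    }, character(1))
  }
  counts <- data.frame(gt_unit = gt_ids, tested_unit = assigned,
                       tp = 0, fn = 0, fp = 0, stringsAsFactors = FALSE)
  perf <- data.frame(gt_unit = gt_ids, accuracy = 0, recall = 0, precision = NA_real_,
                     miss_rate = 1, false_discovery_rate = NA_real_,
                     stringsAsFactors = FALSE)
  for (i in seq_along(gt_ids)) {
    g <- gt_ids[i]
    n_gt <- length(gt$spike_trains[[g]])
    if (is.na(assigned[[g]])) {
      counts$tp[i] <- 0; counts$fn[i] <- n_gt; counts$fp[i] <- 0
      next
    }
    lc <- label_spikes(gt$spike_trains[[g]], tested$spike_trains[[assigned[[g]]]],
                       delta_frames)
    counts$tp[i] <- lc$tp; counts$fn[i] <- lc$fn; counts$fp[i] <- lc$fp
    pm <- performance_measures(lc)
    perf$accuracy[i] <- pm$accuracy
    perf$recall[i] <- pm$recall
    perf$precision[i] <- pm$precision
    perf$miss_rate[i] <- pm$miss_rate
    perf$false_discovery_rate[i] <- pm$false_discovery_rate
  }
  classification <- classify_units(agreement, hmatch,
                                   well_detected_threshold = well_detected_threshold,
                                   false_positive_threshold = false_positive_threshold)
  structure(list(
    agreement = agreement, match = hmatch, counts = counts,
    performance = perf, classification = classification,
    params = list(method = method, delta_time = delta_time,
                  min_score = min_score,
                  well_detected_threshold = well_detected_threshold,
                  false_positive_threshold = false_positive_threshold)
  ), class = "GroundTruthComparison")
}

#' @export
print.GroundTruthComparison <- function(x, ...) {
  cat(sprintf("Ground-truth comparison: %d gt units vs %d tested units\n",
              nrow(x$agreement), ncol(x$agreement)))
  cat(sprintf("mean accuracy %.3f | categories: %s\n",
              mean(x$performance$accuracy),
              paste(sprintf("%s=%d", names(table(x$classification$category)),
                            as.integer(table(x$classification$category))),
                    collapse = ", ")))
  invisible(x)
}
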