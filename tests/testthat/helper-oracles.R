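# Independent oracles used to verify the package's matching machinery.
# These deliberately do NOT share code with the implementation: matching is
# Kuhn's augmenting-path maximum bipartite matching, assignment is an
# exhaustive search over permutations.

# maximum one-to-one pairing size between two trains under |t1-t2| <= delta
oracle_max_matching <- function(t1, t2, delta) {
  n1 <- length(t1); n2 <- length(t2)
  if (n1 == 0L || n2 == 0L) return(0L)
  adj <- lapply(seq_len(n1), function(i) which(abs(t2 - t1[i]) <= delta))
  match2 <- rep(0L, n2)
  visited <- rep(FALSE, n2)
  aug <- function(i) {
    for (j in adj[[i]]) {
      if (!visited[j]) {
        visited[j] <<- TRUE
        if (match2[j] == 0L || aug(match2[j])) {
          match2[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  cnt <- 0L
  for (i in seq_len(n1)) {
    visited[] <- FALSE
    if (aug(i)) cnt <- cnt + 1L
  }
  cnt
}

perm_cache <- new.env(parent = emptyenv())

all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  p <- if (n == 1L) matrix(1L, 1L, 1L) else {
    sub <- all_perms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
      cbind(k, sub + (sub >= k))
    }))
  }
  perm_cache[[key]] <- p
  p
}

# maximum total score of an injective row->column assignment (non-negative
# scores, so it equals the maximum-weight matching total)
oracle_assignment_total <- function(m) {
  if (nrow(m) > ncol(m)) m <- t(m)
  nr <- nrow(m); nc <- ncol(m)
  if (nr == 0L) return(0)
  perms <- all_perms(nc)
  totals <- vapply(seq_len(nrow(perms)), function(r) {
    sum(m[cbind(seq_len(nr), perms[r, seq_len(nr)])])
  }, 1)
  max(totals)
}

# random strictly increasing integer train
random_train <- function(n, max_frame = 1000L) {
  if (n == 0L) return(numeric(0))
  sort(sample.int(max_frame, n)) - 1
}

hungarian_total <- function(match_result) {
  sum(match_result$scores_a, na.rm = TRUE)
}
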