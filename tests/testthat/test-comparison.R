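test_that("matched-spike counting follows the examples and the oracle", {
  t <- c(100, 200, 300)
  expect_identical(count_matched_spikes(t, t, 0)$n_matches, 3L)
  expect_identical(count_matched_spikes(t, t, 12)$n_matches, 3L)
  expect_identical(count_matched_spikes(c(100, 200, 300),
                                        c(100, 205, 400), 12)$n_matches, 2L)
  # injectivity: one spike can absorb only one partner
  expect_identical(count_matched_spikes(c(100, 101), c(100), 5)$n_matches, 1L)
  expect_identical(count_matched_spikes(numeric(0), t, 5)$n_matches, 0L)
  expect_error(count_matched_spikes(c(5, 1), t, 5), "increasing")
  expect_error(count_matched_spikes(t, t, -1), "non-negative")
})

test_that("greedy sweep equals brute-force maximum matching on random pairs", {
  set.seed(101)
  for (i in 1:200) {
    t1 <- random_train(sample(0:15, 1), 300L)
    t2 <- random_train(sample(0:15, 1), 300L)
    delta <- sample(0:20, 1)
    expect_identical(count_matched_spikes(t1, t2, delta)$n_matches,
                     oracle_max_matching(t1, t2, delta))
  }
})

test_that("agreement score algebra", {
  expect_equal(agreement_score(list(n1 = 100, n2 = 100, n_matches = 100)), 1)
  expect_equal(agreement_score(list(n1 = 100, n2 = 80, n_matches = 0)), 0)
  expect_equal(agreement_score(list(n1 = 100, n2 = 80, n_matches = 60)), 0.5)
  expect_equal(agreement_score(list(n1 = 0, n2 = 0, n_matches = 0)), 0)
  # symmetry
  expect_equal(agreement_score(list(n1 = 30, n2 = 70, n_matches = 20)),
               agreement_score(list(n1 = 70, n2 = 30, n_matches = 20)))
  expect_error(agreement_score(list(n1 = 2, n2 = 2, n_matches = 3)), "exceeds")
})

test_that("agreement matrices match a naive recomputation and are symmetric", {
  set.seed(7)
  a <- Sorting(list(a1 = random_train(20, 30000), a2 = random_train(15, 30000),
                    a3 = random_train(10, 30000)), 30000)
  b <- Sorting(list(b1 = random_train(18, 30000), b2 = random_train(12, 30000)),
               30000)
  m <- compute_agreement_matrix(a, b, delta_time = 0.4)
  delta <- round(0.4 * 30000 / 1000)
  for (i in unit_ids(a)) {
    for (j in unit_ids(b)) {
      nm <- oracle_max_matching(spike_train(a, i), spike_train(b, j), delta)
      n1 <- length(spike_train(a, i)); n2 <- length(spike_train(b, j))
      expect_equal(m[i, j], if (n1 + n2 - nm == 0) 0 else nm / (n1 + n2 - nm))
    }
  }
  expect_equal(unclass(compute_agreement_matrix(b, a))[unit_ids(b), unit_ids(a)],
               t(unclass(m)[unit_ids(a), unit_ids(b)]))
  # identical sortings have a unit diagonal
  mm <- compute_agreement_matrix(a, a)
  expect_equal(unname(diag(unclass(mm))), rep(1, 3))
  # empty second sorting: zero columns
  expect_identical(ncol(compute_agreement_matrix(a, Sorting(list(), 30000))), 0L)
  expect_error(compute_agreement_matrix(a, Sorting(list(x = 1), 20000)),
               "frequencies")
})

test_that("agreement scores are monotone in the matching window", {
  set.seed(9)
  for (i in 1:50) {
    t1 <- random_train(sample(1:20, 1), 500L)
    t2 <- random_train(sample(1:20, 1), 500L)
    scores <- vapply(c(0, 2, 5, 10, 25, 100), function(d) {
      agreement_score(count_matched_spikes(t1, t2, d))
    }, 1)
    expect_true(all(diff(scores) >= 0))
  }
})

test_that("Hungarian assignment maximizes total agreement", {
  m <- matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2,
              dimnames = list(c("A1", "A2"), c("B1", "B2")))
  h <- hungarian_match(m, min_score = 0)
  expect_identical(unname(h$a_to_b), c("B1", "B2"))
  expect_equal(hungarian_total(h), 1.7)

  ident <- diag(3); dimnames(ident) <- list(letters[1:3], LETTERS[1:3])
  hi <- hungarian_match(ident, 0)
  expect_identical(unname(hi$a_to_b), c("A", "B", "C"))

  flat <- matrix(0.3, 2, 2)
  expect_true(all(is.na(hungarian_match(flat, min_score = 0.5)$a_to_b)))
  # mutually consistent directions
  expect_identical(h$b_to_a[h$a_to_b[["A1"]]], c(B1 = "A1"))
})

test_that("Hungarian equals exhaustive permutation search on random matrices", {
  set.seed(17)
  for (i in 1:100) {
    nr <- sample(1:5, 1); nc <- sample(1:5, 1)
    m <- matrix(runif(nr * nc), nr, nc)
    h <- hungarian_match(m, min_score = 0)
    expect_equal(hungarian_total(h), oracle_assignment_total(m), tolerance = 1e-9)
  }
})

test_that("best match lists all units above threshold in score order", {
  m <- matrix(c(0.6, 0.3, 0.55), 1, 3,
              dimnames = list("g", c("u1", "u2", "u3")))
  bm <- best_match(m, min_score = 0.5)
  expect_identical(bm$g$unit, c("u1", "u3"))
  expect_equal(bm$g$score, c(0.6, 0.55))
  expect_identical(nrow(best_match(m, min_score = 0.7)$g), 0L)

  set.seed(3)
  big <- matrix(runif(20), 4, 5, dimnames = list(paste0("g", 1:4), paste0("u", 1:5)))
  bm2 <- best_match(big, 0.4)
  for (g in rownames(big)) {
    naive <- sort(big[g, big[g, ] >= 0.4], decreasing = TRUE)
    expect_equal(setNames(bm2[[g]]$score, bm2[[g]]$unit), naive)
  }
})

test_that("spike labeling and performance formulas", {
  t <- c(10, 60, 110)
  l <- label_spikes(t, t, 0)
  expect_identical(unclass(l)[c("tp", "fn", "fp")], list(tp = 3L, fn = 0L, fp = 0L))
  l2 <- label_spikes(t, numeric(0), 5)
  expect_identical(l2$fn, 3L)
  l3 <- label_spikes(c(100, 200, 300, 400), c(100, 200, 505), 12)
  expect_identical(c(l3$tp, l3$fn, l3$fp), c(2L, 2L, 1L))
  # conservation: tp + fn = gt count, tp + fp = tested count
  set.seed(5)
  for (i in 1:25) {
    g <- random_train(sample(0:20, 1), 400L)
    s <- random_train(sample(0:20, 1), 400L)
    lc <- label_spikes(g, s, 10)
    expect_identical(lc$tp + lc$fn, length(g))
    expect_identical(lc$tp + lc$fp, length(s))
  }

  pm <- performance_measures(list(tp = 8, fn = 1, fp = 1))
  expect_equal(pm$accuracy, 0.8)
  expect_equal(pm$recall, 8 / 9)
  expect_equal(pm$precision, 8 / 9)
  expect_equal(pm$miss_rate, 1 / 9)
  expect_equal(pm$false_discovery_rate, 1 / 9)
  perfect <- performance_measures(list(tp = 5, fn = 0, fp = 0))
  expect_equal(unlist(unclass(perfect)),
               c(accuracy = 1, recall = 1, precision = 1, miss_rate = 0,
                 false_discovery_rate = 0))
  expect_equal(performance_measures(list(tp = 0, fn = 5, fp = 5))$accuracy, 0)
  expect_error(performance_measures(list(tp = 0, fn = 0, fp = 0)), "undefined")
})

test_that("ground-truth comparison of a sorting with itself is perfect", {
  gt <- generate_gt_sorting(n_units = 4, duration = 30, seed = 21)
  cmp <- compare_with_ground_truth(gt, gt)
  expect_true(all(cmp$performance$accuracy == 1))
  expect_true(all(cmp$classification$category == "well_detected"))
  expect_identical(unname(cmp$match$a_to_b), unit_ids(gt))
})

test_that("unit classification identifies planted failure modes", {
  gt <- generate_gt_sorting(n_units = 3, duration = 60, firing_rate = 5, seed = 33)
  fs <- gt$sampling_frequency

  # planted pure-noise extra unit -> false_positive
  tested <- corrupt_sorting(gt, n_noise_units = 1, seed = 1)
  cmp <- compare_with_ground_truth(gt, tested)
  cl <- setNames(cmp$classification$category, cmp$classification$unit_id)
  expect_identical(unname(cl[unit_ids(gt)]), rep("well_detected", 3))
  expect_identical(unname(cl[["noise1"]]), "false_positive")

  # planted even split -> the non-best half is redundant
  split <- corrupt_sorting(gt, split_units = "2", seed = 2)
  cmp2 <- compare_with_ground_truth(gt, split)
  cl2 <- setNames(cmp2$classification$category, cmp2$classification$unit_id)
  halves <- cl2[c("2_split1", "2_split2")]
  expect_identical(sort(unname(halves)), c("redundant", "weak_match"))
  # hand-check the planted agreement: n/2 matches of n gt spikes
  n <- length(spike_train(gt, "2"))
  expect_equal(cmp2$agreement["2", "2_split1"],
               ceiling(n / 2) / (n + ceiling(n / 2) - ceiling(n / 2)),
               tolerance = 1e-12)

  # planted merge of two units -> overmerged
  merged <- corrupt_sorting(gt, merge_unit_pairs = list(c("1", "3")), seed = 3)
  cmp3 <- compare_with_ground_truth(gt, merged)
  cl3 <- setNames(cmp3$classification$category, cmp3$classification$unit_id)
  expect_identical(unname(cl3[["1+3"]]), "overmerged")

  # unmatched gt unit keeps recall 0
  dropped <- select_units(gt, c("1", "2"))
  cmp4 <- compare_with_ground_truth(gt, dropped)
  expect_equal(cmp4$performance$recall[cmp4$performance$gt_unit == "3"], 0)
})
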