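test_that("confusion counts are pure set arithmetic", {
  expect_equal(score_calls(c("a", "b", "c"), c("a", "b", "c")),
               tibble::tibble(TP = 3L, FP = 0L, FN = 0L))
  expect_equal(score_calls(c("a", "b", "c"), c("a", "d")),
               tibble::tibble(TP = 1L, FP = 1L, FN = 2L))
  expect_equal(score_calls(character(0), character(0)),
               tibble::tibble(TP = 0L, FP = 0L, FN = 0L))
})

test_that("precision, recall and F follow their definitions", {
  out <- precision_recall_f(data.frame(TP = 3, FP = 1, FN = 2))
  expect_equal(out$precision, 0.75)
  expect_equal(out$recall, 0.6)
  expect_equal(out$f_score, 2 * 0.45 / 1.35)

  perfect <- precision_recall_f(data.frame(TP = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect[, c("precision", "recall", "f_score")]),
               c(precision = 1, recall = 1, f_score = 1))

  # 0/0 cases are undefined, not zero
  none <- precision_recall_f(data.frame(TP = 0, FP = 0, FN = 3))
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)

  # precision == recall implies F equals them (harmonic-mean symmetry)
  set.seed(2)
  for (i in 1:20) {
    tp <- sample(1:10, 1); k <- sample(0:10, 1)
    r <- precision_recall_f(data.frame(TP = tp, FP = k, FN = k))
    expect_equal(r$f_score, r$precision)
    # F lies between precision and recall generally
    r2 <- precision_recall_f(data.frame(TP = tp, FP = sample(0:10, 1),
                                        FN = sample(0:10, 1)))
    if (!is.na(r2$f_score) && r2$f_score > 0) {
      expect_gte(r2$f_score, min(r2$precision, r2$recall) - 1e-12)
      expect_lte(r2$f_score, max(r2$precision, r2$recall) + 1e-12)
    }
  }
})

test_that("run_grid produces conserving, reproducible records", {
  g <- run_grid(replicates = 3, n_changed = c(5, 10), fold_change = 4,
                thresholds = data.frame(alpha = 0.05, bf_threshold = 1.5),
                iterations = 2, seed = 77, bootstrap_iters = 200)
  # 2 combos x 2 iterations x 3 methods
  expect_equal(nrow(g), 12)
  # conservation: TP + FN = n_changed, TP + FP = number of calls >= TP
  expect_true(all(g$TP + g$FN == g$n_changed))
  expect_true(all(g$TP + g$FP >= g$TP))
  expect_false(any(g$failed))

  g2 <- run_grid(replicates = 3, n_changed = c(5, 10), fold_change = 4,
                 thresholds = data.frame(alpha = 0.05, bf_threshold = 1.5),
                 iterations = 2, seed = 77, bootstrap_iters = 200)
  expect_identical(as.data.frame(g), as.data.frame(g2))

  s <- summarize_grid(g)
  expect_equal(nrow(s), 6)
  expect_true(all(s$mean_f >= 0 & s$mean_f <= 1, na.rm = TRUE))
})

test_that("summary means exclude undefined precision rather than zeroing it", {
  g <- tibble::tibble(
    method = "nb_exact", replicates = 3, n_changed = 5, fold_change = 2,
    alpha = 0.05, bf_threshold = 1.5, iteration = 1:3, failed = FALSE,
    TP = c(0L, 4L, 5L), FP = c(0L, 1L, 0L), FN = c(5L, 1L, 0L)
  )
  s <- summarize_grid(precision_recall_f(g))
  expect_equal(s$mean_precision, mean(c(4 / 5, 1)))   # the 0/0 iteration drops
  expect_equal(s$mean_recall, mean(c(0, 4 / 5, 1)))   # recall is defined there
})

test_that("mean recall grows with replication and with fold change", {
  base <- list(n_changed = 10,
               thresholds = data.frame(alpha = 0.05, bf_threshold = 1.5),
               iterations = 5, seed = 2024, bootstrap_iters = 200)
  g <- do.call(run_grid, c(base, list(replicates = c(3, 10),
                                      fold_change = c(1.5, 4))))
  s <- summarize_grid(g)
  for (m in unique(s$method)) {
    sm <- s[s$method == m, ]
    for (f in unique(sm$fold_change)) {
      lo <- sm$mean_recall[sm$fold_change == f & sm$replicates == 3]
      hi <- sm$mean_recall[sm$fold_change == f & sm$replicates == 10]
      expect_gte(hi, lo - 0.05)
    }
    for (r in unique(sm$replicates)) {
      lo <- sm$mean_recall[sm$replicates == r & sm$fold_change == 1.5]
      hi <- sm$mean_recall[sm$replicates == r & sm$fold_change == 4]
      expect_gte(hi, lo - 0.05)
    }
  }
})

test_that("benchmark_verdict surfaces the strongest method per cell", {
  g <- run_grid(replicates = 5, n_changed = c(5, 20), fold_change = 4,
                thresholds = data.frame(alpha = 0.05, bf_threshold = 1.5),
                iterations = 2, seed = 10, bootstrap_iters = 200)
  v <- benchmark_verdict(summarize_grid(g))
  expect_named(v, c("by_cell", "by_n_changed"))
  expect_true(all(v$by_cell$best_method %in%
                  c("nb_exact", "bootstrap_t", "bayes_factor")))
  expect_equal(sort(unique(v$by_n_changed$n_changed)), c(5, 20))
})
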