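toy_partition <- function(labels, ids = NULL) {
  ids <- ids %||% paste0("m", seq_along(labels))
  tibble::tibble(id = ids, cluster = as.integer(labels))
}

toy_activity <- function(classes, ids = NULL) {
  ids <- ids %||% paste0("m", seq_along(classes))
  tibble::tibble(id = ids, class = factor(classes, levels = unique(classes)))
}

test_that("cluster precision/recall/F follow the defining formulas", {
  prf <- cluster_prf(3, 4, 4)
  expect_equal(prf$precision, 0.75)
  expect_equal(prf$recall, 0.75)
  expect_equal(prf$f, 0.75)
  expect_equal(cluster_prf(5, 5, 5)$f, 1)
  expect_equal(cluster_prf(0, 4, 4)$f, 0)
  expect_error(cluster_prf(0, 4, 0), "A = 0")
})

test_that("the partition F-measure is the best cluster F", {
  act <- toy_activity(rep(c("a", "b"), each = 4))
  pure <- toy_partition(rep(1:2, each = 4))
  expect_equal(f_measure(pure, act, "a"), 1)
  expect_equal(f_measure(pure, act, "b"), 1)
  # everything in one cluster: P = A/n, R = 1
  lump <- toy_partition(rep(1, 8))
  expect_equal(f_measure(lump, act, "a"), 2 * (4 / 8) / (4 / 8 + 1))
  # all singletons: best F = 2 / (A + 1)
  single <- toy_partition(1:8)
  expect_equal(f_measure(single, act, "a"), 2 / (4 + 1))
  expect_error(f_measure(pure, act, "zzz"), "unknown activity class")
})

test_that("QPI tallies follow the active-cluster rule", {
  # 10 molecules, A = 4: {3 actives + 1 inactive}, {1 active singleton},
  # {5 inactives} -> active fraction 0.75 > 0.4 -> p=3 q=1 r=0 s=1 -> 0.6
  act <- toy_activity(c(rep("act", 4), rep("inact", 6)))
  p <- toy_partition(c(1, 1, 1, 2, 1, 3, 3, 3, 3, 3))
  tl <- qpi_counts(p, act, "act")
  expect_equal(unlist(tl[c("p", "q", "r", "s")]),
               c(p = 3, q = 1, r = 0, s = 1))
  expect_equal(qpi(p, act, "act"), 0.6)
  # all singletons: p = 0 -> QPI 0
  expect_equal(qpi(toy_partition(1:10), act, "act"), 0)
  # actives exactly fill pure non-singleton clusters -> QPI 1
  p_pure <- toy_partition(c(1, 1, 2, 2, 3, 3, 3, 4, 4, 4))
  expect_equal(qpi(p_pure, act, "act"), 1)
  # equality with the dataset fraction does NOT make a cluster active
  act2 <- toy_activity(c("act", "act", "inact", "inact"))
  p_eq <- toy_partition(c(1, 2, 1, 2))  # each cluster 50% active = dataset 50%
  expect_equal(qpi(p_eq, act2, "act"), 0)
})

test_that("actives are conserved across the QPI tallies", {
  for (s in 1:25) {
    withr::with_seed(s, {
      n <- sample(8:30, 1)
      act <- toy_activity(sample(c("x", "y", "z"), n, TRUE,
                                 prob = c(0.3, 0.3, 0.4)))
      while (length(unique(act$class)) < 3) {
        act <- toy_activity(sample(c("x", "y", "z"), n, TRUE))
      }
      p <- toy_partition(sample.int(max(2, n %/% 3), n, TRUE))
      for (cl in levels(act$class)) {
        tl <- qpi_counts(p, act, cl)
        expect_equal(tl$p + tl$r + tl$s, tl$A)
        expect_gte(min(tl$p, tl$q, tl$r, tl$s), 0)
      }
    })
  }
})

test_that("QPI ignores relabelling and inactive-only cluster shuffles", {
  act <- toy_activity(c(rep("a", 5), rep("b", 7)))
  p <- toy_partition(c(1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4))
  relab <- toy_partition(c(4, 4, 4, 1, 1, 1, 2, 2, 2, 3, 3, 3))
  expect_equal(qpi(p, act, "a"), qpi(relab, act, "a"))
  expect_equal(f_measure(p, act, "a"), f_measure(relab, act, "a"))
})

test_that("splitting a mixed cluster into pure halves never lowers F", {
  for (s in 1:20) {
    withr::with_seed(s, {
      n <- 20
      act <- toy_activity(sample(c("a", "b"), n, TRUE))
      lab <- sample.int(4, n, TRUE)
      f0 <- f_measure(toy_partition(lab), act, "a")
      # split cluster 1 into its active and inactive parts
      lab2 <- lab
      lab2[lab == 1 & act$class == "a"] <- 5L
      f1 <- f_measure(toy_partition(lab2), act, "a")
      expect_gte(f1 + 1e-12, f0)
    })
  }
})

test_that("grid evaluation macro-averages per-class scores on the percent scale", {
  act <- toy_activity(rep(c("a", "b"), each = 4))
  # class a perfectly recovered; class b split in half
  parts <- tibble::tibble(
    id = paste0("m", 1:8), method = "cvaa", distance = "jaccard",
    k = 3L, cluster = c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L)
  )
  report <- evaluate_partitions(parts, act)
  f_a <- 1
  f_b <- 2 * (1 * 0.5) / (1 + 0.5)
  expect_equal(report$f, 100 * mean(c(f_a, f_b)))
  per_class <- tidy(report)
  expect_equal(nrow(per_class), 2)
  expect_true(all(report$f >= 100 * min(per_class$f) - 1e-9 &
                  report$f <= 100 * max(per_class$f) + 1e-9))
  # simple mean check: per-class F of 0.5 and 1.0 reports 75.00
  expect_equal(100 * mean(c(0.5, 1)), 75)
  expect_identical(evaluate_partitions(parts, act), report)
})

test_that("paired t-tests match the closed form and flag degeneracy", {
  tt <- paired_ttest(c(3, 5), c(2, 2))  # differences 1, 3
  expect_equal(tt$mean_diff, 2)
  expect_equal(tt$sd_diff, sqrt(2))
  expect_equal(tt$t_stat, 2)
  expect_equal(tt$df, 1)
  # closed-form dual route on a random vector
  withr::with_seed(8, {
    x <- rnorm(9); y <- rnorm(9)
    tt2 <- paired_ttest(x, y)
    d <- x - y
    expect_equal(tt2$t_stat, mean(d) / (sd(d) / 3))
    expect_equal(tt2$p_two_tailed, 2 * pt(-abs(tt2$t_stat), 8))
    expect_equal(tt2$ci95_low, mean(d) - qt(0.975, 8) * sd(d) / 3)
  })
  deg <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_equal(deg$mean_diff, 0)
  expect_true(is.na(deg$t_stat))
  expect_error(paired_ttest(1:3, 1:2), "equal length")
})

test_that("method comparison pairs the per-k best rows", {
  report <- tibble::tibble(
    method = rep(c("cvaa", "cvaa", "ward"), each = 2),
    distance = c("jaccard", "jaccard", "euclidean", "euclidean", NA, NA),
    k = rep(c(5L, 10L), 3),
    f = c(80, 70, 90, 60, 50, 40),
    qpi = c(80, 70, 90, 60, 50, 40)
  )
  best <- best_per_k(report, "cvaa", "f")
  expect_equal(best$value, c(90, 70))
  # best_row: mean tie between rows breaks alphabetically -> euclidean (90, 60)
  expect_equal(best_row(report, "cvaa", "f")$value, c(90, 60))
  tt <- compare_methods(report, "cvaa", "ward", "f")
  expect_equal(tt$mean_diff, mean(c(90 - 50, 60 - 40)))
  expect_equal(attr(tt, "pair"), "cvaa - ward")
  tt_max <- compare_methods(report, "cvaa", "ward", "f", selection = "per_k_max")
  expect_equal(tt_max$mean_diff, mean(c(90 - 50, 70 - 40)))
})
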