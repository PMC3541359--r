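test_that("co-association counts same-cluster votes exactly", {
  ens <- ens_from_labels(list(a = c(1, 1, 2), b = c(1, 2, 2)))
  S <- coassociation(ens)
  expect_equal(S[1, 2], 0.5)
  expect_equal(S[2, 3], 0.5)
  expect_equal(S[1, 3], 0)
  expect_equal(diag(S), rep(1, 3), ignore_attr = TRUE)
  expect_equal(attr(S, "r"), 2)
  # r = 1: binary entries
  S1 <- coassociation(ens_from_labels(list(a = c(1, 1, 2))))
  expect_true(all(S1 %in% c(0, 1)))
  # identical members: block matrix of the shared partition
  Sb <- coassociation(ens_from_labels(list(a = c(1, 2, 1), b = c(2, 1, 2))))
  expect_equal(unname(Sb), rbind(c(1, 0, 1), c(0, 1, 0), c(1, 0, 1)),
               ignore_attr = TRUE)
})

test_that("co-association is invariant to relabelling and member order and quantised to 1/r", {
  for (s in 1:10) {
    withr::with_seed(s, {
      n <- sample(5:12, 1)
      l1 <- sample.int(3, n, TRUE); l2 <- sample.int(4, n, TRUE)
      l3 <- sample.int(2, n, TRUE)
      ens <- ens_from_labels(list(a = l1, b = l2, c = l3))
      S <- coassociation(ens)
      expect_equal(unname(S * 3), round(unname(S * 3)))  # multiples of 1/r
      perm_lab <- function(l) {
        p <- sample(max(l)); p[l]
      }
      ens2 <- ens_from_labels(list(a = perm_lab(l3), b = perm_lab(l1),
                                   c = perm_lab(l2)))
      expect_equal(unname(coassociation(ens2)), unname(S))
    })
  }
})

test_that("CSPA recovers block structure with zero cut", {
  # two perfectly agreeing 2-cluster members over 8 vertices
  lab <- c(1, 1, 1, 1, 2, 2, 2, 2)
  ens <- ens_from_labels(list(a = lab, b = c(2, 2, 2, 2, 1, 1, 1, 1)))
  S <- coassociation(ens)
  p <- cspa_partition(S, 2)
  expect_equal(ari(p$cluster, lab), 1)
  # oracle: exhaustive over balanced 2-partitions — the shared partition is
  # the unique zero-cut optimum
  W <- S; diag(W) <- 0
  opt <- oracle_min_weight_cut(W, 2, cap = 5)
  expect_equal(opt$min, 0)
  expect_equal(ari(opt$argmin, lab), 1)
  expect_equal(cut_of(W, p$cluster), 0)
  # k blocks returned exactly for a block-diagonal matrix
  lab3 <- rep(1:3, times = c(3, 3, 3))
  ens3 <- ens_from_labels(list(a = lab3, b = lab3, c = lab3))
  p3 <- cspa_partition(ens3, 3)
  expect_equal(ari(p3$cluster, lab3), 1)
  expect_error(cspa_partition(S, 9), "out of range")
})

test_that("CSPA never beats the exhaustive optimum and nails zero-cut cases", {
  for (s in 1:25) {
    withr::with_seed(s, {
      n <- sample(6:9, 1)
      k <- 2
      labs <- lapply(1:3, function(i) sample.int(k, n, TRUE))
      names(labs) <- paste0("m", 1:3)
      ens <- ens_from_labels(labs)
      S <- coassociation(ens)
      W <- S; diag(W) <- 0
      cap <- max(ceiling(n / k), floor(ceiling(n / k) * 1.25))
      p <- cspa_partition(S, k)
      opt <- oracle_min_weight_cut(W, k, cap)
      got <- cut_of(W, p$cluster)
      expect_gte(got + 1e-9, opt$min)
      if (opt$min == 0) expect_equal(got, 0)
    })
  }
})

test_that("HGPA recovers identical ensembles with zero hyperedges cut", {
  lab <- rep(1:3, each = 4)
  ens <- ens_from_labels(list(a = lab, b = lab, c = lab))
  p <- hgpa_partition(ens, 3, seed = 5)
  expect_equal(ari(p$cluster, lab), 1)
  expect_equal(hyperedge_cut_of(ensemble_hyperedges(ens), p$cluster), 0)
  p1 <- hgpa_partition(ens, 1, seed = 5)
  expect_equal(unique(p1$cluster), 1L)
  expect_error(hgpa_partition(ens, 13), "out of range")
})

test_that("HGPA cuts are within one hyperedge of the exhaustive optimum", {
  gaps <- numeric(0)
  for (s in 1:50) {
    withr::with_seed(1000 + s, {
      n <- sample(6:9, 1)
      k <- sample(2:3, 1)
      b <- sample(2:3, 1)
      labs <- lapply(seq_len(b), function(i) {
        kk <- sample(2:3, 1)
        c(seq_len(kk), sample.int(kk, n - kk, TRUE))
      })
      names(labs) <- paste0("m", seq_len(b))
      ens <- ens_from_labels(labs)
      edges <- ensemble_hyperedges(ens)
      cap <- max(ceiling(n / k), floor(ceiling(n / k) * 1.25))
      p <- hgpa_partition(ens, k, seed = s)
      got <- hyperedge_cut_of(edges, p$cluster)
      opt <- oracle_min_hyperedge_cut(edges, n, k, cap)
      expect_gte(got, opt)
      gaps <- c(gaps, got - opt)
    })
  }
  expect_lte(max(gaps), 1)
})

test_that("both graph consensus functions are seed-deterministic", {
  ds <- planted_fixture(n_classes = 3, size = 8, m = 128, seed = 77)
  ens <- generate_ensemble(ds$fingerprints, "hamming", 3, seed = 2)
  expect_identical(cspa_partition(ens, 3, seed = 9)$cluster,
                   cspa_partition(ens, 3, seed = 9)$cluster)
  expect_identical(hgpa_partition(ens, 3, seed = 9)$cluster,
                   hgpa_partition(ens, 3, seed = 9)$cluster)
})

test_that("plug-in partitioners are honoured", {
  lab <- c(1, 1, 2, 2)
  ens <- ens_from_labels(list(a = lab, b = lab))
  fixed <- function(W, k, balance_slack, seed) c(1L, 2L, 1L, 2L)
  p <- cspa_partition(ens, 2, partitioner = fixed)
  expect_equal(p$cluster, c(1L, 2L, 1L, 2L))
  fixed_h <- function(edges, n, k, balance_slack, seed) rep(1:2, length.out = n)
  ph <- hgpa_partition(ens, 2, partitioner = fixed_h)
  expect_equal(ph$cluster, c(1L, 2L, 1L, 2L))
})
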