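test_that("membership matrices are hard indicator matrices", {
  U <- to_membership(c(1L, 1L, 2L), k = 2)
  expect_equal(unname(U), rbind(c(1, 0), c(1, 0), c(0, 1)))
  expect_equal(rowSums(U), rep(1, 3))
  expect_error(to_membership(c(1L, 3L), k = 2), "outside 1..2")
})

test_that("the Ward member is the reference, and must be unique", {
  ens <- ens_from_labels(list(single = c(1, 1, 2, 2), ward = c(1, 2, 2, 2)))
  U0 <- select_reference(ens)
  expect_equal(unname(U0), to_membership(c(1L, 2L, 2L, 2L), 2),
               ignore_attr = TRUE)
  no_ward <- ens_from_labels(list(single = c(1, 1, 2, 2), kmeans = c(1, 2, 2, 2)))
  expect_error(select_reference(no_ward), "no Ward member")
  two_ward <- ens_from_labels(list(ward = c(1, 1, 2, 2)))
  two_ward <- dplyr::bind_rows(two_ward, two_ward)
  attr(two_ward, "ids") <- paste0("mol", 1:4)
  class(two_ward) <- c("chem_ensemble", class(two_ward))
  expect_error(select_reference(two_ward), "multiple Ward")
})

test_that("vote weights reduce to per-cluster membership means", {
  U0 <- to_membership(c(1L, 1L, 2L), k = 2)
  expect_equal(unname(vote_weights(U0, U0)), diag(2))
  Ui <- to_membership(c(1L, 1L, 2L), k = 2)       # {1,2},{3}
  U0b <- to_membership(c(1L, 2L, 2L), k = 2)      # {1},{2,3}
  expect_equal(unname(vote_weights(Ui, U0b)), rbind(c(0.5, 0.5), c(0, 1)))
  bad <- matrix(c(1, 1, 0, 0, 0, 0), 3, 2)        # empty second column
  expect_error(vote_weights(bad, U0), "empty")
})

test_that("counting form equals the explicit matrix formula on 200 random instances", {
  for (s in 1:200) {
    withr::with_seed(s, {
      n <- sample(4:12, 1)
      ki <- sample(2:4, 1)
      k0 <- sample(2:4, 1)
      li <- c(seq_len(ki), sample.int(ki, n - ki, replace = TRUE))
      l0 <- c(seq_len(k0), sample.int(k0, n - k0, replace = TRUE))
      Ui <- to_membership(li, ki)
      # soft reference: random row-stochastic matrix
      U0 <- matrix(rexp(n * k0), n, k0)
      U0 <- U0 / rowSums(U0)
      W_counting <- vote_weights(Ui, U0)
      W_matrix <- solve(t(Ui) %*% Ui) %*% t(Ui) %*% U0
      expect_lt(max(abs(W_counting - W_matrix)), 1e-12)
      expect_equal(rowSums(W_counting), rep(1, ki), tolerance = 1e-12)
    })
  }
})

test_that("the four-molecule aggregation reproduces the exact fractions", {
  ens <- ens_from_labels(list(ward = c(1, 1, 2, 2),
                              m2 = c(1, 1, 1, 2),
                              m3 = c(1, 2, 2, 2)))
  fit <- cvaa_aggregate(ens)
  expect_equal(unname(fit$membership[, 1]),
               c(5 / 6, 37 / 54, 19 / 54, 7 / 54), tolerance = 1e-12)
  expect_equal(unname(rowSums(fit$membership)), rep(1, 4), tolerance = 1e-12)
  # straight-line oracle executing the algorithm with explicit inversion
  oracle <- oracle_cvaa(list(c(1L, 1L, 2L, 2L), c(1L, 1L, 1L, 2L),
                             c(1L, 2L, 2L, 2L)), ref_index = 1)
  expect_lt(max(abs(fit$membership - oracle)), 1e-12)
  hardened <- harden(fit)
  expect_equal(hardened$cluster, c(1L, 1L, 2L, 2L))
})

test_that("hardening takes the argmax with low-index ties", {
  expect_equal(harden(rbind(c(0.6, 0.4), c(0.5, 0.5)))$cluster, c(1L, 1L))
  # empty columns dropped with re-indexing
  U <- rbind(c(0.1, 0.9, 0), c(0.2, 0.8, 0))
  expect_equal(harden(U)$cluster, c(1L, 1L))
  expect_error(harden(rbind(c(0.7, 0.7))), "sum to 1")
})

test_that("aggregation is row-stochastic and fixes identical ensembles", {
  for (s in 1:20) {
    withr::with_seed(s, {
      n <- sample(6:15, 1)
      k <- sample(2:4, 1)
      labs <- lapply(1:5, function(i) c(seq_len(k), sample.int(k, n - k, TRUE)))
      names(labs) <- c("single", "complete", "average", "ward", "kmeans")
      ens <- ens_from_labels(labs)
      fit <- cvaa_aggregate(ens)
      expect_equal(unname(rowSums(fit$membership)), rep(1, n), tolerance = 1e-9)
      expect_true(all(fit$membership >= -1e-12 & fit$membership <= 1 + 1e-12))
    })
  }
  same <- c(1, 1, 2, 2, 3, 3, 1)
  ens <- ens_from_labels(list(single = same, ward = same, kmeans = same))
  expect_equal(ari(harden(cvaa_aggregate(ens))$cluster, same), 1)
})

test_that("relabelling a non-reference member leaves the consensus unchanged", {
  ens1 <- ens_from_labels(list(ward = c(1, 1, 2, 2, 3),
                               kmeans = c(1, 2, 2, 3, 3)))
  relab <- c(3L, 1L, 1L, 2L, 2L)  # permute kmeans labels (1->3, 2->1, 3->2)
  ens2 <- ens_from_labels(list(ward = c(1, 1, 2, 2, 3), kmeans = relab))
  expect_equal(cvaa_aggregate(ens1)$membership,
               cvaa_aggregate(ens2)$membership)
})

test_that("permuting molecules permutes the consensus rows identically", {
  labs <- list(ward = c(1, 1, 2, 2, 3, 3), complete = c(1, 2, 2, 3, 3, 1))
  ens <- ens_from_labels(labs, ids = paste0("m", 1:6))
  perm <- c(4, 1, 6, 2, 5, 3)
  labs_p <- lapply(labs, function(l) l[perm])
  ens_p <- ens_from_labels(labs_p, ids = paste0("m", 1:6)[perm])
  U <- cvaa_aggregate(ens)$membership
  Up <- cvaa_aggregate(ens_p)$membership
  expect_equal(unname(Up), unname(U[perm, ]))
})

test_that("tidy and glance summarise the consensus object", {
  ens <- ens_from_labels(list(ward = c(1, 1, 2, 2), kmeans = c(1, 2, 2, 2)))
  fit <- cvaa_aggregate(ens)
  td <- tidy(fit)
  expect_equal(nrow(td), 4 * fit$k)
  expect_equal(sum(td$membership), 4)
  gl <- glance(fit)
  expect_equal(gl$n, 4)
  expect_equal(gl$b, 2)
  expect_true(gl$mean_max_membership >= 0.5)
})
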