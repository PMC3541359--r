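# Graph-based consensus: CSPA (co-association similarity partitioning) and
# HGPA (hypergraph minimum hyperedge cut), each over a pluggable balanced
# k-way partitioner. The shipped partitioners are pure R: recursive spectral
# bisection with Kernighan-Lin-style boundary refinement for weighted
# graphs, and seeded multi-start greedy vertex moves (Fiduccia-Mattheyses
# flavoured) for hypergraphs. External partitioners can be plugged in
# through the `partitioner` argument as long as they honour the contract:
# non-empty parts, max part size <= ceiling(n/k) * (1 + balance_slack),
# objective = minimise inter-part similarity weight (CSPA) / number of cut
# hyperedges (HGPA).

#' Co-association matrix of an ensemble
#'
#' Entry (a, b) is the fraction of ensemble members placing molecules a and
#' b in the same cluster: pairs co-clustered by every member score 1, pairs
#' never co-clustered score 0, and every entry is an exact multiple of 1/r
#' (integer co-occurrence counts divided by the member count r at the end).
#'
#' @param ens A `chem_ensemble` tibble.
#' @return A symmetric n-by-n matrix with unit diagonal and attribute `"r"`.
#' @export
coassociation <- function(ens) {
  members <- ensemble_members(ens)
  ids <- attr(members, "ids")
  n <- length(ids)
  counts <- matrix(0L, n, n)
  for (labels in members) {
    counts <- counts + (outer(labels, labels, "==") * 1L)
  }
  S <- counts / length(members)
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  attr(S, "r") <- length(members)
  S
}

balance_cap <- function(n, k, balance_slack) {
  max(ceiling(n / k), floor(ceiling(n / k) * (1 + balance_slack)))
}

# --- balanced weighted-graph partitioner (for CSPA) ---------------------

# Fiedler vector with deterministic sign (largest-magnitude entry positive).
fiedler_vector <- function(W) {
  L <- diag(rowSums(W)) - W
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  v <- ev$vectors[, ncol(W) - 1]
  pivot <- which.max(abs(v))
  if (v[pivot] < 0) v <- -v
  v
}

# weight between side A and side B of subgraph W
cut_weight <- function(W, sideA) {
  sum(W[sideA, !sideA, drop = FALSE])
}

# Kernighan-Lin style pair-swap refinement keeping side sizes fixed.
kl_refine <- function(W, sideA, max_swaps = 50L) {
  for (s in seq_len(max_swaps)) {
    a_idx <- which(sideA); b_idx <- which(!sideA)
    # D_v = external - internal connection weight
    Dv <- numeric(length(sideA))
    Dv[a_idx] <- rowSums(W[a_idx, b_idx, drop = FALSE]) -
      rowSums(W[a_idx, a_idx, drop = FALSE])
    Dv[b_idx] <- rowSums(W[b_idx, a_idx, drop = FALSE]) -
      rowSums(W[b_idx, b_idx, drop = FALSE])
    gains <- outer(Dv[a_idx], Dv[b_idx], "+") - 2 * W[a_idx, b_idx, drop = FALSE]
    best <- arrayInd(which.max(gains), dim(gains))
    if (gains[best] <= 1e-12) break
    sideA[a_idx[best[1]]] <- FALSE
    sideA[b_idx[best[2]]] <- TRUE
  }
  sideA
}

# Recursive spectral bisection of a similarity subgraph into k parts.
# Handles disconnected subgraphs by pre-assigning whole components.
partition_graph_recursive <- function(W, k) {
  n <- nrow(W)
  if (k <= 1 || n == 1) return(rep(1L, n))
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no >= 2) {
    if (comp$no >= k) {
      # bin components into k parts, largest first into the lightest bin
      ord <- order(comp$csize, decreasing = TRUE)
      bin_of <- integer(comp$no)
      load <- numeric(k)
      for (ci in ord) {
        b <- which.min(load)
        bin_of[ci] <- b
        load[b] <- load[b] + comp$csize[ci]
      }
      return(as.integer(bin_of[comp$membership]))
    }
    # fewer components than parts: allocate parts proportionally, recurse
    alloc <- pmax(1L, round(comp$csize / n * k))
    while (sum(alloc) > k) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
    while (sum(alloc) < k) alloc[which.max(comp$csize / alloc)] <-
        alloc[which.max(comp$csize / alloc)] + 1L
    labels <- integer(n)
    offset <- 0L
    for (ci in seq_len(comp$no)) {
      idx <- which(comp$membership == ci)
      sub <- partition_graph_recursive(W[idx, idx, drop = FALSE], alloc[ci])
      labels[idx] <- sub + offset
      offset <- offset + max(sub)
    }
    return(labels)
  }
  k1 <- k %/% 2L
  n1 <- round(n * k1 / k)
  n1 <- min(max(n1, 1L), n - 1L)
  v <- fiedler_vector(W)
  ord <- order(v, seq_len(n))  # index tie-break for determinism
  sideA <- rep(FALSE, n)
  sideA[ord[seq_len(n1)]] <- TRUE
  sideA <- kl_refine(W, sideA)
  labels <- integer(n)
  ia <- which(sideA); ib <- which(!sideA)
  labels[ia] <- partition_graph_recursive(W[ia, ia, drop = FALSE], k1)
  labels[ib] <- partition_graph_recursive(W[ib, ib, drop = FALSE], k - k1) + k1
  labels
}

#' CSPA: re-partition the co-association graph into k balanced parts
#'
#' The co-association matrix is viewed as a weighted graph (vertex =
#' molecule, edge weight = co-association) and split into `k` parts
#' minimising the total inter-part similarity weight subject to the balance
#' contract. The default partitioner is deterministic recursive spectral
#' bisection with pair-swap refinement; disconnected graphs are handled by
#' pre-assigning whole components (a zero-cut solution when the component
#' count matches `k`).
#'
#' @param S Co-association matrix from [coassociation()], or a
#'   `chem_ensemble` (the matrix is then built internally).
#' @param k Number of consensus clusters, 2..n.
#' @param balance_slack Allowed relative excess of the largest part over
#'   ceiling(n/k); default 0.25.
#' @param seed Seed forwarded to plug-in partitioners (the default
#'   partitioner is deterministic and ignores it).
#' @param partitioner Optional plug-in `function(W, k, balance_slack, seed)`
#'   returning integer part labels honouring the contract above.
#' @return A partition tibble with method `"cspa"`.
#' @export
cspa_partition <- function(S, k, balance_slack = 0.25, seed = 1,
                           partitioner = NULL) {
  if (inherits(S, "chem_ensemble")) S <- coassociation(S)
  S <- as.matrix(S)
  n <- nrow(S)
  if (k < 2 || k > n) abort(sprintf("k = %d out of range 2..%d", k, n))
  W <- S
  diag(W) <- 0
  labels <- if (is.null(partitioner)) {
    partition_graph_recursive(W, as.integer(k))
  } else {
    as.integer(partitioner(W, as.integer(k), balance_slack, seed))
  }
  if (length(unique(labels)) > k) abort("partitioner returned more than k parts")
  new_partition(rownames(S) %||% as.character(seq_len(n)), labels,
                method = "cspa", k_requested = as.integer(k))
}

# --- hypergraph partitioner (for HGPA) ----------------------------------

#' Hyperedges of an ensemble
#'
#' One unit-weight hyperedge per cluster of every member (vertex-index
#' sets); the raw material of HGPA.
#'
#' @param ens A `chem_ensemble` tibble.
#' @return List of integer vertex-index vectors.
#' @export
ensemble_hyperedges <- function(ens) {
  members <- ensemble_members(ens)
  unlist(lapply(members, function(labels) {
    split(seq_along(labels), labels)
  }), recursive = FALSE, use.names = FALSE)
}

# number of hyperedges spanning more than one part
hyperedge_cut <- function(edges, labels) {
  sum(vapply(edges, function(e) length(unique(labels[e])) > 1L, logical(1)))
}

# Coerce an arbitrary label vector to exactly k parts within the balance
# cap: merge smallest parts / split the largest while needed, then shift
# overflow vertices into the lightest parts. Deterministic.
repair_labels <- function(labels, k, cap) {
  labels <- match(labels, sort(unique(labels)))
  while (max(labels) > k) {
    sizes <- tabulate(labels)
    ord <- order(sizes)
    a <- ord[1]; b <- ord[2]
    labels[labels == a] <- b
    labels <- match(labels, sort(unique(labels)))
  }
  while (max(labels) < k) {
    sizes <- tabulate(labels)
    big <- which.max(sizes)
    v <- which(labels == big)
    labels[v[seq_len(ceiling(length(v) / 2))]] <- max(labels) + 1L
  }
  sizes <- tabulate(labels, nbins = k)
  while (max(sizes) > cap) {
    p <- which.max(sizes)
    q <- which.min(sizes)
    v <- which(labels == p)
    mv <- v[seq_len(min(sizes[p] - cap, cap - sizes[q]))]
    labels[mv] <- q
    sizes <- tabulate(labels, nbins = k)
  }
  labels
}

# Greedy FM-style descent from one seeded balanced start.
hgpa_descent <- function(edges, n, k, cap, labels, max_passes = 30L) {
  e <- length(edges)
  edge_of_vertex <- vector("list", n)
  for (h in seq_len(e)) for (v in edges[[h]]) {
    edge_of_vertex[[v]] <- c(edge_of_vertex[[v]], h)
  }
  # counts[h, p] = vertices of hyperedge h in part p
  counts <- matrix(0L, e, k)
  for (h in seq_len(e)) {
    tab <- tabulate(labels[edges[[h]]], nbins = k)
    counts[h, ] <- tab
  }
  sizes <- tabulate(labels, nbins = k)
  spans <- rowSums(counts > 0L)
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (v in seq_len(n)) {
      p <- labels[v]
      if (sizes[p] <= 1L) next
      he <- edge_of_vertex[[v]]
      best_q <- 0L; best_delta <- 0L
      for (q in seq_len(k)) {
        if (q == p || sizes[q] >= cap) next
        delta <- 0L
        for (h in he) {
          before <- spans[h] > 1L
          np <- counts[h, p] - 1L
          nq <- counts[h, q] + 1L
          span_after <- spans[h] - (np == 0L) + (counts[h, q] == 0L)
          after <- span_after > 1L
          delta <- delta + (after - before)
        }
        if (delta < best_delta) { best_delta <- delta; best_q <- q }
      }
      if (best_q > 0L) {
        q <- best_q
        for (h in he) {
          counts[h, p] <- counts[h, p] - 1L
          counts[h, q] <- counts[h, q] + 1L
          spans[h] <- sum(counts[h, ] > 0L)
        }
        sizes[p] <- sizes[p] - 1L
        sizes[q] <- sizes[q] + 1L
        labels[v] <- q
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(labels = labels, cut = sum(spans > 1L))
}

#' HGPA: balanced k-way hypergraph partition cutting few hyperedges
#'
#' Builds the ensemble hypergraph (one unit-weight hyperedge per cluster of
#' every member) and searches for a k-way vertex partition of approximately
#' equal part sizes that severs as few hyperedges as possible (a hyperedge
#' is cut when its vertices span more than one part). The default
#' partitioner runs seeded multi-start greedy vertex moves and keeps the
#' best start; it is deterministic given `seed`.
#'
#' @param ens A `chem_ensemble` tibble.
#' @param k Number of consensus clusters (k = 1 returns a single part).
#' @param balance_slack Allowed relative excess of the largest part over
#'   ceiling(n/k); default 0.25.
#' @param seed Integer seed for the multi-start initialisation.
#' @param n_starts Number of random balanced starts (default 12).
#' @param partitioner Optional plug-in
#'   `function(edges, n, k, balance_slack, seed)` returning integer labels.
#' @return A partition tibble with method `"hgpa"`.
#' @export
hgpa_partition <- function(ens, k, balance_slack = 0.25, seed = 1,
                           n_starts = 12L, partitioner = NULL) {
  members <- ensemble_members(ens)
  ids <- attr(members, "ids")
  n <- length(ids)
  if (k < 1 || k > n) abort(sprintf("k = %d out of range 1..%d", k, n))
  edges <- ensemble_hyperedges(ens)
  if (!is.null(partitioner)) {
    labels <- as.integer(partitioner(edges, n, as.integer(k), balance_slack, seed))
    return(new_partition(ids, labels, method = "hgpa",
                         k_requested = as.integer(k)))
  }
  if (k == 1) {
    return(new_partition(ids, rep(1L, n), method = "hgpa", k_requested = 1L))
  }
  cap <- balance_cap(n, k, balance_slack)
  # data-derived starts (each member's own partition, repaired to k balanced
  # parts) followed by seeded random balanced starts
  starts <- lapply(members, repair_labels, k = k, cap = cap)
  for (s in seq_len(n_starts)) {
    starts[[length(starts) + 1]] <-
      withr::with_seed((seed + 7919L * s) %% 2147483647L, {
        perm <- sample.int(n)
        lab <- integer(n)
        # balanced chunks of a shuffled vertex order
        lab[perm] <- sort(rep(seq_len(k), length.out = n))
        lab
      })
  }
  best <- NULL
  for (start_labels in starts) {
    res <- hgpa_descent(edges, n, k, cap, start_labels)
    if (is.null(best) || res$cut < best$cut) best <- res
  }
  new_partition(ids, best$labels, method = "hgpa", k_requested = as.integer(k))
}
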