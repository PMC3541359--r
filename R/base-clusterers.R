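# The six base clusterers and ensemble generation.
#
# Five agglomerative linkages run on a precomputed distance matrix via
# stats::hclust; "weighted" is WPGMA (hclust "mcquitty") and Ward applies
# the Lance-Williams update directly to the supplied distances (hclust
# "ward.D"), so it can be crossed with every metric even though Ward is
# classically Euclidean-only. k-means is a Lloyd iteration generalised to
# each metric via metric-specific centroid updates.

HCLUST_METHOD <- c(single = "single", complete = "complete",
                   average = "average", weighted = "mcquitty",
                   ward = "ward.D")

#' Agglomerative clustering of a distance matrix cut at k clusters
#'
#' Builds the merge tree under the requested linkage and cuts it to exactly
#' `k` non-empty clusters. Ward linkage is permitted with any supplied
#' distance (Lance-Williams coefficients applied as-is); a once-per-session
#' warning flags this non-classical use when the distances are not
#' Euclidean.
#'
#' @param D Distance matrix from [pairwise_distance()] (or any symmetric
#'   matrix with zero diagonal).
#' @param linkage One of `"single"`, `"complete"`, `"average"`,
#'   `"weighted"` (WPGMA), `"ward"`.
#' @param k Number of clusters, 2..n.
#' @return A partition tibble (`id`, `cluster`) with provenance attributes.
#' @export
hierarchical_cluster <- function(D, linkage, k) {
  if (!linkage %in% names(HCLUST_METHOD)) {
    abort(paste0("unknown linkage '", linkage, "'"))
  }
  D <- as.matrix(D)
  n <- nrow(D)
  if (k < 2 || k > n) abort(sprintf("k = %d out of range 2..%d", k, n))
  metric <- attr(D, "metric") %||% NA_character_
  if (linkage == "ward" && !is.na(metric) && metric != "euclidean") {
    warn(paste("Ward linkage applied to non-Euclidean distances;",
               "Lance-Williams update used on the supplied matrix as-is"),
         .frequency = "once", .frequency_id = "consenchem_ward_metric")
  }
  hc <- hclust(stats::as.dist(D), method = HCLUST_METHOD[[linkage]])
  labels <- cutree(hc, k = k)
  ids <- rownames(D) %||% as.character(seq_len(n))
  new_partition(ids, labels, method = linkage, distance = metric,
                k_requested = k)
}

# point-to-centroid distances under each metric; X binary n x m, C k x m
centroid_distances <- function(X, C, metric) {
  n <- nrow(X)
  switch(metric,
    euclidean = {
      D2 <- matrix(rowSums(X^2), n, nrow(C)) +
        matrix(rowSums(C^2), n, nrow(C), byrow = TRUE) - 2 * tcrossprod(X, C)
      sqrt(pmax(D2, 0))
    },
    manhattan = apply(C, 1, function(cc) colSums(abs(t(X) - cc))),
    hamming = apply(C, 1, function(cc) colSums(abs(t(X) - cc))) / ncol(X),
    jaccard = {
      inter <- tcrossprod(X, C)
      union <- matrix(rowSums(X), n, nrow(C)) +
        matrix(rowSums(C), n, nrow(C), byrow = TRUE) - inter
      d <- 1 - inter / pmax(union, 1e-300)
      d[union == 0] <- 0  # all-zero point vs all-zero centroid: identical
      d
    },
    cosine = {
      xn <- sqrt(rowSums(X^2)); cn <- sqrt(rowSums(C^2))
      s <- tcrossprod(X / pmax(xn, 1e-300), C / pmax(cn, 1e-300))
      s[, cn == 0] <- 0
      1 - s
    },
    correlation = {
      s <- suppressWarnings(cor(t(X), t(C)))
      s[is.na(s)] <- 0  # constant centroid: treat as uncorrelated
      1 - s
    }
  )
}

# centroid update per metric
update_centroids <- function(X, assign, k, metric) {
  C <- matrix(0, k, ncol(X))
  for (q in seq_len(k)) {
    rows <- X[assign == q, , drop = FALSE]
    if (nrow(rows) == 0) next
    C[q, ] <- switch(metric,
      euclidean = ,
      correlation = ,
      cosine = colMeans(rows),
      manhattan = apply(rows, 2, stats::median),
      hamming = ,
      jaccard = as.numeric(colMeans(rows) >= 0.5)  # bitwise majority, ties -> 1
    )
  }
  C
}

#' Distance-generalised k-means over binary fingerprints
#'
#' Lloyd-style alternation: assign each molecule to its nearest centroid
#' under `metric`, then recompute each centroid as the metric's minimiser —
#' the arithmetic mean for euclidean/correlation/cosine, the coordinate-wise
#' median for manhattan, and the bitwise majority vote (ties set to 1) for
#' hamming/jaccard. Initial centroids are data rows chosen by a seeded
#' maximin sweep: the first is drawn at random with `seed`, each further one
#' is the row farthest (in `metric`) from those already chosen, ties to the
#' lowest row index — a deterministic farthest-point start that spreads the
#' seeds across well-separated groups. Ties in assignment go to the lowest
#' centroid index; a cluster emptied during iteration is re-seeded with the
#' point farthest from its own centroid. Stops when assignments are stable
#' or after 300 iterations.
#'
#' @param fp Fingerprint tibble.
#' @param metric Distance measure name (see [pairwise_distance()]).
#' @param k Number of clusters (k = 1 collapses everything into one cluster).
#' @param seed Integer seed controlling initialisation.
#' @return A partition tibble with provenance attributes.
#' @export
kmeans_cluster <- function(fp, metric, k, seed = 1) {
  if (!metric %in% CHEM_METRICS) abort(paste0("unknown metric '", metric, "'"))
  X <- fp_bits(fp)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (k < 1 || k > n) abort(sprintf("k = %d out of range 1..%d", k, n))
  if (metric == "correlation" && any(apply(X, 1, var) == 0)) {
    abort("constant fingerprint row under correlation metric")
  }
  if (metric == "cosine" && any(rowSums(X) == 0)) {
    abort("all-zero fingerprint row under cosine metric")
  }
  if (k == 1) {
    return(new_partition(rownames(X), rep(1L, n), method = "kmeans",
                         distance = metric, k_requested = 1L))
  }
  first <- withr::with_seed(seed, sample.int(n, 1))
  init <- integer(k)
  init[1] <- first
  if (k > 1) {
    mind <- centroid_distances(X, X[first, , drop = FALSE], metric)[, 1]
    for (j in 2:k) {
      mind[init[seq_len(j - 1)]] <- -Inf
      init[j] <- which.max(mind)  # lowest index on ties
      dj <- centroid_distances(X, X[init[j], , drop = FALSE], metric)[, 1]
      mind <- pmin(mind, dj)
    }
  }
  C <- X[init, , drop = FALSE]
  assign <- integer(n)
  for (iter in seq_len(300L)) {
    D <- centroid_distances(X, C, metric)
    new_assign <- max.col(-D, ties.method = "first")
    # re-seed any emptied centroid with the point farthest from its centroid
    guard <- 0L
    while (length(empty <- setdiff(seq_len(k), unique(new_assign))) > 0 &&
           guard < k) {
      guard <- guard + 1L
      own <- D[cbind(seq_len(n), new_assign)]
      far <- which.max(own)  # lowest index on ties
      C[empty[1], ] <- X[far, ]
      D[, empty[1]] <- centroid_distances(X, C[empty[1], , drop = FALSE], metric)
      new_assign <- max.col(-D, ties.method = "first")
    }
    if (identical(new_assign, assign)) break
    assign <- new_assign
    C <- update_centroids(X, assign, k, metric)
  }
  new_partition(rownames(X), assign, method = "kmeans", distance = metric,
                k_requested = as.integer(k))
}

#' Generate the six-member ensemble at one (metric, k) grid cell
#'
#' Runs the five linkage methods and k-means, all on the same distance
#' measure and the same requested cluster count, in the fixed method order
#' single, complete, average, weighted, ward, kmeans. The Ward member is the
#' designated reference for cumulative-voting aggregation.
#'
#' @param fp Fingerprint tibble.
#' @param metric Distance measure name.
#' @param k Requested cluster count.
#' @param seed Seed forwarded to k-means.
#' @return A long tibble of class `chem_ensemble` with columns `id`,
#'   `method`, `distance`, `k`, `cluster`; b = 6 members.
#' @export
generate_ensemble <- function(fp, metric, k, seed = 1) {
  D <- pairwise_distance(fp, metric)
  parts <- c(
    lapply(c("single", "complete", "average", "weighted", "ward"),
           function(l) hierarchical_cluster(D, l, k)),
    list(kmeans_cluster(fp, metric, k, seed = seed))
  )
  names(parts) <- CHEM_METHODS
  ens <- purrr::imap(parts, function(p, nm) {
    tibble(id = p$id, method = nm, distance = metric, k = as.integer(k),
           cluster = p$cluster)
  }) |> purrr::list_rbind()
  ens$method <- factor(ens$method, levels = CHEM_METHODS)
  attr(ens, "ids") <- fp$id
  class(ens) <- c("chem_ensemble", class(ens))
  ens
}

# Named list of label vectors (aligned to attr "ids" order), one per member.
ensemble_members <- function(ens) {
  ids <- attr(ens, "ids") %||% unique(ens$id)
  methods <- if (is.factor(ens$method)) {
    as.character(unique(ens$method[order(as.integer(ens$method))]))
  } else unique(ens$method)
  out <- lapply(methods, function(mth) {
    sub <- ens[ens$method == mth, ]
    sub$cluster[match(ids, sub$id)]
  })
  names(out) <- methods
  attr(out, "ids") <- ids
  out
}
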