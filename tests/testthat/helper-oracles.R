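# Fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (double loops, explicit matrix inversion, exhaustive
# enumeration) and share no code with the production paths they check.

make_fp <- function(bits, ids = NULL) {
  bits <- as.matrix(bits)
  ids <- ids %||% paste0("mol", seq_len(nrow(bits)))
  colnames(bits) <- paste0("b", seq_len(ncol(bits)))
  dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(as.data.frame(bits)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_fp <- function(n, m, seed, density = 0.4) {
  withr::with_seed(seed, {
    bits <- matrix(rbinom(n * m, 1, density), n, m)
    # ensure rows are valid under every metric (non-constant, not all-zero)
    for (i in seq_len(n)) {
      if (sum(bits[i, ]) == 0) bits[i, 1] <- 1
      if (sum(bits[i, ]) == m) bits[i, 1] <- 0
    }
    make_fp(bits)
  })
}

ari <- function(a, b) {
  if (is.data.frame(a)) a <- a$cluster
  if (is.data.frame(b)) b <- b$cluster
  mclust::adjustedRandIndex(a, b)
}

# Build an ensemble tibble from a named list of label vectors.
ens_from_labels <- function(labels_list, ids = NULL, distance = "jaccard",
                            k = NULL) {
  n <- length(labels_list[[1]])
  ids <- ids %||% paste0("mol", seq_len(n))
  k <- k %||% max(unlist(labels_list))
  ens <- purrr::imap(labels_list, function(lab, nm) {
    tibble::tibble(id = ids, method = nm, distance = distance,
                   k = as.integer(k), cluster = as.integer(lab))
  }) |> purrr::list_rbind()
  attr(ens, "ids") <- ids
  class(ens) <- c("chem_ensemble", class(ens))
  ens
}

# --- brute-force pairwise distances (double loop, scalar formulas) -------

oracle_distance <- function(bits, metric) {
  n <- nrow(bits)
  D <- matrix(0, n, n)
  pair <- function(x, y) {
    switch(metric,
      euclidean = sqrt(sum((x - y)^2)),
      manhattan = sum(abs(x - y)),
      hamming = sum(x != y) / length(x),
      jaccard = {
        u <- sum(x == 1 | y == 1)
        if (u == 0) 0 else sum(x != y) / u
      },
      cosine = 1 - sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2))),
      correlation = 1 - cor(x, y)
    )
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) D[i, j] <- pair(bits[i, ], bits[j, ])
  }
  D
}

# --- straight-line cumulative voting oracle ------------------------------

# Executes the aggregation verbatim with the explicit matrix formula
# W = (Ui' Ui)^-1 Ui' U0 (solve(), no counting shortcut).
oracle_cvaa <- function(labels_list, ref_index) {
  hard <- function(lab) {
    U <- matrix(0, length(lab), max(lab))
    U[cbind(seq_along(lab), lab)] <- 1
    U
  }
  U0 <- hard(labels_list[[ref_index]])
  b <- length(labels_list)
  for (i in seq_len(b)) {
    Ui <- hard(labels_list[[i]])
    W <- solve(t(Ui) %*% Ui) %*% t(Ui) %*% U0
    V <- Ui %*% W
    U0 <- ((i - 1) / i) * U0 + (1 / i) * V
  }
  U0
}

# --- exhaustive balanced-partition oracles -------------------------------

# All label assignments of n vertices into exactly k non-empty parts whose
# largest part has at most `cap` vertices, up to nothing (labels matter for
# enumeration; cut objectives are label-invariant).
enumerate_balanced <- function(n, k, cap) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  keep <- apply(grid, 1, function(lab) {
    tab <- tabulate(lab, k)
    all(tab >= 1) && max(tab) <= cap
  })
  grid[keep, , drop = FALSE]
}

oracle_min_hyperedge_cut <- function(edges, n, k, cap) {
  assigns <- enumerate_balanced(n, k, cap)
  cuts <- apply(assigns, 1, function(lab) {
    sum(vapply(edges, function(e) length(unique(lab[e])) > 1L, logical(1)))
  })
  min(cuts)
}

oracle_min_weight_cut <- function(W, k, cap) {
  n <- nrow(W)
  assigns <- enumerate_balanced(n, k, cap)
  cuts <- apply(assigns, 1, function(lab) {
    s <- 0
    for (p in seq_len(k - 1)) for (q in (p + 1):k) {
      s <- s + sum(W[lab == p, lab == q, drop = FALSE])
    }
    s
  })
  list(min = min(cuts), argmin = assigns[which.min(cuts), ])
}

# Weighted cut of a labelled partition of similarity graph W.
cut_of <- function(W, lab) {
  k <- max(lab)
  s <- 0
  for (p in seq_len(k - 1)) for (q in (p + 1):k) {
    s <- s + sum(W[lab == p, lab == q, drop = FALSE])
  }
  s
}

hyperedge_cut_of <- function(edges, lab) {
  sum(vapply(edges, function(e) length(unique(lab[e])) > 1L, logical(1)))
}

# Well-separated planted dataset used by the recovery tests.
planted_fixture <- function(n_classes = 5, size = 30, m = 512, flip = 0.01,
                            seed = 42) {
  spec <- synth_spec(class_sizes = rep(size, n_classes), m = m,
                     prototype_density = 0.3, flip_prob = flip, seed = seed,
                     min_separation = 10 * ceiling(2 * flip * (1 - flip) * m + 1))
  generate_planted_dataset(spec)
}

planted_truth <- function(ds) as.integer(ds$activity$class)
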