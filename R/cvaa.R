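# Cumulative voting-based aggregation (CVAA) with a fixed Ward reference.
#
# Each ensemble member U^i is soft-relabelled onto the current consensus
# membership U0 through a row-stochastic vote-weight matrix
# W^i = (U^iT U^i)^-1 U^iT U0, and the relabelled votes V^i = U^i W^i are
# folded into the running average U0 <- ((i-1)/i) U0 + (1/i) V^i. Because
# U^i is hard, U^iT U^i is diagonal with the cluster sizes, so W^i reduces
# to per-cluster means of U0 rows — the implementation uses that counting
# form and never inverts a matrix.

#' Hard membership matrix of a partition
#'
#' @param p A partition tibble, or an integer label vector.
#' @param k Number of columns; defaults to the largest label.
#' @return An n-by-k 0/1 matrix with unit row sums.
#' @export
to_membership <- function(p, k = NULL) {
  labels <- if (is.data.frame(p)) p$cluster else as.integer(p)
  k <- as.integer(k %||% max(labels))
  if (any(labels < 1L | labels > k)) {
    abort(sprintf("cluster label %d outside 1..%d",
                  labels[which(labels < 1L | labels > k)[1]], k))
  }
  U <- matrix(0, length(labels), k)
  U[cbind(seq_along(labels), labels)] <- 1
  if (is.data.frame(p)) rownames(U) <- p$id
  U
}

#' Select the fixed Ward reference membership of an ensemble
#'
#' The aggregation reference U0 is the ensemble's Ward-linkage member; its
#' cluster count fixes the consensus k. Exactly one Ward member must be
#' present.
#'
#' @param ens A `chem_ensemble` tibble.
#' @return The Ward member's hard membership matrix.
#' @export
select_reference <- function(ens) {
  members <- ensemble_members(ens)
  n_ward_rows <- sum(ens$method == "ward")
  if (n_ward_rows > length(attr(members, "ids"))) {
    abort("ensemble has multiple Ward members; disambiguate explicitly")
  }
  ward <- which(names(members) == "ward")
  if (length(ward) == 0) abort("ensemble has no Ward member to use as reference")
  U <- to_membership(members[[ward]])
  rownames(U) <- attr(members, "ids")
  U
}

#' Vote-weight matrix relabelling one member onto the reference
#'
#' Row l of the result is the mean reference-membership row over the
#' molecules in cluster l of the member — the counting form of
#' (U^iT U^i)^-1 U^iT U0, valid because the member is hard. Rows sum to 1
#' whenever the reference rows do.
#'
#' @param Ui Hard membership matrix of the member (0/1, unit row sums);
#'   every column must be non-empty.
#' @param U0 Reference membership (possibly soft).
#' @return A k_i-by-k0 nonnegative matrix.
#' @export
vote_weights <- function(Ui, U0) {
  sizes <- colSums(Ui)
  if (any(sizes == 0)) {
    abort(sprintf("member cluster %d is empty; vote weights undefined",
                  which(sizes == 0)[1]))
  }
  if (!all(Ui %in% c(0, 1)) || any(abs(rowSums(Ui) - 1) > 1e-9)) {
    abort("Ui must be a hard membership matrix")
  }
  crossprod(Ui, U0) / sizes
}

#' Cumulative voting-based aggregation of an ensemble
#'
#' Initialises U0 from the Ward member, then folds every ensemble member in
#' order (the Ward member included — its first pass is a no-op since W = I)
#' into the running average. Vote weights are always computed against the
#' *current* U0, which becomes soft after the first update; the reference
#' choice itself stays fixed. The consensus cluster count is inherited from
#' the reference.
#'
#' @param ens A `chem_ensemble` tibble containing exactly one Ward member.
#' @param include_reference Fold the Ward member itself into the average
#'   (default `TRUE`).
#' @return An object of class `cvaa` holding the soft consensus membership;
#'   see [harden()], [tidy.cvaa()], [glance.cvaa()].
#' @export
cvaa_aggregate <- function(ens, include_reference = TRUE) {
  members <- ensemble_members(ens)
  U0 <- select_reference(ens)
  ids <- attr(members, "ids")
  loop <- if (include_reference) seq_along(members) else
    which(names(members) != "ward")
  i <- 0L
  for (idx in loop) {
    i <- i + 1L
    Ui <- to_membership(members[[idx]])
    W <- vote_weights(Ui, U0)
    V <- Ui %*% W
    U0 <- ((i - 1) / i) * U0 + (1 / i) * V
  }
  structure(
    list(membership = U0, ids = ids, k = ncol(U0), b = length(loop),
         distance = as.character(ens$distance[1])),
    class = "cvaa"
  )
}

#' Harden a soft membership into a partition
#'
#' Each molecule goes to its maximum-membership column; ties break to the
#' lowest column index; empty columns are dropped with re-indexing.
#'
#' @param x A `cvaa` object or a row-stochastic membership matrix.
#' @param ... Unused.
#' @return A partition tibble.
#' @export
harden <- function(x, ...) UseMethod("harden")

#' @export
harden.cvaa <- function(x, ...) {
  p <- harden(x$membership)
  attr(p, "method") <- "cvaa"
  attr(p, "distance") <- x$distance
  attr(p, "k_requested") <- x$k
  p
}

#' @export
harden.default <- function(x, ...) {
  U <- as.matrix(x)
  if (any(abs(rowSums(U) - 1) > 1e-6)) {
    abort("membership rows must sum to 1")
  }
  labels <- max.col(U, ties.method = "first")
  ids <- rownames(U) %||% as.character(seq_len(nrow(U)))
  new_partition(ids, labels, method = "cvaa")
}

#' @describeIn cvaa_aggregate Long tibble of soft memberships
#'   (`id`, `cluster`, `membership`).
#' @param x A `cvaa` object.
#' @param ... Unused.
#' @method tidy cvaa
#' @export
tidy.cvaa <- function(x, ...) {
  U <- x$membership
  tibble(
    id = rep(x$ids, times = ncol(U)),
    cluster = rep(seq_len(ncol(U)), each = nrow(U)),
    membership = as.vector(U)
  ) |> dplyr::arrange(.data$id, .data$cluster)
}

#' @describeIn cvaa_aggregate One-row summary (n, k, b, mean maximum
#'   membership — a confidence measure of the consensus).
#' @method glance cvaa
#' @export
glance.cvaa <- function(x, ...) {
  tibble(
    n = nrow(x$membership), k = x$k, b = x$b,
    mean_max_membership = mean(apply(x$membership, 1, max))
  )
}

#' @export
print.cvaa <- function(x, ...) {
  cat(sprintf("<cvaa consensus> %d molecules, k = %d, b = %d members (%s)\n",
              nrow(x$membership), x$k, x$b, x$distance))
  invisible(x)
}

#' @describeIn cvaa_aggregate Membership heatmap (molecules by consensus
#'   cluster).
#' @param object A `cvaa` object.
#' @method autoplot cvaa
#' @export
autoplot.cvaa <- function(object, ...) {
  df <- tidy(object)
  df$id <- factor(df$id, levels = object$ids)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster), y = .data$id,
                                   fill = .data$membership)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "consensus cluster", y = NULL, fill = "membership")
}
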