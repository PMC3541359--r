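# Activity-aware clustering quality: per-class F-measure and Quality
# Partition Index (QPI), macro-averaged over activity classes, plus the
# paired t-test used to compare methods across cluster counts.

#' Precision, recall and F of one cluster against one activity class
#'
#' For a cluster of `n` molecules of which `a` belong to the focal activity
#' class, out of `A` class members in the whole dataset: P = a/n, R = a/A,
#' F = 2PR/(P+R), with F = 0 when a = 0.
#'
#' @param a Actives in the cluster.
#' @param n Cluster size.
#' @param A Total actives of the focal class.
#' @return A one-row tibble with `precision`, `recall`, `f`.
#' @export
cluster_prf <- function(a, n, A) {
  if (A < 1) abort("focal class has no actives (A = 0)")
  if (n < 1 || a < 0 || a > min(n, A)) abort("need 0 <= a <= min(n, A), n >= 1")
  P <- a / n
  R <- a / A
  f <- if (a == 0) 0 else 2 * P * R / (P + R)
  tibble(precision = P, recall = R, f = f)
}

cluster_counts <- function(p, act, focal_class) {
  if (!focal_class %in% as.character(act$class)) {
    abort(paste0("unknown activity class '", focal_class, "'"))
  }
  is_active <- as.character(act$class)[match(p$id, act$id)] == focal_class
  n_c <- tabulate(p$cluster)
  a_c <- vapply(seq_along(n_c), function(q) sum(is_active[p$cluster == q]), 0L)
  keep <- n_c > 0  # tolerate label vectors with unused indices
  list(n_c = n_c[keep], a_c = a_c[keep], A = sum(is_active), n_total = nrow(p))
}

#' F-measure of a partition for one activity class
#'
#' The maximum cluster F over all clusters, treating the focal class as
#' "active" and everything else as inactive.
#'
#' @param p Partition tibble.
#' @param act Activity tibble (id, class).
#' @param focal_class Class label to score.
#' @return F in \[0, 1\].
#' @export
f_measure <- function(p, act, focal_class) {
  cc <- cluster_counts(p, act, focal_class)
  P <- cc$a_c / cc$n_c
  R <- cc$a_c / cc$A
  f <- ifelse(cc$a_c == 0, 0, 2 * P * R / (P + R))
  max(f)
}

#' QPI tallies of a partition for one activity class
#'
#' An *active cluster* is a non-singleton cluster whose fraction of
#' focal-class actives strictly exceeds the dataset-wide fraction. The
#' tallies are p (actives in active clusters), q (inactives in active
#' clusters), r (actives in inactive clusters) and s (singleton actives);
#' p + r + s = A always.
#'
#' @inheritParams f_measure
#' @return A one-row tibble with `p`, `q`, `r`, `s`, `A`.
#' @export
qpi_counts <- function(p, act, focal_class) {
  cc <- cluster_counts(p, act, focal_class)
  frac_dataset <- cc$A / cc$n_total
  singleton <- cc$n_c == 1
  active_cluster <- !singleton & (cc$a_c / cc$n_c > frac_dataset)
  tibble(
    p = sum(cc$a_c[active_cluster]),
    q = sum(cc$n_c[active_cluster] - cc$a_c[active_cluster]),
    r = sum(cc$a_c[!active_cluster & !singleton]),
    s = sum(cc$a_c[singleton]),
    A = cc$A
  )
}

#' Quality Partition Index of a partition for one activity class
#'
#' QPI = p / (p + q + r + s); high when actives sit together in clusters
#' that exclude inactives.
#'
#' @inheritParams f_measure
#' @return QPI in \[0, 1\].
#' @export
qpi <- function(p, act, focal_class) {
  tl <- qpi_counts(p, act, focal_class)
  tl$p / (tl$p + tl$q + tl$r + tl$s)
}

#' Evaluate a grid of partitions against an activity table
#'
#' For every (method, distance, k) cell, the F-measure and QPI are computed
#' per activity class and macro-averaged (arithmetic mean over classes),
#' reported on the percent scale.
#'
#' @param partitions Long tibble with columns `id`, `method`, `distance`,
#'   `k`, `cluster` — one row per molecule per grid cell (an ensemble
#'   tibble, a bound row-collection of them, or consensus partitions stacked
#'   the same way).
#' @param act Activity tibble (id, class).
#' @return A `chem_report` tibble with columns `method`, `distance`, `k`,
#'   `f`, `qpi` (percent scale); per-class scores are retained in attribute
#'   `"per_class"` and via [tidy()].
#' @export
evaluate_partitions <- function(partitions, act) {
  classes <- levels(act$class) %||% unique(as.character(act$class))
  per_class <- partitions |>
    as_tibble() |>
    dplyr::group_by(.data$method, .data$distance, .data$k) |>
    dplyr::group_modify(function(cell, key) {
      p <- new_partition(cell$id, cell$cluster)
      purrr::map(classes, function(cl) {
        tibble(class = cl,
               f = f_measure(p, act, cl),
               qpi = qpi(p, act, cl))
      }) |> purrr::list_rbind()
    }) |>
    dplyr::ungroup()
  report <- per_class |>
    dplyr::group_by(.data$method, .data$distance, .data$k) |>
    dplyr::summarise(f = 100 * mean(.data$f), qpi = 100 * mean(.data$qpi),
                     .groups = "drop") |>
    dplyr::mutate(method = as.character(.data$method))
  attr(report, "per_class") <- dplyr::mutate(per_class,
                                             method = as.character(.data$method))
  class(report) <- c("chem_report", class(report))
  report
}

#' @describeIn evaluate_partitions Per-class breakdown of a report.
#' @param x A `chem_report`.
#' @param ... Unused.
#' @method tidy chem_report
#' @export
tidy.chem_report <- function(x, ...) {
  as_tibble(attr(x, "per_class"))
}

#' @describeIn evaluate_partitions Score curves versus cluster count, by
#'   method and distance.
#' @param object A `chem_report`.
#' @method autoplot chem_report
#' @export
autoplot.chem_report <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("f", "qpi"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value,
                                     colour = .data$method,
                                     group = interaction(.data$method, .data$distance))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "number of clusters", y = "score (%)", colour = "method")
}

#' Paired t-test between two aligned score vectors
#'
#' Classical paired t on d = x - y with two-tailed p from Student's t with
#' n - 1 degrees of freedom and a 95% confidence interval. Zero-variance
#' differences yield a degenerate-flagged result (t and p are `NA`) rather
#' than an error.
#'
#' @param x,y Numeric vectors of equal length >= 2, aligned pair-wise (in
#'   the benchmark layout, by cluster-count column).
#' @return An object of class `paired_ttest`; see [tidy.paired_ttest()].
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("need at least 2 pairs")
  d <- x - y
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  out <- list(mean_diff = m, sd_diff = s, se = s / sqrt(n),
              df = n - 1L, n_pairs = n, degenerate = s == 0)
  if (s == 0) {
    out$t_stat <- NA_real_
    out$p_two_tailed <- NA_real_
    out$ci95_low <- m
    out$ci95_high <- m
  } else {
    tt <- stats::t.test(x, y, paired = TRUE, conf.level = 0.95)
    out$t_stat <- unname(tt$statistic)
    out$p_two_tailed <- tt$p.value
    out$ci95_low <- tt$conf.int[1]
    out$ci95_high <- tt$conf.int[2]
  }
  structure(out, class = "paired_ttest")
}

#' @describeIn paired_ttest One-row tibble of the test statistics.
#' @param x A `paired_ttest`.
#' @param ... Unused.
#' @method tidy paired_ttest
#' @export
tidy.paired_ttest <- function(x, ...) {
  tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff, se = x$se,
         ci95_low = x$ci95_low, ci95_high = x$ci95_high,
         t_stat = x$t_stat, p_two_tailed = x$p_two_tailed,
         df = x$df, degenerate = x$degenerate)
}

#' @export
print.paired_ttest <- function(x, ...) {
  cat(sprintf(
    "paired t: mean diff %.2f (sd %.2f, se %.2f), 95%% CI [%.2f, %.2f], t = %s, p = %s, df = %d%s\n",
    x$mean_diff, x$sd_diff, x$se, x$ci95_low, x$ci95_high,
    format(x$t_stat, digits = 4), format(x$p_two_tailed, digits = 3),
    x$df, if (x$degenerate) " [degenerate: zero-variance differences]" else ""
  ))
  invisible(x)
}

#' Best score per cluster count for one method
#'
#' Within a method, takes the maximum score across distance rows for each
#' cluster count — the per-column best values that feed the method
#' comparisons (methods reported without a distance breakdown, such as the
#' Ward baseline row, contribute their single row).
#'
#' @param report A `chem_report` (or benchmark tibble with the same
#'   columns).
#' @param method Method name.
#' @param measure `"f"` or `"qpi"`.
#' @return Tibble `k`, `value`, ascending in `k`.
#' @export
best_per_k <- function(report, method, measure = c("f", "qpi")) {
  measure <- match.arg(measure)
  sub <- dplyr::filter(as_tibble(report), .data$method == !!method)
  if (nrow(sub) == 0) abort(paste0("method '", method, "' not in report"))
  sub |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(value = max(.data[[measure]]), .groups = "drop") |>
    dplyr::arrange(.data$k)
}

#' Best distance row of a method (highest mean score across cluster counts)
#'
#' Within a method, picks the single distance row whose mean score over the
#' k grid is highest — the row a benchmark table would highlight as that
#' method's distance of choice — and returns its score at every cluster
#' count. Methods reported without a distance breakdown (the Ward baseline)
#' contribute their only row. Ties break alphabetically by distance.
#'
#' @param report A `chem_report` (or benchmark tibble with the same
#'   columns).
#' @param method Method name.
#' @param measure `"f"` or `"qpi"`.
#' @return Tibble `k`, `value`, ascending in `k`.
#' @export
best_row <- function(report, method, measure = c("f", "qpi")) {
  measure <- match.arg(measure)
  sub <- dplyr::filter(as_tibble(report), .data$method == !!method)
  if (nrow(sub) == 0) abort(paste0("method '", method, "' not in report"))
  sub$distance[is.na(sub$distance)] <- ""
  means <- sub |>
    dplyr::group_by(.data$distance) |>
    dplyr::summarise(mean_value = mean(.data[[measure]]), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_value), .data$distance)
  sub |>
    dplyr::filter(.data$distance == means$distance[1]) |>
    dplyr::transmute(k = .data$k, value = .data[[measure]]) |>
    dplyr::arrange(.data$k)
}

#' Compare two methods with a paired t-test over cluster counts
#'
#' Pairs the two methods' scores by cluster count and runs [paired_ttest()]
#' on `method_x - method_y`. With `selection = "best_row"` (default) each
#' method is represented by its best single distance row (see [best_row()]),
#' the convention of the published comparison tables; `"per_k_max"` instead
#' takes the maximum across distance rows independently at every cluster
#' count (see [best_per_k()]).
#'
#' @inheritParams best_per_k
#' @param method_x,method_y Method names to compare.
#' @param selection Row-selection rule, `"best_row"` or `"per_k_max"`.
#' @return A `paired_ttest` with attribute `"pair"`.
#' @export
compare_methods <- function(report, method_x, method_y,
                            measure = c("f", "qpi"),
                            selection = c("best_row", "per_k_max")) {
  measure <- match.arg(measure)
  selection <- match.arg(selection)
  pick <- if (selection == "best_row") best_row else best_per_k
  bx <- pick(report, method_x, measure)
  by <- pick(report, method_y, measure)
  joined <- dplyr::inner_join(bx, by, by = "k", suffix = c("_x", "_y"))
  if (nrow(joined) < 2) abort("fewer than 2 shared cluster counts to pair")
  tt <- paired_ttest(joined$value_x, joined$value_y)
  attr(tt, "pair") <- paste(method_x, "-", method_y)
  tt
}

#' Published MDDR consensus-clustering benchmark grid
#'
#' Reference effectiveness values for consensus clustering of an
#' 8294-molecule, eleven-activity-class MDDR subset represented by ALOGP
#' (120-bit) and ECFP_4 (1024-bit) fingerprints: macro-averaged F-measure
#' and QPI (percent scale) for CVAA, CSPA and HGPA over six ensemble
#' distances, plus the Ward individual-clustering baseline, at cluster
#' counts 500-1000. Shipped as plain text under `extdata`; useful as input
#' to [best_per_k()] and [compare_methods()].
#'
#' @return Tibble with columns `fingerprint` (`"alogp"`/`"ecfp4"`),
#'   `measure` (`"f"`/`"qpi"`), `method`, `distance` (`NA` for the Ward
#'   baseline row), `k`, `value`.
#' @export
mddr_benchmark <- function() {
  path <- system.file("extdata", "mddr_benchmark.csv", package = "consenchem",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = "ccccid", progress = FALSE) |>
    dplyr::mutate(distance = dplyr::na_if(.data$distance, ""))
}

#' Benchmark grid reshaped as an evaluation report
#'
#' Filters [mddr_benchmark()] to one fingerprint and one measure and
#' returns it with `chem_report`-style columns so the comparison helpers
#' apply directly.
#'
#' @param fingerprint `"alogp"` or `"ecfp4"`.
#' @param measure `"f"` or `"qpi"`.
#' @return Tibble `method`, `distance`, `k`, plus the measure column.
#' @export
mddr_benchmark_report <- function(fingerprint = c("alogp", "ecfp4"),
                                  measure = c("f", "qpi")) {
  fingerprint <- match.arg(fingerprint)
  measure <- match.arg(measure)
  mddr_benchmark() |>
    dplyr::filter(.data$fingerprint == !!fingerprint,
                  .data$measure == !!measure) |>
    dplyr::select("method", "distance", "k", value = "value") |>
    dplyr::rename(!!measure := "value")
}
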