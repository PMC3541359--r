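# End-to-end experiment driver: data -> ensembles over the (distance, k)
# grid -> consensus partitions + Ward baseline -> evaluation report ->
# method-comparison t-tests, with optional artifact output.

#' Configure a consensus-clustering experiment
#'
#' @param fingerprints Fingerprint tibble, or a path to a fingerprint CSV.
#'   Mutually exclusive with `synth`.
#' @param activity Activity tibble, or a path to an activity TSV (required
#'   with `fingerprints`).
#' @param synth A [synth_spec()] to generate the data instead.
#' @param distances Subset of the six distance names.
#' @param k_list Ascending cluster counts.
#' @param methods Consensus functions to run, subset of
#'   `c("cvaa", "cspa", "hgpa")`.
#' @param seed Master seed; per-cell seeds are derived deterministically.
#' @param out_dir Optional directory for report/partition/comparison files.
#' @return A `run_config` list.
#' @export
run_config <- function(fingerprints = NULL, activity = NULL, synth = NULL,
                       distances = c("jaccard", "euclidean"),
                       k_list = c(5, 10, 20),
                       methods = c("cvaa", "cspa", "hgpa"),
                       seed = 1, out_dir = NULL) {
  if (is.null(synth) == is.null(fingerprints)) {
    abort("supply exactly one of `fingerprints` or `synth`")
  }
  if (!all(distances %in% CHEM_METRICS) || length(distances) < 1) {
    abort("distances must be a non-empty subset of the six metric names")
  }
  if (!all(methods %in% CONSENSUS_METHODS) || length(methods) < 1) {
    abort("methods must be a non-empty subset of cvaa, cspa, hgpa")
  }
  k_list <- as.integer(k_list)
  if (length(k_list) < 1 || is.unsorted(k_list, strictly = TRUE)) {
    abort("k_list must be strictly ascending")
  }
  structure(
    list(fingerprints = fingerprints, activity = activity, synth = synth,
         distances = distances, k_list = k_list, methods = methods,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

cell_seed <- function(seed, di, ki) {
  (as.integer(seed) + 104729L * di + 1299709L * ki) %% 2147483647L
}

#' Run the full consensus-clustering experiment
#'
#' For every (distance, k) grid cell: generate the six-member ensemble,
#' compute each requested consensus partition, and keep the ensemble's Ward
#' member as the individual-clustering baseline row. All partitions are
#' evaluated with macro-averaged F-measure and QPI, and the report feeds
#' paired t-tests of CVAA against the other methods. A failing cell is
#' logged and skipped; the remaining cells still run.
#'
#' When `out_dir` is set, writes `report_f.csv` / `report_qpi.csv`
#' (benchmark-table layout), one partition TSV per grid cell and method
#' under `partitions/`, `comparisons.csv`, and `run_log.txt` recording the
#' seeds used. Re-running the same configuration reproduces the files
#' byte-for-byte.
#'
#' @param cfg A [run_config()].
#' @return A `chem_experiment` list: `report` (a `chem_report`),
#'   `comparisons` (tidy t-test rows), `partitions` (long tibble),
#'   `failures` (tibble of failed cells), `activity`, `log` (character).
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  if (!is.null(cfg$synth)) {
    ds <- generate_planted_dataset(cfg$synth)
    fp <- ds$fingerprints
    act <- ds$activity
    note("synthetic dataset: %d molecules, %d classes, seed %d",
         nrow(fp), nlevels(act$class), cfg$synth$seed)
  } else {
    fp <- if (is.character(cfg$fingerprints)) {
      read_fingerprints(cfg$fingerprints)
    } else cfg$fingerprints
    act <- if (is.character(cfg$activity)) {
      read_activity(cfg$activity, fp)
    } else activity_table(cfg$activity, fp)
    note("loaded dataset: %d molecules, %d classes", nrow(fp),
         length(unique(act$class)))
  }
  parts <- list()
  failures <- list()
  for (di in seq_along(cfg$distances)) {
    metric <- cfg$distances[di]
    for (ki in seq_along(cfg$k_list)) {
      k <- cfg$k_list[ki]
      sd_cell <- cell_seed(cfg$seed, di, ki)
      note("cell %s k=%d seed=%d", metric, k, sd_cell)
      res <- tryCatch({
        ens <- generate_ensemble(fp, metric, k, seed = sd_cell)
        cell <- list(ward = ens[ens$method == "ward", ])
        if ("cvaa" %in% cfg$methods) {
          cell$cvaa <- harden(cvaa_aggregate(ens))
        }
        if ("cspa" %in% cfg$methods) {
          cell$cspa <- cspa_partition(ens, k, seed = sd_cell)
        }
        if ("hgpa" %in% cfg$methods) {
          cell$hgpa <- hgpa_partition(ens, k, seed = sd_cell)
        }
        cell
      }, error = function(e) e)
      if (inherits(res, "error")) {
        note("cell %s k=%d FAILED: %s", metric, k, conditionMessage(res))
        failures[[length(failures) + 1]] <-
          tibble(distance = metric, k = k, error = conditionMessage(res))
        next
      }
      for (nm in names(res)) {
        p <- res[[nm]]
        tbl <- if (nm == "ward") {
          dplyr::mutate(as_tibble(p), method = "ward")
        } else {
          tibble(id = p$id, method = nm, distance = metric,
                 k = as.integer(k), cluster = p$cluster)
        }
        parts[[length(parts) + 1]] <- tbl[c("id", "method", "distance",
                                            "k", "cluster")]
      }
    }
  }
  if (length(parts) == 0) abort("every grid cell failed")
  partitions <- purrr::list_rbind(parts)
  report <- evaluate_partitions(partitions, act)
  comparisons <- if (length(unique(report$k)) < 2) {
    note("single cluster count: method-comparison t-tests skipped")
    tibble()
  } else purrr::map(c("f", "qpi"), function(ms) {
    purrr::map(intersect(c("ward", "cspa", "hgpa"),
                         c("ward", cfg$methods)), function(other) {
      if (other == "cvaa" || !"cvaa" %in% cfg$methods) return(NULL)
      if (!other %in% report$method) return(NULL)
      tt <- compare_methods(report, "cvaa", other, measure = ms)
      dplyr::mutate(tidy(tt), measure = ms, pair = attr(tt, "pair"),
                    .before = 1)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  out <- structure(
    list(report = report, comparisons = comparisons, partitions = partitions,
         failures = purrr::list_rbind(failures), activity = act, log = log),
    class = "chem_experiment"
  )
  if (!is.null(cfg$out_dir)) write_experiment(out, cfg$out_dir)
  out
}

write_experiment <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "partitions"), showWarnings = FALSE)
  write_report(x$report, file.path(out_dir, "report_f.csv"), "f")
  write_report(x$report, file.path(out_dir, "report_qpi.csv"), "qpi")
  cells <- dplyr::distinct(x$partitions, .data$method, .data$distance, .data$k)
  for (i in seq_len(nrow(cells))) {
    sub <- dplyr::semi_join(x$partitions, cells[i, ],
                            by = c("method", "distance", "k"))
    fn <- sprintf("%s_%s_k%d.tsv", cells$method[i], cells$distance[i],
                  cells$k[i])
    readr::write_tsv(sub[c("id", "cluster")], file.path(out_dir, "partitions", fn),
                     progress = FALSE)
  }
  if (!is.null(x$comparisons) && nrow(x$comparisons) > 0) {
    readr::write_csv(x$comparisons, file.path(out_dir, "comparisons.csv"),
                     progress = FALSE)
  }
  writeLines(x$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.chem_experiment <- function(x, ...) {
  cat(sprintf("<chem_experiment> %d report rows, %d comparison rows, %d failed cells\n",
              nrow(x$report), if (is.null(x$comparisons)) 0L else nrow(x$comparisons),
              if (is.null(x$failures)) 0L else nrow(x$failures)))
  invisible(x)
}

#' @describeIn run_experiment One-row experiment summary.
#' @param x A `chem_experiment`.
#' @param ... Unused.
#' @method glance chem_experiment
#' @export
glance.chem_experiment <- function(x, ...) {
  tibble(
    n_cells = nrow(dplyr::distinct(x$report[c("distance", "k")])),
    n_methods = length(unique(x$report$method)),
    n_failed = if (is.null(x$failures)) 0L else nrow(x$failures),
    best_f = max(x$report$f), best_qpi = max(x$report$qpi)
  )
}
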