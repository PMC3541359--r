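# Readers/writers and the tabular domain objects shared by all stages.
#
# A fingerprint table is a tibble whose first column `id` holds unique
# molecule identifiers and whose remaining columns are strictly 0/1 bits.
# An activity table is a tibble with columns `id` and `class` (a factor
# whose levels are in first-appearance order). A partition is a tibble
# with columns `id` and `cluster` (integers 1..k, every label occupied),
# carrying `method`, `distance` and `k_requested` attributes.

#' Read a binary fingerprint matrix from delimited text
#'
#' The file must have a header row; the first column holds molecule
#' identifiers and every remaining column holds 0/1 bit values (count-valued
#' fingerprints are rejected, not thresholded).
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter, default `","`.
#' @return A tibble with an `id` character column followed by integer bit
#'   columns, one row per molecule, in file order.
#' @export
read_fingerprints <- function(path, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (nrow(raw) < 2) {
    abort("need at least 2 molecules in a fingerprint file")
  }
  names(raw)[1] <- "id"
  raw$id <- as.character(raw$id)
  validate_fingerprints(raw)
  raw[-1] <- lapply(raw[-1], as.integer)
  as_tibble(raw)
}

#' Validate a fingerprint table
#'
#' Checks identifiers are unique and all bit entries are exactly 0 or 1,
#' naming the first offending cell.
#'
#' @param fp A fingerprint tibble (`id` column plus bit columns).
#' @return `fp`, invisibly.
#' @export
validate_fingerprints <- function(fp) {
  if (!is.data.frame(fp) || ncol(fp) < 2 || !"id" %in% names(fp)[1]) {
    abort("fingerprints must be a data frame with an `id` first column and bit columns")
  }
  if (anyDuplicated(fp$id)) {
    dup <- fp$id[duplicated(fp$id)][1]
    abort(paste0("duplicate molecule id: '", dup, "'"))
  }
  if (nrow(fp) < 2) abort("need at least 2 molecules")
  bits <- as.matrix(fp[-1])
  bad <- which(!(bits == 0 | bits == 1) | is.na(bits), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-binary value %s in row %d (id '%s'), bit column '%s'",
      format(bits[bad[1, 1], bad[1, 2]]), bad[1, 1],
      fp$id[bad[1, 1]], names(fp)[-1][bad[1, 2]]
    ))
  }
  invisible(fp)
}

# Bit matrix with ids as rownames; the numeric workhorse representation.
fp_bits <- function(fp) {
  bits <- as.matrix(fp[-1])
  storage.mode(bits) <- "integer"
  rownames(bits) <- fp$id
  bits
}

# Wrap a bit matrix back into the tibble representation.
fp_from_bits <- function(ids, bits) {
  colnames(bits) <- colnames(bits) %||% paste0("bit", seq_len(ncol(bits)))
  out <- as_tibble(as.data.frame(bits))
  dplyr::bind_cols(tibble(id = as.character(ids)), out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an activity table and align it to a fingerprint set
#'
#' The file is tab-separated with two columns, molecule id and activity-class
#' label. Every fingerprint id must be present; ids in the table that have no
#' fingerprint are dropped with a warning. Class levels are recorded in order
#' of first appearance.
#'
#' @param path Path to a two-column TSV (id, class).
#' @param fingerprints Fingerprint tibble the table must cover.
#' @return A tibble with columns `id` and `class` (factor), in fingerprint
#'   order.
#' @export
read_activity <- function(path, fingerprints) {
  raw <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  names(raw)[1:2] <- c("id", "class")
  activity_table(raw, fingerprints)
}

#' Build an activity table from a data frame of id/class pairs
#'
#' @param x Data frame with columns `id` and `class`.
#' @param fingerprints Fingerprint tibble to align against.
#' @return A tibble `id`, `class` in fingerprint order; `class` is a factor
#'   with levels in first-appearance order of `x`.
#' @export
activity_table <- function(x, fingerprints) {
  x$id <- as.character(x$id)
  missing_ids <- setdiff(fingerprints$id, x$id)
  if (length(missing_ids) > 0) {
    abort(paste0(
      "activity table is missing fingerprint id(s): ",
      paste(head(missing_ids, 5), collapse = ", "),
      if (length(missing_ids) > 5) ", ..." else ""
    ))
  }
  unknown <- setdiff(x$id, fingerprints$id)
  if (length(unknown) > 0) {
    warn(paste0(length(unknown), " activity row(s) have no fingerprint; ignored"))
    x <- x[x$id %in% fingerprints$id, ]
  }
  if (anyDuplicated(x$id)) {
    abort(paste0("molecule '", x$id[duplicated(x$id)][1],
                 "' appears more than once in the activity table"))
  }
  levels <- unique(as.character(x$class))
  x$class <- factor(as.character(x$class), levels = levels)
  x <- x[match(fingerprints$id, x$id), c("id", "class")]
  as_tibble(x)
}

# --- partitions ---------------------------------------------------------

new_partition <- function(ids, labels, method = NA_character_,
                          distance = NA_character_, k_requested = NA_integer_) {
  labels <- as.integer(labels)
  stopifnot(length(ids) == length(labels))
  if (anyNA(labels) || any(labels < 1L)) abort("cluster labels must be positive integers")
  # re-index so labels are 1..k with every index occupied
  used <- sort(unique(labels))
  labels <- match(labels, used)
  out <- tibble(id = as.character(ids), cluster = as.integer(labels))
  attr(out, "method") <- method
  attr(out, "distance") <- distance
  attr(out, "k_requested") <- as.integer(k_requested)
  class(out) <- c("chem_partition", class(out))
  out
}

#' Number of clusters in a partition
#' @param p A partition tibble.
#' @return Integer count of occupied clusters.
#' @export
n_clusters <- function(p) max(p$cluster)

#' Write / read a partition as two-column TSV (id, cluster)
#'
#' Labels are written 1-based; reading re-validates that labels form a
#' gap-free 1..k range.
#'
#' @param p A partition tibble.
#' @param path Output file path.
#' @return `write_partition` returns `path` invisibly; `read_partition`
#'   returns a partition tibble.
#' @export
write_partition <- function(p, path) {
  readr::write_tsv(p[c("id", "cluster")], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  raw <- readr::read_tsv(path, col_types = "ci", progress = FALSE)
  names(raw)[1:2] <- c("id", "cluster")
  new_partition(raw$id, raw$cluster)
}

# --- evaluation reports -------------------------------------------------

#' Write an evaluation report in the benchmark-table layout
#'
#' One row per (method, distance), one column per cluster count, for a single
#' score; values printed with two decimals. Methods appear in the fixed order
#' cvaa, cspa, hgpa, then individual clusterers; distances alphabetically;
#' cluster counts ascending. Re-writing the same report is byte-identical.
#'
#' @param report Report tibble from [evaluate_partitions()].
#' @param path Output CSV path.
#' @param measure Which score to lay out, `"f"` or `"qpi"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, measure = c("f", "qpi")) {
  measure <- match.arg(measure)
  if (!is.data.frame(report) || nrow(report) == 0) abort("empty report")
  methods <- unique(report$method)
  method_order <- c(intersect(CONSENSUS_METHODS, methods),
                    sort(setdiff(methods, CONSENSUS_METHODS)))
  wide <- report |>
    dplyr::mutate(
      method = factor(.data$method, levels = method_order),
      distance = ifelse(is.na(.data$distance), "", .data$distance),
      value = sprintf("%.2f", .data[[measure]])
    ) |>
    dplyr::arrange(.data$method, .data$distance, .data$k) |>
    dplyr::select("method", "distance", "k", "value") |>
    tidyr::pivot_wider(names_from = "k", values_from = "value",
                       names_prefix = "k")
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}
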