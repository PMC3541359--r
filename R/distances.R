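# The six pairwise distance measures used for ensemble generation.
#
# On binary rows x, y of length m:
#   euclidean   sqrt(sum (x_i - y_i)^2)
#   manhattan   sum |x_i - y_i|
#   hamming     (1/m) sum [x_i != y_i]
#   jaccard     mismatches among positions where either bit is 1, over the
#               size of that union; 0 for two all-zero rows (identical)
#   cosine      1 - x.y / (|x||y|)
#   correlation 1 - Pearson(x, y)
# Note jaccard distance = 1 - Tanimoto similarity on binary data.

#' Pairwise distance matrix over fingerprints
#'
#' @param fp Fingerprint tibble (id + bit columns).
#' @param metric One of `"correlation"`, `"cosine"`, `"euclidean"`,
#'   `"hamming"`, `"jaccard"`, `"manhattan"`.
#' @return A dense symmetric n-by-n matrix with zero diagonal, molecule ids
#'   as dimnames and the metric stored in attribute `"metric"`.
#' @export
pairwise_distance <- function(fp, metric) {
  if (!is.character(metric) || length(metric) != 1 || !metric %in% CHEM_METRICS) {
    abort(paste0("unknown metric '", paste(metric, collapse = ","),
                 "'; expected one of: ", paste(CHEM_METRICS, collapse = ", ")))
  }
  bits <- fp_bits(fp)
  storage.mode(bits) <- "double"
  n <- nrow(bits)
  m <- ncol(bits)
  D <- switch(metric,
    euclidean = as.matrix(dist(bits, method = "euclidean")),
    manhattan = as.matrix(dist(bits, method = "manhattan")),
    hamming = as.matrix(dist(bits, method = "manhattan")) / m,
    jaccard = {
      d <- as.matrix(dist(bits, method = "binary"))
      d[is.nan(d)] <- 0  # two all-zero rows: identical, distance 0
      d
    },
    cosine = {
      norms <- sqrt(rowSums(bits^2))
      zero <- which(norms == 0)
      if (length(zero) > 0) {
        abort(paste0("all-zero fingerprint row under cosine: '",
                     rownames(bits)[zero[1]], "'"))
      }
      1 - tcrossprod(bits / norms)
    },
    correlation = {
      vr <- apply(bits, 1, var)
      zero <- which(vr == 0)
      if (length(zero) > 0) {
        abort(paste0("constant fingerprint row under correlation: '",
                     rownames(bits)[zero[1]], "'"))
      }
      1 - cor(t(bits))
    }
  )
  D <- (D + t(D)) / 2
  D[D < 0] <- 0
  diag(D) <- 0
  dimnames(D) <- list(rownames(bits), rownames(bits))
  attr(D, "metric") <- metric
  D
}
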