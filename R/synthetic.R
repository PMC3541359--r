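# Planted activity-class fingerprint simulator.
#
# Each activity class gets a random prototype fingerprint; members are noisy
# copies of the prototype under independent symmetric per-bit flips. The flip
# probability is the diversity dial: it has a closed-form link to the
# expected within-class mean pairwise Tanimoto similarity, so the generator
# can be calibrated to hit a target diversity.

#' Specify a planted-class synthetic fingerprint dataset
#'
#' @param class_sizes Positive integer vector, one entry per activity class.
#' @param m Bit count of the fingerprints (default 1024, an ECFP_4-style
#'   length).
#' @param prototype_density Fraction of 1-bits expected in each class
#'   prototype, in (0, 1). Scalar or one value per class.
#' @param flip_prob Per-bit corruption probability applied independently to
#'   every member, in \[0, 0.5). Scalar or one value per class.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @param min_separation Minimum pairwise Hamming distance (bit count)
#'   enforced between class prototypes; 0 disables the check. Used to build
#'   well-separated recovery fixtures.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(class_sizes, m = 1024, prototype_density = 0.05,
                       flip_prob = 0.01, seed = 1, min_separation = 0) {
  class_sizes <- as.integer(class_sizes)
  if (length(class_sizes) < 1 || any(class_sizes < 1)) {
    abort("class_sizes must be positive integers")
  }
  if (sum(class_sizes) < 4) abort("need at least 4 molecules in total")
  g <- length(class_sizes)
  prototype_density <- rep_len(prototype_density, g)
  flip_prob <- rep_len(flip_prob, g)
  if (any(prototype_density <= 0 | prototype_density >= 1)) {
    abort("prototype_density must lie strictly between 0 and 1")
  }
  if (any(flip_prob < 0 | flip_prob >= 0.5)) {
    abort("flip_prob must lie in [0, 0.5)")
  }
  if (m < 1) abort("m must be a positive bit count")
  structure(
    list(class_sizes = class_sizes, m = as.integer(m),
         prototype_density = prototype_density, flip_prob = flip_prob,
         seed = as.integer(seed), min_separation = as.integer(min_separation)),
    class = "synth_spec"
  )
}

#' Generate a fingerprint dataset with planted activity classes
#'
#' Draws one random prototype per class (i.i.d. Bernoulli bits at the class
#' density, resampled until pairwise prototype Hamming distances reach
#' `min_separation`), then corrupts each member bit independently with the
#' class flip probability. Molecule ids encode the planted class
#' (`C<class>_<index>`) so tests can recover the ground truth.
#'
#' @param spec A [synth_spec()].
#' @return A list with elements `fingerprints` (tibble, id + bits),
#'   `activity` (tibble id/class), and `prototypes` (class-by-bit matrix).
#' @export
generate_planted_dataset <- function(spec) {
  if (!inherits(spec, "synth_spec")) abort("spec must be a synth_spec object")
  g <- length(spec$class_sizes)
  m <- spec$m
  withr::with_seed(spec$seed, {
    # fixed-weight prototypes: exactly round(density * m) one-bits at random
    # positions, so the class diversity dial is not blurred by prototype
    # weight variance
    draw_proto <- function(j) {
      w <- max(1L, round(spec$prototype_density[j] * m))
      p <- integer(m)
      p[sample.int(m, w)] <- 1L
      p
    }
    protos <- matrix(0L, g, m)
    for (j in seq_len(g)) protos[j, ] <- draw_proto(j)
    if (spec$min_separation > 0 && g > 1) {
      for (attempt in seq_len(1000L)) {
        ham <- as.matrix(dist(protos, method = "manhattan"))
        diag(ham) <- Inf
        worst <- which(apply(ham, 1, min) < spec$min_separation)
        if (length(worst) == 0) break
        j <- worst[1]
        protos[j, ] <- draw_proto(j)
      }
      ham <- as.matrix(dist(protos, method = "manhattan"))
      diag(ham) <- Inf
      if (min(ham) < spec$min_separation) {
        abort("could not separate prototypes; lower min_separation or raise density")
      }
    }
    n <- sum(spec$class_sizes)
    bits <- matrix(0L, n, m)
    cls <- integer(n)
    row <- 1L
    for (j in seq_len(g)) {
      for (i in seq_len(spec$class_sizes[j])) {
        flips <- stats::rbinom(m, 1L, spec$flip_prob[j])
        bits[row, ] <- as.integer(xor(protos[j, ], flips))
        cls[row] <- j
        row <- row + 1L
      }
    }
    ids <- sprintf("C%02d_%04d", cls, stats::ave(cls, cls, FUN = seq_along))
    colnames(bits) <- paste0("bit", seq_len(m))
    fingerprints <- fp_from_bits(ids, bits)
    activity <- tibble(id = ids, class = factor(paste0("class", cls),
                                                levels = paste0("class", seq_len(g))))
    list(fingerprints = fingerprints, activity = activity, prototypes = protos)
  })
}

#' Mean pairwise Tanimoto similarity of a fingerprint set
#'
#' Tanimoto(x, y) = |x AND y| / |x OR y| on binary vectors, with the
#' convention that two all-zero vectors have similarity 1 (they are
#' identical). The mean is taken over all unordered pairs of rows.
#'
#' @param fp Fingerprint tibble (id + bits) or a binary matrix.
#' @return A similarity in \[0, 1\].
#' @export
mean_pairwise_tanimoto <- function(fp) {
  bits <- if (is.data.frame(fp)) fp_bits(fp) else as.matrix(fp)
  if (nrow(bits) < 2) abort("need at least 2 fingerprints for pairwise similarity")
  storage.mode(bits) <- "double"
  inter <- tcrossprod(bits)
  ones <- rowSums(bits)
  union <- outer(ones, ones, "+") - inter
  sim <- ifelse(union == 0, 1, inter / pmax(union, 1e-300))
  mean(sim[upper.tri(sim)])
}

#' Expected within-class Tanimoto under the bit-flip model
#'
#' For two independent noisy copies of a prototype with 1-bit density `d`
#' corrupted at flip probability `f`, each bit contributes to the
#' intersection with probability d(1-f)^2 + (1-d)f^2 and to the union with
#' probability d(1-f^2) + (1-d)(2f - f^2); the expected Tanimoto is
#' approximated by the ratio of these expectations (tight for large bit
#' counts).
#'
#' @param density Prototype 1-bit density in (0, 1).
#' @param flip_prob Per-bit flip probability in \[0, 0.5).
#' @return The expected similarity.
#' @export
expected_within_class_tanimoto <- function(density, flip_prob) {
  d <- density; f <- flip_prob
  num <- d * (1 - f)^2 + (1 - d) * f^2
  den <- d * (1 - f^2) + (1 - d) * (2 * f - f^2)
  ifelse(den == 0, 1, num / den)
}

#' Calibrate the flip probability to a target within-class diversity
#'
#' Inverts [expected_within_class_tanimoto()] on its low-noise branch (the
#' expectation is monotone decreasing in the flip probability until noise
#' begins to dominate the prototype signal, after which two members look like
#' independent random vectors and similarity creeps back up; only the
#' decreasing branch is useful as a dial).
#'
#' @param target Desired expected within-class mean Tanimoto, in (0, 1).
#' @param density Prototype 1-bit density.
#' @return The flip probability achieving the target expectation.
#' @export
calibrate_flip_prob <- function(target, density) {
  if (target <= 0 || target >= 1) abort("target similarity must be in (0, 1)")
  opt <- stats::optimize(function(f) expected_within_class_tanimoto(density, f),
                         interval = c(0, 0.499))
  if (target < opt$objective) {
    abort(sprintf(
      "target %.3f is below the reachable floor %.3f at density %.3f; lower the density",
      target, opt$objective, density
    ))
  }
  stats::uniroot(
    function(f) expected_within_class_tanimoto(density, f) - target,
    interval = c(0, opt$minimum), tol = 1e-10
  )$root
}
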