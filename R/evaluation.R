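#' Monte-Carlo per-class classification error
#'
#' Draws `mc_samples` points from the class Gaussian and classifies them
#' with the fitted decision model; the error is the fraction that lands
#' outside the class's own decision region. This is a numerical integral
#' of the class Gaussian over the complement of its region — no hold-out
#' set is involved, so it measures geometric class overlap under the
#' fitted uncertainty model rather than generalization error.
#'
#' @param g A `class_gaussian`.
#' @param model A `decision_model` fitted on all classes.
#' @param mc_samples Number of draws, >= 1e3.
#' @param seed Integer seed; the draw is reproducible and leaves the
#'   caller's RNG state untouched.
#' @return Error fraction in `[0, 1]`.
#' @export
estimate_class_error <- function(g, model, mc_samples = 1e5, seed = 1L) {
  stopifnot(inherits(g, "class_gaussian"), inherits(model, "decision_model"))
  if (mc_samples < 1e3) stop("mc_samples must be >= 1000", call. = FALSE)
  d <- length(g$mean)
  draws <- with_seed(seed, {
    if (d == 1) matrix(stats::rnorm(mc_samples, g$mean,
                                    sqrt(g$covariance[1, 1])), ncol = 1)
    else MASS::mvrnorm(mc_samples, g$mean, g$covariance)
  })
  pred <- classify_points(model, draws)
  1 - mean(pred == g$class)
}

#' Mean classification error in percent
#'
#' @param per_class Numeric vector of per-class error fractions.
#' @return 100 times the unweighted mean (classes are balanced by design).
#' @export
mean_error <- function(per_class) {
  if (!length(per_class)) stop("per_class is empty", call. = FALSE)
  100 * mean(per_class)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a predicted and a ground-truth
#' partition, from the pair-counting contingency with the expected-index
#' correction (computed via \code{mclust::adjustedRandIndex}). Equals 1
#' iff the partitions are identical up to relabeling, and has expectation
#' 0 under random labelings.
#'
#' @param true_labels,predicted_labels Equal-length vectors (length >= 2).
#' @return The ARI, a dimensionless value <= 1.
#' @export
adjusted_rand_index <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors have different lengths", call. = FALSE)
  if (length(true_labels) < 2) stop("need at least 2 samples", call. = FALSE)
  mclust::adjustedRandIndex(true_labels, predicted_labels)
}

#' Mean pairwise separation of the class centroids
#'
#' The mean Euclidean distance over all unordered pairs of class means in
#' the embedding plane — the `<D>` trace reported per elimination
#' iteration.
#'
#' @param gaussians List of >= 2 `class_gaussian` objects.
#' @return Mean pairwise centroid distance (embedding units).
#' @export
mean_separation <- function(gaussians) {
  if (length(gaussians) < 2) stop("need at least 2 classes", call. = FALSE)
  means <- do.call(rbind, lapply(gaussians, `[[`, "mean"))
  mean(stats::dist(means))
}
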