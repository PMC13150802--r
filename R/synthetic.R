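#' Specify a synthetic Gaussian screening dataset
#'
#' Describes the screening regime the generator emulates: a few analyte
#' classes, a modest sensor panel, very few replicates per class, and
#' per-class Gaussian sensor responses with partial overlap.
#'
#' @param K Number of analyte classes (>= 2).
#' @param p Number of sensors.
#' @param n_k Replicates per class: scalar or length-K vector, each >= 2.
#' @param means K x p matrix of per-class per-sensor mean responses.
#' @param covariances A single p x p covariance shared by all classes, or
#'   a list of K such matrices. A scalar or length-p vector is taken as a
#'   diagonal.
#' @param informative Optional character/integer ids of the sensors whose
#'   means actually differ across classes (bookkeeping for recovery
#'   experiments).
#' @param seed Integer seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(K, p, n_k, means, covariances = 1,
                           informative = NULL, seed = 1L) {
  K <- as.integer(K); p <- as.integer(p)
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  n_k <- rep_len(as.integer(n_k), K)
  if (any(n_k < 2)) stop("every class needs n_k >= 2", call. = FALSE)
  means <- as.matrix(means)
  if (!identical(dim(means), c(K, p)))
    stop("means must be a K x p matrix", call. = FALSE)
  as_cov <- function(cv) {
    if (is.numeric(cv) && is.null(dim(cv))) cv <- diag(rep_len(cv, p), p)
    cv <- as.matrix(cv)
    if (!identical(dim(cv), c(p, p)))
      stop("covariance must be p x p", call. = FALSE)
    if (any(abs(cv - t(cv)) > 1e-10) ||
        any(eigen(cv, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
      stop("covariance must be symmetric positive semidefinite", call. = FALSE)
    (cv + t(cv)) / 2
  }
  covariances <- if (is.list(covariances)) lapply(covariances, as_cov)
                 else rep(list(as_cov(covariances)), K)
  if (length(covariances) != K)
    stop("need one covariance per class", call. = FALSE)
  structure(list(K = K, p = p, n_k = n_k, means = means,
                 covariances = covariances,
                 informative = informative, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic screening dataset
#'
#' Draws each class's replicates from its Gaussian. Reproducible by the
#' spec seed; the caller's RNG state is untouched.
#'
#' @param spec A [synthetic_spec].
#' @return A list with `table` ([response_table]) and `labeling`
#'   ([class_labeling]); class names are `"C1".."CK"`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  X <- with_seed(spec$seed, {
    do.call(rbind, lapply(seq_len(spec$K), function(k) {
      zero_cov <- all(spec$covariances[[k]] == 0)
      if (zero_cov)
        matrix(rep(spec$means[k, ], each = spec$n_k[k]), spec$n_k[k], spec$p)
      else
        MASS::mvrnorm(spec$n_k[k], spec$means[k, ], spec$covariances[[k]])
    }))
  })
  colnames(X) <- paste0("sensor", seq_len(spec$p))
  labels <- rep(paste0("C", seq_len(spec$K)), spec$n_k)
  list(table = response_table(X),
       labeling = class_labeling(labels))
}

#' Variance-inflation stress dataset
#'
#' Resamples each class from its fitted Gaussian in the PC plane with the
#' mean unchanged and the covariance scaled by `factor^2` (a standard-
#' deviation inflation by `factor`), 50 replicates per class by default —
#' the protocol used to probe how growing experimental uncertainty
#' degrades separability (factors 2, 5 and 10). The PCA loadings of the
#' baseline fit are treated as fixed: when `embedding` is supplied the PC
#' samples are projected back onto the original sensor axes through the
#' baseline loadings, giving a sensor-space table the full pipeline can
#' re-analyze; otherwise the table's "sensors" are the PC coordinates.
#'
#' @param gaussians Baseline list of `class_gaussian` (from an elimination
#'   iteration or a direct fit).
#' @param factor Standard-deviation inflation factor, >= 1.
#' @param samples_per_class Replicates to draw per class (default 50).
#' @param seed Integer seed.
#' @param embedding Optional baseline `embedding` whose loadings map PC
#'   samples back to sensor space.
#' @return A list with `table` and `labeling`.
#' @export
inflate_stress_dataset <- function(gaussians, factor, samples_per_class = 50,
                                   seed = 1L, embedding = NULL) {
  if (factor < 1) stop("inflation factor must be >= 1", call. = FALSE)
  K <- length(gaussians)
  d <- length(gaussians[[1]]$mean)
  scores <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(K), function(k) {
      g <- gaussians[[k]]
      MASS::mvrnorm(samples_per_class, g$mean, factor^2 * g$covariance)
    }))
  })
  labels <- rep(paste0("C", seq_len(K)), each = samples_per_class)
  if (!is.null(embedding)) {
    X <- scores %*% t(embedding$loadings)
    colnames(X) <- embedding$sensor_ids
  } else {
    X <- scores
    colnames(X) <- paste0("PC", seq_len(d))
  }
  list(table = response_table(X), labeling = class_labeling(labels))
}

#' Planted-sensor recovery specification
#'
#' Builds a spec in which only `n_informative` sensors carry class
#' information: their per-class means are laid out so every class pair is
#' at least `separation` apart in the informative subspace, while all
#' remaining sensors respond identically (pure noise) across classes.
#' Used to test whether backward elimination retains exactly the planted
#' sensors.
#'
#' @param K Number of classes.
#' @param p Total sensors.
#' @param n_informative Number of informative sensors (<= p; they are the
#'   first `n_informative` sensor columns).
#' @param separation Minimum inter-class mean distance in the informative
#'   subspace (same units as the noise standard deviation).
#' @param noise_variance Per-sensor response variance (default 1).
#' @param n_k Replicates per class (default 4).
#' @param seed Integer seed.
#' @return A [synthetic_spec] with `informative` set.
#' @export
planted_recovery_spec <- function(K, p, n_informative, separation,
                                  noise_variance = 1, n_k = 4, seed = 1L) {
  if (n_informative > p)
    stop("n_informative must be <= p", call. = FALSE)
  means <- matrix(0, K, p)
  if (n_informative > 0 && separation > 0) {
    if (n_informative == 1) {
      pos <- matrix(seq_len(K) - (K + 1) / 2, ncol = 1)
    } else {
      # classes on a circle in the first two informative axes, the rest 0
      ang <- 2 * pi * (seq_len(K) - 1) / K
      pos <- cbind(cos(ang), sin(ang),
                   matrix(0, K, max(0, n_informative - 2)))
    }
    dmin <- min(stats::dist(pos))
    pos <- pos * (separation / dmin)
    means[, seq_len(n_informative)] <- pos
  }
  synthetic_spec(K, p, n_k, means, covariances = noise_variance,
                 informative = paste0("sensor", seq_len(n_informative)),
                 seed = seed)
}
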