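#' Finite-sample predictive variance inflation
#'
#' Scales an unbiased sample variance so it reflects the posterior
#' predictive spread of a *new* draw when both the class mean and variance
#' were estimated from only `n_k` replicates:
#' \deqn{\tilde\sigma^2 = s^2 (1 + 1/n_k) \frac{n_k - 1}{n_k - 2}, \quad n_k > 2.}
#' The `(1 + 1/n_k)` term accounts for the unknown mean, the
#' `(n_k-1)/(n_k-2)` term for the unknown variance. The factor is > 1 for
#' every finite `n_k > 2` and tends to 1 as replicates accumulate.
#'
#' For `n_k = 2` the variance-uncertainty term diverges, so only the
#' unknown-mean factor `(1 + 1/n_k)` is applied; downstream shrinkage and
#' the eigenvalue floor absorb the remaining uncertainty.
#'
#' @param s2 Unbiased sample variance (>= 0) along a local axis.
#' @param n_k Replicate count, >= 2.
#' @return The inflated variance.
#' @export
predictive_inflate <- function(s2, n_k) {
  if (any(n_k < 2)) stop("n_k must be >= 2", call. = FALSE)
  if (any(s2 < 0)) stop("s2 must be >= 0", call. = FALSE)
  factor <- ifelse(n_k > 2,
                   (1 + 1 / n_k) * (n_k - 1) / (n_k - 2),
                   1 + 1 / n_k)
  s2 * factor
}

#' Build a class Gaussian from its local frame
#'
#' Applies [predictive_inflate()] to each local-axis variance, forms a
#' diagonal covariance in the local coordinates and rotates it back to the
#' global PC plane: the class ellipse is enlarged along its own principal
#' directions while its orientation is preserved. With
#' `inflation = "unadjusted"` the raw class scatter is used unchanged.
#'
#' @param frame A `local_class_frame` from [class_local_pca()].
#' @param inflation `"adjusted"` (default) or `"unadjusted"`.
#' @return An object of class `class_gaussian` with `class`, `mean`,
#'   `covariance` (d x d symmetric), `raw_variances`, `n_k`, `centered`.
#' @export
inflate_class <- function(frame, inflation = c("adjusted", "unadjusted")) {
  stopifnot(inherits(frame, "local_class_frame"))
  inflation <- match.arg(inflation)
  vars <- if (inflation == "adjusted")
    predictive_inflate(frame$variances, frame$n_k) else frame$variances
  R <- frame$rotation
  cov <- R %*% diag(vars, nrow = length(vars)) %*% t(R)
  cov <- (cov + t(cov)) / 2
  structure(list(class = frame$class, mean = frame$mean, covariance = cov,
                 raw_variances = frame$variances, n_k = frame$n_k,
                 centered = frame$centered),
            class = "class_gaussian")
}

# Ledoit-Wolf-style shrinkage intensity of sample covariance S (from
# centered rows Z) toward target T: ratio of the summed sampling variance
# of the covariance entries to the squared distance from the target,
# clipped to [0, 1].
lw_intensity <- function(Z, S, target) {
  n <- nrow(Z)
  if (n < 2) return(1)
  S_ml <- crossprod(Z) / n
  b2 <- 0
  for (i in seq_len(n)) {
    dev <- tcrossprod(Z[i, ]) - S_ml
    b2 <- b2 + sum(dev^2)
  }
  b2 <- b2 / n^2
  d2 <- sum((S - target)^2)
  if (d2 <= .Machine$double.eps) return(0)
  min(1, max(0, b2 / d2))
}

#' Shrink class covariances toward the pooled target and floor eigenvalues
#'
#' Each class covariance is blended with the pooled covariance,
#' `(1 - lambda_k) Sigma_k + lambda_k Sigma_pooled`, with a per-class
#' Ledoit-Wolf-style intensity `lambda_k` estimated from that class's
#' centered scores and clipped to `[0, 1]`. The pooled target is the
#' degrees-of-freedom weighted average `sum((n_k - 1) Sigma_k) / sum(n_k - 1)`.
#' Eigenvalues are then clipped from below at
#' `max(1e-6 * largest pooled eigenvalue, 1e-12)`, a scale-aware floor that
#' repairs rank-deficient classes, so every output is symmetric positive
#' definite and QDA boundaries stay numerically stable.
#'
#' @param gaussians List of `class_gaussian` (>= 2 classes).
#' @param labeling A [class_labeling] (supplies the replicate counts).
#' @return The list of `class_gaussian` with regularized covariances; each
#'   gains a `lambda` element recording its shrinkage intensity.
#' @export
shrink_and_condition <- function(gaussians, labeling) {
  stopifnot(length(gaussians) >= 2)
  dfs <- vapply(gaussians, function(g) g$n_k - 1, numeric(1))
  covs <- lapply(gaussians, `[[`, "covariance")
  pooled <- Reduce(`+`, Map(`*`, covs, dfs)) / sum(dfs)
  floor_val <- max(1e-6 * max(eigen(pooled, symmetric = TRUE,
                                    only.values = TRUE)$values), 1e-12)
  lapply(gaussians, function(g) {
    lam <- lw_intensity(g$centered, g$covariance, pooled)
    cv <- (1 - lam) * g$covariance + lam * pooled
    eg <- eigen((cv + t(cv)) / 2, symmetric = TRUE)
    vals <- pmax(eg$values, floor_val)
    cv <- eg$vectors %*% diag(vals, nrow = length(vals)) %*% t(eg$vectors)
    g$covariance <- (cv + t(cv)) / 2
    g$lambda <- lam
    g
  })
}

#' Confidence ellipse of a 2D class Gaussian
#'
#' The ellipse containing the requested probability mass of the Gaussian:
#' semi-axes `sqrt(q * eigenvalues)` with `q` the chi-squared quantile with
#' 2 degrees of freedom at `level` (5.991 at 0.95), oriented along the
#' covariance eigenvectors.
#'
#' @param g A `class_gaussian` with d = 2.
#' @param level Coverage level in (0, 1); default 0.95.
#' @return An `ellipse_spec`: `center`, `semi_axes` (major, minor),
#'   `angle` (radians of the major axis), `level`.
#' @export
confidence_ellipse <- function(g, level = 0.95) {
  stopifnot(inherits(g, "class_gaussian"))
  if (length(g$mean) != 2)
    stop("confidence_ellipse requires a 2D Gaussian", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must lie in (0,1)", call. = FALSE)
  eg <- eigen(g$covariance, symmetric = TRUE)
  if (any(eg$values <= 0)) stop("covariance is not positive definite", call. = FALSE)
  q <- stats::qchisq(level, df = 2)
  structure(list(center = g$mean,
                 semi_axes = sqrt(q * eg$values),
                 angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
                 level = level),
            class = "ellipse_spec")
}
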