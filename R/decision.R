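#' Fit a decision model over the class Gaussians
#'
#' QDA (the default) uses the per-class regularized covariances; its
#' discriminant for class k is
#' `g_k(x) = -1/2 log|Sigma_k| - 1/2 (x - mu_k)' Sigma_k^-1 (x - mu_k) + log pi_k`.
#' Voronoi ignores the covariances and assigns each point to the nearest
#' class centroid, giving piecewise-linear boundaries at low cost. Priors
#' default to uniform: screening designs are replicate-balanced.
#'
#' @param gaussians List of regularized `class_gaussian` objects (>= 2).
#' @param kind `"qda"` or `"voronoi"`.
#' @param priors Numeric vector of class priors summing to 1; default
#'   uniform.
#' @return An object of class `decision_model`.
#' @export
fit_decision_model <- function(gaussians, kind = c("qda", "voronoi"),
                               priors = NULL) {
  kind <- match.arg(kind)
  K <- length(gaussians)
  if (K < 2) stop("need at least 2 classes", call. = FALSE)
  d <- length(gaussians[[1]]$mean)
  if (is.null(priors)) priors <- rep(1 / K, K)
  if (length(priors) != K || abs(sum(priors) - 1) > 1e-8 || any(priors <= 0))
    stop("priors must be positive and sum to 1", call. = FALSE)
  means <- do.call(rbind, lapply(gaussians, `[[`, "mean"))
  pars <- NULL
  if (kind == "qda") {
    pars <- lapply(gaussians, function(g) {
      eg <- eigen(g$covariance, symmetric = TRUE)
      if (any(eg$values <= 0))
        stop("singular class covariance; regularize before fitting", call. = FALSE)
      list(inv = eg$vectors %*% diag(1 / eg$values, nrow = d) %*% t(eg$vectors),
           logdet = sum(log(eg$values)))
    })
  }
  structure(list(kind = kind, dimension = d, K = K, means = means,
                 priors = priors, gaussians = gaussians, pars = pars),
            class = "decision_model")
}

#' Classify points with a fitted decision model
#'
#' QDA takes the argmax of the quadratic discriminants; Voronoi the argmin
#' of Euclidean distance to the centroids. Ties go to the lowest class
#' index, making the labeling deterministic.
#'
#' @param model A `decision_model`.
#' @param points Numeric matrix (n x d) or vector (d = 1).
#' @return Integer vector of class indices (1..K).
#' @export
classify_points <- function(model, points) {
  stopifnot(inherits(model, "decision_model"))
  if (is.null(dim(points))) points <- matrix(points, ncol = model$dimension)
  points <- as.matrix(points)
  if (ncol(points) != model$dimension)
    stop("points have dimension ", ncol(points), ", model expects ",
         model$dimension, call. = FALSE)
  disc <- decision_scores(model, points)
  max.col(disc, ties.method = "first")
}

# per-class decision scores (higher = preferred), n x K
decision_scores <- function(model, points) {
  K <- model$K
  n <- nrow(points)
  disc <- matrix(0, n, K)
  for (k in seq_len(K)) {
    diffs <- sweep(points, 2, model$means[k, ], "-")
    if (model$kind == "qda") {
      quad <- rowSums((diffs %*% model$pars[[k]]$inv) * diffs)
      disc[, k] <- -0.5 * model$pars[[k]]$logdet - 0.5 * quad +
        log(model$priors[k])
    } else {
      disc[, k] <- -rowSums(diffs^2)
    }
  }
  disc
}

#' Rasterize the decision regions
#'
#' Evaluates the model on a regular grid spanning every class mean plus
#' four standard deviations per axis, so all 99.9% mass regions are
#' covered. Each cell is labeled by classifying its center. The raster is
#' for export and visualization; data points are always classified by
#' direct discriminant evaluation, never by grid lookup.
#'
#' @param model A `decision_model`.
#' @param gaussians The class Gaussians (used only to size the window).
#' @param resolution Cells per axis, >= 50; default 400.
#' @return A `region_grid`: for d = 2 a list with `x`, `y` (cell-center
#'   coordinates) and `class` (resolution x resolution integer matrix);
#'   for d = 1 a list with `x` and `class` vector.
#' @export
region_grid <- function(model, gaussians, resolution = 400) {
  stopifnot(inherits(model, "decision_model"), resolution >= 50)
  d <- model$dimension
  lims <- sapply(seq_len(d), function(j) {
    lo <- hi <- numeric(0)
    for (g in gaussians) {
      sd_j <- sqrt(g$covariance[j, j])
      lo <- c(lo, g$mean[j] - 4 * sd_j)
      hi <- c(hi, g$mean[j] + 4 * sd_j)
    }
    c(min(lo), max(hi))
  })
  ax <- lapply(seq_len(d), function(j)
    seq(lims[1, j], lims[2, j], length.out = resolution))
  if (d == 1) {
    cls <- classify_points(model, matrix(ax[[1]], ncol = 1))
    out <- list(x = ax[[1]], class = cls, dimension = 1L)
  } else {
    pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]]))
    cls <- matrix(classify_points(model, pts), resolution, resolution)
    out <- list(x = ax[[1]], y = ax[[2]], class = cls, dimension = 2L)
  }
  structure(out, class = "region_grid")
}

#' @export
as.data.frame.region_grid <- function(x, ...) {
  if (x$dimension == 1L) return(data.frame(x = x$x, class = x$class))
  data.frame(x = rep(x$x, times = length(x$y)),
             y = rep(x$y, each = length(x$x)),
             class = as.vector(x$class))
}
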