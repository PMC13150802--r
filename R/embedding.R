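#' Global PCA of the current sensor set
#'
#' Principal-component analysis of the (mean-centered) response matrix.
#' The top two components are retained (one if `p = 1`); the full
#' explained-variance spectrum is kept for the dimensionality switch and
#' for reporting. A deterministic sign convention is applied: the
#' largest-magnitude loading entry of each component is made positive, so
#' repeated runs give identical score signs.
#'
#' @param table A mean-centered [response_table].
#' @return An object of class `embedding` with `loadings` (p x d),
#'   `scores` (n x d), `ev_ratio` (length `min(n-1, p)`, non-increasing,
#'   summing to 1), `sdev`, and `dimension` (d, 1 or 2).
#' @export
global_pca <- function(table) {
  stopifnot(inherits(table, "response_table"))
  x <- sweep(table$values, 2, colMeans(table$values), "-")
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  if (all(pc$sdev < 1e-14))
    stop("rank-0 data: all samples identical", call. = FALSE)
  d <- min(2L, table$p)
  load <- pc$rotation[, seq_len(d), drop = FALSE]
  # sign convention: force largest-|loading| entry of each component positive
  for (j in seq_len(d)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  scores <- x %*% load
  var_all <- pc$sdev^2
  ev_ratio <- var_all / sum(var_all)
  structure(list(loadings = load, scores = scores, ev_ratio = ev_ratio,
                 sdev = pc$sdev, dimension = d,
                 sensor_ids = table$sensor_ids),
            class = "embedding")
}

#' Restrict an embedding to its first `d` components
#'
#' @param embedding An [global_pca()] result.
#' @param d 1 or 2, at most `embedding$dimension`.
#' @return The truncated `embedding`.
#' @export
truncate_embedding <- function(embedding, d) {
  stopifnot(inherits(embedding, "embedding"), d %in% c(1L, 2L),
            d <= embedding$dimension)
  embedding$loadings <- embedding$loadings[, seq_len(d), drop = FALSE]
  embedding$scores <- embedding$scores[, seq_len(d), drop = FALSE]
  embedding$dimension <- as.integer(d)
  embedding
}

#' Decide between a 1D and a 2D decision space
#'
#' Returns 1 when the explained-variance flag is active and PC1 explains
#' strictly more than the threshold, or when only one sensor survives;
#' otherwise 2. With the flag off (the default) the two-dimensional
#' decision plane is always kept so boundaries stay visualisable.
#'
#' @param embedding An `embedding`.
#' @param config A [pipeline_config].
#' @return Integer 1 or 2.
#' @export
choose_dimension <- function(embedding, config) {
  stopifnot(inherits(embedding, "embedding"))
  if (embedding$dimension == 1L) return(1L)
  if (isTRUE(config$ev_flag) && embedding$ev_ratio[1] > config$ev_threshold)
    return(1L)
  2L
}

#' Per-class local PCA in the embedding plane
#'
#' For each class, the class scores are mean-centered and decomposed into
#' their own principal axes; the axis variances are unbiased sample
#' variances along those axes. These local frames carry the orientation
#' and spread that the predictive variance inflation acts on. A class
#' whose points are all identical gets the identity rotation and zero
#' variances.
#'
#' @param embedding An `embedding` (already truncated to the decision
#'   dimension).
#' @param labeling A [class_labeling].
#' @return A list of `local_class_frame` objects, one per class, each with
#'   `class`, `rotation` (d x d, columns = local axes), `variances`
#'   (length d, non-increasing), `mean` (length d, in global PC
#'   coordinates), `n_k`, and `centered` (n_k x d centered class scores).
#' @export
class_local_pca <- function(embedding, labeling) {
  stopifnot(inherits(embedding, "embedding"), inherits(labeling, "class_labeling"))
  d <- embedding$dimension
  lapply(seq_len(labeling$K), function(k) {
    s <- embedding$scores[labeling$labels == k, , drop = FALSE]
    n_k <- nrow(s)
    if (n_k < 2) stop("class ", k, " has fewer than 2 samples", call. = FALSE)
    mu <- colMeans(s)
    z <- sweep(s, 2, mu, "-")
    scatter <- crossprod(z) / (n_k - 1)
    if (all(abs(scatter) < 1e-28)) {
      rot <- diag(d); vars <- rep(0, d)
    } else {
      eg <- eigen(scatter, symmetric = TRUE)
      rot <- eg$vectors
      vars <- pmax(eg$values, 0)
      for (j in seq_len(d)) {
        i <- which.max(abs(rot[, j]))
        if (rot[i, j] < 0) rot[, j] <- -rot[, j]
      }
    }
    structure(list(class = k, rotation = rot, variances = vars,
                   mean = mu, n_k = n_k, centered = z),
              class = "local_class_frame")
  })
}
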