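#' Restrict a response table to a subset of sensors
#'
#' @param table A [response_table].
#' @param sensor_ids Character vector of sensors to keep (order respected).
#' @return A [response_table] with only those sensors.
#' @export
subset_sensors <- function(table, sensor_ids) {
  stopifnot(inherits(table, "response_table"))
  missing_ids <- setdiff(sensor_ids, table$sensor_ids)
  if (length(missing_ids))
    stop("unknown sensor(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  response_table(table$values[, sensor_ids, drop = FALSE],
                 sensor_ids, table$sample_ids)
}

# 1D QDA threshold between two classes (uniform priors): solve
# log s2a + (x-ma)^2/s2a = log s2b + (x-mb)^2/s2b for x between the means;
# fall back to the midpoint when no real root lies between them.
qda1d_threshold <- function(ma, s2a, mb, s2b) {
  mid <- (ma + mb) / 2
  if (abs(s2a - s2b) < 1e-12 * max(s2a, s2b, 1e-300)) return(mid)
  A <- 1 / s2a - 1 / s2b
  B <- -2 * (ma / s2a - mb / s2b)
  C <- ma^2 / s2a - mb^2 / s2b + log(s2a / s2b)
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(mid)
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  lo <- min(ma, mb); hi <- max(ma, mb)
  inside <- roots[roots > lo & roots < hi]
  if (!length(inside)) return(mid)
  inside[which.min(abs(inside - mid))]
}

#' Build a decision-aware ruler for one sensor
#'
#' Orders the classes by increasing mean response on this sensor and
#' places a threshold between each consecutive pair: the midpoint of the
#' two class means in `"voronoi"` mode, or the 1D QDA boundary in
#' `"qda1d"` mode. For QDA thresholds the per-class variances are first
#' inflated for finite samples (see [predictive_inflate()]), shrunk toward
#' the pooled variance and floored, mirroring the 2D regularization;
#' when the discriminant equality has no real root between the two means
#' the midpoint is used. Duplicate thresholds (classes with identical
#' means) are deduplicated, so such classes share an interval.
#'
#' @param sensor_values Numeric vector of this sensor's readings.
#' @param labeling A [class_labeling].
#' @param mode `"voronoi"` or `"qda1d"`.
#' @param inflation `"adjusted"` or `"unadjusted"` (qda1d mode only).
#' @param sensor_id Optional sensor name carried in the result.
#' @return A `sensor_ruler`: `thresholds` (strictly increasing),
#'   `interval_class` (class index per interval), `class_order` (classes
#'   by increasing mean), `class_means`, `class_vars`.
#' @export
build_ruler <- function(sensor_values, labeling,
                        mode = c("voronoi", "qda1d"),
                        inflation = c("adjusted", "unadjusted"),
                        sensor_id = NULL) {
  mode <- match.arg(mode)
  inflation <- match.arg(inflation)
  stopifnot(inherits(labeling, "class_labeling"),
            length(sensor_values) == labeling$n)
  K <- labeling$K
  mus <- vapply(seq_len(K), function(k)
    mean(sensor_values[labeling$labels == k]), numeric(1))
  s2 <- vapply(seq_len(K), function(k)
    stats::var(sensor_values[labeling$labels == k]), numeric(1))
  ord <- order(mus)

  if (mode == "qda1d") {
    v <- if (inflation == "adjusted")
      predictive_inflate(s2, labeling$counts) else s2
    dfs <- labeling$counts - 1
    pooled <- sum(dfs * v) / sum(dfs)
    lam <- vapply(seq_len(K), function(k) {
      z <- matrix(sensor_values[labeling$labels == k] - mus[k], ncol = 1)
      lw_intensity(z, matrix(v[k], 1, 1), matrix(pooled, 1, 1))
    }, numeric(1))
    v <- (1 - lam) * v + lam * pooled
    floor_val <- max(1e-6 * pooled, 1e-12)
    v <- pmax(v, floor_val)
  } else {
    v <- s2
  }

  thr <- numeric(0)
  if (K >= 2) {
    for (i in seq_len(K - 1)) {
      a <- ord[i]; b <- ord[i + 1]
      t_ab <- if (mode == "voronoi") (mus[a] + mus[b]) / 2
              else qda1d_threshold(mus[a], v[a], mus[b], v[b])
      thr <- c(thr, t_ab)
    }
  }
  thr <- unique(sort(thr))

  n_int <- length(thr) + 1L
  # map each interval to the first (lowest-mean) class whose mean falls in it
  cls_int <- findInterval(mus[ord], thr, left.open = TRUE) + 1L
  interval_class <- integer(n_int)
  for (i in seq_len(n_int)) {
    in_i <- ord[cls_int == i]
    interval_class[i] <- if (length(in_i)) in_i[1] else NA_integer_
  }
  if (anyNA(interval_class)) {   # orphan intervals inherit the nearest class
    filled <- which(!is.na(interval_class))
    for (i in which(is.na(interval_class)))
      interval_class[i] <- interval_class[filled[which.min(abs(filled - i))]]
  }
  structure(list(sensor_id = sensor_id, thresholds = thr,
                 interval_class = interval_class, class_order = ord,
                 class_means = mus, class_vars = v),
            class = "sensor_ruler")
}

#' Discretize sensor readings with a ruler
#'
#' Maps each value to the index of the ruler interval containing it.
#' Values lying exactly on a threshold go to the left interval.
#'
#' @param values Numeric vector.
#' @param ruler A `sensor_ruler`.
#' @return Integer bin index per value (1 .. number of intervals).
#' @export
discretize <- function(values, ruler) {
  stopifnot(inherits(ruler, "sensor_ruler"))
  findInterval(values, ruler$thresholds, left.open = TRUE) + 1L
}

#' Pearson chi-squared between discretized bins and class labels
#'
#' The plain Pearson statistic `sum((O - E)^2 / E)` on the bin-by-label
#' contingency, without continuity correction. A degenerate table (fewer
#' than two occupied bins or labels) scores 0: such a sensor carries no
#' marginal class information.
#'
#' @param bins Integer bin index per sample.
#' @param labels Class label per sample.
#' @return The chi-squared statistic (>= 0).
#' @export
chi_squared_score <- function(bins, labels) {
  if (length(bins) != length(labels))
    stop("bins and labels have different lengths", call. = FALSE)
  tab <- table(bins, labels)
  if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
  unname(suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic))
}

#' Pairwise-weighted chi-squared score
#'
#' For every class pair (a, b) the Pearson statistic is recomputed on the
#' samples of those two classes only — using the same bins as the full
#' ruler — and the pairwise statistics are averaged with weights
#' `w(a,b) proportional to 1/Delta(a,b)`, normalized to sum to 1, where
#' `Delta(a,b)` is the distance between the two class centroids along the
#' sensor axis. Hard-to-separate pairs therefore dominate the score.
#' Coincident centroids (`Delta = 0`) are capped at `1e-9` times the data
#' range so their weight is large but finite.
#'
#' @param bins Integer bin index per sample (from the full ruler).
#' @param labels Class index per sample (1..K).
#' @param values The sensor readings (used for the class centroids).
#' @param deltas Optional K x K matrix of pair separations overriding the
#'   sample-centroid distances.
#' @return The weighted statistic (>= 0).
#' @export
weighted_chi_squared_score <- function(bins, labels, values, deltas = NULL) {
  labels <- as.integer(labels)
  K <- max(labels)
  if (K < 2) stop("need at least 2 classes", call. = FALSE)
  mus <- vapply(seq_len(K), function(k) mean(values[labels == k]), numeric(1))
  rng <- diff(range(values))
  eps <- 1e-9 * if (rng > 0) rng else 1
  pairs <- utils::combn(K, 2)
  w <- numeric(ncol(pairs)); x2 <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    delta <- if (!is.null(deltas)) deltas[a, b] else abs(mus[a] - mus[b])
    w[j] <- 1 / max(delta, eps)
    keep <- labels %in% c(a, b)
    x2[j] <- chi_squared_score(bins[keep], labels[keep])
  }
  w <- w / sum(w)
  sum(w * x2)
}

#' Pick the sensor to eliminate
#'
#' Removes the sensor with the lowest score — the one contributing least
#' to class discrimination. Ties go to the earlier sensor in table order.
#'
#' @param scores Named numeric vector of per-sensor scores (>= 2 sensors).
#' @return The sensor id to remove.
#' @export
eliminate_one <- function(scores) {
  if (length(scores) < 2)
    stop("only one sensor left; elimination must stop", call. = FALSE)
  names(scores)[which.min(scores)]
}

#' Run the backward-elimination loop
#'
#' At every iteration, on the surviving sensor subset: mean-center,
#' recompute the global PCA and (optionally) the 1D/2D switch, fit the
#' per-class Gaussians with inflation, shrinkage and conditioning, fit the
#' decision model, and record the Monte-Carlo mean error, ARI of the
#' training samples, and mean centroid separation. Then every surviving
#' sensor is scored by (weighted) chi-squared on its decision-aware bins —
#' thresholds are rebuilt each iteration so the discretization tracks the
#' evolving classifier — and the lowest-scoring sensor is removed. The
#' loop continues until one sensor remains. Fully deterministic given
#' `config$seed`.
#'
#' @param table A [response_table] (raw; centering is done internally per
#'   subset).
#' @param labeling A [class_labeling].
#' @param config A [pipeline_config].
#' @return An `elimination_trace`: per-iteration records (including fitted
#'   Gaussians and models for export), the removal order, and the config.
#' @export
run_elimination <- function(table, labeling, config = pipeline_config()) {
  stopifnot(inherits(table, "response_table"),
            inherits(labeling, "class_labeling"),
            inherits(config, "pipeline_config"))
  if (table$n != labeling$n)
    stop("table and labeling sample counts differ", call. = FALSE)
  ruler_mode <- if (config$classifier == "qda") "qda1d" else "voronoi"
  surviving <- table$sensor_ids
  iterations <- vector("list", table$p)
  removed_log <- character(0)

  for (step in seq_len(table$p)) {
    l <- length(surviving)
    centered <- mean_center(subset_sensors(table, surviving))
    emb <- global_pca(centered)
    d <- choose_dimension(emb, config)
    emb <- truncate_embedding(emb, d)
    frames <- class_local_pca(emb, labeling)
    gaussians <- lapply(frames, inflate_class, inflation = config$inflation)
    gaussians <- shrink_and_condition(gaussians, labeling)
    model <- fit_decision_model(gaussians, kind = config$classifier)

    per_class <- vapply(seq_len(labeling$K), function(k)
      estimate_class_error(gaussians[[k]], model, config$mc_samples,
                           seed = mc_seed(config$seed, l, k)),
      numeric(1))
    pred <- classify_points(model, emb$scores)
    rec <- list(n_sensors = l,
                per_class = per_class,
                mean_error = mean_error(per_class),
                ari = adjusted_rand_index(labeling$labels, pred),
                mean_separation = mean_separation(gaussians),
                ev1 = emb$ev_ratio[1],
                ev2 = if (length(emb$ev_ratio) > 1) emb$ev_ratio[2] else NA_real_,
                dimension = d)

    removed <- NA_character_
    scores <- NULL
    if (l > 1) {
      scores <- vapply(surviving, function(s) {
        vals <- centered$values[, s]
        ruler <- build_ruler(vals, labeling, mode = ruler_mode,
                             inflation = config$inflation, sensor_id = s)
        bins <- discretize(vals, ruler)
        if (config$fs_mode == "uniform") chi_squared_score(bins, labeling$labels)
        else weighted_chi_squared_score(bins, labeling$labels, vals)
      }, numeric(1))
      removed <- eliminate_one(scores)
      removed_log <- c(removed_log, removed)
    }
    iterations[[step]] <- list(n_sensors = l, sensors = surviving,
                               removed = removed, record = rec,
                               scores = scores, gaussians = gaussians,
                               model = model, embedding = emb)
    surviving <- setdiff(surviving, removed)
  }
  structure(list(iterations = iterations, p = table$p,
                 sensor_ids = table$sensor_ids,
                 elimination_order = removed_log, config = config),
            class = "elimination_trace")
}

# deterministic per-iteration per-class Monte-Carlo seed from the root seed
mc_seed <- function(root, l, k) {
  (as.numeric(root) + 7919 * l + 131 * k) %% 2147483647
}

#' @export
as.data.frame.elimination_trace <- function(x, ...) {
  do.call(rbind, lapply(x$iterations, function(it) {
    r <- it$record
    data.frame(n_sensors = r$n_sensors,
               removed_sensor = it$removed,
               mean_error = r$mean_error, ari = r$ari,
               mean_separation = r$mean_separation,
               ev1 = r$ev1, ev2 = r$ev2, dimension = r$dimension,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat("elimination_trace:", x$p, "sensors ->", 1, "\n")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Select the working sensor count for a penalty
#'
#' Minimizes the cost `J(l) = e(l) + eta * l` over `l = 1..p`, where
#' `e(l)` is the mean error (in percent) with `l` sensors and `eta` is
#' the penalty (percent error per additional sensor). Ties go to the
#' smaller `l` — parsimony wins when the cost is equal.
#'
#' @param trace An `elimination_trace`.
#' @param eta Penalty >= 0 (percent per sensor). The field defaults are 3
#'   (sparsity-leaning) and 0.5 (accuracy-leaning).
#' @return A `working_point`: `eta`, `l_star`, the selected `sensors`,
#'   `e_at_lstar`, and the full `J` and `e` curves (named by `l`).
#' @export
select_working_point <- function(trace, eta) {
  stopifnot(inherits(trace, "elimination_trace"), eta >= 0)
  l <- vapply(trace$iterations, function(it) it$n_sensors, numeric(1))
  e <- vapply(trace$iterations, function(it) it$record$mean_error, numeric(1))
  J <- e + eta * l
  best <- min(l[J == min(J)])
  idx <- which(l == best)
  structure(list(eta = eta, l_star = as.integer(best),
                 sensors = trace$iterations[[idx]]$sensors,
                 e_at_lstar = e[idx],
                 J = stats::setNames(J, l), e = stats::setNames(e, l)),
            class = "working_point")
}

#' @export
print.working_point <- function(x, ...) {
  cat(sprintf("working_point: eta = %g%%/sensor -> l* = %d (e = %.3f%%)\n",
              x$eta, x$l_star, x$e_at_lstar))
  cat("  sensors:", paste(x$sensors, collapse = ", "), "\n")
  invisible(x)
}

#' Sweep the working point over a range of penalties
#'
#' @param trace An `elimination_trace`.
#' @param etas Numeric vector of penalties (>= 0).
#' @return A data.frame with columns `eta`, `l_star`, `e_at_lstar`;
#'   `l_star` is a non-increasing step function of `eta`.
#' @export
eta_sweep <- function(trace, etas) {
  etas <- sort(etas)
  res <- lapply(etas, function(h) {
    wp <- select_working_point(trace, h)
    data.frame(eta = h, l_star = wp$l_star, e_at_lstar = wp$e_at_lstar)
  })
  do.call(rbind, res)
}
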