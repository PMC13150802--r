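test_that("Voronoi rulers place thresholds at consecutive-class midpoints", {
  lab <- class_labeling(rep(c("A", "B"), each = 3))
  vals <- c(-0.5, 0, 0.5, 1.5, 2, 2.5)  # class means 0 and 2
  r <- build_ruler(vals, lab, mode = "voronoi")
  expect_equal(r$thresholds, 1)
  expect_equal(r$interval_class, c(1L, 2L))

  lab3 <- class_labeling(rep(c("A", "B", "C"), each = 2))
  vals3 <- c(-0.1, 0.1, 0.9, 1.1, 3.9, 4.1)  # means 0, 1, 4
  r3 <- build_ruler(vals3, lab3, mode = "voronoi")
  expect_equal(r3$thresholds, c(0.5, 2.5))
  expect_equal(r3$class_order, 1:3)
})

test_that("1D QDA thresholds reduce to midpoints when variances are equal", {
  lab <- class_labeling(rep(c("A", "B", "C"), each = 2))
  vals <- c(0, 1, 2, 3, 6, 7)  # equal within-class variances (0.5 each)
  rq <- build_ruler(vals, lab, mode = "qda1d")
  rv <- build_ruler(vals, lab, mode = "voronoi")
  expect_equal(rq$thresholds, rv$thresholds, tolerance = 1e-9)
})

test_that("1D QDA thresholds solve the discriminant equality (root oracle)", {
  # unequal variances, n_k = 4 per class
  set.seed(51)
  a <- c(-0.2, 0, 0.1, 0.3); b <- 4 + c(-2, -0.5, 0.5, 2.2)
  lab <- class_labeling(rep(1:2, each = 4))
  r <- build_ruler(c(a, b), lab, mode = "qda1d", inflation = "unadjusted")
  # oracle: brute-force root of the 1D discriminant difference between the
  # class means, with the same shrunk/floored variances the ruler records
  v <- r$class_vars; mu <- r$class_means
  f <- function(x) (log(v[1]) + (x - mu[1])^2 / v[1]) -
                   (log(v[2]) + (x - mu[2])^2 / v[2])
  root <- uniroot(f, c(mu[1], mu[2]), tol = 1e-12)$root
  expect_equal(r$thresholds, root, tolerance = 1e-8)
})

test_that("discretization respects intervals and the left-assignment tie rule", {
  r <- structure(list(sensor_id = "s", thresholds = c(0.5, 2.5),
                      interval_class = 1:3, class_order = 1:3,
                      class_means = c(0, 1, 4), class_vars = c(1, 1, 1)),
                 class = "sensor_ruler")
  expect_equal(discretize(c(-1, 1.2, 3.0), r), c(1L, 2L, 3L))
  expect_equal(discretize(0.5, r), 1L)   # on-threshold goes left
  expect_equal(discretize(2.5, r), 2L)
})

test_that("Pearson chi-squared matches hand-computed contingencies", {
  # perfect 2-class separation, 5 + 5 samples -> n * (k - 1) = 10
  bins <- rep(1:2, each = 5); labs <- rep(c("A", "B"), each = 5)
  expect_equal(chi_squared_score(bins, labs), 10)
  # 3-class perfect diagonal, n = 9 -> 18
  expect_equal(chi_squared_score(rep(1:3, each = 3), rep(1:3, each = 3)), 18)
  # bins independent of labels -> 0
  expect_equal(chi_squared_score(rep(1:2, 4), rep(c("A", "B"), each = 4)), 0)
  # degenerate tables score 0
  expect_equal(chi_squared_score(rep(1L, 8), rep(c("A", "B"), each = 4)), 0)
})

test_that("chi-squared is invariant to relabeling and ruler-preserving maps", {
  set.seed(52)
  bins <- sample(1:3, 30, TRUE); labs <- sample(1:3, 30, TRUE)
  relab <- c(3L, 1L, 2L)[labs]
  expect_equal(chi_squared_score(bins, labs), chi_squared_score(bins, relab))
  # a strictly increasing transform preserving interval membership keeps bins
  # identical, hence the same score by construction
  rebin <- c(2L, 3L, 1L)[bins]  # renaming bins is also immaterial
  expect_equal(chi_squared_score(bins, labs), chi_squared_score(rebin, labs))
})

test_that("weighted chi-squared reduces and weights as specified", {
  # K = 2: single pair, equals the plain score
  bins <- rep(1:2, each = 5); labs <- rep(1:2, each = 5)
  vals <- c(rnorm(5), rnorm(5) + 3)
  expect_equal(weighted_chi_squared_score(bins, labs, vals),
               chi_squared_score(bins, labs))
  # all deltas equal -> unweighted mean of pairwise statistics
  set.seed(53)
  labs3 <- rep(1:3, each = 4)
  bins3 <- sample(1:3, 12, TRUE)
  vals3 <- rnorm(12)
  deq <- matrix(1, 3, 3)
  pair_mean <- mean(c(
    chi_squared_score(bins3[labs3 != 3], labs3[labs3 != 3]),
    chi_squared_score(bins3[labs3 != 2], labs3[labs3 != 2]),
    chi_squared_score(bins3[labs3 != 1], labs3[labs3 != 1])))
  expect_equal(weighted_chi_squared_score(bins3, labs3, vals3, deltas = deq),
               pair_mean)
  # deltas (1, 3, 3) -> weights (0.6, 0.2, 0.2)
  dd <- matrix(0, 3, 3); dd[1, 2] <- 1; dd[1, 3] <- 3; dd[2, 3] <- 3
  x2 <- c(chi_squared_score(bins3[labs3 != 3], labs3[labs3 != 3]),
          chi_squared_score(bins3[labs3 != 2], labs3[labs3 != 2]),
          chi_squared_score(bins3[labs3 != 1], labs3[labs3 != 1]))
  expect_equal(weighted_chi_squared_score(bins3, labs3, vals3, deltas = dd),
               sum(c(0.6, 0.2, 0.2) * x2))
})

test_that("elimination removes the minimum score with first-index ties", {
  expect_equal(eliminate_one(c(a = 10, b = 0.1, c = 7)), "b")
  expect_equal(eliminate_one(c(a = 3, b = 3, c = 5)), "a")
  expect_error(eliminate_one(c(a = 1)), "stop")
})

test_that("the elimination loop visits every sensor exactly once, nested", {
  ds <- tiny_dataset()
  X <- cbind(ds$table$values, s3 = c(0.3, 0.31, 0.29, 0.3, 0.32, 0.28))
  tab <- response_table(X, c("sA", "sB", "s3"))
  cfg <- pipeline_config(mc_samples = 1000, seed = 5)
  tr <- run_elimination(tab, ds$labeling, cfg)
  expect_length(tr$iterations, 3)
  expect_equal(vapply(tr$iterations, function(it) it$n_sensors, numeric(1)),
               c(3, 2, 1))
  expect_length(tr$elimination_order, 2)
  # every sensor appears exactly once as removed or final survivor
  final <- tr$iterations[[3]]$sensors
  expect_setequal(c(tr$elimination_order, final), tab$sensor_ids)
  # strictly nested surviving sets
  for (i in 2:3)
    expect_true(all(tr$iterations[[i]]$sensors %in%
                    tr$iterations[[i - 1]]$sensors))
  # pure-noise sensor s3 is eliminated first
  expect_equal(tr$elimination_order[1], "s3")
})

test_that("reruns with the same seed give identical traces", {
  spec <- planted_recovery_spec(3, 5, 2, separation = 4, n_k = 3, seed = 8)
  ds <- generate_dataset(spec)
  cfg <- pipeline_config(mc_samples = 1000, seed = 17)
  t1 <- run_elimination(ds$table, ds$labeling, cfg)
  t2 <- run_elimination(ds$table, ds$labeling, cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(t1$elimination_order, t2$elimination_order)
})

test_that("working-point selection minimizes J with parsimony tie-breaks", {
  # enumeration example: e(1..3) = (10, 2, 1.9), eta = 3 -> J = (13, 8, 10.9)
  tr <- fabricate_trace(c(10, 2, 1.9))
  wp <- select_working_point(tr, 3)
  expect_equal(unname(wp$J[order(as.numeric(names(wp$J)))]), c(13, 8, 10.9))
  expect_equal(wp$l_star, 2L)
  expect_equal(wp$sensors, c("s1", "s2"))
  # pure penalty: zero error everywhere -> one sensor
  expect_equal(select_working_point(fabricate_trace(c(0, 0, 0, 0)), 2)$l_star, 1L)
  # no penalty: argmin of e, smallest l on ties
  expect_equal(select_working_point(fabricate_trace(c(5, 1, 1)), 0)$l_star, 2L)
  # J - e = eta * l exactly
  expect_equal(unname(wp$J - wp$e), 3 * as.numeric(names(wp$J)))
})

test_that("l*(eta) is a non-increasing step function over any sweep", {
  set.seed(54)
  for (i in 1:10) {
    tr <- fabricate_trace(cumsum(abs(rnorm(8))) [sample(8)])
    sw <- eta_sweep(tr, seq(0, 6, by = 0.25))
    expect_true(all(diff(sw$l_star) <= 0))
  }
})
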