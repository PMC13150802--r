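test_that("generated samples reproduce the spec moments at large n", {
  spec <- synthetic_spec(2, 3, n_k = 1000,
                         means = rbind(rep(0, 3), rep(5, 3)),
                         covariances = 1, seed = 61)
  ds <- generate_dataset(spec)
  expect_equal(ds$table$n, 2000)
  x1 <- ds$table$values[ds$labeling$labels == 1, ]
  expect_lt(max(abs(colMeans(x1))), 0.1)
  expect_lt(max(abs(apply(x1, 2, var) - 1)), 0.1)
  # empirical moments tighten roughly like 1/sqrt(n)
  spec_small <- synthetic_spec(2, 3, n_k = 10,
                               means = rbind(rep(0, 3), rep(5, 3)),
                               covariances = 1, seed = 61)
  reps <- vapply(1:40, function(i) {
    s <- spec_small; s$seed <- i
    mean(colMeans(generate_dataset(s)$table$values[1:10, ])^2)
  }, numeric(1))
  expect_equal(mean(reps), 1 / 10 * 3 / 3, tolerance = 0.5)
})

test_that("zero covariance collapses samples onto the means; seeds reproduce", {
  spec <- synthetic_spec(2, 2, n_k = 3,
                         means = rbind(c(1, 2), c(3, 4)),
                         covariances = 0, seed = 62)
  ds <- generate_dataset(spec)
  expect_equal(unname(ds$table$values[1:3, ]),
               matrix(rep(c(1, 2), each = 3), 3))
  spec2 <- synthetic_spec(3, 4, n_k = 4, means = matrix(rnorm(12), 3, 4),
                          covariances = 2, seed = 63)
  expect_identical(generate_dataset(spec2)$table$values,
                   generate_dataset(spec2)$table$values)
  expect_error(synthetic_spec(2, 2, 3, matrix(0, 2, 2),
                              covariances = matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
})

test_that("stress resampling scales the covariance by the squared factor", {
  gs <- list(make_gaussian(1, c(0, 0), diag(c(1, 0.25))),
             make_gaussian(2, c(5, 0), diag(c(1, 0.25))))
  base <- inflate_stress_dataset(gs, 1, samples_per_class = 4000, seed = 64)
  infl <- inflate_stress_dataset(gs, 2, samples_per_class = 4000, seed = 64)
  v_base <- apply(base$table$values[base$labeling$labels == 1, ], 2, var)
  v_infl <- apply(infl$table$values[infl$labeling$labels == 1, ], 2, var)
  expect_equal(unname(v_infl / v_base), c(4, 4), tolerance = 0.1)
  # means unchanged
  expect_lt(max(abs(colMeans(infl$table$values[infl$labeling$labels == 2, ]) -
                    c(5, 0))), 0.15)
  expect_equal(infl$labeling$counts, c(4000L, 4000L))
  expect_error(inflate_stress_dataset(gs, 0.5), "factor")
})

test_that("stress samples can be projected back through baseline loadings", {
  ds <- generate_dataset(planted_recovery_spec(3, 6, 2, 6, n_k = 4, seed = 65))
  emb <- truncate_embedding(global_pca(mean_center(ds$table)), 2L)
  frames <- class_local_pca(emb, ds$labeling)
  gs <- shrink_and_condition(lapply(frames, inflate_class), ds$labeling)
  out <- inflate_stress_dataset(gs, 2, samples_per_class = 10, seed = 66,
                                embedding = emb)
  expect_equal(out$table$p, 6)
  expect_equal(out$table$sensor_ids, ds$table$sensor_ids)
  # the projected table lies in the 2D plane spanned by the loadings
  expect_equal(qr(out$table$values)$rank, 2)
})

test_that("higher stress factors give strictly more downstream error", {
  mus <- rbind(c(0, 0), c(3, 0), c(1.5, 2.5))
  gs <- lapply(1:3, function(k) make_gaussian(k, mus[k, ], diag(2)))
  err_at <- vapply(c(2, 10), function(f) {
    ds <- inflate_stress_dataset(gs, f, samples_per_class = 50, seed = 67)
    emb <- truncate_embedding(global_pca(mean_center(ds$table)), 2L)
    frames <- class_local_pca(emb, ds$labeling)
    g2 <- shrink_and_condition(lapply(frames, inflate_class), ds$labeling)
    m <- fit_decision_model(g2, "qda")
    mean_error(vapply(1:3, function(k)
      estimate_class_error(g2[[k]], m, 1e4, seed = 68 + k), numeric(1)))
  }, numeric(1))
  expect_gt(err_at[2], err_at[1])
})

test_that("planted specs span chance-level to separable regimes", {
  # separation 0: no sensor informative; full overlap puts the mean error
  # at the chance level (K - 1) / K under the deterministic tie rule
  spec0 <- planted_recovery_spec(4, 6, 2, separation = 0, n_k = 3, seed = 69)
  ds0 <- generate_dataset(spec0)
  expect_true(all(ds0$table$values[, 3:6] != 0))  # noise sensors still vary
  emb <- truncate_embedding(global_pca(mean_center(ds0$table)), 2L)
  frames <- class_local_pca(emb, ds0$labeling)
  gs <- shrink_and_condition(lapply(frames, inflate_class), ds0$labeling)
  m <- fit_decision_model(gs, "qda")
  errs <- vapply(1:4, function(k)
    estimate_class_error(gs[[k]], m, 5e3, seed = 70 + k), numeric(1))
  expect_equal(mean_error(errs), 100 * 3 / 4, tolerance = 12)
  # large separation: first-iteration error is essentially zero
  spec_big <- planted_recovery_spec(4, 6, 2, separation = 12, n_k = 4, seed = 71)
  ds1 <- generate_dataset(spec_big)
  cfg <- pipeline_config(mc_samples = 1000, seed = 72)
  tr <- run_elimination(ds1$table, ds1$labeling, cfg)
  expect_lt(tr$iterations[[1]]$record$mean_error, 2)
  # min pairwise class-mean distance in sensor space equals the separation
  d <- min(dist(spec_big$means))
  expect_equal(d, 12, tolerance = 1e-9)
})

test_that("synthetic data satisfy every downstream module invariant", {
  spec <- planted_recovery_spec(3, 5, 2, separation = 5, n_k = 4, seed = 73)
  ds <- generate_dataset(spec)
  cfg <- pipeline_config(mc_samples = 1000, seed = 74)
  tr <- run_elimination(ds$table, ds$labeling, cfg)
  df <- as.data.frame(tr)
  expect_true(all(df$mean_error >= 0 & df$mean_error <= 100))
  expect_true(all(df$ari <= 1))
  expect_true(all(df$mean_separation >= 0))
  expect_true(all(df$ev1 >= df$ev2, na.rm = TRUE))
  for (it in tr$iterations) {
    for (g in it$gaussians)
      expect_gt(min(eigen(g$covariance, symmetric = TRUE)$values), 0)
  }
})
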