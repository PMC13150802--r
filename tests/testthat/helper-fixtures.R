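# fixtures built in code; no data files

# a class Gaussian built directly, bypassing the fitting path
make_gaussian <- function(class, mean, covariance, n_k = 5L) {
  d <- length(mean)
  covariance <- matrix(as.numeric(covariance), d, d)
  structure(list(class = class, mean = as.numeric(mean),
                 covariance = covariance,
                 raw_variances = diag(covariance), n_k = as.integer(n_k),
                 centered = matrix(0, n_k, d)),
            class = "class_gaussian")
}

# random SPD covariance
random_spd <- function(d = 2) {
  A <- matrix(stats::rnorm(d * d), d)
  crossprod(A) + 0.2 * diag(d)
}

# K random class Gaussians in d dimensions
random_gaussians <- function(K, d = 2, spread = 4) {
  lapply(seq_len(K), function(k)
    make_gaussian(k, stats::rnorm(d, sd = spread), random_spd(d)))
}

# a 6-sample, 2-sensor, 2-class screening table
tiny_dataset <- function() {
  X <- matrix(c(0.10, 0.20,
                0.12, 0.18,
                0.11, 0.22,
                0.50, 0.60,
                0.52, 0.58,
                0.51, 0.62), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("sA", "sB")))
  list(table = response_table(X),
       labeling = class_labeling(c("A", "A", "A", "B", "B", "B")))
}

# write a small CSV screening table, return its path
tiny_csv <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ds <- tiny_dataset()
  path <- file.path(dir, "tiny.csv")
  write_response_table(ds$table, ds$labeling, path)
  path
}

# fabricate a minimal elimination trace from an error curve e_by_l[l] (in %)
fabricate_trace <- function(e_by_l) {
  p <- length(e_by_l)
  iterations <- lapply(seq(p, 1), function(l)
    list(n_sensors = l, sensors = paste0("s", seq_len(l)),
         removed = NA_character_,
         record = list(n_sensors = l, mean_error = e_by_l[l],
                       ari = NA_real_, mean_separation = NA_real_,
                       ev1 = NA_real_, ev2 = NA_real_, dimension = 2L)))
  structure(list(iterations = iterations, p = p,
                 sensor_ids = paste0("s", seq_len(p)),
                 elimination_order = character(0),
                 config = pipeline_config()),
            class = "elimination_trace")
}

# independent pair-counting ARI oracle
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) sum(choose(x, 2))
  idx <- comb2(tab)
  ai <- comb2(rowSums(tab)); bi <- comb2(colSums(tab))
  exp_idx <- ai * bi / choose(n, 2)
  max_idx <- (ai + bi) / 2
  if (abs(max_idx - exp_idx) < 1e-12) return(0)
  (idx - exp_idx) / (max_idx - exp_idx)
}
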