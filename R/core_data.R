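#' Construct a response table
#'
#' A response table holds the screening matrix `X` (n samples x p sensors)
#' of unitless fractional sensor responses together with sensor and sample
#' identifiers. It is the basic data container passed through the pipeline.
#'
#' @param values Numeric matrix, n samples x p sensors. No missing values.
#' @param sensor_ids Character vector of p unique sensor names. Defaults to
#'   the column names of `values`.
#' @param sample_ids Character vector of n sample names. Defaults to row
#'   names or `"s1"..."sn"`.
#' @return An object of class `response_table` with elements `values`,
#'   `sensor_ids`, `sample_ids`, `n`, `p`.
#' @export
response_table <- function(values, sensor_ids = colnames(values),
                           sample_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, , drop = TRUE]
    stop("non-finite or missing value at row ", bad[1], ", column ", bad[2],
         "; missing values are rejected, not imputed", call. = FALSE)
  }
  if (nrow(values) < 2) stop("need at least 2 samples (n >= 2)", call. = FALSE)
  if (ncol(values) < 1) stop("need at least 1 sensor (p >= 1)", call. = FALSE)
  if (is.null(sensor_ids)) sensor_ids <- paste0("sensor", seq_len(ncol(values)))
  sensor_ids <- as.character(sensor_ids)
  if (length(sensor_ids) != ncol(values))
    stop("length(sensor_ids) != ncol(values)", call. = FALSE)
  if (anyDuplicated(sensor_ids))
    stop("sensor_ids must be unique; duplicated: ",
         paste(unique(sensor_ids[duplicated(sensor_ids)]), collapse = ", "),
         call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) != nrow(values)", call. = FALSE)
  dimnames(values) <- list(sample_ids, sensor_ids)
  structure(list(values = values, sensor_ids = sensor_ids,
                 sample_ids = sample_ids, n = nrow(values), p = ncol(values)),
            class = "response_table")
}

#' @export
print.response_table <- function(x, ...) {
  cat("response_table:", x$n, "samples x", x$p, "sensors\n")
  invisible(x)
}

#' Construct a class labeling
#'
#' Maps each sample to one of K analyte classes. Every class must have at
#' least two replicates: the finite-sample variance inflation is undefined
#' below that, and a single replicate carries no variance information.
#'
#' @param labels Vector (character, factor or integer) of length n, one
#'   class label per sample.
#' @param class_names Optional ordered character vector of class names;
#'   defaults to the sorted unique labels.
#' @return An object of class `class_labeling` with elements `labels`
#'   (integer class index in 1..K per sample), `class_names`, `counts`
#'   (n_k per class), `K`, `n`.
#' @export
class_labeling <- function(labels, class_names = NULL) {
  if (is.null(class_names)) {
    f <- factor(labels)
  } else {
    f <- factor(labels, levels = class_names)
    if (anyNA(f)) stop("labels contain values not in class_names", call. = FALSE)
  }
  class_names <- levels(f)
  K <- nlevels(f)
  if (K < 2) stop("need at least 2 classes (K >= 2)", call. = FALSE)
  counts <- as.integer(table(f))
  if (any(counts < 2)) {
    offender <- class_names[which(counts < 2)[1]]
    stop("class '", offender, "' has fewer than 2 replicates; ",
         "at least two samples per class are required (n_k >= 2)",
         call. = FALSE)
  }
  structure(list(labels = as.integer(f), class_names = class_names,
                 counts = counts, K = K, n = length(f)),
            class = "class_labeling")
}

#' @export
print.class_labeling <- function(x, ...) {
  cat("class_labeling:", x$K, "classes (",
      paste0(x$class_names, "=", x$counts, collapse = ", "), ")\n")
  invisible(x)
}

#' Load a screening table from a delimited file
#'
#' Reads a CSV or TSV file whose header row names the sensors, with one
#' column holding the analyte-class label, and validates it into a
#' [response_table()] plus [class_labeling()]. Row order is preserved.
#'
#' @param path Path to a CSV (`.csv`) or TSV (`.tsv`/`.txt`) file.
#' @param label_column Name of the class-label column. Default `"class"`.
#' @return A list with elements `table` ([response_table]) and `labeling`
#'   ([class_labeling]).
#' @export
load_response_table <- function(path, label_column = "class") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_column %in% names(df))
    stop("label column not found: '", label_column, "' (columns: ",
         paste(names(df), collapse = ", "), ")", call. = FALSE)
  labels <- df[[label_column]]
  df[[label_column]] <- NULL
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      stop("non-numeric cell in sensor column '", names(df)[j],
           "', row ", bad, call. = FALSE)
    }
  }
  tab <- response_table(as.matrix(df),
                        sensor_ids = names(df),
                        sample_ids = if (is.null(rownames(df))) NULL else rownames(df))
  list(table = tab, labeling = class_labeling(labels))
}

#' Write a response table (plus labels) back to CSV
#'
#' @param table A [response_table].
#' @param labeling A [class_labeling] for the same samples.
#' @param path Output file path (`.csv` for comma, otherwise tab).
#' @param label_column Name for the label column.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(table, labeling, path, label_column = "class") {
  stopifnot(inherits(table, "response_table"), inherits(labeling, "class_labeling"))
  df <- as.data.frame(table$values, check.names = FALSE)
  df[[label_column]] <- labeling$class_names[labeling$labels]
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fractional response from raw intensity and baseline
#'
#' Converts raw sensor intensities `I` and their baselines `I0` to the
#' unitless fractional response `(I - I0) / I0`.
#'
#' @param intensity Numeric matrix of raw intensities.
#' @param baseline Numeric matrix of the same shape, strictly nonzero.
#' @return Matrix of fractional responses, same shape.
#' @export
fractional_response <- function(intensity, baseline) {
  intensity <- as.matrix(intensity); baseline <- as.matrix(baseline)
  if (!identical(dim(intensity), dim(baseline)))
    stop("intensity and baseline shapes differ", call. = FALSE)
  if (any(baseline == 0)) {
    bad <- which(baseline == 0, arr.ind = TRUE)[1, , drop = TRUE]
    stop("zero baseline at row ", bad[1], ", column ", bad[2], call. = FALSE)
  }
  (intensity - baseline) / baseline
}

#' Mean-center each sensor column
#'
#' Subtracts the per-sensor mean so every column has mean zero. Variances
#' are unchanged; no unit-variance scaling is applied.
#'
#' @param table A [response_table].
#' @return A mean-centered [response_table].
#' @export
mean_center <- function(table) {
  stopifnot(inherits(table, "response_table"))
  v <- sweep(table$values, 2, colMeans(table$values), "-")
  response_table(v, table$sensor_ids, table$sample_ids)
}

#' Pipeline configuration
#'
#' Collects every tunable of the elimination pipeline with its default.
#'
#' @param classifier Decision model: `"qda"` (default) or `"voronoi"`.
#' @param fs_mode Sensor scoring: `"uniform"` (default) or `"weighted"`.
#' @param inflation `"adjusted"` (default; finite-sample predictive
#'   inflation applied) or `"unadjusted"` (raw class scatter).
#' @param ev_flag If `TRUE`, switch to a 1D decision model whenever PC1
#'   explains more than `ev_threshold` of the variance. Off by default.
#' @param ev_threshold Explained-variance fraction for the 1D switch
#'   (default 0.95).
#' @param etas Working-point penalties in percent error per sensor
#'   (defaults 3 and 0.5).
#' @param mc_samples Monte-Carlo draws per class for error estimation
#'   (default 1e5, minimum 1e3).
#' @param grid_resolution Cells per axis for decision-region rasters
#'   (default 400).
#' @param seed Integer root seed for all randomness.
#' @param ellipse_level Coverage of the confidence ellipses (default 0.95).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(classifier = c("qda", "voronoi"),
                            fs_mode = c("uniform", "weighted"),
                            inflation = c("adjusted", "unadjusted"),
                            ev_flag = FALSE,
                            ev_threshold = 0.95,
                            etas = c(3.0, 0.5),
                            mc_samples = 1e5,
                            grid_resolution = 400,
                            seed = 1L,
                            ellipse_level = 0.95) {
  classifier <- match.arg(classifier)
  fs_mode <- match.arg(fs_mode)
  inflation <- match.arg(inflation)
  if (ev_threshold <= 0 || ev_threshold >= 1)
    stop("ev_threshold must lie in (0,1)", call. = FALSE)
  if (any(etas < 0)) stop("etas must be >= 0", call. = FALSE)
  if (mc_samples < 1e3) stop("mc_samples must be >= 1000", call. = FALSE)
  if (ellipse_level <= 0 || ellipse_level >= 1)
    stop("ellipse_level must lie in (0,1)", call. = FALSE)
  structure(list(classifier = classifier, fs_mode = fs_mode,
                 inflation = inflation, ev_flag = isTRUE(ev_flag),
                 ev_threshold = ev_threshold, etas = as.numeric(etas),
                 mc_samples = as.integer(mc_samples),
                 grid_resolution = as.integer(grid_resolution),
                 seed = as.integer(seed), ellipse_level = ellipse_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Any field omitted in the file keeps the [pipeline_config()] default.
#'
#' @param path Path to a YAML key-value file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

# run the expression with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
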