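#' Run the full elimination pipeline and export its outputs
#'
#' End-to-end driver: loads (or accepts) a screening table, runs
#' [run_elimination()], selects a working point for every configured
#' penalty, and writes the audit trail — the per-iteration trace, the
#' elimination order, the working-point summary, and per-iteration
#' confidence-ellipse parameters. Decision-region rasters are exported
#' when `export_rasters = TRUE` (off by default; at the default 400x400
#' resolution they dominate the output size).
#'
#' @param input Path to a CSV/TSV screening table, or a list with `table`
#'   and `labeling` as returned by [load_response_table()] or
#'   [generate_dataset()].
#' @param config A [pipeline_config], or a path to a YAML config file, or
#'   `NULL` for defaults.
#' @param output_dir Directory for the output files (created if needed).
#' @param label_column Label column name when `input` is a path.
#' @param export_rasters Also write per-iteration region rasters.
#' @return A `run_manifest`: config snapshot, seed, input hash, trace,
#'   working points, output file list and per-stage timing.
#' @export
run_pipeline <- function(input, config = NULL, output_dir = ".",
                         label_column = "class", export_rasters = FALSE) {
  if (is.null(config)) config <- pipeline_config()
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  input_hash <- NA_character_
  if (is.character(input)) {
    input_hash <- unname(tools::md5sum(input))
    input <- load_response_table(input, label_column)
  }
  table <- input$table; labeling <- input$labeling
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)

  timing <- c(elimination = NA_real_, selection = NA_real_, export = NA_real_)
  t0 <- proc.time()[["elapsed"]]
  trace <- run_elimination(table, labeling, config)
  timing["elimination"] <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  wps <- lapply(config$etas, function(h) select_working_point(trace, h))
  timing["selection"] <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  outputs <- export_trace(trace, wps, output_dir, config,
                          export_rasters = export_rasters)
  timing["export"] <- proc.time()[["elapsed"]] - t0

  manifest <- structure(list(config = config, seed = config$seed,
                             input_hash = input_hash, trace = trace,
                             working_points = wps, outputs = outputs,
                             timing = timing),
                        class = "run_manifest")
  stopifnot(all(file.exists(outputs)))
  manifest
}

# write trace / order / working points / ellipses (+ optional rasters)
export_trace <- function(trace, working_points, output_dir, config,
                         export_rasters = FALSE) {
  paths <- character(0)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) formatC(v, digits = 10, format = "g"))
    df
  }
  wr <- function(df, name) {
    path <- file.path(output_dir, name)
    utils::write.table(fmt(df), path, sep = ",", row.names = FALSE, quote = FALSE)
    path
  }

  paths <- c(paths, wr(as.data.frame(trace), "trace.csv"))
  ord <- data.frame(iteration = seq_along(trace$elimination_order),
                    removed_sensor = trace$elimination_order)
  paths <- c(paths, wr(ord, "elimination_order.csv"))

  wp_df <- do.call(rbind, lapply(working_points, function(w)
    data.frame(eta = w$eta, l_star = w$l_star, e_at_lstar = w$e_at_lstar,
               sensors = paste(w$sensors, collapse = ";"))))
  paths <- c(paths, wr(wp_df, "working_points.csv"))

  ell <- do.call(rbind, lapply(trace$iterations, function(it) {
    if (it$record$dimension != 2) return(NULL)
    do.call(rbind, lapply(it$gaussians, function(g) {
      e <- confidence_ellipse(g, config$ellipse_level)
      data.frame(n_sensors = it$n_sensors, class = g$class,
                 center_x = e$center[1], center_y = e$center[2],
                 semi_major = e$semi_axes[1], semi_minor = e$semi_axes[2],
                 angle = e$angle, level = e$level)
    }))
  }))
  if (!is.null(ell)) paths <- c(paths, wr(ell, "ellipses.csv"))

  if (export_rasters) {
    for (it in trace$iterations) {
      grid <- region_grid(it$model, it$gaussians, config$grid_resolution)
      paths <- c(paths, wr(as.data.frame(grid),
                           sprintf("regions_l%02d.csv", it$n_sensors)))
    }
  }
  paths
}

#' Print a human-readable elimination report
#'
#' Tabulates the mean error, ARI and mean separation per surviving sensor
#' count, and marks the selected working point for every penalty.
#'
#' @param trace An `elimination_trace`.
#' @param working_points List of `working_point` objects (may be empty).
#' @return The report lines, invisibly (they are also printed).
#' @export
emit_report <- function(trace, working_points = list()) {
  df <- as.data.frame(trace)
  lines <- c(sprintf("Backward elimination over %d sensors", trace$p),
             sprintf("%9s %12s %8s %8s", "sensors", "error(%)", "ARI", "<D>"))
  for (i in seq_len(nrow(df))) {
    marks <- vapply(working_points, function(w)
      w$l_star == df$n_sensors[i], logical(1))
    tag <- if (any(marks))
      paste0("  <- l* (eta=", paste(vapply(working_points[marks],
             function(w) format(w$eta), character(1)), collapse = ","), ")")
      else ""
    lines <- c(lines, sprintf("%9d %12.3f %8.3f %8.3f%s", df$n_sensors[i],
                              df$mean_error[i], df$ari[i],
                              df$mean_separation[i], tag))
  }
  if (!length(working_points)) {
    warning("no working-point penalties supplied; reporting the trace only",
            call. = FALSE)
  } else {
    for (w in working_points)
      lines <- c(lines, sprintf("eta = %g%%/sensor: l* = %d, sensors: %s",
                                w$eta, w$l_star,
                                paste(w$sensors, collapse = ", ")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest (seed", x$seed, ")\n")
  emit_report(x$trace, x$working_points)
  cat(sprintf("outputs: %d files; elapsed %.2fs\n", length(x$outputs),
              sum(x$timing, na.rm = TRUE)))
  invisible(x)
}
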