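# Portable persistence: plain-text array bundles (TSV matrices + JSON
# metadata) for leadfields, sensor arrays, source spaces and measurements,
# plus CSV/JSON export of scan results and error summaries. Dataset names
# mirror a hierarchical layout (`leadfield/gain`, `sensors/positions`,
# `sources/positions`, `measurement/data`) so bundles stay self-describing.

write_tsv_matrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = !is.null(colnames(m)), quote = FALSE)
}

read_tsv_matrix <- function(path, header) {
  as.matrix(utils::read.table(path, sep = "\t", header = header))
}

#' Write a leadfield stack to a plain-text array bundle
#'
#' Creates a directory containing `leadfield_gain.tsv` (sensors x 3*nodes,
#' node-major column triples), `sensors_positions.tsv`, `sources_positions.tsv`
#' and `meta.json` (attributes `modality`, `units`, `model_label`, shapes).
#'
#' @param lf a `leadfield`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_leadfield_bundle <- function(lf, dir) {
  stopifnot(inherits(lf, "leadfield"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_matrix(lf$gain, file.path(dir, "leadfield_gain.tsv"))
  write_tsv_matrix(lf$sensors$positions, file.path(dir, "sensors_positions.tsv"))
  if (!is.null(lf$sensors$orientations)) {
    write_tsv_matrix(lf$sensors$orientations, file.path(dir, "sensors_orientations.tsv"))
  }
  write_tsv_matrix(lf$positions, file.path(dir, "sources_positions.tsv"))
  meta <- list(
    modality = lf$modality, units = lf$units, model_label = lf$model_label,
    n_sensors = nrow(lf$gain), n_nodes = lf$n_nodes,
    gradiometer_baseline = lf$sensors$gradiometer_baseline,
    reference = lf$sensors$reference,
    layout = c("leadfield/gain", "sensors/positions", "sources/positions")
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a leadfield stack from a plain-text array bundle
#'
#' @param dir directory written by [write_leadfield_bundle()].
#' @return A `leadfield`.
#' @export
read_leadfield_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  gain <- unname(read_tsv_matrix(file.path(dir, "leadfield_gain.tsv"), header = FALSE))
  pos <- unname(read_tsv_matrix(file.path(dir, "sources_positions.tsv"), header = FALSE))
  spos <- unname(read_tsv_matrix(file.path(dir, "sensors_positions.tsv"), header = FALSE))
  ori_path <- file.path(dir, "sensors_orientations.tsv")
  sensors <- new_sensor_array(
    positions = spos,
    orientations = if (file.exists(ori_path)) unname(read_tsv_matrix(ori_path, header = FALSE)) else NULL,
    modality = meta$modality,
    gradiometer_baseline = meta$gradiometer_baseline,
    reference = meta$reference %||% "none"
  )
  new_leadfield(gain, pos, meta$modality, meta$units, meta$model_label, sensors)
}

#' Write a measurement to a plain-text bundle with a JSON truth sidecar
#'
#' @param meas a `measurement`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_measurement_bundle <- function(meas, dir) {
  stopifnot(inherits(meas, "measurement"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_matrix(meas$data, file.path(dir, "measurement_data.tsv"))
  meta <- list(rate = meas$rate, modality = meas$modality, units = meas$units,
               n_channels = meas$n_channels, n_samples = meas$n_samples)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(meas$truth)) {
    jsonlite::write_json(meas$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a measurement bundle
#' @param dir directory written by [write_measurement_bundle()].
#' @return A `measurement`.
#' @export
read_measurement_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  data <- unname(read_tsv_matrix(file.path(dir, "measurement_data.tsv"), header = FALSE))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  new_measurement(data, meta$rate, meta$modality, meta$units, truth = truth)
}

#' Export a scan map as CSV
#'
#' Columns: `node_id, x, y, z, constraint, variance_output, kurtosis_output,
#' ori_x, ori_y, ori_z`.
#'
#' @param scan a `bf_scan`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  cols <- c("node_id", "x", "y", "z", "constraint", "variance_output",
            "kurtosis_output", "ori_x", "ori_y", "ori_z")
  utils::write.csv(as.data.frame(scan)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Export an experiment summary as JSON
#'
#' @param summary a summary table from [summarize_experiment()] (or any data
#'   frame).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Boxplot figure of per-condition error summaries
#'
#' Mirrors the study's reporting layout: one box per head model, panels by
#' condition code (orientation class x modality x noise), with the
#' study's whisker rule and the 40 mm display cap. Requires ggplot2.
#'
#' @param summary_table output of [summarize_experiment()].
#' @param cap display cap (mm).
#' @return A ggplot object.
#' @export
plot_error_summaries <- function(summary_table, cap = 40) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  d <- summary_table
  d$condition <- paste0(
    ifelse(d$orientation_class == "quasi_tangential", "T", "R"),
    toupper(substr(d$modality, 1, 1)),
    ifelse(d$noise == "low", "L", "H")
  )
  for (col in c("median", "q1", "q3", "whisker_low", "whisker_high")) {
    d[[col]] <- pmin(d[[col]], cap)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_low, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_high, fill = .data$model),
      stat = "identity"
    ) +
    ggplot2::geom_hline(yintercept = cap, linetype = "dashed") +
    ggplot2::facet_grid(constraint ~ condition + criterion) +
    ggplot2::labs(y = "localization error (mm)", x = "head model") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   legend.position = "none")
}
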