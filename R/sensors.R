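#' Sensor array descriptions
#'
#' Sensor geometries are generated, not measured: electrodes are packed
#' quasi-uniformly on the scalp sphere over a cap that mimics standard 10/10
#' coverage, and MEG axial gradiometers sit on an offset helmet-like cap with
#' radially oriented coil normals. Channel counts default to the common
#' 80-electrode EEG and 273-gradiometer whole-head MEG setups.
#'
#' @name sensor_arrays
NULL

new_sensor_array <- function(positions, orientations, modality,
                             gradiometer_baseline = NULL,
                             reference = c("none", "common_average")) {
  reference <- match.arg(reference)
  structure(
    list(
      positions = positions,
      orientations = orientations,
      modality = modality,
      gradiometer_baseline = gradiometer_baseline,
      reference = reference,
      n = nrow(positions)
    ),
    class = "sensor_array"
  )
}

#' @export
print.sensor_array <- function(x, ...) {
  cat("<sensor_array>", x$n, toupper(x$modality), "channels",
      if (!is.null(x$gradiometer_baseline)) sprintf("(axial gradiometers, %g mm baseline)", x$gradiometer_baseline),
      "\n  reference:", x$reference, "\n")
  invisible(x)
}

#' EEG electrode array on the scalp sphere
#'
#' @param n_channels number of electrodes (default 80).
#' @param shells [shell_model()]; electrodes are placed on its outermost radius.
#' @param max_polar_angle_deg cap extent from the vertex, in degrees (default
#'   125, reaching below the ears like a full 10/10 montage).
#' @return A `sensor_array` with common-average reference.
#' @export
eeg_sensor_array <- function(n_channels = 80, shells = make_shell_model("reference"),
                             max_polar_angle_deg = 125) {
  stopifnot(n_channels >= 2)
  R <- max(shells$radii)
  dirs <- fibonacci_directions(n_channels, zmin = cos(max_polar_angle_deg * pi / 180), zmax = 1)
  new_sensor_array(
    positions = dirs * R,
    orientations = NULL,
    modality = "eeg",
    reference = "common_average"
  )
}

#' MEG axial-gradiometer array on a helmet cap
#'
#' First coils lie on a sphere offset outside the head; each gradiometer's
#' second coil sits `baseline` mm further out along the (radial) coil normal.
#' The gradiometer reading is first-coil field minus second-coil field along
#' that normal.
#'
#' @param n_channels number of gradiometers (default 273).
#' @param helmet_radius radius of the first-coil sphere in mm; must exceed the
#'   outermost shell radius.
#' @param baseline coil separation in mm (default 50).
#' @param shells [shell_model()] used only to validate that coils are outside
#'   the conductor.
#' @param max_polar_angle_deg helmet cap extent from the vertex (default 112).
#' @return A `sensor_array`.
#' @export
meg_sensor_array <- function(n_channels = 273, helmet_radius = 110, baseline = 50,
                             shells = make_shell_model("reference"),
                             max_polar_angle_deg = 112) {
  stopifnot(n_channels >= 2, baseline > 0)
  if (helmet_radius <= max(shells$radii)) {
    stop("helmet radius must be outside the outermost shell", call. = FALSE)
  }
  dirs <- fibonacci_directions(n_channels, zmin = cos(max_polar_angle_deg * pi / 180), zmax = 1)
  new_sensor_array(
    positions = dirs * helmet_radius,
    orientations = dirs, # radial outward coil normals (unit)
    modality = "meg",
    gradiometer_baseline = baseline,
    reference = "none"
  )
}
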