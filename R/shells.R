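#' Concentric-shell volume conductor model
#'
#' A spherical head conductor described by shell outer radii (mm, strictly
#' increasing from the innermost "brain" shell outwards) and per-shell
#' conductivities (S/m). Conductivity values follow the standard compartment
#' table used in realistic head modelling: brain 0.33, CSF 1.79, skull 0.01,
#' skin 0.43 S/m.
#'
#' @param radii numeric vector of shell outer radii in mm, strictly increasing.
#' @param conductivities numeric vector of shell conductivities in S/m,
#'   same length as `radii`, all positive.
#' @param label text tag describing the model.
#' @return An object of class `shell_model`.
#' @export
#' @examples
#' shell_model(c(80, 85, 90, 92), c(0.33, 1.79, 0.01, 0.43), "4-shell")
shell_model <- function(radii, conductivities, label = "shell-model") {
  radii <- as.numeric(radii)
  conductivities <- as.numeric(conductivities)
  if (length(radii) < 1L) stop("a shell model needs at least one shell", call. = FALSE)
  if (length(radii) != length(conductivities)) {
    stop("`radii` and `conductivities` must have the same length", call. = FALSE)
  }
  if (any(diff(radii) <= 0) || any(radii <= 0)) {
    stop("`radii` must be positive and strictly increasing", call. = FALSE)
  }
  if (any(conductivities <= 0) || any(!is.finite(conductivities))) {
    stop("all conductivities must be finite and > 0", call. = FALSE)
  }
  structure(
    list(radii = radii, conductivities = conductivities, label = as.character(label)[1]),
    class = "shell_model"
  )
}

#' @export
print.shell_model <- function(x, ...) {
  cat("<shell_model>", x$label, "\n")
  print(data.frame(outer_radius_mm = x$radii, sigma_S_per_m = x$conductivities))
  invisible(x)
}

# Registered cascade configurations. Default geometry: brain/CSF/skull/skin
# analogue at 80/85/90/92 mm. The 3-shell level merges the CSF layer into the
# brain compartment (the classic skin/skull/brain model); the 4-shell level
# separates it at 1.79 S/m and serves as the reference.
.shell_cascade <- list(
  `3C` = list(radii = c(85, 90, 92), sigma = c(0.33, 0.01, 0.43),
              label = "3-shell (skin/skull/brain)"),
  `4C` = list(radii = c(80, 85, 90, 92), sigma = c(0.33, 1.79, 0.01, 0.43),
              label = "4-shell (+CSF)"),
  reference = list(radii = c(80, 85, 90, 92), sigma = c(0.33, 1.79, 0.01, 0.43),
                   label = "reference (4-shell)")
)

#' Build a registered shell model from the simplification cascade
#'
#' The cascade emulates head-model simplification with analytic spherical
#' conductors: `"3C"` is the classic three-compartment skin/skull/brain model
#' (no CSF layer), `"4C"` adds the high-conductivity CSF shell at 1.79 S/m,
#' and `"reference"` is the most detailed registered model (identical to
#' `"4C"`). Finer-grained model divergence is produced separately with
#' [perturb_leadfield()].
#'
#' @param cascade_level one of `"3C"`, `"4C"`, `"reference"`.
#' @return A [shell_model()].
#' @export
#' @examples
#' make_shell_model("3C")
make_shell_model <- function(cascade_level = c("reference", "3C", "4C")) {
  cascade_level <- as.character(cascade_level)[1]
  if (!cascade_level %in% names(.shell_cascade)) {
    stop("unknown cascade level '", cascade_level, "'; registered levels: ",
         paste(names(.shell_cascade), collapse = ", "), call. = FALSE)
  }
  cfg <- .shell_cascade[[cascade_level]]
  shell_model(cfg$radii, cfg$sigma, cfg$label)
}
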