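#' Standing COP sway features
#'
#' From the two-foot COP excursion trajectory of the 45 s standing window:
#' the range of variation on the medial-lateral (`x`) and
#' anterior-posterior (`y`) axes, the total trajectory length (sum of
#' inter-sample Euclidean distances) and the surface covered by the
#' excursion. The surface is measured as the convex-hull area of the
#' path, which stays well defined for self-intersecting sway paths.
#'
#' @param recording Windowed standing [insole_recording()] (kPa or N; the
#'   COP is scale invariant).
#' @param layout A [sensor_layout()] with both feet.
#' @return Named numeric vector: `standing_cop.range_x` (mm),
#'   `standing_cop.range_y` (mm), `standing_cop.path_length` (mm),
#'   `standing_cop.surface` (mm2).
#' @export
standing_cop_features <- function(recording, layout) {
  path <- cop_path(recording, layout, foot = "both")
  standing_path_features(path)
}

#' Standing sway features of a pre-computed COP path
#'
#' Same four statistics as [standing_cop_features()], computed directly
#' from an ordered COP path (useful for analytic test paths).
#'
#' @param path Data frame with `x_mm`, `y_mm`.
#' @return Named numeric vector of the four sway features.
#' @export
standing_path_features <- function(path) {
  m <- path_metrics(path$x_mm, path$y_mm)
  if (m$n == 0) abort_data("COP undefined for every standing sample")
  c(standing_cop.range_x = m$range_x,
    standing_cop.range_y = m$range_y,
    standing_cop.path_length = m$path_length,
    standing_cop.surface = m$surface)
}
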