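#' Canonical 7-sensor insole layout
#'
#' The insole carries seven pressure sensors: heel, lateral midfoot, centre
#' midfoot, lateral forefoot, centre forefoot, medial forefoot and big toe.
#' The device documentation gives no printed coordinates, so the package
#' adopts a fixed canonical geometry drawn from typical adult foot anatomy,
#' scaled by insole length. Coordinates are in millimetres with `y` the
#' anterior-posterior axis (heel towards toe, heel sensor has the minimal
#' `y`, big-toe sensor the maximal `y`) and `x` the medial-lateral axis.
#' The right-foot x-axis is mirrored so that +x points lateral-to-medial on
#' both feet, which makes left/right feature differences geometrically
#' comparable.
#'
#' @param insole_length_mm Insole length in mm (insoles come in 220-280 mm
#'   sizes; default 250). All coordinates scale linearly with it.
#' @param feet Which feet to include, any of `"left"`, `"right"`.
#'
#' @return A tibble with columns `foot`, `sensor` (1-7), `sensor_name`,
#'   `x_mm`, `y_mm`.
#' @examples
#' sensor_layout()
#' @export
sensor_layout <- function(insole_length_mm = 250,
                          feet = c("left", "right")) {
  if (!is_pos(insole_length_mm)) {
    abort_config("insole_length_mm", "must be a positive number")
  }
  feet <- match.arg(feet, c("left", "right"), several.ok = TRUE)
  base <- tibble(
    sensor = 1:7,
    sensor_name = c("heel", "lateral_midfoot", "center_midfoot",
                    "lateral_forefoot", "center_forefoot",
                    "medial_forefoot", "big_toe"),
    # +x = lateral -> medial; y = posterior -> anterior; for a 250 mm insole
    x_mm = c(0, -25, 0, -30, 0, 28, 15),
    y_mm = c(30, 100, 120, 175, 185, 180, 235)
  )
  scale <- insole_length_mm / 250
  purrr::map(feet, function(f) {
    dplyr::mutate(base, foot = f,
                  x_mm = .data$x_mm * scale, y_mm = .data$y_mm * scale)
  }) |>
    list_rbind() |>
    dplyr::select("foot", "sensor", "sensor_name", "x_mm", "y_mm")
}

#' Distance between the lateral and medial forefoot sensors
#'
#' Normalising constant of the centre-of-pressure excursion index (CPEI).
#'
#' @param layout A layout tibble from [sensor_layout()].
#' @param foot Which foot's geometry to use.
#' @return Distance in mm.
#' @export
forefoot_sensor_distance <- function(layout, foot = "left") {
  l <- dplyr::filter(layout, .data$foot == !!foot)
  a <- dplyr::filter(l, .data$sensor == 4L)
  b <- dplyr::filter(l, .data$sensor == 6L)
  sqrt((a$x_mm - b$x_mm)^2 + (a$y_mm - b$y_mm)^2)
}

# Sensor positions of both feet in a common (global) standing frame:
# feet stand side by side, heels 80 mm apart, so each foot's medial border
# faces the body midline. Global +x points to the subject's right.
layout_global_standing <- function(layout, foot_center_offset_mm = 50) {
  stopifnot(all(c("left", "right") %in% layout$foot))
  dplyr::mutate(
    layout,
    x_mm = ifelse(.data$foot == "left",
                  -foot_center_offset_mm + .data$x_mm,
                  foot_center_offset_mm - .data$x_mm),
    y_mm = .data$y_mm - 130
  )
}

check_layout <- function(layout) {
  for (f in unique(layout$foot)) {
    l <- dplyr::filter(layout, .data$foot == f)
    if (nrow(l) != 7 || anyDuplicated(l[, c("x_mm", "y_mm")]) > 0) {
      abort_data(sprintf("layout for %s foot must have 7 distinct sensors", f))
    }
    if (which.min(l$y_mm) != which(l$sensor == 1L) ||
        which.max(l$y_mm) != which(l$sensor == 7L)) {
      abort_data("heel sensor must be most posterior and big toe most anterior")
    }
  }
  invisible(layout)
}
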