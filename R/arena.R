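#' Arena geometry for a foraging compartment
#'
#' Describes one compartment of the experimental box: a rectangular floor of
#' `width` x `depth` cm with the separation panel along the far (high-y) edge,
#' the feeder placed in front of that panel in the corner opposite the
#' entrance, and a fixed pixel-to-cm calibration. The coordinate convention is
#' x across the width, y increasing toward the separation panel, origin at the
#' entrance-side corner.
#'
#' @param width compartment width in cm (x extent).
#' @param depth compartment depth in cm (y extent, toward the panel).
#' @param feeder_center numeric length-2, feeder centre `(x, y)` in cm.
#' @param entrance numeric length-2, entrance point `(x, y)` in cm.
#' @param px_per_cm pixels per cm of the camera calibration (> 0).
#' @param feeder_zone_radius radius (cm) around the feeder centre within which
#'   the head position counts as a feeding frame.
#'
#' @return An object of class `arena_geometry`.
#' @export
#' @examples
#' geom <- arena_geometry()
#' geom$feeder_center
arena_geometry <- function(width = 60, depth = 50,
                           feeder_center = c(55, 45),
                           entrance = c(5, 5),
                           px_per_cm = 10,
                           feeder_zone_radius = 6) {
  if (!is.numeric(width) || width <= 0 || !is.numeric(depth) || depth <= 0)
    stop_mf("arena width and depth must be positive", class = "config_error")
  if (px_per_cm <= 0)
    stop_mf("px_per_cm must be > 0", class = "config_error")
  if (feeder_zone_radius <= 0)
    stop_mf("feeder_zone_radius must be > 0", class = "config_error")
  feeder_center <- as.numeric(feeder_center)
  entrance <- as.numeric(entrance)
  if (length(feeder_center) != 2 || length(entrance) != 2)
    stop_mf("feeder_center and entrance must be (x, y) pairs",
            class = "config_error")
  inside <- function(p) p[1] >= 0 && p[1] <= width && p[2] >= 0 && p[2] <= depth
  if (!inside(feeder_center))
    stop_mf("feeder_center lies outside the compartment", class = "config_error")
  if (!inside(entrance))
    stop_mf("entrance lies outside the compartment", class = "config_error")
  structure(
    list(width = width, depth = depth, feeder_center = feeder_center,
         entrance = entrance, px_per_cm = px_per_cm,
         feeder_zone_radius = feeder_zone_radius),
    class = "arena_geometry"
  )
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf("<arena_geometry> %g x %g cm, feeder (%g, %g), zone r = %g cm, %g px/cm\n",
              x$width, x$depth, x$feeder_center[1], x$feeder_center[2],
              x$feeder_zone_radius, x$px_per_cm))
  invisible(x)
}
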