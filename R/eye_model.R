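#' Schematic eye model
#'
#' Builds the rotating schematic eye used by the simulator: two spheres (the
#' eyeball and the corneal surface) sharing the optical axis through the
#' eyeball center `O_e`, the cornea center `O_c` and the pupil center `P_c`.
#' The visual axis deviates from the optical axis by the angle Kappa.
#' Geometric defaults follow Gullstrand--Le Grand-style schematic-eye values;
#' all of them can be overridden and are recorded in simulator output.
#'
#' @param eyeball_center 3-vector, mm, world coordinates of `O_e`. The world
#'   origin sits at the bottom-center of the viewed plane (the screen), with
#'   `x` to the right, `y` up, and `z` toward the viewer, so the default eye
#'   position is 550 mm in front of the screen, level with its center.
#' @param eyeball_radius eyeball sphere radius, mm.
#' @param cornea_center_offset distance `O_e` to `O_c` along the optical
#'   axis, mm.
#' @param cornea_radius corneal sphere radius, mm.
#' @param pupil_distance distance `O_e` to `P_c` along the optical axis, mm.
#' @param kappa angles `(K_alpha, K_beta)` in degrees between the optical and
#'   the visual axis: horizontal and vertical component, applied as a rotation
#'   about the eye's horizontal axis and then its vertical axis. The sign
#'   convention models a left eye: positive `K_alpha` deviates the visual
#'   axis nasally (toward `+x`) and positive `K_beta` deviates it upward.
#' @param refraction_index refractive index of the aqueous humor relative to
#'   air (> 1); rays from the pupil center refract once at the corneal sphere.
#' @param rotation_limits named vector in degrees: maximal rotation
#'   `left`/`right` about the vertical axis and `up`/`down` about the
#'   horizontal axis.
#' @param nodal_point either `"cornea"` (the visual axis passes through the
#'   cornea center, the default) or `"eyeball"` (through `O_e`).
#' @return an object of class `eye_model`.
#' @export
eye_model <- function(eyeball_center = c(0, 200, 550),
                      eyeball_radius = 12,
                      cornea_center_offset = 5.3,
                      cornea_radius = 7.8,
                      pupil_distance = 9.2,
                      kappa = c(6, 2),
                      refraction_index = 1.336,
                      rotation_limits = c(left = 35, right = 35, up = 25, down = 30),
                      nodal_point = c("cornea", "eyeball")) {
  nodal_point <- match.arg(nodal_point)
  stopifnot(
    length(eyeball_center) == 3, is.finite(eyeball_center),
    eyeball_radius > 0, cornea_radius > 0,
    cornea_center_offset >= 0, pupil_distance > 0,
    length(kappa) == 2, refraction_index > 1
  )
  if (pupil_distance <= cornea_center_offset - cornea_radius ||
      pupil_distance >= cornea_center_offset + cornea_radius) {
    stop("pupil center must lie inside the corneal sphere")
  }
  lims <- c(left = 35, right = 35, up = 25, down = 30)
  lims[names(rotation_limits)] <- rotation_limits
  structure(
    list(
      eyeball_center = as.numeric(eyeball_center),
      eyeball_radius = eyeball_radius,
      cornea_center_offset = cornea_center_offset,
      cornea_radius = cornea_radius,
      pupil_distance = pupil_distance,
      kappa = as.numeric(kappa),
      refraction_index = refraction_index,
      rotation_limits = lims,
      nodal_point = nodal_point
    ),
    class = "eye_model"
  )
}

#' @export
print.eye_model <- function(x, ...) {
  cat("Schematic eye model\n")
  cat(sprintf("  eyeball center O_e : (%g, %g, %g) mm\n",
              x$eyeball_center[1], x$eyeball_center[2], x$eyeball_center[3]))
  cat(sprintf("  radii (eyeball/cornea): %g / %g mm\n",
              x$eyeball_radius, x$cornea_radius))
  cat(sprintf("  O_e->O_c %g mm, O_e->P_c %g mm\n",
              x$cornea_center_offset, x$pupil_distance))
  cat(sprintf("  kappa (%g, %g) deg, refraction index %g, nodal point: %s\n",
              x$kappa[1], x$kappa[2], x$refraction_index, x$nodal_point))
  invisible(x)
}

#' Screen description
#'
#' @param width,height physical size of the viewed plane, mm.
#' @param x_range,y_range range of displayed target coordinates, mm, in world
#'   coordinates (origin at the bottom-center of the plane).
#' @param pixel_pitch optional physical pixel size, mm, used when converting
#'   screen coordinates to pixels.
#' @return an object of class `screen_spec`.
#' @export
screen_spec <- function(width = 400, height = 300,
                        x_range = c(-200, 200), y_range = c(50, 350),
                        pixel_pitch = NULL) {
  structure(
    list(width = width, height = height,
         x_range = as.numeric(x_range), y_range = as.numeric(y_range),
         pixel_pitch = pixel_pitch),
    class = "screen_spec"
  )
}

#' Pinhole eye-camera description
#'
#' The camera looks at `look_at` (by default the eyeball center, so the camera
#' axis joins the eyeball center and the camera center). Image coordinates are
#' metric sensor coordinates `u = f * x_c / z_c` relative to the principal
#' point; an optional `pixels_per_mm` scale and `image_center` convert them to
#' image pixels when exporting data.
#'
#' @param position 3-vector, mm, world coordinates of the camera center.
#' @param look_at 3-vector or `NULL` (resolved to the eyeball center).
#' @param focal_length focal length, mm.
#' @param principal_point 2-vector, image offset of the principal point.
#' @param pixels_per_mm optional sensor scale for pixel output.
#' @param image_center optional 2-vector, pixel coordinates of the principal
#'   point.
#' @return an object of class `camera_spec`.
#' @export
camera_spec <- function(position = c(0, 200, 0), look_at = NULL,
                        focal_length = 35, principal_point = c(0, 0),
                        pixels_per_mm = NULL, image_center = c(0, 0)) {
  stopifnot(length(position) == 3, is.finite(position), focal_length > 0)
  structure(
    list(position = as.numeric(position), look_at = look_at,
         focal_length = focal_length,
         principal_point = as.numeric(principal_point),
         pixels_per_mm = pixels_per_mm,
         image_center = as.numeric(image_center)),
    class = "camera_spec"
  )
}

#' Eye-tracker scene
#'
#' Places a screen, a pinhole eye-camera, optional infrared LEDs and a
#' schematic eye in a world coordinate system anchored at the bottom-center of
#' the screen.
#'
#' @param screen a [screen_spec()].
#' @param camera a [camera_spec()].
#' @param leds `NULL` or a 4 x 3 matrix of LED world positions, mm (one per
#'   screen corner in enumerated order).
#' @param eye an [eye_model()].
#' @return an object of class `scene`.
#' @export
scene <- function(screen = screen_spec(), camera = camera_spec(),
                  leds = NULL, eye = eye_model()) {
  stopifnot(inherits(screen, "screen_spec"), inherits(camera, "camera_spec"),
            inherits(eye, "eye_model"))
  if (is.null(camera$look_at)) camera$look_at <- eye$eyeball_center
  if (sum((camera$position - eye$eyeball_center)^2) < 1e-12) {
    stop("camera must not coincide with the eyeball center")
  }
  if (!is.null(leds)) {
    leds <- .as_row(leds)
    if (nrow(leds) != 4) stop("leds must be a 4 x 3 matrix")
  }
  structure(list(screen = screen, camera = camera, leds = leds, eye = eye),
            class = "scene")
}

#' Four LEDs at the screen corners
#'
#' Convenience helper placing one infrared LED at each corner of the screen's
#' target range, on the screen plane, enumerated bottom-left, bottom-right,
#' top-right, top-left.
#'
#' @param screen a [screen_spec()].
#' @return a 4 x 3 matrix of world positions, mm.
#' @export
corner_leds <- function(screen = screen_spec()) {
  xr <- screen$x_range
  yr <- screen$y_range
  rbind(
    c(xr[1], yr[1], 0), c(xr[2], yr[1], 0),
    c(xr[2], yr[2], 0), c(xr[1], yr[2], 0)
  )
}

#' @export
print.scene <- function(x, ...) {
  cat("Eye-tracker scene (world origin at screen bottom-center)\n")
  cat(sprintf("  screen %g x %g mm, targets x[%g,%g] y[%g,%g]\n",
              x$screen$width, x$screen$height,
              x$screen$x_range[1], x$screen$x_range[2],
              x$screen$y_range[1], x$screen$y_range[2]))
  cat(sprintf("  camera at (%g, %g, %g) mm, f = %g mm\n",
              x$camera$position[1], x$camera$position[2],
              x$camera$position[3], x$camera$focal_length))
  cat(sprintf("  LEDs: %s\n", if (is.null(x$leds)) "none" else "4"))
  print(x$eye)
  invisible(x)
}

# Vectorized fixation solver. targets is an n x 2 matrix of screen
# coordinates (mm, screen plane z = 0). Returns matrices of unit optical and
# visual axes plus the world pupil and cornea centers. The eye orientation is
# found by fixed-point iteration: the visual axis must join the nodal point
# and the target, and the optical axis is the visual axis with the Kappa
# rotation undone (about the eye's current horizontal axis by -K_beta, then
# its vertical axis by -K_alpha).
.gaze_states <- function(eye, targets) {
  targets <- matrix(as.numeric(targets), ncol = 2)
  n <- nrow(targets)
  t3 <- cbind(targets, 0)
  oe <- matrix(eye$eyeball_center, n, 3, byrow = TRUE)
  o <- .vunit(t3 - oe)
  ka <- eye$kappa[1]
  kb <- eye$kappa[2]
  for (it in seq_len(60)) {
    fr <- .gaze_frame(o)
    nodal <- if (eye$nodal_point == "cornea") {
      oe + eye$cornea_center_offset * o
    } else {
      oe
    }
    v_des <- .vunit(t3 - nodal)
    o_new <- .rotate_about(v_des, fr$u, ka)
    o_new <- .rotate_about(o_new, fr$h, -kb)
    delta <- max(abs(o_new - o))
    o <- o_new
    if (delta < 1e-14) break
  }
  fr <- .gaze_frame(o)
  visual <- .rotate_about(o, fr$h, kb)
  visual <- .rotate_about(visual, fr$u, -ka)
  # rotation-limit check on the optical axis relative to straight ahead (0,0,-1)
  hor <- .rad2deg(atan2(o[, 1], -o[, 3]))
  ver <- .rad2deg(atan2(o[, 2], sqrt(o[, 1]^2 + o[, 3]^2)))
  lim <- eye$rotation_limits
  if (any(hor < -lim[["left"]]) || any(hor > lim[["right"]])) {
    stop(sprintf("horizontal eye rotation out of range (limit %g/%g deg left/right)",
                 lim[["left"]], lim[["right"]]))
  }
  if (any(ver > lim[["up"]]) || any(ver < -lim[["down"]])) {
    stop(sprintf("vertical eye rotation out of range (limit %g up / %g down deg)",
                 lim[["up"]], lim[["down"]]))
  }
  list(
    optical = o,
    visual = visual,
    pupil = oe + eye$pupil_distance * o,
    cornea = oe + eye$cornea_center_offset * o,
    targets = targets
  )
}

#' Rotate the eye to fixate a screen target
#'
#' Orients the schematic eye so that its visual axis, leaving the nodal point,
#' passes through the given screen target; the optical axis is the visual axis
#' with the Kappa rotation removed, and the pupil center follows the optical
#' axis at the configured pupil distance.
#'
#' @param eye an [eye_model()].
#' @param target 2-vector, screen coordinates in mm (screen plane `z = 0`).
#' @return an object of class `eye_state`: unit `optical_axis` and
#'   `visual_axis`, `pupil_center_world`, `cornea_center_world` and the
#'   `gazed_target`.
#' @export
gaze_at <- function(eye, target) {
  stopifnot(inherits(eye, "eye_model"), length(target) == 2)
  st <- .gaze_states(eye, matrix(target, 1))
  structure(
    list(
      optical_axis = st$optical[1, ],
      visual_axis = st$visual[1, ],
      pupil_center_world = st$pupil[1, ],
      cornea_center_world = st$cornea[1, ],
      gazed_target = as.numeric(target),
      eye = eye
    ),
    class = "eye_state"
  )
}

#' @export
print.eye_state <- function(x, ...) {
  cat(sprintf("Eye state fixating (%g, %g) mm\n",
              x$gazed_target[1], x$gazed_target[2]))
  cat(sprintf("  optical axis (%.4f, %.4f, %.4f)\n",
              x$optical_axis[1], x$optical_axis[2], x$optical_axis[3]))
  cat(sprintf("  pupil center (%.3f, %.3f, %.3f) mm\n",
              x$pupil_center_world[1], x$pupil_center_world[2],
              x$pupil_center_world[3]))
  invisible(x)
}
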