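# Pinhole imaging, corneal refraction and glint formation.

# Camera rotation: rows are the camera axes (x right, y up, z from the camera
# center toward the look-at point).
.camera_frame <- function(camera) {
  zc <- camera$look_at - camera$position
  nz <- sqrt(sum(zc^2))
  if (nz < 1e-12) stop("camera look-at point coincides with the camera center")
  zc <- zc / nz
  up <- c(0, 1, 0)
  xc <- c(up[2] * zc[3] - up[3] * zc[2],
          up[3] * zc[1] - up[1] * zc[3],
          up[1] * zc[2] - up[2] * zc[1])
  nx <- sqrt(sum(xc^2))
  if (nx < 1e-9) stop("camera looks straight up/down; view frame undefined")
  xc <- xc / nx
  yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
          zc[3] * xc[1] - zc[1] * xc[3],
          zc[1] * xc[2] - zc[2] * xc[1])
  rbind(xc, yc, zc)
}

# Pinhole projection of world points (n x 3) to metric image coordinates.
.project_points <- function(P, camera, frame = NULL) {
  if (is.null(frame)) frame <- .camera_frame(camera)
  pc <- sweep(P, 2, camera$position) %*% t(frame)
  if (any(pc[, 3] <= 1e-9)) stop("point at or behind the camera center")
  cbind(camera$focal_length * pc[, 1] / pc[, 3] + camera$principal_point[1],
        camera$focal_length * pc[, 2] / pc[, 3] + camera$principal_point[2])
}

# Refraction of unit direction d at unit normal nrm (rows), entering a medium
# with relative index eta = n1/n2. Assumes cos(i) = -d.nrm > 0.
.refract_dir <- function(dx, dy, nx, ny, eta) {
  cosi <- -(dx * nx + dy * ny)
  k <- 1 - eta^2 * (1 - cosi^2)
  k <- pmax(k, 0)
  f <- eta * cosi - sqrt(k)
  list(x = eta * dx + f * nx, y = eta * dy + f * ny)
}

# Find, for each record, the point on the corneal sphere where a ray from the
# camera center refracts toward the pupil center (Snell's law, one surface).
# By symmetry the point lies in the plane spanned by the camera and pupil
# directions seen from the cornea center, so the search is one-dimensional in
# the polar angle on that plane's great circle. A coarse sign scan brackets
# the root; bisection then reduces it below the requested tolerance (mm).
# Returns the world refraction points (n x 3).
.refraction_points <- function(pupil, cornea, camera_pos, R, n_index,
                               tol = 1e-9) {
  n <- nrow(pupil)
  C <- matrix(camera_pos, n, 3, byrow = TRUE)
  cv <- C - cornea
  cu <- .vnorm(cv)
  if (any(cu <= R)) stop("camera center inside the corneal sphere")
  u <- cv / cu
  pv <- pupil - cornea
  p_u <- .vdot(pv, u)
  perp <- pv - p_u * u
  p_w <- .vnorm(perp)
  axial <- p_w < 1e-12
  w <- perp
  w[!axial, ] <- perp[!axial, , drop = FALSE] / p_w[!axial]
  if (any(axial)) {
    # camera on the optical axis: any transverse direction works
    alt <- .gaze_frame(u[axial, , drop = FALSE])$h
    w[axial, ] <- alt
  }
  eta <- 1 / n_index
  # residual: signed in-plane cross product between the refracted direction
  # and the direction from the surface point to the pupil center
  gfun <- function(th) {
    sx <- R * cos(th)
    sy <- R * sin(th)
    dx <- sx - cu
    dy <- sy
    dn <- sqrt(dx * dx + dy * dy)
    dx <- dx / dn
    dy <- dy / dn
    tr <- .refract_dir(dx, dy, sx / R, sy / R, eta)
    rx <- p_u - sx
    ry <- p_w - sy
    tr$x * ry - tr$y * rx
  }
  th_p <- atan2(p_w, p_u)
  th_lim <- acos(pmin(R / cu, 1)) - 1e-6
  lo <- rep(-0.15, n)
  hi <- pmin(th_p + 1.0, th_lim)
  # coarse scan for a sign change
  m <- 40L
  glo <- gfun(lo)
  found <- rep(FALSE, n)
  a <- lo
  b <- hi
  prev_th <- lo
  prev_g <- glo
  for (j in seq_len(m)) {
    th <- lo + (hi - lo) * j / m
    g <- gfun(th)
    new_hit <- !found & (sign(g) != sign(prev_g))
    a[new_hit] <- prev_th[new_hit]
    b[new_hit] <- th[new_hit]
    found <- found | new_hit
    prev_th <- th
    prev_g <- g
  }
  if (!all(found)) {
    stop(sprintf("no corneal refraction solution for %d record(s); %s",
                 sum(!found),
                 "the camera is likely behind the eye or at grazing incidence"))
  }
  ga <- gfun(a)
  it_max <- ceiling(log2(max(b - a) * R / tol)) + 2L
  for (j in seq_len(it_max)) {
    mid <- (a + b) / 2
    gm <- gfun(mid)
    left <- sign(gm) == sign(ga)
    a[left] <- mid[left]
    ga[left] <- gm[left]
    b[!left] <- mid[!left]
  }
  th <- (a + b) / 2
  cornea + R * (cos(th) * u + sin(th) * w)
}

# Vectorized pupil observation for precomputed gaze states.
.observe_pupils <- function(states, scene, refraction = TRUE, frame = NULL) {
  cam <- scene$camera
  if (is.null(cam$look_at)) cam$look_at <- scene$eye$eyeball_center
  if (refraction) {
    pts <- .refraction_points(states$pupil, states$cornea, cam$position,
                              scene$eye$cornea_radius,
                              scene$eye$refraction_index)
  } else {
    pts <- states$pupil
  }
  .project_points(pts, cam, frame)
}

#' Image the pupil center with the eye-camera
#'
#' Projects the pupil center of a fixating eye into the pinhole eye-camera.
#' With `refraction = TRUE` (the default) the camera sees the virtual pupil
#' image formed by rays from the pupil center refracted once at the corneal
#' sphere (Snell's law, aqueous-to-air index ratio from the eye model); the
#' refraction point on the cornea is solved numerically to below 1e-9 mm.
#'
#' @param state an [gaze_at()] eye state.
#' @param scene a [scene()] (its eye must match the state's eye).
#' @param refraction logical; image the pupil through the cornea or project
#'   the geometric pupil center directly.
#' @return 2-vector of metric image coordinates.
#' @export
observe_pupil <- function(state, scene, refraction = TRUE) {
  stopifnot(inherits(state, "eye_state"), inherits(scene, "scene"))
  st <- list(pupil = matrix(state$pupil_center_world, 1),
             cornea = matrix(state$cornea_center_world, 1))
  drop(.observe_pupils(st, scene, refraction))
}

# Specular reflection (glint) of one LED on the corneal sphere, seen from the
# camera. One-dimensional solve in the plane through the LED, the camera and
# the cornea center; the mirror condition is that the bisector of the
# incident and reflected directions is parallel to the surface normal.
.glint_point <- function(led, cornea, camera_pos, R) {
  cv <- camera_pos - cornea
  cu <- sqrt(sum(cv^2))
  u <- cv / cu
  lv <- led - cornea
  l_u <- sum(lv * u)
  perp <- lv - l_u * u
  l_w <- sqrt(sum(perp^2))
  if (l_w < 1e-9) {
    # LED on the camera axis: retro-reflection at the nearest corneal point
    th <- 0
    w <- .gaze_frame(matrix(u, 1))$h[1, ]
  } else {
    w <- perp / l_w
    gf <- function(th) {
      sx <- R * cos(th)
      sy <- R * sin(th)
      dcx <- cu - sx
      dcy <- -sy
      dn <- sqrt(dcx^2 + dcy^2)
      dcx <- dcx / dn
      dcy <- dcy / dn
      dlx <- l_u - sx
      dly <- l_w - sy
      ln <- sqrt(dlx^2 + dly^2)
      dlx <- dlx / ln
      dly <- dly / ln
      bx <- dcx + dlx
      by <- dcy + dly
      bx * sin(th) - by * cos(th)
    }
    th_l <- atan2(l_w, l_u)
    hi <- min(th_l, acos(min(R / cu, 1)))
    if (gf(0) * gf(hi) > 0) return(rep(NA_real_, 3))
    th <- stats::uniroot(gf, c(0, hi), tol = 1e-12)$root
  }
  S <- cornea + R * (cos(th) * u + sin(th) * w)
  nrm <- (S - cornea) / R
  if (sum((camera_pos - S) * nrm) <= 0 || sum((led - S) * nrm) <= 0) {
    return(rep(NA_real_, 3))
  }
  S
}

#' Image the corneal reflections of the scene LEDs
#'
#' For each LED the specular reflection point on the corneal sphere toward the
#' camera center is solved numerically and projected by the pinhole model.
#' Reflections outside the visible corneal cap are returned as `NA` (missing
#' glint). Output rows follow the LED order.
#'
#' @param state an [gaze_at()] eye state.
#' @param scene a [scene()] with 4 LEDs configured.
#' @return 4 x 2 matrix of metric image coordinates (rows may be `NA`).
#' @export
observe_glints <- function(state, scene) {
  stopifnot(inherits(state, "eye_state"), inherits(scene, "scene"))
  if (is.null(scene$leds)) stop("scene has no LEDs configured")
  cam <- scene$camera
  if (is.null(cam$look_at)) cam$look_at <- scene$eye$eyeball_center
  frame <- .camera_frame(cam)
  out <- matrix(NA_real_, nrow(scene$leds), 2)
  for (i in seq_len(nrow(scene$leds))) {
    S <- .glint_point(scene$leds[i, ], state$cornea_center_world,
                      cam$position, scene$eye$cornea_radius)
    if (!anyNA(S)) out[i, ] <- .project_points(matrix(S, 1), cam, frame)
  }
  out
}

#' Uniform target grid
#'
#' @param nx,ny number of targets per axis.
#' @param x_range,y_range target coordinate ranges, mm.
#' @return a `nx*ny` x 2 matrix in row-major order (x varies fastest within
#'   each row of targets, rows sweep y from bottom to top).
#' @export
target_grid <- function(nx = 21, ny = 21, x_range = c(-200, 200),
                        y_range = c(50, 350)) {
  xs <- seq(x_range[1], x_range[2], length.out = nx)
  ys <- seq(y_range[1], y_range[2], length.out = ny)
  as.matrix(expand.grid(x = xs, y = ys))
}

#' Indices of the 3 x 3 calibration subset of a uniform target grid
#'
#' Selects the nine calibration targets (four corners, four edge midpoints and
#' the center) out of an `nx` x `ny` uniform grid; both counts must be odd.
#'
#' @param nx,ny grid dimensions.
#' @return integer vector of nine row indices into [target_grid()] order.
#' @export
calibration_indices <- function(nx = 21, ny = 21) {
  if (nx %% 2 == 0 || ny %% 2 == 0) {
    stop("calibration subset requires odd grid dimensions")
  }
  ix <- c(1L, (nx + 1L) %/% 2L, nx)
  iy <- c(1L, (ny + 1L) %/% 2L, ny)
  as.integer(outer(ix, (iy - 1L) * nx, `+`))
}

#' Simulate one eye-tracking session
#'
#' Rotates the eye over a grid of screen targets and images the pupil center
#' (and, when LEDs are configured, the four corneal reflections) at a fixed
#' camera position. The output is deterministic: one record per target in
#' row-major target order.
#'
#' @param scene a [scene()].
#' @param targets either a target matrix (n x 2, mm) or a list
#'   `list(nx =, ny =)` describing a uniform grid over the screen's target
#'   range (default 21 x 21).
#' @param refraction image the pupil through the cornea (default `TRUE`).
#' @return a `feature_set`: a data frame with columns `target_id`, `target_x`,
#'   `target_y`, `pupil_x`, `pupil_y` (metric image coordinates) and, with
#'   LEDs, `glint1_x` .. `glint4_y`; the scene, camera position and grid shape
#'   are kept as attributes.
#' @export
simulate_session <- function(scene, targets = list(nx = 21, ny = 21),
                             refraction = TRUE) {
  stopifnot(inherits(scene, "scene"))
  grid_dim <- NULL
  if (is.list(targets) && !is.matrix(targets)) {
    grid_dim <- c(targets$nx, targets$ny)
    targets <- target_grid(targets$nx, targets$ny,
                           scene$screen$x_range, scene$screen$y_range)
  } else {
    targets <- matrix(as.numeric(targets), ncol = 2)
  }
  st <- .gaze_states(scene$eye, targets)
  .session_from_states(st, scene, refraction, grid_dim)
}

# Build a feature_set from precomputed gaze states (shared by sweeps so the
# fixation solve is done once per target set).
.session_from_states <- function(st, scene, refraction = TRUE,
                                 grid_dim = NULL) {
  cam <- scene$camera
  if (is.null(cam$look_at)) cam$look_at <- scene$eye$eyeball_center
  frame <- .camera_frame(cam)
  feats <- .observe_pupils(st, scene, refraction, frame)
  n <- nrow(feats)
  df <- data.frame(
    target_id = seq_len(n),
    target_x = st$targets[, 1], target_y = st$targets[, 2],
    pupil_x = feats[, 1], pupil_y = feats[, 2]
  )
  if (!is.null(scene$leds)) {
    g <- matrix(NA_real_, n, 8)
    for (i in seq_len(n)) {
      for (k in 1:4) {
        S <- .glint_point(scene$leds[k, ], st$cornea[i, ], cam$position,
                          scene$eye$cornea_radius)
        if (!anyNA(S)) g[i, c(2 * k - 1, 2 * k)] <-
            .project_points(matrix(S, 1), cam, frame)
      }
    }
    colnames(g) <- as.vector(t(outer(paste0("glint", 1:4),
                                     c("_x", "_y"), paste0)))
    df <- cbind(df, as.data.frame(g))
  }
  feature_set(df, camera_position = cam$position, scene = scene,
              grid_dim = grid_dim, refraction = refraction)
}

#' Feature-set container
#'
#' A `feature_set` is a data frame of corresponded records (viewed target,
#' pupil feature and optional glints) for one session, i.e. one fixed camera
#' position. It is the exchange type between the simulator, the annotated-CSV
#' readers and the gaze-estimation pipelines.
#'
#' @param df data frame with at least `target_x`, `target_y`, `pupil_x`,
#'   `pupil_y`.
#' @param camera_position 3-vector, mm (or `NA` for imported data).
#' @param scene optional originating [scene()].
#' @param grid_dim optional `c(nx, ny)` of the target grid.
#' @param refraction logical flag recorded from the simulation.
#' @param space which plane the pupil feature lives in: the raw eye/image
#'   plane, the glint-normalized space or the normalized unit square.
#' @return the data frame with class `feature_set` and metadata attributes.
#' @export
feature_set <- function(df, camera_position = c(NA_real_, NA_real_, NA_real_),
                        scene = NULL, grid_dim = NULL, refraction = NA,
                        space = c("eye", "glint", "normalized")) {
  space <- match.arg(space)
  need <- c("target_x", "target_y", "pupil_x", "pupil_y")
  if (!all(need %in% names(df))) {
    stop("feature_set needs columns ", paste(need, collapse = ", "))
  }
  structure(df,
            class = c("feature_set", "data.frame"),
            camera_position = as.numeric(camera_position),
            scene = scene, grid_dim = grid_dim, refraction = refraction,
            space = space)
}

#' @export
print.feature_set <- function(x, ...) {
  cp <- attr(x, "camera_position")
  cat(sprintf("Feature set: %d records, space '%s', camera (%s)\n",
              nrow(x), attr(x, "space"),
              paste(signif(cp, 6), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("  ... %d more records\n", nrow(x) - 4))
  invisible(x)
}

# Matrix views of a feature set.
.fs_features <- function(fs) cbind(fs$pupil_x, fs$pupil_y)
.fs_targets <- function(fs) cbind(fs$target_x, fs$target_y)

#' Sweep the eye-camera over a 3-D grid of positions
#'
#' Repeats [simulate_session()] with the camera at every node of a uniform
#' position grid while the eye, screen and targets stay fixed. The fixation
#' states are solved once and shared across positions.
#'
#' @param scene a [scene()]; its camera supplies every parameter except the
#'   position.
#' @param grid list with numeric vectors `x`, `y`, `z` of camera coordinates
#'   (mm); the sweep covers their full Cartesian product, z fastest.
#' @param targets as in [simulate_session()].
#' @param refraction as in [simulate_session()].
#' @param summarise optional `function(feature_set)`; when given, only its
#'   value is stored per position (memory-friendly for large sweeps).
#' @return a `sweep_result`: list with `positions` (n x 3 matrix) and
#'   `results` (list of feature sets or summaries).
#' @export
camera_sweep <- function(scene, grid = list(x = seq(-200, 200, 20),
                                            y = seq(50, 350, 15),
                                            z = seq(0, 400, 20)),
                         targets = list(nx = 21, ny = 21),
                         refraction = TRUE, summarise = NULL) {
  stopifnot(inherits(scene, "scene"))
  pos <- as.matrix(expand.grid(z = grid$z, y = grid$y,
                               x = grid$x))[, 3:1, drop = FALSE]
  colnames(pos) <- c("x", "y", "z")
  if (is.list(targets) && !is.matrix(targets)) {
    grid_dim <- c(targets$nx, targets$ny)
    tmat <- target_grid(targets$nx, targets$ny,
                        scene$screen$x_range, scene$screen$y_range)
  } else {
    grid_dim <- NULL
    tmat <- matrix(as.numeric(targets), ncol = 2)
  }
  st <- .gaze_states(scene$eye, tmat)
  results <- vector("list", nrow(pos))
  for (i in seq_len(nrow(pos))) {
    sc <- scene
    sc$camera$position <- unname(pos[i, ])
    sc$camera$look_at <- scene$eye$eyeball_center
    fs <- .session_from_states(st, sc, refraction, grid_dim)
    results[[i]] <- if (is.null(summarise)) fs else summarise(fs)
  }
  structure(list(positions = pos, results = results, grid = grid),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Camera sweep over %d positions (x %d, y %d, z %d)\n",
              nrow(x$positions), length(x$grid$x), length(x$grid$y),
              length(x$grid$z)))
  invisible(x)
}
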