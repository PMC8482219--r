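# Geometric eye-tracker simulator: fixation kinematics, corneal refraction,
# glints, sessions and camera sweeps.

test_that("fixation geometry is symmetric and respects the kappa offset", {
  eye0 <- eye_model(kappa = c(0, 0))
  # zero kappa, target straight ahead: optical axis points at the screen
  st <- gaze_at(eye0, c(0, 200))
  expect_close(st$optical_axis, c(0, 0, -1), 1e-12)
  expect_close(st$pupil_center_world,
               eye0$eyeball_center + eye0$pupil_distance * c(0, 0, -1),
               1e-12)
  # mirrored targets give mirrored optical axes
  stl <- gaze_at(eye0, c(-120, 260))
  str <- gaze_at(eye0, c(120, 260))
  expect_close(stl$optical_axis * c(-1, 1, 1), str$optical_axis, 1e-12)

  # with kappa on, the optical/visual separation equals the composed
  # rotation angle for every fixation (brute-force Rodrigues oracle)
  eye <- eye_model(kappa = c(6, 2))
  rot <- function(v, k, th) {
    v * cos(th) + c(k[2] * v[3] - k[3] * v[2],
                    k[3] * v[1] - k[1] * v[3],
                    k[1] * v[2] - k[2] * v[1]) * sin(th) +
      k * sum(k * v) * (1 - cos(th))
  }
  o <- c(0, 0, -1)
  v <- rot(rot(o, c(1, 0, 0), 2 * pi / 180), c(0, 1, 0), -6 * pi / 180)
  expected <- vec_angle(o, v) * 180 / pi   # = acos(cos 6 cos 2) ~ 6.3245 deg
  for (tgt in list(c(0, 200), c(-150, 80), c(180, 330))) {
    st <- gaze_at(eye, tgt)
    expect_equal(vec_angle(st$optical_axis, st$visual_axis) * 180 / pi,
                 expected, tolerance = 1e-10)
    expect_equal(sqrt(sum(st$optical_axis^2)), 1, tolerance = 1e-12)
  }
  # exact composed angle acos(cos 6 cos 2) = 6.3234; the small-angle
  # root-sum-of-squares 6.32 approximation is good to ~1e-3 deg
  expect_equal(expected, 6.3234, tolerance = 1e-3)
})

test_that("rotation limits raise axis-specific errors", {
  eye <- eye_model(eyeball_center = c(0, 200, 100))  # very close: huge angles
  expect_error(gaze_at(eye, c(-200, 200)), "horizontal")
  expect_error(gaze_at(eye, c(0, 350)), "vertical")
})

test_that("pupil observation obeys axial symmetry and the refraction limit", {
  eye0 <- eye_model(kappa = c(0, 0))
  sc <- scene(camera = camera_spec(position = c(0, 200, 0)), eye = eye0)
  st <- gaze_at(eye0, c(0, 200))
  # camera on the optical axis: feature at the principal point, with and
  # without refraction
  expect_close(observe_pupil(st, sc, refraction = TRUE), c(0, 0), 1e-9)
  expect_close(observe_pupil(st, sc, refraction = FALSE), c(0, 0), 1e-12)

  # refraction displaces an off-axis observation, continuously in the index
  sc2 <- scene(camera = camera_spec(position = c(-100, 100, 0)))
  st2 <- gaze_at(eye_model(), c(100, 300))
  p_off <- observe_pupil(st2, sc2, refraction = FALSE)
  p_on <- observe_pupil(st2, sc2, refraction = TRUE)
  expect_gt(sqrt(sum((p_on - p_off)^2)), 1e-3)
  disp <- sapply(c(1.1, 1.01, 1.001, 1.0001), function(ri) {
    eye <- eye_model(refraction_index = ri)
    st <- gaze_at(eye, c(100, 300))
    sqrt(sum((observe_pupil(st, scene(camera = camera_spec(c(-100, 100, 0)),
                                      eye = eye)) - p_off)^2))
  })
  expect_true(all(diff(disp) < 0))        # monotone vanishing
  expect_lt(disp[4], 1e-5)                # index -> 1 recovers the pinhole
})

test_that("on-axis depth change rescales the feature grid", {
  # two aligned cameras 550 mm apart; without refraction the grids are
  # related by a single scale factor of about one half, up to the small
  # non-coplanarity of the pupil sphere
  f1 <- simulate_session(scene(camera = camera_spec(c(0, 200, 0))),
                         list(nx = 16, ny = 16), refraction = FALSE)
  f2 <- simulate_session(scene(camera = camera_spec(c(0, 200, -550))),
                         list(nx = 16, ny = 16), refraction = FALSE)
  m1 <- cbind(f1$pupil_x, f1$pupil_y)
  m2 <- cbind(f2$pupil_x, f2$pupil_y)
  s <- sum(m1 * m2) / sum(m1 * m1)
  expect_equal(s, 0.5, tolerance = 0.02)
  resid <- sqrt(mean((m2 - s * m1)^2)) / stats::sd(as.vector(m1))
  expect_lt(resid, 1e-3)
})

test_that("glints satisfy the mirror equation and LED ordering", {
  scr <- screen_spec()
  sc <- scene(camera = camera_spec(c(0, 100, 50)), leds = corner_leds(scr))
  st <- gaze_at(sc$eye, c(0, 200))
  g <- observe_glints(st, sc)
  expect_equal(dim(g), c(4, 2))
  expect_false(anyNA(g))
  # residual check of the solver's own geometry: incident and reflected
  # angles at the solved corneal point agree
  for (k in 1:4) {
    S <- gazecomp:::.glint_point(sc$leds[k, ], st$cornea_center_world,
                                 sc$camera$position, sc$eye$cornea_radius)
    nrm <- (S - st$cornea_center_world) / sc$eye$cornea_radius
    ai <- vec_angle(sc$leds[k, ] - S, nrm)
    ar <- vec_angle(sc$camera$position - S, nrm)
    expect_lt(abs(ai - ar), 1e-6)
  }
  # eye centered between symmetric LEDs: glint quad symmetric in x
  eye0 <- eye_model(kappa = c(0, 0))
  sc0 <- scene(camera = camera_spec(c(0, 200, 0)), leds = corner_leds(scr),
               eye = eye0)
  g0 <- observe_glints(gaze_at(eye0, c(0, 200)), sc0)
  expect_close(g0[1, ], c(-g0[2, 1], g0[2, 2]), 1e-9)
  expect_close(g0[4, ], c(-g0[3, 1], g0[3, 2]), 1e-9)

  # LED at the camera center retro-reflects at the nearest corneal point
  sc_r <- scene(camera = camera_spec(c(50, 150, 20)),
                leds = rbind(c(50, 150, 20), corner_leds(scr)[2:4, ]),
                eye = eye0)
  st_r <- gaze_at(eye0, c(0, 200))
  S <- gazecomp:::.glint_point(c(50, 150, 20), st_r$cornea_center_world,
                               c(50, 150, 20), sc_r$eye$cornea_radius)
  dir_cam <- (c(50, 150, 20) - st_r$cornea_center_world)
  nearest <- st_r$cornea_center_world +
    sc_r$eye$cornea_radius * dir_cam / sqrt(sum(dir_cam^2))
  expect_close(S, nearest, 1e-9)
})

test_that("sessions are deterministic with the documented record layout", {
  sc <- scene(camera = camera_spec(c(-50, 120, 0)))
  fs <- simulate_session(sc, list(nx = 21, ny = 21))
  expect_s3_class(fs, "feature_set")
  expect_equal(nrow(fs), 441)
  expect_identical(fs, simulate_session(sc, list(nx = 21, ny = 21)))
  # row-major target order: x varies fastest
  expect_equal(fs$target_x[1:3], c(-200, -180, -160))
  expect_equal(fs$target_y[1:3], rep(50, 3))
  # 1 x 1 grid reproduces observe_pupil
  one <- simulate_session(sc, matrix(c(40, 260), 1))
  st <- gaze_at(sc$eye, c(40, 260))
  expect_close(c(one$pupil_x, one$pupil_y), observe_pupil(st, sc), 1e-12)
})

test_that("with zero kappa and a centered camera the feature distribution is
           symmetric under x-negation of targets", {
  eye0 <- eye_model(kappa = c(0, 0))
  sc <- scene(camera = camera_spec(c(0, 200, 0)), eye = eye0)
  fs <- simulate_session(sc, list(nx = 11, ny = 11))
  m <- cbind(fs$pupil_x, fs$pupil_y)
  flip <- m[order(-fs$target_x, fs$target_y), ]
  orig <- m[order(fs$target_x, fs$target_y), ]
  expect_close(flip[, 1], -orig[, 1], 1e-9)
  expect_close(flip[, 2], orig[, 2], 1e-9)
})

test_that("camera sweeps cover the configured grid and degenerate to a
           session", {
  sc <- scene()
  sw <- camera_sweep(sc, grid = list(x = c(-100, 0, 100), y = c(100, 200),
                                     z = c(0, 200)),
                     targets = list(nx = 5, ny = 5))
  expect_equal(nrow(sw$positions), 12)
  expect_length(sw$results, 12)
  # x-only sweep
  sw1 <- camera_sweep(sc, grid = list(x = seq(-200, 200, 20), y = 200, z = 0),
                      targets = list(nx = 3, ny = 3),
                      summarise = function(fs) nrow(fs))
  expect_equal(nrow(sw1$positions), 21)
  expect_true(all(unlist(sw1$results) == 9))
  # 1 x 1 x 1 grid equals simulate_session at that position
  sw0 <- camera_sweep(sc, grid = list(x = 30, y = 150, z = 100),
                      targets = list(nx = 5, ny = 5))
  sc0 <- scene(camera = camera_spec(c(30, 150, 100)))
  expect_equal(as.data.frame(sw0$results[[1]]),
               as.data.frame(simulate_session(sc0, list(nx = 5, ny = 5))))
})

test_that("invalid geometry is rejected with diagnostics", {
  eye <- eye_model()
  expect_error(scene(camera = camera_spec(eye$eyeball_center)), "coincide")
  # a world point behind the camera cannot be projected
  cam <- camera_spec(c(0, 200, 0), look_at = eye$eyeball_center)
  expect_error(gazecomp:::.project_points(matrix(c(0, 200, -100), 1), cam),
               "behind the camera")
  # pupil center must stay inside the corneal sphere
  expect_error(eye_model(pupil_distance = 14), "corneal sphere")
})
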