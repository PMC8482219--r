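# Eye-camera location compensation and quad-glint normalization.

test_that("normalization maps calibration features onto the ideal grid", {
  # features already equal to the ideal grid: identity-like polynomial
  g <- unit_grid3()
  tgt <- cbind(200 * g[, 1], 150 * g[, 2] + 200)
  df <- data.frame(target_x = tgt[, 1], target_y = tgt[, 2],
                   pupil_x = g[, 1], pupil_y = g[, 2])
  fs <- feature_set(df)
  nm <- fit_normalization(fs, calib_indices = 1:9,
                          x_range = c(-200, 200), y_range = c(50, 350))
  expect_close(nm$poly$a, c(0, 0, 0, 1, 0, 0), 1e-10)
  expect_close(nm$poly$b, c(0, 0, 0, 0, 1, 0), 1e-10)
  expect_close(nm$calib_grid_n, g, 1e-12)

  # simulated session: calibration features land on the grid up to the
  # least-squares residual, and all normalized features stay near the square
  sc <- scene(camera = camera_spec(c(-150, 300, 0)))
  sess <- simulate_session(sc, list(nx = 21, ny = 21))
  nm2 <- fit_normalization(sess)
  nf <- normalize_features(nm2, sess)
  cal <- calibration_indices(21, 21)
  res <- sqrt(max(rowSums((cbind(nf$pupil_x, nf$pupil_y)[cal, ] -
                             nm2$calib_grid_n)^2)))
  expect_lt(res, 0.05)
  eps <- res + 0.1
  expect_true(all(abs(nf$pupil_x) <= 1 + eps))
  expect_true(all(abs(nf$pupil_y) <= 1 + eps))
  expect_identical(attr(nf, "space"), "normalized")
})

test_that("normalization virtually re-centers the eye-camera (epipole near
           the screen center)", {
  sc <- scene(camera = camera_spec(c(-250, 400, 0)))
  sess <- simulate_session(sc, list(nx = 21, ny = 21))
  raw <- epipole_diagnostics(sess)
  nf <- normalize_features(fit_normalization(sess), sess)
  comp <- epipole_diagnostics(nf)
  expect_gt(raw$alpha_deg, 15)
  expect_lt(comp$alpha_deg, 5)
})

test_that("normalization absorbs on-axis camera depth to first order", {
  # the pupil sphere is not a plane, so the match is not exact; the residual
  # is orders of magnitude below the feature scale
  mk <- function(z) {
    s <- simulate_session(scene(camera = camera_spec(c(0, 200, z))),
                          list(nx = 21, ny = 21))
    nf <- normalize_features(fit_normalization(s), s)
    cbind(nf$pupil_x, nf$pupil_y)
  }
  d <- sqrt(rowSums((mk(0) - mk(-550))^2))
  expect_lt(max(d), 1e-3)
})

test_that("normalized aligned-camera features show barrel curvature", {
  # middle row of a 16x16 grid from an aligned camera bends toward the
  # center: positive radial distortion
  sc <- scene(camera = camera_spec(c(0, 200, 0)))
  sess <- simulate_session(sc, list(nx = 21, ny = 21))
  nf <- normalize_features(fit_normalization(sess), sess)
  top <- nf$pupil_y[nf$target_y == 350]     # top edge row
  mid <- top[order(nf$target_x[nf$target_y == 350])]
  # barrel shape: the middle of the top row bulges outward past the pinned
  # corners
  expect_gt(abs(mid[11]), abs(mid[1]))
  expect_gt(abs(mid[11]), abs(mid[21]))
})

test_that("compensation brings feature sets from different camera positions
           together (beyond similarity alignment)", {
  skip_if_not_installed("vegan")
  sessions <- lapply(list(c(-200, 350, 0), c(150, 100, 200)), function(p) {
    simulate_session(scene(camera = camera_spec(p)), list(nx = 11, ny = 11))
  })
  raw <- lapply(sessions, function(s) cbind(s$pupil_x, s$pupil_y))
  nrm <- lapply(sessions, function(s) {
    nf <- normalize_features(fit_normalization(s, calibration_indices(11, 11)),
                             s)
    cbind(nf$pupil_x, nf$pupil_y)
  })
  # best similarity alignment of the raw sets (Procrustes with scaling)
  pr <- vegan::procrustes(raw[[1]], raw[[2]], scale = TRUE)
  raw_dist <- mean(sqrt(rowSums((pr$X - pr$Yrot)^2))) /
    stats::sd(as.vector(pr$X))
  nrm_dist <- mean(sqrt(rowSums((nrm[[1]] - nrm[[2]])^2))) /
    stats::sd(as.vector(nrm[[1]]))
  expect_lt(nrm_dist, raw_dist)
})

test_that("quad-glint normalization is exactly projective-invariant", {
  quad <- rbind(c(10, 12), c(52, 14), c(50, 48), c(8, 50))
  pupil <- c(30, 31)
  base <- glint_normalize(pupil, quad)
  # square quad: centroid maps to the center, corner 1 to (0,0)
  sq <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)) + 20
  expect_close(glint_normalize(c(22, 22), sq), c(0.5, 0.5), 1e-10)
  expect_close(glint_normalize(c(20, 20), sq), c(0, 0), 1e-10)
  set.seed(5)
  for (rep in 1:5) {
    P <- random_homography()
    quad2 <- apply_homography(P, quad)
    pupil2 <- apply_homography(P, pupil)
    expect_close(glint_normalize(pupil2, quad2), base, 1e-9)
  }
  # joint translation changes nothing
  expect_close(glint_normalize(pupil + c(7, -3), quad + rep(c(7, -3), each = 4)),
               base, 1e-10)
  # missing glints flag the record instead of failing
  quad_na <- quad
  quad_na[2, ] <- NA
  expect_true(all(is.na(glint_normalize(pupil, quad_na))))
})
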