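# Fundamental-matrix diagnostics: estimation, epipoles, epipolar lines.

test_that("the eight-point estimate satisfies a synthetic two-view oracle", {
  set.seed(17)
  # random 3-D points seen by two pinhole cameras built in the helper
  X <- cbind(stats::runif(40, -50, 50), stats::runif(40, -50, 50),
             stats::runif(40, 200, 400))
  look <- function(C) {
    z <- colMeans(X) - C
    z <- z / sqrt(sum(z^2))
    x <- c(z[3], 0, -z[1])
    x <- x / sqrt(sum(x^2))
    rbind(x, c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
               z[1] * x[2] - z[2] * x[1]), z)
  }
  C1 <- c(-80, 20, 0)
  C2 <- c(100, -40, 30)
  p1 <- project_oracle(X, C1, look(C1))
  p2 <- project_oracle(X, C2, look(C2))
  Fm <- estimate_fundamental(p1[1:30, ], p2[1:30, ])
  # rank 2, unit norm, small epipolar residual on held-out points
  expect_lt(svd(Fm$F)$d[3], 1e-10)
  expect_equal(norm(Fm$F, "F"), 1, tolerance = 1e-12)
  held <- 31:40
  resid <- abs(rowSums(cbind(p2[held, ], 1) *
                         (cbind(p1[held, ], 1) %*% t(Fm$F))))
  expect_lt(max(resid), 1e-8)
  # swapping the point sets transposes F (up to sign)
  Fs <- estimate_fundamental(p2[1:30, ], p1[1:30, ])
  expect_lt(min(norm(Fs$F - t(Fm$F), "F"), norm(Fs$F + t(Fm$F), "F")), 1e-8)
})

test_that("epipoles localize a simulated eye-camera for a kappa-free eye", {
  # with zero kappa the visual ray passes through a fixed nodal region and
  # (target <-> feature) is an exact two-view pair: the viewed-plane epipole
  # falls on the generating camera's x-y location
  eye0 <- eye_model(kappa = c(0, 0))
  for (cam in list(c(250, 0, 0), c(-250, 400, 0))) {
    fs <- simulate_session(scene(camera = camera_spec(cam), eye = eye0),
                           list(nx = 21, ny = 21))
    Fm <- estimate_fundamental(cbind(fs$pupil_x, fs$pupil_y),
                               cbind(fs$target_x, fs$target_y))
    e <- epipole_of(Fm, "dst")
    expect_close(e, cam[1:2], 1e-6)
  }
  # with the study's kappa the pupil leaves the visual ray and the epipole
  # picks up a systematic offset of a few centimetres -- a property of the
  # eye, not of the estimator
  fs <- simulate_session(scene(camera = camera_spec(c(250, 0, 0))),
                         list(nx = 21, ny = 21))
  e2 <- epipole_of(estimate_fundamental(cbind(fs$pupil_x, fs$pupil_y),
                                        cbind(fs$target_x, fs$target_y)),
                   "dst")
  expect_lt(sqrt(sum((e2 - c(250, 0))^2)), 80)
  expect_gt(sqrt(sum((e2 - c(250, 0))^2)), 10)
})

test_that("epipolar lines pass through the epipole and ignore F's scale", {
  fs <- simulate_session(scene(camera = camera_spec(c(120, 80, 0)),
                               eye = eye_model(kappa = c(0, 0))),
                         list(nx = 11, ny = 11))
  src <- cbind(fs$pupil_x, fs$pupil_y)
  dst <- cbind(fs$target_x, fs$target_y)
  Fm <- estimate_fundamental(src, dst)
  e <- epipole_of(Fm, "dst")
  L <- epipolar_line(Fm, src[seq(1, 121, 12), ])
  expect_lt(max(abs(L[, 1] * e[1] + L[, 2] * e[2] + L[, 3])), 1e-6)
  expect_close(sqrt(L[, 1]^2 + L[, 2]^2), rep(1, nrow(L)), 1e-12)
  # each line passes through its matching point within the fit residual
  d <- abs(rowSums(cbind(dst[seq(1, 121, 12), ], 1) * L))
  expect_lt(max(d), 10 * Fm$residual_rms + 1e-6)
  expect_equal(epipolar_line(5 * Fm$F, src[1, ]),
               epipolar_line(Fm$F, src[1, ]))
  # a constructed F with known null vector returns that epipole
  e0 <- c(3, -2)
  A <- matrix(stats::rnorm(9), 3, 3)
  Fc <- A - A %*% c(e0, 1) %*% t(c(e0, 1)) / sum(c(e0, 1)^2)
  expect_close(epipole_of(Fc / norm(Fc, "F"), "src"), e0, 1e-8)
})

test_that("near-homographic correspondences are flagged, not failed", {
  # exactly coplanar data: correspondences follow a homography and F is a
  # one-parameter family; the degeneracy diagnostic must say so
  set.seed(9)
  g <- as.matrix(expand.grid(seq(-1, 1, 0.25), seq(-1, 1, 0.25)))
  H <- random_homography()
  dst <- apply_homography(H, g)
  Fm <- estimate_fundamental(g, dst)
  expect_false(Fm$reliable)
  # the simulated (curved) grids are informative by comparison
  fs <- simulate_session(scene(camera = camera_spec(c(250, 0, 0)),
                               eye = eye_model(kappa = c(0, 0))),
                         list(nx = 21, ny = 21))
  Fs <- estimate_fundamental(cbind(fs$pupil_x, fs$pupil_y),
                             cbind(fs$target_x, fs$target_y))
  expect_gt(Fs$degeneracy, Fm$degeneracy)
})
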