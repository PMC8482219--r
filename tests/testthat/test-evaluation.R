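# Visual-angle conversion, Gaussian band analysis, KDE reduction, outlier
# filtering.

test_that("degree conversions follow the right-angled-triangle rule", {
  expect_equal(pixels_to_degrees(0), 0)
  # frozen from the independent arctangent evaluation
  # atan(100 * 0.27675 / 450) * 180 / pi
  expect_equal(pixels_to_degrees(100, 0.27675, 450), 3.5192580,
               tolerance = 1e-6)
  off <- seq(0, 500, 50)
  expect_true(all(diff(pixels_to_degrees(off)) > 0))
  expect_equal(mm_to_degrees(450, 450), 45)
})

test_that("gaze errors decompose into signed axes and magnitude", {
  t0 <- cbind(c(0, 10, -30), c(0, 5, 40))
  expect_true(all(as.matrix(gaze_errors(t0, t0, 550)[, 1:5]) == 0))
  e <- gaze_errors(t0 + rep(c(20, 0), each = 3), t0, 550)
  expect_equal(e$ey_deg, rep(0, 3))
  expect_equal(e$magnitude_deg, abs(e$ex_deg))
  # brute-force per-point oracle on random pairs
  set.seed(31)
  est <- matrix(stats::runif(200, -200, 200), 100)
  tgt <- matrix(stats::runif(200, -200, 200), 100)
  e2 <- gaze_errors(est, tgt, 550)
  oracle <- sapply(1:100, function(i) {
    dx <- atan((est[i, 1] - tgt[i, 1]) / 550) * 180 / pi
    dy <- atan((est[i, 2] - tgt[i, 2]) / 550) * 180 / pi
    sqrt(dx^2 + dy^2)
  })
  expect_close(e2$magnitude_deg, oracle, 1e-12)
  expect_error(gaze_errors(est[1:3, ], tgt, 550), "same length")
})

test_that("the Gaussian fit is consistent, equivariant and degenerate-safe", {
  set.seed(101)
  x <- stats::rnorm(1e4, 0.2, 0.1)
  g <- fit_gaussian(x)
  expect_lt(abs(g$mu - 0.2), 3 * 0.1 / sqrt(1e4))
  expect_lt(abs(g$sigma - 0.1), 5e-3)
  # affine equivariance
  g2 <- fit_gaussian(3 * x - 1)
  expect_equal(g2$mu, 3 * g$mu - 1, tolerance = 1e-12)
  expect_equal(g2$sigma, 3 * g$sigma, tolerance = 1e-12)
  # constant sample: point mass
  gc <- fit_gaussian(rep(0.3, 10))
  expect_equal(gc$sigma, 0)
  expect_equal(gc$p_high, 1)
  expect_equal(fit_gaussian(rep(0.8, 10))$p_high, 0)
})

test_that("band probability matches quadrature and is monotone", {
  g <- list(mu = 0, sigma = 0.5, band = c(-0.5, 0.5))
  expect_equal(high_accuracy_probability(g), 0.6826895, tolerance = 1e-6)
  set.seed(77)
  for (rep in 1:5) {
    mu <- stats::rnorm(1)
    sg <- stats::runif(1, 0.05, 2)
    p <- high_accuracy_probability(list(mu = mu, sigma = sg,
                                        band = c(-0.5, 0.5)))
    q <- stats::integrate(function(x) stats::dnorm(x, mu, sg), -0.5, 0.5,
                          rel.tol = 1e-12)$value
    expect_lt(abs(p - q), 1e-10)
    total <- stats::integrate(function(x) stats::dnorm(x, mu, sg), -Inf, Inf,
                              rel.tol = 1e-12)$value
    expect_lt(abs(total - 1), 1e-10)
  }
  # p decreases in sigma at mu = 0, and in |mu| at fixed sigma
  ps <- sapply(seq(0.1, 2, 0.1), function(s)
    high_accuracy_probability(list(mu = 0, sigma = s, band = c(-0.5, 0.5))))
  expect_true(all(diff(ps) < 0))
  pm <- sapply(seq(0, 2, 0.1), function(m)
    high_accuracy_probability(list(mu = m, sigma = 0.4, band = c(-0.5, 0.5))))
  expect_true(all(diff(pm) < 0))
})

test_that("the two-component mixture mode captures bimodal error masses", {
  skip_if_not_installed("mclust")
  set.seed(88)
  x <- c(stats::rnorm(600, -0.4, 0.1), stats::rnorm(400, 0.6, 0.15))
  g <- fit_gaussian(x, mixture = TRUE)
  emp <- mean(x >= -0.5 & x <= 0.5)
  expect_lt(abs(g$p_high - emp), 0.05)
  # the bimodal structure is resolved
  expect_equal(length(g$components$mu), 2)
  expect_lt(min(g$components$mu), -0.2)
  expect_gt(max(g$components$mu), 0.4)
})

test_that("the KDE representative tracks the dense part of a sample", {
  # tight cluster plus far outliers: a cluster point wins
  set.seed(55)
  cl <- cbind(stats::rnorm(30, 0, 0.05), stats::rnorm(30, 0, 0.05))
  out <- rbind(c(5, 5), c(-6, 4), c(5, -7))
  r <- kde_representative(rbind(cl, out))
  expect_lt(sqrt(sum(r^2)), 0.3)
  # symmetric cloud: mode near the mean, within half a bandwidth
  xy <- cbind(stats::rnorm(150, 2, 0.3), stats::rnorm(150, -1, 0.3))
  bw <- max(stats::bw.nrd0(xy[, 1]), stats::bw.nrd0(xy[, 2]))
  r2 <- kde_representative(xy)
  expect_lt(sqrt(sum((r2 - colMeans(xy))^2)), 0.5 * bw + 0.1)
  # identical points return that point
  expect_equal(kde_representative(matrix(c(1, 2), 5, 2, byrow = TRUE)),
               c(1, 2))
})

test_that("outlier filtering implements the two-stage rule", {
  clean <- data.frame(magnitude_deg = rep(c(0.2, 0.4, 0.6), 30))
  f <- filter_outliers(clean, trial = rep(1:3, each = 30))
  expect_equal(f$report$rows_removed_stage1, 0)
  expect_equal(f$report$rows_removed_stage2, 0)
  # one gross trial among clean trials is removed whole
  bad <- data.frame(magnitude_deg = c(rep(0.3, 60), rep(10, 30)))
  f2 <- filter_outliers(bad, trial = rep(1:3, each = 30))
  expect_equal(f2$report$trials_removed, 1)
  expect_equal(f2$report$rows_removed_stage1, 30)
  expect_equal(nrow(f2$data), 60)
  # a large normal sample loses about the 3-sigma tail mass (~0.27%)
  set.seed(202)
  nrm <- data.frame(magnitude_deg = stats::rnorm(1e4, 0, 1))
  f3 <- filter_outliers(nrm)
  frac <- f3$report$rows_removed_stage2 / 1e4
  expect_gt(frac, 0.0005)
  expect_lt(frac, 0.006)
})

test_that("fixation clouds reduce to one representative record per target", {
  base <- data.frame(
    target_id = rep(1:4, each = 40),
    target_x = rep(c(0, 100, 0, 100), each = 40),
    target_y = rep(c(0, 0, 100, 100), each = 40),
    pupil_x = rep(c(10, 20, 10, 20), each = 40) + stats::rnorm(160, 0, 0.1),
    pupil_y = rep(c(10, 10, 20, 20), each = 40) + stats::rnorm(160, 0, 0.1)
  )
  fs <- feature_set(base)
  red <- reduce_fixations(fs)
  expect_equal(nrow(red), 4)
  expect_equal(red$target_id, 1:4)
  expect_close(red$pupil_x, c(10, 20, 10, 20), 0.5)
})
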