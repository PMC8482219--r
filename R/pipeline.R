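# The six gaze-estimation pipelines evaluated throughout: the traditional
# homography (Hes) and second-order polynomial (Pes) mappings, each in three
# variants -- raw eye features, with eye-camera location compensation (+),
# and with compensation plus eye-feature undistortion (*).

#' Names of the available gaze-estimation pipelines
#'
#' `Hes`/`Pes` map raw eye features straight to the screen; the `+` variants
#' first normalize the features into the unit square (eye-camera location
#' compensation); the `*` variants additionally fit and apply the
#' lens-distortion correction before the final mapping.
#'
#' @return character vector of method names.
#' @export
gaze_methods <- function() c("Hes", "Hes+", "Hes*", "Pes", "Pes+", "Pes*")

.final_map <- function(kind, src_cal, dst_cal, src_all) {
  if (kind == "H") {
    apply_homography(fit_homography(src_cal, dst_cal), src_all)
  } else {
    apply_poly2(fit_poly2(src_cal, dst_cal), src_all)
  }
}

# Shared estimation core: features and targets as matrices, returns a named
# list of n x 2 estimate matrices, computing the normalization and the
# distortion fit once across methods.
.methods_estimates <- function(feats, targets, calib, x_range, y_range,
                               methods, free = c("k1", "k2", "p1", "p2",
                                                 "s1", "s2", "s3", "s4")) {
  est <- vector("list", length(methods))
  names(est) <- methods
  kinds <- substr(methods, 1, 1)
  stages <- ifelse(endsWith(methods, "*"), "star",
                   ifelse(endsWith(methods, "+"), "plus", "raw"))
  t_cal <- targets[calib, , drop = FALSE]
  for (i in which(stages == "raw")) {
    est[[i]] <- .final_map(kinds[i], feats[calib, , drop = FALSE], t_cal,
                           feats)
  }
  if (any(stages != "raw")) {
    grid_n <- ideal_normalized_grid(t_cal, x_range, y_range)
    nm <- fit_poly2(feats[calib, , drop = FALSE], grid_n)
    fn <- apply_poly2(nm, feats)
    for (i in which(stages == "plus")) {
      est[[i]] <- .final_map(kinds[i], fn[calib, , drop = FALSE], t_cal, fn)
    }
    if (any(stages == "star")) {
      dm <- fit_distortion(fn[calib, , drop = FALSE], grid_n, free = free)
      fu <- apply_distortion(dm, fn)
      for (i in which(stages == "star")) {
        est[[i]] <- .final_map(kinds[i], fu[calib, , drop = FALSE], t_cal, fu)
      }
    }
  }
  est
}

#' Estimate gaze for every record of a feature set
#'
#' Calibrates the chosen pipeline on the calibration subset and maps every
#' pupil feature to screen coordinates.
#'
#' @param features a `feature_set`.
#' @param method one of [gaze_methods()].
#' @param calib_indices calibration record indices (default: the 3 x 3
#'   subset of the stored target grid).
#' @param use_glints apply quad-glint normalization first (requires glint
#'   columns); the default uses raw pupil features.
#' @param free free distortion coefficients for the `*` variants.
#' @return n x 2 matrix of gaze estimates in screen units.
#' @export
estimate_gaze <- function(features, method = "Hes", calib_indices = NULL,
                          use_glints = FALSE,
                          free = c("k1", "k2", "p1", "p2",
                                   "s1", "s2", "s3", "s4")) {
  stopifnot(inherits(features, "feature_set"))
  method <- match.arg(method, gaze_methods())
  if (use_glints) features <- glint_normalize_features(features)
  if (is.null(calib_indices)) {
    gd <- attr(features, "grid_dim")
    if (is.null(gd)) stop("calib_indices must be given for non-grid sessions")
    calib_indices <- calibration_indices(gd[1], gd[2])
  }
  sc <- attr(features, "scene")
  xr <- if (!is.null(sc)) sc$screen$x_range else range(features$target_x)
  yr <- if (!is.null(sc)) sc$screen$y_range else range(features$target_y)
  ok <- stats::complete.cases(.fs_features(features))
  if (!all(ok[calib_indices])) {
    stop("calibration records contain missing features")
  }
  out <- matrix(NA_real_, nrow(features), 2)
  feats <- .fs_features(features)
  est <- .methods_estimates(feats[ok, , drop = FALSE],
                            .fs_targets(features)[ok, , drop = FALSE],
                            match(calib_indices, which(ok)),
                            xr, yr, method, free)[[1]]
  out[ok, ] <- est
  out
}

#' Evaluate gaze-estimation pipelines on one session
#'
#' Runs each requested pipeline on a feature set (calibrating on the 3 x 3
#' subset), computes per-target gaze errors in visual degrees and the
#' Gaussian high-accuracy statistics of the signed per-axis errors.
#'
#' @param features a `feature_set`.
#' @param methods subset of [gaze_methods()].
#' @param calib_indices calibration record indices.
#' @param distance_mm viewing distance for the degree conversion; defaults to
#'   the simulated eye-to-screen distance stored in the feature set.
#' @param pixel_size_mm pixel pitch when screen units are pixels.
#' @param band high-accuracy band, degrees.
#' @param use_glints apply quad-glint normalization first.
#' @return a `session_evaluation`: list with per-method `errors`
#'   ([gaze_errors()] frames), a `summary` data frame (mean/sd error,
#'   Gaussian band masses per axis) and the band.
#' @export
evaluate_session <- function(features, methods = gaze_methods(),
                             calib_indices = NULL, distance_mm = NULL,
                             pixel_size_mm = NULL, band = c(-0.5, 0.5),
                             use_glints = FALSE) {
  stopifnot(inherits(features, "feature_set"))
  methods <- match.arg(methods, gaze_methods(), several.ok = TRUE)
  if (is.null(distance_mm)) {
    sc <- attr(features, "scene")
    if (is.null(sc)) stop("distance_mm is required for imported feature sets")
    distance_mm <- abs(sc$eye$eyeball_center[3])
  }
  errors <- list()
  rows <- list()
  for (m in methods) {
    est <- estimate_gaze(features, m, calib_indices, use_glints = use_glints)
    ok <- stats::complete.cases(est)
    e <- gaze_errors(est[ok, , drop = FALSE],
                     .fs_targets(features)[ok, , drop = FALSE],
                     distance_mm, pixel_size_mm,
                     meta = list(method = m,
                                 camera = attr(features, "camera_position")))
    errors[[m]] <- e
    gx <- fit_gaussian(e$ex_deg, band)
    gy <- fit_gaussian(e$ey_deg, band)
    rows[[m]] <- data.frame(
      method = m, n = nrow(e),
      mean_error_deg = mean(e$magnitude_deg),
      sd_error_deg = stats::sd(e$magnitude_deg),
      p_high_x = gx$p_high, p_high_y = gy$p_high,
      mu_x = gx$mu, sigma_x = gx$sigma, mu_y = gy$mu, sigma_y = gy$sigma
    )
  }
  structure(list(errors = errors, summary = do.call(rbind, rows),
                 band = band),
            class = "session_evaluation")
}

#' @export
print.session_evaluation <- function(x, ...) {
  cat("Session evaluation\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Evaluate pipelines over a camera sweep
#'
#' Moves the eye-camera over a position grid, simulates a session at every
#' position and evaluates the requested pipelines, sharing the fixation solve
#' and the normalization across methods. Per-position mean angular errors are
#' always returned; with `collect = "errors"` the pooled signed per-axis
#' errors are kept as well (used for the Gaussian band analysis of
#' single-axis sweeps).
#'
#' @param scene a [scene()]; the camera position is taken from `grid`.
#' @param grid list of camera coordinate vectors `x`, `y`, `z` (mm).
#' @param targets target grid spec, as in [simulate_session()].
#' @param methods subset of [gaze_methods()].
#' @param collect `"summary"` (per-position means only), `"errors"` (keep
#'   every signed per-axis error) or `"moments"` (accumulate the sufficient
#'   statistics -- mean, variance and band counts -- of the pooled signed
#'   errors per axis, which supports the Gaussian band analysis of arbitrarily
#'   large sweeps at constant memory).
#' @param band high-accuracy band used for the `"moments"` band counts.
#' @param refraction as in [simulate_session()].
#' @param free free distortion coefficients for the `*` variants.
#' @return a `sweep_evaluation`: `summary` data frame with one row per
#'   (position, method) holding `x`, `y`, `z`, `mean_error_deg`, and
#'   optionally `errors` (signed per-axis degree errors for every target,
#'   position and method) or `moments`.
#' @export
evaluate_sweep <- function(scene,
                           grid = list(x = seq(-200, 200, 20),
                                       y = seq(50, 350, 15),
                                       z = seq(0, 400, 20)),
                           targets = list(nx = 21, ny = 21),
                           methods = gaze_methods(),
                           collect = c("summary", "errors", "moments"),
                           band = c(-0.5, 0.5),
                           refraction = TRUE,
                           free = c("k1", "k2", "p1", "p2",
                                    "s1", "s2", "s3", "s4")) {
  stopifnot(inherits(scene, "scene"))
  methods <- match.arg(methods, gaze_methods(), several.ok = TRUE)
  collect <- match.arg(collect)
  if (is.list(targets) && !is.matrix(targets)) {
    nx <- targets$nx
    ny <- targets$ny
  } else {
    stop("evaluate_sweep needs a grid target spec (list(nx =, ny =))")
  }
  calib <- calibration_indices(nx, ny)
  xr <- scene$screen$x_range
  yr <- scene$screen$y_range
  dist <- abs(scene$eye$eyeball_center[3])
  tmat <- target_grid(nx, ny, xr, yr)
  st <- .gaze_states(scene$eye, tmat)
  pos <- as.matrix(expand.grid(z = grid$z, y = grid$y, x = grid$x))[, 3:1,
                                                                   drop = FALSE]
  colnames(pos) <- c("x", "y", "z")
  npos <- nrow(pos)
  mean_err <- matrix(NA_real_, npos, length(methods),
                     dimnames = list(NULL, methods))
  err_x <- if (collect == "errors") {
    array(NA_real_, c(nrow(tmat), npos, length(methods)))
  }
  err_y <- err_x
  mom <- if (collect == "moments") {
    stats::setNames(rep(list(c(n = 0, sum_x = 0, sumsq_x = 0, in_x = 0,
                               sum_y = 0, sumsq_y = 0, in_y = 0)),
                        length(methods)), methods)
  }
  cam <- scene$camera
  failures <- 0L
  for (i in seq_len(npos)) {
    cam$position <- unname(pos[i, ])
    cam$look_at <- scene$eye$eyeball_center
    sc_i <- scene
    sc_i$camera <- cam
    res <- tryCatch({
      feats <- .observe_pupils(st, sc_i, refraction)
      .methods_estimates(feats, tmat, calib, xr, yr, methods, free)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      next
    }
    for (j in seq_along(methods)) {
      dx <- mm_to_degrees(res[[j]][, 1] - tmat[, 1], dist)
      dy <- mm_to_degrees(res[[j]][, 2] - tmat[, 2], dist)
      mean_err[i, j] <- mean(sqrt(dx^2 + dy^2))
      if (collect == "errors") {
        err_x[, i, j] <- dx
        err_y[, i, j] <- dy
      } else if (collect == "moments") {
        mom[[j]] <- mom[[j]] + c(
          length(dx), sum(dx), sum(dx^2),
          sum(dx >= band[1] & dx <= band[2]),
          sum(dy), sum(dy^2), sum(dy >= band[1] & dy <= band[2])
        )
      }
    }
  }
  if (failures > 0) {
    warning(sprintf("%d sweep position(s) failed and were skipped", failures))
  }
  summary <- data.frame(
    x = rep(pos[, 1], length(methods)),
    y = rep(pos[, 2], length(methods)),
    z = rep(pos[, 3], length(methods)),
    method = rep(methods, each = npos),
    mean_error_deg = as.vector(mean_err)
  )
  out <- list(summary = summary, positions = pos, methods = methods,
              grid = grid, band = band)
  if (collect == "errors") {
    out$errors <- list(ex_deg = err_x, ey_deg = err_y)
  } else if (collect == "moments") {
    out$moments <- mom
  }
  structure(out, class = "sweep_evaluation")
}

#' Gaussian band analysis of pooled sweep errors
#'
#' Fits the Gaussian of the signed errors of one axis pooled over all sweep
#' positions and targets and reports the high-accuracy band mass, working
#' from either the stored errors or the accumulated moments. The `z`-axis
#' error of an on-screen gaze estimate is identically zero, so its Gaussian
#' degenerates to a point mass at the origin (band mass 1 whenever the band
#' contains 0). The empirical proportion of errors inside the band is
#' attached as `p_empirical`.
#'
#' @param sweep a [evaluate_sweep()] result with `collect = "errors"` or
#'   `"moments"`.
#' @param method method name.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param band band override, degrees (must equal the accumulation band for
#'   moment-based sweeps).
#' @return a `gaussian_accuracy`.
#' @export
sweep_gaussian <- function(sweep, method, axis = c("x", "y", "z"),
                           band = NULL) {
  axis <- match.arg(axis)
  if (is.null(band)) band <- sweep$band
  if (is.null(band)) band <- c(-0.5, 0.5)
  if (axis == "z") {
    g <- structure(list(mu = 0, sigma = 0, band = band,
                        n = nrow(sweep$positions)),
                   class = "gaussian_accuracy")
    g$p_high <- high_accuracy_probability(g)
    g$p_empirical <- g$p_high
    return(g)
  }
  if (!is.null(sweep$moments)) {
    if (!isTRUE(all.equal(band, sweep$band))) {
      stop("band differs from the moment-accumulation band")
    }
    m <- sweep$moments[[method]]
    if (is.null(m)) stop("method not present in the sweep evaluation")
    mu <- m[[paste0("sum_", axis)]] / m[["n"]]
    sigma <- sqrt(max(m[[paste0("sumsq_", axis)]] / m[["n"]] - mu^2, 0))
    g <- structure(list(mu = mu, sigma = sigma, band = band,
                        n = as.integer(m[["n"]])),
                   class = "gaussian_accuracy")
    g$p_high <- high_accuracy_probability(g)
    g$p_empirical <- m[[paste0("in_", axis)]] / m[["n"]]
    return(g)
  }
  e <- sweep_errors(sweep, method, axis)
  g <- fit_gaussian(e, band)
  g$p_empirical <- mean(e >= band[1] & e <= band[2])
  g
}

#' @export
print.sweep_evaluation <- function(x, ...) {
  cat(sprintf("Sweep evaluation: %d positions x %d methods\n",
              nrow(x$positions), length(x$methods)))
  agg <- stats::aggregate(mean_error_deg ~ method, x$summary, mean)
  print(agg, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pooled signed errors of one method from a sweep evaluation
#'
#' @param sweep a [evaluate_sweep()] result with `collect = "errors"`.
#' @param method method name.
#' @param axis `"x"` or `"y"`.
#' @return numeric vector of signed degree errors pooled over all positions
#'   and targets.
#' @export
sweep_errors <- function(sweep, method, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (is.null(sweep$errors)) {
    stop("sweep was evaluated with collect = 'summary'")
  }
  j <- match(method, sweep$methods)
  if (is.na(j)) stop("method not present in the sweep evaluation")
  a <- if (axis == "x") sweep$errors$ex_deg else sweep$errors$ey_deg
  as.vector(a[, , j])
}

#' Run a full experiment from a configuration
#'
#' Orchestrates the simulated protocol end to end: build (or load) the
#' scene, run the requested pipelines either on a single session or over a
#' camera sweep, and write a report (per-method summary CSV plus a JSON file
#' of Gaussian high-accuracy statistics and the parameters used).
#'
#' @param config list (or path to a YAML/JSON file) with elements:
#'   `scene` (path or [scene()]; optional, defaults to the standard scene),
#'   `methods` (non-empty subset of [gaze_methods()]),
#'   `sweep` (optional list of `x`, `y`, `z` camera coordinate vectors; when
#'   absent a single session at the scene's camera position is run),
#'   `targets` (list `nx`, `ny`; default 21 x 21),
#'   `band` (default `c(-0.5, 0.5)`), `seed` (optional), `out` (output
#'   directory; optional), `overwrite` (default `FALSE`).
#' @return the evaluation object, invisibly; reports are written when `out`
#'   is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$methods) || length(config$methods) == 0) {
    stop("config error: 'methods' must be a non-empty list")
  }
  methods <- match.arg(config$methods, gaze_methods(), several.ok = TRUE)
  sc <- config$scene
  if (is.null(sc)) sc <- scene()
  if (is.character(sc)) sc <- read_scene(sc)
  targets <- config$targets
  if (is.null(targets)) targets <- list(nx = 21, ny = 21)
  band <- config$band
  if (is.null(band)) band <- c(-0.5, 0.5)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (!is.null(config$sweep)) {
    res <- evaluate_sweep(sc, config$sweep, targets, methods,
                          collect = "errors")
    gauss <- lapply(methods, function(m) {
      gx <- fit_gaussian(sweep_errors(res, m, "x"), band)
      gy <- fit_gaussian(sweep_errors(res, m, "y"), band)
      list(method = m, p_high_x = gx$p_high, p_high_y = gy$p_high,
           mu_x = gx$mu, sigma_x = gx$sigma, mu_y = gy$mu,
           sigma_y = gy$sigma)
    })
    summary_df <- res$summary
  } else {
    fs <- simulate_session(sc, targets)
    res <- evaluate_session(fs, methods, band = band)
    gauss <- lapply(methods, function(m) {
      s <- res$summary[res$summary$method == m, ]
      list(method = m, p_high_x = s$p_high_x, p_high_y = s$p_high_y,
           mu_x = s$mu_x, sigma_x = s$sigma_x, mu_y = s$mu_y,
           sigma_y = s$sigma_y)
    })
    summary_df <- res$summary
  }
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(config$out, "summary.csv")
    js <- file.path(config$out, "gaussian.json")
    if (!isTRUE(config$overwrite) && (file.exists(csv) || file.exists(js))) {
      stop("output files exist; set overwrite to replace them")
    }
    utils::write.csv(summary_df, csv, row.names = FALSE)
    jsonlite::write_json(
      list(band = band, methods = gauss,
           eye = unclass(sc$eye), screen = unclass(sc$screen)),
      js, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(res)
}
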