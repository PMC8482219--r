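# Gaze-error computation and accuracy statistics: visual-angle conversion,
# Gaussian fit with the +-0.5 degree high-accuracy band, KDE sample
# reduction and the two-stage outlier filter.

#' Convert a pixel offset on the screen to visual degrees
#'
#' Uses the right-angled triangle between the viewer and the screen:
#' `atan(offset_px * pixel_size_mm / distance_mm)`.
#'
#' @param offset_px offset on the screen, pixels (vectorized).
#' @param pixel_size_mm physical pixel pitch, mm (default 0.27675, a 24-inch
#'   1920 x 1080 panel).
#' @param distance_mm viewer-to-screen distance, mm (default 450).
#' @return offset in degrees.
#' @export
pixels_to_degrees <- function(offset_px, pixel_size_mm = 0.27675,
                              distance_mm = 450) {
  stopifnot(distance_mm > 0)
  .rad2deg(atan(offset_px * pixel_size_mm / distance_mm))
}

#' Convert a millimetre offset on the screen to visual degrees
#'
#' @param offset_mm offset on the screen, mm (vectorized, signed).
#' @param distance_mm viewer-to-screen distance, mm.
#' @return offset in degrees.
#' @export
mm_to_degrees <- function(offset_mm, distance_mm) {
  stopifnot(distance_mm > 0)
  .rad2deg(atan(offset_mm / distance_mm))
}

#' Per-target gaze errors
#'
#' Signed per-axis errors (estimate minus target) and their Euclidean
#' magnitude, in screen units and visual degrees. The magnitude is
#' `sqrt(ex^2 + ey^2)` of the per-axis degree errors.
#'
#' @param estimates,targets n x 2 matrices in screen units.
#' @param distance_mm viewer-to-screen distance, mm.
#' @param pixel_size_mm when the screen units are pixels, the pixel pitch in
#'   mm; `NULL` (default) means the units are already mm.
#' @param meta optional list (method name, camera position) attached as
#'   attributes.
#' @return an `error_set` data frame: `ex`, `ey` (screen units), `ex_deg`,
#'   `ey_deg`, `magnitude_deg`.
#' @export
gaze_errors <- function(estimates, targets, distance_mm,
                        pixel_size_mm = NULL, meta = list()) {
  estimates <- matrix(as.numeric(estimates), ncol = 2)
  targets <- matrix(as.numeric(targets), ncol = 2)
  if (nrow(estimates) != nrow(targets)) {
    stop("estimates and targets must have the same length")
  }
  ex <- estimates[, 1] - targets[, 1]
  ey <- estimates[, 2] - targets[, 2]
  if (is.null(pixel_size_mm)) {
    exd <- mm_to_degrees(ex, distance_mm)
    eyd <- mm_to_degrees(ey, distance_mm)
  } else {
    exd <- pixels_to_degrees(ex, pixel_size_mm, distance_mm)
    eyd <- pixels_to_degrees(ey, pixel_size_mm, distance_mm)
  }
  out <- data.frame(ex = ex, ey = ey, ex_deg = exd, ey_deg = eyd,
                    magnitude_deg = sqrt(exd^2 + eyd^2))
  structure(out, class = c("error_set", "data.frame"), meta = meta)
}

#' Gaussian fit with high-accuracy band mass
#'
#' Maximum-likelihood Gaussian fit of a signed gaze-error sample (mean and
#' ML standard deviation), plus the probability mass of the fitted density
#' inside the high-accuracy band (default -0.5 to +0.5 degrees). With
#' `mixture = TRUE` a two-component Gaussian mixture is fitted instead (for
#' multi-peak error distributions) and the band mass is the weighted sum of
#' the component masses; this mode requires the mclust package.
#'
#' @param errors numeric vector of signed errors, degrees; n >= 2.
#' @param band 2-vector `(lo, hi)`, degrees.
#' @param mixture fit a two-component mixture instead of a single Gaussian.
#' @return a `gaussian_accuracy`: `mu`, `sigma`, `p_high`, `band`, `n` (and
#'   component parameters in mixture mode).
#' @export
fit_gaussian <- function(errors, band = c(-0.5, 0.5), mixture = FALSE) {
  errors <- errors[is.finite(errors)]
  if (length(errors) < 2) stop("fit_gaussian needs at least 2 observations")
  if (mixture) {
    if (!requireNamespace("mclust", quietly = TRUE)) {
      stop("mixture mode requires the mclust package")
    }
    # Mclust resolves mclustBIC in the caller's frame; bind it locally so
    # the suggested package need not be attached
    mclustBIC <- mclust::mclustBIC
    fit <- mclust::Mclust(errors, G = 2, modelNames = "V", verbose = FALSE)
    w <- fit$parameters$pro
    mu <- fit$parameters$mean
    sg <- sqrt(fit$parameters$variance$sigmasq)
    p <- sum(w * (stats::pnorm(band[2], mu, sg) -
                    stats::pnorm(band[1], mu, sg)))
    return(structure(
      list(mu = sum(w * mu), sigma = stats::sd(errors), p_high = p,
           band = band, n = length(errors),
           components = list(weight = w, mu = mu, sigma = sg)),
      class = "gaussian_accuracy"
    ))
  }
  mu <- mean(errors)
  sigma <- sqrt(mean((errors - mu)^2))
  g <- structure(list(mu = mu, sigma = sigma, band = band,
                      n = length(errors)),
                 class = "gaussian_accuracy")
  g$p_high <- high_accuracy_probability(g)
  g
}

#' Probability mass of a Gaussian fit inside the high-accuracy band
#'
#' `Phi((hi - mu)/sigma) - Phi((lo - mu)/sigma)`; the underlying density
#' integrates to one over the real line. A zero-sigma fit is treated as a
#' point mass at `mu`.
#'
#' @param g a [fit_gaussian()] result (or a list with `mu`, `sigma`, `band`).
#' @param band optional band override, degrees.
#' @return probability in `[0, 1]`.
#' @export
high_accuracy_probability <- function(g, band = NULL) {
  if (is.null(band)) band <- g$band
  if (is.null(band)) band <- c(-0.5, 0.5)
  stopifnot(g$sigma >= 0)
  if (g$sigma == 0) {
    return(as.numeric(g$mu >= band[1] && g$mu <= band[2]))
  }
  stats::pnorm(band[2], g$mu, g$sigma) - stats::pnorm(band[1], g$mu, g$sigma)
}

#' @export
print.gaussian_accuracy <- function(x, ...) {
  cat(sprintf(
    "Gaussian accuracy: mu = %.4f, sigma = %.4f deg (n = %d)\n",
    x$mu, x$sigma, x$n))
  cat(sprintf("  P(error in [%g, %g] deg) = %.4f\n",
              x$band[1], x$band[2], x$p_high))
  invisible(x)
}

#' Most representative point of a fixation sample (KDE mode)
#'
#' Evaluates a product-Gaussian kernel density estimate (Silverman
#' bandwidths per axis) at every sample point and returns the sample point of
#' maximal density: the single eye feature that stands for a fixation cloud
#' (e.g. 150 raw samples per target reduced to 1).
#'
#' @param xy n x 2 matrix, n >= 5.
#' @return 2-vector: the densest sample point.
#' @export
kde_representative <- function(xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  xy <- xy[stats::complete.cases(xy), , drop = FALSE]
  if (nrow(xy) < 5) stop("kde_representative needs at least 5 points")
  bx <- stats::bw.nrd0(xy[, 1])
  by <- stats::bw.nrd0(xy[, 2])
  if (bx <= 0 || by <= 0) return(colMeans(xy))
  dx <- outer(xy[, 1], xy[, 1], "-") / bx
  dy <- outer(xy[, 2], xy[, 2], "-") / by
  dens <- rowSums(exp(-0.5 * (dx^2 + dy^2)))
  xy[which.max(dens), ]
}

#' Two-stage outlier filter for gaze-error trials
#'
#' Stage 1 drops whole trials whose mean gaze-error magnitude exceeds
#' `trial_limit_deg` (default 5 degrees); stage 2 drops individual
#' estimations farther than `k_sigma` standard deviations from the mean of
#' the remaining magnitudes (default 3, the 99.7th percentile of a normal
#' sample).
#'
#' @param errors data frame with a `magnitude_deg` column.
#' @param trial optional factor/vector of trial identifiers (one value per
#'   row); by default all rows form one trial.
#' @param trial_limit_deg stage-1 threshold, degrees.
#' @param k_sigma stage-2 threshold, standard deviations.
#' @return list with the filtered `data` and a `report` of counts removed at
#'   each stage.
#' @export
filter_outliers <- function(errors, trial = NULL, trial_limit_deg = 5,
                            k_sigma = 3) {
  stopifnot("magnitude_deg" %in% names(errors))
  n0 <- nrow(errors)
  if (is.null(trial)) trial <- rep(1L, n0)
  trial_mean <- tapply(errors$magnitude_deg, trial, mean)
  bad_trials <- names(trial_mean)[trial_mean > trial_limit_deg]
  keep1 <- !(as.character(trial) %in% bad_trials)
  e1 <- errors[keep1, , drop = FALSE]
  m <- mean(e1$magnitude_deg)
  s <- stats::sd(e1$magnitude_deg)
  keep2 <- if (is.na(s) || s == 0) {
    rep(TRUE, nrow(e1))
  } else {
    abs(e1$magnitude_deg - m) <= k_sigma * s
  }
  out <- e1[keep2, , drop = FALSE]
  if (nrow(out) == 0) warning("outlier filtering removed every estimation")
  list(
    data = out,
    report = list(
      n_input = n0,
      trials_removed = length(bad_trials),
      rows_removed_stage1 = n0 - nrow(e1),
      rows_removed_stage2 = sum(!keep2),
      n_output = nrow(out)
    )
  )
}

#' Reduce raw fixation samples to one representative record per target
#'
#' Real sessions record many raw samples per viewed target (150 per target in
#' the standard protocol); this reduces each target's cloud to the single
#' most representative record via [kde_representative()] on the pupil
#' coordinates. Glints and other columns are taken from the selected record.
#' When some records are invalid (missing glints), the representative is
#' chosen among the valid ones if any exist.
#'
#' @param features a `feature_set` (or annotated records converted with
#'   [as_feature_set()]) with a `target_id` column.
#' @param require_glints prefer records with a complete glint quad when
#'   glint columns are present.
#' @return a `feature_set` with one record per target, in increasing
#'   `target_id` order.
#' @export
reduce_fixations <- function(features, require_glints = TRUE) {
  stopifnot(inherits(features, "feature_set"),
            "target_id" %in% names(features))
  gcols <- grep("^glint", names(features), value = TRUE)
  ids <- sort(unique(features$target_id))
  rows <- integer(length(ids))
  for (k in seq_along(ids)) {
    idx <- which(features$target_id == ids[k] &
                   is.finite(features$pupil_x) &
                   is.finite(features$pupil_y))
    if (require_glints && length(gcols)) {
      ok <- idx[stats::complete.cases(features[idx, gcols])]
      if (length(ok) >= 5) idx <- ok
    }
    if (length(idx) == 0) stop("target ", ids[k], " has no valid samples")
    if (length(idx) < 5) {
      rows[k] <- idx[1]
    } else {
      rep_pt <- kde_representative(cbind(features$pupil_x[idx],
                                         features$pupil_y[idx]))
      d2 <- (features$pupil_x[idx] - rep_pt[1])^2 +
        (features$pupil_y[idx] - rep_pt[2])^2
      rows[k] <- idx[which.min(d2)]
    }
  }
  out <- features[rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}
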