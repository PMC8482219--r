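# Eye-camera location compensation: polynomial normalization of the eye
# feature distribution into the unit square [-1, 1]^2, plus quad-glint
# normalization for head-movement robustness on real data.

#' Ideal normalized coordinates of calibration targets
#'
#' Linearly rescales screen-coordinate targets to the normalized unit square
#' `[-1, 1]^2` (the corners of the target range map to the square's corners),
#' so the normalized plane stays affine to the viewed plane for the targets.
#'
#' @param targets n x 2 matrix, mm.
#' @param x_range,y_range the screen's target ranges, mm.
#' @return n x 2 matrix in `[-1, 1]^2`.
#' @export
ideal_normalized_grid <- function(targets, x_range = c(-200, 200),
                                  y_range = c(50, 350)) {
  targets <- matrix(as.numeric(targets), ncol = 2)
  cbind(2 * (targets[, 1] - mean(x_range)) / diff(x_range),
        2 * (targets[, 2] - mean(y_range)) / diff(y_range))
}

#' Fit the eye-camera location compensation (normalization) mapping
#'
#' Fits the second-order polynomial that carries the calibration eye features
#' onto the ideal normalized 3 x 3 grid in `[-1, 1]^2`. Reusing the
#' gaze-mapping calibration data this way virtually re-aligns the eye-camera
#' with the eye's optical axis: after normalization the feature distribution
#' no longer depends on where the physical camera sat.
#'
#' @param features a `feature_set` (raw eye-plane or glint-normalized).
#' @param calib_indices indices of the calibration records (>= 9). `NULL`
#'   selects the 3 x 3 subset of the stored target grid when available.
#' @param x_range,y_range target ranges; defaults come from the feature set's
#'   scene when present.
#' @return a `normalization_map`: the fitted `poly2_map`, the ideal
#'   normalized grid and the calibration indices.
#' @export
fit_normalization <- function(features, calib_indices = NULL,
                              x_range = NULL, y_range = NULL) {
  stopifnot(inherits(features, "feature_set"))
  sc <- attr(features, "scene")
  if (is.null(x_range)) {
    x_range <- if (!is.null(sc)) sc$screen$x_range else range(features$target_x)
  }
  if (is.null(y_range)) {
    y_range <- if (!is.null(sc)) sc$screen$y_range else range(features$target_y)
  }
  if (is.null(calib_indices)) {
    gd <- attr(features, "grid_dim")
    if (is.null(gd)) stop("calib_indices must be given for non-grid sessions")
    calib_indices <- calibration_indices(gd[1], gd[2])
  }
  if (length(calib_indices) < 9) {
    stop("the normalization fit needs at least 9 calibration records")
  }
  tgt <- .fs_targets(features)[calib_indices, , drop = FALSE]
  grid_n <- ideal_normalized_grid(tgt, x_range, y_range)
  poly <- fit_poly2(.fs_features(features)[calib_indices, , drop = FALSE],
                    grid_n)
  structure(
    list(poly = poly, calib_grid_n = grid_n, calib_indices = calib_indices,
         x_range = x_range, y_range = y_range),
    class = "normalization_map"
  )
}

#' @export
print.normalization_map <- function(x, ...) {
  cat("Eye-camera location compensation (eye plane -> [-1,1]^2)\n")
  print(x$poly)
  invisible(x)
}

#' Map a feature set into the normalized plane
#'
#' Applies the fitted normalization polynomial to every pupil feature; viewed
#' targets pass through unchanged.
#'
#' @param map a [fit_normalization()] result.
#' @param features a `feature_set`.
#' @return the feature set with pupil coordinates in the normalized plane.
#' @export
normalize_features <- function(map, features) {
  stopifnot(inherits(map, "normalization_map"),
            inherits(features, "feature_set"))
  pn <- apply_poly2(map$poly, .fs_features(features))
  out <- features
  out$pupil_x <- pn[, 1]
  out$pupil_y <- pn[, 2]
  attr(out, "space") <- "normalized"
  out
}

#' Quad-glint normalization of a pupil center
#'
#' Maps the pupil center by the homography that carries the quadrilateral of
#' the four corneal reflections onto the unit square `[0, 1]^2` (glint 1 to
#' (0,0), glint 2 to (1,0), glint 3 to (1,1), glint 4 to (0,1); the
#' enumerated input order is kept, never re-sorted). The result is exactly
#' invariant to any projective transform applied jointly to the pupil and the
#' glints, which removes the head-movement component of the raw feature.
#'
#' @param pupil 2-vector, image coordinates.
#' @param glints 4 x 2 matrix of glint image coordinates in enumerated corner
#'   order.
#' @return 2-vector in the glint space `[0, 1]^2`, or `c(NA, NA)` when a
#'   glint is missing or the quadrilateral is degenerate.
#' @export
glint_normalize <- function(pupil, glints) {
  glints <- matrix(as.numeric(glints), ncol = 2)
  if (nrow(glints) != 4) stop("glint_normalize needs exactly 4 glints")
  if (anyNA(glints) || anyNA(pupil)) return(c(NA_real_, NA_real_))
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  H <- tryCatch(fit_homography(glints, square), error = function(e) NULL)
  if (is.null(H)) return(c(NA_real_, NA_real_))
  apply_homography(H, as.numeric(pupil))
}

#' Apply quad-glint normalization to a whole feature set
#'
#' @param features a `feature_set` with `glint1_x` .. `glint4_y` columns.
#' @return the feature set with pupil coordinates in the glint space; records
#'   with missing or degenerate glints become `NA` and are flagged in the
#'   `valid` column.
#' @export
glint_normalize_features <- function(features) {
  stopifnot(inherits(features, "feature_set"))
  gc <- as.vector(t(outer(paste0("glint", 1:4), c("_x", "_y"), paste0)))
  if (!all(gc %in% names(features))) {
    stop("feature set has no glint columns")
  }
  out <- features
  for (i in seq_len(nrow(features))) {
    g <- matrix(as.numeric(features[i, gc]), 4, 2, byrow = TRUE)
    p <- glint_normalize(c(features$pupil_x[i], features$pupil_y[i]), g)
    out$pupil_x[i] <- p[1]
    out$pupil_y[i] <- p[2]
  }
  out$valid <- !is.na(out$pupil_x)
  attr(out, "space") <- "glint"
  out
}
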