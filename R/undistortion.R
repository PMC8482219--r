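# Eye-feature distribution undistortion: the non-coplanarity of the eye plane
# is modelled as radial + tangential + thin-prism distortion of the
# normalized feature, exactly as in the calibrated-camera lens model, and the
# coefficients are fitted from the calibration correspondences by nonlinear
# least squares.

.DIST_COEF <- c(paste0("k", 1:6), "p1", "p2", paste0("s", 1:4))

#' Lens-distortion model for the normalized eye feature
#'
#' @param k six radial coefficients `k1..k6` (rational model: `k1..k3` in the
#'   numerator, `k4..k6` in the denominator).
#' @param p two tangential coefficients `p1`, `p2`.
#' @param s four thin-prism coefficients `s1..s4`.
#' @return a `distortion_model`; the all-zero model is the identity
#'   correction.
#' @export
distortion_model <- function(k = numeric(6), p = numeric(2), s = numeric(4)) {
  k <- c(k, numeric(6))[1:6]
  p <- c(p, numeric(2))[1:2]
  s <- c(s, numeric(4))[1:4]
  stopifnot(is.finite(k), is.finite(p), is.finite(s))
  structure(list(k = unname(k), p = unname(p), s = unname(s)),
            class = "distortion_model")
}

#' @export
print.distortion_model <- function(x, ...) {
  cf <- coef(x)
  cat("Radial/tangential/thin-prism distortion model\n")
  print(signif(cf[cf != 0 | names(cf) %in% c("k1", "p1")], 5))
  if (!is.null(x$residual_rms)) {
    cat(sprintf("  fit residual (RMS): %.3g%s\n", x$residual_rms,
                if (isFALSE(x$converged)) "  [not converged]" else ""))
  }
  invisible(x)
}

#' @export
coef.distortion_model <- function(object, ...) {
  stats::setNames(c(object$k, object$p, object$s), .DIST_COEF)
}

#' Apply the distortion correction to normalized features
#'
#' Computes, with `r^2 = x^2 + y^2`,
#' \deqn{\rho = \frac{1 + k_1 r^2 + k_2 r^4 + k_3 r^6}
#'                   {1 + k_4 r^2 + k_5 r^4 + k_6 r^6},}
#' the tangential terms
#' \eqn{\tau_x = 2 p_1 x y + p_2 (r^2 + 2x^2)},
#' \eqn{\tau_y = p_1 (r^2 + 2y^2) + 2 p_2 x y},
#' the thin-prism terms \eqn{\phi_x = s_1 r^2 + s_2 r^4},
#' \eqn{\phi_y = s_3 r^2 + s_4 r^4}, and returns
#' \eqn{(x \rho + \tau_x + \phi_x,\; y \rho + \tau_y + \phi_y)}.
#' The radial factor multiplies the feature componentwise; the tangential and
#' prism terms are additive offsets.
#'
#' @param m a [distortion_model()].
#' @param p point (2-vector) or n x 2 matrix in the normalized plane.
#' @return corrected point(s), same shape as `p`.
#' @export
apply_distortion <- function(m, p) {
  single <- is.null(dim(p))
  p <- matrix(as.numeric(p), ncol = 2)
  x <- p[, 1]
  y <- p[, 2]
  r2 <- x^2 + y^2
  r4 <- r2^2
  r6 <- r2^3
  num <- 1 + m$k[1] * r2 + m$k[2] * r4 + m$k[3] * r6
  den <- 1 + m$k[4] * r2 + m$k[5] * r4 + m$k[6] * r6
  if (any(abs(den) < 1e-12)) {
    stop("rational radial factor has a vanishing denominator")
  }
  rho <- num / den
  tx <- 2 * m$p[1] * x * y + m$p[2] * (r2 + 2 * x^2)
  ty <- m$p[1] * (r2 + 2 * y^2) + 2 * m$p[2] * x * y
  px <- m$s[1] * r2 + m$s[2] * r4
  py <- m$s[3] * r2 + m$s[4] * r4
  out <- cbind(x * rho + tx + px, y * rho + ty + py)
  if (single) drop(out) else out
}

# Residuals and analytic Jacobian of the correction wrt the coefficient
# vector (order .DIST_COEF), at observed points obs against ideal targets.
.dist_residual <- function(theta, obs, ideal, free) {
  cf <- stats::setNames(numeric(12), .DIST_COEF)
  cf[free] <- theta
  m <- distortion_model(cf[1:6], cf[7:8], cf[9:12])
  as.vector(apply_distortion(m, obs) - ideal)
}

.dist_jacobian <- function(theta, obs, ideal, free) {
  cf <- stats::setNames(numeric(12), .DIST_COEF)
  cf[free] <- theta
  x <- obs[, 1]
  y <- obs[, 2]
  r2 <- x^2 + y^2
  r4 <- r2^2
  r6 <- r2^3
  num <- 1 + cf["k1"] * r2 + cf["k2"] * r4 + cf["k3"] * r6
  den <- 1 + cf["k4"] * r2 + cf["k5"] * r4 + cf["k6"] * r6
  z <- numeric(length(x))
  Jx <- cbind(
    k1 = x * r2 / den, k2 = x * r4 / den, k3 = x * r6 / den,
    k4 = -x * num * r2 / den^2, k5 = -x * num * r4 / den^2,
    k6 = -x * num * r6 / den^2,
    p1 = 2 * x * y, p2 = r2 + 2 * x^2,
    s1 = r2, s2 = r4, s3 = z, s4 = z
  )
  Jy <- cbind(
    k1 = y * r2 / den, k2 = y * r4 / den, k3 = y * r6 / den,
    k4 = -y * num * r2 / den^2, k5 = -y * num * r4 / den^2,
    k6 = -y * num * r6 / den^2,
    p1 = r2 + 2 * y^2, p2 = 2 * x * y,
    s1 = z, s2 = z, s3 = r2, s4 = r4
  )
  rbind(Jx[, free, drop = FALSE], Jy[, free, drop = FALSE])
}

#' Fit the distortion coefficients from calibration data
#'
#' Finds the coefficient set minimizing the summed squared distance between
#' the corrected normalized features and their ideal unit-square positions,
#' by damped (Levenberg--Marquardt) least squares with zero initialization
#' and an analytic Jacobian. The default free set `{k1, k2, p1, p2, s1..s4}`
#' keeps the problem well conditioned on a 3 x 3 calibration grid (8
#' parameters against 18 equations); the rational radial tail `k3..k6` can be
#' unlocked for denser calibrations.
#'
#' @param observed n x 2 matrix of normalized features (n >= 9).
#' @param ideal n x 2 matrix of ideal normalized positions in `[-1, 1]^2`.
#' @param free character vector of coefficient names to fit.
#' @param max_iter iteration cap (default 500).
#' @return a [distortion_model()] with fit metadata: `residual_rms`,
#'   `converged` and the optimizer message. Non-convergence returns the best
#'   iterate with a warning.
#' @export
fit_distortion <- function(observed, ideal,
                           free = c("k1", "k2", "p1", "p2",
                                    "s1", "s2", "s3", "s4"),
                           max_iter = 500) {
  observed <- matrix(as.numeric(observed), ncol = 2)
  ideal <- matrix(as.numeric(ideal), ncol = 2)
  stopifnot(nrow(observed) == nrow(ideal))
  if (nrow(observed) < 9) {
    stop("fit_distortion needs at least 9 correspondences")
  }
  free <- match.arg(free, .DIST_COEF, several.ok = TRUE)
  fit <- minpack.lm::nls.lm(
    par = stats::setNames(numeric(length(free)), free),
    fn = .dist_residual, jac = .dist_jacobian,
    obs = observed, ideal = ideal, free = free,
    control = minpack.lm::nls.lm.control(
      maxiter = min(max_iter, 1024), ftol = 1e-15, ptol = 1e-15, gtol = 1e-10
    )
  )
  converged <- fit$info %in% 1:4
  if (!converged) {
    warning("distortion fit did not converge: ", fit$message)
  }
  cf <- stats::setNames(numeric(12), .DIST_COEF)
  cf[free] <- fit$par
  m <- distortion_model(cf[1:6], cf[7:8], cf[9:12])
  m$residual_rms <- sqrt(mean(fit$fvec^2))
  m$converged <- converged
  m$message <- fit$message
  m$free <- free
  m
}

#' Undistort a normalized feature set
#'
#' @param m a [distortion_model()].
#' @param features a `feature_set` in the normalized plane.
#' @return the feature set with corrected pupil coordinates.
#' @export
undistort_features <- function(m, features) {
  stopifnot(inherits(m, "distortion_model"),
            inherits(features, "feature_set"))
  pc <- apply_distortion(m, .fs_features(features))
  out <- features
  out$pupil_x <- pc[, 1]
  out$pupil_y <- pc[, 2]
  out
}
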