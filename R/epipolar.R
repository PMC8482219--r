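# Epipolar diagnostics between the eye plane and the viewed plane. Treating
# the two planes as a stereo pair, the fundamental matrix's epipole in the
# viewed plane localizes the (virtual) eye-camera relative to the screen;
# after compensation it should sit near the screen center.

#' Estimate the fundamental matrix (normalized 8-point algorithm)
#'
#' Fits `F` such that `dst_h' * F * src_h = 0` for homogeneous corresponding
#' points, with Hartley normalization of both sets and rank-2 enforcement by
#' truncated SVD. With `src` the eye features and `dst` the viewed targets,
#' `epipolar_line(F, p_e)` is the epipolar line of an eye feature in the
#' viewed plane and [epipole_of()] returns the viewed-plane epipole.
#'
#' Grids of corresponded gaze data are close to homographic (coplanar), which
#' makes `F` ill-determined in the exact planar limit; the deviation from
#' coplanarity is precisely what localizes the epipole. The ratio of the
#' 8th to the 9th singular value of the design matrix is reported as a
#' condition diagnostic (`degeneracy`); small values flag an unreliable
#' epipole rather than failing.
#'
#' @param src,dst n x 2 matrices of corresponding points, n >= 8.
#' @return a `fundamental_matrix`: unit-norm rank-2 `F`, the RMS epipolar
#'   (point-to-line) distance of the inputs, the `degeneracy` ratio and a
#'   `reliable` flag.
#' @export
estimate_fundamental <- function(src, dst) {
  src <- matrix(as.numeric(src), ncol = 2)
  dst <- matrix(as.numeric(dst), ncol = 2)
  stopifnot(nrow(src) == nrow(dst))
  if (nrow(src) < 8) stop("estimate_fundamental needs at least 8 points")
  Ts <- .hartley_transform(src)
  Td <- .hartley_transform(dst)
  ps <- .to_homog(src) %*% t(Ts)
  pd <- .to_homog(dst) %*% t(Td)
  A <- cbind(pd[, 1] * ps[, 1], pd[, 1] * ps[, 2], pd[, 1],
             pd[, 2] * ps[, 1], pd[, 2] * ps[, 2], pd[, 2],
             ps[, 1], ps[, 2], 1)
  sv <- svd(A, nu = 0, nv = 9)
  degeneracy <- sv$d[8] / max(sv$d[9], .Machine$double.eps * sv$d[1])
  Fh <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  fs <- svd(Fh)
  Fh <- fs$u %*% diag(c(fs$d[1:2], 0)) %*% t(fs$v)
  Fm <- t(Td) %*% Fh %*% Ts
  Fm <- Fm / norm(Fm, "F")
  i <- which.max(abs(Fm))
  if (Fm[i] < 0) Fm <- -Fm
  ln <- .to_homog(src) %*% t(Fm)
  d <- abs(rowSums(.to_homog(dst) * ln)) / sqrt(ln[, 1]^2 + ln[, 2]^2)
  structure(
    list(F = Fm, residual_rms = sqrt(mean(d^2)), degeneracy = degeneracy,
         reliable = degeneracy > 2),
    class = "fundamental_matrix"
  )
}

#' @export
print.fundamental_matrix <- function(x, ...) {
  cat("Fundamental matrix (unit norm, rank 2)\n")
  print(signif(x$F, 5))
  cat(sprintf("  epipolar residual (RMS): %.3g; degeneracy ratio s8/s9: %.3g%s\n",
              x$residual_rms, x$degeneracy,
              if (!x$reliable) "  [near-homographic: epipole unreliable]" else ""))
  invisible(x)
}

#' Epipole of a fundamental matrix
#'
#' The epipole in the destination (viewed) plane is the left null vector of
#' `F` (`F' e = 0`); with `which = "src"` the right null vector gives the
#' source-plane epipole. An epipole at infinity is reported as a unit
#' direction with `at_infinity = TRUE`.
#'
#' @param Fm a `fundamental_matrix` (or a plain 3 x 3 matrix).
#' @param which `"dst"` (default) or `"src"`.
#' @return 2-vector with attribute `at_infinity`.
#' @export
epipole_of <- function(Fm, which = c("dst", "src")) {
  which <- match.arg(which)
  M <- if (is.matrix(Fm)) Fm else Fm$F
  sv <- svd(M)
  e <- if (which == "dst") sv$u[, 3] else sv$v[, 3]
  if (abs(e[3]) < 1e-9 * sqrt(sum(e^2))) {
    out <- e[1:2] / sqrt(sum(e[1:2]^2))
    attr(out, "at_infinity") <- TRUE
  } else {
    out <- e[1:2] / e[3]
    attr(out, "at_infinity") <- FALSE
  }
  out
}

#' Epipolar line of a source-plane point
#'
#' `l = F * (x, y, 1)'`, normalized so that `a^2 + b^2 = 1`; the line
#' `a x + b y + c = 0` lives in the destination plane and passes through the
#' destination epipole.
#'
#' @param Fm a `fundamental_matrix` (or a plain 3 x 3 matrix).
#' @param p source-plane point (2-vector) or n x 2 matrix.
#' @return named vector `(a, b, c)` or an n x 3 matrix.
#' @export
epipolar_line <- function(Fm, p) {
  M <- if (is.matrix(Fm)) Fm else Fm$F
  single <- is.null(dim(p))
  l <- .to_homog(matrix(as.numeric(p), ncol = 2)) %*% t(M)
  l <- l / sqrt(l[, 1]^2 + l[, 2]^2)
  colnames(l) <- c("a", "b", "c")
  if (single) drop(l) else l
}

#' Virtual-camera angle diagnostic
#'
#' Angle, seen from the eyeball center, between the screen center and the
#' epipole of the (features vs. targets) correspondence: the alpha angle of
#' the virtual eye-camera. After location compensation it should be small
#' (under about 5 degrees).
#'
#' @param features a `feature_set` (raw or normalized).
#' @param eye an [eye_model()]; defaults to the feature set's scene.
#' @param screen_center 2-vector, mm.
#' @return list with the `epipole` (screen mm), `alpha_deg` and the
#'   underlying `fundamental_matrix`.
#' @export
epipole_diagnostics <- function(features, eye = NULL,
                                screen_center = NULL) {
  stopifnot(inherits(features, "feature_set"))
  sc <- attr(features, "scene")
  if (is.null(eye)) {
    if (is.null(sc)) stop("supply an eye model for imported feature sets")
    eye <- sc$eye
  }
  if (is.null(screen_center)) {
    screen_center <- if (!is.null(sc)) {
      c(mean(sc$screen$x_range), mean(sc$screen$y_range))
    } else {
      c(mean(range(features$target_x)), mean(range(features$target_y)))
    }
  }
  Fm <- estimate_fundamental(.fs_features(features), .fs_targets(features))
  e <- epipole_of(Fm, "dst")
  if (isTRUE(attr(e, "at_infinity"))) {
    return(list(epipole = e, alpha_deg = Inf, fundamental = Fm))
  }
  oe <- eye$eyeball_center
  v1 <- c(e[1], e[2], 0) - oe
  v2 <- c(screen_center, 0) - oe
  alpha <- acos(pmin(pmax(sum(v1 * v2) /
                            sqrt(sum(v1^2) * sum(v2^2)), -1), 1))
  list(epipole = e, alpha_deg = .rad2deg(alpha), fundamental = Fm)
}
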