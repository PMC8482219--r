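# Interpolation-based gaze mappings: second-order polynomial and homography.

.poly2_design <- function(p) {
  p <- matrix(as.numeric(p), ncol = 2)
  cbind(p[, 1]^2, p[, 2]^2, p[, 1] * p[, 2], p[, 1], p[, 2], 1)
}

#' Fit a second-order polynomial mapping
#'
#' Least-squares fit of the two-axis second-order polynomial
#' \deqn{x' = a_0 x^2 + a_1 y^2 + a_2 x y + a_3 x + a_4 y + a_5}
#' \deqn{y' = b_0 x^2 + b_1 y^2 + b_2 x y + b_3 x + b_4 y + b_5}
#' solved per axis by QR decomposition (no regularization; the calibration
#' grids used here keep the 6-column design well conditioned).
#'
#' @param src,dst n x 2 matrices of corresponding points, n >= 6 (nine
#'   calibration points in the standard protocol).
#' @return a `poly2_map` with coefficient vectors `a` and `b` and the RMS
#'   fitting residual.
#' @export
fit_poly2 <- function(src, dst) {
  src <- matrix(as.numeric(src), ncol = 2)
  dst <- matrix(as.numeric(dst), ncol = 2)
  stopifnot(nrow(src) == nrow(dst))
  if (nrow(src) < 6) stop("fit_poly2 needs at least 6 correspondences")
  A <- .poly2_design(src)
  qrA <- qr(A)
  if (qrA$rank < 6) {
    stop("singular polynomial fit: calibration points are degenerate")
  }
  cf <- qr.coef(qrA, dst)
  res <- A %*% cf - dst
  structure(
    list(a = unname(cf[, 1]), b = unname(cf[, 2]),
         residual_rms = sqrt(mean(res^2))),
    class = "poly2_map"
  )
}

#' Apply a second-order polynomial mapping
#'
#' @param m a `poly2_map` from [fit_poly2()] (or a list with `a`, `b`).
#' @param p point (2-vector) or n x 2 matrix.
#' @return mapped point(s), same shape as `p`.
#' @export
apply_poly2 <- function(m, p) {
  single <- is.null(dim(p))
  A <- .poly2_design(p)
  out <- cbind(A %*% m$a, A %*% m$b)
  if (single) drop(out) else out
}

#' @export
print.poly2_map <- function(x, ...) {
  cat("Second-order polynomial mapping\n")
  cat("  a:", paste(signif(x$a, 5), collapse = " "), "\n")
  cat("  b:", paste(signif(x$b, 5), collapse = " "), "\n")
  cat(sprintf("  fit residual (RMS): %.3g\n", x$residual_rms))
  invisible(x)
}

# Hartley isotropic normalization: translate the centroid to the origin and
# scale the mean distance to sqrt(2). Returns the 3 x 3 similarity.
.hartley_transform <- function(p) {
  ctr <- colMeans(p)
  d <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
}

.to_homog <- function(p) cbind(p, 1)

#' Fit a homography by the normalized direct linear transform
#'
#' Both point sets are Hartley-normalized (centroid at the origin, mean
#' distance sqrt(2)); the DLT system is solved by SVD, minimizing the
#' algebraic error. The returned matrix is scaled to unit Frobenius norm with
#' a fixed sign convention; `as.matrix()` on the result gives the matrix
#' rescaled so the bottom-right entry is 1 when it is not near zero.
#'
#' @param src,dst n x 2 matrices of corresponding points, n >= 4.
#' @return a `homography_map` with the 3 x 3 matrix `H` and the maximal
#'   reprojection residual on the input points.
#' @export
fit_homography <- function(src, dst) {
  src <- matrix(as.numeric(src), ncol = 2)
  dst <- matrix(as.numeric(dst), ncol = 2)
  stopifnot(nrow(src) == nrow(dst))
  n <- nrow(src)
  if (n < 4) stop("fit_homography needs at least 4 correspondences")
  Ts <- .hartley_transform(src)
  Td <- .hartley_transform(dst)
  ps <- .to_homog(src) %*% t(Ts)
  pd <- .to_homog(dst) %*% t(Td)
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), 4:6] <- -pd[, 3] * ps
  A[seq(1, 2 * n, 2), 7:9] <- pd[, 2] * ps
  A[seq(2, 2 * n, 2), 1:3] <- pd[, 3] * ps
  A[seq(2, 2 * n, 2), 7:9] <- -pd[, 1] * ps
  sv <- svd(A, nu = 0, nv = 9)
  if (n > 4 && sv$d[8] < 1e-10 * sv$d[1]) {
    stop("singular homography fit: degenerate point configuration")
  }
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(Td) %*% Hn %*% Ts
  if (abs(det(H)) < 1e-12 * norm(H, "F")^3) {
    stop("singular homography fit: degenerate point configuration")
  }
  H <- H / norm(H, "F")
  if (H[3, 3] < 0 || (H[3, 3] == 0 && H[1, 1] < 0)) H <- -H
  est <- apply_homography(list(H = H), src)
  structure(
    list(H = H, residual_max = max(sqrt(rowSums((est - dst)^2)))),
    class = "homography_map"
  )
}

#' Apply a homography
#'
#' @param H a `homography_map` (or a list with element `H`).
#' @param p point (2-vector) or n x 2 matrix.
#' @return mapped point(s) after perspective division.
#' @export
apply_homography <- function(H, p) {
  M <- if (is.matrix(H)) H else H$H
  single <- is.null(dim(p))
  ph <- .to_homog(matrix(as.numeric(p), ncol = 2)) %*% t(M)
  if (any(abs(ph[, 3]) < 1e-14 * norm(M, "F") *
            sqrt(rowSums(matrix(as.numeric(p), ncol = 2)^2) + 1))) {
    stop("homography maps a point to infinity (w = 0)")
  }
  out <- ph[, 1:2, drop = FALSE] / ph[, 3]
  if (single) drop(out) else out
}

#' @export
as.matrix.homography_map <- function(x, ...) {
  H <- x$H
  if (abs(H[3, 3]) > 1e-8) H / H[3, 3] else H
}

#' @export
print.homography_map <- function(x, ...) {
  cat("Homography (bottom-right normalized when possible):\n")
  print(signif(as.matrix(x), 6))
  cat(sprintf("  max reprojection residual: %.3g\n", x$residual_max))
  invisible(x)
}
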