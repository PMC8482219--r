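# Small 3-D vector helpers used by the simulator. All point sets are n x 3
# matrices in millimetres; directions are unit row vectors.

.vnorm <- function(v) sqrt(rowSums(v * v))

.vunit <- function(v) {
  n <- .vnorm(v)
  if (any(n < 1e-300)) stop("cannot normalize a zero-length vector")
  v / n
}

.vcross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

.vdot <- function(a, b) rowSums(a * b)

.as_row <- function(p, n = NULL) {
  m <- if (is.matrix(p)) {
    matrix(as.numeric(p), nrow(p), ncol(p))
  } else {
    matrix(as.numeric(p), ncol = 3, byrow = TRUE)
  }
  if (!is.null(n) && nrow(m) == 1L) m <- m[rep(1L, n), , drop = FALSE]
  m
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# Rodrigues rotation of row vectors v about unit axes k by angle (degrees).
# v and k are n x 3; angle is scalar or length n.
.rotate_about <- function(v, k, angle_deg) {
  th <- .deg2rad(angle_deg)
  cs <- cos(th)
  sn <- sin(th)
  kxv <- .vcross(k, v)
  kdv <- .vdot(k, v)
  v * cs + kxv * sn + k * (kdv * (1 - cs))
}

# Right-handed frame attached to a forward direction f (n x 3, unit):
# h is the horizontal axis (points toward +x when f looks down -z),
# u the vertical axis (toward +y). World up is +y.
.gaze_frame <- function(f) {
  up <- matrix(c(0, 1, 0), nrow(f), 3, byrow = TRUE)
  h <- .vunit(.vcross(f, up))
  u <- .vcross(h, f)
  list(h = h, u = u)
}
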