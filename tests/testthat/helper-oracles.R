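# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no stored data.

# 3 x 3 grid on [-1, 1]^2
unit_grid3 <- function() {
  as.matrix(expand.grid(x = c(-1, 0, 1), y = c(-1, 0, 1)))
}

# brute-force normal-equations solution of the poly2 least-squares problem
poly2_oracle <- function(src, dst) {
  A <- cbind(src[, 1]^2, src[, 2]^2, src[, 1] * src[, 2],
             src[, 1], src[, 2], 1)
  solve(t(A) %*% A, t(A) %*% dst)
}

# numeric inverse of a radial-only distortion: find p such that
# apply_distortion(m, p) = q (used to synthesize observed features whose fit
# recovers a known model exactly); s_hi must stay below the fold of the
# radial response s * rho(s^2)
radial_inverse <- function(m, q, s_hi = 1.2) {
  t(apply(q, 1, function(v) {
    r <- sqrt(sum(v^2))
    if (r == 0) return(v)
    s <- stats::uniroot(function(s) {
      sum(drop(apply_distortion(m, s * v / r)) * (v / r)) - r
    }, c(1e-9, s_hi), tol = 1e-14)$root
    s * v / r
  }))
}

# random proper projective matrix, bounded away from degeneracy
random_homography <- function() {
  repeat {
    H <- matrix(stats::rnorm(9), 3, 3) + 2 * diag(3)
    if (abs(det(H)) > 0.3) return(H)
  }
}

# pinhole projection oracle for synthetic two-view geometry tests
project_oracle <- function(X, C, R, f = 30) {
  pc <- sweep(X, 2, C) %*% t(R)
  cbind(f * pc[, 1] / pc[, 3], f * pc[, 2] / pc[, 3])
}

# angle (rad) between two 3-vectors
vec_angle <- function(a, b) {
  acos(min(max(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), -1), 1))
}

expect_close <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}
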