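#' Construct a quaternion
#'
#' A quaternion q = w + ix + jy + kz is stored as a numeric vector of length
#' four in the fixed component order (w, x, y, z): one real (scalar) part `w`
#' and a three-component vector part (x, y, z).
#'
#' @param w Real scalar part.
#' @param x,y,z Real components of the vector part.
#' @return An object of class `"quaternion"`: a named numeric vector
#'   `c(w, x, y, z)`.
#' @examples
#' quaternion(1, 2, 3, 4)
#' q_mul(quaternion(0, 1, 0, 0), quaternion(0, 0, 1, 0)) # i * j = k
#' @export
quaternion <- function(w, x, y, z) {
  q <- c(w = as.numeric(w), x = as.numeric(x),
         y = as.numeric(y), z = as.numeric(z))
  if (length(q) != 4L || anyNA(q)) {
    stop("quaternion components must be four finite numbers", call. = FALSE)
  }
  class(q) <- "quaternion"
  q
}

#' Construct a pure quaternion (zero scalar part)
#'
#' Pure quaternions represent 3-vectors; the rotation operator maps pure
#' quaternions to pure quaternions.
#'
#' @param x,y,z Real components of the vector part.
#' @return A `"quaternion"` with scalar part exactly 0.
#' @export
pure_quaternion <- function(x, y, z) {
  quaternion(0, x, y, z)
}

# Accept a quaternion, a plain length-4 (w,x,y,z) vector, or a length-3
# 3-vector (promoted to a pure quaternion).
as_quat <- function(q) {
  q <- unclass(q)
  if (length(q) == 3L) q <- c(0, q)
  if (length(q) != 4L || !is.numeric(q)) {
    stop("expected a quaternion: a numeric vector of length 4 (w, x, y, z) ",
         "or length 3 (pure)", call. = FALSE)
  }
  as.numeric(q)
}

#' @export
print.quaternion <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("quaternion: % .6g %+.6gi %+.6gj %+.6gk\n",
              v[1], v[2], v[3], v[4]))
  invisible(x)
}

#' Quaternion sum
#'
#' @param q,p Quaternions (see [quaternion()]).
#' @return The componentwise sum, a `"quaternion"`.
#' @export
q_add <- function(q, p) {
  out <- as_quat(q) + as_quat(p)
  quaternion(out[1], out[2], out[3], out[4])
}

#' Hamilton product of two quaternions
#'
#' Non-commutative quaternion multiplication: the scalar part is
#' s_q s_p - v_q . v_p and the vector part is s_p v_q + s_q v_p + v_q x v_p,
#' so the imaginary units satisfy i^2 = j^2 = k^2 = ijk = -1 and
#' ij = k, jk = i, ki = j.
#'
#' @inheritParams q_add
#' @return The product q (x) p, a `"quaternion"`.
#' @export
q_mul <- function(q, p) {
  out <- quat_mat_mul(matrix(as_quat(q), 1L), matrix(as_quat(p), 1L))
  quaternion(out[1], out[2], out[3], out[4])
}

#' Scalar (4-vector inner) product of two quaternions
#'
#' @inheritParams q_add
#' @return The real number s_q s_p + v_q . v_p.
#' @export
q_dot <- function(q, p) {
  sum(as_quat(q) * as_quat(p))
}

#' Quaternion conjugate
#'
#' Negates the vector part and preserves the scalar part.
#'
#' @param q A quaternion.
#' @return The conjugate, a `"quaternion"`.
#' @export
q_conj <- function(q) {
  q <- as_quat(q)
  quaternion(q[1], -q[2], -q[3], -q[4])
}

#' Quaternion norm
#'
#' Euclidean norm of the 4-vector, sqrt(w^2 + x^2 + y^2 + z^2). The norm is
#' multiplicative: `q_norm(q_mul(q, p)) == q_norm(q) * q_norm(p)`.
#'
#' @param q A quaternion.
#' @return A nonnegative real number.
#' @export
q_norm <- function(q) {
  sqrt(sum(as_quat(q)^2))
}

#' Quaternion inverse
#'
#' The multiplicative inverse conj(q) / ||q||^2, so that
#' `q_mul(q, q_inv(q))` is the identity quaternion (1, 0, 0, 0).
#'
#' @param q A nonzero quaternion.
#' @return The inverse, a `"quaternion"`.
#' @export
q_inv <- function(q) {
  q <- as_quat(q)
  n2 <- sum(q^2)
  if (n2 == 0) {
    stop("the zero quaternion is not invertible", call. = FALSE)
  }
  quaternion(q[1] / n2, -q[2] / n2, -q[3] / n2, -q[4] / n2)
}

#' Rotation quaternion from an axis and an angle
#'
#' Builds the unit quaternion cos(theta/2) + sin(theta/2) * a encoding a
#' rotation of `theta` radians about the unit axis `a`. An axis whose norm
#' deviates from 1 by at most `tol` is renormalized; a larger deviation is
#' an error.
#'
#' @param axis Rotation axis: a pure quaternion or a numeric 3-vector with
#'   unit norm (within `tol`).
#' @param theta Rotation angle in radians.
#' @param tol Maximum tolerated deviation of `||axis||` from 1.
#' @return A unit `"quaternion"`.
#' @export
from_axis_angle <- function(axis, theta, tol = 1e-6) {
  a <- as_quat(axis)
  if (abs(a[1]) > tol) {
    stop("rotation axis must be a pure quaternion (zero scalar part)",
         call. = FALSE)
  }
  v <- a[2:4]
  nv <- sqrt(sum(v^2))
  if (abs(nv - 1) > tol) {
    stop(sprintf("rotation axis must have unit norm (got %.8g)", nv),
         call. = FALSE)
  }
  v <- v / nv
  s <- sin(theta / 2)
  quaternion(cos(theta / 2), s * v[1], s * v[2], s * v[3])
}

#' Rotate a 3-vector by a quaternion
#'
#' Applies the sandwich operator r' = q (x) r (x) q^-1 (mode `"inverse"`,
#' the default), which preserves `||r||` for any nonzero q because the
#' inverse cancels the norm of q. Mode `"conjugate"` applies
#' q (x) r (x) conj(q) instead, which scales the result by `||q||^2`; it is
#' provided for exploring the difference between the two conventions.
#'
#' @param q A nonzero quaternion defining the rotation.
#' @param r The vector to rotate: a pure quaternion or a numeric 3-vector.
#' @param mode `"inverse"` (true sandwich product, default) or
#'   `"conjugate"`.
#' @return The rotated vector as a pure `"quaternion"` (its scalar part is
#'   0 up to floating-point error; it is returned as computed, not clamped).
#' @export
q_rotate <- function(q, r, mode = c("inverse", "conjugate")) {
  mode <- match.arg(mode)
  q <- as_quat(q)
  r <- as_quat(r)
  right <- if (mode == "inverse") as_quat(q_inv(q)) else as_quat(q_conj(q))
  out <- quat_mat_mul(quat_mat_mul(matrix(q, 1L), matrix(r, 1L)),
                      matrix(right, 1L))
  quaternion(out[1], out[2], out[3], out[4])
}

# Row-wise Hamilton product of two n x 4 matrices in (w, x, y, z) order.
# Vectorized workhorse shared by the scalar API and the stream pipeline.
quat_mat_mul <- function(A, B) {
  w1 <- A[, 1L]; x1 <- A[, 2L]; y1 <- A[, 3L]; z1 <- A[, 4L]
  w2 <- B[, 1L]; x2 <- B[, 2L]; y2 <- B[, 3L]; z2 <- B[, 4L]
  cbind(
    w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2,
    deparse.level = 0
  )
}

# Row-wise conjugate / squared norm for n x 4 matrices.
quat_mat_conj <- function(A) {
  cbind(A[, 1L], -A[, 2L], -A[, 3L], -A[, 4L], deparse.level = 0)
}

quat_mat_norm2 <- function(A) {
  A[, 1L]^2 + A[, 2L]^2 + A[, 3L]^2 + A[, 4L]^2
}
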