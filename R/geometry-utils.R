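# Low-level rigid-body helpers shared by frame fitting and step-parameter
# computation. All rotations are 3x3 proper orthonormal matrices acting on
# column vectors; angles are degrees at the API surface, radians internally.

DEG <- 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `theta` degrees about `axis` (need not be unit
#' length; zero-length axis with nonzero angle is an error).
#'
#' @param axis numeric length-3 axis of rotation.
#' @param theta rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_about <- function(axis, theta) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) {
    if (abs(theta) < 1e-12) return(diag(3))
    stop("rotation axis has zero length")
  }
  u <- axis / n
  th <- theta / DEG
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Signed angle (degrees) from vector a to vector b about unit axis `about`.
# a and b are projected onto the plane normal to `about` first.
signed_angle <- function(a, b, about) {
  u <- about / sqrt(sum(about^2))
  a <- a - sum(a * u) * u
  b <- b - sum(b * u) * u
  s <- sum(cross3(a, b) * u)
  c <- sum(a * b)
  atan2(s, c) * DEG
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Axis-angle decomposition of a rotation matrix. Returns list(axis, angle)
# with angle in degrees in [0, 180]. Axis is arbitrary for angle ~ 0.
axis_angle <- function(R) {
  c_th <- (sum(diag(R)) - 1) / 2
  c_th <- max(-1, min(1, c_th))
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  s_th <- sqrt(sum(v^2)) / 2
  ang <- atan2(s_th, c_th) * DEG
  if (s_th > 1e-9) {
    axis <- v / (2 * s_th)
  } else if (c_th > 0) {
    axis <- c(0, 0, 1)                      # identity: axis irrelevant
  } else {
    # 180 degree rotation: axis from the symmetric part
    M <- (R + diag(3)) / 2
    k <- which.max(diag(M))
    axis <- M[, k] / sqrt(M[k, k])
  }
  list(axis = axis, angle = ang)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `||(R P + t) - Q||` over paired coordinate rows, with reflection
#' excluded so mirror-image inputs still yield a proper rotation.
#'
#' @param P n x 3 matrix of source coordinates (the standard geometry).
#' @param Q n x 3 matrix of target coordinates (the observed atoms).
#' @return list with `R` (3x3, det +1), `t` (length 3) and `rmsd`.
#' @keywords internal
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - as.vector(R %*% cp)
  fit <- sweep(P0 %*% t(R), 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((fit - Q)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

#' Construct a reference frame
#'
#' A reference frame is an origin plus a right-handed orthonormal triad
#' stored column-wise (x, y, z).
#'
#' @param origin length-3 numeric origin, Angstrom.
#' @param axes 3x3 orthonormal matrix with columns x, y, z and det +1.
#' @return object of class `ref_frame`.
#' @export
ref_frame <- function(origin = c(0, 0, 0), axes = diag(3)) {
  stopifnot(length(origin) == 3, all(dim(axes) == c(3, 3)))
  if (max(abs(t(axes) %*% axes - diag(3))) > 1e-6)
    stop("frame axes are not orthonormal")
  if (det(axes) < 0)
    stop("frame axes are left-handed")
  structure(list(origin = as.numeric(origin), axes = unname(axes)),
            class = "ref_frame")
}

#' @export
print.ref_frame <- function(x, ...) {
  cat("reference frame\n  origin:", sprintf("%8.3f", x$origin), "\n")
  for (i in 1:3)
    cat(" ", c("x", "y", "z")[i], "axis:", sprintf("%8.4f", x$axes[, i]), "\n")
  invisible(x)
}
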