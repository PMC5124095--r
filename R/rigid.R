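.eulerToMatrix <- function(rotDeg) {
  r <- rotDeg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

.matrixToEuler <- function(R) {
  # inverse of Rz(g) Ry(b) Rx(a); gimbal-safe enough away from |b| = 90 deg
  b <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(b)) > 1e-10) {
    a <- atan2(R[3, 2], R[3, 3])
    g <- atan2(R[2, 1], R[1, 1])
  } else {
    a <- atan2(-R[2, 3], R[2, 2])
    g <- 0
  }
  c(a, b, g) * 180 / pi
}

#' Construct a rigid transform
#'
#' @param translation 3-vector, voxels of the target grid.
#' @param rotation 3 Euler angles, degrees (Rz Ry Rx order).
#' @param centerUm rotation centre, physical micrometres.
#' @param pitchUm target-grid pitch, micrometres.
#' @param fitMetric optional similarity value.
#' @return A [RigidTransform-class].
#' @examples
#' tr <- rigidTransform(c(3, -2, 1), c(0, 0, 0), pitchUm = 59.51)
#' invertRigid(tr)
#' @export
rigidTransform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                           centerUm = c(0, 0, 0), pitchUm = 1,
                           fitMetric = NA_real_) {
  new("RigidTransform", translation = as.numeric(translation),
      rotation = as.numeric(rotation), centerUm = as.numeric(centerUm),
      pitchUm = as.numeric(pitchUm), fitMetric = as.numeric(fitMetric))
}

#' Apply a rigid transform to physical points
#'
#' Maps points (rows, micrometres) from the target frame to the moving
#' frame: `x_mov = R (x - c) + c + t`.
#'
#' @param transform a [RigidTransform-class].
#' @param points n x 3 matrix of physical coordinates, micrometres.
#' @return n x 3 matrix of mapped coordinates.
#' @export
transformPoints <- function(transform, points) {
  points <- matrix(points, ncol = 3)
  R <- .eulerToMatrix(transform@rotation)
  tUm <- transform@translation * transform@pitchUm
  ctr <- transform@centerUm
  t(R %*% (t(points) - ctr) + ctr + tUm)
}

#' Invert a rigid transform
#'
#' Returns the transform mapping the moving frame back to the target frame;
#' composing a transform with its inverse is the identity to numerical
#' precision.
#'
#' @param transform a [RigidTransform-class].
#' @return The inverse [RigidTransform-class] (same centre and pitch).
#' @export
invertRigid <- function(transform) {
  R <- .eulerToMatrix(transform@rotation)
  Rinv <- t(R)
  tUm <- transform@translation * transform@pitchUm
  ctr <- transform@centerUm
  # x_f = Rinv (x_m - c - t) + c = Rinv (x_m - c) + c + [Rinv(-t) + (Rinv - I) 0]
  tInv <- as.numeric(-Rinv %*% tUm)
  rigidTransform(translation = tInv / transform@pitchUm,
                 rotation = .matrixToEuler(Rinv),
                 centerUm = ctr, pitchUm = transform@pitchUm)
}

#' Compose two rigid transforms
#'
#' `composeRigid(a, b)` returns the transform equivalent to applying `b`
#' first, then `a` (both must share centre and pitch).
#'
#' @param a,b [RigidTransform-class] objects with identical `centerUm` and
#'   `pitchUm`.
#' @return A [RigidTransform-class].
#' @export
composeRigid <- function(a, b) {
  stopifnot(all(abs(a@centerUm - b@centerUm) < 1e-9),
            abs(a@pitchUm - b@pitchUm) < 1e-12)
  Ra <- .eulerToMatrix(a@rotation)
  Rb <- .eulerToMatrix(b@rotation)
  R <- Ra %*% Rb
  tUm <- as.numeric(Ra %*% (b@translation * b@pitchUm)) +
    a@translation * a@pitchUm
  rigidTransform(translation = tUm / a@pitchUm,
                 rotation = .matrixToEuler(R),
                 centerUm = a@centerUm, pitchUm = a@pitchUm)
}
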