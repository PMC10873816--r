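#' Rigid transform between two volumes
#'
#' A rotation plus translation mapping a moving volume into a fixed volume's
#' frame. Rotation is given as three Euler angles in degrees, applied about
#' the grid axes in the order z, then y, then x, around the grid center
#' (0-based center `(dim - 1) / 2`). Translation is in voxels, continuous.
#' The forward point map is `T(p) = R (p - c) + c + t`; [apply_transform()]
#' resamples a volume so that `out(x) = vol(T^-1(x))`.
#'
#' @param rotation Numeric length 3, degrees, in order `(z, y, x)`.
#' @param translation Numeric length 3, voxels, in order `(x, y, z)`.
#' @param score Alignment metric value in `[-1, 1]` (normalized
#'   cross-correlation), `NA` when not produced by registration.
#' @return An object of class `rigid_transform`.
#' @export
#' @examples
#' t1 <- rigid_transform(rotation = c(10, 0, 0), translation = c(3, -2, 5))
#' compose_transforms(invert_transform(t1), t1)  # ~ identity
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0), score = NA_real_) {
  rotation <- as.numeric(rotation)
  translation <- as.numeric(translation)
  stopifnot(length(rotation) == 3, length(translation) == 3,
            all(is.finite(rotation)), all(is.finite(translation)))
  structure(
    list(rotation = rotation, translation = translation, score = as.numeric(score)),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> rot (z,y,x) = %s deg, shift (x,y,z) = %s vox, score = %s\n",
    paste(signif(x$rotation, 5), collapse = ", "),
    paste(signif(x$translation, 5), collapse = ", "),
    ifelse(is.na(x$score), "NA", signif(x$score, 5))
  ))
  invisible(x)
}

#' Rotation matrix from z-y-x Euler angles (degrees)
#'
#' @param rotation Angles `(z, y, x)` in degrees.
#' @return 3x3 rotation matrix `Rx %*% Ry %*% Rz`.
#' @export
euler_to_matrix <- function(rotation) {
  a <- rotation * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rx %*% Ry %*% Rz
}

#' Euler angles (z-y-x order, degrees) from a rotation matrix
#'
#' @param R 3x3 rotation matrix.
#' @return Angles `(z, y, x)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  sy <- max(-1, min(1, R[1, 3]))
  ry <- asin(sy)
  if (abs(sy) < 1 - 1e-9) {
    rz <- atan2(-R[1, 2], R[1, 1])
    rx <- atan2(-R[2, 3], R[3, 3])
  } else {
    # gimbal lock: fold all in-plane rotation into rz
    rz <- atan2(R[2, 1], R[2, 2])
    rx <- 0
  }
  c(rz, ry, rx) * 180 / pi
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param second,first [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(second, first) {
  R2 <- euler_to_matrix(second$rotation)
  R1 <- euler_to_matrix(first$rotation)
  rigid_transform(
    rotation = matrix_to_euler(R2 %*% R1),
    translation = as.numeric(R2 %*% first$translation) + second$translation
  )
}

#' Invert a rigid transform
#'
#' @param t A [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(t) {
  R <- euler_to_matrix(t$rotation)
  rigid_transform(
    rotation = matrix_to_euler(t(R)),
    translation = as.numeric(-t(R) %*% t$translation)
  )
}

#' Resample a volume under a rigid transform
#'
#' Trilinear interpolation; samples falling outside the input grid are filled
#' with 0; grid extents are unchanged. An exact identity transform returns
#' voxel values unchanged, and integer shifts are exact on interior voxels
#' (interpolation weights collapse to 0/1).
#'
#' @param scan A [volume_scan()].
#' @param t A [rigid_transform()].
#' @return A [volume_scan()] in the transformed frame.
#' @export
apply_transform <- function(scan, t) {
  stopifnot(inherits(scan, "volume_scan"), inherits(t, "rigid_transform"))
  scan$intensities <- resample_rigid(scan$intensities, t$rotation, t$translation)
  scan
}

# out(x) = vol(R^T (x - c - t) + c); coordinates 0-based, c = (dim-1)/2.
# with_valid attaches a logical array marking in-bounds samples.
resample_rigid <- function(vol, rotation, translation, with_valid = FALSE) {
  d <- dim(vol)
  if (all(rotation == 0) && all(translation == 0)) {
    if (with_valid) attr(vol, "valid") <- array(TRUE, d)
    return(vol)
  }
  A <- t(euler_to_matrix(rotation))
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2; cz <- (d[3] - 1) / 2
  px <- rep.int(0:(d[1] - 1), d[2] * d[3]) - cx - translation[1]
  py <- rep.int(rep(0:(d[2] - 1), each = d[1]), d[3]) - cy - translation[2]
  pz <- rep(0:(d[3] - 1), each = d[1] * d[2]) - cz - translation[3]
  qx <- A[1, 1] * px + A[1, 2] * py + A[1, 3] * pz + cx
  qy <- A[2, 1] * px + A[2, 2] * py + A[2, 3] * pz + cy
  qz <- A[3, 1] * px + A[3, 2] * py + A[3, 3] * pz + cz
  trilinear_sample(vol, qx, qy, qz, with_valid = with_valid)
}

trilinear_sample <- function(vol, qx, qy, qz, with_valid = FALSE) {
  d <- dim(vol)
  s <- trilinear_points(vol, qx, qy, qz)
  out <- array(s$values, d)
  if (with_valid) attr(out, "valid") <- array(s$valid, d)
  out
}

# trilinear interpolation at arbitrary 0-based points; out-of-grid -> 0
trilinear_points <- function(vol, qx, qy, qz) {
  d <- dim(vol)
  valid <- qx >= 0 & qx <= d[1] - 1 & qy >= 0 & qy <= d[2] - 1 & qz >= 0 & qz <= d[3] - 1
  i0 <- floor(qx); j0 <- floor(qy); k0 <- floor(qz)
  fx <- qx - i0; fy <- qy - j0; fz <- qz - k0
  i0[!valid] <- 0; j0[!valid] <- 0; k0[!valid] <- 0
  i1 <- pmin(i0 + 1, d[1] - 1); j1 <- pmin(j0 + 1, d[2] - 1); k1 <- pmin(k0 + 1, d[3] - 1)
  lin <- function(i, j, k) vol[1 + i + d[1] * (j + d[2] * k)]
  gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz
  out <-
    lin(i0, j0, k0) * gx * gy * gz + lin(i1, j0, k0) * fx * gy * gz +
    lin(i0, j1, k0) * gx * fy * gz + lin(i1, j1, k0) * fx * fy * gz +
    lin(i0, j0, k1) * gx * gy * fz + lin(i1, j0, k1) * fx * gy * fz +
    lin(i0, j1, k1) * gx * fy * fz + lin(i1, j1, k1) * fx * fy * fz
  out[!valid] <- 0
  list(values = out, valid = valid)
}
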