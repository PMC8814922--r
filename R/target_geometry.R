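# Fiducial-based NLR (nasion-left-right) head frame, least-squares rigid
# registration, and the coil-pose construction (surface normal + 45-degree
# angulation rule), with quaternion export.

.norm3 <- function(v) sqrt(sum(v^2))
.unit <- function(v) {
  n <- .norm3(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}
.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a fiducial landmark set
#'
#' Nasion and left/right preauricular points in anatomical (T1) space, mm.
#' The three points must be non-collinear (triangle area above 1 mm^2).
#'
#' @param nasion,left_preauricular,right_preauricular numeric mm triples.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(nasion, left_preauricular, right_preauricular) {
  N <- as.numeric(nasion); L <- as.numeric(left_preauricular)
  R <- as.numeric(right_preauricular)
  stopifnot(length(N) == 3L, length(L) == 3L, length(R) == 3L)
  area <- .norm3(.cross(L - N, R - N)) / 2
  if (!is.finite(area) || area < 1)
    stop("degenerate landmarks: nasion and preauricular points are (near-)collinear")
  structure(list(nasion = N, left_preauricular = L, right_preauricular = R),
            class = "landmark_set")
}

#' Origin of the NLR coordinate system
#'
#' The origin is the intersection of the line through both preauricular
#' points with its perpendicular through the nasion, i.e. the orthogonal
#' projection of the nasion onto the preauricular (interaural) line:
#' \deqn{O = R + \frac{(N-R)\cdot(L-R)}{\lVert L-R \rVert^2}(L-R)}
#'
#' @param landmarks a `landmark_set`.
#' @return numeric mm triple.
#' @export
nlr_origin <- function(landmarks) {
  N <- landmarks$nasion; L <- landmarks$left_preauricular
  R <- landmarks$right_preauricular
  lr <- L - R
  if (.norm3(lr) < 1)
    stop("degenerate landmarks: preauricular points closer than 1 mm")
  R + sum((N - R) * lr) / sum(lr^2) * lr
}

#' Fiducial coordinates in NLR space
#'
#' By construction of the frame the origin maps to (0,0,0), the nasion to
#' (+d_N, 0, 0), the left preauricular point to (0, +d_L, 0) and the right
#' preauricular point to (0, -d_R, 0), where d_X is the distance of X from
#' the origin.
#'
#' @param landmarks a `landmark_set`.
#' @return A 4 x 3 matrix with rows origin, nasion, left, right.
#' @export
landmarks_in_nlr <- function(landmarks) {
  O <- nlr_origin(landmarks)
  N <- landmarks$nasion; L <- landmarks$left_preauricular
  R <- landmarks$right_preauricular
  if (.norm3(N - O) < 1)
    stop("degenerate landmarks: nasion lies on the preauricular line")
  out <- rbind(origin = c(0, 0, 0),
               nasion = c(.norm3(N - O), 0, 0),
               left   = c(0, .norm3(L - O), 0),
               right  = c(0, -.norm3(R - O), 0))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Rigid map from anatomical (T1) space to NLR space
#'
#' Builds the orthonormal NLR axes (x toward the nasion, y toward the left
#' preauricular point, z toward the vertex) and returns the rotation and
#' translation such that `p_nlr = rotation %*% p_t1 + translation`.
#'
#' @param landmarks a `landmark_set`.
#' @return A `rigid_transform`: list with `rotation` (3x3, det +1) and
#'   `translation` (length 3).
#' @export
nlr_frame <- function(landmarks) {
  O <- nlr_origin(landmarks)
  xhat <- .unit(landmarks$nasion - O)
  yhat <- .unit(landmarks$left_preauricular - O)
  zhat <- .cross(xhat, yhat)
  R <- rbind(xhat, yhat, .unit(zhat))
  rigid_transform(R, -as.numeric(R %*% O))
}

#' Construct a rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3.
#' @return An object of class `rigid_transform`; apply it with
#'   [apply_rigid()].
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  stopifnot(all(dim(rotation) == c(3L, 3L)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("`rotation` must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform a `rigid_transform`.
#' @param points numeric length-3 vector or n x 3 matrix.
#' @return Transformed points, same shape as the input.
#' @export
apply_rigid <- function(transform, points) {
  if (is.null(dim(points))) {
    as.numeric(transform$rotation %*% as.numeric(points) + transform$translation)
  } else {
    t(transform$rotation %*% t(points) + transform$translation)
  }
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Least-squares rigid fit between corresponding point sets
#'
#' Finds the rotation (determinant +1, enforced by sign correction of the
#' smallest singular direction) and translation minimizing
#' `sum || R s_i + t - d_i ||^2` — the Kabsch/Umeyama solution via the SVD
#' of the centred cross-covariance.
#'
#' @param src,dst n x 3 matrices of corresponding points (n >= 3,
#'   non-collinear source points).
#' @return A `rigid_transform` with an `rmsd` attribute (root-mean-square
#'   residual).
#' @export
fit_rigid <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 3L, ncol(dst) == 3L, nrow(src) == nrow(dst))
  if (nrow(src) < 3L) stop("at least 3 correspondences are required")
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2, cs); B <- sweep(dst, 2, cd)
  if (qr(A)$rank < 2L) stop("collinear source points: rigid fit is underdetermined")
  H <- crossprod(A, B)
  sv <- svd(H)
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  t_vec <- cd - as.numeric(R %*% cs)
  out <- rigid_transform(R, t_vec)
  resid <- sweep(t(R %*% t(src)), 2, -t_vec) - dst
  attr(out, "rmsd") <- sqrt(mean(rowSums(resid^2)))
  out
}

#' Coil pose from a surface normal in NLR space
#'
#' Builds the coil coordinate frame at a scalp vertex: the coil z-axis is
#' the outward surface normal; the coil y-axis is the unique tangent
#' direction whose projection onto the NLR xy-plane is parallel to the
#' in-plane handle direction `u` (default anterior-left, 45 degrees from
#' the NLR x-axis), i.e. `c_y ~ u - ((u . c_z)/c_z[3]) e_z`; the x-axis
#' completes a right-handed frame (`c_x = c_y x c_z`). The projection of
#' the coil y-axis onto the NLR xy-plane therefore makes the requested
#' angle with the NLR x-axis (the midsagittal axis) exactly.
#'
#' @param normal unit outward surface normal in NLR space.
#' @param scalp_vertex mm triple in NLR space.
#' @param angle_deg planar angle between the projected coil y-axis and the
#'   NLR x-axis, in degrees (default 45). The sign selects the anterior-left
#'   (+) or anterior-right (-) solution.
#' @return A `coil_pose`: list with `scalp_vertex`, `rotation` (columns
#'   c_x, c_y, c_z), and `quaternion` (w, x, y, z with w >= 0).
#' @export
coil_pose <- function(normal, scalp_vertex, angle_deg = 45) {
  cz <- .unit(as.numeric(normal))
  th <- angle_deg * pi / 180
  u <- c(cos(th), sin(th), 0)
  # c_y must be tangent (c_y . c_z = 0) with xy-projection parallel to u,
  # hence c_y ~ u + alpha e_z with alpha = -(u . c_z) / c_z[3]
  tangent_with_projection <- function(u, cz) {
    if (abs(cz[3]) < 1e-6) {
      if (abs(sum(u * cz)) < 1e-6) return(u)    # u already tangent
      return(NULL)                              # no tangent vector projects onto u
    }
    .unit(u + c(0, 0, -sum(u * cz) / cz[3]))
  }
  cy <- tangent_with_projection(u, cz)
  if (is.null(cy)) {
    warning("surface normal is parallel to the requested handle direction; ",
            "falling back to the mirrored in-plane direction")
    u <- c(cos(th), -sin(th), 0)
    cy <- tangent_with_projection(u, cz)
    if (is.null(cy))
      stop("degenerate orientation: normal parallel to both candidate handle directions")
  }
  cx <- .cross(cy, cz)
  R <- cbind(cx, cy, cz)
  dimnames(R) <- NULL
  structure(list(scalp_vertex = as.numeric(scalp_vertex),
                 rotation = R,
                 quaternion = rotation_to_quaternion(R)),
            class = "coil_pose")
}

#' @export
print.coil_pose <- function(x, ...) {
  cat(sprintf("<coil_pose> scalp vertex (%s) mm, quaternion (%s)\n",
              paste(format(x$scalp_vertex, digits = 4), collapse = ", "),
              paste(format(x$quaternion, digits = 6), collapse = ", ")))
  invisible(x)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Scalar-first Hamilton convention (w, x, y, z) with w >= 0, using
#' Shepperd's numerically stable branch selection.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1 (tolerance
#'   1e-6).
#' @return numeric length-4 unit quaternion.
#' @export
rotation_to_quaternion <- function(rotation) {
  R <- unname(as.matrix(rotation))
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("input is not a rotation matrix (orthonormal, det +1)")
  tr <- sum(diag(R))
  # pick the largest of (w, x, y, z) as pivot for stability
  w2 <- (1 + tr) / 4
  x2 <- (1 + 2 * R[1, 1] - tr) / 4
  y2 <- (1 + 2 * R[2, 2] - tr) / 4
  z2 <- (1 + 2 * R[3, 3] - tr) / 4
  pivot <- which.max(c(w2, x2, y2, z2))
  if (pivot == 1L) {
    w <- sqrt(w2)
    x <- (R[3, 2] - R[2, 3]) / (4 * w)
    y <- (R[1, 3] - R[3, 1]) / (4 * w)
    z <- (R[2, 1] - R[1, 2]) / (4 * w)
  } else if (pivot == 2L) {
    x <- sqrt(x2)
    w <- (R[3, 2] - R[2, 3]) / (4 * x)
    y <- (R[1, 2] + R[2, 1]) / (4 * x)
    z <- (R[1, 3] + R[3, 1]) / (4 * x)
  } else if (pivot == 3L) {
    y <- sqrt(y2)
    w <- (R[1, 3] - R[3, 1]) / (4 * y)
    x <- (R[1, 2] + R[2, 1]) / (4 * y)
    z <- (R[2, 3] + R[3, 2]) / (4 * y)
  } else {
    z <- sqrt(z2)
    w <- (R[2, 1] - R[1, 2]) / (4 * z)
    x <- (R[1, 3] + R[3, 1]) / (4 * z)
    y <- (R[2, 3] + R[3, 2]) / (4 * z)
  }
  q <- c(w, x, y, z)
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q numeric length-4 quaternion (w, x, y, z); normalized internally.
#' @return 3x3 rotation matrix.
#' @export
quaternion_to_rotation <- function(q) {
  stopifnot(length(q) == 4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}
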