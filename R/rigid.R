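# 6-parameter rigid transforms in world coordinates, y = R x + t,
# conventionally mapping the moving (TOF) frame into the fixed (CISS) frame.

#' Construct a rigid world-coordinate transform
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation in mm.
#' @return An object of class `nvc_rigid`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "nvc_rigid")
}

#' @export
print.nvc_rigid <- function(x, ...) {
  cat(sprintf("<nvc_rigid  angle %.3f deg  |t| %.3f mm>\n",
              rotation_angle(x$rotation), sqrt(sum(x$translation^2))))
  invisible(x)
}

# Rodrigues rotation from an axis-angle vector (radians).
rotation_from_vector <- function(rvec) {
  th <- sqrt(sum(rvec^2))
  if (th < 1e-12) return(diag(3))
  k <- rvec / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Geodesic rotation angle of R (optionally relative to Rref), in degrees.
rotation_angle <- function(R, Rref = diag(3)) {
  M <- crossprod(Rref, R)
  c_ <- (sum(diag(M)) - 1) / 2
  acos(pmin(pmax(c_, -1), 1)) * 180 / pi
}

# Parameter vector (axis-angle radians, translation mm) about a center:
# y = R (x - center) + center + tau.
rigid_from_params <- function(p, center = c(0, 0, 0)) {
  R <- rotation_from_vector(p[1:3])
  t <- as.numeric(center - R %*% center) + p[4:6]
  rigid_transform(R, t)
}

#' Apply a rigid transform to points
#' @param T an `nvc_rigid`.
#' @param pts n x 3 matrix of world coordinates.
#' @return n x 3 matrix.
#' @export
apply_rigid <- function(T, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  pts %*% t(T$rotation) + matrix(T$translation, nrow(pts), 3, byrow = TRUE)
}

#' Invert a rigid transform
#' @param T an `nvc_rigid`.
#' @export
rigid_inverse <- function(T) {
  Rt <- t(T$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% T$translation))
}

#' Rotation / translation discrepancy between two rigid transforms
#'
#' Rotation error is the geodesic angle between the two rotations in
#' degrees; translation error is the Euclidean distance (mm) between the
#' images of `ref_point` (defaults to the origin-free comparison of the
#' translation vectors about `ref_point`).
#'
#' @param Ta,Tb `nvc_rigid` objects.
#' @param ref_point world point at which to measure the displacement
#'   discrepancy (use the anatomy center to avoid lever-arm inflation).
#' @return named vector `c(rot_deg, trans_mm)`.
#' @export
rigid_error <- function(Ta, Tb, ref_point = c(0, 0, 0)) {
  rot <- rotation_angle(Ta$rotation, Tb$rotation)
  pa <- apply_rigid(Ta, matrix(ref_point, 1))
  pb <- apply_rigid(Tb, matrix(ref_point, 1))
  c(rot_deg = rot, trans_mm = sqrt(sum((pa - pb)^2)))
}

# Serialize to/from a plain list (for JSON).
rigid_to_list <- function(T) {
  list(matrix = rbind(cbind(T$rotation, T$translation), c(0, 0, 0, 1)))
}
rigid_from_list <- function(l) {
  M <- l$matrix
  if (is.list(M)) M <- do.call(rbind, lapply(M, unlist))
  M <- matrix(as.numeric(M), 4, 4)
  rigid_transform(M[1:3, 1:3], M[1:3, 4])
}
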