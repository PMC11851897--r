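# Rigid transforms, the Euler parameterization of the pose, and the chain of
# coordinate transforms linking CT voxel, patient, and X-ray source frames.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Construct a six-parameter rigid pose
#'
#' @param alpha,beta,theta rotations about the x, y and z axes, degrees.
#' @param dx,dy,dz translations along x, y and z, mm.
#' @return a [Pose6-class] object.
#' @examples
#' pose6(theta = 90, dx = 1)
#' @export
pose6 <- function(alpha = 0, beta = 0, theta = 0, dx = 0, dy = 0, dz = 0) {
  p <- c(alpha = alpha, beta = beta, theta = theta, dx = dx, dy = dy, dz = dz)
  if (!all(is.finite(p))) stop("pose parameters must be finite")
  new("Pose6", params = p)
}

#' @describeIn pose6 the named parameter vector of a pose.
#' @param pose a [Pose6-class].
#' @export
poseParams <- function(pose) pose@params

#' Construct a rigid transform from a 4x4 matrix
#'
#' @param m numeric 4x4 homogeneous matrix with an orthonormal,
#'   determinant +1 rotation block.
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(m) new("RigidTransform", matrix = unname(m))

#' @describeIn rigidTransform the underlying 4x4 matrix.
#' @param x a [RigidTransform-class].
#' @export
transformMatrix <- function(x) x@matrix

#' Identity rigid transform
#' @export
identityTransform <- function() rigidTransform(diag(4))

#' Pose to homogeneous transform matrix
#'
#' Builds the 4x4 rigid transform for a pose: rotation about x by
#' \code{alpha}, about y by \code{beta} and about z by \code{theta}
#' (applied in that order, i.e. the rotation block equals
#' Rz(theta) Ry(beta) Rx(alpha)), with translation (dx, dy, dz). The
#' matrix elements are written out explicitly in terms of the angle sines
#' and cosines; angles are converted from degrees internally.
#'
#' @param pose a [Pose6-class].
#' @return a [RigidTransform-class].
#' @seealso [matrixToPose()] for the inverse.
#' @export
poseToMatrix <- function(pose) {
  stopifnot(is(pose, "Pose6"))
  p <- pose@params
  ca <- cos(.deg2rad(p[["alpha"]])); sa <- sin(.deg2rad(p[["alpha"]]))
  cb <- cos(.deg2rad(p[["beta"]]));  sb <- sin(.deg2rad(p[["beta"]]))
  ct <- cos(.deg2rad(p[["theta"]])); st <- sin(.deg2rad(p[["theta"]]))
  m <- matrix(c(
    cb * ct, sa * sb * ct - ca * st, ca * sb * ct + sa * st, p[["dx"]],
    cb * st, sa * sb * st + ca * ct, ca * sb * st - sa * ct, p[["dy"]],
    -sb,     sa * cb,                ca * cb,                p[["dz"]],
    0,       0,                      0,                      1),
    nrow = 4, byrow = TRUE)
  rigidTransform(m)
}

#' Transform matrix to pose
#'
#' Recovers the six pose parameters from a rigid transform. \code{beta} is
#' taken from -sin(beta) in matrix element (3,1) with \code{beta} in
#' [-90, 90] degrees. In the gimbal-lock case |cos(beta)| ~ 0 the
#' decomposition is not unique; the convention \code{theta = 0} is applied
#' (the z rotation is folded into \code{alpha}) and a warning is emitted.
#'
#' @param transform a [RigidTransform-class].
#' @return a [Pose6-class] such that \code{poseToMatrix()} reproduces the
#'   input matrix.
#' @export
matrixToPose <- function(transform) {
  stopifnot(is(transform, "RigidTransform"))
  m <- transform@matrix
  sb <- -m[3, 1]
  sb <- max(-1, min(1, sb))
  cb <- sqrt(max(0, 1 - sb * sb))
  if (cb < 1e-8) {
    warning("gimbal lock (|beta| = 90 degrees): applying theta = 0 convention")
    if (sb > 0) {        # beta = +90: R[1,2] = sin(alpha - theta)
      alpha <- atan2(m[1, 2], m[2, 2])
      beta <- pi / 2
    } else {             # beta = -90: R[1,2] = -sin(alpha + theta)
      alpha <- atan2(-m[1, 2], m[2, 2])
      beta <- -pi / 2
    }
    theta <- 0
  } else {
    alpha <- atan2(m[3, 2], m[3, 3])
    beta <- asin(sb)
    theta <- atan2(m[2, 1], m[1, 1])
  }
  pose6(alpha = .rad2deg(alpha), beta = .rad2deg(beta),
        theta = .rad2deg(theta), dx = m[1, 4], dy = m[2, 4], dz = m[3, 4])
}

#' Compose and invert rigid transforms
#'
#' \code{composeTransform(A, B)} returns the transform applying B first and
#' A second (matrix product A B). Long composition chains accumulate
#' floating-point drift in the rotation block; whenever the orthonormality
#' defect of a product exceeds 1e-10 the rotation is re-projected onto
#' SO(3) via its singular value decomposition (nearest rotation in the
#' Frobenius norm), so arbitrary chains stay orthonormal to well below
#' 1e-9.
#'
#' @param A,B [RigidTransform-class] objects.
#' @return a [RigidTransform-class].
#' @export
composeTransform <- function(A, B) {
  stopifnot(is(A, "RigidTransform"), is(B, "RigidTransform"))
  m <- A@matrix %*% B@matrix
  R <- m[1:3, 1:3]
  if (.rot_defect(R) > 1e-10) {
    s <- svd(R)
    m[1:3, 1:3] <- s$u %*% t(s$v)
  }
  rigidTransform(m)
}

#' @describeIn composeTransform the inverse transform: rotation transposed,
#'   translation mapped accordingly.
#' @export
invertTransform <- function(A) {
  stopifnot(is(A, "RigidTransform"))
  R <- A@matrix[1:3, 1:3]
  t <- A@matrix[1:3, 4]
  m <- diag(4)
  m[1:3, 1:3] <- t(R)
  m[1:3, 4] <- -t(R) %*% t
  rigidTransform(m)
}

#' Apply a rigid transform to 3D points
#'
#' @param transform a [RigidTransform-class].
#' @param points numeric matrix with one point per row (n x 3), or a
#'   length-3 vector.
#' @return transformed points, same shape as the input.
#' @export
transformPoints <- function(transform, points) {
  stopifnot(is(transform, "RigidTransform"))
  vec <- is.null(dim(points))
  if (vec) points <- matrix(points, nrow = 1)
  stopifnot(ncol(points) == 3)
  R <- transform@matrix[1:3, 1:3]
  t <- transform@matrix[1:3, 4]
  out <- points %*% t(R) + rep(t, each = nrow(points))
  if (vec) drop(out) else out
}

#' Construct a volume geometry
#'
#' @param dims voxel counts per axis (length 3).
#' @param spacing per-axis voxel size, mm (scalar or length 3).
#' @param offset origin offset (a, b, c) of the grid in the scanner frame,
#'   mm; defaults to zero.
#' @return a [VolumeGeometry-class].
#' @export
volumeGeometry <- function(dims, spacing = 1, offset = c(0, 0, 0)) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  new("VolumeGeometry", dims = as.integer(rep_len(dims, 3L)),
      spacing = spacing, offset = as.numeric(rep_len(offset, 3L)))
}

#' @describeIn volumeGeometry physical extent (L, W, H) = dims * spacing, mm.
#' @param geom a [VolumeGeometry-class].
#' @export
physicalExtent <- function(geom) geom@dims * geom@spacing

#' @describeIn volumeGeometry voxel counts per axis.
#' @export
gridDims <- function(geom) geom@dims

#' @describeIn volumeGeometry per-axis voxel size, mm.
#' @export
voxelSpacing <- function(geom) geom@spacing

#' @describeIn volumeGeometry origin offset (a, b, c), mm.
#' @export
originOffset <- function(geom) geom@offset

#' CT-to-patient coordinate transform
#'
#' Pure translation that places the geometric center of the CT volume at
#' the origin of the patient frame: translation
#' (-(a + L/2), -(b + W/2), -(c + H/2)), where (a, b, c) is the voxel
#' origin offset and (L, W, H) the physical extent of the grid in mm.
#'
#' @param geom a [VolumeGeometry-class].
#' @return a [RigidTransform-class] with identity rotation.
#' @export
patientFromCT <- function(geom) {
  stopifnot(is(geom, "VolumeGeometry"))
  ext <- physicalExtent(geom)
  m <- diag(4)
  m[1:3, 4] <- -(geom@offset + ext / 2)
  rigidTransform(m)
}

#' Patient-to-source coordinate transform
#'
#' The X-ray source frame shares the patient frame's axis orientation up
#' to the C-arm extrinsic rotation \code{Ri} and sits at distance SOD from
#' the patient origin along +z: rotation \code{Ri}, translation
#' (0, 0, -SOD). In the single-view setup the primary and secondary C-arm
#' angles are zero, so \code{Ri} is the identity.
#'
#' @param sod source-to-object distance, mm (nonnegative).
#' @param Ri 3x3 orthonormal extrinsic rotation of the imaging device.
#' @return a [RigidTransform-class].
#' @export
sourceFromPatient <- function(sod, Ri = diag(3)) {
  if (!is.finite(sod) || sod < 0) stop("sod must be a nonnegative number")
  Ri <- unname(as.matrix(Ri))
  if (!identical(dim(Ri), c(3L, 3L)) || .rot_defect(Ri) > 1e-6 ||
      abs(det(Ri) - 1) > 1e-6)
    stop("Ri must be a 3x3 orthonormal rotation matrix")
  m <- diag(4)
  m[1:3, 1:3] <- Ri
  m[1:3, 4] <- c(0, 0, -sod)
  rigidTransform(m)
}

#' CT-to-source coordinate transform
#'
#' Chains the CT-to-patient and patient-to-source transforms,
#' \code{inv(patientFromCT) . sourceFromPatient}, linking the CT voxel
#' frame to the X-ray source frame for projection.
#'
#' @inheritParams patientFromCT
#' @inheritParams sourceFromPatient
#' @return a [RigidTransform-class].
#' @export
ctFromSource <- function(geom, sod, Ri = diag(3)) {
  composeTransform(invertTransform(patientFromCT(geom)),
                   sourceFromPatient(sod, Ri))
}

# ---- serialization ----------------------------------------------------------

#' Read and write transforms and poses
#'
#' Transforms serialize to a plain-text 4x4 matrix file (whitespace
#' separated, full precision); poses to a JSON record with keys
#' \code{alpha, beta, theta, dx, dy, dz} (degrees and mm).
#'
#' @param transform a [RigidTransform-class].
#' @param path file path.
#' @name transform-io
NULL

#' @rdname transform-io
#' @export
writeTransform <- function(transform, path) {
  stopifnot(is(transform, "RigidTransform"))
  m <- format(transform@matrix, digits = 17)
  writeLines(apply(m, 1, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname transform-io
#' @export
readTransform <- function(path) {
  if (!file.exists(path)) stop("no such transform file: ", path)
  m <- as.matrix(utils::read.table(path))
  rigidTransform(unname(m))
}

#' @rdname transform-io
#' @param pose a [Pose6-class].
#' @export
writePose <- function(pose, path) {
  stopifnot(is(pose, "Pose6"))
  jsonlite::write_json(as.list(pose@params), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname transform-io
#' @export
readPose <- function(path) {
  if (!file.exists(path)) stop("no such pose file: ", path)
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(.POSE_NAMES, names(v))
  if (length(missing))
    stop("pose record lacks fields: ", paste(missing, collapse = ", "))
  do.call(pose6, as.list(unlist(v[.POSE_NAMES])))
}
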