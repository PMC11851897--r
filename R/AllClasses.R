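#' @useDynLib drrpose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.POSE_NAMES <- c("alpha", "beta", "theta", "dx", "dy", "dz")

#' Six-parameter rigid pose
#'
#' A rigid pose in 3D: three rotations \code{alpha}, \code{beta},
#' \code{theta} about the x, y and z axes (degrees) and three translations
#' \code{dx}, \code{dy}, \code{dz} (mm). This is the regression target of
#' the learning-based registration and the parameterization used by the
#' optimization baselines.
#'
#' @slot params named numeric of length 6 in the fixed order
#'   \code{alpha, beta, theta, dx, dy, dz}.
#' @seealso [pose6()], [poseToMatrix()]
#' @export
setClass("Pose6", representation(params = "numeric"))

setValidity("Pose6", function(object) {
  p <- object@params
  if (length(p) != 6L) return("params must have length 6")
  if (!all(is.finite(p))) return("all pose parameters must be finite")
  if (!identical(names(p), .POSE_NAMES))
    return(sprintf("params must be named %s", paste(.POSE_NAMES, collapse = ", ")))
  TRUE
})

#' Rigid transform in SE(3)
#'
#' A 4x4 homogeneous matrix whose rotation block is orthonormal with
#' determinant +1 and whose last row is (0, 0, 0, 1). Points are column
#' vectors and transforms act by left multiplication.
#'
#' @slot matrix the 4x4 homogeneous matrix.
#' @export
setClass("RigidTransform", representation(matrix = "matrix"))

.rot_defect <- function(R) {
  max(abs(crossprod(R) - diag(3)))
}

setValidity("RigidTransform", function(object) {
  m <- object@matrix
  if (!is.numeric(m) || !identical(dim(m), c(4L, 4L)))
    return("matrix must be a numeric 4x4 matrix")
  if (!all(is.finite(m))) return("matrix must be finite")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    return("last row must be (0, 0, 0, 1)")
  R <- m[1:3, 1:3]
  if (.rot_defect(R) > 1e-6)
    return("rotation block is not orthonormal")
  if (abs(det(R) - 1) > 1e-6)
    return("rotation block must have determinant +1 (no reflections)")
  TRUE
})

#' Physical geometry of a voxel grid
#'
#' Voxel counts, per-axis spacing (mm) and the origin offset (a, b, c) of
#' the grid in the scanner frame (mm). The physical extent L, W, H is
#' always \code{dims * spacing}.
#'
#' @slot dims integer voxel counts per axis.
#' @slot spacing per-axis voxel size, mm.
#' @slot offset origin offset (a, b, c), mm.
#' @export
setClass("VolumeGeometry",
         representation(dims = "integer", spacing = "numeric",
                        offset = "numeric"))

setValidity("VolumeGeometry", function(object) {
  if (length(object@dims) != 3L || any(object@dims < 1L))
    return("dims must be three positive integers")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be three positive numbers")
  if (length(object@offset) != 3L || any(!is.finite(object@offset)))
    return("offset must be three finite numbers")
  TRUE
})

#' Cone-beam projection geometry
#'
#' The camera model for DRR simulation: source-to-detector distance (SDD),
#' source-to-object distance (SOD, by default SDD/2 so the patient origin
#' sits halfway between source and detector), detector pixel counts and
#' pixel spacing, and the principal point (detector coordinates of the
#' central ray, in pixels, 0-based at the first pixel center).
#'
#' @slot sdd source-to-detector distance, mm.
#' @slot sod source-to-object distance, mm.
#' @slot detRows,detCols detector pixel counts.
#' @slot pixelSpacing detector pixel pitch, mm.
#' @slot principalPoint length-2 (column, row) pixel coordinates of the
#'   central ray.
#' @export
setClass("ProjectionGeometry",
         representation(sdd = "numeric", sod = "numeric",
                        detRows = "integer", detCols = "integer",
                        pixelSpacing = "numeric", principalPoint = "numeric"))

setValidity("ProjectionGeometry", function(object) {
  if (object@sdd <= 0 || !is.finite(object@sdd))
    return("sdd must be positive")
  if (object@sod <= 0 || object@sod >= object@sdd)
    return("sod must satisfy 0 < sod < sdd")
  if (object@detRows < 1L || object@detCols < 1L)
    return("detector must have at least one pixel per axis")
  if (object@pixelSpacing <= 0) return("pixelSpacing must be positive")
  if (length(object@principalPoint) != 2L ||
      any(!is.finite(object@principalPoint)))
    return("principalPoint must be two finite numbers")
  TRUE
})

#' CT volume in Hounsfield units
#'
#' @slot hu 3D array of Hounsfield units, clamped to [-1024, 3071].
#' @slot geometry a [VolumeGeometry-class].
#' @slot name identifier string.
#' @export
setClass("CTVolume",
         representation(hu = "array", geometry = "VolumeGeometry",
                        name = "character"))

setValidity("CTVolume", function(object) {
  d <- dim(object@hu)
  if (length(d) != 3L) return("hu must be a 3D array")
  if (!identical(as.integer(d), object@geometry@dims))
    return("hu dimensions must match geometry dims")
  r <- range(object@hu)
  if (!all(is.finite(r))) return("hu must be finite")
  if (r[1] < -1024 - 1e-9 || r[2] > 3071 + 1e-9)
    return("hu must lie within [-1024, 3071]; clamp before construction")
  TRUE
})

#' Linear attenuation volume
#'
#' Voxel grid of linear attenuation coefficients mu (1/mm), the quantity
#' integrated along rays by the DRR projector.
#'
#' @slot mu 3D array of nonnegative attenuation coefficients, 1/mm.
#' @slot geometry a [VolumeGeometry-class].
#' @export
setClass("AttenuationVolume",
         representation(mu = "array", geometry = "VolumeGeometry"))

setValidity("AttenuationVolume", function(object) {
  d <- dim(object@mu)
  if (length(d) != 3L) return("mu must be a 3D array")
  if (!identical(as.integer(d), object@geometry@dims))
    return("mu dimensions must match geometry dims")
  if (any(!is.finite(object@mu))) return("mu must be finite")
  if (min(object@mu) < 0) return("mu must be nonnegative")
  TRUE
})

#' Digitally reconstructed radiograph
#'
#' A simulated projection image: each pixel is the radiological path
#' integral of attenuation (dimensionless) along the ray from the X-ray
#' source to that detector pixel, together with the pose and projection
#' geometry used to generate it.
#'
#' @slot pixels matrix of line-integral values (detRows x detCols).
#' @slot pose the [Pose6-class] applied to the patient during rendering.
#' @slot geometry the [ProjectionGeometry-class] used.
#' @export
setClass("DRRImage",
         representation(pixels = "matrix", pose = "Pose6",
                        geometry = "ProjectionGeometry"))

setValidity("DRRImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (nrow(p) != object@geometry@detRows ||
      ncol(p) != object@geometry@detCols)
    return("pixel dimensions must match detector geometry")
  if (any(!is.finite(p))) return("pixels must be finite")
  if (min(p) < -1e-9) return("line integrals must be nonnegative")
  TRUE
})

#' Capture range of the six pose parameters
#'
#' Per-parameter [low, high] bounds (mm for translations, degrees for
#' rotations) over which training/test poses are sampled and within which
#' registration is expected to succeed.
#'
#' @slot bounds 6x2 matrix, rows in pose order, columns low/high.
#' @export
setClass("CaptureRange", representation(bounds = "matrix"))

setValidity("CaptureRange", function(object) {
  b <- object@bounds
  if (!identical(dim(b), c(6L, 2L))) return("bounds must be a 6x2 matrix")
  if (!identical(rownames(b), .POSE_NAMES))
    return("bounds rows must be named alpha, beta, theta, dx, dy, dz")
  if (any(!is.finite(b))) return("bounds must be finite")
  if (any(b[, 1] > b[, 2])) return("each low bound must be <= its high bound")
  TRUE
})

#' Pose-labelled DRR dataset
#'
#' A file-backed set of projection images with one pose label per image,
#' plus the capture range, projection geometry and seed that produced it.
#'
#' @slot dir directory holding the images and manifest.
#' @slot manifest data.frame with one row per image: file, the six pose
#'   parameters, split and seed.
#' @slot geometry the [ProjectionGeometry-class] used for rendering.
#' @slot captureRange the [CaptureRange-class] poses were drawn from.
#' @slot imageSize side length of the stored (preprocessed) images.
#' @export
setClass("PoseDataset",
         representation(dir = "character", manifest = "data.frame",
                        geometry = "ProjectionGeometry",
                        captureRange = "CaptureRange",
                        imageSize = "integer"))

setValidity("PoseDataset", function(object) {
  need <- c("file", .POSE_NAMES, "split", "seed")
  if (!all(need %in% names(object@manifest)))
    return(sprintf("manifest must contain columns %s",
                   paste(need, collapse = ", ")))
  TRUE
})

#' Result of one registration run
#'
#' @slot pose the estimated [Pose6-class].
#' @slot method label of the algorithm that produced it.
#' @slot similarity final similarity value (GradNCC for the optimizers).
#' @slot trace per-iteration best objective values.
#' @slot iterations iterations consumed.
#' @slot converged TRUE if the tolerance criterion stopped the run before
#'   the iteration cap.
#' @slot evaluations number of objective (DRR render) evaluations.
#' @slot seconds wall-clock time.
#' @export
setClass("RegistrationResult",
         representation(pose = "Pose6", method = "character",
                        similarity = "numeric", trace = "numeric",
                        iterations = "integer", converged = "logical",
                        evaluations = "integer", seconds = "numeric"))

# ---- show methods -----------------------------------------------------------

setMethod("show", "Pose6", function(object) {
  p <- object@params
  cat(sprintf(
    "Pose6: rot (%.3f, %.3f, %.3f) deg | trans (%.3f, %.3f, %.3f) mm\n",
    p[1], p[2], p[3], p[4], p[5], p[6]))
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform (4x4 homogeneous, SE(3)):\n")
  print(round(object@matrix, 6))
})

setMethod("show", "VolumeGeometry", function(object) {
  ext <- object@dims * object@spacing
  cat(sprintf("VolumeGeometry: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  extent (L, W, H) = (%.2f, %.2f, %.2f) mm, offset (%g, %g, %g) mm\n",
              ext[1], ext[2], ext[3],
              object@offset[1], object@offset[2], object@offset[3]))
})

setMethod("show", "ProjectionGeometry", function(object) {
  cat(sprintf(
    "ProjectionGeometry: SDD %g mm, SOD %g mm, detector %d x %d @ %g mm/px\n",
    object@sdd, object@sod, object@detRows, object@detCols,
    object@pixelSpacing))
})

setMethod("show", "CTVolume", function(object) {
  cat(sprintf("CTVolume '%s': HU range [%.0f, %.0f]\n", object@name,
              min(object@hu), max(object@hu)))
  show(object@geometry)
})

setMethod("show", "AttenuationVolume", function(object) {
  cat(sprintf("AttenuationVolume: mu range [%.5f, %.5f] 1/mm\n",
              min(object@mu), max(object@mu)))
  show(object@geometry)
})

setMethod("show", "DRRImage", function(object) {
  cat(sprintf("DRRImage %d x %d, line-integral range [%.3f, %.3f]\n",
              nrow(object@pixels), ncol(object@pixels),
              min(object@pixels), max(object@pixels)))
  show(object@pose)
})

setMethod("show", "CaptureRange", function(object) {
  cat("CaptureRange (mm / degrees):\n")
  print(object@bounds)
})

setMethod("show", "PoseDataset", function(object) {
  cat(sprintf("PoseDataset: %d images (%d x %d) in %s\n",
              nrow(object@manifest), object@imageSize, object@imageSize,
              object@dir))
  print(table(object@manifest$split))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf(
    "RegistrationResult [%s]: similarity %.5f after %d iterations (%s)\n",
    object@method, object@similarity, object@iterations,
    if (object@converged) "converged" else "iteration cap"))
  show(object@pose)
})
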