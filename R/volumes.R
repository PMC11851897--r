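# CT volume I/O and the synthetic phantom generator used throughout the
# test-suite in place of clinical scans.

#' Synthetic phantom specification
#'
#' Describes a rigid, pose-identifiable test object with bone-like
#' contrast: an ellipsoidal bone shell enclosing soft tissue in air, a
#' vertebra-like bone rod, optional spherical inclusions, and off-axis
#' high-density asymmetry markers that break every rigid symmetry of the
#' grid (so no two distinct poses produce the same projection). All
#' positions and radii are in mm relative to the volume center.
#'
#' @param dims voxel counts per axis (scalar or length 3).
#' @param spacing voxel size in mm (scalar or length 3).
#' @param shellRadii outer semi-axes of the bone shell, mm; defaults scale
#'   with the volume extent.
#' @param shellCenter center of the bone shell relative to the volume
#'   center, mm; off-center by default so that no 180-degree rotation maps
#'   the phantom onto itself.
#' @param shellThickness bone shell thickness, mm.
#' @param shellHU,tissueHU,airHU Hounsfield values of shell, interior and
#'   background.
#' @param inclusions list of \code{list(center=, radius=, hu=)} spheres
#'   and rods (\code{rod = TRUE}, optional \code{axis}) inside the shell;
#'   centers are relative to the shell center, and structures are clipped
#'   to the shell interior. A vertebra-like column, oblique rods and
#'   dense/lucent spheres are used when \code{NULL}.
#' @param markers matrix (n x 3) of asymmetry-marker centers, mm; at least
#'   one marker must be off every symmetry plane of the grid.
#' @param markerRadius,markerHU marker size and density.
#' @param seed integer; jitters marker positions deterministically so
#'   different seeds give different (but equally asymmetric) phantoms.
#' @return a classed list of validated phantom parameters.
#' @export
phantomSpec <- function(dims = 128L, spacing = 1, shellRadii = NULL,
                        shellCenter = NULL, shellThickness = NULL,
                        shellHU = 1000, tissueHU = 40,
                        airHU = -1000, inclusions = NULL, markers = NULL,
                        markerRadius = NULL, markerHU = 2000, seed = 1L) {
  dims <- as.integer(rep_len(dims, 3L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  ext <- dims * spacing
  if (is.null(shellRadii)) shellRadii <- 0.5 * ext * c(0.74, 0.64, 0.80)
  if (is.null(shellCenter)) shellCenter <- ext * c(0.06, -0.05, 0.07)
  if (is.null(shellThickness)) shellThickness <- 0.05 * min(ext)
  if (is.null(markerRadius)) markerRadius <- 0.05 * min(ext)
  if (is.null(inclusions)) {
    # vertebra-like axial column plus oblique rods and dense/lucent
    # spheres at mid-to-large radius: elongated, high-contrast structures
    # give projections a strong orientation signature
    inclusions <- list(
      list(center = c(0, 0.22 * ext[2], 0), radius = 0.10 * min(ext),
           hu = shellHU, rod = TRUE),
      list(center = c(0.05 * ext[1], -0.12 * ext[2], 0.18 * ext[3]),
           radius = 0.035 * min(ext), hu = 1800, rod = TRUE, axis = 1),
      list(center = c(0.20 * ext[1], 0.10 * ext[2], -0.22 * ext[3]),
           radius = 0.035 * min(ext), hu = 1800, rod = TRUE, axis = 2),
      list(center = c(-0.16 * ext[1], -0.10 * ext[2], 0.12 * ext[3]),
           radius = 0.08 * min(ext), hu = -800),
      list(center = c(0.18 * ext[1], 0.05 * ext[2], -0.15 * ext[3]),
           radius = 0.06 * min(ext), hu = 1500),
      list(center = c(-0.22 * ext[1], 0.16 * ext[2], -0.10 * ext[3]),
           radius = 0.05 * min(ext), hu = 2200),
      list(center = c(0.10 * ext[1], -0.20 * ext[2], -0.18 * ext[3]),
           radius = 0.045 * min(ext), hu = 2000),
      list(center = c(-0.08 * ext[1], 0.05 * ext[2], 0.28 * ext[3]),
           radius = 0.05 * min(ext), hu = 1700))
  }
  if (is.null(markers)) {
    markers <- rbind(c(0.30, 0.25, 0.35), c(-0.25, 0.30, -0.28),
                     c(0.26, -0.32, 0.27)) * rep(ext, each = 3) * 0.5
    jit <- .with_seed(as.integer(seed),
                      matrix(stats::runif(9, -0.01, 0.01), 3) *
                        rep(ext, each = 3))
    markers <- markers + jit
  }
  markers <- as.matrix(markers)
  off_all <- apply(abs(markers) > 2 * markerRadius, 1, all)
  if (!any(off_all))
    stop("phantom spec invalid: need at least one asymmetry marker off ",
         "every symmetry plane of the grid")
  structure(list(dims = dims, spacing = spacing, shellRadii = shellRadii,
                 shellCenter = shellCenter,
                 shellThickness = shellThickness, shellHU = shellHU,
                 tissueHU = tissueHU, airHU = airHU, inclusions = inclusions,
                 markers = markers, markerRadius = markerRadius,
                 markerHU = markerHU, seed = as.integer(seed)),
            class = "PhantomSpec")
}

# Run code under a temporary RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic CT phantom
#'
#' Rasterizes a [phantomSpec()] into a Hounsfield-unit voxel grid. The
#' result is deterministic given the spec (including its seed), has HU
#' clamped to [-1024, 3071], and carries no nontrivial rigid symmetry, so
#' its projections identify the pose.
#'
#' @param spec a [phantomSpec()].
#' @param name identifier stored on the volume.
#' @return a [CTVolume-class] whose geometry is centered on the patient
#'   origin (offset = -extent / 2).
#' @export
makePhantom <- function(spec = phantomSpec(), name = "phantom") {
  stopifnot(inherits(spec, "PhantomSpec"))
  d <- spec$dims
  sp <- spec$spacing
  ext <- d * sp
  # voxel-center coordinates relative to the volume center
  cx <- (seq_len(d[1]) - 0.5) * sp[1] - ext[1] / 2
  cy <- (seq_len(d[2]) - 0.5) * sp[2] - ext[2] / 2
  cz <- (seq_len(d[3]) - 0.5) * sp[3] - ext[3] / 2
  X <- array(cx, dim = d)
  Y <- array(rep(cy, each = d[1]), dim = d)
  Z <- array(rep(cz, each = d[1] * d[2]), dim = d)

  hu <- array(spec$airHU, dim = d)
  Xs <- X - spec$shellCenter[1]
  Ys <- Y - spec$shellCenter[2]
  Zs <- Z - spec$shellCenter[3]
  r2out <- (Xs / spec$shellRadii[1])^2 + (Ys / spec$shellRadii[2])^2 +
    (Zs / spec$shellRadii[3])^2
  rin <- spec$shellRadii - spec$shellThickness
  r2in <- (Xs / rin[1])^2 + (Ys / rin[2])^2 + (Zs / rin[3])^2
  hu[r2out <= 1] <- spec$shellHU
  hu[r2in <= 1] <- spec$tissueHU

  for (inc in spec$inclusions) {
    ctr <- inc$center + spec$shellCenter
    if (isTRUE(inc$rod)) {
      ax <- if (is.null(inc$axis)) 3L else inc$axis
      per <- setdiff(1:3, ax)
      crd <- list(X, Y, Z)
      half <- 0.30 * ext[ax]
      m <- (crd[[per[1]]] - ctr[per[1]])^2 +
        (crd[[per[2]]] - ctr[per[2]])^2 <= inc$radius^2 &
        abs(crd[[ax]] - ctr[ax]) <= half
    } else {
      m <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= inc$radius^2
    }
    hu[m & r2in <= 1] <- inc$hu
  }
  for (i in seq_len(nrow(spec$markers))) {
    ctr <- spec$markers[i, ]
    m <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <=
      spec$markerRadius^2
    hu[m] <- spec$markerHU
  }
  hu[hu < -1024] <- -1024
  hu[hu > 3071] <- 3071
  new("CTVolume", hu = hu, name = name,
      geometry = volumeGeometry(d, sp, offset = -ext / 2))
}

#' @describeIn makePhantom the HU array of a CT volume.
#' @param ct a [CTVolume-class].
#' @export
ctHU <- function(ct) ct@hu

#' @describeIn makePhantom the [VolumeGeometry-class] of a CT volume.
#' @export
ctGeometry <- function(ct) ct@geometry

#' Load a CT volume from NIfTI
#'
#' Reads a NIfTI-1 file (.nii or .nii.gz), populating voxel spacing and the
#' origin offset (a, b, c) from the header. Only axis-aligned orientations
#' are supported: per-axis flips are resolved by reversing the array, but
#' oblique direction cosines raise an unsupported-orientation error. The
#' header origin names the center of the first voxel; the stored offset is
#' the corner of the voxel grid (origin - spacing / 2), matching the
#' projector's plane convention. HU values are clamped to [-1024, 3071].
#'
#' @param path NIfTI file path.
#' @param name identifier; defaults to the file name.
#' @return a [CTVolume-class].
#' @seealso [saveCT()] for the lossless inverse.
#' @export
loadCT <- function(path, name = NULL) {
  if (!file.exists(path)) stop("cannot read CT volume, no such file: ", path)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D volume: ", path)
  arr <- array(as.numeric(arr), dim = dim(arr))
  R <- xf[1:3, 1:3]
  if (max(abs(R - diag(diag(R)))) > 1e-4 * max(abs(diag(R))))
    stop("unsupported orientation (oblique direction cosines): ", path)
  origin <- xf[1:3, 4]
  step <- diag(R)
  for (ax in 1:3) {
    if (step[ax] < 0) {
      arr <- .flip_axis(arr, ax)
      origin[ax] <- origin[ax] + (dim(arr)[ax] - 1) * step[ax]
      step[ax] <- -step[ax]
    }
  }
  arr[arr < -1024] <- -1024
  arr[arr > 3071] <- 3071
  new("CTVolume", hu = arr,
      geometry = volumeGeometry(dim(arr), step, offset = origin - step / 2),
      name = if (is.null(name)) basename(path) else name)
}

.flip_axis <- function(arr, ax) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[ax]] <- rev(seq_len(dim(arr)[ax]))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Save a CT volume to NIfTI
#'
#' Writes the HU grid with an axis-aligned xform so that [loadCT()]
#' recovers a bit-identical grid and geometry.
#'
#' @param ct a [CTVolume-class].
#' @param path output path (.nii or .nii.gz).
#' @export
saveCT <- function(ct, path) {
  stopifnot(is(ct, "CTVolume"))
  g <- ct@geometry
  xf <- diag(4)
  diag(xf)[1:3] <- g@spacing
  xf[1:3, 4] <- g@offset + g@spacing / 2
  hu <- ct@hu
  attr(hu, "pixdim") <- g@spacing
  img <- RNifti::asNifti(hu, datatype = "double")
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a volume in MetaImage format
#'
#' Emits an uncompressed .mha (header plus little-endian float64 voxels)
#' for interchange with common medical-imaging viewers. No reader is
#' provided; NIfTI is the package's round-trip format.
#'
#' @param vol a [CTVolume-class] or [AttenuationVolume-class].
#' @param path output .mha path.
#' @export
writeMha <- function(vol, path) {
  arr <- if (is(vol, "CTVolume")) vol@hu else vol@mu
  g <- if (is(vol, "CTVolume")) vol@geometry else vol@geometry
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(arr), collapse = " ")),
           paste("ElementSpacing =", paste(g@spacing, collapse = " ")),
           paste("Offset =", paste(g@offset + g@spacing / 2, collapse = " ")),
           "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.vector(arr), con, size = 8, endian = "little")
  invisible(path)
}
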