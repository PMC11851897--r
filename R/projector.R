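# DRR generation: the line-integral imaging model via Siddon ray casting,
# plus a slow dense-sampling reference used in tests.
#
# Frame conventions: the X-ray source sits at patient-frame (0, 0, +SOD);
# the detector plane lies at z = SOD - SDD with its axes parallel to the
# patient x (columns) and y (rows) axes; the principal point defaults to
# the detector center. The pose moves the CT volume within the patient
# frame; rays are cast in the CT frame after applying the inverse chain.

#' Construct a projection geometry
#'
#' Defaults follow a mobile C-arm: 1536 x 1536 detector at 0.194 mm pixel
#' pitch and SDD = 1020 mm, with the patient origin halfway between source
#' and detector (SOD = SDD / 2).
#'
#' @param sdd source-to-detector distance, mm.
#' @param sod source-to-object distance, mm; default \code{sdd / 2}.
#' @param detRows,detCols detector pixel counts.
#' @param pixelSpacing detector pixel pitch, mm.
#' @param principalPoint length-2 (column, row) 0-based pixel coordinates
#'   of the central ray; default is the detector center.
#' @return a [ProjectionGeometry-class].
#' @export
projectionGeometry <- function(sdd = 1020, sod = sdd / 2, detRows = 1536L,
                               detCols = 1536L, pixelSpacing = 0.194,
                               principalPoint = NULL) {
  if (is.null(principalPoint))
    principalPoint <- c((detCols - 1) / 2, (detRows - 1) / 2)
  new("ProjectionGeometry", sdd = as.numeric(sdd), sod = as.numeric(sod),
      detRows = as.integer(detRows), detCols = as.integer(detCols),
      pixelSpacing = as.numeric(pixelSpacing),
      principalPoint = as.numeric(principalPoint))
}

#' Convert Hounsfield units to linear attenuation
#'
#' Linear HU scale: mu = muWater * (1 + HU / 1000), so water (0 HU) maps
#' to muWater and air (-1000 HU) to zero. Values are clamped below at 0.
#'
#' @param ct a [CTVolume-class] (or a bare HU array with a
#'   \code{geometry} supplied via \code{geom}).
#' @param muWater attenuation of water, 1/mm; only relative contrast
#'   matters after display normalization.
#' @param geom required when \code{ct} is a bare array.
#' @return an [AttenuationVolume-class].
#' @export
huToAttenuation <- function(ct, muWater = 0.02, geom = NULL) {
  if (!is.finite(muWater) || muWater <= 0)
    stop("muWater must be a positive number")
  if (is(ct, "CTVolume")) {
    hu <- ct@hu
    geom <- ct@geometry
  } else {
    hu <- ct
    if (is.null(geom)) stop("geom is required for a bare HU array")
  }
  if (any(!is.finite(hu))) stop("HU values must be finite")
  mu <- muWater * (1 + hu / 1000)
  mu[mu < 0] <- 0
  new("AttenuationVolume", mu = mu, geometry = geom)
}

# Detector pixel centers in the patient frame, ordered so that
# matrix(values, detRows, detCols) lands value (r, c) at pixel (r, c).
.detector_points <- function(geom) {
  ps <- geom@pixelSpacing
  xs <- ((0:(geom@detCols - 1)) - geom@principalPoint[1]) * ps
  ys <- ((0:(geom@detRows - 1)) - geom@principalPoint[2]) * ps
  cbind(rep(xs, each = geom@detRows),
        rep(ys, times = geom@detCols),
        geom@sod - geom@sdd)
}

# Source point and detector points mapped into the CT voxel frame for the
# given pose: CT -> patient is pose . patientFromCT, rays use its inverse.
.rays_in_ct_frame <- function(vol_geom, geom, pose) {
  M <- composeTransform(poseToMatrix(pose), patientFromCT(vol_geom))
  Minv <- invertTransform(M)
  list(src = transformPoints(Minv, c(0, 0, geom@sod)),
       pix = transformPoints(Minv, .detector_points(geom)))
}

#' Project an attenuation volume to a DRR (Siddon ray casting)
#'
#' Computes, for every detector pixel, the exact radiological path integral
#' of the attenuation field along the segment from the X-ray source to that
#' pixel through the rigidly posed voxel grid, using Siddon's parametric
#' plane-crossing traversal. Rays that miss the volume yield 0.
#'
#' @param vol an [AttenuationVolume-class].
#' @param geom a [ProjectionGeometry-class].
#' @param pose the [Pose6-class] applied to the patient (default: neutral).
#' @return a [DRRImage-class] whose pixels are the line integrals
#'   (dimensionless: mm times 1/mm).
#' @export
projectSiddon <- function(vol, geom, pose = pose6()) {
  stopifnot(is(vol, "AttenuationVolume"), is(geom, "ProjectionGeometry"),
            is(pose, "Pose6"))
  rays <- .rays_in_ct_frame(vol@geometry, geom, pose)
  vals <- .cpp_project_siddon(as.vector(vol@mu), vol@geometry@dims,
                              vol@geometry@offset, vol@geometry@spacing,
                              rays$src, rays$pix)
  vals[vals < 0] <- 0
  new("DRRImage", pixels = matrix(vals, geom@detRows, geom@detCols),
      pose = pose, geometry = geom)
}

#' Dense-sampling projection reference
#'
#' Trapezoidal integration of the trilinearly interpolated attenuation
#' along each ray at a fixed step. Converges to [projectSiddon()] as the
#' step shrinks (up to interpolation bias at sharp boundaries); used as an
#' independent reference for the ray caster.
#'
#' @inheritParams projectSiddon
#' @param step integration step along the ray, mm; must be positive and at
#'   most half the smallest voxel spacing.
#' @return a [DRRImage-class].
#' @export
projectDenseOracle <- function(vol, geom, pose = pose6(), step = NULL) {
  stopifnot(is(vol, "AttenuationVolume"), is(geom, "ProjectionGeometry"),
            is(pose, "Pose6"))
  smin <- min(vol@geometry@spacing)
  if (is.null(step)) step <- smin / 4
  if (!is.finite(step) || step <= 0) stop("step must be positive")
  if (step > smin / 2 + 1e-12)
    stop("step must be at most half the smallest voxel spacing")
  rays <- .rays_in_ct_frame(vol@geometry, geom, pose)
  vals <- .cpp_project_dense(as.vector(vol@mu), vol@geometry@dims,
                             vol@geometry@offset, vol@geometry@spacing,
                             rays$src, rays$pix, step)
  vals[vals < 0] <- 0
  new("DRRImage", pixels = matrix(vals, geom@detRows, geom@detCols),
      pose = pose, geometry = geom)
}

#' Display rendering of a DRR
#'
#' Min-max normalizes the line-integral image to [0, 1], optionally
#' inverting the polarity (1 - v) to match radiographic convention (dense
#' structures bright on film). A constant image maps to all zeros.
#'
#' @param drr a [DRRImage-class] or a bare numeric matrix.
#' @param invert flip intensity polarity after normalization.
#' @return a numeric matrix with values in [0, 1].
#' @export
renderDisplay <- function(drr, invert = FALSE) {
  px <- if (is(drr, "DRRImage")) drr@pixels else drr
  stopifnot(is.matrix(px))
  rng <- range(px)
  out <- if (rng[2] - rng[1] <= 0) {
    matrix(0, nrow(px), ncol(px))
  } else {
    (px - rng[1]) / (rng[2] - rng[1])
  }
  if (invert) out <- 1 - out
  out
}

#' @describeIn drr-io the pixel matrix of a DRR.
#' @export
drrPixels <- function(drr) drr@pixels

#' @describeIn drr-io the pose a DRR was rendered at.
#' @export
drrPose <- function(drr) drr@pose

.geom_to_list <- function(geom) {
  list(sdd = geom@sdd, sod = geom@sod, detRows = geom@detRows,
       detCols = geom@detCols, pixelSpacing = geom@pixelSpacing,
       principalPoint = geom@principalPoint)
}

.geom_from_list <- function(x) {
  projectionGeometry(sdd = x$sdd, sod = x$sod, detRows = x$detRows,
                     detCols = x$detCols, pixelSpacing = x$pixelSpacing,
                     principalPoint = unlist(x$principalPoint))
}

#' Write and read DRR images
#'
#' DRRs are stored as 16-bit grayscale TIFF of the display-normalized
#' image, with a JSON sidecar (\code{<path>.json}) holding the pose, the
#' projection geometry and the normalization range so the line-integral
#' scale can be recovered.
#'
#' @param drr a [DRRImage-class].
#' @param path output TIFF path.
#' @param invert stored polarity, see [renderDisplay()].
#' @name drr-io
#' @export
writeDRR <- function(drr, path, invert = FALSE) {
  stopifnot(is(drr, "DRRImage"))
  img <- renderDisplay(drr, invert = invert)
  tiff::writeTIFF(img, path, bits.per.sample = 16L, compression = "none")
  side <- list(pose = as.list(drr@pose@params),
               geometry = .geom_to_list(drr@geometry),
               range = range(drr@pixels), invert = invert)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname drr-io
#' @export
readDRR <- function(path) {
  if (!file.exists(path)) stop("no such DRR file: ", path)
  img <- tiff::readTIFF(path)
  sidep <- paste0(path, ".json")
  if (!file.exists(sidep)) stop("missing DRR sidecar: ", sidep)
  side <- jsonlite::read_json(sidep, simplifyVector = TRUE)
  rng <- as.numeric(side$range)
  px <- if (side$invert) 1 - img else img
  px <- px * (rng[2] - rng[1]) + rng[1]
  new("DRRImage", pixels = px,
      pose = do.call(pose6, as.list(unlist(side$pose))),
      geometry = .geom_from_list(side$geometry))
}
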