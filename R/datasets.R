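# Pose sampling within capture ranges and construction of pose-labelled
# DRR training/test sets.

#' Construct a capture range
#'
#' @param alpha,beta,theta per-parameter [low, high] rotation bounds,
#'   degrees (about x, y and z).
#' @param dx,dy,dz per-parameter [low, high] translation bounds, mm.
#' @return a [CaptureRange-class].
#' @seealso [captureRangePreset()] for the per-anatomy presets.
#' @export
captureRange <- function(alpha = c(0, 0), beta = c(0, 0), theta = c(0, 0),
                         dx = c(0, 0), dy = c(0, 0), dz = c(0, 0)) {
  b <- rbind(alpha = alpha, beta = beta, theta = theta,
             dx = dx, dy = dy, dz = dz)
  colnames(b) <- c("low", "high")
  new("CaptureRange", bounds = b)
}

#' Capture-range presets per anatomical region
#'
#' The per-anatomy 6-DOF capture ranges used for dataset generation. The
#' in-plane rotation (about z, the projection axis) is kept narrow since
#' it is well controlled clinically; the z translation range is widest
#' because depth along the source axis varies most. The head translation
#' and pelvis x-rotation ranges are off-center: they pre-position the scan
#' so the region of interest is centered (head) or seen anterior-posterior
#' (pelvis), and are regressed as absolute values.
#'
#' @param region one of "head", "chest", "pelvis".
#' @return a [CaptureRange-class].
#' @export
captureRangePreset <- function(region = c("chest", "head", "pelvis")) {
  region <- match.arg(region)
  switch(region,
    head = captureRange(alpha = c(-15, 15), beta = c(-15, 15),
                        theta = c(-5, 5), dx = c(-105, -75),
                        dy = c(-15, 15), dz = c(30, 90)),
    chest = captureRange(alpha = c(-15, 15), beta = c(-15, 15),
                         theta = c(-5, 5), dx = c(-25, 25),
                         dy = c(-15, 15), dz = c(-30, 30)),
    pelvis = captureRange(alpha = c(-105, -75), beta = c(-15, 15),
                          theta = c(-5, 5), dx = c(-25, 25),
                          dy = c(-25, 25), dz = c(-50, 50)))
}

#' @describeIn captureRange the 6x2 bounds matrix.
#' @param range a [CaptureRange-class].
#' @export
rangeBounds <- function(range) range@bounds

#' @describeIn captureRange range midpoints (length 6).
#' @export
rangeMidpoint <- function(range) rowMeans(range@bounds)

#' @describeIn captureRange range half-widths (length 6).
#' @export
rangeHalfWidth <- function(range) (range@bounds[, 2] - range@bounds[, 1]) / 2

#' Sample poses within a capture range
#'
#' Each parameter is drawn independently from a normal distribution
#' truncated to its [low, high] bounds, with mean at the range midpoint
#' and standard deviation a quarter of the range width (both
#' configurable), via the inverse-CDF method; or uniformly over the range
#' when \code{sampler = "uniform"}. A degenerate range (low = high) yields
#' that constant. Reproducible under \code{seed}.
#'
#' @param range a [CaptureRange-class].
#' @param n number of poses (>= 1).
#' @param seed integer seed.
#' @param sampler "truncnorm" (default) or "uniform".
#' @param mean,sd optional length-6 overrides of the per-parameter
#'   untruncated mean and standard deviation.
#' @param asMatrix return an n x 6 matrix instead of a list of
#'   [Pose6-class] objects.
#' @return list of poses, or a matrix when \code{asMatrix = TRUE}.
#' @export
samplePoses <- function(range, n, seed = 1L,
                        sampler = c("truncnorm", "uniform"),
                        mean = NULL, sd = NULL, asMatrix = FALSE) {
  stopifnot(is(range, "CaptureRange"))
  if (!is.finite(n) || n < 1) stop("n must be >= 1")
  sampler <- match.arg(sampler)
  b <- range@bounds
  if (is.null(mean)) mean <- rowMeans(b)
  if (is.null(sd)) sd <- (b[, 2] - b[, 1]) / 4
  out <- matrix(0, n, 6, dimnames = list(NULL, .POSE_NAMES))
  .with_seed(as.integer(seed), {
    for (j in 1:6) {
      lo <- b[j, 1]; hi <- b[j, 2]
      if (hi <= lo) {
        out[, j] <- lo
      } else if (sampler == "uniform") {
        out[, j] <- stats::runif(n, lo, hi)
      } else {
        plo <- stats::pnorm(lo, mean[j], sd[j])
        phi <- stats::pnorm(hi, mean[j], sd[j])
        u <- stats::runif(n, plo, phi)
        x <- stats::qnorm(u, mean[j], sd[j])
        out[, j] <- pmin(pmax(x, lo), hi)
      }
    }
  })
  if (asMatrix) return(out)
  lapply(seq_len(n), function(i) do.call(pose6, as.list(out[i, ])))
}

# ---- preprocessing ----------------------------------------------------------

.drrpose_cache <- new.env(parent = emptyenv())

# Area-average (box-overlap) 1D resampling operator, nout x nin, row sums 1.
.resize_operator <- function(nin, nout) {
  key <- sprintf("rs_%d_%d", nin, nout)
  hit <- .drrpose_cache[[key]]
  if (!is.null(hit)) return(hit)
  scale <- nin / nout
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (o in seq_len(nout)) {
    a <- (o - 1) * scale
    bnd <- o * scale
    j0 <- floor(a) + 1
    j1 <- ceiling(bnd)
    js <- j0:min(j1, nin)
    w <- pmin(js, bnd) - pmax(js - 1, a)
    keep <- w > 1e-12
    ii <- c(ii, rep(o, sum(keep))); jj <- c(jj, js[keep])
    ww <- c(ww, w[keep] / scale)
  }
  op <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(nout, nin))
  .drrpose_cache[[key]] <- op
  op
}

#' Preprocess a radiograph for the pose regressor
#'
#' Anti-aliased area-average down-sampling to \code{size x size}, min-max
#' normalization to [0, 1], and optional intensity inversion (for real
#' radiographs whose polarity is opposite the DRR convention).
#' Deterministic; a constant image maps to all zeros.
#'
#' @param image a [DRRImage-class] or single-channel numeric matrix.
#' @param size output side length, pixels.
#' @param invert flip the polarity after normalization.
#' @return a \code{size x size} matrix with values in [0, 1].
#' @export
preprocessXray <- function(image, size = 224L, invert = FALSE) {
  px <- if (is(image, "DRRImage")) image@pixels else image
  if (!is.matrix(px) || !is.numeric(px))
    stop("input must be a single-channel 2D image")
  Ar <- .resize_operator(nrow(px), size)
  Ac <- .resize_operator(ncol(px), size)
  out <- as.matrix(Ar %*% px %*% Matrix::t(Ac))
  renderDisplay(out, invert = invert)
}

# ---- dataset construction ---------------------------------------------------

#' Build a pose-labelled DRR dataset
#'
#' Renders \code{n} DRRs of a CT volume at poses sampled from the capture
#' range, preprocesses each to \code{imageSize}, and stores them as 16-bit
#' grayscale TIFFs with a CSV manifest binding each image to its pose
#' label. Rendering at full C-arm detector resolution is supported but
#' slow; \code{renderSize} renders on a coarser detector grid (same field
#' of view) before preprocessing.
#'
#' @param vol a [CTVolume-class] or [AttenuationVolume-class].
#' @param geom a [ProjectionGeometry-class].
#' @param range a [CaptureRange-class].
#' @param n number of images.
#' @param seed integer seed controlling the pose draw; use disjoint seeds
#'   for train and test splits.
#' @param dir output directory (created).
#' @param split split tag recorded in the manifest.
#' @param imageSize stored (preprocessed) image side, pixels.
#' @param renderSize detector grid used for rendering; defaults to the
#'   geometry's full resolution.
#' @param muWater attenuation scale for the HU conversion when \code{vol}
#'   is a CT volume.
#' @param overwrite refuse to clobber an existing manifest unless TRUE.
#' @return a [PoseDataset-class].
#' @export
buildPoseDataset <- function(vol, geom, range, n, seed, dir,
                             split = "train", imageSize = 224L,
                             renderSize = NULL, muWater = 0.02,
                             overwrite = FALSE) {
  stopifnot(is(geom, "ProjectionGeometry"), is(range, "CaptureRange"))
  att <- if (is(vol, "CTVolume")) huToAttenuation(vol, muWater) else vol
  stopifnot(is(att, "AttenuationVolume"))
  rgeom <- .render_geometry(geom, renderSize)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(dir, "manifest.csv")
  if (file.exists(manifest_path)) {
    old <- utils::read.csv(manifest_path)
    if (any(old$split == split) && !overwrite)
      stop("manifest in ", dir, " already contains split '", split,
           "'; pass overwrite = TRUE to replace it")
    old <- old[old$split != split, , drop = FALSE]
  } else old <- NULL

  poses <- samplePoses(range, n, seed = seed, asMatrix = TRUE)
  files <- sprintf("%s_%05d.tiff", split, seq_len(n))
  for (i in seq_len(n)) {
    drr <- projectSiddon(att, rgeom,
                         do.call(pose6, as.list(poses[i, ])))
    img <- preprocessXray(drr, size = imageSize)
    tiff::writeTIFF(img, file.path(dir, files[i]), bits.per.sample = 16L,
                    compression = "none")
  }
  man <- data.frame(file = files, poses, split = split, seed = seed,
                    stringsAsFactors = FALSE)
  man <- rbind(old, man)
  utils::write.csv(man, manifest_path, row.names = FALSE)
  meta <- list(geometry = .geom_to_list(geom),
               renderGeometry = .geom_to_list(rgeom),
               bounds = range@bounds, imageSize = imageSize,
               muWater = muWater)
  jsonlite::write_json(meta, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  new("PoseDataset", dir = dir, manifest = man, geometry = rgeom,
      captureRange = range, imageSize = as.integer(imageSize))
}

# Coarser detector with the identical field of view and principal ray.
.render_geometry <- function(geom, renderSize) {
  if (is.null(renderSize) ||
      (renderSize == geom@detRows && renderSize == geom@detCols))
    return(geom)
  fov <- geom@detRows * geom@pixelSpacing
  ps <- fov / renderSize
  projectionGeometry(sdd = geom@sdd, sod = geom@sod, detRows = renderSize,
                     detCols = renderSize, pixelSpacing = ps)
}

#' Load a dataset written by [buildPoseDataset()]
#'
#' @param dir dataset directory.
#' @return a [PoseDataset-class].
#' @export
loadPoseDataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) stop("no manifest in ", dir)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  b <- as.matrix(meta$bounds)
  dimnames(b) <- list(.POSE_NAMES, c("low", "high"))
  new("PoseDataset", dir = dir, manifest = man,
      geometry = .geom_from_list(meta$renderGeometry),
      captureRange = new("CaptureRange", bounds = b),
      imageSize = as.integer(meta$imageSize))
}

#' @describeIn loadPoseDataset the manifest data frame.
#' @param ds a [PoseDataset-class].
#' @export
datasetManifest <- function(ds) ds@manifest

#' @describeIn loadPoseDataset pose labels as an n x 6 matrix.
#' @export
datasetLabels <- function(ds) {
  as.matrix(ds@manifest[, .POSE_NAMES])
}

#' @describeIn loadPoseDataset read stored images; returns a list of
#'   matrices (values in [0, 1]).
#' @param indices manifest rows to read; default all.
#' @export
datasetImages <- function(ds, indices = NULL) {
  if (is.null(indices)) indices <- seq_len(nrow(ds@manifest))
  lapply(indices, function(i)
    tiff::readTIFF(file.path(ds@dir, ds@manifest$file[i])))
}
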