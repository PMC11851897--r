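# Evaluation suite: per-parameter MAE, mean target registration error
# (mTRE), gross failure rate (GFR), and comparison-report tables.

#' Default landmark set for a volume
#'
#' The eight corners of the CT physical bounding box plus its centroid, in
#' the patient frame (volume centered at the origin). Spanning the volume
#' weights rotational error in the registration-error metric.
#'
#' @param geom a [VolumeGeometry-class].
#' @return numeric matrix, one landmark per row (mm).
#' @export
defaultLandmarks <- function(geom) {
  stopifnot(is(geom, "VolumeGeometry"))
  h <- physicalExtent(geom) / 2
  corners <- as.matrix(expand.grid(c(-h[1], h[1]), c(-h[2], h[2]),
                                   c(-h[3], h[3])))
  dimnames(corners) <- NULL
  rbind(corners, c(0, 0, 0))
}

#' Per-parameter mean absolute error
#'
#' Computes, for each of the six pose parameters, the mean and standard
#' deviation of |predicted - true| in native units (degrees for the
#' rotations, mm for the translations), plus the aggregate mean
#' translation and rotation errors obtained by further averaging the
#' three translation (rotation) MAEs.
#'
#' @param pred,truth n x 6 pose matrices (columns alpha, beta, theta, dx,
#'   dy, dz) or lists of [Pose6-class].
#' @return list with elements \code{mae} (named length-6), \code{sd}
#'   (named length-6), \code{meanTranslation}, \code{meanRotation}.
#' @export
maeByParameter <- function(pred, truth) {
  pred <- .as_pose_matrix(pred)
  truth <- .as_pose_matrix(truth)
  if (nrow(pred) != nrow(truth))
    stop("pred and truth must have the same number of poses")
  if (nrow(pred) < 1) stop("need at least one pose pair")
  err <- abs(pred - truth)
  mae <- colMeans(err)
  sdv <- apply(err, 2, stats::sd)
  sdv[is.na(sdv)] <- 0
  list(mae = mae, sd = sdv,
       meanRotation = mean(mae[1:3]),
       meanTranslation = mean(mae[4:6]))
}

.as_pose_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x))
    x <- do.call(rbind, lapply(x, poseParams))
  x <- as.matrix(x)
  if (ncol(x) != 6) stop("pose matrix must have 6 columns")
  colnames(x) <- .POSE_NAMES
  x
}

#' Mean target registration error
#'
#' The mean Euclidean distance (mm) between the images of a set of 3D
#' landmark points under the estimated and ground-truth rigid transforms.
#'
#' @param reg,gt estimated and ground-truth transforms
#'   ([RigidTransform-class] or [Pose6-class]).
#' @param landmarks landmark points, one per row (n x 3), mm.
#' @return mTRE in mm.
#' @export
mtre <- function(reg, gt, landmarks) {
  if (is(reg, "Pose6")) reg <- poseToMatrix(reg)
  if (is(gt, "Pose6")) gt <- poseToMatrix(gt)
  stopifnot(is(reg, "RigidTransform"), is(gt, "RigidTransform"))
  landmarks <- as.matrix(landmarks)
  if (nrow(landmarks) < 1) stop("landmark set must be non-empty")
  d <- transformPoints(reg, landmarks) - transformPoints(gt, landmarks)
  mean(sqrt(rowSums(d * d)))
}

#' Gross failure rate
#'
#' The percentage of registrations whose mTRE exceeds the failure
#' threshold (strictly greater than; 10 mm by default, the conventional
#' clinical failure definition).
#'
#' @param mtreValues numeric vector of mTRE values, mm.
#' @param threshold failure threshold, mm.
#' @return failure percentage in [0, 100].
#' @export
gfr <- function(mtreValues, threshold = 10) {
  if (length(mtreValues) < 1) stop("need at least one mTRE value")
  if (any(!is.finite(mtreValues))) stop("mTRE values must be finite")
  100 * sum(mtreValues > threshold) / length(mtreValues)
}

#' Build a comparison report table
#'
#' Aggregates per-method registration results into the standard
#' comparison layout: per-parameter MAE, mean translation/rotation error,
#' mTRE and GFR, each as mean +/- sd where applicable.
#'
#' @param results named list; one element per method, each a list with
#'   \code{pred} and \code{truth} pose matrices and optionally
#'   \code{mtre} (vector of per-case mTRE values, mm).
#' @param digits printed precision for the formatted columns.
#' @return a data.frame with one row per method, carrying both numeric
#'   columns and formatted "mean +/- sd" strings.
#' @export
buildReport <- function(results, digits = 2) {
  stopifnot(length(results) >= 1, !is.null(names(results)))
  fmt <- function(m, s) sprintf(paste0("%.", digits, "f ± %.",
                                       digits, "f"), m, s)
  rows <- lapply(names(results), function(method) {
    r <- results[[method]]
    m <- maeByParameter(r$pred, r$truth)
    row <- data.frame(method = method,
                      meanTranslation = m$meanTranslation,
                      meanRotation = m$meanRotation,
                      stringsAsFactors = FALSE)
    for (p in .POSE_NAMES) {
      row[[paste0("mae_", p)]] <- m$mae[[p]]
      row[[paste0("fmt_", p)]] <- fmt(m$mae[[p]], m$sd[[p]])
    }
    if (!is.null(r$mtre)) {
      row$mtre_mean <- mean(r$mtre)
      row$mtre_sd <- if (length(r$mtre) > 1) stats::sd(r$mtre) else 0
      row$fmt_mtre <- fmt(row$mtre_mean, row$mtre_sd)
      row$gfr <- gfr(r$mtre)
    }
    row
  })
  out <- do.call(rbind, rows)
  out[order(out$method), , drop = FALSE]
}

#' Write a report as CSV or Markdown
#'
#' @param report data.frame from [buildReport()].
#' @param path output path; format chosen by extension (.csv or .md).
#' @export
writeReport <- function(report, path) {
  if (grepl("\\.md$", path)) {
    cols <- names(report)
    lines <- c(paste0("| ", paste(cols, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(cols)), collapse = "|"),
                      "|"),
               apply(report, 1, function(r)
                 paste0("| ", paste(r, collapse = " | "), " |")))
    writeLines(lines, path)
  } else {
    utils::write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}

#' Signed difference image between two radiographs
#'
#' A simple error-map writer: the signed difference of two normalized
#' images, for visualizing residual misalignment.
#'
#' @param a,b numeric matrices of equal shape.
#' @return matrix of signed differences a - b.
#' @export
differenceImage <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a - b
}
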