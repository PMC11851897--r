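# The dual-channel pose regressor: encoder + regression head, prediction,
# the training loop, and the attention-cost calculator.

#' Partition an image into patch tokens
#'
#' Splits a square single-channel image into non-overlapping
#' \code{patchSize x patchSize} patches, one token per patch, each the
#' flattened patch pixel vector. A 224 x 224 image with 4 x 4 patches
#' yields a 56 x 56 token grid of length-16 tokens. Sides not divisible
#' by the patch size are zero-padded at the bottom/right with a warning.
#'
#' @param image numeric matrix (square, single channel).
#' @param patchSize patch side, pixels.
#' @return matrix of tokens, one per row (row-major over the grid with x
#'   fastest), with attributes \code{grid} (token grid side) and
#'   \code{side} (padded image side).
#' @export
patchPartition <- function(image, patchSize = 4L) {
  stopifnot(is.matrix(image), nrow(image) == ncol(image))
  S <- nrow(image)
  if (S %% patchSize != 0) {
    Sp <- as.integer(ceiling(S / patchSize) * patchSize)
    warning("image side ", S, " not divisible by patch size ", patchSize,
            "; zero-padding to ", Sp)
    padded <- matrix(0, Sp, Sp)
    padded[1:S, 1:S] <- image
    image <- padded
    S <- Sp
  }
  pidx <- .patch_index(S, patchSize)
  out <- matrix(image[pidx], nrow(pidx), patchSize^2)
  attr(out, "grid") <- S %/% patchSize
  attr(out, "side") <- S
  out
}

#' @describeIn patchPartition exact inverse: reassembles tokens into the
#'   (padded) image.
#' @param tokens token matrix from [patchPartition()].
#' @export
patchReassemble <- function(tokens, patchSize = 4L) {
  S <- attr(tokens, "side")
  if (is.null(S)) S <- as.integer(sqrt(nrow(tokens)) * patchSize)
  img <- matrix(0, S, S)
  img[.patch_index(S, patchSize)] <- tokens
  img
}

#' Attention cost of global versus windowed self-attention
#'
#' Evaluates the standard complexity formulas for one multi-head
#' self-attention layer on an h x w feature map with C channels: global
#' attention costs 4 h w C^2 + 2 (h w)^2 C, while window-local attention
#' with M x M windows costs 4 h w C^2 + 2 M^2 h w C. The two coincide
#' exactly when M^2 = h w.
#'
#' @param h,w feature-map height and width.
#' @param C channel depth.
#' @param M window side.
#' @return list with \code{msa} and \code{wmsa}, exact counts (doubles;
#'   exact up to 2^53).
#' @export
attentionCost <- function(h, w, C, M) {
  stopifnot(h > 0, w > 0, C > 0, M > 0)
  hw <- as.numeric(h) * as.numeric(w)
  C <- as.numeric(C)
  list(msa = 4 * hw * C^2 + 2 * hw^2 * C,
       wmsa = 4 * hw * C^2 + 2 * as.numeric(M)^2 * hw * C)
}

#' Mean squared error over a pose batch
#'
#' The scalar training loss: the mean over batch entries and the six pose
#' parameters of the squared prediction residual, computed on normalized
#' parameter units.
#'
#' @param pred,truth numeric matrices of equal shape (n x 6).
#' @return scalar loss.
#' @export
mseLoss <- function(pred, truth) {
  pred <- as.matrix(pred)
  truth <- as.matrix(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have identical shapes")
  mean((pred - truth)^2)
}

# ---- model ------------------------------------------------------------------

.init_head <- function(cfg) {
  D <- length(cfg$depths) * cfg$fpnDim
  h <- cfg$headDims
  c(.setNames2(.init_linear(2L * D, h[1]), c("W1", "b1")),
    .setNames2(.init_linear(h[1], h[2]), c("W2", "b2")),
    .setNames2(.init_linear(h[2], 6L), c("W3", "b3")))
}

.setNames2 <- function(x, nm) { names(x) <- nm; x }

#' Initialize a pose-regression model
#'
#' Creates the dual-channel model with seeded weights: a shared (or
#' per-channel) encoder and the fully connected regression head. Pose
#' parameters are standardized for training by the capture range's
#' midpoint and half-width, which balances degree and millimetre scales
#' in the shared loss; the normalization travels with the model.
#'
#' @param config an [encoderConfig()].
#' @param range the [CaptureRange-class] poses will be drawn from (sets
#'   the normalization).
#' @param seed integer seed for weight initialization.
#' @return an object of class \code{PoseModel}.
#' @export
initPoseModel <- function(config = encoderConfig(),
                          range = captureRangePreset("chest"), seed = 1L) {
  stopifnot(inherits(config, "EncoderConfig"), is(range, "CaptureRange"))
  hw <- rangeHalfWidth(range)
  hw[hw == 0] <- 1
  params <- .with_seed(as.integer(seed), {
    p <- list(encoder = .init_encoder(config), head = .init_head(config))
    if (!config$sharedEncoder) p$encoder2 <- .init_encoder(config)
    p
  })
  structure(list(config = config, params = params,
                 norm = list(mid = rangeMidpoint(range), halfw = hw)),
            class = "PoseModel")
}

.as_image_array <- function(images, S) {
  if (is.array(images) && length(dim(images)) == 3L) {
    stopifnot(dim(images)[1] == S, dim(images)[2] == S)
    return(images)
  }
  if (is.matrix(images)) images <- list(images)
  stopifnot(is.list(images), length(images) >= 1)
  arr <- array(0, c(S, S, length(images)))
  for (i in seq_along(images)) {
    if (!is.matrix(images[[i]]) || nrow(images[[i]]) != S ||
        ncol(images[[i]]) != S)
      stop("each image must be a ", S, " x ", S, " matrix; got ",
           nrow(images[[i]]), " x ", ncol(images[[i]]))
    arr[, , i] <- images[[i]]
  }
  arr
}

#' Encode images to pyramid feature vectors
#'
#' Runs the encoder of one channel, producing one pooled multi-scale
#' feature vector per image (length 4 x pyramid width; 3072 with default
#' settings).
#'
#' @param model a [initPoseModel()] model.
#' @param images matrix, list of matrices, or (S, S, n) array of
#'   preprocessed images in [0, 1].
#' @param channel 1 (moving) or 2 (reference); distinct only for
#'   unshared encoders.
#' @return n x outputDim feature matrix.
#' @export
encodeImages <- function(model, images, channel = 1L) {
  stopifnot(inherits(model, "PoseModel"))
  arr <- .as_image_array(images, model$config$inputSize)
  enc <- if (channel == 2L && !model$config$sharedEncoder)
    model$params$encoder2 else model$params$encoder
  .encode_fwd(enc, model$config, arr, keep = FALSE)$out
}

#' Precompute reference-channel features
#'
#' The reference image is fixed across predictions, so its encoding can
#' be computed once and served from cache.
#'
#' @inheritParams encodeImages
#' @param reference the preprocessed reference image.
#' @return a length-outputDim feature vector.
#' @export
referenceFeatures <- function(model, reference) {
  drop(encodeImages(model, reference, channel = 2L))
}

.head_fwd <- function(Z, hp, dropout = 0, keep = FALSE) {
  h1p <- .linear_fwd(Z, hp$W1, hp$b1)
  h1 <- .relu_fwd(h1p)
  mask <- NULL
  if (dropout > 0) {
    mask <- matrix(stats::rbinom(length(h1), 1L, 1 - dropout) /
                     (1 - dropout), nrow(h1), ncol(h1))
    h1 <- h1 * mask
  }
  h2p <- .linear_fwd(h1, hp$W2, hp$b2)
  h2 <- .relu_fwd(h2p)
  out <- .linear_fwd(h2, hp$W3, hp$b3)
  list(out = out,
       cache = if (keep) list(Z = Z, h1p = h1p, h1 = h1, mask = mask,
                              h2p = h2p, h2 = h2))
}

.head_bwd <- function(dOut, hp, cache) {
  g <- list()
  lb3 <- .linear_bwd(dOut, cache$h2, hp$W3)
  g$W3 <- lb3$dW; g$b3 <- lb3$db
  dh2p <- lb3$dX * (cache$h2p > 0)
  lb2 <- .linear_bwd(dh2p, cache$h1, hp$W2)
  g$W2 <- lb2$dW; g$b2 <- lb2$db
  dh1 <- lb2$dX
  if (!is.null(cache$mask)) dh1 <- dh1 * cache$mask
  dh1p <- dh1 * (cache$h1p > 0)
  lb1 <- .linear_bwd(dh1p, cache$Z, hp$W1)
  g$W1 <- lb1$dW; g$b1 <- lb1$db
  list(dZ = lb1$dX, grads = g)
}

#' Predict the 6-DOF pose of a radiograph
#'
#' Feeds the moving image and the reference image through the two encoder
#' channels, concatenates their feature vectors and applies the regression
#' head. Predictions are denormalized back to degrees and millimetres.
#'
#' @param model a trained [initPoseModel()] model.
#' @param moving one preprocessed image (matrix) or several (list/array).
#' @param reference the preprocessed reference image; ignored when
#'   \code{refFeatures} is given.
#' @param refFeatures optional precomputed [referenceFeatures()].
#' @param normalized return normalized training units instead of
#'   degrees/mm.
#' @return a [Pose6-class] for a single image, else an n x 6 matrix.
#' @export
predictPose <- function(model, moving, reference = NULL, refFeatures = NULL,
                        normalized = FALSE) {
  stopifnot(inherits(model, "PoseModel"))
  single <- is.matrix(moving)
  encM <- encodeImages(model, moving, channel = 1L)
  if (is.null(refFeatures)) {
    if (is.null(reference))
      stop("either reference or refFeatures must be supplied")
    refFeatures <- referenceFeatures(model, reference)
  }
  if (length(refFeatures) != ncol(encM))
    stop("refFeatures length does not match the encoder output")
  Z <- cbind(encM, matrix(refFeatures, nrow(encM), length(refFeatures),
                          byrow = TRUE))
  pred <- .head_fwd(Z, model$params$head)$out
  if (!normalized)
    pred <- pred * rep(model$norm$halfw, each = nrow(pred)) +
      rep(model$norm$mid, each = nrow(pred))
  colnames(pred) <- .POSE_NAMES
  if (single) do.call(pose6, as.list(pred[1, ])) else pred
}

# ---- training ---------------------------------------------------------------

#' Train the pose regressor
#'
#' Minimizes the mean squared error between predicted and true poses (in
#' normalized units) with Adam. Deterministic under \code{seed}: weight
#' initialization (if \code{model} is a config), shuffling and dropout all
#' draw from one seeded stream.
#'
#' @param model a \code{PoseModel} (or an [encoderConfig()], in which case
#'   a fresh model is initialized for \code{range}).
#' @param images training images: list of matrices or (S, S, n) array.
#' @param labels n x 6 matrix of true poses (degrees/mm).
#' @param reference the preprocessed reference image.
#' @param range [CaptureRange-class] for normalization when initializing.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param lr Adam learning rate: a scalar, or a vector recycled to one
#'   rate per epoch (a step-decay schedule). The clinical-scale default
#'   is 1e-5; desk-scale runs converge in fewer epochs with larger rates
#'   decayed over the run.
#' @param valFraction fraction of the data held out for per-epoch
#'   validation loss.
#' @param seed integer seed.
#' @param verbose print per-epoch losses.
#' @return list with the trained \code{model} and a \code{history}
#'   data.frame (epoch, trainLoss, valLoss).
#' @export
trainPoseModel <- function(model, images, labels, reference,
                           range = captureRangePreset("chest"),
                           epochs = 10L, batchSize = 32L, lr = 1e-5,
                           valFraction = 0, seed = 1L, verbose = FALSE) {
  if (inherits(model, "EncoderConfig"))
    model <- initPoseModel(model, range, seed = seed)
  stopifnot(inherits(model, "PoseModel"))
  cfg <- model$config
  if (length(images) == 0)
    stop("training dataset is empty")
  arr <- .as_image_array(images, cfg$inputSize)
  n <- dim(arr)[3]
  labels <- .as_pose_matrix(labels)
  if (nrow(labels) != n) stop("need one label per image")
  if (n < 1) stop("training set is empty")
  refArr <- .as_image_array(reference, cfg$inputSize)
  Yn <- (labels - rep(model$norm$mid, each = n)) /
    rep(model$norm$halfw, each = n)

  params <- model$params
  shared <- cfg$sharedEncoder
  lr_epoch <- rep_len(lr, epochs)
  history <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                        valLoss = numeric(0))
  .with_seed(as.integer(seed) + 1L, {
    idx <- sample.int(n)
    nval <- floor(valFraction * n)
    val <- if (nval > 0) idx[seq_len(nval)] else integer(0)
    tr <- if (nval > 0) idx[-seq_len(nval)] else idx
    state <- new.env(parent = emptyenv())
    state$t <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample(tr)
      losses <- numeric(0)
      for (start in seq(1, length(ord), by = batchSize)) {
        bi <- ord[start:min(start + batchSize - 1, length(ord))]
        B <- length(bi)
        ef <- .encode_fwd(params$encoder, cfg,
                          arr[, , bi, drop = FALSE], keep = TRUE)
        encR <- if (shared)
          .encode_fwd(params$encoder, cfg, refArr, keep = TRUE)
        else .encode_fwd(params$encoder2, cfg, refArr, keep = TRUE)
        Z <- cbind(ef$out, matrix(encR$out, B, ncol(encR$out),
                                  byrow = TRUE))
        hf <- .head_fwd(Z, params$head, dropout = cfg$dropout, keep = TRUE)
        resid <- hf$out - Yn[bi, , drop = FALSE]
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop("training aborted: non-finite loss at epoch ", ep,
               " (lr too high or degenerate inputs)")
        losses <- c(losses, loss)
        dPred <- 2 * resid / length(resid)
        hb <- .head_bwd(dPred, params$head, hf$cache)
        D <- ncol(ef$out)
        dEncM <- hb$dZ[, 1:D, drop = FALSE]
        dEncR <- matrix(colSums(hb$dZ[, (D + 1):(2 * D), drop = FALSE]),
                        1, D)
        gM <- .encode_bwd(dEncM, params$encoder, cfg, ef$cache)
        gR <- if (shared)
          .encode_bwd(dEncR, params$encoder, cfg, encR$cache)
        else .encode_bwd(dEncR, params$encoder2, cfg, encR$cache)
        grads <- if (shared)
          list(encoder = .tree_add(gM, gR), head = hb$grads)
        else list(encoder = gM, head = hb$grads, encoder2 = gR)
        upd <- .adam_step(params, grads, state, lr_epoch[ep])
        params <- upd$params
        state <- upd$state
      }
      valLoss <- NA_real_
      if (nval > 0) {
        model$params <- params
        pv <- predictPose(model, arr[, , val, drop = FALSE],
                          reference = refArr[, , 1], normalized = TRUE)
        valLoss <- mean((pv - Yn[val, , drop = FALSE])^2)
      }
      history <- rbind(history,
                       data.frame(epoch = ep, trainLoss = mean(losses),
                                  valLoss = valLoss))
      if (verbose)
        message(sprintf("epoch %d: train %.5f val %s", ep, mean(losses),
                        format(valLoss, digits = 4)))
    }
  })
  model$params <- params
  list(model = model, history = history)
}

#' Save and load model checkpoints
#'
#' Checkpoints embed the configuration, all weights and the pose
#' normalization; reloading restores bit-identical predictions.
#'
#' @param model a \code{PoseModel}.
#' @param path checkpoint path (.rds).
#' @name model-io
#' @export
saveModel <- function(model, path) {
  stopifnot(inherits(model, "PoseModel"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname model-io
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path)
  structure(readRDS(path), class = "PoseModel")
}
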