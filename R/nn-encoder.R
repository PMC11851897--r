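# The hierarchical shifted-window attention encoder with SE channel
# reweighting and feature-pyramid fusion, with hand-written forward and
# backward passes.

#' Encoder configuration
#'
#' Architecture hyperparameters of the pose-regression encoder. The
#' defaults give the standard hierarchy for 224 x 224 inputs: 4 x 4 patch
#' tokens (56 x 56 grid), embedding width 96 doubling at each of three
#' patch-merging steps (96, 192, 384, 768), paired attention blocks per
#' stage with depths (2, 2, 6, 2) and heads (3, 6, 12, 24), 7 x 7
#' attention windows alternating between aligned and half-window-shifted
#' placement, SE reduction 16, and a 768-channel feature pyramid whose
#' four pooled levels concatenate to a 3072-vector per image channel.
#'
#' @param inputSize input image side, pixels; must be divisible by
#'   \code{patchSize * 2^(number of stages - 1)}.
#' @param patchSize pixels per token side.
#' @param window attention window side M; grids not divisible by M are
#'   zero-padded and the padding masked out of attention.
#' @param embedDim channel width after the linear embedding.
#' @param depths attention blocks per stage; each must be even (blocks
#'   pair an aligned-window with a shifted-window layer).
#' @param heads attention heads per stage; must divide the stage width.
#' @param mlpRatio hidden-width multiple of the per-block MLP.
#' @param seReduction SE bottleneck reduction ratio r.
#' @param fpnDim pyramid channel width; default \code{embedDim * 2^(n-1)}
#'   (the deepest stage width).
#' @param headDims hidden widths of the regression head.
#' @param dropout dropout rate in the regression head (training only).
#' @param sharedEncoder use one set of encoder weights for both image
#'   channels (siamese); FALSE trains the channels separately.
#' @return a classed list of validated settings.
#' @export
encoderConfig <- function(inputSize = 224L, patchSize = 4L, window = 7L,
                          embedDim = 96L, depths = c(2L, 2L, 6L, 2L),
                          heads = c(3L, 6L, 12L, 24L), mlpRatio = 4,
                          seReduction = 16L, fpnDim = NULL,
                          headDims = c(1024L, 256L), dropout = 0.2,
                          sharedEncoder = TRUE) {
  ns <- length(depths)
  if (ns != length(heads)) stop("depths and heads must have equal length")
  if (any(depths %% 2 != 0))
    stop("stage depths must be even: attention blocks come in ",
         "aligned/shifted pairs")
  if (inputSize %% patchSize != 0)
    stop("inputSize must be divisible by patchSize")
  G1 <- inputSize %/% patchSize
  if (G1 %% (2^(ns - 1)) != 0)
    stop("token grid must be divisible by 2^(stages - 1) for patch merging")
  widths <- embedDim * 2^(0:(ns - 1))
  if (any(widths %% heads != 0))
    stop("heads must divide the stage channel width")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (is.null(fpnDim)) fpnDim <- widths[ns]
  grids <- as.integer(G1 %/% 2^(0:(ns - 1)))
  # a stage whose grid is no larger than the window uses one whole-grid
  # window and no shift (the shifted layer would be a no-op)
  winEff <- pmin(as.integer(window), grids)
  shifts <- ifelse(winEff < grids, winEff %/% 2L, 0L)
  structure(list(inputSize = as.integer(inputSize),
                 patchSize = as.integer(patchSize),
                 window = as.integer(window),
                 embedDim = as.integer(embedDim),
                 depths = as.integer(depths), heads = as.integer(heads),
                 mlpRatio = mlpRatio, seReduction = as.integer(seReduction),
                 fpnDim = as.integer(fpnDim),
                 headDims = as.integer(headDims), dropout = dropout,
                 sharedEncoder = isTRUE(sharedEncoder),
                 widths = as.integer(widths), grids = grids,
                 winEff = as.integer(winEff), shifts = as.integer(shifts)),
            class = "EncoderConfig")
}

#' @describeIn encoderConfig a miniature configuration for desk-scale
#'   training studies: 64 x 64 inputs, embedding width 24, depths
#'   (2, 2, 2, 2), and a small regression head.
#' @export
miniEncoderConfig <- function(inputSize = 64L, embedDim = 24L,
                              depths = c(2L, 2L, 2L, 2L),
                              heads = c(3L, 6L, 12L, 24L),
                              seReduction = 4L,
                              headDims = c(256L, 64L), dropout = 0.2) {
  encoderConfig(inputSize = inputSize, embedDim = embedDim, depths = depths,
                heads = heads, seReduction = seReduction,
                headDims = headDims, dropout = dropout)
}

#' Shape contract of an encoder configuration
#'
#' @param config an [encoderConfig()].
#' @return list with the token grid sides per stage, channel widths per
#'   stage, pooled pyramid width, and encoder output length.
#' @export
encoderShapes <- function(config) {
  stopifnot(inherits(config, "EncoderConfig"))
  list(patchGrid = config$grids[1], grids = config$grids,
       widths = config$widths, pooledDim = config$fpnDim,
       outputDim = length(config$depths) * config$fpnDim,
       headInputDim = 2L * length(config$depths) * config$fpnDim)
}

# ---- parameter initialization -----------------------------------------------

.tnorm <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

.init_linear <- function(nin, nout, sd = 0.02, bias = TRUE) {
  out <- list(W = matrix(.tnorm(nin * nout, sd), nin, nout))
  if (bias) out$b <- numeric(nout)
  out
}

.init_block <- function(C, heads, M, mlpRatio) {
  qkv <- .init_linear(C, 3L * C)
  proj <- .init_linear(C, C)
  mlp1 <- .init_linear(C, round(mlpRatio * C))
  mlp2 <- .init_linear(round(mlpRatio * C), C)
  list(ln1G = rep(1, C), ln1B = numeric(C),
       Wqkv = qkv$W, bqkv = qkv$b, Wo = proj$W, bo = proj$b,
       relTab = matrix(.tnorm((2 * M - 1)^2 * heads),
                       (2 * M - 1)^2, heads),
       ln2G = rep(1, C), ln2B = numeric(C),
       W1 = mlp1$W, b1 = mlp1$b, W2 = mlp2$W, b2 = mlp2$b)
}

.init_encoder <- function(cfg) {
  p2 <- cfg$patchSize^2
  ns <- length(cfg$depths)
  emb <- .init_linear(p2, cfg$embedDim)
  params <- list(embed = list(W = emb$W, b = emb$b,
                              lnG = rep(1, cfg$embedDim),
                              lnB = numeric(cfg$embedDim)),
                 stages = vector("list", ns),
                 merges = vector("list", ns),
                 se = vector("list", ns),
                 fpn = vector("list", ns))
  for (s in seq_len(ns)) {
    C <- cfg$widths[s]
    params$stages[[s]] <- lapply(seq_len(cfg$depths[s]), function(i)
      .init_block(C, cfg$heads[s], cfg$winEff[s], cfg$mlpRatio))
    if (s > 1) {
      Cin <- cfg$widths[s - 1]
      params$merges[[s]] <- list(lnG = rep(1, 4 * Cin),
                                 lnB = numeric(4 * Cin),
                                 W = matrix(.tnorm(4 * Cin * C), 4 * Cin, C))
    } else params$merges[[s]] <- list(unused = numeric(0))
    Cr <- max(1L, C %/% cfg$seReduction)
    se1 <- .init_linear(C, Cr)
    se2 <- .init_linear(Cr, C)
    params$se[[s]] <- list(W1 = se1$W, b1 = se1$b, W2 = se2$W, b2 = se2$b)
    lat <- .init_linear(C, cfg$fpnDim)
    params$fpn[[s]] <- list(W = lat$W, b = lat$b)
  }
  params
}

# ---- attention block --------------------------------------------------------

.block_fwd <- function(X, p, plan, wb, heads, keep = FALSE) {
  C <- ncol(X)
  dh <- C %/% heads
  M2 <- plan$M^2
  ln1 <- .ln_fwd(X, p$ln1G, p$ln1B)
  QKV <- .linear_fwd(ln1$y, p$Wqkv, p$bqkv)
  scale <- 1 / sqrt(dh)
  af <- .cpp_wattn_fwd(QKV, wb$gidx, wb$pad, wb$inv, M2, C, heads,
                       plan$nW, p$relTab, .relpos_index(plan$M),
                       plan$maskCube, plan$useMask, scale, keep)
  attn <- af$attn
  proj <- .linear_fwd(attn, p$Wo, p$bo)
  X1 <- X + proj
  ln2 <- .ln_fwd(X1, p$ln2G, p$ln2B)
  H1p <- .linear_fwd(ln2$y, p$W1, p$b1)
  H1 <- .gelu_fwd(H1p)
  out <- X1 + .linear_fwd(H1, p$W2, p$b2)
  cache <- if (keep)
    list(X = X, ln1 = ln1, QKVw = af$QKVw, A = af$A, attn = attn,
         X1 = X1, ln2 = ln2, H1p = H1p, H1 = H1, heads = heads,
         plan = plan, wb = wb)
  list(out = out, cache = cache)
}

.block_bwd <- function(dOut, p, cache) {
  C <- ncol(cache$X)
  heads <- cache$heads
  dh <- C %/% heads
  plan <- cache$plan
  M2 <- plan$M^2
  g <- list()
  # MLP branch
  lb2 <- .linear_bwd(dOut, cache$H1, p$W2)
  g$W2 <- lb2$dW; g$b2 <- lb2$db
  dH1p <- .gelu_bwd(lb2$dX, cache$H1p)
  lb1 <- .linear_bwd(dH1p, cache$ln2$y, p$W1)
  g$W1 <- lb1$dW; g$b1 <- lb1$db
  ln2b <- .ln_bwd(lb1$dX, cache$ln2, p$ln2G)
  g$ln2G <- ln2b$dg; g$ln2B <- ln2b$db
  dX1 <- dOut + ln2b$dX
  # projection
  lbo <- .linear_bwd(dX1, cache$attn, p$Wo)
  g$Wo <- lbo$dW; g$bo <- lbo$db
  scale <- 1 / sqrt(dh)
  ab <- .cpp_wattn_bwd(cache$QKVw, cache$A, lbo$dX, cache$wb$gidx,
                       cache$wb$inv, M2, C, heads,
                       .relpos_index(plan$M), (2 * plan$M - 1)^2, scale)
  g$relTab <- ab$dTab
  lbq <- .linear_bwd(ab$dQKV, cache$ln1$y, p$Wqkv)
  g$Wqkv <- lbq$dW; g$bqkv <- lbq$db
  ln1b <- .ln_bwd(lbq$dX, cache$ln1, p$ln1G)
  g$ln1G <- ln1b$dg; g$ln1B <- ln1b$db
  list(dX = dX1 + ln1b$dX, grads = g)
}

# ---- patch merging ----------------------------------------------------------

# Gather indices for 2x2 neighborhood grouping on a G x G grid.
.merge_index <- function(G) {
  .plan_cache(sprintf("mi_%d", G), function() {
    g <- G %/% 2L
    x <- rep(seq_len(g), times = g)
    y <- rep(seq_len(g), each = g)
    at <- function(yy, xx) xx + (yy - 1L) * G
    cbind(at(2 * y - 1, 2 * x - 1), at(2 * y, 2 * x - 1),
          at(2 * y - 1, 2 * x), at(2 * y, 2 * x))
  })
}

.merge_batch_index <- function(G, B) {
  .plan_cache(sprintf("mib_%d_%d", G, B), function() {
    mi <- .merge_index(G)
    Nn <- nrow(mi)
    N <- G * G
    do.call(cbind, lapply(1:4, function(k)
      rep(mi[, k], B) + rep((0:(B - 1)) * N, each = Nn)))
  })
}

.merge_fwd <- function(X, p, G, B, keep = FALSE) {
  if (G %% 2 != 0) stop("patch merging requires an even grid")
  mib <- .merge_batch_index(G, B)
  cat4 <- cbind(X[mib[, 1], , drop = FALSE], X[mib[, 2], , drop = FALSE],
                X[mib[, 3], , drop = FALSE], X[mib[, 4], , drop = FALSE])
  ln <- .ln_fwd(cat4, p$lnG, p$lnB)
  out <- ln$y %*% p$W
  list(out = out,
       cache = if (keep) list(cat4 = cat4, ln = ln, G = G, B = B,
                              nIn = nrow(X)))
}

.merge_bwd <- function(dOut, p, cache) {
  g <- list()
  g$W <- crossprod(cache$ln$y, dOut)
  dlny <- tcrossprod(dOut, p$W)
  lnb <- .ln_bwd(dlny, cache$ln, p$lnG)
  g$lnG <- lnb$dg; g$lnB <- lnb$db
  C <- ncol(lnb$dX) %/% 4L
  mib <- .merge_batch_index(cache$G, cache$B)
  dX <- matrix(0, cache$nIn, C)
  for (k in 1:4)
    dX[mib[, k], ] <- lnb$dX[, ((k - 1) * C + 1):(k * C), drop = FALSE]
  list(dX = dX, grads = g)
}

# ---- squeeze-and-excitation -------------------------------------------------

.se_fwd <- function(X, p, B, keep = FALSE) {
  N <- nrow(X) %/% B
  grp <- rep(seq_len(B), each = N)
  s <- rowsum(X, grp) / N
  z1p <- .linear_fwd(s, p$W1, p$b1)
  z1 <- .relu_fwd(z1p)
  z2p <- .linear_fwd(z1, p$W2, p$b2)
  w <- 1 / (1 + exp(-z2p))
  out <- X * w[grp, , drop = FALSE]
  list(out = out, weights = w,
       cache = if (keep) list(X = X, s = s, z1p = z1p, z1 = z1, w = w,
                              grp = grp, N = N))
}

.se_bwd <- function(dOut, p, cache) {
  g <- list()
  grp <- cache$grp
  dX <- dOut * cache$w[grp, , drop = FALSE]
  dw <- rowsum(dOut * cache$X, grp)
  dz2p <- dw * cache$w * (1 - cache$w)
  g$W2 <- crossprod(cache$z1, dz2p); g$b2 <- colSums(dz2p)
  dz1 <- tcrossprod(dz2p, p$W2)
  dz1p <- dz1 * (cache$z1p > 0)
  g$W1 <- crossprod(cache$s, dz1p); g$b1 <- colSums(dz1p)
  ds <- tcrossprod(dz1p, p$W1)
  dX <- dX + ds[grp, , drop = FALSE] / cache$N
  list(dX = dX, grads = g)
}

# ---- feature pyramid --------------------------------------------------------

# stageX: list of (B*Ns x Cs) reweighted stage outputs; top-down fusion
# with bilinear x2 upsampling, then per-level global average pooling.
.fpn_fwd <- function(stageX, params, cfg, B, keep = FALSE) {
  ns <- length(stageX)
  Fdim <- cfg$fpnDim
  L <- vector("list", ns)
  for (s in seq_len(ns))
    L[[s]] <- .linear_fwd(stageX[[s]], params$fpn[[s]]$W,
                          params$fpn[[s]]$b)
  P <- vector("list", ns)
  P[[ns]] <- L[[ns]]
  for (s in (ns - 1):1) {
    up <- .upsample_operator(cfg$grids[s + 1])$P
    N <- cfg$grids[s + 1]^2
    # fold samples into columns so one sparse multiply serves the batch
    m <- P[[s + 1]]
    dim(m) <- NULL
    m <- matrix(m, N, B * Fdim)
    upX <- as.matrix(up %*% m)
    dim(upX) <- NULL
    P[[s]] <- L[[s]] + matrix(upX, B * 4 * N, Fdim)
  }
  pooled <- vector("list", ns)
  for (s in seq_len(ns)) {
    N <- cfg$grids[s]^2
    pooled[[s]] <- rowsum(P[[s]], rep(seq_len(B), each = N)) / N
  }
  out <- do.call(cbind, pooled)
  list(out = out, cache = if (keep) list(stageX = stageX, B = B))
}

.fpn_bwd <- function(dOut, params, cfg, cache) {
  ns <- length(cache$stageX)
  B <- cache$B
  Fdim <- cfg$fpnDim
  dP <- vector("list", ns)
  for (s in seq_len(ns)) {
    N <- cfg$grids[s]^2
    dpool <- dOut[, ((s - 1) * Fdim + 1):(s * Fdim), drop = FALSE]
    dP[[s]] <- dpool[rep(seq_len(B), each = N), , drop = FALSE] / N
  }
  # push fused gradients up the pyramid (reverse of top-down fusion)
  for (s in seq_len(ns - 1)) {
    upT <- .upsample_operator(cfg$grids[s + 1])$Pt
    N <- cfg$grids[s + 1]^2
    m <- dP[[s]]
    dim(m) <- NULL
    m <- matrix(m, 4 * N, B * Fdim)
    add <- as.matrix(upT %*% m)
    dim(add) <- NULL
    dP[[s + 1]] <- dP[[s + 1]] + matrix(add, B * N, Fdim)
  }
  grads <- vector("list", ns)
  dStage <- vector("list", ns)
  for (s in seq_len(ns)) {
    lb <- .linear_bwd(dP[[s]], cache$stageX[[s]], params$fpn[[s]]$W)
    grads[[s]] <- list(W = lb$dW, b = lb$db)
    dStage[[s]] <- lb$dX
  }
  list(dStage = dStage, grads = grads)
}

# ---- full encoder -----------------------------------------------------------

# imgs: array (S, S, B). Returns (B x ns*fpnDim) features.
.encode_fwd <- function(params, cfg, imgs, keep = FALSE) {
  S <- cfg$inputSize
  B <- dim(imgs)[3]
  ns <- length(cfg$depths)
  p2 <- cfg$patchSize^2
  N1 <- cfg$grids[1]^2
  pidx <- .patch_index(S, cfg$patchSize)
  pidxB <- pidx[rep(seq_len(N1), B), , drop = FALSE] +
    rep((0:(B - 1)) * S * S, each = N1)
  X0 <- matrix(imgs[pidxB], B * N1, p2)
  X <- .linear_fwd(X0, params$embed$W, params$embed$b)
  ln <- .ln_fwd(X, params$embed$lnG, params$embed$lnB)
  X <- ln$y
  cache <- if (keep) list(X0 = X0, embed_ln = ln, B = B)
  stage_caches <- vector("list", ns)
  stageX <- vector("list", ns)
  for (s in seq_len(ns)) {
    G <- cfg$grids[s]
    N <- G * G
    if (s > 1) {
      mf <- .merge_fwd(X, params$merges[[s]], 2L * G, B, keep)
      X <- mf$out
      if (keep) stage_caches[[s]]$merge <- mf$cache
    }
    plans <- list(.win_plan(G, G, cfg$winEff[s], 0L),
                  .win_plan(G, G, cfg$winEff[s], cfg$shifts[s]))
    blocks <- params$stages[[s]]
    if (keep) stage_caches[[s]]$blocks <- vector("list", length(blocks))
    for (i in seq_along(blocks)) {
      plan <- plans[[2L - i %% 2L]]
      wb <- .win_batch(plan, B, N)
      bf <- .block_fwd(X, blocks[[i]], plan, wb, cfg$heads[s], keep)
      X <- bf$out
      if (keep) stage_caches[[s]]$blocks[[i]] <- bf$cache
    }
    sf <- .se_fwd(X, params$se[[s]], B, keep)
    X <- sf$out
    if (keep) stage_caches[[s]]$se <- sf$cache
    stageX[[s]] <- X
  }
  ff <- .fpn_fwd(stageX, params, cfg, B, keep)
  if (keep) {
    cache$stages <- stage_caches
    cache$fpn <- ff$cache
  }
  list(out = ff$out, cache = cache)
}

.encode_bwd <- function(dOut, params, cfg, cache) {
  ns <- length(cfg$depths)
  B <- cache$B
  fb <- .fpn_bwd(dOut, params, cfg, cache$fpn)
  grads <- list(embed = NULL, stages = vector("list", ns),
                merges = vector("list", ns), se = vector("list", ns),
                fpn = fb$grads)
  dX <- NULL
  for (s in ns:1) {
    dS <- fb$dStage[[s]]
    if (!is.null(dX)) dS <- dS + dX
    sb <- .se_bwd(dS, params$se[[s]], cache$stages[[s]]$se)
    grads$se[[s]] <- sb$grads
    dX <- sb$dX
    blocks <- params$stages[[s]]
    grads$stages[[s]] <- vector("list", length(blocks))
    for (i in rev(seq_along(blocks))) {
      bb <- .block_bwd(dX, blocks[[i]], cache$stages[[s]]$blocks[[i]])
      grads$stages[[s]][[i]] <- bb$grads
      dX <- bb$dX
    }
    if (s > 1) {
      mb <- .merge_bwd(dX, params$merges[[s]], cache$stages[[s]]$merge)
      grads$merges[[s]] <- mb$grads
      dX <- mb$dX
    } else grads$merges[[s]] <- list(unused = numeric(0))
  }
  lnb <- .ln_bwd(dX, cache$embed_ln, params$embed$lnG)
  lbe <- .linear_bwd(lnb$dX, cache$X0, params$embed$W)
  grads$embed <- list(W = lbe$dW, b = lbe$db, lnG = lnb$dg, lnB = lnb$db)
  grads
}
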