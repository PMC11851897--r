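# Fast, unit-level checks of the encoder components. Heavier end-to-end
# learning checks live in test-acceptance.R.

mini_cfg <- function(...) miniEncoderConfig(...)

tiny_cfg <- function() {
  encoderConfig(inputSize = 16L, patchSize = 4L, window = 3L,
                embedDim = 4L, depths = c(2L, 2L), heads = c(2L, 2L),
                mlpRatio = 2, seReduction = 2L, fpnDim = 8L,
                headDims = c(10L, 5L), dropout = 0)
}

sym_range <- function(w = 5) {
  captureRange(alpha = c(-w, w), beta = c(-w, w), theta = c(-w, w),
               dx = c(-w, w), dy = c(-w, w), dz = c(-w, w))
}

test_that("config validation enforces the architecture invariants", {
  expect_error(encoderConfig(depths = c(2, 3, 6, 2)), "pairs")
  expect_error(encoderConfig(inputSize = 225), "divisible")
  expect_error(encoderConfig(inputSize = 48), "patch merging")
  expect_error(encoderConfig(heads = c(5, 6, 12, 24)), "divide")
  sh <- encoderShapes(encoderConfig())
  expect_identical(sh$patchGrid, 56L)
  expect_identical(sh$grids, c(56L, 28L, 14L, 7L))
  expect_identical(sh$widths, c(96L, 192L, 384L, 768L))
  expect_identical(sh$pooledDim, 768L)
  expect_identical(sh$outputDim, 3072L)
})

test_that("patch partition tokenizes 4x4 blocks bijectively", {
  set.seed(1)
  img <- matrix(runif(224 * 224), 224)
  tok <- patchPartition(img, 4L)
  expect_identical(attr(tok, "grid"), 56L)
  expect_identical(ncol(tok), 16L)          # 4*4*1 pixels per token
  expect_identical(nrow(tok), 56L * 56L)
  expect_identical(patchReassemble(tok, 4L), img)
  expect_warning(patchPartition(matrix(0, 30, 30), 4L), "padding")
})

test_that("a 56-grid with 7-windows yields 64 attention windows", {
  plan <- drrpose:::.win_plan(56L, 56L, 7L, 0L)
  expect_identical(plan$nW, 64L)
  expect_false(plan$useMask)                # no padding, no shift
  planS <- drrpose:::.win_plan(56L, 56L, 7L, 3L)
  expect_true(planS$useMask)                # shifted windows are masked
})

test_that("degenerate attention (uniform weights) averages values per window", {
  # Q = K = 0 and zero bias make every attention row uniform, so the
  # output must equal the per-window mean of V
  G <- 6L; M <- 3L; C <- 4L
  set.seed(8)
  X <- matrix(rnorm(G * G * C), G * G, C)
  QKV <- cbind(matrix(0, G * G, 2 * C), X)  # V = X
  plan <- drrpose:::.win_plan(G, G, M, 0L)
  wb <- drrpose:::.win_batch(plan, 1L, G * G)
  af <- drrpose:::.cpp_wattn_fwd(QKV, wb$gidx, wb$pad, wb$inv,
                                 M^2, C, 2L, plan$nW,
                                 matrix(0, (2 * M - 1)^2, 2),
                                 drrpose:::.relpos_index(M),
                                 plan$maskCube, plan$useMask,
                                 1 / sqrt(C / 2), FALSE)
  # brute-force per-window averaging oracle
  expected <- X
  for (w in seq_len(plan$nW)) {
    rows <- plan$idx[((w - 1) * M^2 + 1):(w * M^2)]
    expected[rows, ] <- matrix(colMeans(X[rows, , drop = FALSE]),
                               M^2, C, byrow = TRUE)
  }
  expect_lt(max(abs(af$attn - expected)), 1e-12)
})

test_that("attention blocks preserve feature shape", {
  cfg <- tiny_cfg()
  model <- initPoseModel(cfg, sym_range(), seed = 2)
  p <- model$params$encoder$stages[[1]][[1]]
  G <- cfg$grids[1]
  plan <- drrpose:::.win_plan(G, G, cfg$winEff[1], 0L)
  wb <- drrpose:::.win_batch(plan, 2L, G * G)
  X <- matrix(rnorm(2 * G * G * cfg$embedDim), 2 * G * G, cfg$embedDim)
  out <- drrpose:::.block_fwd(X, p, plan, wb, cfg$heads[1])$out
  expect_identical(dim(out), dim(X))
})

test_that("patch merging halves the grid, doubles channels, permutes values", {
  G <- 8L; C <- 6L; B <- 2L
  set.seed(3)
  X <- matrix(rnorm(B * G * G * C), B * G * G, C)
  p <- list(lnG = rep(1, 4 * C), lnB = numeric(4 * C),
            W = diag(1, 4 * C, 2 * C))
  mf <- drrpose:::.merge_fwd(X, p, G, B, keep = TRUE)
  expect_equal(dim(mf$out), c(B * (G %/% 2)^2, 2L * C))
  # pre-projection concatenation is exactly a rearrangement of X
  expect_identical(sort(as.vector(mf$cache$cat4)), sort(as.vector(X)))
  # three merges of the default hierarchy: 56->28->14->7, 96->768
  cfg <- encoderConfig()
  expect_identical(cfg$grids, c(56L, 28L, 14L, 7L))
  expect_identical(cfg$widths[4], 768L)
})

test_that("SE gating stays in [0,1], gates multiplicatively and can be forced open", {
  C <- 8L; B <- 3L; N <- 16L
  set.seed(4)
  X <- matrix(rnorm(B * N * C), B * N, C)
  se1 <- drrpose:::.init_linear(C, 4L)
  se2 <- drrpose:::.init_linear(4L, C)
  p <- list(W1 = se1$W, b1 = se1$b, W2 = se2$W, b2 = se2$b)
  sf <- drrpose:::.se_fwd(X, p, B)
  expect_true(all(sf$weights >= 0 & sf$weights <= 1))
  expect_true(all(abs(sf$out) <= abs(X) + 1e-12))  # never amplifies
  # zero input -> zero output (multiplicative gate)
  expect_equal(drrpose:::.se_fwd(X * 0, p, B)$out, X * 0)
  # saturated excitation (huge positive bias) -> identity gate
  p2 <- list(W1 = se1$W * 0, b1 = se1$b * 0, W2 = se2$W * 0,
             b2 = rep(50, C))
  expect_equal(drrpose:::.se_fwd(X, p2, B)$out, X, tolerance = 1e-12)
})

test_that("feature pyramid pools each level to fpnDim and concatenates", {
  cfg <- tiny_cfg()
  model <- initPoseModel(cfg, sym_range(), seed = 5)
  B <- 2L
  stageX <- lapply(seq_along(cfg$depths), function(s)
    matrix(rnorm(B * cfg$grids[s]^2 * cfg$widths[s]),
           B * cfg$grids[s]^2, cfg$widths[s]))
  ff <- drrpose:::.fpn_fwd(stageX, model$params$encoder, cfg, B)
  expect_identical(dim(ff$out), c(B, length(cfg$depths) * cfg$fpnDim))
  # with zero top-stage features and zero lateral biases, the fused next
  # level equals its lateral projection alone
  par2 <- model$params$encoder
  for (s in seq_along(par2$fpn)) par2$fpn[[s]]$b[] <- 0
  stage0 <- stageX
  stage0[[length(stage0)]][] <- 0
  ff2 <- drrpose:::.fpn_fwd(stage0, par2, cfg, B)
  ns <- length(cfg$depths)
  lat <- stage0[[ns - 1]] %*% par2$fpn[[ns - 1]]$W
  pooled <- rowsum(lat, rep(seq_len(B), each = cfg$grids[ns - 1]^2)) /
    cfg$grids[ns - 1]^2
  got <- ff2$out[, ((ns - 2) * cfg$fpnDim + 1):((ns - 1) * cfg$fpnDim)]
  expect_equal(got, pooled, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("pose prediction is six-valued, deterministic and cache-consistent", {
  cfg <- tiny_cfg()
  rng <- sym_range()
  model <- initPoseModel(cfg, rng, seed = 6)
  set.seed(10)
  mov <- matrix(runif(256), 16)
  ref <- matrix(runif(256), 16)
  p1 <- predictPose(model, mov, reference = ref)
  expect_s4_class(p1, "Pose6")
  expect_identical(length(poseParams(p1)), 6L)
  p2 <- predictPose(model, mov, reference = ref)
  expect_identical(poseParams(p1), poseParams(p2))  # bit-stable
  rf <- referenceFeatures(model, ref)
  p3 <- predictPose(model, mov, refFeatures = rf)
  expect_lt(max(abs(poseParams(p3) - poseParams(p1))), 1e-6)
})

test_that("MSE loss matches the brute-force two-loop summation", {
  a <- matrix(1:12, 2)
  expect_equal(mseLoss(a, a), 0)
  expect_equal(mseLoss(a, a - 1), 1)
  set.seed(12)
  P <- matrix(rnorm(48), 8)
  Q <- matrix(rnorm(48), 8)
  s <- 0
  for (i in 1:8) for (j in 1:6) s <- s + (P[i, j] - Q[i, j])^2
  expect_lt(abs(mseLoss(P, Q) - s / 48), 1e-10)
  expect_error(mseLoss(P, Q[1:2, ]), "identical shapes")
})

test_that("attention-cost formulas evaluate exactly and cross over at M^2 = hw", {
  # window attention replaces the quadratic token term 2(hw)^2 C with
  # 2 M^2 hw C; both formulas share the projection term 4 hw C^2
  ac <- attentionCost(56, 56, 96, 7)
  hw <- 56 * 56
  expect_identical(ac$msa, 4 * hw * 96^2 + 2 * hw^2 * 96)
  expect_identical(ac$wmsa, 4 * hw * 96^2 + 2 * 49 * hw * 96)
  expect_lt(ac$wmsa, ac$msa)
  # coincide when the window covers the whole map
  ac2 <- attentionCost(7, 7, 32, 7)
  expect_identical(ac2$msa, ac2$wmsa)
  # quadratic-term ratio is hw / M^2
  expect_equal((ac$msa - 4 * hw * 96^2) / (ac$wmsa - 4 * hw * 96^2),
               hw / 49)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_cfg()
  model <- initPoseModel(cfg, sym_range(), seed = 3)
  set.seed(9)
  B <- 2L
  imgs <- array(runif(16 * 16 * B), c(16, 16, B))
  ref <- matrix(runif(256), 16, 16)
  Y <- matrix(runif(B * 6, -1, 1), B, 6)
  params <- model$params
  loss_fn <- function(params) {
    ef <- drrpose:::.encode_fwd(params$encoder, cfg, imgs)
    er <- drrpose:::.encode_fwd(params$encoder, cfg,
                                array(ref, c(16, 16, 1)))
    Z <- cbind(ef$out, matrix(er$out, B, ncol(er$out), byrow = TRUE))
    mean((drrpose:::.head_fwd(Z, params$head)$out - Y)^2)
  }
  ef <- drrpose:::.encode_fwd(params$encoder, cfg, imgs, keep = TRUE)
  er <- drrpose:::.encode_fwd(params$encoder, cfg,
                              array(ref, c(16, 16, 1)), keep = TRUE)
  Z <- cbind(ef$out, matrix(er$out, B, ncol(er$out), byrow = TRUE))
  hf <- drrpose:::.head_fwd(Z, params$head, keep = TRUE)
  dPred <- 2 * (hf$out - Y) / length(Y)
  hb <- drrpose:::.head_bwd(dPred, params$head, hf$cache)
  D <- ncol(ef$out)
  gM <- drrpose:::.encode_bwd(hb$dZ[, 1:D, drop = FALSE],
                              params$encoder, cfg, ef$cache)
  gR <- drrpose:::.encode_bwd(
    matrix(colSums(hb$dZ[, (D + 1):(2 * D), drop = FALSE]), 1, D),
    params$encoder, cfg, er$cache)
  g <- list(encoder = drrpose:::.tree_add(gM, gR), head = hb$grads)

  check_leaf <- function(path, nidx = 3) {
    leaf <- params
    ga <- g
    for (k in path) {
      leaf <- leaf[[k]]
      ga <- ga[[k]]
    }
    set.seed(sum(unlist(lapply(path, function(k)
      if (is.character(k)) utf8ToInt(k) else k))))
    idxs <- sample(length(leaf), min(nidx, length(leaf)))
    eps <- 1e-5
    for (ii in idxs) {
      p2 <- params
      ref_leaf <- leaf
      ref_leaf[ii] <- leaf[ii] + eps
      p2 <- .assign_path(p2, path, ref_leaf)
      f1 <- loss_fn(p2)
      ref_leaf[ii] <- leaf[ii] - eps
      p2 <- .assign_path(p2, path, ref_leaf)
      f0 <- loss_fn(p2)
      gn <- (f1 - f0) / (2 * eps)
      expect_lt(abs(gn - ga[ii]),
                1e-3 * max(abs(gn), abs(ga[ii])) + 1e-7)
    }
  }
  .assign_path <- function(tree, path, value) {
    if (length(path) == 1) {
      tree[[path[[1]]]] <- value
    } else {
      tree[[path[[1]]]] <- .assign_path(tree[[path[[1]]]],
                                        path[-1], value)
    }
    tree
  }
  check_leaf(list("encoder", "embed", "W"))
  check_leaf(list("encoder", "stages", 1L, 1L, "Wqkv"))
  check_leaf(list("encoder", "stages", 1L, 2L, "relTab"))
  check_leaf(list("encoder", "stages", 2L, 2L, "W1"))
  check_leaf(list("encoder", "merges", 2L, "W"))
  check_leaf(list("encoder", "se", 1L, "W2"))
  check_leaf(list("encoder", "fpn", 1L, "W"))
  check_leaf(list("head", "W1"))
})

test_that("training is deterministic under a seed and reduces the loss", {
  cfg <- tiny_cfg()
  rng <- sym_range()
  set.seed(20)
  n <- 12
  labels <- samplePoses(rng, n, seed = 2, asMatrix = TRUE)
  # images carry a simple pose-dependent signature so there is structure
  imgs <- lapply(seq_len(n), function(i) {
    m <- matrix(runif(256, 0, 0.2), 16)
    m[1:8, ] <- m[1:8, ] + labels[i, "dx"] / 20 + 0.3
    m
  })
  ref <- matrix(runif(256), 16)
  f1 <- trainPoseModel(cfg, imgs, labels, ref, range = rng, epochs = 3,
                       batchSize = 4, lr = 1e-2, seed = 7)
  f2 <- trainPoseModel(cfg, imgs, labels, ref, range = rng, epochs = 3,
                       batchSize = 4, lr = 1e-2, seed = 7)
  expect_identical(f1$history$trainLoss, f2$history$trainLoss)
  expect_lt(f1$history$trainLoss[3], f1$history$trainLoss[1])
  expect_error(trainPoseModel(cfg, list(), labels[0, ], ref, range = rng),
               "empty")
})

test_that("checkpoints restore bit-identical predictions", {
  cfg <- tiny_cfg()
  rng <- sym_range()
  model <- initPoseModel(cfg, rng, seed = 13)
  set.seed(5)
  mov <- matrix(runif(256), 16)
  ref <- matrix(runif(256), 16)
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "m.rds")
  saveModel(model, f)
  back <- loadModel(f)
  expect_identical(poseParams(predictPose(back, mov, reference = ref)),
                   poseParams(predictPose(model, mov, reference = ref)))
})
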