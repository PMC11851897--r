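# Low-level numerical machinery for the pose-regression encoder: index
# plans for patch/window partitioning, layer primitives with hand-written
# backward passes, parameter-tree utilities and the Adam optimizer.
#
# Feature maps are (tokens x channels) matrices; tokens are ordered
# row-major over the grid with x fastest (t = x + (y-1) * W). Batches are
# stacked sample-major along the token dimension.

# ---- cached index plans -----------------------------------------------------

.plan_cache <- function(key, builder) {
  hit <- .drrpose_cache[[key]]
  if (is.null(hit)) {
    hit <- builder()
    .drrpose_cache[[key]] <- hit
  }
  hit
}

# Linear pixel indices of each token's patch: (H*W) x p^2 matrix.
.patch_index <- function(S, p) {
  .plan_cache(sprintf("pi_%d_%d", S, p), function() {
    G <- S %/% p
    stopifnot(G * p == S)
    n <- G * G
    gx <- rep(seq_len(G), times = G)   # x fastest
    gy <- rep(seq_len(G), each = G)
    px <- rep(seq_len(p), each = p)    # within patch: (py fastest, col-major)
    py <- rep(seq_len(p), times = p)
    rows <- outer((gy - 1) * p, py, "+")   # n x p^2 image rows
    cols <- outer((gx - 1) * p, px, "+")
    rows + (cols - 1L) * S
  })
}

# Window-partition plan for an H x W grid, window M, cyclic shift s.
# idx: token source index (0 = zero padding) for every padded/rolled
# position, window-major then x-fastest within each window.
# masks: per-window M^2 x M^2 additive masks (NULL when unmasked).
.win_plan <- function(H, W, M, shift) {
  .plan_cache(sprintf("wp_%d_%d_%d_%d", H, W, M, shift), function() {
    Hp <- as.integer(ceiling(H / M) * M)
    Wp <- as.integer(ceiling(W / M) * M)
    region <- function(np) {
      if (shift == 0) return(rep(0L, np))
      r <- integer(np)
      r[seq_len(np) > np - M] <- 1L
      r[seq_len(np) > np - shift] <- 2L
      r
    }
    ry <- region(Hp)
    rx <- region(Wp)
    # rolled source coordinates for every padded position
    pos <- expand.grid(px = seq_len(Wp), py = seq_len(Hp))
    sy <- ((pos$py + shift - 1L) %% Hp) + 1L
    sx <- ((pos$px + shift - 1L) %% Wp) + 1L
    real <- sy <= H & sx <= W
    tok <- ifelse(real, sx + (sy - 1L) * W, 0L)
    lab <- ifelse(real, ry[sy] * 3L + rx[sx], -1L)
    # window-major gather order
    wy <- (pos$py - 1L) %/% M
    wx <- (pos$px - 1L) %/% M
    win <- wx + wy * (Wp %/% M)
    iy <- (pos$py - 1L) %% M
    ix <- (pos$px - 1L) %% M
    within <- ix + iy * M
    ord <- order(win, within)
    idx <- tok[ord]
    labs <- lab[ord]
    nW <- (Hp %/% M) * (Wp %/% M)
    M2 <- M * M
    maskCube <- array(0, c(M2, M2, nW))
    any_mask <- FALSE
    for (w in seq_len(nW)) {
      l <- labs[((w - 1) * M2 + 1):(w * M2)]
      if (length(unique(l)) > 1L) {
        mk <- matrix(0, M2, M2)
        mk[outer(l, l, "!=")] <- -1e9
        maskCube[, , w] <- mk
        any_mask <- TRUE
      }
    }
    if (!any_mask) maskCube <- array(0, c(1, 1, 1))
    list(H = H, W = W, M = M, shift = shift, Hp = Hp, Wp = Wp, nW = nW,
         idx = idx, maskCube = maskCube, useMask = any_mask)
  })
}

# Batched gather/scatter indices for a window plan.
.win_batch <- function(plan, B, N) {
  key <- sprintf("wb_%d_%d_%d_%d_%d_%d", plan$H, plan$W, plan$M,
                 plan$shift, B, N)
  .plan_cache(key, function() {
    n <- length(plan$idx)
    idxB <- rep(plan$idx, B) +
      rep((0:(B - 1)) * N, each = n) * (rep(plan$idx, B) > 0)
    # inverse permutation over real tokens for the backward scatter
    inv <- integer(B * N)
    real <- idxB > 0L
    inv[idxB[real]] <- which(real)
    list(idxB = idxB, gidx = pmax(idxB, 1L), inv = inv,
         pad = which(!real))
  })
}

.gather_win <- function(X, wb) {
  out <- X[wb$gidx, , drop = FALSE]
  if (length(wb$pad)) out[wb$pad, ] <- 0
  out
}

.scatter_win <- function(dXw, wb) {
  dXw[wb$inv, , drop = FALSE]
}

# Relative-position index within an M x M window (x fastest token order):
# M^2 x M^2 matrix of 1-based indices into a (2M-1)^2 table.
.relpos_index <- function(M) {
  .plan_cache(sprintf("rp_%d", M), function() {
    x <- rep(seq_len(M), times = M)
    y <- rep(seq_len(M), each = M)
    dx <- outer(x, x, function(a, b) b - a)
    dy <- outer(y, y, function(a, b) b - a)
    (dy + M - 1) * (2 * M - 1) + (dx + M - 1) + 1L
  })
}

# Bilinear x2 upsampling operator on token vectors (grid g -> 2g), sparse.
.upsample_operator <- function(g) {
  .plan_cache(sprintf("up_%d", g), function() {
    n <- 2L * g
    src <- pmin(pmax((seq_len(n) - 0.5) / 2 - 0.5, 0), g - 1)
    j0 <- floor(src)
    w1 <- src - j0
    j1 <- pmin(j0 + 1, g - 1)
    U <- Matrix::sparseMatrix(
      i = c(seq_len(n), seq_len(n)), j = c(j0 + 1, j1 + 1),
      x = c(1 - w1, w1), dims = c(n, g))
    P <- Matrix::kronecker(U, U)   # token order has x fastest
    list(P = P, Pt = Matrix::t(P))
  })
}

# ---- layer primitives -------------------------------------------------------

.linear_fwd <- function(X, W, b = NULL) .cpp_linear(X, W, b)

.linear_bwd <- function(dY, X, W, has_b = TRUE) {
  list(dX = tcrossprod(dY, W), dW = crossprod(X, dY),
       db = if (has_b) colSums(dY) else NULL)
}

.ln_fwd <- function(X, g, b) .cpp_ln_fwd(X, g, b)

.ln_bwd <- function(dY, cache, g) {
  out <- .cpp_ln_bwd(dY, cache$xhat, cache$inv, g)
  list(dX = out$dX, dg = drop(out$dg), db = drop(out$db))
}

.gelu_fwd <- function(X) .cpp_gelu_fwd(X)

.gelu_bwd <- function(dY, X) .cpp_gelu_bwd(dY, X)

.relu_fwd <- function(X) X * (X > 0)

.softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# ---- parameter-tree utilities ----------------------------------------------

.tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) .tree_map(f, x)) else f(tree)
}

.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    nmOK <- !is.null(names(a)) && !is.null(names(b)) &&
      all(names(a) %in% names(b))
    for (i in seq_along(a)) {
      bi <- if (nmOK) b[[names(a)[i]]] else b[[i]]
      out[[i]] <- .tree_map2(f, a[[i]], bi)
    }
    out
  } else f(a, b)
}

.tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  .tree_map2(`+`, a, b)
}

.tree_zero <- function(tree) .tree_map(function(x) x * 0, tree)

# One Adam step over a parameter tree; state holds first/second moments.
.adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  if (is.null(state$m)) {
    state$m <- .tree_zero(params)
    state$v <- .tree_zero(params)
  }
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- .tree_map(function(m) m / bc1, state$m)
  vh <- .tree_map(function(v) v / bc2, state$v)
  upd <- .tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mh, vh)
  list(params = .tree_map2(`-`, params, upd), state = state)
}
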