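# Intensity-based optimization registration: GradNCC similarity driven by
# Powell's direction-set method or CMA-ES, with the DRR renderer as the
# forward model.

#' Gradient normalized cross-correlation
#'
#' Computes central-difference image gradients along x and y for both
#' images, takes the normalized cross-correlation of each gradient
#' component, and returns their mean — a similarity in [-1, 1] that is
#' invariant to affine intensity changes and symmetric in its arguments.
#' A constant image has no gradient structure; the correlation is defined
#' as 0 there, with a warning.
#'
#' @param a,b numeric matrices of identical shape.
#' @return similarity value in [-1, 1].
#' @export
gradncc <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images must have identical shapes")
  ga <- .central_gradients(a)
  gb <- .central_gradients(b)
  nccs <- c(.ncc(ga$gx, gb$gx), .ncc(ga$gy, gb$gy))
  if (any(is.na(nccs))) {
    warning("constant image (zero gradient variance): GradNCC defined as 0")
    nccs[is.na(nccs)] <- 0
  }
  mean(nccs)
}

.central_gradients <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3 || nc < 3) stop("images must be at least 3 x 3")
  list(gx = (img[, 3:nc] - img[, 1:(nc - 2)])[2:(nr - 1), , drop = FALSE] / 2,
       gy = (img[3:nr, ] - img[1:(nr - 2), ])[, 2:(nc - 1), drop = FALSE] / 2)
}

.ncc <- function(u, v) {
  u <- as.vector(u) - mean(u)
  v <- as.vector(v) - mean(v)
  su <- sqrt(sum(u * u))
  sv <- sqrt(sum(v * v))
  if (su == 0 || sv == 0) return(NA_real_)
  sum(u * v) / (su * sv)
}

#' Optimization protocol for intensity-based registration
#'
#' @param method "powell" (direction-set) or "cmaes".
#' @param tol termination tolerance on the similarity change.
#' @param maxIter iteration cap: objective-improvement sweeps for Powell,
#'   generations for CMA-ES.
#' @param renderSize detector grid used for DRRs inside the loop (the
#'   full field of view at reduced resolution).
#' @param sigma0 CMA-ES initial step size; degrees and mm are treated
#'   as-is, so this is a range-matched mixed-unit step.
#' @param powellScales per-parameter initial direction scales
#'   (degrees / mm).
#' @return a classed protocol list.
#' @export
optimizerProtocol <- function(method = c("powell", "cmaes"), tol = 1e-3,
                              maxIter = 100L, renderSize = 224L,
                              sigma0 = 3, powellScales = rep(2, 6)) {
  method <- match.arg(method)
  if (tol <= 0) stop("tol must be positive")
  if (maxIter < 1) stop("maxIter must be >= 1")
  structure(list(method = method, tol = tol, maxIter = as.integer(maxIter),
                 renderSize = as.integer(renderSize), sigma0 = sigma0,
                 powellScales = rep_len(powellScales, 6)),
            class = "OptimizerProtocol")
}

#' Register a volume to a target radiograph by optimization
#'
#' Minimizes \code{1 - gradncc(target, render(pose))} over the six pose
#' parameters, rendering a DRR at each candidate pose as the forward
#' model. Stops when the similarity improvement falls below the protocol
#' tolerance or at the iteration cap.
#'
#' @param vol a [CTVolume-class] or [AttenuationVolume-class].
#' @param geom a [ProjectionGeometry-class] (full-resolution; rendering
#'   happens at the protocol's \code{renderSize}).
#' @param target the target radiograph (numeric matrix in [0, 1]; any
#'   square size — renders are resampled to match).
#' @param protocol an [optimizerProtocol()].
#' @param init starting [Pose6-class].
#' @param seed integer seed (CMA-ES sampling; Powell is deterministic).
#' @param muWater HU-to-attenuation scale when \code{vol} is a CT volume.
#' @return a [RegistrationResult-class].
#' @export
registerOptim <- function(vol, geom, target, protocol = optimizerProtocol(),
                          init = pose6(), seed = 1L, muWater = 0.02) {
  stopifnot(inherits(protocol, "OptimizerProtocol"), is(init, "Pose6"))
  att <- if (is(vol, "CTVolume")) huToAttenuation(vol, muWater) else vol
  stopifnot(is(att, "AttenuationVolume"))
  target <- as.matrix(target)
  rgeom <- .render_geometry(geom, protocol$renderSize)
  evals <- 0L
  objective <- function(x) {
    evals <<- evals + 1L
    drr <- projectSiddon(att, rgeom, do.call(pose6, as.list(x)))
    img <- preprocessXray(drr, size = nrow(target))
    1 - gradncc(target, img)
  }
  x0 <- unname(poseParams(init))
  t0 <- proc.time()[["elapsed"]]
  res <- if (protocol$method == "powell") {
    .powell(objective, x0, protocol$powellScales, protocol$tol,
            protocol$maxIter)
  } else {
    .with_seed(as.integer(seed),
               .cmaes(objective, x0, protocol$sigma0, protocol$tol,
                      protocol$maxIter))
  }
  secs <- proc.time()[["elapsed"]] - t0
  names(res$x) <- .POSE_NAMES
  new("RegistrationResult", pose = do.call(pose6, as.list(res$x)),
      method = protocol$method, similarity = 1 - res$f,
      trace = res$trace, iterations = as.integer(res$iterations),
      converged = res$converged, evaluations = evals,
      seconds = secs)
}

#' @describeIn registerOptim accessors for a result's estimated pose,
#'   best-similarity trace, and iteration count.
#' @param result a [RegistrationResult-class].
#' @export
resultPose <- function(result) result@pose

#' @rdname registerOptim
#' @export
resultTrace <- function(result) result@trace

# Powell's direction-set method with Brent line minimization
# (stats::optimize) along each direction; classic direction replacement
# with the extrapolation test.
.powell <- function(f, x0, scales, tol, maxIter) {
  n <- length(x0)
  dirs <- diag(scales, n)
  x <- x0
  fx <- f(x)
  trace <- fx
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(maxIter)) {
    iter <- it
    fp <- fx
    xsave <- x
    del <- 0
    ibig <- 0L
    for (i in seq_len(n)) {
      g <- function(t) f(x + t * dirs[, i])
      # bracket wide enough to cross the protocol's initial offsets
      opt <- stats::optimize(g, c(-4, 4), tol = 1e-3)
      if (opt$objective < fx) {
        if (fx - opt$objective > del) {
          del <- fx - opt$objective
          ibig <- i
        }
        x <- x + opt$minimum * dirs[, i]
        fx <- opt$objective
      }
    }
    trace <- c(trace, fx)
    if (fp - fx <= tol) {
      converged <- TRUE
      break
    }
    xe <- 2 * x - xsave
    fe <- f(xe)
    if (fe < fp && ibig > 0L) {
      tcrit <- 2 * (fp - 2 * fx + fe) * (fp - fx - del)^2 -
        del * (fp - fe)^2
      if (tcrit < 0) {
        d <- x - xsave
        g <- function(t) f(x + t * d)
        opt <- stats::optimize(g, c(0, 2), tol = 1e-3)
        if (opt$objective < fx) {
          x <- x + opt$minimum * d
          fx <- opt$objective
        }
        dirs[, ibig] <- dirs[, n]
        dirs[, n] <- d
      }
    }
  }
  list(x = x, f = fx, trace = trace, iterations = iter,
       converged = converged)
}

# Covariance matrix adaptation evolution strategy, standard
# (mu/mu_w, lambda) form with rank-one and rank-mu covariance updates and
# cumulative step-size adaptation. Iterations are generations; the trace
# records the elitist best-so-far objective, which is non-increasing.
.cmaes <- function(f, x0, sigma0, tol, maxIter) {
  n <- length(x0)
  lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- x0
  sigma <- sigma0
  C <- diag(n)
  pc <- numeric(n)
  ps <- numeric(n)
  best_x <- x0
  best_f <- f(x0)
  trace <- best_f
  converged <- FALSE
  prev_gen_best <- Inf
  stall <- 0L
  iter <- 0L
  for (g in seq_len(maxIter)) {
    iter <- g
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-20))
    Bm <- eig$vectors
    BD <- Bm %*% diag(D, n)
    Z <- matrix(stats::rnorm(n * lambda), n, lambda)
    Y <- BD %*% Z
    X <- xmean + sigma * Y
    fit <- apply(X, 2, f)
    ord <- order(fit)
    prev_best <- best_f
    if (fit[ord[1]] < best_f) {
      best_f <- fit[ord[1]]
      best_x <- X[, ord[1]]
    }
    trace <- c(trace, best_f)
    ymean <- Y[, ord[seq_len(mu)], drop = FALSE] %*% w
    xmean <- xmean + sigma * drop(ymean)
    Cinvsqrt <- Bm %*% diag(1 / D, n) %*% t(Bm)
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * drop(Cinvsqrt %*% ymean)
    hsig <- sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * g)) / chiN < 1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc +
      hsig * sqrt(cc * (2 - cc) * mueff) * drop(ymean)
    Ymu <- Y[, ord[seq_len(mu)], drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * Ymu %*% diag(w, mu) %*% t(Ymu)
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    # termination on the similarity change between the best samples of
    # consecutive generations (the elitist best-so-far stays exactly
    # flat for long stretches and would trigger far too early); ask for
    # two consecutive sub-tol generation-to-generation changes
    gen_best <- fit[ord[1]]
    if (abs(prev_gen_best - gen_best) < tol) {
      stall <- stall + 1L
      if (stall >= 2L) {
        converged <- TRUE
        break
      }
    } else stall <- 0L
    prev_gen_best <- gen_best
  }
  list(x = best_x, f = best_f, trace = trace, iterations = iter,
       converged = converged)
}
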