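# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# small pose-identifiable phantom
fx_phantom <- function(dims = 64L) {
  fx_cached(paste0("ph", dims), function()
    makePhantom(phantomSpec(dims = dims, spacing = 128 / dims)))
}

fx_attenuation <- function(dims = 64L) {
  fx_cached(paste0("att", dims), function() huToAttenuation(fx_phantom(dims)))
}

# reduced-resolution C-arm geometry with the standard field of view
fx_geometry <- function(px = 64L) {
  projectionGeometry(detRows = px, detCols = px,
                     pixelSpacing = 1536 * 0.194 / px)
}

# smooth random attenuation field (sum of Gaussian blobs) for projector
# agreement tests
fx_smooth_volume <- function(n = 64L, seed = 7L, nblobs = 6L) {
  fx_cached(sprintf("smooth_%d_%d", n, seed), function() {
    set.seed(seed)
    cx <- (seq_len(n) - 0.5) - n / 2
    X <- array(cx, c(n, n, n))
    Y <- array(rep(cx, each = n), c(n, n, n))
    Z <- array(rep(cx, each = n * n), c(n, n, n))
    mu <- array(0, c(n, n, n))
    for (i in seq_len(nblobs)) {
      c0 <- runif(3, -n / 4, n / 4)
      s <- runif(1, n / 10, n / 5)
      a <- runif(1, 0.005, 0.02)
      mu <- mu + a * exp(-((X - c0[1])^2 + (Y - c0[2])^2 +
                            (Z - c0[3])^2) / (2 * s^2))
    }
    new("AttenuationVolume", mu = mu,
        geometry = volumeGeometry(c(n, n, n), 1,
                                  offset = c(-n / 2, -n / 2, -n / 2)))
  })
}

# independent elementary rotation matrices (test oracle; intentionally
# written from scratch, not via the package)
oracle_rx <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
}
oracle_ry <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, byrow = TRUE)
}
oracle_rz <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
}

rand_pose <- function(beta_lim = 89) {
  pose6(alpha = runif(1, -179, 179), beta = runif(1, -beta_lim, beta_lim),
        theta = runif(1, -179, 179), dx = runif(1, -50, 50),
        dy = runif(1, -50, 50), dz = runif(1, -50, 50))
}
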