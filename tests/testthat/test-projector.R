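test_that("HU-to-attenuation conversion follows the linear HU scale", {
  g <- volumeGeometry(c(2, 2, 2), 1)
  hu <- array(c(0, -1000, 1000, 500, -500, 3000, 0, 0), c(2, 2, 2))
  att <- huToAttenuation(hu, muWater = 0.02, geom = g)
  mu <- att@mu
  expect_equal(mu[1, 1, 1], 0.02)       # water
  expect_equal(mu[2, 1, 1], 0)          # air
  expect_equal(mu[1, 2, 1], 0.04)       # +1000 HU doubles water
  expect_equal(mu[2, 2, 1], 0.03)       # linear in between
  # clamping below zero never produces negative attenuation
  hu2 <- array(-1024, c(2, 2, 2))
  expect_true(all(huToAttenuation(hu2, geom = g)@mu >= 0))
  expect_error(huToAttenuation(hu, muWater = 0, geom = g), "positive")
})

test_that("central ray through a homogeneous cube yields the analytic chord", {
  n <- 20
  vg <- volumeGeometry(c(n, n, n), 1, offset = c(-n / 2, -n / 2, -n / 2))
  av <- new("AttenuationVolume", mu = array(1, c(n, n, n)), geometry = vg)
  geo <- projectionGeometry(sdd = 1000, detRows = 5, detCols = 5,
                            pixelSpacing = 1)
  # central pixel: ray perpendicular to the cube face, chord = 20 mm
  sid <- drrPixels(projectSiddon(av, geo))
  expect_equal(sid[3, 3], n, tolerance = 1e-6)
  den <- drrPixels(projectDenseOracle(av, geo, step = 0.25))
  expect_equal(den[3, 3], n, tolerance = 5e-3)
})

test_that("rays that miss the volume integrate to zero", {
  av <- fx_smooth_volume(32)
  # huge pixel spacing sends the corner rays far outside the volume
  geo <- projectionGeometry(sdd = 1000, detRows = 3, detCols = 3,
                            pixelSpacing = 500)
  px <- drrPixels(projectSiddon(av, geo))
  expect_equal(px[1, 1], 0)
  expect_equal(px[3, 3], 0)
  expect_gt(px[2, 2], 0)
})

test_that("projection is linear in the attenuation field", {
  av <- fx_smooth_volume(32)
  geo <- fx_geometry(32)
  pose <- pose6(5, -3, 2, 4, -2, 8)
  p1 <- drrPixels(projectSiddon(av, geo, pose))
  av2 <- new("AttenuationVolume", mu = 2 * av@mu + 0.5 * av@mu,
             geometry = av@geometry)
  p2 <- drrPixels(projectSiddon(av2, geo, pose))
  expect_lt(max(abs(p2 - 2.5 * p1)), 1e-9 * max(1, max(p2)))
})

test_that("Siddon agrees with the dense-sampling oracle on a smooth volume", {
  av <- fx_smooth_volume(64)
  geo <- fx_geometry(64)
  pose <- pose6(8, -5, 3, 4, -6, 10)
  sid <- drrPixels(projectSiddon(av, geo, pose))
  den <- drrPixels(projectDenseOracle(av, geo, pose, step = 0.25))
  expect_lt(max(abs(sid - den)) / max(den), 0.01)
})

test_that("dense oracle converges under step halving and validates its step", {
  av <- fx_smooth_volume(32)
  geo <- fx_geometry(32)
  pose <- pose6(2, 1, -1, 0, 0, 5)
  d1 <- drrPixels(projectDenseOracle(av, geo, pose, step = 0.5))
  d2 <- drrPixels(projectDenseOracle(av, geo, pose, step = 0.25))
  expect_lt(max(abs(d1 - d2)) / max(d2), 0.001)
  zero <- new("AttenuationVolume", mu = array(0, dim(av@mu)),
              geometry = av@geometry)
  expect_true(all(drrPixels(projectDenseOracle(zero, geo, step = 0.5)) == 0))
  expect_error(projectDenseOracle(av, geo, pose, step = 0), "positive")
  expect_error(projectDenseOracle(av, geo, pose, step = 5), "half")
})

test_that("translating the volume shifts the projection accordingly", {
  av <- fx_attenuation(64)
  geo <- fx_geometry(64)
  base <- renderDisplay(projectSiddon(av, geo))
  dxmm <- 10
  shifted <- renderDisplay(projectSiddon(av, geo, pose6(dx = dxmm)))
  # cross-correlation peak displacement along x (detector columns);
  # at the patient origin the magnification is SDD/SOD = 2
  cc <- sapply(-8:8, function(s) {
    a <- base[, 20:45]
    b <- shifted[, 20:45 + s]
    stats::cor(as.vector(a), as.vector(b))
  })
  best <- (-8:8)[which.max(cc)]
  expected_px <- dxmm * (geo@sdd / geo@sod) / geo@pixelSpacing
  expect_equal(best, round(expected_px), tolerance = 1)
})

test_that("display rendering normalizes, inverts and survives degenerate input", {
  m <- matrix(c(1, 2, 3, 4), 2)
  r <- renderDisplay(m)
  expect_equal(range(r), c(0, 1))
  expect_equal(renderDisplay(matrix(5, 3, 3)), matrix(0, 3, 3))
  inv <- renderDisplay(m, invert = TRUE)
  expect_equal(1 - inv, r)
  expect_true(all(renderDisplay(matrix(rnorm(100), 10)) >= 0))
})

test_that("DRR files round trip through TIFF plus sidecar", {
  av <- fx_attenuation(64)
  geo <- fx_geometry(32)
  drr <- projectSiddon(av, geo, pose6(3, -2, 1, 5, 0, -4))
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "drr.tiff")
  writeDRR(drr, f)
  back <- readDRR(f)
  expect_equal(poseParams(drrPose(back)), poseParams(drrPose(drr)))
  # 16-bit quantization bounds the reconstruction error
  expect_lt(max(abs(drrPixels(back) - drrPixels(drr))),
            diff(range(drrPixels(drr))) / 65535 + 1e-12)
})
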