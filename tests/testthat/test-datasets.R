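test_that("capture-range presets encode the per-anatomy bounds", {
  ch <- rangeBounds(captureRangePreset("chest"))
  expect_equal(unname(ch["dz", ]), c(-30, 30))
  expect_equal(unname(ch["dx", ]), c(-25, 25))
  expect_equal(unname(ch["theta", ]), c(-5, 5))   # narrow in-plane rotation
  hd <- rangeBounds(captureRangePreset("head"))
  expect_equal(unname(hd["dx", ]), c(-105, -75))  # off-center pre-adjustment
  expect_equal(unname(hd["dz", ]), c(30, 90))
  pv <- rangeBounds(captureRangePreset("pelvis"))
  expect_equal(unname(pv["alpha", ]), c(-105, -75))
  expect_equal(unname(pv["dz", ]), c(-50, 50))
  expect_error(captureRange(dx = c(5, -5)), "low")
})

test_that("sampled poses stay in bounds and are reproducible", {
  rng <- captureRangePreset("chest")
  a <- samplePoses(rng, 200, seed = 4, asMatrix = TRUE)
  b <- samplePoses(rng, 200, seed = 4, asMatrix = TRUE)
  expect_identical(a, b)
  bounds <- rangeBounds(rng)
  for (j in 1:6) {
    expect_gte(min(a[, j]), bounds[j, 1])
    expect_lte(max(a[, j]), bounds[j, 2])
  }
  expect_false(identical(a, samplePoses(rng, 200, seed = 5,
                                        asMatrix = TRUE)))
  # degenerate range yields the constant
  cr <- captureRange(dx = c(3, 3))
  expect_true(all(samplePoses(cr, 10, seed = 1,
                              asMatrix = TRUE)[, "dx"] == 3))
})

test_that("truncated-normal sampling has the stated moments", {
  # dz over [-30, 30]: mean 0, sd = quarter-range = 15 before truncation
  rng <- captureRangePreset("chest")
  x <- samplePoses(rng, 1e5, seed = 8, asMatrix = TRUE)[, "dz"]
  expect_lt(abs(mean(x)), 0.5)
  # truncation at +/- 2 sd shrinks the sd slightly below 15
  sd_trunc <- 15 * sqrt(1 - 2 * 2 * dnorm(2) / (pnorm(2) - pnorm(-2)))
  expect_lt(abs(sd(x) - sd_trunc) / sd_trunc, 0.05)
})

test_that("sampled parameters match the truncated normal by KS test", {
  rng <- captureRangePreset("chest")
  x <- samplePoses(rng, 1e4, seed = 12, asMatrix = TRUE)[, "dy"]
  lo <- -15; hi <- 15; m <- 0; s <- 7.5
  ptrunc <- function(q) (pnorm(q, m, s) - pnorm(lo, m, s)) /
    (pnorm(hi, m, s) - pnorm(lo, m, s))
  ks <- suppressWarnings(stats::ks.test(x, ptrunc))
  expect_gt(ks$p.value, 0.01)
})

test_that("uniform sampling mode covers the range", {
  rng <- captureRangePreset("chest")
  x <- samplePoses(rng, 5e3, seed = 2, sampler = "uniform",
                   asMatrix = TRUE)[, "dx"]
  ks <- suppressWarnings(stats::ks.test(x, "punif", -25, 25))
  expect_gt(ks$p.value, 0.01)
})

test_that("preprocessing downsamples, normalizes and validates input", {
  img <- matrix(runif(1536 * 1536), 1536)
  out <- preprocessXray(img, size = 224)
  expect_identical(dim(out), c(224L, 224L))
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
  expect_equal(preprocessXray(matrix(3, 64, 64), size = 16),
               matrix(0, 16, 16))
  expect_error(preprocessXray(array(0, c(4, 4, 2))), "2D")
  # area averaging preserves the mean before normalization
  rs <- drrpose:::.resize_operator(100, 30)
  expect_equal(Matrix::rowSums(rs), rep(1, 30), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("dataset build binds labels to images and regenerates exactly", {
  ph <- fx_phantom(48)
  geom <- fx_geometry(48)
  rng <- captureRangePreset("chest")
  tmp <- withr::local_tempdir()
  ds <- buildPoseDataset(ph, geom, rng, n = 8, seed = 21,
                         dir = file.path(tmp, "ds"), split = "train",
                         imageSize = 48L)
  man <- datasetManifest(ds)
  expect_identical(nrow(man), 8L)
  expect_true(all(file.exists(file.path(tmp, "ds", man$file))))

  # labels stay within the capture range
  b <- rangeBounds(rng)
  lab <- datasetLabels(ds)
  for (j in 1:6) expect_true(all(lab[, j] >= b[j, 1] & lab[, j] <= b[j, 2]))

  # regeneration oracle: re-render any image from its stored label and
  # recover the stored pixels exactly (same quantization path)
  att <- huToAttenuation(ph)
  i <- 5
  drr <- projectSiddon(att, ds@geometry, do.call(pose6, as.list(lab[i, ])))
  img <- preprocessXray(drr, size = 48)
  f2 <- file.path(tmp, "regen.tiff")
  tiff::writeTIFF(img, f2, bits.per.sample = 16L, compression = "none")
  expect_identical(tiff::readTIFF(f2), datasetImages(ds, i)[[1]])

  # shuffling keeps the pairing intact
  perm <- sample(8)
  ds2 <- ds
  ds2@manifest <- man[perm, ]
  expect_identical(datasetImages(ds2, 1)[[1]],
                   datasetImages(ds, perm[1])[[1]])

  # same seed reproduces the manifest bit for bit
  ds3 <- buildPoseDataset(ph, geom, rng, n = 8, seed = 21,
                          dir = file.path(tmp, "ds2"), split = "train",
                          imageSize = 48L)
  expect_identical(datasetLabels(ds3), lab)

  # refuses to clobber an existing split without overwrite
  expect_error(buildPoseDataset(ph, geom, rng, n = 2, seed = 1,
                                dir = file.path(tmp, "ds"),
                                split = "train", imageSize = 48L),
               "overwrite")

  # reload round trip
  ds4 <- loadPoseDataset(file.path(tmp, "ds"))
  expect_equal(datasetLabels(ds4), lab, ignore_attr = TRUE)
  expect_identical(ds4@imageSize, 48L)
})
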