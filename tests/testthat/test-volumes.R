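test_that("phantom generation is deterministic and in HU range", {
  a <- makePhantom(phantomSpec(dims = 48L, seed = 5L))
  b <- makePhantom(phantomSpec(dims = 48L, seed = 5L))
  expect_identical(ctHU(a), ctHU(b))
  c <- makePhantom(phantomSpec(dims = 48L, seed = 6L))
  expect_false(identical(ctHU(a), ctHU(c)))
  expect_gte(min(ctHU(a)), -1024)
  expect_lte(max(ctHU(a)), 3071)
})

test_that("phantom has no nontrivial 90-degree rotational symmetry", {
  ph <- fx_phantom(64)
  hu <- ctHU(ph)
  rot_z <- function(a) aperm(a, c(2, 1, 3))[, dim(a)[1]:1, , drop = FALSE]
  rot_x <- function(a) aperm(a, c(1, 3, 2))[, , dim(a)[2]:1, drop = FALSE]
  rot_y <- function(a) aperm(a, c(3, 2, 1))[dim(a)[3]:1, , , drop = FALSE]
  # the 23 nontrivial rotations of the cube are generated by the two
  # generators; enumerate orientations by BFS over compositions
  seen <- list(hu)
  frontier <- list(hu)
  worst <- Inf
  while (length(frontier) > 0 && length(seen) < 24) {
    nxt <- list()
    for (a in frontier) {
      for (r in list(rot_x(a), rot_y(a), rot_z(a))) {
        dup <- any(vapply(seen, function(s)
          identical(dim(s), dim(r)) && isTRUE(all.equal(s, r)),
          logical(1)))
        if (!dup) {
          seen[[length(seen) + 1]] <- r
          nxt[[length(nxt) + 1]] <- r
          if (identical(dim(r), dim(hu)))
            worst <- min(worst, mean(abs(hu - r)))
        }
      }
    }
    frontier <- nxt
  }
  expect_gte(length(seen), 24)
  expect_gt(worst, 50)
})

test_that("phantom spec rejects markers on the symmetry planes", {
  expect_error(
    phantomSpec(dims = 64L, markers = rbind(c(0, 20, 20), c(20, 0, 20))),
    "asymmetry")
})

test_that("NIfTI save/load round trips the HU grid and geometry", {
  ph <- fx_phantom(32)
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "vol.nii.gz")
  saveCT(ph, f)
  back <- loadCT(f)
  expect_identical(dim(ctHU(back)), dim(ctHU(ph)))
  expect_equal(ctHU(back), ctHU(ph))
  expect_equal(voxelSpacing(ctGeometry(back)), voxelSpacing(ctGeometry(ph)))
  expect_equal(originOffset(ctGeometry(back)), originOffset(ctGeometry(ph)))
})

test_that("NIfTI loader derives physical extent from header spacing", {
  # pelvis-style anisotropic spacing
  g <- volumeGeometry(c(24, 24, 30), c(0.74, 0.74, 0.8),
                      offset = c(-8.88, -8.88, -12))
  set.seed(2)
  hu <- array(round(runif(24 * 24 * 30, -1000, 2000)), c(24, 24, 30))
  ct <- new("CTVolume", hu = hu, geometry = g, name = "synthetic")
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "aniso.nii.gz")
  saveCT(ct, f)
  back <- loadCT(f)
  expect_equal(physicalExtent(ctGeometry(back)),
               c(24, 24, 30) * c(0.74, 0.74, 0.8))
  expect_equal(ctHU(back), hu)
})

test_that("loader errors name the missing path", {
  expect_error(loadCT("/nonexistent/vol.nii"), "/nonexistent/vol.nii")
})

test_that("DRRs from distinct poses in the capture range are distinguishable", {
  av <- fx_attenuation(64)
  geo <- fx_geometry(64)
  rng <- captureRangePreset("chest")
  set.seed(31)
  poses <- samplePoses(rng, 6, seed = 31)
  imgs <- lapply(poses, function(p)
    renderDisplay(projectSiddon(av, geo, p)))
  for (i in 1:5) for (j in (i + 1):6) {
    d <- abs(poseParams(poses[[i]]) - poseParams(poses[[j]]))
    if (max(d) > 1) {
      ncc <- stats::cor(as.vector(imgs[[i]]), as.vector(imgs[[j]]))
      expect_lt(ncc, 0.999)
    }
  }
})

test_that("rotations are not mimicked exactly by translations", {
  # identifiability: the best pure-translation imitation of a rotated
  # projection leaves visible gradient-correlation residual
  att <- huToAttenuation(fx_phantom(128))
  geo <- fx_geometry(64)
  img <- function(p) preprocessXray(projectSiddon(att, geo, p), size = 64)
  rotated <- img(pose6(alpha = 5))
  best <- -2
  for (dy in seq(-6, 2, by = 1)) for (dz in seq(-12, 12, by = 4)) {
    v <- gradncc(rotated, img(pose6(dy = dy, dz = dz)))
    if (v > best) best <- v
  }
  expect_lt(best, 0.999)
  expect_gt(best, gradncc(rotated, img(pose6())) - 1e-9)
})

test_that("MetaImage writer emits a parseable header", {
  ph <- fx_phantom(32)
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "vol.mha")
  writeMha(ph, f)
  hdr <- readLines(f, n = 9, warn = FALSE)
  expect_match(hdr[1], "ObjectType = Image")
  expect_match(hdr[grep("DimSize", hdr)], "32 32 32")
})
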