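test_that("pose-to-matrix equals the elementary-rotation product oracle", {
  # identity and an elementary rotation
  expect_equal(transformMatrix(poseToMatrix(pose6())), diag(4))
  T90 <- transformMatrix(poseToMatrix(pose6(theta = 90)))
  expect_equal(T90[1:3, 1], c(0, 1, 0), tolerance = 1e-12)

  # explicit three-matrix product at a fixed pose
  Tm <- transformMatrix(poseToMatrix(pose6(10, 20, 30, 1, 2, 3)))
  R <- oracle_rz(30) %*% oracle_ry(20) %*% oracle_rx(10)
  expect_lt(max(abs(Tm[1:3, 1:3] - R)), 1e-12)
  expect_equal(Tm[1:3, 4], c(1, 2, 3))
  expect_equal(Tm[4, ], c(0, 0, 0, 1))

  # 1000 random poses
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    p <- rand_pose()
    pp <- poseParams(p)
    Tm <- transformMatrix(poseToMatrix(p))
    R <- oracle_rz(pp[["theta"]]) %*% oracle_ry(pp[["beta"]]) %*%
      oracle_rx(pp[["alpha"]])
    worst <- max(worst, max(abs(Tm[1:3, 1:3] - R)))
  }
  expect_lt(worst, 1e-12)
})

test_that("non-finite pose parameters are rejected", {
  expect_error(pose6(alpha = NaN), "finite")
  expect_error(pose6(dx = Inf), "finite")
})

test_that("matrix-to-pose round trip is exact away from gimbal lock", {
  expect_equal(poseParams(matrixToPose(identityTransform())),
               poseParams(pose6()))
  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    p <- rand_pose(beta_lim = 89)
    Tm <- poseToMatrix(p)
    back <- poseToMatrix(matrixToPose(Tm))
    worst <- max(worst, max(abs(transformMatrix(Tm) -
                                  transformMatrix(back))))
  }
  expect_lt(worst, 1e-9)
})

test_that("round trip holds on a 10x10x10 angle grid within |beta| < 90", {
  angs <- seq(-80, 80, length.out = 10)
  worst <- 0
  for (a in angs) for (b in angs) for (t in angs) {
    Tm <- poseToMatrix(pose6(a, b, t))
    p2 <- poseParams(matrixToPose(Tm))
    worst <- max(worst, max(abs(p2[1:3] - c(a, b, t))))
  }
  expect_lt(worst, 1e-9)
})

test_that("gimbal lock applies the theta = 0 convention and still reproduces the matrix", {
  Tg <- poseToMatrix(pose6(alpha = 25, beta = 90, theta = 40))
  expect_warning(p <- matrixToPose(Tg), "gimbal")
  expect_identical(poseParams(p)[["theta"]], 0)
  expect_lt(max(abs(transformMatrix(poseToMatrix(p)) -
                      transformMatrix(Tg))), 1e-9)
})

test_that("compose and invert behave as SE(3) group operations", {
  expect_equal(transformMatrix(invertTransform(identityTransform())),
               diag(4))
  Tt <- poseToMatrix(pose6(dx = 3, dy = -4, dz = 5))
  expect_equal(transformMatrix(invertTransform(Tt))[1:3, 4], c(-3, 4, -5))

  set.seed(11)
  A <- poseToMatrix(rand_pose())
  B <- poseToMatrix(rand_pose())
  pts <- matrix(runif(300, -100, 100), 100)
  lhs <- transformPoints(composeTransform(A, B), pts)
  rhs <- transformPoints(A, transformPoints(B, pts))
  expect_lt(max(abs(lhs - rhs)), 1e-10)
  expect_lt(max(abs(transformMatrix(composeTransform(A, invertTransform(A))) -
                      diag(4))), 1e-12)
})

test_that("rotation blocks stay orthonormal over long composition chains", {
  set.seed(3)
  acc <- identityTransform()
  step <- poseToMatrix(pose6(0.37, -0.91, 1.13, 0.2, -0.1, 0.3))
  for (i in 1:10000) acc <- composeTransform(acc, step)
  R <- transformMatrix(acc)[1:3, 1:3]
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
})

test_that("patient-from-CT centers the volume per the offset arithmetic", {
  g0 <- volumeGeometry(c(100, 100, 100), 1, offset = c(0, 0, 0))
  expect_equal(transformMatrix(patientFromCT(g0))[1:3, 4], c(-50, -50, -50))

  # head-scan geometry: 1024 x 1024 x 202 voxels at 0.558 x 0.558 x 2 mm,
  # offset (-286, -208, -759); direct arithmetic oracle
  gh <- volumeGeometry(c(1024, 1024, 202), c(0.558, 0.558, 2),
                       offset = c(-286, -208, -759))
  tr <- transformMatrix(patientFromCT(gh))[1:3, 4]
  expect_equal(tr, -(c(-286, -208, -759) +
                       c(1024, 1024, 202) * c(0.558, 0.558, 2) / 2))
  expect_lt(abs(tr[1]), 1)  # nearly centered along x
  expect_lt(max(abs(transformMatrix(
    composeTransform(patientFromCT(gh),
                     invertTransform(patientFromCT(gh)))) - diag(4))),
    1e-12)
})

test_that("source-from-patient places the source at distance SOD", {
  expect_equal(transformMatrix(sourceFromPatient(0)), diag(4))
  # half the standard 1020 mm source-detector distance
  Ts <- transformMatrix(sourceFromPatient(0.5 * 1020))
  expect_equal(Ts[1:3, 4], c(0, 0, -510))
  expect_equal(Ts[1:3, 1:3], diag(3))
  expect_error(sourceFromPatient(100, Ri = matrix(1, 3, 3)), "orthonormal")
})

test_that("the CT-to-source chain maps CT-frame points pointwise", {
  g <- volumeGeometry(c(64, 64, 64), c(1.5, 1.5, 2), offset = c(-20, 5, -80))
  sod <- 510
  Tcs <- ctFromSource(g, sod)
  # independent composition oracle
  ext <- c(64, 64, 64) * c(1.5, 1.5, 2)
  tpc <- c(-(-20 + ext[1] / 2), -(5 + ext[2] / 2), -(-80 + ext[3] / 2))
  set.seed(5)
  pts <- matrix(runif(30, -40, 40), 10)
  # inv(T_PC) p then T_PS: here both are translations
  expected <- (pts - rep(tpc, each = 10)) +
    rep(c(0, 0, -sod), each = 10)
  expect_lt(max(abs(transformPoints(Tcs, pts) - expected)), 1e-10)
})

test_that("transforms and poses serialize losslessly", {
  tmp <- withr::local_tempdir()
  Tm <- poseToMatrix(pose6(10.5, -3.25, 77, 1.125, -2.5, 3))
  f <- file.path(tmp, "T.txt")
  writeTransform(Tm, f)
  expect_equal(transformMatrix(readTransform(f)), transformMatrix(Tm),
               tolerance = 1e-15)
  p <- pose6(1.5, -2.25, 3, -4, 5.5, -6)
  g <- file.path(tmp, "p.json")
  writePose(p, g)
  expect_identical(poseParams(readPose(g)), poseParams(p))
  expect_error(readTransform(file.path(tmp, "nope.txt")), "nope.txt")
})
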