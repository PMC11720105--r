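test_that("euler/matrix conversion follows the declared convention", {
  expect_equal(eulerToMatrix(c(0, 0, 0)), diag(3))
  # yaw 90: +x anterior maps to +y left
  expect_equal(as.vector(eulerToMatrix(c(0, 0, 90)) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  # pure single-axis rotations match the textbook matrices
  a <- 37 * pi / 180
  expect_equal(eulerToMatrix(c(37, 0, 0)),
               matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3),
               tolerance = 1e-12)
  expect_equal(matrixToEuler(diag(3)), c(roll = 0, pitch = 0, yaw = 0))
})

test_that("euler round trip is exact away from gimbal lock", {
  withr::with_seed(101, {
    for (i in 1:1000) {
      e <- c(runif(1, -179, 179), runif(1, -85, 85), runif(1, -179, 179))
      R <- eulerToMatrix(e)
      expect_lt(max(abs(matrixToEuler(R) - e)), 1e-9)
      expect_lt(max(abs(eulerToMatrix(matrixToEuler(R)) - R)), 1e-9)
    }
  })
})

test_that("gimbal lock assigns the free angle to yaw", {
  e <- matrixToEuler(eulerToMatrix(c(0, 90, 0)))
  expect_equal(e[["pitch"]], 90, tolerance = 1e-7)
  expect_equal(e[["roll"]], 0)
  # a locked matrix with combined roll/yaw still round-trips as a matrix
  R <- eulerToMatrix(c(25, 90, -40))
  expect_lt(max(abs(eulerToMatrix(matrixToEuler(R)) - R)), 1e-7)
})

test_that("matrixToEuler rejects non-rotations", {
  expect_error(matrixToEuler(matrix(1:9, 3, 3)), "not a valid rotation")
  expect_error(matrixToEuler(diag(c(1, 1, -1))), "not a valid rotation")
})

test_that("projectToSO3 returns the nearest proper rotation", {
  withr::with_seed(7, {
    R0 <- randomRotation()
    expect_lt(max(abs(projectToSO3(R0) - R0)), 1e-12)
    expect_lt(max(abs(projectToSO3(2 * R0) - R0)), 1e-12)
    # reflective input still yields det +1
    M <- diag(c(1, 1, -1))
    P <- projectToSO3(M)
    expect_equal(det(P), 1, tolerance = 1e-9)
    # nearest-rotation property against random candidate rotations
    for (i in 1:20) {
      A <- matrix(rnorm(9, sd = 2), 3, 3)
      P <- projectToSO3(A)
      expect_true(isRotationMatrix(P, tol = 1e-9))
      dP <- sqrt(sum((P - A)^2))
      for (j in 1:200) {
        Q <- randomRotation()
        expect_lte(dP, sqrt(sum((Q - A)^2)) + 1e-12)
      }
    }
  })
  expect_error(projectToSO3(matrix(c(NA, rnorm(8)), 3, 3)), "non-finite")
})

test_that("rotation error matches the closed form and is a metric-like score", {
  expect_equal(rotationError(eulerToMatrix(c(0, 0, 30)), diag(3)), 30,
               tolerance = 1e-9)
  # trace = -1 case: 180-degree rotation
  expect_equal(rotationError(eulerToMatrix(c(180, 0, 0)), diag(3)), 180,
               tolerance = 1e-9)
  withr::with_seed(8, {
    for (i in 1:50) {
      R1 <- randomRotation(); R2 <- randomRotation(); L <- randomRotation()
      re <- rotationError(R1, R2)
      expect_equal(re, rotationError(R2, R1), tolerance = 1e-9)
      # invariant under simultaneous left multiplication
      expect_equal(re, rotationError(L %*% R1, L %*% R2), tolerance = 1e-8)
    }
    expect_equal(rotationError(diag(3), diag(3)), 0)
  })
})

test_that("angleMAE averages per-axis absolute errors independently", {
  p <- rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  t0 <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  out <- angleMAE(p, t0)
  expect_equal(unname(out$mae), c(2, 0, 0))
  expect_equal(unname(out$sd), c(1, 0, 0))
  expect_equal(angleMAE(p, p)$mae, c(roll = 0, pitch = 0, yaw = 0))
  out2 <- angleMAE(rbind(c(2, 0, 0)), rbind(c(0, 0, 0)))
  expect_equal(unname(out2$mae), c(2, 0, 0))
  expect_error(angleMAE(p, t0[1:2, ]), "equal dimensions")
})

test_that("applyRotation rotates about the requested centre", {
  P <- rbind(c(1, 0, 0), c(-1, 0, 0))
  expect_equal(applyRotation(P, diag(3)), P)
  R <- eulerToMatrix(c(0, 0, 90))
  # point at distance 1 from centre moves by the chord sqrt(2) under 90 deg
  moved <- applyRotation(rbind(c(1, 0, 0)), R, center = c(0, 0, 0))
  expect_equal(sqrt(sum((moved - c(1, 0, 0))^2)), sqrt(2), tolerance = 1e-12)
  # R then t(R) restores the input (default centroid centre)
  withr::with_seed(5, {
    X <- matrix(rnorm(30), 10, 3)
    R <- randomRotation()
    expect_lt(max(abs(applyRotation(applyRotation(X, R), t(R)) - X)), 1e-9)
  })
})

test_that("surface distance follows the chord formula", {
  mesh <- triangleMesh(rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0)),
                       rbind(c(1L, 2L, 3L)))
  R <- eulerToMatrix(c(0, 0, 60))
  sd1 <- surfaceDistance(mesh, R, diag(3), center = c(0, 0, 0))
  # every vertex sits at distance 1 from the z axis: chord = 2 sin(30) = 1
  expect_equal(sd1$distances, rep(1, 3), tolerance = 1e-12)
  expect_equal(sd1$mean, 1, tolerance = 1e-12)
  expect_equal(surfaceDistance(mesh, R, R)$distances, rep(0, 3))
  # distances scale linearly with the distance from the rotation centre
  mesh2 <- triangleMesh(3 * meshVertices(mesh), meshFaces(mesh))
  sd2 <- surfaceDistance(mesh2, R, diag(3), center = c(0, 0, 0))
  expect_equal(sd2$distances, 3 * sd1$distances, tolerance = 1e-12)
})
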