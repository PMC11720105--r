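test_that("farthest point sampling matches the greedy definition", {
  # collinear points 0..9: after the start, the far end is picked first
  P <- cbind(0:9, 0, 0)
  expect_equal(farthestPointSample(P, 2), c(1L, 10L))
  expect_equal(farthestPointSample(P, 3), c(1L, 10L, 5L))
  # k = n returns all indices in selection order
  expect_setequal(farthestPointSample(P, 10), 1:10)
  expect_error(farthestPointSample(P, 11), "exceeds")
  # oracle equivalence on random instances
  withr::with_seed(55, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      X <- matrix(rnorm(3 * n), n, 3)
      k <- sample(seq_len(n), 1)
      expect_identical(farthestPointSample(X, k), as.integer(bruteFPS(X, k)))
    }
  })
})

test_that("radius grouping matches brute-force membership with pad/truncate", {
  withr::with_seed(56, {
    for (rep in 1:20) {
      X <- matrix(rnorm(96), 32, 3)
      cIdx <- farthestPointSample(X, 6)
      r <- runif(1, 0.3, 1.5)
      m <- sample(3:10, 1)
      G <- radiusGroup(X, cIdx, r, m)
      for (i in seq_along(cIdx)) {
        members <- bruteGroupMembers(X, cIdx[i], r)
        expect_true(cIdx[i] %in% G[i, ])       # centroid in its own group
        if (length(members) >= m) {
          # the m nearest members, exactly
          d <- sqrt(colSums((t(X[members, , drop = FALSE]) - X[cIdx[i], ])^2))
          expect_setequal(G[i, ], members[order(d, members)][seq_len(m)])
        } else {
          expect_setequal(unique(G[i, ]), members)
          expect_equal(sum(G[i, ] == cIdx[i]),
                       m - length(members) + 1L)  # padded with the centroid
        }
      }
    }
  })
  # radius covering the whole cloud keeps every point (pre-truncation)
  X <- matrix(rnorm(24), 8, 3)
  G <- radiusGroup(X, c(1L, 5L), r = 100, maxGroupSize = 8)
  expect_setequal(G[1, ], 1:8)
  expect_setequal(G[2, ], 1:8)
  # radius below the minimum gap isolates each centroid
  Y <- cbind(seq(0, 70, by = 10), 0, 0)
  G2 <- radiusGroup(Y, c(2L, 4L), r = 1, maxGroupSize = 4)
  expect_equal(G2[1, ], rep(2L, 4))
  expect_equal(G2[2, ], rep(4L, 4))
})

test_that("point convolution obeys its algebraic structure", {
  withr::with_seed(57, {
    X <- matrix(rnorm(30), 10, 3)
    Fin <- X
    cIdx <- farthestPointSample(X, 4)
    G <- radiusGroup(X, cIdx, 1.5, 5)
    rho <- kernelDensity(X, 0.5)
    h <- 4L
    p <- list(A1 = matrix(rnorm(3 * h), 3, h), b1 = rnorm(h),
              A2 = matrix(rnorm(h * h), h, h), b2 = rnorm(h),
              P = matrix(rnorm(3 * h * 6), 3 * h, 6), bp = rep(0, 6))
    # all-zero weights give all-zero output
    pz <- lapply(p, function(x) x * 0)
    outZ <- pointConv(X, Fin, cIdx, G, rho, pz)
    expect_true(all(outZ$features == 0))
    expect_true(all(outZ$aggregate == 0))
    # doubling densities halves the pre-projection aggregate exactly
    out1 <- pointConv(X, Fin, cIdx, G, rho, p)
    out2 <- pointConv(X, Fin, cIdx, G, 2 * rho, p)
    expect_equal(out2$aggregate, out1$aggregate / 2, tolerance = 1e-12)
    # single-point groups against a direct hand evaluation
    Gself <- matrix(cIdx, ncol = 1)
    outS <- pointConv(X, Fin, cIdx, Gself, rho, p)
    for (i in seq_along(cIdx)) {
      w0 <- as.vector(pmax(p$b1, 0) %*% p$A2) + p$b2   # W(offset = 0)
      fj <- Fin[cIdx[i], ] / rho[cIdx[i]]
      agg <- as.vector(t(outer(fj, w0)))               # channel-major layout
      expect_equal(outS$aggregate[i, ], agg, tolerance = 1e-9)
      expect_equal(outS$features[i, ],
                   pmax(as.vector(agg %*% p$P) + p$bp, 0), tolerance = 1e-9)
    }
  })
})

test_that("forward pass is deterministic and permutation-invariant under
          controlled sampling", {
  withr::with_seed(58, {
    P <- matrix(rnorm(90), 30, 3)
    P <- P / max(sqrt(rowSums(P^2)))
    cfg <- networkConfig(sab1 = sabConfig(8, 0.6, 30, 4, 6),
                         sab2 = sabConfig(4, 1.0, 8, 4, 8,
                                          densityBandwidth = 0.3),
                         headWidths = c(10, 9), seed = 3)
    model <- initModel(cfg)
    expect_identical(nhpForward(P, model), nhpForward(P, model))
    expect_warning(nhpForward(P * 3, model), "not normalized")

    # permutation invariance of one SAB + GMP when grouping keeps all points
    perm <- sample(nrow(P))
    params <- modelParams(model)$sab1
    cIdx <- c(4L, 17L)
    G <- radiusGroup(P, cIdx, 10, 30)
    rho <- kernelDensity(P, 0.2)
    f1 <- pointConv(P, P, cIdx, G, rho, params)$features
    Pp <- P[perm, ]
    cIdxP <- match(cIdx, perm)
    GP <- radiusGroup(Pp, cIdxP, 10, 30)
    rhoP <- kernelDensity(Pp, 0.2)
    f2 <- pointConv(Pp, Pp, cIdxP, GP, rhoP, params)$features
    gmp1 <- apply(f1, 2, max)
    gmp2 <- apply(f2, 2, max)
    expect_equal(gmp1, gmp2, tolerance = 1e-12)
  })
})

test_that("parameter counts match hand-computed sums and the output layer", {
  cfg <- networkConfig(sab1 = sabConfig(4, 0.5, 2, 2, 3),
                       sab2 = sabConfig(2, 0.8, 2, 2, 4,
                                        densityBandwidth = 0.2),
                       headWidths = c(5, 9), seed = 1)
  # sab1 (3 input channels):      (3*2+2) + (2*2+2) + (6*3+3)  = 35
  # sab2 (3 coords + 3 channels): (3*2+2) + (2*2+2) + (12*4+4) = 66
  # head: (4*5+5) + (5*9+9) = 79
  expect_equal(countParameters(cfg), 180L)
  # a bare linear map 3 -> 9 with bias contributes 3*9+9 = 36
  w <- c(3, 9)
  expect_equal(sum(w[1] * w[2] + w[2]), 36)
  model <- initModel(cfg)
  expect_equal(length(unlist(modelParams(model))), countParameters(cfg))
})

test_that("analytic gradients match finite differences off the ReLU kink", {
  withr::with_seed(59, {
    P <- matrix(rnorm(60), 20, 3)
    P <- P / max(sqrt(rowSums(P^2)))
    cfg <- networkConfig(sab1 = sabConfig(8, 0.5, 4, 3, 5),
                         sab2 = sabConfig(4, 0.8, 4, 3, 6,
                                          densityBandwidth = 0.2),
                         headWidths = c(7, 9), seed = 7)
    model <- initModel(cfg)
    # jitter parameters so no pre-activation sits exactly at zero
    params <- nhpnet:::.mapLeaves(function(x) x + rnorm(length(x), 0, 0.05),
                                  modelParams(model))
    st <- nhpnet:::.buildStructure(P, unclass(cfg))
    target <- eulerToMatrix(c(4, -6, 3))
    lossCfg <- list(kind = "wing", omega = 10, epsilon = 3, delta = 1)
    f <- function(pp) nhpnet:::.lossValueGrad(
      nhpnet:::.forwardFull(pp, st), target, lossCfg)$value
    cache <- nhpnet:::.forwardFull(params, st, cache = TRUE)
    lg <- nhpnet:::.lossValueGrad(cache$out, target, lossCfg)
    grads <- nhpnet:::.backwardFull(params, st, cache, lg$grad)
    fp <- unlist(params, use.names = FALSE)
    fg <- unlist(grads, use.names = FALSE)
    eps <- 1e-6
    for (ii in sort(sample(length(fp), 50))) {
      up <- fp; up[ii] <- up[ii] + eps
      dn <- fp; dn[ii] <- dn[ii] - eps
      num <- (f(utils::relist(up, params)) - f(utils::relist(dn, params))) /
        (2 * eps)
      expect_lt(abs(num - fg[ii]), 1e-6)
    }
    # gradient flow: every parameter tensor receives signal somewhere
    leafNonzero <- rapply(grads, function(g) any(g != 0), how = "unlist")
    expect_true(all(leafNonzero))
  })
})
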