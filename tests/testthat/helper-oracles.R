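# Independent brute-force oracles, deliberately written in the most direct
# way possible so they share no code path with the package implementations.

# Greedy farthest point sampling by explicit double loop.
bruteFPS <- function(P, k, start = 1L) {
  n <- nrow(P)
  sel <- start
  while (length(sel) < k) {
    best <- -1
    besti <- NA
    for (i in seq_len(n)) {
      dmin <- Inf
      for (s in sel) dmin <- min(dmin, sqrt(sum((P[i, ] - P[s, ])^2)))
      if (dmin > best) {  # strict: first (lowest-index) max wins
        best <- dmin
        besti <- i
      }
    }
    sel <- c(sel, besti)
  }
  sel
}

# Radius group membership by explicit pairwise distances (unpadded sets).
bruteGroupMembers <- function(P, centroid, r) {
  d <- apply(P, 1, function(q) sqrt(sum((q - P[centroid, ])^2)))
  which(d <= r)
}

# Uniform random rotation via QR of a Gaussian matrix with sign fix.
randomRotation <- function() {
  qr0 <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr0)
  d <- diag(qr.R(qr0))
  Q <- Q %*% diag(sign(d))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# A small fast proxy mesh for pipeline tests.
tinyProxy <- function(...) makeSkullProxy(shapeParams(meshResolution = 1L, ...))

# Closed-form SD of a zero-mean normal truncated at +/- b.
truncatedNormalSD <- function(sigma, b) {
  a <- b / sigma
  sigma * sqrt(1 - 2 * a * dnorm(a) / (2 * pnorm(a) - 1))
}
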