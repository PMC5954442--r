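# Shared fixtures and independent oracles used across the suite.

# random SPD covariance with eigenvalues in a sane range (nm^2)
random_spd <- function(scale = 0.05, floor = 0.004) {
  A <- matrix(rnorm(9) * scale, 3)
  crossprod(A) + diag(3) * floor
}

# random anisotropic component
random_component <- function(pos_sd = 0.3) {
  gmm_component(runif(1, 0.5, 2), rnorm(3, 0, pos_sd), random_spd())
}

# random normalized GMM
random_gmm <- function(K, pos_sd = 0.5) {
  w <- runif(K, 0.5, 2)
  gmm(w / sum(w), matrix(rnorm(3 * K, 0, pos_sd), K, 3),
      vapply(seq_len(K), function(i) random_spd(), matrix(0, 3, 3)),
      normalized = TRUE)
}

# quadrature oracle for the overlap integral: midpoint sum of the product
# of the two weighted normal densities over a box of +-8 combined sd
quadrature_overlap <- function(a, b, npts = 81) {
  S <- a$cov + b$cov
  sdmax <- sqrt(max(eigen(S, symmetric = TRUE, only.values = TRUE)$values))
  ctr <- (a$mean + b$mean) / 2
  gr <- seq(-8 * sdmax, 8 * sdmax, length.out = npts)
  h <- gr[2] - gr[1]
  gg <- as.matrix(expand.grid(x = gr + ctr[1], y = gr + ctr[2],
                              z = gr + ctr[3]))
  dens <- function(comp) {
    d <- sweep(gg, 2, comp$mean)
    iS <- solve(comp$cov)
    comp$weight * exp(-0.5 * rowSums((d %*% iS) * d)) /
      sqrt((2 * pi)^3 * det(comp$cov))
  }
  sum(dens(a) * dens(b)) * h^3
}

# brute-force GROMOS clustering oracle (straight transcription of the
# published algorithm, independent of the package implementation)
gromos_oracle <- function(rmsd, cutoff) {
  F2 <- nrow(rmsd)
  adj <- rmsd <= cutoff
  membership <- rep(NA_integer_, F2)
  cl <- 0L
  repeat {
    un <- which(is.na(membership))
    if (length(un) == 0) break
    counts <- vapply(un, function(i) sum(adj[i, un]), 0L)
    center <- un[which.max(counts)] # which.max takes the first maximum
    memb <- un[adj[center, un]]
    cl <- cl + 1L
    membership[memb] <- cl
    if (!center %in% memb) membership[center] <- cl
  }
  membership
}

# quaternion-based superposition RMSD (independent of the Kabsch/SVD path)
quaternion_rmsd <- function(a, b) {
  A <- matrix(a, ncol = 3, byrow = TRUE)
  B <- matrix(b, ncol = 3, byrow = TRUE)
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  M <- t(B) %*% A
  K <- matrix(0, 4, 4)
  K[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  K[1, 2] <- K[2, 1] <- M[2, 3] - M[3, 2]
  K[1, 3] <- K[3, 1] <- M[3, 1] - M[1, 3]
  K[1, 4] <- K[4, 1] <- M[1, 2] - M[2, 1]
  K[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  K[2, 3] <- K[3, 2] <- M[1, 2] + M[2, 1]
  K[2, 4] <- K[4, 2] <- M[1, 3] + M[3, 1]
  K[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  K[3, 4] <- K[4, 3] <- M[2, 3] + M[3, 2]
  K[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lmax) / nrow(A)
  sqrt(max(0, msd))
}

# tiny deterministic map: one anisotropic Gaussian rasterized on a coarse grid
toy_map <- function(voxel = 0.2, span = 2.4) {
  g <- gmm(1, matrix(c(0.1, -0.2, 0.05), 1), array(random_spd(), c(3, 3, 1)))
  grid <- map_template(rbind(rep(-span, 3), rep(span, 3)), voxel)
  rasterize(g, grid)
}
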