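# Gaussian components, analytic overlaps, rasterization, cross-correlation.

test_that("component and mixture invariants are enforced", {
  expect_error(gmm_component(0, c(0, 0, 0), 0.01), "weight")
  expect_error(gmm_component(1, c(0, 0, 0),
                             matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)),
               "symmetric")
  expect_error(gmm_component(1, c(0, 0, 0), diag(c(0.01, 0.01, 1e-12))),
               "degenerate")
  expect_error(gmm(c(0.6, 0.6), matrix(0, 2, 3), c(0.01, 0.01),
                   normalized = TRUE), "sum to 1")
  g <- gmm(c(0.5, 0.5), rbind(c(0, 0, 0), c(1, 0, 0)), c(0.01, 0.02),
           normalized = TRUE)
  expect_equal(length(g), 2L)
})

test_that("pair_overlap matches its closed form on isotropic pairs", {
  a <- gmm_component(1, c(0, 0, 0), 0.01)
  b <- gmm_component(1, c(0.2, 0, 0), 0.01)
  closed <- (2 * pi)^(-1.5) * 0.02^(-1.5)
  expect_equal(pair_overlap(a, a), closed, tolerance = 1e-12)
  expect_equal(pair_overlap(a, b), closed * exp(-1), tolerance = 1e-12)
})

test_that("analytic overlap agrees with 3-D quadrature on anisotropic pairs", {
  set.seed(11)
  for (i in 1:20) {
    a <- random_component()
    b <- random_component()
    expect_equal(pair_overlap(a, b), quadrature_overlap(a, b),
                 tolerance = 1e-6)
  }
})

test_that("pair_overlap is symmetric and bilinear in the weights", {
  set.seed(12)
  for (i in 1:10) {
    a <- random_component()
    b <- random_component()
    expect_equal(pair_overlap(a, b), pair_overlap(b, a), tolerance = 1e-12)
    a2 <- gmm_component(3.5 * a$weight, a$mean, a$cov)
    b2 <- gmm_component(0.25 * b$weight, b$mean, b$cov)
    expect_equal(pair_overlap(a2, b2), 3.5 * 0.25 * pair_overlap(a, b),
                 tolerance = 1e-12)
  }
})

test_that("mixture_component_overlap sums pairs and honors neighbor subsets", {
  set.seed(13)
  model <- random_gmm(10)
  comp <- random_component()
  brute <- sum(vapply(1:10, function(k)
    pair_overlap(gmm_get(model, k), comp), 0))
  expect_equal(mixture_component_overlap(model, comp), brute,
               tolerance = 1e-12)
  expect_identical(mixture_component_overlap(model, comp, integer(0)), 0)
  sub <- c(2L, 5L, 7L)
  brute_sub <- sum(vapply(sub, function(k)
    pair_overlap(gmm_get(model, k), comp), 0))
  expect_equal(mixture_component_overlap(model, comp, sub), brute_sub,
               tolerance = 1e-12)
  # far-separated components contribute nothing
  far <- gmm(rep(1, 5), matrix(rnorm(15, 50, 1), 5, 3), rep(0.01, 5))
  expect_lt(mixture_component_overlap(far, gmm_component(1, c(0, 0, 0), 0.01)),
            1e-15)
})

test_that("self_overlaps: closed forms, positivity, reorder invariance", {
  one <- gmm(1, matrix(0, 1, 3), 0.01, normalized = TRUE)
  expect_equal(self_overlaps(one), (2 * pi)^(-1.5) * 0.02^(-1.5),
               tolerance = 1e-12)
  two <- gmm(c(0.5, 0.5), matrix(0, 2, 3), c(0.01, 0.01), normalized = TRUE)
  expect_equal(self_overlaps(two),
               rep(0.5 * (2 * pi)^(-1.5) * 0.02^(-1.5), 2),
               tolerance = 1e-12)
  set.seed(14)
  g <- random_gmm(50)
  ov <- self_overlaps(g)
  expect_true(all(ov > 0))
  # each entry is at least its own diagonal term
  diag_term <- vapply(1:50, function(i)
    pair_overlap(gmm_get(g, i), gmm_get(g, i)), 0)
  expect_true(all(ov >= diag_term - 1e-12))
  # brute force and reorder invariance
  brute <- vapply(1:50, function(i)
    mixture_component_overlap(g, gmm_get(g, i)), 0)
  expect_equal(ov, brute, tolerance = 1e-10)
  perm <- sample(50)
  gp <- gmm(g$w[perm], g$mu[perm, ], g$sigma[, , perm], normalized = TRUE)
  expect_equal(sort(self_overlaps(gp)), sort(ov), tolerance = 1e-10)
})

test_that("rasterize conserves mass and vanishes off-support", {
  set.seed(15)
  g <- gmm(2.5, matrix(c(0.1, 0, -0.1), 1), 0.02)
  grid <- map_template(rbind(rep(-1.6, 3), rep(1.6, 3)), 0.05)
  m <- rasterize(g, grid)
  expect_equal(sum(m$values) * prod(m$voxel), 2.5, tolerance = 0.01)
  corner <- m$values[1, 1, 1] # ~1.6 nm from the mean, >10 sd away
  expect_lt(corner, 1e-10)
  # grid not covering the support warns
  small <- map_template(rbind(rep(-0.2, 3), rep(0.2, 3)), 0.05)
  expect_warning(rasterize(g, small), "support")
})

test_that("global_cc: identity, negation, shift invariance, grid checks", {
  set.seed(16)
  m <- toy_map()
  expect_equal(global_cc(m, m), 1.0)
  neg <- density_map(-m$values, m$voxel, m$origin)
  expect_equal(global_cc(m, neg), -1.0)
  shifted <- density_map(m$values + 3.7, m$voxel, m$origin)
  expect_equal(global_cc(m, shifted), 1.0, tolerance = 1e-12)
  scaled <- density_map(2.2 * m$values + 0.5, m$voxel, m$origin)
  expect_equal(global_cc(m, scaled), 1.0, tolerance = 1e-12)
  other <- density_map(m$values[1:5, 1:5, 1:5], m$voxel, m$origin)
  expect_error(global_cc(m, other), "mismatch")
})

test_that("local_cc matches direct window computation and is scale invariant", {
  set.seed(17)
  a <- density_map(array(rnorm(11^3), c(11, 11, 11)), 0.1)
  b <- density_map(array(rnorm(11^3), c(11, 11, 11)), 0.1)
  lc <- local_cc(a, b, window = 5)
  # direct Pearson over the full window at the center voxel
  wa <- a$values[4:8, 4:8, 4:8]
  wb <- b$values[4:8, 4:8, 4:8]
  expect_equal(lc$values[6, 6, 6], cor(as.vector(wa), as.vector(wb)),
               tolerance = 1e-10)
  # truncated corner window
  ca <- a$values[1:3, 1:3, 1:3]
  cb <- b$values[1:3, 1:3, 1:3]
  expect_equal(lc$values[1, 1, 1], cor(as.vector(ca), as.vector(cb)),
               tolerance = 1e-10)
  # identity and affine invariance
  self <- local_cc(a, a, window = 5)
  expect_true(all(abs(self$values - 1) < 1e-9, na.rm = TRUE))
  b2 <- density_map(2 * a$values + 1, a$voxel, a$origin)
  expect_true(all(abs(local_cc(a, b2, 5)$values - 1) < 1e-9, na.rm = TRUE))
  expect_error(local_cc(a, b, window = 4), "odd")
  expect_error(local_cc(a, b, window = 13), "larger")
})
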