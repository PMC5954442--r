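# RMSD, GROMOS clustering, population errors, distance CVs, free-energy
# surfaces.

test_that("backbone_rmsd removes rigid motion and matches the quaternion oracle", {
  set.seed(61)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(backbone_rmsd(a, a), 0, tolerance = 1e-12)
  # rigid rotation + translation
  th <- 0.8
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  b <- a %*% t(R) + matrix(rep(c(1, -2, 0.5), each = 10), 10, 3)
  expect_lt(backbone_rmsd(a, b), 1e-9)
  # hand-built 4-point sets against the quaternion implementation
  for (i in 1:10) {
    p <- matrix(rnorm(12), 4, 3)
    q <- matrix(rnorm(12), 4, 3)
    expect_equal(backbone_rmsd(p, q),
                 quaternion_rmsd(as.vector(t(p)), as.vector(t(q))),
                 tolerance = 1e-10)
  }
  # symmetry and selections
  expect_equal(backbone_rmsd(a, b + 0.3), backbone_rmsd(b + 0.3, a),
               tolerance = 1e-12)
  expect_lt(backbone_rmsd(a, b, selection = 3:8), 1e-7)
  # degenerate (collinear) selection is refused
  line <- cbind(1:5, 0, 0)
  expect_error(backbone_rmsd(line, line + 1), "degenerate")
  expect_error(backbone_rmsd(a[1:2, ], a[1:2, ]), "3 points")
})

test_that("gromos_cluster handles the trivial and constructed cases", {
  set.seed(62)
  base <- matrix(rnorm(30), 1, 30)
  # all frames within the cutoff of each other -> one cluster
  frames <- base[rep(1, 8), ] + matrix(rnorm(8 * 30, 0, 1e-4), 8)
  cl <- gromos_cluster(frames, cutoff = 0.35)
  expect_equal(length(cl$centers), 1L)
  expect_equal(cl$populations, 1)
  # two tight groups far apart, sizes 30 and 10 -> populations 0.75 / 0.25
  g1 <- base[rep(1, 30), ] + matrix(rnorm(30 * 30, 0, 1e-3), 30)
  g2 <- (base * 3)[rep(1, 10), ] + matrix(rnorm(10 * 30, 0, 1e-3), 10)
  cl2 <- gromos_cluster(rbind(g1, g2), cutoff = 0.35)
  expect_equal(length(cl2$centers), 2L)
  expect_equal(cl2$populations, c(0.75, 0.25))
  expect_true(all(cl2$membership[1:30] == 1L))
  expect_true(all(cl2$membership[31:40] == 2L))
})

test_that("gromos_cluster agrees exactly with the brute-force oracle", {
  set.seed(63)
  for (i in 1:20) {
    F2 <- sample(5:50, 1)
    n <- sample(4:8, 1)
    frames <- matrix(rnorm(F2 * 3 * n, 0, 0.6), F2)
    cutoff <- runif(1, 0.3, 1.2)
    cl <- gromos_cluster(frames, cutoff = cutoff)
    oracle <- gromos_oracle(rmsd_matrix(frames), cutoff)
    expect_identical(cl$membership, oracle)
    # memberships form a partition; populations sum to one
    expect_false(anyNA(cl$membership))
    expect_equal(sum(cl$populations), 1, tolerance = 1e-12)
  }
})

test_that("population errors shrink for stationary labels and count the discard", {
  # synthetic membership: stationary two-state labels, 10^4 frames
  set.seed(64)
  memb <- sample(1:2, 1e4, replace = TRUE, prob = c(0.7, 0.3))
  fake <- structure(list(centers = c(1L, 2L), membership = memb,
                         populations = tabulate(memb) / 1e4,
                         sizes = tabulate(memb), cutoff = 0.35,
                         n_frames = 1e4L), class = "cluster_result")
  pe <- population_errors(fake, discard = 0.2)
  expect_equal(pe$population[1], 0.7, tolerance = 0.02)
  expect_true(all(pe$sd < 0.02))
  # alternating labels -> populations exactly 0.5, tiny sd
  alt <- structure(list(centers = c(1L, 2L), membership = rep(1:2, 500),
                        populations = c(0.5, 0.5), sizes = c(500L, 500L),
                        cutoff = 0.35, n_frames = 1000L),
                   class = "cluster_result")
  pa <- population_errors(alt, discard = 0.2)
  expect_equal(pa$population, c(0.5, 0.5), tolerance = 1e-3)
  expect_true(all(pa$sd < 0.05))
  # the first 20% of frames are provably excluded
  memb2 <- c(rep(1L, 200), rep(2L, 800))
  fake2 <- structure(list(centers = c(1L, 2L), membership = memb2,
                          populations = c(0.2, 0.8), sizes = c(200L, 800L),
                          cutoff = 0.35, n_frames = 1000L),
                     class = "cluster_result")
  pe2 <- population_errors(fake2, discard = 0.2)
  expect_equal(pe2$population[pe2$cluster == 1], 0) # all excluded
  expect_equal(pe2$population[pe2$cluster == 2], 1)
})

test_that("distance_cv computes atom and group-center distances, rigid invariant", {
  f <- rbind(c(0, 0, 0), c(0, 0, 2), c(0, 3, 1), c(0, 0, 1))
  expect_equal(distance_cv(f, 1, 4, mode = "atom-pair"), 1.0)
  expect_equal(distance_cv(f, c(1, 2), 3), 3.0) # center (0,0,1) to (0,3,1)
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  f2 <- f %*% t(R) + 5
  expect_equal(distance_cv(f2, c(1, 2), 3), 3.0, tolerance = 1e-12)
  expect_error(distance_cv(f, integer(0), 1), "empty")
  expect_error(distance_cv(f, c(1, 2), 3, mode = "atom-pair"), "single")
})

test_that("free_energy_surface inverts a Gaussian and respects weights", {
  set.seed(65)
  x <- rnorm(1e5)
  fes <- free_energy_surface(x, bins = 50, kBT = 1, limits = c(-4, 4))
  ctr <- abs(fes$grid[[1]]) < 1.5
  quad <- fes$grid[[1]][ctr]^2 / 2
  got <- fes$F[ctr]
  fit <- lm(got ~ quad)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
  expect_equal(min(fes$F, na.rm = TRUE), 0)
  # uniform samples are flat
  u <- runif(1e5)
  fu <- free_energy_surface(u, bins = 20, kBT = 1)
  expect_lt(max(abs(fu$F), na.rm = TRUE), 0.1)
  # doubling all weights changes nothing
  w <- runif(1e4, 0.5, 2)
  f1 <- free_energy_surface(x[1:1e4], bins = 30, weights = w,
                            limits = c(-4, 4))
  f2 <- free_energy_surface(x[1:1e4], bins = 30, weights = 2 * w,
                            limits = c(-4, 4))
  expect_equal(f1$F, f2$F, tolerance = 1e-12)
  # guard rails
  expect_error(free_energy_surface(rnorm(50)), ">= 100")
  expect_warning(free_energy_surface(rep(1, 200), bins = 10,
                                     limits = c(0, 2)), "one bin")
  # 2-D surface has the right shape and a zero minimum
  xy <- cbind(rnorm(1e4), rnorm(1e4, 2, 0.5))
  f2d <- free_energy_surface(xy, bins = c(20, 25))
  expect_identical(dim(f2d$F), c(20L, 25L))
  expect_equal(min(f2d$F, na.rm = TRUE), 0)
})
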