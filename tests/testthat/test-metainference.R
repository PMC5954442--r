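# Noise model: sigma_SEM, Gaussian likelihood, marginalized erf score,
# forces, Gibbs sampling and a posteriori noise estimation.

test_that("sigma_sem scales self-overlaps and guards the singular limit", {
  expect_equal(sigma_sem(5.0, 0.01), 0.05)
  expect_equal(sigma_sem(5.0, 0.1), 0.5)
  expect_equal(sigma_sem(c(1, 2, 4), 0.1), c(0.1, 0.2, 0.4))
  expect_error(sigma_sem(5.0, 1e-7), "singular")
})

test_that("gaussian_likelihood is the stated normal density", {
  expect_equal(gaussian_likelihood(1, 1, 0, 0.1), 1 / (sqrt(2 * pi) * 0.1),
               tolerance = 1e-12)
  expect_equal(gaussian_likelihood(1.1, 1, 0, 0.1),
               exp(-0.5) / (sqrt(2 * pi) * 0.1), tolerance = 1e-12)
  # combined variance and normalization over delta
  f <- function(d) gaussian_likelihood(d, 0, 0.3, 0.4)
  expect_equal(integrate(Vectorize(f), -Inf, Inf)$value, 1, tolerance = 1e-8)
  expect_equal(f(0), dnorm(0, 0, 0.5), tolerance = 1e-12)
})

test_that("marginal_score equals the Jeffreys-marginalized likelihood (erf identity)", {
  # 100-point grid over (delta, sigma), including delta = 0
  deltas <- c(0, 10^seq(-8, 0.5, length.out = 9))
  sigmas <- 10^seq(-2, 0.5, length.out = 10)
  for (d in deltas) for (s in sigmas) {
    got <- marginal_score(5 + d, 5, s, kBT = 1, per_component = TRUE)
    quad <- -log(integrate(function(x) (1 / x) * dnorm(d, 0, x), s, Inf,
                           rel.tol = 1e-13)$value)
    expect_equal(got, quad, tolerance = 1e-6)
  }
})

test_that("marginal_score: small-delta limit, evenness, monotonicity, asymptote", {
  s <- 0.1
  expect_equal(marginal_score(5, 5, s, kBT = 1, per_component = TRUE),
               -log(1 / (sqrt(2 * pi) * s)), tolerance = 1e-12)
  dd <- c(0.03, 0.4, 2)
  up <- marginal_score(5 + dd, rep(5, 3), s, kBT = 1, per_component = TRUE)
  dn <- marginal_score(5 - dd, rep(5, 3), s, kBT = 1, per_component = TRUE)
  expect_equal(up, dn, tolerance = 1e-12)
  grid <- marginal_score(5 + seq(0, 3, by = 0.1), rep(5, 31), s, kBT = 1,
                         per_component = TRUE)
  expect_true(all(diff(grid) > 0))
  # large-delta asymptote: energy -> log(2 delta)
  expect_equal(marginal_score(5 + 50, 5, s, kBT = 1, per_component = TRUE),
               log(2 * 50), tolerance = 1e-6)
  # continuity across the series/exact switch
  u_switch <- 0.1 * sqrt(2) * s
  eps <- 1e-9
  lo <- marginal_score(5 + u_switch - eps, 5, s, kBT = 1, per_component = TRUE)
  hi <- marginal_score(5 + u_switch + eps, 5, s, kBT = 1, per_component = TRUE)
  expect_equal(lo, hi, tolerance = 1e-9)
})

test_that("score_gradient matches central finite differences on a 10-particle system", {
  set.seed(51)
  pr <- hinge_chain_prior(n_beads = 10)
  models <- lapply(1:2, function(r)
    atomic_model(pr$conformers$open + matrix(rnorm(30, 0, 0.05), 10, 3),
                 "BEAD", size = 0.45))
  data <- random_gmm(6)
  ovDD <- self_overlaps(data)
  sg <- sigma_sem(ovDD, 0.1)
  r <- score_gradient(models, data, ovDD, sg, kBT = kbt())
  h <- 1e-5
  fscale <- max(abs(unlist(r$forces)))
  for (rr in 1:2) for (m in c(1, 4, 10)) for (a in 1:3) {
    pm <- models
    xp <- pm[[rr]]$xyz; xp[m, a] <- xp[m, a] + h; pm[[rr]]$xyz <- xp
    e1 <- score_gradient(pm, data, ovDD, sg, kBT = kbt())$energy
    xp[m, a] <- xp[m, a] - 2 * h; pm[[rr]]$xyz <- xp
    e2 <- score_gradient(pm, data, ovDD, sg, kBT = kbt())$energy
    fd <- -(e1 - e2) / (2 * h)
    expect_lt(abs(r$forces[[rr]][m, a] - fd),
              1e-5 * max(fscale, abs(fd)))
  }
})

test_that("forces are finite and zero-gradient at the all-delta-zero point", {
  set.seed(52)
  models <- list(atomic_model(matrix(rnorm(30, 0, 0.3), 10, 3), "BEAD",
                              size = 0.4))
  data <- random_gmm(5)
  r0 <- replica_averaged_overlaps(models, data)
  # feed the model's own overlaps as the data: every delta is exactly 0
  sg <- sigma_sem(self_overlaps(data), 0.1)
  r <- score_gradient(models, data, r0$ovbar, sg, kBT = kbt())
  expect_true(all(is.finite(unlist(r$forces))))
  expect_lt(max(abs(unlist(r$forces))), 1e-8)
})

test_that("perturbing one replica moves others' deltas only through the 1/N average", {
  set.seed(53)
  pr <- hinge_chain_prior(n_beads = 8)
  models <- lapply(1:3, function(r)
    atomic_model(pr$conformers$open + matrix(rnorm(24, 0, 0.05), 8, 3),
                 "BEAD", size = 0.45))
  data <- random_gmm(4)
  ovDD <- self_overlaps(data)
  sg <- sigma_sem(ovDD, 0.1)
  base <- score_gradient(models, data, ovDD, sg)
  pert <- models
  pert[[2]]$xyz <- pert[[2]]$xyz + 0.05
  after <- score_gradient(pert, data, ovDD, sg)
  # replica 1 and 3 overlaps unchanged; ovbar moves by the replica-2 shift / N
  expect_equal(after$ov_replica[1, ], base$ov_replica[1, ], tolerance = 1e-12)
  expect_equal(after$ov_replica[3, ], base$ov_replica[3, ], tolerance = 1e-12)
  expect_equal(after$ovbar - base$ovbar,
               (after$ov_replica[2, ] - base$ov_replica[2, ]) / 3,
               tolerance = 1e-12)
})

test_that("Gibbs chain targets the quadrature posterior of sigmaB", {
  set.seed(54)
  sg <- 0.1
  # large single deviation: posterior mode of total sigma near |delta|
  delta <- 2.0
  out <- gibbs_sample_sigma(delta, sg, support = c(1e-4, 100),
                            n_steps = 1e5, seed = 9)
  expect_gt(out$acceptance, 0.1)
  # quadrature posterior on the same support
  grid <- exp(seq(log(1e-4), log(100), length.out = 2000))
  lp <- -log(grid) + dnorm(delta, 0, sqrt(grid^2 + sg^2), log = TRUE)
  post <- exp(lp - max(lp)) * grid
  post <- post / sum(post)
  # posterior density mode of sigmaB under Jeffreys is delta/sqrt(2)
  mode_q <- grid[which.max(post / grid)]
  expect_equal(log(mode_q), log(delta / sqrt(2)), tolerance = 0.05)
  # chain histogram vs quadrature CDF within 3% total variation
  edges <- exp(seq(log(1e-4), log(100), length.out = 41))
  hc <- table(cut(out$chain, edges)) / length(out$chain)
  hq <- vapply(seq_len(40), function(i)
    sum(post[grid > edges[i] & grid <= edges[i + 1]]), 0)
  expect_lt(0.5 * sum(abs(as.vector(hc) - hq)), 0.03)
  # all-zero deviations concentrate at the lower support bound
  out0 <- gibbs_sample_sigma(rep(0, 200), sg, support = c(1e-4, 100),
                             n_steps = 2e4, seed = 10)
  expect_lt(median(out0$chain), sg / 2)
})

test_that("noise estimator recovers an injected sigmaB within 10% across 5 seeds", {
  sg <- 0.2
  truth <- sqrt(3) * sg # total sd 2*sg => sigmaB = sqrt(3)*sg
  for (seed in 1:5) {
    set.seed(seed)
    d <- matrix(rnorm(1e4, 0, 2 * sg), ncol = 1)
    est <- estimate_noise_posterior(5 - d, ovDD = 5, sigmaSEM = sg)
    expect_equal(est$sigmaB, truth, tolerance = 0.1)
  }
  # zero deviations -> sigmaB below sigmaSEM / 10
  est0 <- estimate_noise_posterior(matrix(5, 500, 1), ovDD = 5, sigmaSEM = sg)
  expect_lt(est0$sigmaB, sg / 10)
  expect_error(estimate_noise_posterior(matrix(5, 50, 1), 5, sg), ">= 100")
})

test_that("error density map projects relative errors onto the grid", {
  g <- gmm(c(0.5, 0.5), rbind(c(-1, 0, 0), c(1, 0, 0)), c(0.03, 0.03),
           normalized = TRUE)
  grid <- map_template(rbind(c(-2, -0.6, -0.6), c(2, 0.6, 0.6)), 0.1)
  # equal relative errors -> constant map on the support
  noise <- data.frame(component = 1:2, sigmaB = c(1, 1),
                      rel_error = c(0.3, 0.3))
  em <- error_density_map(noise, g, grid)
  on_support <- em$values[rasterize(g, grid, support_sigmas = 0)$values > 1e-6]
  expect_true(all(abs(on_support - 0.3) < 1e-9))
  # distinct errors -> peak at the noisy component, monotone between them
  noise2 <- data.frame(component = 1:2, sigmaB = c(1, 1),
                       rel_error = c(0.1, 0.5))
  em2 <- error_density_map(noise2, g, grid)
  nx <- dim(em2$values)[1]
  iy <- ceiling(dim(em2$values)[2] / 2)
  iz <- ceiling(dim(em2$values)[3] / 2)
  profile <- em2$values[, iy, iz]
  xs <- em2$origin[1] + (seq_len(nx) - 1) * em2$voxel[1]
  inner <- xs > -1 & xs < 1
  expect_true(all(diff(profile[inner]) > -1e-9))
  expect_true(all(profile >= 0.1 - 1e-9 & profile <= 0.5 + 1e-9))
})
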