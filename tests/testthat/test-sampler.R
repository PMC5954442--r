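# Hinge-chain prior, Langevin sampler, multiple-time-step restraint and
# well-tempered metadynamics.

test_that("hinge-chain prior: gradient consistency, conformers, well warnings", {
  set.seed(71)
  pr <- hinge_chain_prior(n_beads = 10, com_k = 5, com_ref = c(0.5, 0, 0))
  x <- pr$conformers$open + matrix(rnorm(30, 0, 0.05), 10, 3)
  F <- pr$gradient(x)
  h <- 1e-6
  for (m in c(1, 5, 10)) for (a in 1:3) {
    xp <- x; xp[m, a] <- xp[m, a] + h
    xm <- x; xm[m, a] <- xm[m, a] - h
    fd <- -(pr$energy(xp) - pr$energy(xm)) / (2 * h)
    expect_equal(F[m, a], fd, tolerance = 1e-6)
  }
  # the two minimized conformers are distinct states
  expect_gt(backbone_rmsd(pr$conformers$open, pr$conformers$closed), 0.3)
  # minimized geometry: bonds at rest length, hinge at the well minimum
  d <- diff(pr$conformers$open)
  expect_equal(sqrt(rowSums(d^2)), rep(pr$params$r0, 9), tolerance = 1e-9)
  expect_equal(hinge_angle(pr$conformers$open, pr), pr$wells[["open"]],
               tolerance = 1e-9)
  # single-well parameters warn with the computed barrier
  expect_warning(hinge_chain_prior(n_beads = 8, barrier = 0.5,
                                   tilt = 10), "single well")
})

test_that("well-tempered hill heights: first hill, decay recursion, infinite gamma", {
  kBT <- kbt()
  b <- metadynamics_bias(W0 = 3, bias_factor = 11, width = 0.5, pace = 10)
  kBdT <- (11 - 1) * kBT
  # repeated deposition at a fixed CV value
  heights <- numeric(6)
  for (k in 1:6) {
    up <- wt_metadynamics_update(b, 2.0, step = 10 * k)
    b <- up$bias
    heights[k] <- tail(b$hills$heights, 1)
  }
  expect_equal(heights[1], 3) # V = 0 at the first hill
  # exact recursion h_{k+1} = h_k * exp(-h_k_cumulative.../kBdT): heights
  # follow h_{k+1} = W0 * exp(-V_k / kBdT) with V_k the sum of earlier hills
  expect_equal(heights[2] / heights[1], exp(-3 / kBdT), tolerance = 1e-9)
  for (k in 2:5)
    expect_equal(heights[k + 1], 3 * exp(-sum(heights[1:k]) / kBdT),
                 tolerance = 1e-9)
  # no deposition off the pace; energy/gradient still reported
  up2 <- wt_metadynamics_update(b, 2.3, step = 7)
  expect_equal(length(up2$bias$hills$heights), 6L)
  expect_gt(up2$energy, 0)
  # bias gradient matches finite differences of the hill sum
  vfun <- function(s) sum(b$hills$heights *
                            exp(-(s - b$hills$centers)^2 / (2 * 0.5^2)))
  g <- wt_metadynamics_update(b, 2.4, step = 7)$gradient
  expect_equal(g, (vfun(2.4 + 1e-6) - vfun(2.4 - 1e-6)) / 2e-6,
               tolerance = 1e-5)
  # infinite bias factor: constant hill heights (standard metadynamics)
  binf <- metadynamics_bias(W0 = 3, bias_factor = 1e12, width = 0.5,
                            pace = 10)
  for (k in 1:4) binf <- wt_metadynamics_update(binf, 1.0, 10 * k)$bias
  expect_equal(binf$hills$heights, rep(3, 4), tolerance = 1e-9)
})

test_that("identical seeds give bit-identical trajectories", {
  bench <- make_two_state_benchmark(n_beads = 10, hinge = 5)
  data <- fit_gmm_dc(bench$maps$mixture, fit_config(budget = 16, seed = 2))
  ens <- initial_ensemble(bench, 2)
  pp <- meta_params(save_stride = 200)
  t1 <- run_metainference(ens, bench$prior, data, params = pp,
                          steps = 4000, seed = 42)
  t2 <- run_metainference(ens, bench$prior, data, params = pp,
                          steps = 4000, seed = 42)
  expect_identical(t1$xyz, t2$xyz)
  expect_identical(t1$ovbar, t2$ovbar)
  t3 <- run_metainference(ens, bench$prior, data, params = pp,
                          steps = 4000, seed = 43)
  expect_false(identical(t1$xyz, t3$xyz))
})

test_that("prior-only sampling reproduces the Boltzmann hinge-angle marginal", {
  # small system so the hinge exchanges many times within the run; the
  # internal-coordinate marginal of the hinge angle is sin(theta)*exp(-V/kBT)
  pr <- hinge_chain_prior(n_beads = 10, barrier = 1.5)
  tr <- run_metainference(replica_ensemble(pr$conformers$open, 2), pr,
                          data = NULL, params = meta_params(save_stride = 500),
                          steps = 1.5e6, seed = 8)
  ang <- hinge_angle(traj_frames(tr, discard = 0.2), pr)
  # symmetric wells at 60 and 120 degrees: equal visitation
  occ <- mean(ang > pi / 2)
  expect_gt(occ, 0.35)
  expect_lt(occ, 0.65)
  # histogram against the analytic marginal
  edges <- seq(0.6, 2.6, length.out = 21)
  keep <- ang > edges[1] & ang < edges[21]
  hc <- table(cut(ang[keep], edges)) / sum(keep)
  th <- seq(0.6, 2.6, length.out = 800)
  dens <- sin(th) * exp(-pr$hinge_potential(th) / kbt())
  cdf <- cumsum(dens) / sum(dens)
  hq <- diff(approx(th, cdf, xout = edges, rule = 2)$y)
  expect_lt(0.5 * sum(abs(as.vector(hc) - hq)), 0.1)
})

test_that("a single replica restrained to a one-state map stays in that state", {
  bench <- make_two_state_benchmark(n_beads = 10, hinge = 5, w = 1)
  data <- fit_gmm_dc(bench$maps$mixture, fit_config(budget = 16, seed = 3))
  ens <- replica_ensemble(bench$conformers$open, 1)
  tr <- run_metainference(ens, bench$prior, data,
                          params = meta_params(save_stride = 500),
                          steps = 4e5, seed = 5)
  ang <- hinge_angle(traj_frames(tr, discard = 0.2), bench$prior)
  expect_gt(mean(ang > pi / 2), 0.95)
})

test_that("restraint strides 1 and 2 sample consistent ensembles", {
  bench <- make_two_state_benchmark(n_beads = 10, hinge = 5, w = 1)
  data <- fit_gmm_dc(bench$maps$mixture, fit_config(budget = 16, seed = 3))
  ens <- replica_ensemble(bench$conformers$open, 1)
  ov <- lapply(c(1L, 2L), function(st) {
    tr <- run_metainference(ens, bench$prior, data,
                            params = meta_params(stride = st,
                                                 save_stride = 500),
                            steps = 3e5, seed = 11)
    colMeans(tr$ovbar[-(1:100), ], na.rm = TRUE)
  })
  expect_lt(max(abs(ov[[1]] - ov[[2]]) / pmax(abs(ov[[1]]), 1e-12)), 0.1)
})

test_that("the force bound aborts after one capped overflow", {
  pr <- hinge_chain_prior(n_beads = 8)
  ens <- replica_ensemble(pr$conformers$open, 1)
  expect_error(
    suppressWarnings(run_metainference(ens, pr, NULL,
                        params = meta_params(save_stride = 100,
                                             fmax = 1e-4),
                        steps = 1000, seed = 1)),
    "force overflow")
})

test_that("biased and unbiased sampling give the same reweighted well free energies", {
  # small hinge chain, prior only: wells are symmetric, so the free-energy
  # difference is 0; hinge-angle metadynamics plus final-bias reweighting
  # must reproduce it within 0.5 kBT
  pr <- hinge_chain_prior(n_beads = 10, barrier = 1.5)
  pp <- meta_params(save_stride = 500)
  ens <- replica_ensemble(pr$conformers$open, 2)
  dF_of <- function(ang, wts) {
    po <- sum(wts * (ang > pi / 2)) / sum(wts)
    -log(po / (1 - po)) # kBT units
  }
  un <- run_metainference(ens, pr, NULL, params = pp, steps = 1.5e6,
                          seed = 21)
  ang_u <- hinge_angle(traj_frames(un, discard = 0.2), pr)
  b <- metadynamics_bias(W0 = 1.5, bias_factor = 10, width = 0.12,
                         pace = 1000, cv = "hinge")
  bi <- run_metainference(ens, pr, NULL, params = pp, bias = b,
                          steps = 1.5e6, seed = 22)
  fr <- traj_frames(bi, discard = 0.2, pool = FALSE)
  angm <- sapply(fr, function(m) hinge_angle(m, pr))
  wts <- metad_weights(bi, cv_values = angm)
  dF_u <- dF_of(ang_u, rep(1, length(ang_u)))
  dF_b <- dF_of(as.vector(angm), as.vector(wts))
  expect_lt(abs(dF_u), 0.75)       # symmetric wells
  expect_lt(abs(dF_b - dF_u), 0.5) # off/on agreement after reweighting
})
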