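# Bayesian scoring machinery: sigma_SEM assignment, Gaussian likelihood,
# Jeffreys-marginalized erf score and gradients, Gibbs sampling of noise,
# a posteriori noise estimation and error density maps.

#' Statistical error of the replica average
#'
#' The finite-replica statistical error assigned to each data component,
#' proportional to its self-overlap: `sigma_SEM_i = alpha * ovDD_i`. This
#' sets the maximum strength of the map restraint in the absence of data
#' noise.
#'
#' @param ovDD per-component self-overlaps (nm^-3), all > 0.
#' @param alpha dimensionless scale (common choices: 0.01 for near-atomistic
#'   data-GMMs, 0.1 for coarser fits).
#' @return Per-component sigma_SEM (nm^-3).
#' @export
sigma_sem <- function(ovDD, alpha) {
  stopifnot(all(ovDD > 0))
  if (!is.finite(alpha) || alpha < 1e-6)
    stop("alpha must be >= 1e-6: with alpha -> 0 the marginalized restraint ",
         "becomes singular and cannot be integrated stably")
  alpha * ovDD
}

#' Gaussian data likelihood for one component
#'
#' Normal density of the deviation between the data self-overlap and the
#' replica-averaged model overlap, with total variance
#' `sigmaB^2 + sigmaSEM^2`.
#'
#' @param ovDD_i,ovMD_bar_i data and replica-averaged model overlaps
#'   (nm^-3).
#' @param sigmaB noise parameter (>= 0).
#' @param sigmaSEM statistical error (> 0).
#' @return Probability density.
#' @export
gaussian_likelihood <- function(ovDD_i, ovMD_bar_i, sigmaB, sigmaSEM) {
  stopifnot(sigmaB >= 0, sigmaSEM > 0)
  stats::dnorm(ovDD_i - ovMD_bar_i, mean = 0,
               sd = sqrt(sigmaB^2 + sigmaSEM^2))
}

#' Marginalized metainference score
#'
#' Per-component energy `-kBT log[(1/(2 Delta_i)) erf(Delta_i / (sqrt(2)
#' sigmaSEM_i))]` with `Delta_i = ovDD_i - ovMD_bar_i`: the Gaussian
#' likelihood marginalized over the total uncertainty `sigma >= sigmaSEM`
#' under a Jeffreys prior. Even in each `Delta_i`, finite at `Delta_i = 0`
#' (limit `-kBT log[1/(sqrt(2 pi) sigmaSEM_i)]`), evaluated with a series
#' expansion at small `|Delta|/sigmaSEM` for stability. Energies are
#' meaningful up to an additive constant.
#'
#' @param ovDD,ovMD_bar per-component data and model overlap vectors.
#' @param sigmaSEM per-component statistical errors (> 0).
#' @param kBT thermal energy, kJ/mol.
#' @param per_component return the per-component energies instead of their
#'   sum.
#' @return Total score (kJ/mol), or per-component vector.
#' @export
marginal_score <- function(ovDD, ovMD_bar, sigmaSEM, kBT = kbt(),
                           per_component = FALSE) {
  stopifnot(length(ovDD) == length(ovMD_bar), all(sigmaSEM > 0))
  sigmaSEM <- rep_len(sigmaSEM, length(ovDD))
  r <- cpp_score_terms(ovDD - ovMD_bar, sigmaSEM, kBT)
  if (per_component) r$energy else sum(r$energy)
}

#' Derivative of the marginal score with respect to Delta
#'
#' @inheritParams marginal_score
#' @return Per-component dE/dDelta (kJ/mol per nm^-3).
#' @keywords internal
marginal_score_ddelta <- function(ovDD, ovMD_bar, sigmaSEM, kBT = kbt()) {
  sigmaSEM <- rep_len(sigmaSEM, length(ovDD))
  cpp_score_terms(ovDD - ovMD_bar, sigmaSEM, kBT)$dEdDelta
}

#' Forces of the metainference map restraint
#'
#' Gradient of the marginalized score with respect to every particle of
#' every replica, using the chain rule through the replica-averaged
#' overlaps: the force on particle k of replica r is `-dE/dx_k`, with
#' `d ovbar_i / dx_k = (1/N) d ov_i^r / dx_k`. Forces sum to zero over all
#' particles (translating model and data together leaves the score
#' unchanged).
#'
#' @param models an [atomic_model()] or list of them (one per replica).
#' @param data the data-GMM ([gmm()]).
#' @param ovDD per-component self-overlaps of `data`.
#' @param sigmaSEM per-component statistical errors.
#' @param kBT thermal energy, kJ/mol.
#' @param nl optional [build_neighbor_list()]; `NULL` = exact sums.
#' @param table scattering table.
#' @return List with `energy` (kJ/mol), `forces` (list of n x 3 matrices,
#'   kJ/mol/nm, one per replica), `ovbar`, and `ov_replica`.
#' @export
score_gradient <- function(models, data, ovDD, sigmaSEM, kBT = kbt(),
                           nl = NULL, table = scattering_table()) {
  if (inherits(models, "atomic_model")) models <- list(models)
  stopifnot(inherits(data, "gmm"), length(ovDD) == length(data$w))
  sigmaSEM <- rep_len(sigmaSEM, length(ovDD))
  p <- .particle_gaussians(models[[1]], table)
  pos <- lapply(models, `[[`, "xyz")
  nlist <- if (is.null(nl)) NULL else lapply(nl$pairs, as.integer)
  r <- cpp_meta_score(pos, p$w, p$v, data$w, data$mu, data$sigma,
                      ovDD, sigmaSEM, kBT, nlist)
  list(energy = r$energy, forces = r$forces, ovbar = r$ovbar,
       ov_replica = r$ov_replica)
}

# log-likelihood of deviations under total sd sqrt(sigmaB^2+sigmaSEM^2),
# from sufficient statistics (nobs, sum of squares)
.noise_loglik <- function(sigmaB, ss, nobs, sigmaSEM) {
  v <- sigmaB^2 + sigmaSEM^2
  -nobs / 2 * log(2 * pi * v) - ss / (2 * v)
}

#' Gibbs sampling of a noise parameter
#'
#' Metropolis-within-Gibbs chain for one per-component noise parameter
#' sigmaB given a set of observed deviations, targeting
#' `p(sigmaB | Delta) ~ Jeffreys(sigmaB) * prod_t N(Delta_t; 0, sigmaB^2 +
#' sigmaSEM^2)` on a bounded support. Moves are Gaussian in `log(sigmaB)`.
#' This is the non-marginalized sampling path; the default workflow
#' marginalizes sigmaB instead ([marginal_score()]).
#'
#' @param delta numeric vector of deviations `ovDD_i - ovbar_i` (one or many
#'   samples).
#' @param sigmaSEM statistical error (> 0).
#' @param support length-2 positive vector: bounds of sigmaB.
#' @param n_steps chain length.
#' @param move_width Gaussian move width in log-space.
#' @param seed RNG seed.
#' @return List with `chain` (sigmaB samples), `acceptance` rate.
#' @export
gibbs_sample_sigma <- function(delta, sigmaSEM, support, n_steps = 10000,
                               move_width = 0.3, seed = 1) {
  stopifnot(length(support) == 2, all(support > 0), support[1] < support[2],
            sigmaSEM > 0)
  set.seed(seed)
  ss <- sum(delta^2); nobs <- length(delta)
  lpost <- function(s) .noise_loglik(s, ss, nobs, sigmaSEM) - log(s)
  cur <- sqrt(support[1] * support[2])
  lcur <- lpost(cur)
  chain <- numeric(n_steps)
  acc <- 0L
  for (t in seq_len(n_steps)) {
    prop <- cur * exp(move_width * stats::rnorm(1))
    if (prop >= support[1] && prop <= support[2]) {
      lprop <- lpost(prop)
      # log-normal proposal: q(cur|prop)/q(prop|cur) = prop/cur
      if (log(stats::runif(1)) < lprop - lcur + log(prop) - log(cur)) {
        cur <- prop; lcur <- lprop; acc <- acc + 1L
      }
    }
    chain[t] <- cur
  }
  list(chain = chain, acceptance = acc / n_steps)
}

#' A posteriori noise estimation from an ensemble
#'
#' For each data component, estimates the noise level sigmaB from the
#' trajectory of replica-averaged overlaps: the posterior of sigmaB under
#' the Gaussian likelihood of all frame deviations with a Jeffreys prior is
#' integrated by 1-D quadrature on a log-spaced grid, and summarized by its
#' median. The relative error is `sigmaB_hat / ovDD_i`.
#'
#' @param ovbar_traj F x K matrix: replica-averaged overlaps per saved frame.
#' @param ovDD per-component self-overlaps (length K).
#' @param sigmaSEM per-component statistical errors.
#' @param min_frames minimum number of frames required (default 100).
#' @param support_scale sigmaB support as multiples of `ovDD_i` (default
#'   `c(1e-6, 1e3)`).
#' @param n_grid quadrature grid size.
#' @return An object of class `noise_estimate`: data.frame with `component`,
#'   `sigmaB`, `rel_error`, plus attributes.
#' @export
estimate_noise_posterior <- function(ovbar_traj, ovDD, sigmaSEM,
                                     min_frames = 100,
                                     support_scale = c(1e-6, 1e3),
                                     n_grid = 400) {
  ovbar_traj <- as.matrix(ovbar_traj)
  K <- length(ovDD)
  stopifnot(ncol(ovbar_traj) == K)
  ovbar_traj <- ovbar_traj[stats::complete.cases(ovbar_traj), , drop = FALSE]
  nf <- nrow(ovbar_traj)
  if (nf < min_frames)
    stop("noise estimation needs >= ", min_frames, " frames (got ", nf, ")")
  sigmaSEM <- rep_len(sigmaSEM, K)
  sigmaB <- numeric(K)
  for (i in seq_len(K)) {
    d <- ovDD[i] - ovbar_traj[, i]
    grid <- exp(seq(log(support_scale[1] * ovDD[i]),
                    log(support_scale[2] * ovDD[i]), length.out = n_grid))
    ll <- .noise_loglik(grid, sum(d^2), nf, sigmaSEM[i]) - log(grid)
    w <- exp(ll - max(ll)) * grid # d(sigma) = sigma d(log sigma)
    cdf <- cumsum(w) / sum(w)
    sigmaB[i] <- grid[which(cdf >= 0.5)[1]]
  }
  structure(data.frame(component = seq_len(K), sigmaB = sigmaB,
                       rel_error = sigmaB / ovDD),
            class = c("noise_estimate", "data.frame"),
            n_frames = nf, sigmaSEM = sigmaSEM)
}

#' Error density map
#'
#' Projects per-component relative errors onto a voxel grid as the
#' density-weighted mean of the component relative errors:
#' `sum_i phi_Di(x) relerr_i / sum_i phi_Di(x)`, zero where the total
#' density is below 1e-12.
#'
#' @param noise a [estimate_noise_posterior()] result (or data.frame with
#'   `rel_error`).
#' @param data the data-GMM the estimates refer to.
#' @param grid a [density_map()] grid template.
#' @return A [density_map()] of relative errors.
#' @export
error_density_map <- function(noise, data, grid) {
  stopifnot(inherits(data, "gmm"), nrow(noise) == length(data$w))
  total <- rasterize(data, grid, support_sigmas = 0)
  wsum <- density_map(array(0, dim(grid$values)), grid$voxel, grid$origin)
  vals <- array(0, dim(grid$values))
  for (i in seq_along(data$w)) {
    gi <- gmm(data$w[i], data$mu[i, , drop = FALSE],
              data$sigma[, , i, drop = FALSE])
    vals <- vals + rasterize(gi, grid, support_sigmas = 0)$values *
      noise$rel_error[i]
  }
  out <- vals / pmax(total$values, 1e-12)
  out[total$values < 1e-12] <- 0
  density_map(out, grid$voxel, grid$origin)
}

#' Write a noise estimate as a tab-separated table
#'
#' @param noise a [estimate_noise_posterior()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_noise_table <- function(noise, path) {
  utils::write.table(as.data.frame(noise), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
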