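# Multi-replica sampling of the metainference posterior: hinge-chain toy
# prior, overdamped Langevin dynamics, multiple-time-step map restraint and
# well-tempered metadynamics.

#' Hinge-chain prior potential
#'
#' A bead chain with harmonic bonds, harmonic bending angles (straight rest
#' geometry), and a quartic double well on one hinge angle giving two
#' metastable conformations ("open" and "closed") separated by a tunable
#' barrier, optionally tilted to create a free-energy gap. This is the
#' desk-scale structural prior used by the synthetic benchmark; any object
#' exposing the same `energy`/`gradient`/`model` interface can be used as a
#' prior.
#'
#' @param n_beads number of beads (>= 4).
#' @param bond_length rest bond length, nm (also used as the bead size for
#'   the forward model).
#' @param kb bond stiffness, kJ/mol/nm^2.
#' @param ka bending stiffness of non-hinge angles, kJ/mol/rad^2.
#' @param barrier double-well barrier height, kJ/mol.
#' @param half_sep half-separation of the two wells, rad: minima at
#'   `theta_center +- half_sep`.
#' @param theta_center center of the double well, rad.
#' @param tilt linear tilt `tilt * (theta - theta_center)` creating a
#'   free-energy gap between the wells, kJ/mol/rad.
#' @param hinge index of the hinge bead (angle center); default: middle.
#' @param com_k weak harmonic tether on the chain centroid, kJ/mol/nm^2
#'   (0 = off). Nonperiodic vacuum simulations remove or restrain rigid-body
#'   center-of-mass drift; the tether is this package's equivalent and does
#'   not act on internal coordinates.
#' @param com_ref tether reference point (3-vector, nm).
#' @param bead_sizes per-bead sizes (nm) used by the forward model; the
#'   default is an aperiodic pattern `bond_length * (1 + 0.3 sin(2.4 i))`
#'   emulating the mass variation along a real polymer chain. A homogeneous
#'   chain produces a featureless rod of density that a model can slide
#'   along freely; the pattern locks the registration of model and map.
#' @return An object of class `hinge_chain_prior` with elements `params`,
#'   `energy(x)`, `gradient(x)` (returns forces, i.e. -dE/dx), `model` (an
#'   [atomic_model()] of beads), and `conformers` (list of minimized `open`
#'   and `closed` n x 3 coordinate matrices).
#' @export
hinge_chain_prior <- function(n_beads = 30, bond_length = 0.45, kb = 300,
                              ka = 1000, barrier = 2.5, half_sep = pi / 6,
                              theta_center = pi / 2, tilt = 0,
                              hinge = NULL, com_k = 0,
                              com_ref = c(0, 0, 0), bead_sizes = NULL) {
  stopifnot(n_beads >= 4)
  if (is.null(hinge)) hinge <- (n_beads + 1L) %/% 2L
  stopifnot(hinge >= 2, hinge <= n_beads - 1)
  params <- list(kb = kb, r0 = bond_length, ka = ka, barrier = barrier,
                 half_sep = half_sep, theta_center = theta_center,
                 tilt = tilt, hinge = as.integer(hinge),
                 n_beads = as.integer(n_beads), com_k = com_k,
                 com_ref = as.numeric(com_ref))
  vhinge <- function(th) {
    t <- th - theta_center
    barrier * (t^2 - half_sep^2)^2 / half_sep^4 + tilt * t
  }
  # locate the two wells (exact at theta_center +- half_sep when tilt = 0)
  w_lo <- stats::optimize(vhinge, c(theta_center - 2 * half_sep,
                                    theta_center))$minimum
  w_hi <- stats::optimize(vhinge, c(theta_center,
                                    theta_center + 2 * half_sep))$minimum
  thb <- stats::optimize(vhinge, c(w_lo, w_hi), maximum = TRUE)
  barr_eff <- min(thb$objective - vhinge(w_lo), thb$objective - vhinge(w_hi))
  if (barr_eff <= 0)
    warning("double-well parameters give a single well (computed barrier ",
            format(barr_eff, digits = 3), " kJ/mol)")
  build <- function(theta_hinge) {
    x <- matrix(0, n_beads, 3)
    dir <- 0 # direction angle in the xy-plane
    for (i in 2:n_beads) {
      if (i == hinge + 1L) dir <- dir + (pi - theta_hinge)
      x[i, ] <- x[i - 1, ] + bond_length * c(cos(dir), sin(dir), 0)
    }
    x
  }
  conformers <- list(open = build(w_hi), closed = build(w_lo))
  if (is.null(bead_sizes))
    bead_sizes <- bond_length * (1 + 0.3 * sin(2.4 * seq_len(n_beads)))
  model <- atomic_model(conformers$open, species = "BEAD",
                        size = bead_sizes)
  structure(list(
    params = params,
    energy = function(x) cpp_chain_energy(x, params)$energy,
    gradient = function(x) cpp_chain_energy(x, params)$forces,
    model = model,
    conformers = conformers,
    wells = c(closed = w_lo, open = w_hi),
    hinge_potential = vhinge
  ), class = c("hinge_chain_prior", "prior_potential"))
}

#' Hinge angle of chain conformations
#'
#' @param x n x 3 coordinate matrix, or 3n vector, or a stack of frames
#'   (F x 3n matrix).
#' @param prior the [hinge_chain_prior()] defining the hinge index.
#' @return Hinge angle(s), rad.
#' @export
hinge_angle <- function(x, prior) {
  h <- prior$params$hinge
  one <- function(v) {
    m <- matrix(v, ncol = 3, byrow = TRUE)
    u <- m[h - 1, ] - m[h, ]; w <- m[h + 1, ] - m[h, ]
    acos(pmin(1, pmax(-1, sum(u * w) / sqrt(sum(u^2) * sum(w^2)))))
  }
  if (is.matrix(x) && ncol(x) == 3) return(one(t(x)))
  if (is.matrix(x)) return(apply(x, 1, one))
  one(x)
}

#' Replica ensemble
#'
#' @param x0 starting coordinates: a single n x 3 matrix (replicated) or a
#'   list of one matrix per replica.
#' @param n_replicas number of replicas N.
#' @return An object of class `replica_ensemble`.
#' @export
replica_ensemble <- function(x0, n_replicas = 4) {
  if (is.matrix(x0)) x0 <- rep(list(x0), n_replicas)
  stopifnot(length(x0) == n_replicas, n_replicas >= 1)
  n <- nrow(x0[[1]])
  for (x in x0) stopifnot(is.matrix(x), nrow(x) == n, ncol(x) == 3)
  structure(list(positions = x0, n_replicas = as.integer(n_replicas),
                 n_particles = n), class = "replica_ensemble")
}

#' Metainference run parameters
#'
#' @param alpha sigma_SEM scale: `sigma_SEM_i = alpha * ovDD_i`.
#' @param temperature temperature, K.
#' @param stride restraint stride: the map restraint is recomputed every
#'   `stride` MD steps and applied scaled by `stride` (multiple time step).
#' @param nl_cutoff neighbor-list exponent-factor cutoff.
#' @param nl_update neighbor-list rebuild frequency, MD steps (must be a
#'   multiple of `stride`).
#' @param dt integration step, ps.
#' @param friction Langevin friction (overdamped mobility = dt/friction),
#'   amu/ps.
#' @param save_stride save a frame every this many steps.
#' @param fmax force bound, kJ/mol/nm; the first overflow is capped and
#'   logged, a second aborts the run.
#' @return A `meta_params` list.
#' @export
meta_params <- function(alpha = 0.1, temperature = 300, stride = 2,
                        nl_cutoff = 0.01, nl_update = 100, dt = 1.2e-5,
                        friction = 0.5, save_stride = 1000, fmax = 1e7) {
  stopifnot(alpha > 0, temperature > 0, stride >= 1,
            nl_update %% stride == 0, dt > 0, friction > 0)
  structure(list(alpha = alpha, temperature = temperature,
                 stride = as.integer(stride), nl_cutoff = nl_cutoff,
                 nl_update = as.integer(nl_update), dt = dt,
                 friction = friction, save_stride = as.integer(save_stride),
                 fmax = fmax), class = "meta_params")
}

#' Well-tempered metadynamics bias settings
#'
#' @param W0 initial hill height, kJ/mol.
#' @param bias_factor well-tempered bias factor gamma (> 1); hill heights
#'   decay as `W0 * exp(-V(s) / (kB * (gamma - 1) * T))`.
#' @param width hill width in CV units (kJ/mol for the restraint-score CV,
#'   rad for the hinge-angle CV).
#' @param pace deposition pace, MD steps (must be a multiple of the
#'   restraint stride for the restraint-score CV).
#' @param span half-extent of the bias grid around the initial CV value
#'   (restraint-score CV only; the angle CV grid spans `[0, pi]`).
#' @param cv collective variable the bias acts on: the per-replica
#'   map-restraint score (`"restraint"`, default) or the per-replica hinge
#'   angle of a hinge-chain prior (`"hinge"`).
#' @param bias_steps deposit hills only during the first `bias_steps` MD
#'   steps (default `Inf`: the whole run).
#' @param hold_steps after deposition stops, the accumulated static bias is
#'   faded linearly to zero over `hold_steps` steps (adiabatic release;
#'   default 0 = immediate switch-off). With a finite `bias_steps` the bias
#'   is an equilibration device: frames after `bias_steps + hold_steps` are
#'   sampled without bias and need no reweighting.
#' @return A `metadynamics_bias` object with an empty hill list.
#' @export
metadynamics_bias <- function(W0 = 2.5, bias_factor = 1e4, width = 2,
                              pace = 500, span = 500,
                              cv = c("restraint", "hinge"),
                              bias_steps = Inf, hold_steps = 0) {
  stopifnot(W0 > 0, bias_factor > 1, width > 0, pace >= 1, bias_steps > 0,
            hold_steps >= 0)
  structure(list(W0 = W0, bias_factor = bias_factor, width = width,
                 pace = as.integer(pace), span = span, cv = match.arg(cv),
                 bias_steps = bias_steps, hold_steps = hold_steps,
                 hills = list(centers = numeric(0), heights = numeric(0))),
            class = "metadynamics_bias")
}

#' One well-tempered metadynamics update
#'
#' Deposits a hill of height `W0 * exp(-V(s)/(kB dT))` (with
#' `dT = (gamma - 1) T`) at the current CV value and returns the updated
#' bias with its energy and gradient at `s`. The reference implementation
#' used inside [run_metainference()] accumulates the same hills on a grid.
#'
#' @param bias a [metadynamics_bias()].
#' @param cv_value current collective-variable value.
#' @param step current MD step (hills are deposited when `step %% pace == 0`).
#' @param kBT thermal energy, kJ/mol.
#' @return List with `bias` (updated), `energy` `V(s)` and `gradient`
#'   `dV/ds` at `cv_value`.
#' @export
wt_metadynamics_update <- function(bias, cv_value, step, kBT = kbt()) {
  stopifnot(inherits(bias, "metadynamics_bias"))
  kBdT <- (bias$bias_factor - 1) * kBT
  vfun <- function(s) {
    if (length(bias$hills$centers) == 0) return(0)
    sum(bias$hills$heights *
          exp(-(s - bias$hills$centers)^2 / (2 * bias$width^2)))
  }
  if (step %% bias$pace == 0) {
    h <- bias$W0 * exp(-vfun(cv_value) / kBdT)
    bias$hills$centers <- c(bias$hills$centers, cv_value)
    bias$hills$heights <- c(bias$hills$heights, h)
  }
  g <- if (length(bias$hills$centers) == 0) 0 else
    sum(bias$hills$heights *
          exp(-(cv_value - bias$hills$centers)^2 / (2 * bias$width^2)) *
          -(cv_value - bias$hills$centers) / bias$width^2)
  list(bias = bias, energy = vfun(cv_value), gradient = g)
}

#' Run a multi-replica metainference simulation
#'
#' Overdamped Langevin dynamics of `N` replicas under the prior potential
#' plus the marginalized cryo-EM metainference restraint on the
#' replica-averaged model/data overlaps. The restraint is recomputed every
#' `params$stride` steps with a neighbor list and applied as a
#' multiple-time-step impulse; replicas advance in lockstep so the averaged
#' overlaps always use same-step coordinates. Optionally, a shared
#' well-tempered metadynamics bias acts on the per-replica restraint score
#' (multiple-walker deposition). Fully reproducible from `seed`.
#'
#' @param ensemble a [replica_ensemble()].
#' @param prior a [hinge_chain_prior()] (or object with the same interface).
#' @param data the data-GMM ([gmm()], normalized), or `NULL` to sample the
#'   prior alone.
#' @param params a [meta_params()].
#' @param bias optional [metadynamics_bias()].
#' @param steps number of MD steps.
#' @param seed integer master seed; one stream per replica is derived from
#'   it.
#' @param normalize_model scale the model-GMM weights to mass fractions
#'   (total 1) inside the restraint, matching the weight-normalized data-GMM
#'   convention (default `TRUE`).
#' @param ramp_steps annealing: the restraint force is scaled linearly from
#'   0 to full strength over the first `ramp_steps` steps (0 = full strength
#'   from the start). Frames from the ramp are equilibration, not
#'   production.
#' @return An object of class `meta_traj` with elements `xyz`
#'   (3n x N x F array of saved frames), `ovbar` (F x K replica-averaged
#'   overlaps), `cv` (F x N per-replica restraint scores), `ebias`,
#'   `erestraint`, `final`, `bias` (grid + hills if biased), `ovDD`,
#'   `sigmaSEM`, and the run settings.
#' @export
run_metainference <- function(ensemble, prior, data, params = meta_params(),
                              bias = NULL, steps = 1e5, seed = 1,
                              normalize_model = TRUE, ramp_steps = 0) {
  stopifnot(inherits(ensemble, "replica_ensemble"),
            inherits(prior, "prior_potential"))
  if (!is.null(data) && !data$normalized)
    stop("the data-GMM must be normalized")
  if (nrow(prior$model$xyz) != ensemble$n_particles)
    stop("ensemble/prior topology mismatch")
  steps <- as.integer(steps)
  if (steps %% params$save_stride != 0)
    stop("steps must be a multiple of save_stride")
  p <- .particle_gaussians(prior$model)
  if (normalize_model) p$w <- p$w / sum(p$w)
  restraint_on <- !is.null(data)
  if (restraint_on) {
    ovDD <- self_overlaps(data)
    sigmaSEM <- sigma_sem(ovDD, params$alpha)
    wD <- data$w; muD <- data$mu; sigD <- data$sigma
  } else {
    ovDD <- sigmaSEM <- 1
    wD <- 1; muD <- matrix(0, 1, 3); sigD <- array(diag(3), c(3, 3, 1))
  }
  use_bias <- !is.null(bias)
  if (use_bias) {
    stopifnot(inherits(bias, "metadynamics_bias"))
    if (bias$cv == "restraint" && bias$pace %% params$stride != 0)
      stop("bias pace must be a multiple of the restraint stride")
    if (bias$cv == "hinge" && !inherits(prior, "hinge_chain_prior"))
      stop("the hinge-angle CV needs a hinge_chain_prior")
  }
  kBT <- kbt(params$temperature)
  r <- cpp_run_meta(ensemble$positions, prior$params, p$w, p$v, wD, muD,
                    sigD, ovDD, sigmaSEM, kBT, restraint_on, params$dt,
                    params$friction, steps, params$stride, params$nl_cutoff,
                    params$nl_update, params$save_stride, use_bias,
                    if (use_bias) bias$W0 else 1,
                    if (use_bias) bias$bias_factor else 2,
                    if (use_bias) bias$width else 1,
                    if (use_bias) bias$pace else 1L,
                    if (use_bias) bias$span else 1,
                    as.numeric(seed), params$fmax, as.integer(ramp_steps),
                    if (use_bias && bias$cv == "hinge") 1L else 0L,
                    if (use_bias) min(bias$bias_steps, steps + 1) else 0,
                    if (use_bias) min(bias$bias_steps + bias$hold_steps,
                                      steps + 1) else 0)
  if (r$halved > 0)
    warning("force bound exceeded once; the offending force was capped")
  structure(list(xyz = r$traj, ovbar = r$ovbar, cv = r$cv, ebias = r$ebias,
                 erestraint = r$erestraint, final = r$final, bias = r$bias,
                 ovDD = if (restraint_on) ovDD else NULL,
                 sigmaSEM = if (restraint_on) sigmaSEM else NULL,
                 params = params, steps = steps, seed = seed,
                 ramp_steps = as.integer(ramp_steps),
                 n_replicas = ensemble$n_replicas,
                 n_particles = ensemble$n_particles,
                 kBT = kBT),
            class = "meta_traj")
}

#' @export
print.meta_traj <- function(x, ...) {
  cat(sprintf("metainference trajectory: %d replicas x %d saved frames, %d particles\n",
              x$n_replicas, dim(x$xyz)[3], x$n_particles))
  invisible(x)
}

#' Extract frames from a trajectory
#'
#' @param traj a [run_metainference()] result.
#' @param discard fraction of initial frames to discard (burn-in).
#' @param pool pool all replicas (`TRUE`) or return per-replica list.
#' @return A (F*N) x 3n coordinate matrix (pooled, replica-major within each
#'   frame) or a list of F x 3n matrices.
#' @export
traj_frames <- function(traj, discard = 0, pool = TRUE) {
  stopifnot(inherits(traj, "meta_traj"))
  d <- dim(traj$xyz)
  keep <- seq_len(d[3]) > floor(discard * d[3])
  xs <- traj$xyz[, , keep, drop = FALSE]
  N <- d[2]
  out <- lapply(seq_len(N), function(r) t(xs[, r, , drop = TRUE]))
  if (!pool) return(out)
  F2 <- sum(keep)
  m <- matrix(0, F2 * N, d[1])
  for (r in seq_len(N)) m[seq(r, F2 * N, by = N), ] <- out[[r]]
  m
}
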