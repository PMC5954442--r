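# Synthetic two-state benchmark: a hinge-chain system whose "experimental"
# map is the weighted average of the maps of two metastable conformers,
# mirroring the construction of ensemble-averaged cryo-EM data from a
# conformational mixture. Ground truth (mixing weights, conformers) is kept
# alongside so that recovered populations and inferred noise can be scored.

#' Build the two-state benchmark
#'
#' Builds the hinge-chain prior and its two minimized conformers, rasterizes
#' each through the coarse-grained forward model, and mixes the two per-state
#' maps with weights `w` and `1 - w` into the benchmark "experimental" map.
#'
#' @param n_beads beads in the chain (default 30).
#' @param w mixing weight of the open state in the average map.
#' @param voxel map voxel size, nm (default 0.3).
#' @param margin empty border around the conformers, nm.
#' @param barrier hinge double-well barrier, kJ/mol.
#' @param com_k center-of-mass tether stiffness passed to the prior
#'   (kJ/mol/nm^2); keeps replicas from diffusing bodily out of the map
#'   region, as center-of-mass motion removal does in nonperiodic MD.
#' @param seed seed recorded in the benchmark settings (map construction is
#'   deterministic).
#' @param ... further arguments to [hinge_chain_prior()].
#' @return An object of class `two_state_benchmark`: `prior`, `conformers`,
#'   `maps` (`open`, `closed`, `mixture` on a shared grid), `truth` (mixing
#'   weights and conformer coordinates), `spec`.
#' @export
make_two_state_benchmark <- function(n_beads = 30, w = 0.5, voxel = 0.3,
                                     margin = 1.5, barrier = 2.5, seed = 1,
                                     com_k = 10, ...) {
  stopifnot(w >= 0, w <= 1)
  prior <- hinge_chain_prior(n_beads = n_beads, barrier = barrier, ...)
  if (com_k > 0) {
    ctr <- colMeans(rbind(prior$conformers$open, prior$conformers$closed))
    prior <- hinge_chain_prior(n_beads = n_beads, barrier = barrier,
                               com_k = com_k, com_ref = ctr, ...)
  }
  conf <- prior$conformers
  sep <- backbone_rmsd(conf$open, conf$closed)
  if (sep < 0.2)
    stop("conformers are only ", format(sep, digits = 3),
         " nm RMSD apart; the two states are not distinguishable at ",
         "benchmark resolution")
  all_xyz <- rbind(conf$open, conf$closed)
  span <- rbind(apply(all_xyz, 2, min) - margin,
                apply(all_xyz, 2, max) + margin)
  grid <- map_template(span, voxel)
  gm_open <- model_gmm(atomic_model(conf$open, "BEAD",
                                    size = prior$model$size))
  gm_closed <- model_gmm(atomic_model(conf$closed, "BEAD",
                                      size = prior$model$size))
  map_open <- rasterize(gm_open, grid)
  map_closed <- rasterize(gm_closed, grid)
  mixture <- density_map(w * map_open$values + (1 - w) * map_closed$values,
                         grid$voxel, grid$origin)
  structure(list(
    prior = prior,
    conformers = conf,
    maps = list(open = map_open, closed = map_closed, mixture = mixture),
    grid = grid,
    truth = list(weights = c(open = w, closed = 1 - w),
                 conformers = conf, separation_rmsd = sep),
    spec = list(n_beads = n_beads, w = w, voxel = voxel, margin = margin,
                barrier = barrier, seed = seed)
  ), class = "two_state_benchmark")
}

#' Initial replica ensemble from the prior's minima
#'
#' Under the symmetric hinge prior the two wells carry exactly equal
#' Boltzmann weight (the internal-coordinate marginal of the hinge angle is
#' `sin(theta) exp(-V(theta)/kBT)`, symmetric about the well midpoint), so
#' the prior's equilibrium replica composition is a 50/50 mixture of the
#' two conformers. Replicas are initialized stratified across the two
#' minima (odd replicas open, even closed), which is the minimum-variance
#' draw from that distribution; the restraint ramp of the production run
#' then reshapes the composition to match the data. Starting structures sit
#' in the map frame, as after the rigid-body docking that precedes any
#' flexible-fitting protocol.
#'
#' @param bench a [make_two_state_benchmark()].
#' @param n_replicas number of replicas.
#' @return A [replica_ensemble()].
#' @export
initial_ensemble <- function(bench, n_replicas = 4) {
  x0 <- lapply(seq_len(n_replicas), function(r)
    if (r %% 2 == 1) bench$conformers$open else bench$conformers$closed)
  ens <- replica_ensemble(x0[[1]], n_replicas)
  ens$positions <- x0
  ens
}

#' Serialize / restore the benchmark ground truth
#'
#' @param bench a [make_two_state_benchmark()] result.
#' @param path JSON path.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` the truth record.
#' @export
write_ground_truth <- function(bench, path) {
  gt <- list(weights = as.list(bench$truth$weights),
             open = bench$truth$conformers$open,
             closed = bench$truth$conformers$closed,
             separation_rmsd = bench$truth$separation_rmsd,
             spec = bench$spec)
  jsonlite::write_json(gt, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$open <- matrix(unlist(gt$open), ncol = 3)
  gt$closed <- matrix(unlist(gt$closed), ncol = 3)
  gt
}

#' Inject spurious density into a data-GMM
#'
#' Adds off-model components — a shell of small Gaussians placed at least
#' `min_dist` from every bead position of both conformers — carrying a
#' fraction `fraction` of the total weight after renormalization. Emulates
#' density in the map that the structural model cannot explain (ligands,
#' detergent, reconstruction artifacts), which noise inference should flag.
#'
#' @param data the (normalized) data-GMM.
#' @param bench the benchmark (source of bead positions).
#' @param fraction spurious weight fraction in (0, 0.5).
#' @param n_spurious number of spurious components.
#' @param min_dist minimum distance from any bead mean, nm.
#' @param sd standard deviation of the spurious Gaussians, nm.
#' @param seed RNG seed for shell placement.
#' @return List: `gmm` (renormalized), `spurious` (logical label per
#'   component).
#' @export
inject_spurious_density <- function(data, bench, fraction = 0.1,
                                    n_spurious = 6, min_dist = 1, sd = 0.25,
                                    seed = 1) {
  stopifnot(inherits(data, "gmm"), fraction >= 0, fraction < 0.5)
  if (fraction == 0)
    return(list(gmm = data, spurious = rep(FALSE, length(data$w))))
  set.seed(seed)
  beads <- rbind(bench$conformers$open, bench$conformers$closed)
  ctr <- colMeans(beads)
  rmax <- sqrt(max(rowSums(sweep(beads, 2, ctr)^2)))
  K <- length(data$w)
  mu_s <- matrix(0, n_spurious, 3)
  for (j in seq_len(n_spurious)) {
    repeat {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      pos <- ctr + u * (rmax + min_dist + 0.2)
      if (min(sqrt(rowSums(sweep(beads, 2, pos)^2))) >= min_dist) break
    }
    mu_s[j, ] <- pos
  }
  w <- c(data$w * (1 - fraction), rep(fraction / n_spurious, n_spurious))
  mu <- rbind(data$mu, mu_s)
  sig <- array(0, c(3, 3, K + n_spurious))
  sig[, , seq_len(K)] <- data$sigma
  for (j in seq_len(n_spurious)) sig[, , K + j] <- diag(3) * sd^2
  list(gmm = gmm(w, mu, sig, normalized = TRUE, label = "data+spurious"),
       spurious = c(rep(FALSE, K), rep(TRUE, n_spurious)))
}

#' Run the full two-state experiment
#'
#' The complete pipeline on the synthetic benchmark: fit a data-GMM to the
#' mixture map (divide and conquer), optionally inject spurious density,
#' run multi-replica metainference with replicas seeded from the prior's
#' minima ([initial_ensemble()]) under a restraint ramp, cluster the pooled
#' ensemble, map clusters to the ground-truth states by RMSD, and report
#' recovered populations, cluster-center accuracy, and (when spurious
#' density was injected) per-component noise with clean/spurious labels.
#'
#' @param bench a [make_two_state_benchmark()].
#' @param n_replicas replicas N (default 4).
#' @param steps MD steps per replica.
#' @param seed master seed.
#' @param alpha sigma_SEM scale.
#' @param budget data-GMM component budget.
#' @param spurious_fraction weight fraction of injected spurious density
#'   (0 = none).
#' @param cutoff clustering RMSD cutoff, nm. The default 0.5 nm sits between
#'   the thermal RMSD spread inside one state of the bead system and the
#'   open/closed separation.
#' @param major_threshold population above which a cluster counts as major.
#' @param max_cluster_frames cap on pooled frames entering clustering
#'   (deterministic thinning).
#' @param ramp_fraction fraction of the run over which the restraint is
#'   annealed from zero to full strength: replicas partition between the
#'   states while still mobile, before the full-strength restraint locks
#'   the ensemble composition.
#' @param discard fraction of initial frames excluded from analysis (must
#'   cover the ramp).
#' @param bias a [metadynamics_bias()], `NULL` (no bias), or `"auto"`
#'   (default): well-tempered metadynamics on the per-replica hinge angle,
#'   active during the ramp only, so that replicas exchange states freely
#'   while the annealed restraint selects the ensemble composition;
#'   production frames are unbiased.
#' @param params optional [meta_params()] override.
#' @return An object of class `two_state_report`.
#' @export
run_two_state_experiment <- function(bench, n_replicas = 4, steps = 2e6,
                                     seed = 1, alpha = 0.1, budget = 64,
                                     spurious_fraction = 0, cutoff = 0.5,
                                     major_threshold = 0.1,
                                     max_cluster_frames = 1200,
                                     ramp_fraction = 0.05, discard = 0.75,
                                     bias = "auto", params = NULL) {
  stopifnot(inherits(bench, "two_state_benchmark"))
  fitcfg <- fit_config(budget = budget, seed = seed)
  data <- fit_gmm_dc(bench$maps$mixture, fitcfg)
  fit_cc <- tail(attr(data, "report")$cc, 1)
  labels <- rep(FALSE, length(data$w))
  if (spurious_fraction > 0) {
    inj <- inject_spurious_density(data, bench, fraction = spurious_fraction,
                                   seed = seed)
    data <- inj$gmm
    labels <- inj$spurious
  }
  if (is.null(params)) params <- meta_params(alpha = alpha)
  else params$alpha <- alpha
  ens <- initial_ensemble(bench, n_replicas)
  ramp_steps <- floor(ramp_fraction * steps)
  if (identical(bias, "auto"))
    bias <- metadynamics_bias(W0 = 2, bias_factor = 8, width = 0.12,
                              pace = 1000, cv = "hinge",
                              bias_steps = floor(0.3 * steps),
                              hold_steps = floor(0.4 * steps))
  traj <- run_metainference(ens, bench$prior, data, params = params,
                            bias = bias, steps = steps, seed = seed,
                            ramp_steps = ramp_steps)
  pooled <- traj_frames(traj, discard = discard)
  if (nrow(pooled) > max_cluster_frames) {
    # thin whole frames (all replicas of a time point together) so the
    # stride cannot alias with the replica interleaving
    nf <- nrow(pooled) / n_replicas
    fkeep <- seq(1, nf, by = ceiling(nf * n_replicas / max_cluster_frames))
    keep <- as.vector(outer(seq_len(n_replicas), (fkeep - 1) * n_replicas,
                            `+`))
    pooled <- pooled[keep, , drop = FALSE]
  }
  cl <- gromos_cluster(pooled, cutoff = cutoff)
  refs <- rbind(as.vector(t(bench$conformers$open)),
                as.vector(t(bench$conformers$closed)))
  major <- which(cl$populations >= major_threshold)
  dmat <- cpp_rmsd_to_refs(pooled[cl$centers[major], , drop = FALSE], refs)
  state <- c("open", "closed")[max.col(-dmat)]
  ambiguous <- length(major) > 1 && length(unique(state)) < 2 &&
    min(bench$truth$weights) > 0.05
  pop_state <- c(open = 0, closed = 0)
  for (j in seq_along(major))
    pop_state[state[j]] <- pop_state[state[j]] + cl$populations[major[j]]
  pop_norm <- pop_state / sum(pop_state)
  noise <- NULL
  if (!is.null(traj$ovbar)) {
    ok <- stats::complete.cases(traj$ovbar)
    ov <- traj$ovbar[ok, , drop = FALSE]
    ov <- ov[seq_len(nrow(ov)) > floor(discard * nrow(ov)), , drop = FALSE]
    if (nrow(ov) >= 100) { # short exploratory runs skip noise inference
      noise <- estimate_noise_posterior(ov, traj$ovDD, traj$sigmaSEM)
      noise$spurious <- labels
    }
  }
  structure(list(
    data_gmm = data, fit_cc = fit_cc, traj = traj, clusters = cl,
    major = major, major_state = state,
    major_populations = cl$populations[major],
    center_rmsd_to_truth = apply(dmat, 1, min),
    populations = pop_state, populations_normalized = pop_norm,
    ratio = if (length(major) >= 2 && !ambiguous && all(pop_norm > 0))
      max(pop_norm) / min(pop_norm) else NA_real_,
    ambiguous = ambiguous, noise = noise,
    truth = bench$truth$weights,
    settings = list(n_replicas = n_replicas, steps = steps, seed = seed,
                    alpha = alpha, budget = budget, cutoff = cutoff,
                    spurious_fraction = spurious_fraction,
                    ramp_fraction = ramp_fraction, discard = discard)
  ), class = "two_state_report")
}

#' @export
print.two_state_report <- function(x, ...) {
  cat("two-state benchmark report\n")
  cat(sprintf("  data-GMM: %d components, fit CC %.4f\n",
              length(x$data_gmm$w), x$fit_cc))
  cat(sprintf("  %d major cluster(s): %s\n", length(x$major),
              paste(sprintf("%s %.3f", x$major_state, x$major_populations),
                    collapse = ", ")))
  cat(sprintf("  recovered open fraction %.3f (truth %.2f)%s\n",
              x$populations_normalized[["open"]], x$truth[["open"]],
              if (x$ambiguous) " [AMBIGUOUS STATE MAPPING]" else ""))
  if (!is.null(x$noise) && any(x$noise$spurious))
    cat(sprintf("  relative noise: spurious median %.3g vs clean median %.3g\n",
                stats::median(x$noise$rel_error[x$noise$spurious]),
                stats::median(x$noise$rel_error[!x$noise$spurious])))
  invisible(x)
}

#' JSON-serializable benchmark report
#'
#' @param report a [run_two_state_experiment()] result.
#' @param path optional path; when given the JSON is written there.
#' @return The report list (invisibly when `path` is given).
#' @export
report_to_json <- function(report, path = NULL) {
  out <- list(
    schema = "densemble/two-state-report/1",
    settings = report$settings,
    fit_cc = report$fit_cc,
    n_major_clusters = length(report$major),
    major_state = report$major_state,
    major_populations = report$major_populations,
    populations_normalized = as.list(report$populations_normalized),
    ratio = report$ratio,
    ambiguous = report$ambiguous,
    truth = as.list(report$truth),
    center_rmsd_to_truth = report$center_rmsd_to_truth,
    noise = if (!is.null(report$noise)) list(
      median_rel_error_clean =
        stats::median(report$noise$rel_error[!report$noise$spurious]),
      median_rel_error_spurious = if (any(report$noise$spurious))
        stats::median(report$noise$rel_error[report$noise$spurious])
    )
  )
  if (!is.null(path)) {
    jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
    return(invisible(out))
  }
  out
}
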