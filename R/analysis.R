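# Ensemble analysis: Kabsch RMSD, GROMOS clustering, population errors,
# distance collective variables and free-energy surfaces.

.frame_coords <- function(frame, selection = NULL) {
  if (is.matrix(frame) && ncol(frame) == 3) frame <- as.vector(t(frame))
  frame <- as.numeric(frame)
  if (!is.null(selection)) {
    idx <- as.vector(t(outer(3 * (selection - 1), 1:3, `+`)))
    frame <- frame[idx]
  }
  frame
}

#' Backbone RMSD after optimal superposition
#'
#' Least-squares optimal-rotation (Kabsch) RMSD between two conformations;
#' symmetric, zero for identical frames and for frames differing only by a
#' rigid motion.
#'
#' @param frame_a,frame_b conformations as n x 3 matrices or length-3n
#'   vectors (x1 y1 z1 x2 ...), nm.
#' @param selection optional particle indices used both for the fit and the
#'   RMSD; at least 3 non-collinear points.
#' @return RMSD, nm.
#' @export
backbone_rmsd <- function(frame_a, frame_b, selection = NULL) {
  a <- .frame_coords(frame_a, selection)
  b <- .frame_coords(frame_b, selection)
  stopifnot(length(a) == length(b), length(a) %% 3 == 0)
  m <- matrix(a, ncol = 3, byrow = TRUE)
  if (nrow(m) < 3) stop("selection must contain at least 3 points")
  sv <- svd(scale(m, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate (collinear) selection")
  cpp_rmsd_pair(a, b)
}

#' Pairwise RMSD matrix
#'
#' @param frames F x 3n coordinate matrix.
#' @param selection optional particle indices.
#' @return F x F symmetric matrix of superposed RMSDs, nm.
#' @export
rmsd_matrix <- function(frames, selection = NULL) {
  if (!is.null(selection)) {
    idx <- as.vector(t(outer(3 * (selection - 1), 1:3, `+`)))
    frames <- frames[, idx, drop = FALSE]
  }
  cpp_rmsd_matrix(frames)
}

#' GROMOS clustering
#'
#' Greedy neighbor-count clustering of conformations under an RMSD cutoff:
#' iteratively, the unassigned frame with the most unassigned neighbors
#' within `cutoff` becomes a cluster center (ties broken by lowest frame
#' index); it and its neighbors form a cluster and are removed.
#'
#' @param frames F x 3n coordinate matrix (e.g. from [traj_frames()]).
#' @param cutoff RMSD cutoff, nm (default 0.35).
#' @param selection optional particle indices used for the RMSD.
#' @return An object of class `cluster_result`: list with `centers` (frame
#'   indices), `membership` (cluster id per frame, in discovery order =
#'   decreasing size), `populations`, `sizes`, `cutoff`.
#' @export
gromos_cluster <- function(frames, cutoff = 0.35, selection = NULL) {
  frames <- as.matrix(frames)
  F2 <- nrow(frames)
  stopifnot(F2 >= 1)
  rm <- rmsd_matrix(frames, selection)
  adj <- rm <= cutoff
  membership <- rep(NA_integer_, F2)
  centers <- integer(0)
  cl <- 0L
  unassigned <- rep(TRUE, F2)
  while (any(unassigned)) {
    cl <- cl + 1L
    counts <- rowSums(adj[, unassigned, drop = FALSE]) # includes self
    counts[!unassigned] <- -1
    center <- which.max(counts) # ties: lowest index
    memb <- which(unassigned & adj[center, ])
    membership[memb] <- cl
    centers <- c(centers, center)
    unassigned[memb] <- FALSE
  }
  sizes <- tabulate(membership, nbins = cl)
  structure(list(centers = centers, membership = membership,
                 populations = sizes / F2, sizes = sizes, cutoff = cutoff,
                 n_frames = F2),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("GROMOS clustering: %d frames, %d clusters (cutoff %.3g nm)\n",
              x$n_frames, length(x$centers), x$cutoff))
  k <- head(order(-x$populations), 10)
  for (i in k)
    cat(sprintf("  cluster %d: population %.3f (center frame %d)\n", i,
                x$populations[i], x$centers[i]))
  invisible(x)
}

#' Cluster population errors from run halves
#'
#' For each run, the initial `discard` fraction of its frames is dropped,
#' the remainder is split into first and second half, and per-cluster
#' populations are computed in each half. Reported are the mean and
#' standard deviation over the halves, per run.
#'
#' @param result a [gromos_cluster()] result over the concatenated runs.
#' @param runs integer vector: run label of every clustered frame, in
#'   temporal order within each run.
#' @param discard initial fraction of each run to discard (default 0.2).
#' @return data.frame with `cluster`, `run`, `population`, `sd`.
#' @export
population_errors <- function(result, runs = rep(1L, result$n_frames),
                              discard = 0.2) {
  stopifnot(inherits(result, "cluster_result"),
            length(runs) == result$n_frames)
  ncl <- length(result$centers)
  out <- list()
  for (r in unique(runs)) {
    idx <- which(runs == r)
    idx <- idx[seq_along(idx) > floor(discard * length(idx))]
    if (length(idx) < 2) stop("run ", r, " has an empty half after discard")
    halves <- split(idx, seq_along(idx) > length(idx) / 2)
    pops <- vapply(halves, function(h)
      tabulate(result$membership[h], nbins = ncl) / length(h),
      numeric(ncl))
    out[[length(out) + 1L]] <- data.frame(
      cluster = seq_len(ncl), run = r,
      population = rowMeans(pops), sd = apply(pops, 1, stats::sd))
  }
  do.call(rbind, out)
}

#' Distance collective variable
#'
#' Euclidean distance between two atoms or between the unweighted geometric
#' centers of two particle groups.
#'
#' @param frame an n x 3 matrix or length-3n vector.
#' @param group_a,group_b particle index vectors (singletons in `atom-pair`
#'   mode).
#' @param mode `"geometric-centers"` (default) or `"atom-pair"`.
#' @return Distance, nm.
#' @export
distance_cv <- function(frame, group_a, group_b,
                        mode = c("geometric-centers", "atom-pair")) {
  mode <- match.arg(mode)
  if (!is.matrix(frame) || ncol(frame) != 3)
    frame <- matrix(as.numeric(frame), ncol = 3, byrow = TRUE)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("empty selection")
  if (mode == "atom-pair" && (length(group_a) != 1 || length(group_b) != 1))
    stop("atom-pair mode needs single-atom selections")
  ca <- colMeans(frame[group_a, , drop = FALSE])
  cb <- colMeans(frame[group_b, , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

#' Free-energy surface from CV samples
#'
#' Boltzmann inversion of a (weighted) histogram: `F = -kBT log(density)`,
#' shifted so the minimum is zero. Unvisited bins are `NA` (flagged, not
#' zero).
#'
#' @param samples numeric vector (1-D) or 2-column matrix (2-D) of CV
#'   samples.
#' @param bins number of bins per axis (default 50).
#' @param kBT thermal energy used for the inversion; `F` is returned in
#'   units of kBT when `kBT = 1`.
#' @param weights optional per-sample weights (e.g. metadynamics
#'   reweighting); doubling all weights leaves `F` unchanged.
#' @param limits optional range (1-D: length-2; 2-D: 2 x 2 matrix, rows =
#'   axis).
#' @return An object of class `free_energy_surface`: `grid` (bin centers,
#'   list per axis), `F` (vector or matrix, min 0), `counts`.
#' @export
free_energy_surface <- function(samples, bins = 50, kBT = 1,
                                weights = NULL, limits = NULL) {
  if (is.matrix(samples) && ncol(samples) == 2) d <- 2L
  else { samples <- cbind(as.numeric(samples)); d <- 1L }
  M <- nrow(samples)
  if (M < 100) stop("need >= 100 samples (got ", M, ")")
  if (is.null(weights)) weights <- rep(1, M)
  stopifnot(length(weights) == M, all(weights >= 0))
  bins <- rep_len(as.integer(bins), d)
  if (is.null(limits)) {
    limits <- t(apply(samples, 2, range))
  } else if (d == 1L && is.null(dim(limits))) limits <- matrix(limits, 1)
  edges <- lapply(seq_len(d), function(a)
    seq(limits[a, 1], limits[a, 2], length.out = bins[a] + 1))
  idx <- vapply(seq_len(d), function(a) {
    i <- findInterval(samples[, a], edges[[a]], rightmost.closed = TRUE)
    pmin(pmax(i, 1L), bins[a])
  }, integer(M))
  flat <- idx[, 1]
  if (d == 2L) flat <- flat + bins[1] * (idx[, 2] - 1L)
  counts <- numeric(prod(bins))
  for (j in seq_len(M)) counts[flat[j]] <- counts[flat[j]] + weights[j]
  if (sum(counts > 0) <= 1) warning("all samples fall in one bin")
  dens <- counts / sum(counts)
  Fv <- ifelse(counts > 0, -kBT * log(dens), NA_real_)
  Fv <- Fv - min(Fv, na.rm = TRUE)
  grid <- lapply(edges, function(e) (head(e, -1) + tail(e, -1)) / 2)
  if (d == 2L) { dim(Fv) <- bins; dim(counts) <- bins }
  structure(list(grid = grid, F = Fv, counts = counts, kBT = kBT,
                 bins = bins, dims = d),
            class = "free_energy_surface")
}

#' Plot a free-energy surface
#'
#' @param x a [free_energy_surface()].
#' @param xlab,ylab axis labels.
#' @param ... passed to the underlying plot function.
#' @return Invisibly, `x`.
#' @export
plot.free_energy_surface <- function(x, xlab = "CV", ylab = NULL, ...) {
  if (x$dims == 1L) {
    graphics::plot(x$grid[[1]], x$F, type = "l", xlab = xlab,
                   ylab = if (is.null(ylab)) "F (kBT)" else ylab, ...)
  } else {
    graphics::image(x$grid[[1]], x$grid[[2]], x$F, xlab = xlab,
                    ylab = if (is.null(ylab)) "CV 2" else ylab,
                    col = grDevices::hcl.colors(64, "viridis"), ...)
    graphics::contour(x$grid[[1]], x$grid[[2]], x$F, add = TRUE)
  }
  invisible(x)
}

#' Metadynamics reweighting factors
#'
#' Final-bias reweighting: per-frame weights `exp(V_final(s_t) / kBT)` from
#' the accumulated bias potential of a biased run, suitable for the
#' `weights` argument of [free_energy_surface()].
#'
#' @param traj a biased [run_metainference()] result.
#' @param cv_values F x N matrix of the per-frame CV values the bias acted
#'   on; defaults to the stored per-replica restraint score (`traj$cv`).
#'   For a hinge-angle bias pass the per-frame hinge angles instead.
#' @return F x N matrix of weights (1 everywhere for unbiased runs).
#' @export
metad_weights <- function(traj, cv_values = NULL) {
  stopifnot(inherits(traj, "meta_traj"))
  if (is.null(cv_values)) cv_values <- traj$cv
  if (is.null(traj$bias))
    return(matrix(1, nrow(cv_values), ncol(cv_values)))
  vb <- apply(cv_values, 2, function(s)
    stats::approx(traj$bias$grid, traj$bias$potential, xout = s,
                  rule = 2)$y)
  w <- exp((vb - max(vb, na.rm = TRUE)) / traj$kBT)
  w[is.na(w)] <- 0
  w
}
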