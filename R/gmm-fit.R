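# Fit a data-GMM to a voxel map: density-weighted EM with seeded k-means++
# initialization, refined hierarchically (divide and conquer).

#' Fitting configuration
#'
#' @param K0 number of components of the initial global fit.
#' @param branching children per split during refinement (>= 2).
#' @param budget target total component count (divide-and-conquer stop).
#' @param target_cc stop refining once the rasterized fit reaches this global
#'   cross-correlation with the input map.
#' @param tol relative log-likelihood change declaring EM convergence.
#' @param max_iter maximum EM iterations.
#' @param seed RNG seed (initialization is the only stochastic step).
#' @param min_density voxels below `min_density * max(map)` are ignored as
#'   numerically empty (after clipping negatives to zero).
#' @param polish_iter global EM iterations run on the assembled mixture
#'   after each divide-and-conquer level (keeps the hierarchical fit at a
#'   global likelihood optimum).
#' @return A `fit_config` list.
#' @export
fit_config <- function(K0 = 4, branching = 4, budget = NULL,
                       target_cc = NULL, tol = 1e-6, max_iter = 200,
                       seed = 1, min_density = 1e-8, polish_iter = 10) {
  stopifnot(K0 >= 1, branching >= 2, tol > 0, max_iter >= 1,
            polish_iter >= 0)
  structure(list(K0 = as.integer(K0), branching = as.integer(branching),
                 budget = if (!is.null(budget)) as.integer(budget),
                 target_cc = target_cc, tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 min_density = min_density,
                 polish_iter = as.integer(polish_iter)),
            class = "fit_config")
}

# voxel centers + clipped density weights of a map
.map_points <- function(map, min_density) {
  dims <- dim(map$values)
  v <- pmax(as.vector(map$values), 0)
  keep <- v > min_density * max(v)
  idx <- which(keep) - 1L
  ix <- idx %% dims[1]
  iy <- (idx %/% dims[1]) %% dims[2]
  iz <- idx %/% (dims[1] * dims[2])
  x <- cbind(map$origin[1] + ix * map$voxel[1],
             map$origin[2] + iy * map$voxel[2],
             map$origin[3] + iz * map$voxel[3])
  list(x = x, w = v[keep] / sum(v[keep]))
}

# weighted k-means++ seeding
.kmeanspp <- function(x, w, K) {
  M <- nrow(x)
  centers <- matrix(0, K, 3)
  i <- sample.int(M, 1, prob = w)
  centers[1, ] <- x[i, ]
  if (K > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (k in 2:K) {
      p <- w * d2
      i <- sample.int(M, 1, prob = p / sum(p))
      centers[k, ] <- x[i, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[k, ])^2))
    }
  }
  centers
}

# log-density of K Gaussians at M points -> M x K
.log_dens <- function(x, mu, sigma) {
  K <- nrow(mu)
  out <- matrix(0, nrow(x), K)
  for (k in seq_len(K)) {
    ch <- chol(sigma[, , k])
    d <- sweep(x, 2, mu[k, ])
    out[, k] <- -0.5 * rowSums((d %*% chol2inv(ch)) * d) -
      sum(log(diag(ch))) - 1.5 * log(2 * pi)
  }
  out
}

.floor_cov <- function(S, floor_var) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, floor_var)
  e$vectors %*% (ev * t(e$vectors))
}

#' Weighted EM fit of a K-component GMM to a density map
#'
#' Each voxel center is a data point weighted by its (negative-clipped)
#' density; EM maximizes the weighted Gaussian-mixture log-likelihood.
#' Covariance eigenvalues are floored at `(voxel/2)^2` so no component can
#' collapse below voxel scale. Initialization is density-weighted k-means++
#' under the configured seed (deterministic).
#'
#' @param map a [density_map()].
#' @param K component count.
#' @param config a [fit_config()].
#' @param init optional [gmm()] used as starting point instead of k-means++.
#' @return A normalized [gmm()] with attributes `loglik` (per-iteration
#'   trace) and `iterations`.
#' @export
fit_gmm_em <- function(map, K, config = fit_config(), init = NULL) {
  pts <- .map_points(map, config$min_density)
  floor_var <- (min(map$voxel) / 2)^2
  fit <- .em_fit(pts$x, pts$w, K, config, floor_var, init = init,
                 seed = config$seed)
  out <- gmm(fit$pi, fit$mu, fit$sigma, normalized = TRUE, label = "em fit")
  attr(out, "loglik") <- fit$loglik
  attr(out, "iterations") <- fit$iterations
  out
}

# core weighted EM on points; returns list(pi, mu, sigma, loglik, iterations,
# assign (hard max-responsibility labels))
.em_fit <- function(x, w, K, config, floor_var, init = NULL, seed = 1) {
  M <- nrow(x)
  if (K > M) stop("K = ", K, " exceeds the ", M, " positive-density voxels")
  if (is.null(init)) {
    set.seed(seed)
    centers <- .kmeanspp(x, w, K)
    d2 <- vapply(seq_len(K),
                 function(k) rowSums(sweep(x, 2, centers[k, ])^2),
                 numeric(M))
    lab <- max.col(-d2, ties.method = "first")
    pi_k <- numeric(K); mu <- matrix(0, K, 3); sigma <- array(0, c(3, 3, K))
    for (k in seq_len(K)) {
      sel <- lab == k
      wk <- w[sel]
      if (sum(wk) <= 0) { # empty cell: fall back to the seeding center
        pi_k[k] <- 1e-8; mu[k, ] <- centers[k, ]
        sigma[, , k] <- diag(3) * max(floor_var, 4 * floor_var)
        next
      }
      pi_k[k] <- sum(wk)
      mu[k, ] <- colSums(x[sel, , drop = FALSE] * wk) / sum(wk)
      d <- sweep(x[sel, , drop = FALSE], 2, mu[k, ])
      sigma[, , k] <- .floor_cov(crossprod(d * sqrt(wk)) / sum(wk), floor_var)
    }
    pi_k <- pi_k / sum(pi_k)
  } else {
    pi_k <- init$w / sum(init$w); mu <- init$mu; sigma <- init$sigma
    K <- length(pi_k)
  }
  loglik <- numeric(0)
  for (it in seq_len(config$max_iter)) {
    lg <- .log_dens(x, mu, sigma)
    lg <- sweep(lg, 2, log(pi_k), `+`)
    m <- apply(lg, 1, max)
    p <- exp(lg - m)
    rs <- rowSums(p)
    ll <- sum(w * (log(rs) + m))
    loglik <- c(loglik, ll)
    r <- p / rs
    nk <- colSums(w * r)
    live <- nk > 1e-12
    if (!all(live)) {
      warning("pruning ", sum(!live), " collapsed component(s)")
      keep <- which(live)
      pi_k <- pi_k[keep]; mu <- mu[keep, , drop = FALSE]
      sigma <- sigma[, , keep, drop = FALSE]
      K <- length(keep)
      next
    }
    for (k in seq_len(K)) {
      wr <- w * r[, k]
      mu[k, ] <- colSums(x * wr) / nk[k]
      d <- sweep(x, 2, mu[k, ])
      sigma[, , k] <- .floor_cov(crossprod(d * sqrt(wr)) / nk[k], floor_var)
    }
    pi_k <- nk / sum(nk)
    if (it > 1 &&
        abs(loglik[it] - loglik[it - 1]) <=
          config$tol * abs(loglik[it - 1])) break
  }
  lg <- sweep(.log_dens(x, mu, sigma), 2, log(pi_k), `+`)
  list(pi = pi_k, mu = mu, sigma = sigma, loglik = loglik,
       iterations = length(loglik),
       assign = max.col(lg, ties.method = "first"))
}

#' Divide-and-conquer GMM fit
#'
#' Hierarchical refinement: a global `K0`-component EM fit partitions the
#' voxels by maximum posterior responsibility; leaves are then repeatedly
#' split into `branching` children (heaviest leaves first, deterministic
#' order), each child fitted by EM on the parent's voxel partition and
#' re-weighted by the parent's mass fraction, until the component budget is
#' reached or the rasterized fit attains the target cross-correlation.
#' After every level the assembled mixture is polished by a few global EM
#' iterations.
#'
#' @param map a [density_map()].
#' @param config a [fit_config()] with `budget` and/or `target_cc` set.
#' @return A flat normalized [gmm()] with attribute `report` (per-level
#'   component counts and CC values).
#' @export
fit_gmm_dc <- function(map, config = fit_config(budget = 64)) {
  if (is.null(config$budget) && is.null(config$target_cc))
    stop("config needs a component budget and/or a target CC")
  budget <- if (is.null(config$budget)) .Machine$integer.max else config$budget
  pts <- .map_points(map, config$min_density)
  floor_var <- (min(map$voxel) / 2)^2
  K0 <- min(config$K0, budget)
  root <- .em_fit(pts$x, pts$w, K0, config, floor_var, seed = config$seed)
  leaves <- lapply(seq_along(root$pi), function(k) {
    sel <- root$assign == k
    list(pi = root$pi[k], mu = root$mu[k, ], sigma = root$sigma[, , k],
         idx = which(sel))
  })
  cc_of <- function(leaves) {
    g <- .leaves_gmm(leaves)
    global_cc(rasterize(g, map, support_sigmas = 0), map)
  }
  report <- data.frame(level = 0L, components = length(leaves),
                       cc = cc_of(leaves))
  level <- 0L
  repeat {
    level <- level + 1L
    if (!is.null(config$target_cc) &&
        report$cc[nrow(report)] >= config$target_cc) break
    nsplit_max <- (budget - length(leaves)) %/% (config$branching - 1L)
    if (nsplit_max < 1L) break
    splittable <- which(vapply(leaves, function(l)
      length(l$idx) >= 2L * config$branching, TRUE))
    if (length(splittable) == 0L) break
    ord <- splittable[order(-vapply(leaves[splittable], `[[`, 0, "pi"),
                            splittable)]
    todo <- head(ord, nsplit_max)
    new_leaves <- list()
    for (j in seq_along(leaves)) {
      l <- leaves[[j]]
      if (!(j %in% todo)) { new_leaves <- c(new_leaves, list(l)); next }
      sub <- .em_fit(pts$x[l$idx, , drop = FALSE],
                     pts$w[l$idx] / sum(pts$w[l$idx]), config$branching,
                     config, floor_var,
                     seed = config$seed + 1000L * level + j)
      if (length(sub$pi) < 2L) { # split failed: keep parent
        warning("leaf ", j, " did not split; keeping parent component")
        new_leaves <- c(new_leaves, list(l))
        next
      }
      kids <- lapply(seq_along(sub$pi), function(k) {
        list(pi = l$pi * sub$pi[k], mu = sub$mu[k, ],
             sigma = sub$sigma[, , k], idx = l$idx[sub$assign == k])
      })
      new_leaves <- c(new_leaves, kids)
    }
    if (length(new_leaves) == length(leaves)) break
    leaves <- new_leaves
    if (config$polish_iter > 0) {
      pol_cfg <- config
      pol_cfg$max_iter <- config$polish_iter
      pol <- .em_fit(pts$x, pts$w, length(leaves), pol_cfg, floor_var,
                     init = .leaves_gmm(leaves))
      leaves <- lapply(seq_along(pol$pi), function(k)
        list(pi = pol$pi[k], mu = pol$mu[k, ], sigma = pol$sigma[, , k],
             idx = which(pol$assign == k)))
    }
    report <- rbind(report, data.frame(level = level,
                                       components = length(leaves),
                                       cc = cc_of(leaves)))
  }
  out <- .leaves_gmm(leaves)
  out$label <- "divide-and-conquer fit"
  attr(out, "report") <- report
  out
}

.leaves_gmm <- function(leaves) {
  w <- vapply(leaves, `[[`, 0, "pi")
  gmm(w / sum(w), do.call(rbind, lapply(leaves, `[[`, "mu")),
      vapply(leaves, `[[`, matrix(0, 3, 3), "sigma"), normalized = TRUE)
}
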