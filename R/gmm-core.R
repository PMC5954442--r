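# Core Gaussian-mixture types and analytic overlap integrals.
#
# All lengths are nm, covariances nm^2, overlaps nm^-3. The data-GMM (phi_D)
# is weight-normalized; model-GMMs (phi_M) carry physical weights.

# Smallest admissible covariance eigenvalue (nm^2); below this a component is
# numerically degenerate and its overlap integrals are not invertible.
.SIGMA_EIG_MIN <- 1e-10

#' Single Gaussian component
#'
#' A weighted, normalized 3-D Gaussian: `weight * G(x | mean, cov)`.
#'
#' @param weight positive scalar weight (dimensionless).
#' @param mean numeric 3-vector, nm.
#' @param cov 3x3 symmetric positive-definite covariance, nm^2. A scalar is
#'   interpreted as an isotropic covariance `cov * I`.
#' @return An object of class `gmm_component`.
#' @examples
#' gmm_component(1, c(0, 0, 0), 0.01)
#' @export
gmm_component <- function(weight, mean, cov) {
  stopifnot(length(weight) == 1L, is.finite(weight), length(mean) == 3L,
            all(is.finite(mean)))
  if (length(cov) == 1L) cov <- diag(3) * cov
  cov <- as.matrix(cov)
  stopifnot(identical(dim(cov), c(3L, 3L)), all(is.finite(cov)))
  if (weight <= 0) stop("component weight must be > 0")
  if (max(abs(cov - t(cov))) > 1e-12 * max(1, max(abs(cov))))
    stop("covariance must be symmetric (tolerance 1e-12)")
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= .SIGMA_EIG_MIN)
    stop("degenerate covariance: smallest eigenvalue ", format(min(ev)),
         " <= ", .SIGMA_EIG_MIN, " nm^2")
  structure(list(weight = as.numeric(weight), mean = as.numeric(mean),
                 cov = cov), class = "gmm_component")
}

#' Gaussian mixture model
#'
#' Container for an ordered set of [gmm_component()]s, stored in matrix form:
#' weights `w` (length K), means `mu` (K x 3), covariances `sigma`
#' (3 x 3 x K).
#'
#' @param w numeric vector of positive weights.
#' @param mu K x 3 matrix of means, nm.
#' @param sigma 3 x 3 x K array of covariances, nm^2, or a length-K vector of
#'   isotropic variances.
#' @param normalized logical; data-GMMs are normalized (weights sum to 1).
#' @param label free-text label.
#' @return An object of class `gmm`.
#' @examples
#' g <- gmm(c(0.5, 0.5), rbind(c(0, 0, 0), c(1, 0, 0)), c(0.01, 0.02),
#'          normalized = TRUE)
#' length(g)
#' @export
gmm <- function(w, mu, sigma, normalized = FALSE, label = "") {
  w <- as.numeric(w)
  mu <- matrix(as.numeric(mu), ncol = 3)
  K <- length(w)
  if (K < 1L) stop("a GMM needs at least one component")
  if (nrow(mu) != K) stop("mu must have one row per component")
  if (is.null(dim(sigma))) {
    v <- rep_len(as.numeric(sigma), K)
    sigma <- vapply(v, function(s) diag(3) * s, matrix(0, 3, 3))
  }
  sigma <- array(sigma, dim = c(3, 3, K))
  if (any(!is.finite(w)) || any(w <= 0)) stop("all weights must be > 0 and finite")
  if (any(!is.finite(mu)) || any(!is.finite(sigma)))
    stop("non-finite GMM parameters")
  for (k in seq_len(K)) {
    s <- sigma[, , k]
    if (max(abs(s - t(s))) > 1e-12 * max(1, max(abs(s))))
      stop("covariance ", k, " not symmetric")
    sigma[, , k] <- (s + t(s)) / 2
  }
  if (isTRUE(normalized) && abs(sum(w) - 1) > 1e-9)
    stop("normalized GMM weights must sum to 1 within 1e-9 (got ",
         format(sum(w)), ")")
  structure(list(w = w, mu = mu, sigma = sigma,
                 normalized = isTRUE(normalized), label = label),
            class = "gmm")
}

#' @export
length.gmm <- function(x) length(x$w)

#' @export
print.gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture '%s': %d components, total weight %.6g%s\n",
              x$label, length(x$w), sum(x$w),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Extract one component of a mixture
#'
#' @param x a [gmm()].
#' @param i component index.
#' @return A [gmm_component()].
#' @export
gmm_get <- function(x, i) {
  stopifnot(inherits(x, "gmm"), i >= 1, i <= length(x$w))
  gmm_component(x$w[i], x$mu[i, ], x$sigma[, , i])
}

#' Build a mixture from components
#'
#' @param components list of [gmm_component()].
#' @inheritParams gmm
#' @return A [gmm()].
#' @export
gmm_from_components <- function(components, normalized = FALSE, label = "") {
  stopifnot(length(components) >= 1)
  gmm(vapply(components, `[[`, 0, "weight"),
      do.call(rbind, lapply(components, `[[`, "mean")),
      vapply(components, `[[`, matrix(0, 3, 3), "cov"),
      normalized = normalized, label = label)
}

#' Renormalize mixture weights to sum to one
#'
#' @param x a [gmm()].
#' @return A normalized [gmm()].
#' @export
gmm_normalize <- function(x) {
  gmm(x$w / sum(x$w), x$mu, x$sigma, normalized = TRUE, label = x$label)
}

.as_gmm <- function(x) {
  if (inherits(x, "gmm")) return(x)
  if (inherits(x, "gmm_component"))
    return(gmm(x$weight, matrix(x$mean, 1), array(x$cov, c(3, 3, 1))))
  stop("expected a gmm or gmm_component")
}

#' Analytic overlap of two Gaussian components
#'
#' The overlap is the integral of the product of the two weighted Gaussians,
#' `ov = w_a w_b (2*pi)^(-3/2) det(Sa+Sb)^(-1/2) exp(-d' (Sa+Sb)^-1 d / 2)`
#' with `d = mu_a - mu_b`. Units nm^-3.
#'
#' @param a,b [gmm_component()]s.
#' @return Scalar overlap (nm^-3), strictly positive and symmetric in `a`, `b`.
#' @examples
#' a <- gmm_component(1, c(0, 0, 0), 0.01)
#' pair_overlap(a, a) # (2*pi)^(-3/2) * 0.02^(-3/2)
#' @export
pair_overlap <- function(a, b) {
  stopifnot(inherits(a, "gmm_component"), inherits(b, "gmm_component"))
  S <- a$cov + b$cov
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= .SIGMA_EIG_MIN)
    stop("degenerate summed covariance in pair_overlap")
  d <- a$mean - b$mean
  q <- sum(d * solve(S, d))
  a$weight * b$weight * (2 * pi)^(-1.5) / sqrt(prod(ev)) * exp(-q / 2)
}

#' All pairwise overlaps between two mixtures
#'
#' @param a,b [gmm()]s (or single components).
#' @return A `length(a)` x `length(b)` matrix of pair overlaps (nm^-3).
#' @export
overlap_matrix <- function(a, b) {
  a <- .as_gmm(a); b <- .as_gmm(b)
  cpp_overlap_matrix(a$w, a$mu, a$sigma, b$w, b$mu, b$sigma)
}

#' Overlap of a mixture with one data component
#'
#' `ov_MD,i`: the integral of the model mixture times data component `i`,
#' i.e. the sum of [pair_overlap()] over (a subset of) the model components.
#'
#' @param model a [gmm()] (model-GMM phi_M).
#' @param comp a [gmm_component()], typically one data-GMM component.
#' @param pairs optional integer vector of model component indices (neighbor
#'   subset); `NULL` means all. An empty subset returns 0.
#' @return Scalar overlap (nm^-3).
#' @export
mixture_component_overlap <- function(model, comp, pairs = NULL) {
  model <- .as_gmm(model)
  if (!is.null(pairs)) {
    if (length(pairs) == 0L) return(0)
    model <- gmm(model$w[pairs], model$mu[pairs, , drop = FALSE],
                 model$sigma[, , pairs, drop = FALSE])
  }
  sum(overlap_matrix(model, comp))
}

#' Self-overlaps of a data-GMM
#'
#' `ov_DD,i`: the overlap of each component of the data-GMM with the entire
#' data-GMM. These are the "experimental data points" the noise model
#' restrains the model overlaps against.
#'
#' @param data a normalized [gmm()].
#' @return Numeric vector of per-component overlaps (nm^-3), all positive.
#' @export
self_overlaps <- function(data) {
  stopifnot(inherits(data, "gmm"))
  if (!data$normalized) stop("self_overlaps expects a normalized data-GMM")
  colSums(cpp_overlap_matrix(data$w, data$mu, data$sigma,
                             data$w, data$mu, data$sigma))
}

#' Density map on a voxel grid
#'
#' @param values 3-D numeric array of voxel values (arbitrary density units).
#' @param voxel numeric 3-vector of voxel edge lengths, nm.
#' @param origin numeric 3-vector, nm: position of the center of voxel
#'   `[1, 1, 1]`.
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, voxel, origin = c(0, 0, 0)) {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3L, all(dim(values) >= 1L))
  voxel <- rep_len(as.numeric(voxel), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(voxel <= 0)) stop("voxel sizes must be > 0")
  if (any(!is.finite(values))) stop("map values must be finite")
  structure(list(values = values, voxel = voxel, origin = origin),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density map %dx%dx%d, voxel %.4g x %.4g x %.4g nm, origin (%.3g, %.3g, %.3g) nm\n",
              d[1], d[2], d[3], x$voxel[1], x$voxel[2], x$voxel[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  values in [%.4g, %.4g], sum*voxvol = %.6g\n",
              min(x$values), max(x$values),
              sum(x$values) * prod(x$voxel)))
  invisible(x)
}

#' Grid template helper
#'
#' Builds an empty [density_map()] covering `span` (a 2 x 3 matrix of lower /
#' upper bounds, nm) at the requested voxel size.
#'
#' @param span 2 x 3 matrix: rows are lower and upper corner, nm.
#' @param voxel voxel size (scalar or 3-vector), nm.
#' @return A zero-valued [density_map()].
#' @export
map_template <- function(span, voxel) {
  voxel <- rep_len(as.numeric(voxel), 3L)
  lo <- span[1, ]; hi <- span[2, ]
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel)))
  density_map(array(0, dims), voxel, origin = lo + voxel / 2)
}

.grids_match <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$voxel - b$voxel)) < 1e-9 &&
    max(abs(a$origin - b$origin)) < 1e-9
}

#' Rasterize a Gaussian mixture onto a voxel grid
#'
#' Evaluates the mixture density at every voxel center of the template grid.
#' When the grid fully contains the mixture support, `sum(values) * voxel
#' volume` approximates the total mixture weight.
#'
#' @param x a [gmm()].
#' @param grid a [density_map()] used as grid template (its values are
#'   ignored).
#' @param support_sigmas warn when any component mean is closer than
#'   `support_sigmas` standard deviations to the grid boundary (default 4).
#' @return A [density_map()] with the rasterized density.
#' @export
rasterize <- function(x, grid, support_sigmas = 4) {
  stopifnot(inherits(x, "gmm"), inherits(grid, "density_map"))
  dims <- dim(grid$values)
  lo <- grid$origin - grid$voxel / 2
  hi <- grid$origin + (dims - 0.5) * grid$voxel
  sdmax <- sqrt(apply(x$sigma, 3, function(s) max(diag(s))))
  out <- FALSE
  for (k in seq_along(x$w)) {
    m <- x$mu[k, ]
    if (any(m - support_sigmas * sdmax[k] < lo) ||
        any(m + support_sigmas * sdmax[k] > hi)) out <- TRUE
  }
  if (out)
    warning("grid does not cover the mixture support to ", support_sigmas,
            " sigma; rasterized mass will be truncated")
  vals <- cpp_rasterize(x$w, x$mu, x$sigma, dims, grid$voxel, grid$origin)
  density_map(vals, grid$voxel, grid$origin)
}

#' Global cross-correlation of two maps
#'
#' Pearson correlation over all voxels (optionally restricted to voxels where
#' either map exceeds a density threshold). Both maps must live on the same
#' grid.
#'
#' @param a,b [density_map()]s on identical grids.
#' @param threshold optional density threshold; when given, only voxels with
#'   `a > threshold | b > threshold` enter the correlation. Default: no mask.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
global_cc <- function(a, b, threshold = NULL) {
  stopifnot(inherits(a, "density_map"), inherits(b, "density_map"))
  if (!.grids_match(a, b))
    stop("grid mismatch: maps must share dims, voxel size and origin ",
         "(resample first)")
  va <- as.vector(a$values); vb <- as.vector(b$values)
  if (!is.null(threshold)) {
    keep <- va > threshold | vb > threshold
    if (sum(keep) < 2) stop("threshold leaves fewer than 2 voxels")
    va <- va[keep]; vb <- vb[keep]
  }
  stats::cor(va, vb)
}

#' Local cross-correlation map
#'
#' Per-voxel Pearson correlation computed in a cubic sliding window of
#' `window` voxels per side centered on each voxel; windows are truncated at
#' the map edges. Voxels whose window has zero variance in either map get
#' `NA`.
#'
#' @param a,b [density_map()]s on identical grids.
#' @param window odd window size in voxels (default 5).
#' @return A [density_map()] of local correlations (NA where undefined).
#' @export
local_cc <- function(a, b, window = 5) {
  stopifnot(inherits(a, "density_map"), inherits(b, "density_map"))
  if (!.grids_match(a, b)) stop("grid mismatch")
  window <- as.integer(window)
  if (window %% 2L != 1L || window < 1L) stop("window must be odd and >= 1")
  if (any(window > dim(a$values)))
    stop("window larger than a grid dimension")
  vals <- cpp_local_cc(a$values, b$values, window)
  m <- density_map(array(0, dim(a$values)), a$voxel, a$origin)
  m$values <- vals  # may contain NA; bypass finite check intentionally
  m
}
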