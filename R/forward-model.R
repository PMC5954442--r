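# Forward model: one isotropic Gaussian per heavy atom (parameters from
# electron scattering factors) or per coarse-grained bead (width proportional
# to bead size), plus neighbor-listed replica-averaged overlaps.

.densemble_cache <- new.env(parent = emptyenv())

# Width of a bead Gaussian as a fraction of the bead size (diameter):
# sd = BEAD_WIDTH_FACTOR * size. Half the bead size puts ~95% of the bead
# mass inside its nominal diameter.
BEAD_WIDTH_FACTOR <- 0.5

#' Particle-based structural model
#'
#' @param xyz n x 3 matrix of positions, nm.
#' @param species character vector of element symbols (e.g. `"C"`) or
#'   `"BEAD"` for coarse-grained particles.
#' @param size per-particle bead size (nm); required for `"BEAD"` species.
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(xyz, species, size = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  species <- rep_len(as.character(species), n)
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  if (!is.null(size)) size <- rep_len(as.numeric(size), n)
  if (any(species == "BEAD") && is.null(size))
    stop("bead models need a `size`")
  structure(list(xyz = xyz, species = species, size = size),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic model: %d particles (%s)\n", nrow(x$xyz),
              paste(unique(x$species), collapse = ", ")))
  invisible(x)
}

#' Single-Gaussian electron scattering table
#'
#' For each supported element, the tabulated five-Gaussian electron atomic
#' scattering factor `f(s) = sum_i a_i exp(-b_i s^2)` is collapsed to a
#' single Gaussian `A exp(-B s^2)` by least squares over spatial frequencies
#' `s` in 0-0.5 1/Angstrom, and converted to a real-space Gaussian: weight
#' `A`, variance `B / (8 pi^2)` (in Angstrom^2, returned in nm^2).
#'
#' @param path optional path to a coefficient table with the packaged format;
#'   default is the table shipped with the package.
#' @return data.frame with columns `element`, `weight`, `variance` (nm^2).
#' @export
scattering_table <- function(path = NULL) {
  key <- if (is.null(path)) ".default_scatter" else path
  cached <- .densemble_cache[[key]]
  if (!is.null(cached)) return(cached)
  if (is.null(path))
    path <- system.file("extdata", "electron_scattering_5g.tsv",
                        package = "densemble")
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  s <- seq(0, 0.5, length.out = 201)
  fit_one <- function(a, b) {
    f <- colSums(a * exp(-outer(b, s^2)))
    amp_for <- function(B) {
      e <- exp(-B * s^2)
      sum(f * e) / sum(e * e)
    }
    sse <- function(B) {
      e <- exp(-B * s^2)
      A <- sum(f * e) / sum(e * e)
      sum((A * e - f)^2)
    }
    B <- stats::optimize(sse, c(0.05, 200))$minimum
    c(A = amp_for(B), B = B)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    p <- fit_one(as.numeric(tab[i, 2:6]), as.numeric(tab[i, 7:11]))
    data.frame(element = tab$element[i], weight = p[["A"]],
               variance = p[["B"]] / (8 * pi^2) * 0.01) # A^2 -> nm^2
  }))
  rownames(out) <- NULL
  .densemble_cache[[key]] <- out
  out
}

# per-particle (weight, variance): elements via the scattering table, beads
# via the declared width-proportionality
.particle_gaussians <- function(model, table = scattering_table()) {
  n <- nrow(model$xyz)
  w <- numeric(n); v <- numeric(n)
  is_bead <- model$species == "BEAD"
  if (any(is_bead)) {
    sz <- model$size[is_bead]
    w[is_bead] <- sz # scattering weight proportional to the bead size
    v[is_bead] <- (BEAD_WIDTH_FACTOR * sz)^2
  }
  if (any(!is_bead)) {
    idx <- match(model$species[!is_bead], table$element)
    if (anyNA(idx))
      stop("no scattering-table entry for element(s): ",
           paste(unique(model$species[!is_bead][is.na(idx)]), collapse = ", "),
           " (particles ",
           paste(head(which(!is_bead)[is.na(idx)], 5), collapse = ", "), ")")
    w[!is_bead] <- table$weight[idx]
    v[!is_bead] <- table$variance[idx]
  }
  list(w = w, v = v)
}

#' Model-GMM from particle coordinates
#'
#' One isotropic Gaussian per particle: mean at the particle position,
#' weight and variance from the scattering table (elements) or from the bead
#' size (weight 1, sd = `BEAD_WIDTH_FACTOR * size`). The result is not
#' weight-normalized: model mass is physical.
#'
#' @param model an [atomic_model()].
#' @param table scattering table (see [scattering_table()]).
#' @return A [gmm()] with one component per particle, order-preserving.
#' @export
model_gmm <- function(model, table = scattering_table()) {
  stopifnot(inherits(model, "atomic_model"))
  p <- .particle_gaussians(model, table)
  gmm(p$w, model$xyz, p$v, normalized = FALSE, label = "model")
}

#' Build a model/data neighbor list
#'
#' A pair (particle m, data component i) is retained when its Gaussian
#' exponent factor `exp(-d' (Sm + SD_i)^-1 d / 2)` is at least `cutoff` for
#' at least one replica at build time.
#'
#' @param models an [atomic_model()] or list of them (one per replica).
#' @param data the data-GMM ([gmm()]).
#' @param cutoff dimensionless exponent-factor cutoff in (0, 1); default
#'   0.01.
#' @param update_every rebuild frequency in MD steps (bookkeeping for the
#'   sampler; default 100).
#' @param table scattering table.
#' @return An object of class `neighbor_list`: per data component, the model
#'   particle indices retained.
#' @export
build_neighbor_list <- function(models, data, cutoff = 0.01,
                                update_every = 100,
                                table = scattering_table()) {
  if (inherits(models, "atomic_model")) models <- list(models)
  stopifnot(inherits(data, "gmm"), cutoff > 0, cutoff < 1)
  p <- .particle_gaussians(models[[1]], table)
  qmax <- -2 * log(cutoff)
  K <- length(data$w)
  n <- nrow(models[[1]]$xyz)
  pairs <- vector("list", K)
  for (i in seq_len(K)) {
    qmin <- rep(Inf, n)
    for (mod in models) {
      d <- sweep(mod$xyz, 2, data$mu[i, ])
      # per-particle combined covariance differs only through the bead class
      for (cls in unique(p$v)) {
        sel <- p$v == cls
        Sinv <- solve(data$sigma[, , i] + diag(3) * cls)
        q <- rowSums((d[sel, , drop = FALSE] %*% Sinv) *
                       d[sel, , drop = FALSE])
        qmin[sel] <- pmin(qmin[sel], q)
      }
    }
    pairs[[i]] <- which(qmin <= qmax)
  }
  if (all(lengths(pairs) == 0))
    message("neighbor list is empty at cutoff ", cutoff)
  structure(list(pairs = pairs, cutoff = cutoff,
                 update_every = as.integer(update_every), built_at = 0L),
            class = "neighbor_list")
}

#' Replica-averaged model/data overlaps
#'
#' Computes the per-replica overlap of each replica's model-GMM with every
#' data component, and their arithmetic mean over replicas (the
#' ensemble-averaged forward model the noise model compares against the
#' data).
#'
#' @param models an [atomic_model()] or list of them (one per replica, same
#'   topology).
#' @param data the data-GMM ([gmm()]).
#' @param nl optional [build_neighbor_list()] result; `NULL` = exact sums.
#' @param table scattering table.
#' @return List with `ovbar` (length-K vector) and `ov_replica` (N x K
#'   matrix), nm^-3.
#' @export
replica_averaged_overlaps <- function(models, data, nl = NULL,
                                      table = scattering_table()) {
  if (inherits(models, "atomic_model")) models <- list(models)
  stopifnot(length(models) >= 1, inherits(data, "gmm"))
  n <- nrow(models[[1]]$xyz)
  for (m in models)
    if (nrow(m$xyz) != n || !identical(m$species, models[[1]]$species))
      stop("replica topology mismatch")
  K <- length(data$w)
  ovr <- matrix(0, length(models), K)
  for (r in seq_along(models)) {
    om <- overlap_matrix(model_gmm(models[[r]], table), data) # n x K
    if (is.null(nl)) {
      ovr[r, ] <- colSums(om)
    } else {
      for (i in seq_len(K))
        ovr[r, i] <- sum(om[nl$pairs[[i]], i])
    }
  }
  list(ovbar = colMeans(ovr), ov_replica = ovr)
}
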