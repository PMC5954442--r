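# Map, structure and GMM text I/O.
#
# MRC2014/CCP4 maps are read/written directly with readBin/writeBin; lengths
# are converted A -> nm at this boundary so that everything downstream is nm.

.mrc_modes <- c(`0` = "int8", `1` = "int16", `2` = "float32", `6` = "uint16")

#' Read an MRC/CCP4 density map
#'
#' Supports MRC2014 and legacy CCP4 maps, modes 0 (int8), 1 (int16),
#' 2 (float32) and 6 (uint16). Values are reordered to canonical x-fastest
#' axis order; the origin is taken from the ORIGIN record when nonzero, and
#' otherwise from the start indices times the voxel size. Lengths are
#' converted from Angstrom to nm.
#'
#' @param path path to an MRC/CCP4 file.
#' @return A [density_map()] (values as stored, units of the file).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nxyz <- hdr_int[1:3]
  mode <- hdr_int[4]
  nstart <- hdr_int[5:7]
  mxyz <- hdr_int[8:10]
  cella <- hdr_num[11:13]
  mapcrs <- hdr_int[17:19]
  if (any(nxyz <= 0) || any(mxyz <= 0))
    stop("inconsistent MRC header: non-positive dimensions in ", path)
  if (!as.character(mode) %in% names(.mrc_modes))
    stop("unsupported MRC mode ", mode, " in ", path)
  if (!identical(sort(mapcrs), 1:3))
    stop("invalid axis order in MRC header: ", paste(mapcrs, collapse = ","))
  origin_rec <- hdr_num[50:52]
  nvox <- prod(nxyz)
  seek(con, 1024 + hdr_int[24]) # skip extended header (NSYMBT bytes)
  vals <- switch(as.character(mode),
    `0` = as.numeric(readBin(con, "integer", n = nvox, size = 1,
                             signed = TRUE, endian = "little")),
    `1` = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                             signed = TRUE, endian = "little")),
    `2` = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    `6` = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                             signed = FALSE, endian = "little")))
  if (length(vals) != nvox) stop("truncated MRC data in ", path)
  arr <- array(vals, dim = nxyz)
  # stored dim j runs along axis mapcrs[j]; canonicalize to x,y,z
  perm <- match(1:3, mapcrs)
  arr <- aperm(arr, perm)
  voxel_A <- cella / mxyz            # per axis x,y,z
  if (any(voxel_A <= 0)) stop("inconsistent MRC header: non-positive cell")
  if (any(abs(origin_rec) > 1e-6)) {
    origin_A <- origin_rec
  } else {
    # nstart applies to the stored (column/row/section) frame
    origin_A <- numeric(3)
    origin_A[mapcrs] <- nstart * voxel_A[mapcrs]
  }
  density_map(arr, voxel_A / 10, origin_A / 10)
}

#' Write a density map as MRC2014 (mode 2)
#'
#' @param map a [density_map()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_mrc <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  if (any(!is.finite(map$values))) stop("cannot write non-finite map values")
  dims <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dims)                         # NX NY NZ
  wi(2L)                           # MODE 2 = float32
  wi(c(0L, 0L, 0L))                # NXSTART..
  wi(dims)                         # MX MY MZ
  wf(dims * map$voxel * 10)        # CELLA, Angstrom
  wf(c(90, 90, 90))                # CELLB
  wi(1:3)                          # MAPC MAPR MAPS
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(c(1L, 0L))                    # ISPG, NSYMBT
  writeBin(raw(100), con)          # EXTRA, bytes 96-195
  wf(map$origin * 10)              # ORIGIN record, Angstrom
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # little-endian stamp
  wf(stats::sd(as.vector(map$values)))
  wi(0L)                           # NLABL
  writeBin(raw(800), con)          # labels
  writeBin(as.numeric(map$values), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a structure in PDB format
#'
#' Thin wrapper over [bio3d::read.pdb()]: keeps ATOM/HETATM records, keeps the
#' first alternate location, optionally drops hydrogens (the forward model
#' places one Gaussian per heavy atom), converts coordinates to nm, and
#' resolves the element symbol from the element column with an atom-name
#' fallback.
#'
#' @param path path to a PDB file.
#' @param drop_hydrogens drop H atoms (default `TRUE`).
#' @return An [atomic_model()].
#' @export
read_structure <- function(path, drop_hydrogens = TRUE) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (!is.null(at$alt)) {
    keep_alt <- is.na(at$alt) | at$alt %in% c("", "A", "1")
    at <- at[keep_alt, , drop = FALSE]
  }
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | trimws(at$elesy) == "",
                                NA, at$elesy)))
  # fallback: first alphabetic character of the atom name (handles " CA ",
  # "1HB2"); two-letter symbols must come from the element column
  fb <- toupper(substr(gsub("[^A-Za-z].*$", "",
                            sub("^[0-9]*", "", trimws(at$elety))), 1, 1))
  elem[is.na(elem)] <- fb[is.na(elem)]
  if (any(elem == "" | is.na(elem)))
    stop("cannot resolve element for atoms: ",
         paste(head(which(elem == "" | is.na(elem)), 5), collapse = ", "))
  keep <- rep(TRUE, nrow(at))
  if (drop_hydrogens) keep <- !(elem %in% c("H", "D"))
  xyz <- cbind(at$x, at$y, at$z)[keep, , drop = FALSE] / 10
  atomic_model(xyz, species = elem[keep])
}

#' Read a Gaussian mixture from the GMM text dialect
#'
#' One component per line: index, mean (3 floats, nm), covariance upper
#' triangle (6 floats, nm^2, order xx xy xz yy yz zz), weight, and an optional
#' beta/group column. Comment lines start with `#`; comma and whitespace
#' separators are both accepted.
#'
#' @param path input path.
#' @return A [gmm()]; `normalized` is set when the weights sum to 1 within
#'   1e-6.
#' @export
read_gmm <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("no components in ", path)
  K <- length(lines)
  w <- numeric(K); mu <- matrix(0, K, 3); sig <- array(0, c(3, 3, K))
  for (k in seq_len(K)) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[k]),
                                              "[,[:space:]]+")[[1]]))
    if (length(f) < 11 || any(is.na(f[1:11])))
      stop("malformed GMM line ", lineno[k], " in ", path)
    mu[k, ] <- f[2:4]
    S <- matrix(c(f[5], f[6], f[7],
                  f[6], f[8], f[9],
                  f[7], f[9], f[10]), 3, 3)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("non-SPD covariance at line ", lineno[k], " in ", path)
    sig[, , k] <- S
    w[k] <- f[11]
  }
  gmm(w, mu, sig, normalized = abs(sum(w) - 1) < 1e-6,
      label = basename(path))
}

#' Write a Gaussian mixture in the GMM text dialect
#'
#' @param x a [gmm()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmm <- function(x, path) {
  stopifnot(inherits(x, "gmm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# GMM components: index mean_x mean_y mean_z (nm)",
               "#   cov_xx cov_xy cov_xz cov_yy cov_yz cov_zz (nm^2) weight beta"),
             con)
  for (k in seq_along(x$w)) {
    S <- x$sigma[, , k]
    writeLines(paste(c(k, sprintf("%.9e", c(x$mu[k, ], S[1, 1], S[1, 2],
                                            S[1, 3], S[2, 2], S[2, 3],
                                            S[3, 3], x$w[k])), 0),
                     collapse = " "), con)
  }
  invisible(path)
}
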