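## Forward kinematic diffraction simulator and model oracle.
##
## Elastic (single) scattering, no absorption: each exposure is
## I(pixel) = |sum_j f_j(q) exp(2*pi*i q . (R r_j))|^2 evaluated on the Ewald
## sphere, with R an independent uniformly random 3D rotation per exposure.

#' Structure model: atom positions and scattering factors
#'
#' Scattering factors follow a single-Gaussian form
#' `f(q) = f0 * exp(-b * q^2)`; `b = 0` gives point scatterers.
#'
#' @param positions `n x 3` matrix of atom coordinates in nm.
#' @param f0 amplitude(s), recycled over atoms.
#' @param b Gaussian width(s) in nm^2, recycled over atoms.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(positions, f0 = 1, b = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  if (nrow(positions) < 1) stop("at least one atom is required")
  if (!all(is.finite(positions))) stop("positions must be finite")
  structure(list(positions = positions,
                 f0 = rep_len(as.numeric(f0), nrow(positions)),
                 b = rep_len(as.numeric(b), nrow(positions))),
            class = "structure_model")
}

#' Regular hexagon of point scatterers
#'
#' Six unit-amplitude point scatterers at the vertices of a regular hexagon
#' of side `d` in the plane z = 0, centroid at the origin (circumradius
#' equals the side, so the nearest-neighbour distance is `d`).
#'
#' @param d nearest-neighbour distance in nm.
#' @return a [structure_model()].
#' @export
make_hexagon <- function(d = 15) {
  if (d <= 0) stop("d must be > 0")
  a <- (0:5) * pi / 3
  structure_model(cbind(d * cos(a), d * sin(a), 0))
}

#' Detector geometry reproducing a given edge q on a square grid
#'
#' Chooses the pixel width so that the q recorded at the nearest edge of an
#' `npix` x `npix` detector (beam centred) equals `q_edge`.
#'
#' @param npix detector width in pixels.
#' @param q_edge q at the detector edge in 1/nm.
#' @param wavelength wavelength in nm.
#' @param distance sample-to-detector distance in m.
#' @return a [detector_geometry()].
#' @export
square_detector <- function(npix = 256, q_edge = 1.28, wavelength = 0.1,
                            distance = 1) {
  th <- 2 * asin(q_edge * wavelength / 2)
  pw <- distance * tan(th) / (npix / 2)
  detector_geometry(wavelength, distance, pw, c(npix, npix))
}

#' Uniformly random 3D rotation matrix
#'
#' Draws a rotation uniformly from SO(3) by normalizing a 4-vector of
#' standard normals to a unit quaternion. Uses R's RNG stream, so results
#' are reproducible under `set.seed()`.
#'
#' @return a 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  qv <- stats::rnorm(4)
  rotation_from_quaternion(qv / sqrt(sum(qv^2)))
}

#' Rotation matrix from a unit quaternion
#'
#' @param q numeric length-4 unit quaternion `(w, x, y, z)`.
#' @return a 3 x 3 rotation matrix.
#' @export
rotation_from_quaternion <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Simulate one kinematic diffraction pattern
#'
#' @param model a [structure_model()].
#' @param geometry a [detector_geometry()].
#' @param rotation 3 x 3 rotation applied to the model.
#' @param solid_angle multiply by the `cos^3(theta)` solid-angle factor of
#'   flat-detector pixels.
#' @param photons if not `NULL`, scale the pattern to this expected total
#'   photon count and Poisson-sample it (noise-free by default).
#' @param qgrid optional precomputed [ewald_grid()] for `geometry` (reused
#'   across exposures for speed).
#' @return `nx x ny` intensity matrix.
#' @export
simulate_pattern <- function(model, geometry, rotation = diag(3),
                             solid_angle = FALSE, photons = NULL,
                             qgrid = NULL) {
  if (!inherits(model, "structure_model")) stop("model must be a structure_model")
  if (is.null(qgrid)) qgrid <- ewald_grid(geometry)
  pos <- model$positions %*% t(rotation)
  phase <- 2 * pi * (qgrid %*% t(pos))
  if (all(model$b == 0)) {
    f <- model$f0
    re <- cos(phase) %*% f
    im <- sin(phase) %*% f
  } else {
    q2 <- rowSums(qgrid^2)
    re <- im <- numeric(nrow(qgrid))
    for (j in seq_len(nrow(pos))) {
      fj <- model$f0[j] * exp(-model$b[j] * q2)
      re <- re + fj * cos(phase[, j])
      im <- im + fj * sin(phase[, j])
    }
  }
  I <- matrix(re^2 + im^2, geometry$image_size[1], geometry$image_size[2])
  if (solid_angle) {
    ct <- 1 + qgrid[, 3] * geometry$wavelength   # cos(theta) of each pixel
    I <- I * matrix(ct^3, nrow(I), ncol(I))
  }
  if (!is.null(photons)) {
    if (photons < 0) stop("photon count must be >= 0")
    tot <- sum(I)
    if (tot > 0) {
      I[] <- stats::rpois(length(I), I * (photons / tot))
    }
  }
  I
}

#' Simulate a serial diffraction data set
#'
#' `n` exposures of `model`, each in an independent uniformly random 3D
#' orientation.
#'
#' @inheritParams simulate_pattern
#' @param n number of exposures.
#' @param seed optional RNG seed for reproducibility.
#' @return object of class `exposure_set`: list with `patterns` (list of
#'   matrices), `rotations` (list of 3 x 3 matrices), `geometry`, `seed`.
#' @export
simulate_dataset <- function(model, geometry, n, seed = NULL,
                             solid_angle = FALSE, photons = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  qgrid <- ewald_grid(geometry)
  rotations <- vector("list", n)
  patterns <- vector("list", n)
  for (i in seq_len(n)) {
    rotations[[i]] <- random_rotation()
    patterns[[i]] <- simulate_pattern(model, geometry, rotations[[i]],
                                      solid_angle = solid_angle,
                                      photons = photons, qgrid = qgrid)
  }
  structure(list(patterns = patterns, rotations = rotations,
                 geometry = geometry, seed = seed),
            class = "exposure_set")
}

#' Simulate a data set directly in polar coordinates
#'
#' Streams exposures through [to_polar()] without keeping the detector
#' images, which is the memory-friendly route for large runs.
#'
#' @inheritParams simulate_dataset
#' @param nq,ntheta,qmax,order polar grid, as in [to_polar()].
#' @return list with `polar` (nq x ntheta x n array), `q`, `theta`,
#'   `geometry`, `seed`.
#' @export
simulate_polar_dataset <- function(model, geometry, n, nq, ntheta,
                                   qmax = NULL, seed = NULL,
                                   order = "cubic", solid_angle = FALSE,
                                   photons = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  qgrid <- ewald_grid(geometry)
  out <- array(0, c(nq, ntheta, n))
  qg <- NULL; thg <- NULL
  for (i in seq_len(n)) {
    img <- simulate_pattern(model, geometry, random_rotation(),
                            solid_angle = solid_angle, photons = photons,
                            qgrid = qgrid)
    p <- to_polar(img, geometry, nq, ntheta, qmax = qmax, order = order)
    out[, , i] <- p$values
    if (is.null(qg)) { qg <- p$q; thg <- p$theta }
  }
  list(polar = out, q = qg, theta = thg, geometry = geometry, seed = seed)
}

#' Write an exposure set to disk with a manifest
#'
#' One image file per exposure (NPY) plus a `manifest.txt` recording the
#' seed, geometry and model.
#'
#' @param dataset an `exposure_set` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix; files are named `<prefix>_<i>.npy`.
#' @param model optional [structure_model()] recorded in the manifest.
#' @return invisibly, the vector of written file paths.
#' @export
write_dataset <- function(dataset, dir, prefix = "pattern", model = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$patterns)
  paths <- file.path(dir, sprintf("%s_%d.npy", prefix, seq_len(n) - 1))
  for (i in seq_len(n)) write_npy(dataset$patterns[[i]], paths[i])
  g <- dataset$geometry
  man <- c(
    paste("n_patterns =", n),
    paste("seed =", dataset$seed %||% "NULL"),
    paste("wavelength =", g$wavelength),
    paste("distance =", g$distance),
    paste("pixel_size =", g$pixel_size),
    paste("image_size =", paste(g$image_size, collapse = " ")),
    paste("beam_centre =", paste(format(g$beam_centre), collapse = " "))
  )
  if (!is.null(model))
    man <- c(man, paste("atom =", apply(cbind(model$positions, model$f0,
                                              model$b), 1, paste,
                                        collapse = " ")))
  writeLines(man, file.path(dir, "manifest.txt"))
  invisible(paths)
}

#' Brute-force model PADF oracle
#'
#' Enumerates every ordered pair of ordered atom pairs `((i,j),(k,l))` with
#' `i != j`, `k != l` and accumulates the weight `f_i f_j f_k f_l` into a 3D
#' histogram over the two pair distances and the angle between the pair
#' vectors. Used to compute ideal peak positions and height ratios for a
#' known model; no kernel smoothing is applied.
#'
#' @param model a [structure_model()].
#' @param r_edges bin edges for both pair distances, in nm (must cover the
#'   model's pair distances).
#' @param theta_edges bin edges for the inter-pair angle, in degrees on
#'   `[0, 180]`.
#' @return list with `counts` (3D array `nr x nr x ntheta`), `r_mid`,
#'   `theta_mid` (bin midpoints).
#' @export
model_padf_oracle <- function(model, r_edges, theta_edges) {
  pos <- model$positions
  n <- nrow(pos)
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  ij <- ij[ij$i != ij$j, ]
  vec <- pos[ij$j, , drop = FALSE] - pos[ij$i, , drop = FALSE]
  len <- sqrt(rowSums(vec^2))
  w <- model$f0[ij$i] * model$f0[ij$j]
  if (any(len < min(r_edges)) || any(len > max(r_edges)))
    stop("r_edges must cover all pair distances (",
         format(min(len)), " to ", format(max(len)), " nm)")
  npair <- nrow(vec)
  nr <- length(r_edges) - 1
  nth <- length(theta_edges) - 1
  counts <- array(0, c(nr, nr, nth))
  rbin <- findInterval(len, r_edges, rightmost.closed = TRUE)
  unit <- vec / len
  cosang <- tcrossprod(unit)
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  tbin <- matrix(findInterval(ang, theta_edges, rightmost.closed = TRUE),
                 npair, npair)
  ww <- outer(w, w)
  for (a in seq_len(npair)) for (b in seq_len(npair)) {
    counts[rbin[a], rbin[b], tbin[a, b]] <-
      counts[rbin[a], rbin[b], tbin[a, b]] + ww[a, b]
  }
  list(counts = counts,
       r_mid = (r_edges[-1] + r_edges[-length(r_edges)]) / 2,
       theta_mid = (theta_edges[-1] + theta_edges[-length(theta_edges)]) / 2)
}
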