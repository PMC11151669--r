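## Detector geometry and polar resampling.
##
## Conventions: wavelength in nm, q in 1/nm (electron convention,
## q = 2 sin(theta/2) / lambda; multiply by 2*pi for the crystallographic
## convention), detector distance and pixel width in m. Pixel (0,0) spans
## [0,1)^2 so pixel centres sit at half-integer coordinates; the beam centre
## is given in fractional pixel units. The azimuth theta is measured
## counter-clockwise from the +x detector axis on [0, 2*pi).

#' Detector geometry
#'
#' @param wavelength radiation wavelength in nm.
#' @param distance sample-to-detector distance in m.
#' @param pixel_size detector pixel width in m.
#' @param image_size integer vector `(nx, ny)` in pixels.
#' @param beam_centre beam centre `(x, y)` in fractional pixel units;
#'   default is the image centre.
#' @return object of class `detector_geometry`.
#' @export
detector_geometry <- function(wavelength, distance, pixel_size, image_size,
                              beam_centre = NULL) {
  if (wavelength <= 0) stop("wavelength must be > 0")
  if (distance <= 0) stop("distance must be > 0")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  image_size <- as.integer(rep(image_size, length.out = 2))
  if (any(image_size < 2)) stop("image_size must be at least 2x2")
  if (is.null(beam_centre)) beam_centre <- image_size / 2
  structure(list(wavelength = wavelength, distance = distance,
                 pixel_size = pixel_size, image_size = image_size,
                 beam_centre = as.numeric(beam_centre)),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat("<detector_geometry>\n")
  cat("  wavelength :", x$wavelength, "nm\n")
  cat("  distance   :", x$distance, "m\n")
  cat("  pixel size :", x$pixel_size, "m\n")
  cat("  image size :", paste(x$image_size, collapse = " x "), "px\n")
  cat("  beam centre:", paste(format(x$beam_centre), collapse = ", "), "px\n")
  cat("  edge q     :", format(q_at_edge(x)), "1/nm\n")
  invisible(x)
}

#' Scattering angle and q magnitude of a radial detector position
#'
#' The scattering angle is `theta = atan(r / z)` and the momentum transfer
#' magnitude `q = (2 / lambda) * sin(theta / 2)` (electron convention).
#'
#' @param r radial distance from the beam centre, in m (vectorized).
#' @param geometry a [detector_geometry()].
#' @return list with elements `theta` (radians) and `q` (1/nm).
#' @export
pixel_q <- function(r, geometry) {
  if (any(r < 0)) stop("radial distance must be >= 0")
  theta <- atan(r / geometry$distance)
  q <- (2 / geometry$wavelength) * sin(theta / 2)
  list(theta = theta, q = q)
}

#' Detector radius at which a given q magnitude is recorded
#'
#' Inverse of [pixel_q()]: `r = z * tan(2 * asin(q * lambda / 2))`.
#'
#' @param q momentum transfer magnitude in 1/nm (vectorized).
#' @param geometry a [detector_geometry()].
#' @return radial distance from the beam centre, in m.
#' @export
q_to_radius <- function(q, geometry) {
  s <- q * geometry$wavelength / 2
  if (any(s > 1)) stop("q beyond back-scattering for this wavelength")
  geometry$distance * tan(2 * asin(s))
}

#' q at the nearest detector edge
#'
#' @param geometry a [detector_geometry()].
#' @return q (1/nm) of the detector edge closest to the beam centre.
#' @export
q_at_edge <- function(geometry) {
  cx <- geometry$beam_centre[1]; cy <- geometry$beam_centre[2]
  nx <- geometry$image_size[1];  ny <- geometry$image_size[2]
  dmin <- min(cx, nx - cx, cy, ny - cy) * geometry$pixel_size
  pixel_q(dmin, geometry)$q
}

#' Ewald-sphere scattering vector of a detector position
#'
#' Returns `(s_hat - z_hat) / lambda` where `s_hat` is the unit vector from
#' the sample to the pixel centre and `z_hat` the beam axis, so the third
#' component is `(cos(theta) - 1) / lambda <= 0` and the magnitude equals
#' [pixel_q()]'s q for the same radius.
#'
#' @param x,y pixel coordinates (fractional pixel units, vectorized).
#' @param geometry a [detector_geometry()].
#' @return an `n x 3` matrix of q vectors in 1/nm.
#' @export
ewald_qvector <- function(x, y, geometry) {
  dx <- (x - geometry$beam_centre[1]) * geometry$pixel_size
  dy <- (y - geometry$beam_centre[2]) * geometry$pixel_size
  z <- geometry$distance
  s <- sqrt(dx^2 + dy^2 + z^2)
  cbind(dx / s, dy / s, z / s - 1) / geometry$wavelength
}

#' Ewald q vectors of every pixel centre
#'
#' @param geometry a [detector_geometry()].
#' @return an `(nx*ny) x 3` matrix, pixels in column-major order (x fastest),
#'   pixel centres at half-integer coordinates.
#' @export
ewald_grid <- function(geometry) {
  nx <- geometry$image_size[1]; ny <- geometry$image_size[2]
  px <- seq_len(nx) - 0.5
  py <- seq_len(ny) - 0.5
  ewald_qvector(rep(px, times = ny), rep(py, each = nx), geometry)
}

## Image interpolation ---------------------------------------------------------

.catmull_rom_weights <- function(t) {
  cbind(-0.5 * t^3 + t^2 - 0.5 * t,
         1.5 * t^3 - 2.5 * t^2 + 1,
        -1.5 * t^3 + 2 * t^2 + 0.5 * t,
         0.5 * t^3 - 0.5 * t^2)
}

#' Interpolate a detector image at non-integer pixel coordinates
#'
#' Separable polynomial interpolation of the image values at fractional pixel
#' coordinates (pixel `(0,0)` spans `[0,1)^2`, value located at its centre).
#' `"cubic"` uses the Catmull-Rom kernel, falling back to bilinear in the
#' one-pixel border; `"linear"` is bilinear throughout. Coordinates outside
#' the image give 0.
#'
#' @param image numeric matrix.
#' @param x,y coordinates in fractional pixel units (vectorized).
#' @param order `"cubic"` or `"linear"`.
#' @return numeric vector of interpolated values.
#' @export
interp_image <- function(image, x, y, order = c("cubic", "linear")) {
  order <- match.arg(order)
  n1 <- nrow(image); n2 <- ncol(image)
  fx <- x + 0.5; fy <- y + 0.5   # matrix indices of pixel centres
  i0 <- floor(fx); j0 <- floor(fy)
  tx <- fx - i0; ty <- fy - j0
  v <- numeric(length(fx))
  lin <- i0 >= 1 & i0 <= n1 - 1 & j0 >= 1 & j0 <= n2 - 1
  if (order == "cubic") {
    cub <- i0 >= 2 & i0 <= n1 - 2 & j0 >= 2 & j0 <= n2 - 2
    if (any(cub)) {
      wx <- .catmull_rom_weights(tx[cub])
      wy <- .catmull_rom_weights(ty[cub])
      acc <- 0
      for (a in -1:2) {
        rowv <- 0
        for (b in -1:2)
          rowv <- rowv + wy[, b + 2] * image[cbind(i0[cub] + a, j0[cub] + b)]
        acc <- acc + wx[, a + 2] * rowv
      }
      v[cub] <- acc
    }
    lin <- lin & !cub
  }
  if (any(lin)) {
    ii <- i0[lin]; jj <- j0[lin]; sx <- tx[lin]; sy <- ty[lin]
    v[lin] <- (1 - sx) * (1 - sy) * image[cbind(ii, jj)] +
      sx * (1 - sy) * image[cbind(ii + 1, jj)] +
      (1 - sx) * sy * image[cbind(ii, jj + 1)] +
      sx * sy * image[cbind(ii + 1, jj + 1)]
  }
  v
}

## Polar resampling ------------------------------------------------------------

#' Resample a detector image onto a uniform (q, theta) polar grid
#'
#' Sample `(k, j)` holds the interpolated intensity at detector radius
#' `r(q_k) = z * tan(2 * asin(q_k * lambda / 2))` and azimuth `theta_j`; the
#' q grid is uniform on `[0, qmax]` and the theta grid uniform on
#' `[0, 2*pi)`. Samples mapping outside the detector are 0.
#'
#' @param image numeric matrix (non-negative intensities).
#' @param geometry a [detector_geometry()].
#' @param nq,ntheta grid sizes (both >= 2).
#' @param qmax maximum q in 1/nm; defaults to (and must not exceed) the q of
#'   the nearest detector edge.
#' @param order interpolation order, `"cubic"` (default) or `"linear"`.
#' @return object of class `polar_intensity`: list with `values` (nq x ntheta
#'   matrix), `q`, `theta`.
#' @export
to_polar <- function(image, geometry, nq, ntheta, qmax = NULL,
                     order = c("cubic", "linear")) {
  order <- match.arg(order)
  if (nq < 2 || ntheta < 2) stop("nq and ntheta must be >= 2")
  edge <- q_at_edge(geometry)
  if (is.null(qmax)) qmax <- edge
  if (qmax > edge * (1 + 1e-12))
    stop("qmax exceeds detector coverage; maximum allowed is ", format(edge))
  qg <- seq(0, qmax, length.out = nq)
  thg <- seq(0, 2 * pi, length.out = ntheta + 1)[seq_len(ntheta)]
  rp <- q_to_radius(qg, geometry) / geometry$pixel_size   # radius in pixels
  xs <- outer(rp, cos(thg)) + geometry$beam_centre[1]
  ys <- outer(rp, sin(thg)) + geometry$beam_centre[2]
  vals <- matrix(interp_image(image, xs, ys, order = order), nq, ntheta)
  structure(list(values = vals, q = qg, theta = thg),
            class = "polar_intensity")
}

## Raw-image pre-processing ----------------------------------------------------

#' Crop a square region about a centre
#'
#' Integer crop of `size` x `size` pixels approximately centred on `centre`
#' (fractional pixel units); used to centre raw images on the beam before
#' polar resampling.
#'
#' @param image numeric matrix.
#' @param size crop width in pixels.
#' @param centre centre `(x, y)` in fractional pixel units; default image centre.
#' @return list with `image` (cropped matrix) and `centre` (the centre
#'   coordinates within the cropped frame).
#' @export
centre_crop <- function(image, size, centre = NULL) {
  if (is.null(centre)) centre <- dim(image) / 2
  size <- as.integer(size)
  x0 <- round(centre[1] - size / 2)
  y0 <- round(centre[2] - size / 2)
  if (x0 < 0 || y0 < 0 || x0 + size > nrow(image) || y0 + size > ncol(image))
    stop("crop window extends outside the image")
  list(image = image[x0 + seq_len(size), y0 + seq_len(size)],
       centre = c(centre[1] - x0, centre[2] - y0))
}

#' Rebin an image by an integer factor (mean pooling)
#'
#' @param image numeric matrix whose dimensions are multiples of `factor`.
#' @param factor integer rebin factor.
#' @return rebinned matrix (`dim(image) / factor`).
#' @export
rebin_image <- function(image, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  d <- dim(image)
  if (any(d %% factor != 0)) stop("image dimensions must be multiples of factor")
  n1 <- d[1] %/% factor; n2 <- d[2] %/% factor
  a <- array(image, c(factor, n1, factor, n2))
  apply(a, c(2, 4), mean)
}
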