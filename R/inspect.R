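## Slicing, smoothing, plotting and peak quantification of 3D volumes.

.vol_grids <- function(V) {
  if (inherits(V, "padf_volume"))
    list(values = V$values, g1 = V$r, g3 = V$theta, angular_unit = "deg")
  else if (inherits(V, "correlation_volume"))
    list(values = V$values, g1 = V$q, g3 = V$theta * 180 / pi,
         angular_unit = "deg")
  else if (is.array(V) && length(dim(V)) == 3)
    list(values = V, g1 = seq_len(dim(V)[1]), g3 = seq_len(dim(V)[3]),
         angular_unit = "index")
  else stop("V must be a padf_volume, correlation_volume or 3D array")
}

.nearest_index <- function(grid, at) {
  if (at < min(grid) - 1e-9 || at > max(grid) + 1e-9)
    stop("coordinate ", format(at), " outside the grid range [",
         format(min(grid)), ", ", format(max(grid)), "]")
  which.min(abs(grid - at))
}

#' Extract 1D/2D sections of a 3D volume
#'
#' `"req"` returns the `r = r'` (or `q = q'`) diagonal plane as a
#' radius x angle matrix; `"theta"` a constant-angle 2D slice; `"r"` a
#' constant-radius 2D slice; `"line-r"` the radial line at fixed
#' `(r', theta)`; `"line-theta"` the angular line at fixed `(r, r')`.
#' Coordinates snap to the nearest grid plane. Angles are in degrees, radii
#' in the volume's radial units.
#'
#' @param V a `padf_volume`, `correlation_volume` or 3D array.
#' @param kind slice type.
#' @param at first coordinate (angle for `"theta"`, radius otherwise).
#' @param at2 second coordinate where needed (`"line-r"`: theta;
#'   `"line-theta"`: r').
#' @return matrix or vector with dimnames carrying the grid values.
#' @export
slice_volume <- function(V, kind = c("req", "theta", "r", "line-r",
                                     "line-theta"), at = NULL, at2 = NULL) {
  kind <- match.arg(kind)
  vg <- .vol_grids(V)
  vals <- vg$values
  n1 <- dim(vals)[1]
  switch(kind,
    "req" = {
      out <- t(vapply(seq_len(n1), function(k) vals[k, k, ],
                      numeric(dim(vals)[3])))
      dimnames(out) <- list(format(vg$g1), format(vg$g3))
      out
    },
    "theta" = {
      k <- .nearest_index(vg$g3, at)
      out <- vals[, , k]
      dimnames(out) <- list(format(vg$g1), format(vg$g1))
      out
    },
    "r" = {
      k <- .nearest_index(vg$g1, at)
      out <- vals[k, , ]
      dimnames(out) <- list(format(vg$g1), format(vg$g3))
      out
    },
    "line-r" = {
      j <- .nearest_index(vg$g1, at)
      k <- .nearest_index(vg$g3, at2)
      stats::setNames(vals[, j, k], format(vg$g1))
    },
    "line-theta" = {
      i <- .nearest_index(vg$g1, at)
      j <- .nearest_index(vg$g1, if (is.null(at2)) at else at2)
      stats::setNames(vals[i, j, ], format(vg$g3))
    })
}

.gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-h, h), sd = sigma)
  k / sum(k)
}

# reflective-boundary separable convolution along one array dimension
.conv_dim <- function(V, k, dim) {
  if (length(k) == 1) return(V)
  h <- (length(k) - 1) / 2
  n <- base::dim(V)[dim]
  if (h >= n) stop("kernel wider than the volume axis")
  idx <- c(rev(seq_len(h)), seq_len(n), n + 1 - rev(seq_len(h)))
  perm <- c(dim, setdiff(1:3, dim))
  A <- aperm(V, perm)
  d <- base::dim(A)
  M <- matrix(A, d[1], d[2] * d[3])[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(M))
  for (i in seq_along(k)) out <- out + k[i] * M[(seq_len(n)) + (i - 1), ,
                                                drop = FALSE]
  aperm(array(out, d), order(perm))
}

#' Gaussian smoothing of a PADF (or correlation) volume
#'
#' Separable Gaussian convolution along r, r' (same radial width) and theta.
#' Kernels are normalized and truncated at 3 half-widths; boundaries are
#' reflective, which matches the even symmetry of the PADF about theta = 0
#' and 180 degrees. The half-width is interpreted as the Gaussian sigma by
#' default; `interpret = "hwhm"` converts from half-width-at-half-maximum.
#'
#' @param V a `padf_volume` (or `correlation_volume`).
#' @param r_halfwidth radial half-width in the volume's radial units.
#' @param theta_halfwidth angular half-width in degrees.
#' @param interpret `"sigma"` (default) or `"hwhm"`.
#' @return the smoothed volume (same class).
#' @export
gaussian_smooth <- function(V, r_halfwidth, theta_halfwidth,
                            interpret = c("sigma", "hwhm")) {
  interpret <- match.arg(interpret)
  if (r_halfwidth < 0 || theta_halfwidth < 0)
    stop("half-widths must be >= 0")
  fac <- if (interpret == "hwhm") 1 / sqrt(2 * log(2)) else 1
  vg <- .vol_grids(V)
  dr <- if (length(vg$g1) > 1) vg$g1[2] - vg$g1[1] else 1
  dth <- if (length(vg$g3) > 1) vg$g3[2] - vg$g3[1] else 1
  kr <- .gauss_kernel(fac * r_halfwidth / dr)
  kt <- .gauss_kernel(fac * theta_halfwidth / dth)
  vals <- vg$values
  vals <- .conv_dim(vals, kr, 1)
  vals <- .conv_dim(vals, kr, 2)
  vals <- .conv_dim(vals, kt, 3)
  if (is.list(V)) { V$values <- vals; V } else vals
}

#' Windowed peak table and height ratios
#'
#' For each search window the grid-point maximum of the volume is located
#' and reported with its `(r, r', theta)` coordinates and height. Heights
#' are read from the volume as given (smooth first with
#' [gaussian_smooth()] if desired). Ratios between all labelled rows are
#' attached as an attribute.
#'
#' @param V a `padf_volume` (or compatible volume).
#' @param windows named list of windows; each window is a list with numeric
#'   ranges `r`, `rp` (radial, both `c(min, max)`) and `theta` (degrees).
#' @return data frame with columns `label`, `r`, `rp`, `theta`, `height`;
#'   attribute `"ratios"` holds the matrix of `height[i] / height[j]`.
#' @export
peak_table <- function(V, windows) {
  vg <- .vol_grids(V)
  if (is.null(names(windows)))
    names(windows) <- paste0("peak", seq_along(windows))
  rows <- lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    i <- which(vg$g1 >= w$r[1] & vg$g1 <= w$r[2])
    j <- which(vg$g1 >= w$rp[1] & vg$g1 <= w$rp[2])
    k <- which(vg$g3 >= w$theta[1] & vg$g3 <= w$theta[2])
    if (!length(i) || !length(j) || !length(k))
      stop("window '", nm, "' contains no grid points")
    sub <- vg$values[i, j, k, drop = FALSE]
    m <- arrayInd(which.max(sub), dim(sub))
    data.frame(label = nm, r = vg$g1[i[m[1]]], rp = vg$g1[j[m[2]]],
               theta = vg$g3[k[m[3]]], height = sub[m])
  })
  out <- do.call(rbind, rows)
  h <- out$height
  ratios <- outer(h, h, "/")
  dimnames(ratios) <- list(out$label, out$label)
  attr(out, "ratios") <- ratios
  out
}

#' Plot a slice of a correlation or PADF volume to PNG
#'
#' @param V volume accepted by [slice_volume()].
#' @param kind,at,at2 slice selection, as in [slice_volume()].
#' @param png output path; `NULL` draws on the current device.
#' @param smooth_r,smooth_theta optional Gaussian half-widths applied before
#'   slicing.
#' @param main plot title.
#' @return invisibly, the sliced values.
#' @export
plot_slice <- function(V, kind = "req", at = NULL, at2 = NULL, png = NULL,
                       smooth_r = 0, smooth_theta = 0, main = NULL) {
  if (smooth_r > 0 || smooth_theta > 0)
    V <- gaussian_smooth(V, smooth_r, smooth_theta)
  s <- slice_volume(V, kind, at = at, at2 = at2)
  if (!is.null(png)) {
    grDevices::png(png, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  if (is.matrix(s)) {
    xg <- as.numeric(rownames(s)); yg <- as.numeric(colnames(s))
    graphics::image(xg, yg, s, col = grDevices::hcl.colors(128, "viridis"),
                    xlab = "", ylab = "", main = main %||% kind)
  } else {
    xg <- as.numeric(names(s))
    graphics::plot(xg, s, type = "l", xlab = "", ylab = "",
                   main = main %||% kind)
  }
  invisible(s)
}
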