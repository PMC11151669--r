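## Inversion of the correlation volume to the PADF.
##
## The orientation-averaged correlation has the Legendre form
##   C(q, q', theta) = sum_{even l} B_l(q, q') P_l(cos psi(q, q', theta)),
## where cos psi accounts for the Ewald-sphere tilt of the two q vectors.
## B_l(q, q') is recovered per ring pair by a regularized least-squares fit;
## two discrete spherical Bessel transforms carry each B_l to real space; a
## Legendre sum over even l then assembles Theta(r, r', theta).

#' Legendre argument on the Ewald sphere
#'
#' Cosine of the angle between two scattering vectors of magnitudes `q` and
#' `q'` whose detector azimuths differ by `theta`:
#' `cos psi = cos(th_q) cos(th_q') + sin(th_q) sin(th_q') cos(theta)`, where
#' `cos(th_q) = q * lambda / 2` is the Ewald polar tilt (equal to the half
#' scattering angle). In the flat-Ewald limit `lambda -> 0`,
#' `cos psi -> cos(theta)`.
#'
#' @param q,qp vector magnitudes in 1/nm.
#' @param theta azimuthal separation in radians (vectorized).
#' @param wavelength wavelength in nm; `q * lambda / 2` must not exceed 1.
#' @return `cos psi` in `[-1, 1]`.
#' @export
legendre_argument <- function(q, qp, theta, wavelength) {
  ct1 <- q * wavelength / 2
  ct2 <- qp * wavelength / 2
  if (any(ct1 > 1) || any(ct2 > 1))
    stop("q * wavelength / 2 > 1: beyond back-scattering")
  ct1 * ct2 + sqrt(1 - ct1^2) * sqrt(1 - ct2^2) * cos(theta)
}

# P_0..P_lmax at x (columns l = 0..lmax), by the three-term recurrence.
legendre_matrix <- function(x, lmax) {
  P <- matrix(0, length(x), lmax + 1)
  P[, 1] <- 1
  if (lmax >= 1) P[, 2] <- x
  if (lmax >= 2) for (l in 1:(lmax - 1))
    P[, l + 2] <- ((2 * l + 1) * x * P[, l + 1] - l * P[, l]) / (l + 1)
  P
}

#' Extract B_l(q, q') matrices from a correlation volume
#'
#' For each ring pair `(q, q')` the theta profile is fitted with even-order
#' Legendre polynomials in `cos psi` by weighted least squares under the
#' Legendre measure (rows weighted by `sqrt(|sin theta|)`, consuming any
#' `|sin theta|` conditioning already applied to the volume). Columns are
#' equilibrated to unit norm and singular values below
#' `regularization * sigma_max` are discarded, which removes only directions
#' the Ewald geometry leaves near-degenerate. The design matrix depends only
#' on the ring pair and the geometry, not on the data.
#'
#' @param C a `correlation_volume`, normally conditioned with
#'   [apply_sintheta_weight()].
#' @param lmax maximum spherical-harmonic order (even).
#' @param wavelength wavelength in nm (Ewald argument).
#' @param regularization relative SVD cutoff (default 0.5).
#' @param force proceed even if the volume lacks the sin-theta conditioning
#'   record.
#' @return object of class `blq_set`: list with `l` (even orders),
#'   `matrices` (one `nq x nq` symmetric matrix per order), `q`,
#'   `wavelength`, `lmax`.
#' @export
extract_bl <- function(C, lmax = 32, wavelength, regularization = 0.5,
                       force = FALSE) {
  if (lmax %% 2 != 0) stop("lmax must be even")
  expo <- C$conditioning$sintheta_exponent %||% 0
  if (expo == 0 && !force)
    stop("correlation volume lacks the sin-theta sampling weight; ",
         "apply_sintheta_weight() first or use force = TRUE")
  q <- C$q
  nq <- length(q)
  th <- C$theta
  evenl <- seq(0, lmax, 2)
  nl <- length(evenl)
  sth <- abs(sin(th))
  # row weights: sqrt(sin) measure overall; the data already carry sin^expo
  wdesign <- sqrt(sth)
  wdata <- ifelse(sth > 0, sth^(0.5 - expo), 0)
  ct <- q * wavelength / 2
  if (any(ct > 1)) stop("q * wavelength / 2 > 1: beyond back-scattering")
  st <- sqrt(1 - ct^2)
  costh <- cos(th)
  mats <- array(0, c(nq, nq, nl))
  for (a in seq_len(nq)) {
    for (b in a:nq) {
      cospsi <- ct[a] * ct[b] + st[a] * st[b] * costh
      A <- wdesign * legendre_matrix(cospsi, lmax)[, evenl + 1, drop = FALSE]
      cn <- sqrt(colSums(A^2))
      cn[cn == 0] <- 1
      sv <- svd(sweep(A, 2, cn, "/"))
      keep <- sv$d >= regularization * sv$d[1]
      if (!any(keep)) {
        warning("all singular values discarded at ring pair (", a, ",", b,
                "); B_l row set to 0")
        next
      }
      bb <- wdata * C$values[a, b, ]
      coef <- (sv$v[, keep, drop = FALSE] %*%
                 ((t(sv$u[, keep, drop = FALSE]) %*% bb) / sv$d[keep])) / cn
      mats[a, b, ] <- coef
      mats[b, a, ] <- coef
    }
  }
  structure(list(l = evenl,
                 matrices = lapply(seq_len(nl), function(i) mats[, , i]),
                 q = q, wavelength = wavelength, lmax = lmax,
                 sampling = "uniform"),
            class = "blq_set")
}

## Spherical Bessel machinery --------------------------------------------------

#' Spherical Bessel function of the first kind
#'
#' @param l order (single non-negative integer).
#' @param x argument (vectorized, >= 0).
#' @return `j_l(x)`.
#' @export
sbessel_j <- function(l, x) {
  out <- numeric(length(x))
  small <- x < 1e-6
  if (any(!small))
    out[!small] <- sqrt(pi / (2 * x[!small])) * besselJ(x[!small], l + 0.5)
  if (any(small))
    out[small] <- if (l == 0) 1 - x[small]^2 / 6
                  else x[small]^l / prod(seq(1, 2 * l + 1, 2))
  out
}

.zeros_cache <- new.env(parent = emptyenv())

#' Zeros of the spherical Bessel functions j_0 .. j_lmax
#'
#' Computed by bracketed root search using the interlacing property
#' `u_{l,n} < u_{l+1,n} < u_{l,n+1}` starting from `u_{0,n} = n * pi`.
#' Results are cached per `(lmax, n)`.
#'
#' @param lmax maximum order.
#' @param n number of zeros per order.
#' @return list of length `lmax + 1`; element `l + 1` holds the first `n`
#'   positive zeros of `j_l`.
#' @export
sbessel_zeros <- function(lmax, n) {
  key <- paste(lmax, n, sep = "_")
  if (!is.null(.zeros_cache[[key]])) return(.zeros_cache[[key]])
  n0 <- n + lmax + 2
  z <- vector("list", lmax + 1)
  z[[1]] <- (1:n0) * pi
  if (lmax >= 1) for (l in 1:lmax) {
    prev <- z[[l]]
    cur <- numeric(length(prev) - 1)
    for (k in seq_len(length(prev) - 1))
      cur[k] <- stats::uniroot(function(x) sbessel_j(l, x),
                               c(prev[k], prev[k + 1]), tol = 1e-13)$root
    z[[l + 1]] <- cur
  }
  z <- lapply(z, function(v) v[seq_len(n)])
  .zeros_cache[[key]] <- z
  z
}

# 1D interpolation of the rows of a matrix at fractional indices, cubic with
# linear fallback near the edges; rows with out-of-range index are zero.
.interp_rows <- function(G, idx, inside) {
  n <- nrow(G)
  out <- matrix(0, length(idx), ncol(G))
  i0 <- floor(idx); tt <- idx - i0
  cub <- inside & i0 >= 2 & i0 <= n - 2
  if (any(cub)) {
    w <- .catmull_rom_weights(tt[cub])
    acc <- 0
    for (a in -1:2) acc <- acc + w[, a + 2] * G[i0[cub] + a, , drop = FALSE]
    out[cub, ] <- acc
  }
  lin <- inside & !cub
  if (any(lin)) {
    i0l <- pmax(pmin(i0[lin], n - 1), 1)
    tl <- idx[lin] - i0l
    out[lin, ] <- (1 - tl) * G[i0l, , drop = FALSE] +
      tl * G[i0l + 1, , drop = FALSE]
  }
  out
}

.interp_matrix <- function(G, idx, inside, order = "cubic") {
  if (order == "linear") {
    n <- nrow(G)
    i0 <- pmax(pmin(floor(idx), n - 1), 1)
    tt <- idx - i0
    M1 <- matrix(0, length(idx), ncol(G))
    M1[inside, ] <- (1 - tt[inside]) * G[i0[inside], , drop = FALSE] +
      tt[inside] * G[i0[inside] + 1, , drop = FALSE]
  } else {
    M1 <- .interp_rows(G, idx, inside)
  }
  if (order == "linear") {
    M2 <- matrix(0, length(idx), length(idx))
    i0 <- pmax(pmin(floor(idx), ncol(G) - 1), 1)
    tt <- idx - i0
    M2[, inside] <- (1 - rep(tt[inside], each = nrow(M1))) *
      M1[, i0[inside], drop = FALSE] +
      rep(tt[inside], each = nrow(M1)) * M1[, i0[inside] + 1, drop = FALSE]
    M2
  } else {
    t(.interp_rows(t(M1), idx, inside))
  }
}

#' Resample B_l matrices onto the spherical-Bessel sampling grids
#'
#' The discrete spherical Bessel transform samples each order at
#' `q_{l,n} = u_{l,n} / (2 * pi * R)` where `u_{l,n}` is the n-th zero of
#' `j_l`. For `l = 0` these points are uniform (`u_{0,n} = n * pi`); each
#' `l > 0` matrix is interpolated onto its own grid. Points beyond the
#' measured q range are set to zero.
#'
#' @param blq a `blq_set` on a uniform q grid (from [extract_bl()]).
#' @param nr number of radial samples (zeros retained per order).
#' @param rmax maximum real-space distance R in nm.
#' @param order interpolation order, `"cubic"` (default) or `"linear"`.
#' @return a `blq_set` with `sampling = "bessel"`, carrying per-order
#'   q grids and the zeros used.
#' @export
resample_bl <- function(blq, nr, rmax, order = c("cubic", "linear")) {
  order <- match.arg(order)
  if (rmax <= 0) stop("rmax must be > 0")
  stopifnot(inherits(blq, "blq_set"), identical(blq$sampling, "uniform"))
  q <- blq$q
  dq <- q[2] - q[1]
  zeros <- sbessel_zeros(max(blq$l) + 1, nr)
  qgrids <- lapply(blq$l, function(l) zeros[[l + 1]] / (2 * pi * rmax))
  mats <- vector("list", length(blq$l))
  for (i in seq_along(blq$l)) {
    qt <- qgrids[[i]]
    idx <- (qt - q[1]) / dq + 1
    inside <- qt <= max(q) + 1e-12 & qt >= q[1] - 1e-12
    snap <- abs(idx - round(idx)) < 1e-9
    idx[snap] <- round(idx[snap])
    exact <- inside & snap
    M <- .interp_matrix(blq$matrices[[i]], idx, inside, order)
    if (all(exact)) M <- blq$matrices[[i]][round(idx), round(idx)]
    mats[[i]] <- M
  }
  structure(list(l = blq$l, matrices = mats, q = qgrids, zeros = zeros,
                 wavelength = blq$wavelength, lmax = blq$lmax,
                 nr = nr, rmax = rmax, sampling = "bessel"),
            class = "blq_set")
}

#' Discrete spherical Bessel transform of B_l(q,q') to B_l(r,r')
#'
#' Applies, along both axes, the discrete transform
#' `f(r) = sum_n f(q_{l,n}) j_l(u_{l,n} r / R) / (2 pi R^3 j_{l+1}(u_{l,n})^2)`,
#' which inverts the radial transform with kernel `j_l(2 pi q r)` exactly for
#' functions supported on `[0, R]` sampled at the `j_l` zeros. The output is
#' evaluated on the common uniform grid `r_k = k * R / nr`.
#'
#' @param blq a `blq_set` resampled with [resample_bl()].
#' @return object of class `blr_set`: `l`, `matrices` (one `nr x nr` per
#'   order), `r`, `rmax`, `lmax`.
#' @export
sbt_bl <- function(blq) {
  stopifnot(inherits(blq, "blq_set"), identical(blq$sampling, "bessel"))
  nr <- blq$nr; R <- blq$rmax
  r <- seq_len(nr) * R / nr
  mats <- vector("list", length(blq$l))
  for (i in seq_along(blq$l)) {
    l <- blq$l[i]
    u <- blq$zeros[[l + 1]]
    TT <- matrix(0, nr, nr)
    for (n in seq_len(nr)) TT[, n] <- sbessel_j(l, u[n] * r / R)
    TT <- sweep(TT, 2, 2 * pi * R^3 * sbessel_j(l + 1, u)^2, "/")
    mats[[i]] <- TT %*% blq$matrices[[i]] %*% t(TT)
  }
  structure(list(l = blq$l, matrices = mats, r = r, rmax = R,
                 lmax = blq$lmax),
            class = "blr_set")
}

#' Assemble the PADF from real-space B_l matrices
#'
#' Forms `Theta(r, r', theta) = sum_{even l} w_l B_l(r, r') P_l(cos theta)`
#' on a uniform theta grid over `[0, 180]` degrees and applies the final
#' scaling. The default weight `w_l = 1/2` completes the delta-kernel
#' reconstruction of the pair-angle density (the extracted `B_l` already
#' carry the `(2l+1)` addition-theorem factor); `"plancherel"` uses
#' `(2l+1)/(4 pi)` instead. The default scaling multiplies by
#' `r^2 r'^2 |sin theta|`, after which peak heights are proportional to
#' pair-pair multiplicities; values within about `(360 / lmax) / 2` degrees
#' of theta = 0 are flagged unreliable in the scaling record. In absolute
#' mode the result is divided by `8 pi^3 rho0^2 NI^2`.
#'
#' @param blr a `blr_set` from [sbt_bl()].
#' @param dtheta angular step in degrees.
#' @param sintheta multiply by `|sin theta|` (default `TRUE`).
#' @param radial_weight multiply by `r^2 r'^2` (default `TRUE`).
#' @param lweight `"delta"` (constant 1/2) or `"plancherel"`
#'   (`(2l+1)/(4 pi)`), or a numeric vector of per-order weights.
#' @param rho0,NI mean density (1/nm^3) and incident quanta for absolute
#'   scaling; both `NULL` by default (relative units).
#' @return object of class `padf_volume`: `values` (`nr x nr x ntheta`),
#'   `r`, `theta` (degrees), `lmax`, `scaling` record.
#' @export
assemble_padf <- function(blr, dtheta = 1, sintheta = TRUE,
                          radial_weight = TRUE, lweight = "delta",
                          rho0 = NULL, NI = NULL) {
  stopifnot(inherits(blr, "blr_set"))
  theta <- seq(0, 180, by = dtheta)
  x <- cos(theta * pi / 180)
  nl <- length(blr$l)
  w <- if (is.numeric(lweight)) rep_len(lweight, nl)
       else switch(match.arg(lweight, c("delta", "plancherel")),
                   delta = rep(0.5, nl),
                   plancherel = (2 * blr$l + 1) / (4 * pi))
  P <- legendre_matrix(x, blr$lmax)[, blr$l + 1, drop = FALSE]
  nr <- length(blr$r)
  Bflat <- vapply(seq_len(nl), function(i) as.numeric(blr$matrices[[i]]),
                  numeric(nr * nr))
  vals <- array(Bflat %*% t(P * rep(w, each = length(theta))),
                c(nr, nr, length(theta)))
  scaling <- list(lweight = w, theta_weight = if (sintheta) "sin" else "none",
                  radial_weight = if (radial_weight) "r2r2" else "none",
                  unreliable_theta_deg = (360 / blr$lmax) / 2)
  if (radial_weight) {
    rw <- outer(blr$r^2, blr$r^2)
    for (k in seq_along(theta)) vals[, , k] <- vals[, , k] * rw
  }
  if (sintheta) {
    s <- abs(sin(theta * pi / 180))
    vals <- sweep(vals, 3, s, "*")
  }
  if (!is.null(rho0) && !is.null(NI)) {
    vals <- vals / (8 * pi^3 * rho0^2 * NI^2)
    scaling$absolute <- c(rho0 = rho0, NI = NI)
  }
  structure(list(values = vals, r = blr$r, theta = theta, lmax = blr$lmax,
                 scaling = scaling),
            class = "padf_volume")
}

#' @export
print.padf_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<padf_volume> %d x %d x %d (r x r' x theta), lmax=%d\n",
              d[1], d[2], d[3], x$lmax))
  cat("  rmax:", format(max(x$r)), "nm; theta: 0..", max(x$theta), "deg\n")
  cat("  scaling: theta =", x$scaling$theta_weight,
      ", radial =", x$scaling$radial_weight,
      "; unreliable below", format(x$scaling$unreliable_theta_deg), "deg\n")
  invisible(x)
}

#' Correlation volume to PADF in one call
#'
#' Chains [extract_bl()], [resample_bl()], [sbt_bl()] and
#' [assemble_padf()].
#'
#' @inheritParams extract_bl
#' @inheritParams resample_bl
#' @inheritParams assemble_padf
#' @param nr number of radial samples; default `round(2 * rmax * qmax)`,
#'   which matches the real-space sampling limit of the measured q range.
#' @param keep_bl also return the intermediate `blq_set`/`blr_set`.
#' @return a `padf_volume`, or a list `(padf, blq, blr)` if `keep_bl`.
#' @export
padf_from_correlation <- function(C, lmax = 32, wavelength, rmax,
                                  nr = NULL, regularization = 0.5,
                                  dtheta = 1, sintheta = TRUE,
                                  radial_weight = TRUE, lweight = "delta",
                                  force = FALSE, keep_bl = FALSE) {
  if (is.null(nr)) nr <- round(2 * rmax * max(C$q))
  blq <- extract_bl(C, lmax = lmax, wavelength = wavelength,
                    regularization = regularization, force = force)
  blqb <- resample_bl(blq, nr = nr, rmax = rmax)
  blr <- sbt_bl(blqb)
  padf <- assemble_padf(blr, dtheta = dtheta, sintheta = sintheta,
                        radial_weight = radial_weight, lweight = lweight)
  if (keep_bl) list(padf = padf, blq = blq, blr = blr) else padf
}
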