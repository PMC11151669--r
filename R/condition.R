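## Conditioning of the correlation volume before inversion.
##
## All three operations are elementwise masks/weights on the theta or q axes,
## so they commute exactly; each records itself in the volume's conditioning
## record, which the inversion consults.

#' Apply the |sin(theta)|^exponent sampling weight
#'
#' The correlation volume is computed on a uniform theta grid, while the
#' Legendre orthogonality that underlies the inversion holds with respect to
#' cos(theta); weighting by `|sin(theta)|` converts the uniform-theta
#' quadrature to the cos(theta) measure. The applied exponent is recorded in
#' the conditioning record and consumed by [extract_bl()].
#'
#' @param C a `correlation_volume`.
#' @param exponent weight exponent (default 1, the Jacobian).
#' @return the weighted `correlation_volume`.
#' @export
apply_sintheta_weight <- function(C, exponent = 1) {
  w <- abs(sin(C$theta))^exponent
  C$values <- sweep(C$values, 3, w, "*")
  C$conditioning$sintheta_exponent <-
    (C$conditioning$sintheta_exponent %||% 0) + exponent
  C
}

#' Band-pass filter on the q axes
#'
#' Entries whose `q` or `q'` lies outside `[q_low, q_high]` are set to zero.
#' The cut is hard by default; `taper` > 0 applies a cosine half-window of
#' that width (in 1/nm) inside each cut, so the value at the cut is half the
#' interior value.
#'
#' @param C a `correlation_volume`.
#' @param q_low,q_high band edges in 1/nm, `0 <= q_low < q_high`.
#' @param taper cosine taper width in 1/nm (0 = hard cut).
#' @return the filtered `correlation_volume`.
#' @export
q_bandpass <- function(C, q_low = 0, q_high = max(C$q), taper = 0) {
  if (q_low < 0 || q_high <= q_low) stop("need 0 <= q_low < q_high")
  q <- C$q
  w <- as.numeric(q >= q_low & q <= q_high)
  if (taper > 0) {
    lo <- q >= q_low & q < q_low + taper
    w[lo] <- 0.5 * (1 - cos(pi * (q[lo] - q_low) / taper))
    hi <- q > q_high - taper & q <= q_high
    w[hi] <- 0.5 * (1 - cos(pi * (q_high - q[hi]) / taper))
    # value exactly at the cut is 0; half the interior value sits at the cut
    w[q == q_low] <- 0.5
    w[q == q_high] <- 0.5
  }
  C$values <- sweep(sweep(C$values, 1, w, "*"), 2, w, "*")
  C$conditioning$q_band <- c(q_low, q_high, taper)
  C
}

#' Mask the noise-variance region near theta = 0
#'
#' Uncorrelated detector noise produces a spurious peak confined to
#' `theta ~ 0` at `q = q'` (its height equals the per-ring noise variance).
#' This sets to zero all theta samples within `half_width` degrees of 0,
#' including the mirror region near 2*pi, which is equally contaminated by
#' the correlation's symmetry.
#'
#' @param C a `correlation_volume`.
#' @param half_width angular half-width in degrees (>= 0).
#' @return the masked `correlation_volume`.
#' @export
theta_zero_mask <- function(C, half_width) {
  if (half_width < 0) stop("half_width must be >= 0")
  hw <- half_width * pi / 180
  d <- pmin(C$theta, 2 * pi - C$theta)   # angular distance to 0 (mod 2pi)
  kill <- d <= hw + 1e-12
  C$values[, , kill] <- 0
  C$conditioning$theta_zero_halfwidth <- half_width
  C
}
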