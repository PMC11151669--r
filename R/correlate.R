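## Angular intensity cross-correlation.
##
## The correlation volume C(q, q', theta) is the dataset average of circular
## cross-correlations between the theta profiles of rings q and q', divided
## by ntheta so that C is independent of the angular sampling rate:
##   C(q, q', theta_k) = (1 / (N * ntheta)) *
##                       sum_i sum_j I_i(q, theta_j) I_i(q', theta_j + theta_k).
## Rings are correlated with the 1D FFT and the convolution theorem; the
## background estimator pairs distinct exposures, and the difference
## estimator correlates pattern differences so that, with a shared pairing,
## C_DIFF = 2 * (C - C_BG) holds exactly.

new_correlation_volume <- function(values, q, theta, mode, n_patterns,
                                   split = "all", mask_corrected = FALSE,
                                   conditioning = list()) {
  structure(list(values = values, q = q, theta = theta, mode = mode,
                 n_patterns = n_patterns, split = split,
                 mask_corrected = mask_corrected,
                 conditioning = conditioning),
            class = "correlation_volume")
}

#' @export
print.correlation_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<correlation_volume> %d x %d x %d, mode=%s, split=%s, n=%s\n",
              d[1], d[2], d[3], x$mode, x$split, format(x$n_patterns)))
  cat("  qmax:", format(max(x$q)), "1/nm; mask_corrected:", x$mask_corrected, "\n")
  if (length(x$conditioning))
    cat("  conditioning:", paste(names(x$conditioning), collapse = ", "), "\n")
  invisible(x)
}

#' Circular cross-correlation of two ring profiles
#'
#' `c(theta_k) = sum_j a(theta_j) b(theta_j + theta_k)` with circular
#' indexing, computed with the FFT and the convolution theorem (no
#' normalization is applied here).
#'
#' @param a,b numeric vectors of equal length.
#' @return numeric vector of the same length.
#' @export
ring_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("ring profiles must have equal length")
  Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) /
    length(a)
}

#' Random derangement (fixed-point-free permutation)
#'
#' Used to pick the background/difference pairing `j(i) != i`.
#'
#' @param n number of elements (>= 2).
#' @return integer permutation of `1:n` with no fixed point.
#' @export
random_derangement <- function(n) {
  if (n < 2) stop("a derangement needs n >= 2")
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

.polar_to_array <- function(patterns) {
  if (is.list(patterns) && !is.null(patterns$polar)) {
    return(list(arr = patterns$polar, q = patterns$q, theta = patterns$theta))
  }
  if (is.array(patterns) && length(dim(patterns)) == 3) {
    d <- dim(patterns)
    return(list(arr = patterns, q = seq_len(d[1]) - 1, theta =
                  seq(0, 2 * pi, length.out = d[2] + 1)[seq_len(d[2])]))
  }
  if (inherits(patterns, "polar_intensity")) patterns <- list(patterns)
  if (is.list(patterns) && all(vapply(patterns, inherits, TRUE,
                                      "polar_intensity"))) {
    arr <- vapply(patterns, function(p) p$values,
                  patterns[[1]]$values)
    return(list(arr = arr, q = patterns[[1]]$q, theta = patterns[[1]]$theta))
  }
  stop("patterns must be polar_intensity objects, a list of them, ",
       "a 3D array, or the output of simulate_polar_dataset()")
}

# Accumulate sum over patterns of Conj(fft ring a) * (fft ring b) per angular
# frequency, as nq x nq matrices, using BLAS complex products.
.corr_accumulate <- function(Eh, pairing = NULL, mode = "standard") {
  nth <- dim(Eh)[1]; nq <- dim(Eh)[2]; n <- dim(Eh)[3]
  S <- array(complex(real = 0), c(nth, nq, nq))
  for (w in seq_len(nth)) {
    M <- matrix(Eh[w, , ], nq, n)
    S[w, , ] <- switch(mode,
      standard = Conj(M) %*% t(M),
      background = {
        Mp <- M[, pairing, drop = FALSE]
        (Conj(M) %*% t(Mp) + Conj(Mp) %*% t(M)) / 2
      },
      difference = {
        D <- M - M[, pairing, drop = FALSE]
        Conj(D) %*% t(D)
      })
  }
  S
}

#' Angular cross-correlation volume of a data set
#'
#' Computes C(q, q', theta) in one of three modes: `"standard"` correlates
#' each exposure with itself; `"background"` correlates randomly paired
#' distinct exposures (accumulated symmetrically over the pairing and its
#' reverse, which estimates the static background); `"difference"`
#' correlates the pattern differences `I_i - I_j(i)` with themselves. With a
#' shared `pairing`, `C_DIFF = 2 * (C - C_BG)` exactly.
#'
#' @param patterns polar data: a list of `polar_intensity`, an
#'   `nq x ntheta x n` array, or the output of [simulate_polar_dataset()].
#' @param mode `"standard"`, `"background"` or `"difference"`.
#' @param pairing integer derangement of `1:n` (defaults to a random
#'   derangement from the current RNG stream; ignored in standard mode).
#' @param split if `TRUE`, additionally return independent volumes from the
#'   odd and even exposures (file-list positions 0, 2, 4, ... form the `"a"`
#'   half) for convergence checks.
#' @param chunk number of exposures FFT'd per block in standard mode.
#' @return a `correlation_volume`, or, with `split = TRUE`, a list with
#'   elements `all`, `a`, `b`.
#' @export
dataset_correlation <- function(patterns, mode = c("standard", "background",
                                                   "difference"),
                                pairing = NULL, split = FALSE, chunk = 64) {
  mode <- match.arg(mode)
  p <- .polar_to_array(patterns)
  arr <- p$arr
  nq <- dim(arr)[1]; nth <- dim(arr)[2]; n <- dim(arr)[3]
  if (mode != "standard" && n < 2)
    stop("background/difference correlation needs at least 2 patterns")

  corr_of <- function(idx, pairing_sub = NULL) {
    m <- length(idx)
    if (mode == "standard") {
      S <- array(complex(real = 0), c(nth, nq, nq))
      done <- 0
      while (done < m) {
        take <- idx[(done + 1):min(done + chunk, m)]
        Eh <- array(complex(real = 0), c(nth, nq, length(take)))
        for (k in seq_along(take))
          Eh[, , k] <- stats::mvfft(t(arr[, , take[k]]))
        S <- S + .corr_accumulate(Eh, mode = "standard")
        done <- done + length(take)
      }
    } else {
      Eh <- array(complex(real = 0), c(nth, nq, m))
      for (k in seq_len(m)) Eh[, , k] <- stats::mvfft(t(arr[, , idx[k]]))
      if (is.null(pairing_sub)) pairing_sub <- random_derangement(m)
      if (length(pairing_sub) != m || any(pairing_sub == seq_len(m)) ||
          any(sort(pairing_sub) != seq_len(m)))
        stop("pairing must be a derangement of 1:", m)
      S <- .corr_accumulate(Eh, pairing = pairing_sub, mode = mode)
    }
    Cm <- Re(stats::mvfft(matrix(S, nth, nq * nq), inverse = TRUE))
    vals <- aperm(array(Cm, c(nth, nq, nq)), c(2, 3, 1)) / (nth * nth * m)
    vals
  }

  make_vol <- function(vals, m, split_label)
    new_correlation_volume(vals, q = p$q, theta = p$theta, mode = mode,
                           n_patterns = m, split = split_label)

  out_all <- make_vol(corr_of(seq_len(n), pairing), n, "all")
  if (!split) return(out_all)
  ia <- seq(1, n, 2); ib <- seq(2, n, 2)
  list(all = out_all,
       a = make_vol(corr_of(ia), length(ia), "a"),
       b = make_vol(corr_of(ib), length(ib), "b"))
}

#' Correlation volume of a detector mask
#'
#' The single-pattern standard correlation of the polar-resampled binary
#' mask, used by [mask_correction()].
#'
#' @param mask_polar a `polar_intensity` of the mask (values in `[0, 1]`),
#'   or an `nq x ntheta` matrix.
#' @return a `correlation_volume` with mode `"mask"` (non-negative
#'   everywhere).
#' @export
mask_correlation <- function(mask_polar) {
  if (inherits(mask_polar, "polar_intensity")) {
    vals <- mask_polar$values; q <- mask_polar$q; th <- mask_polar$theta
  } else {
    vals <- as.matrix(mask_polar)
    q <- seq_len(nrow(vals)) - 1
    th <- seq(0, 2 * pi, length.out = ncol(vals) + 1)[seq_len(ncol(vals))]
  }
  vol <- dataset_correlation(array(vals, c(dim(vals), 1)), mode = "standard")
  vol$q <- q; vol$theta <- th
  vol$mode <- "mask"
  vol$values[vol$values < 0] <- 0   # clip FFT round-off
  vol
}

#' Correct a correlation volume for a detector mask
#'
#' Divides elementwise by the mask correlation wherever it exceeds
#' `tol * max(C_mask)` and sets the rest to zero. With an all-ones mask the
#' mask correlation is identically 1 under the package normalization, so the
#' correction is the identity.
#'
#' @param C a `correlation_volume`.
#' @param C_mask the mask correlation from [mask_correlation()].
#' @param tol relative tolerance defining the mask support.
#' @return the corrected `correlation_volume` (flagged `mask_corrected`).
#' @export
mask_correction <- function(C, C_mask, tol = 1e-10) {
  if (!identical(dim(C$values), dim(C_mask$values)))
    stop("correlation and mask-correlation grids differ")
  thresh <- tol * max(C_mask$values)
  ok <- C_mask$values > thresh
  vals <- array(0, dim(C$values))
  vals[ok] <- C$values[ok] / C_mask$values[ok]
  out <- C
  out$values <- vals
  out$mask_corrected <- TRUE
  out
}
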