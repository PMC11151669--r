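test_that("the Legendre argument matches the Ewald vector geometry", {
  # flat-Ewald limit: cos(psi) -> cos(theta)
  th <- seq(0, 2 * pi, length.out = 37)
  expect_equal(legendre_argument(1, 1, th, 1e-6), cos(th), tolerance = 1e-6)
  # zero separation of equal rings gives exactly 1
  expect_equal(legendre_argument(0.7, 0.7, 0, 0.1), 1)
  expect_error(legendre_argument(30, 30, 0, 0.1), "back-scattering")

  # oracle: dot product of two ewald_qvector outputs at azimuthal
  # separation theta, for random ring pairs
  g <- square_detector(npix = 512, q_edge = 1.28, wavelength = 0.1)
  set.seed(31)
  for (i in 1:100) {
    q1 <- runif(1, 0.05, 1.2); q2 <- runif(1, 0.05, 1.2)
    dth <- runif(1, 0, 2 * pi)
    r1 <- q_to_radius(q1, g) / g$pixel_size
    r2 <- q_to_radius(q2, g) / g$pixel_size
    a1 <- runif(1, 0, 2 * pi)
    v1 <- ewald_qvector(g$beam_centre[1] + r1 * cos(a1),
                        g$beam_centre[2] + r1 * sin(a1), g)
    v2 <- ewald_qvector(g$beam_centre[1] + r2 * cos(a1 + dth),
                        g$beam_centre[2] + r2 * sin(a1 + dth), g)
    cospsi <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    expect_lt(abs(cospsi - legendre_argument(q1, q2, dth, 0.1)), 1e-10)
  }
})

test_that("extract_bl recovers planted even-order coefficients", {
  q <- seq(0, 1.2, length.out = 6)
  # pure P_0: C == 1 everywhere
  C1 <- synth_correlation(list(matrix(1, 6, 6)), 0, q, 90, 0.05)
  bl1 <- extract_bl(C1, lmax = 8, wavelength = 0.05, force = TRUE)
  expect_equal(bl1$matrices[[1]], matrix(1, 6, 6), tolerance = 1e-9)
  for (i in 2:5) expect_lt(max(abs(bl1$matrices[[i]])), 1e-9)

  # random symmetric B_l for l <= 8 through the forward Legendre form
  set.seed(17)
  l <- c(0, 2, 4, 6, 8)
  Bl <- lapply(l, function(li) {
    M <- matrix(rnorm(36), 6, 6); (M + t(M)) / 2
  })
  C <- synth_correlation(Bl, l, q, 180, 0.05)
  # unconditioned path (force) ...
  rec <- extract_bl(C, lmax = 8, wavelength = 0.05, force = TRUE)
  for (i in seq_along(l))
    expect_lt(max(abs(rec$matrices[[i]] - Bl[[i]])), 1e-6)
  # ... and the standard path through the sin-theta conditioning
  recw <- extract_bl(apply_sintheta_weight(C), lmax = 8, wavelength = 0.05)
  for (i in seq_along(l))
    expect_lt(max(abs(recw$matrices[[i]] - Bl[[i]])), 1e-6)
  # symmetric matrices, even orders only
  expect_equal(rec$l, l)
  expect_equal(rec$matrices[[3]], t(rec$matrices[[3]]), tolerance = 1e-9)
  # refusing unconditioned volumes unless forced
  expect_error(extract_bl(C, lmax = 8, wavelength = 0.05), "sin-theta")
  expect_error(extract_bl(C, lmax = 7, wavelength = 0.05, force = TRUE),
               "even")
})

test_that("hexagon B_l energy concentrates in six-fold orders", {
  C <- apply_sintheta_weight(hex_corr_std())
  bl <- hex_blq_std()
  # strongest off-origin ring pair on the diagonal
  strength <- vapply(2:256, function(k) sum(abs(C$values[k, k, ])), 0)
  k <- which.max(strength) + 1
  e <- vapply(seq_along(bl$l), function(i) bl$matrices[[i]][k, k]^2, 0)
  sixfold <- bl$l %% 6 == 0
  expect_gt(sum(e[sixfold]), 5 * sum(e[!sixfold]))
})

test_that("spherical Bessel zeros and transforms check out", {
  z <- sbessel_zeros(3, 20)
  # j_0 zeros are n*pi
  expect_equal(z[[1]], (1:20) * pi, tolerance = 1e-12)
  # interlacing and residual
  expect_true(all(z[[2]] > z[[1]] & z[[2]] < (2:21) * pi))
  for (l in 0:3) expect_lt(max(abs(sbessel_j(l, z[[l + 1]]))), 1e-10)

  # zero input -> zero output
  q <- seq(0, 1.28, length.out = 33)
  blq <- structure(list(l = c(0, 2), matrices = list(matrix(0, 33, 33),
                                                     matrix(0, 33, 33)),
                        q = q, wavelength = 0.1, lmax = 2,
                        sampling = "uniform"), class = "blq_set")
  br <- sbt_bl(resample_bl(blq, nr = 32, rmax = 12.5))
  expect_true(all(br$matrices[[1]] == 0) && all(br$matrices[[2]] == 0))
})

test_that("the discrete SBT reconstructs its own basis exactly", {
  # f(r) = j_l(u_lm r / R) has transform samples
  # f~(q_ln) = 2 pi R^3 j_{l+1}(u_ln)^2 delta_nm; applying the discrete
  # transform to those samples must return the basis function on any grid
  nr <- 24; R <- 10
  for (l in c(0, 4)) {
    u <- sbessel_zeros(l + 1, nr)[[l + 1]]
    set.seed(l + 1)
    coef <- rnorm(nr)
    ftilde <- 2 * pi * R^3 * sbessel_j(l + 1, u)^2 * coef
    M <- outer(ftilde, ftilde)   # separable B_l(q,q')
    blq <- structure(list(l = l, matrices = list(M),
                          q = list(u / (2 * pi * R)),
                          zeros = sbessel_zeros(l + 1, nr),
                          wavelength = 0.1, lmax = l, nr = nr, rmax = R,
                          sampling = "bessel"), class = "blq_set")
    br <- sbt_bl(blq)
    r <- br$r
    direct <- as.numeric(vapply(r, function(rr)
      sum(coef * sbessel_j(l, u * rr / R)), 0))
    expect_lt(max(abs(br$matrices[[1]] - outer(direct, direct))),
              1e-6 * max(abs(outer(direct, direct))))
  }
})

test_that("a single-shell B_0 transforms to a real-space peak at r0", {
  nr <- 64; R <- 25; r0 <- 9
  u <- sbessel_zeros(1, nr)[[1]]
  qs <- u / (2 * pi * R)
  shell <- sbessel_j(0, 2 * pi * qs * r0)
  blq <- structure(list(l = 0, matrices = list(outer(shell, shell)),
                        q = list(qs), zeros = sbessel_zeros(1, nr),
                        wavelength = 0.1, lmax = 0, nr = nr, rmax = R,
                        sampling = "bessel"), class = "blq_set")
  br <- sbt_bl(blq)
  dg <- diag(br$matrices[[1]]) * br$r^2   # undo the radial density factor
  expect_lt(abs(br$r[which.max(dg)] - r0), R / nr + 1e-9)
})

test_that("resampling onto Bessel grids is exact on coincident grids", {
  # with nr = nq - 1 and rmax = nr / (2 qmax), the l = 0 Bessel grid is the
  # uniform correlation grid without its origin: bit-identical subset
  nq <- 17; qmax <- 1.28
  q <- seq(0, qmax, length.out = nq)
  nr <- nq - 1; rmax <- nr / (2 * qmax)
  set.seed(3)
  M <- matrix(rnorm(nq * nq), nq, nq); M <- M + t(M)
  blq <- structure(list(l = 0, matrices = list(M), q = q, wavelength = 0.1,
                        lmax = 0, sampling = "uniform"), class = "blq_set")
  rs <- resample_bl(blq, nr = nr, rmax = rmax)
  expect_identical(rs$matrices[[1]], M[2:nq, 2:nq])
  expect_equal(rs$q[[1]], q[2:nq], tolerance = 1e-12)

  # smooth analytic surface: interpolation error < 1e-3 relative
  qf <- seq(0, qmax, length.out = 129)
  G <- function(a, b) exp(-((a - 0.5)^2 + (b - 0.6)^2) / 0.08)
  blq2 <- structure(list(l = 6, matrices = list(outer(qf, qf, G)), q = qf,
                         wavelength = 0.1, lmax = 6, sampling = "uniform"),
                    class = "blq_set")
  rs2 <- resample_bl(blq2, nr = 80, rmax = 40)
  qt <- rs2$q[[1]]
  inside <- qt <= qmax
  direct <- outer(qt[inside], qt[inside], G)
  expect_lt(max(abs(rs2$matrices[[1]][inside, inside] - direct)), 1e-3)
  expect_true(all(rs2$matrices[[1]][!inside, ] == 0))
  expect_error(resample_bl(blq2, nr = 10, rmax = -1), "rmax")
})

test_that("assemble_padf forms the weighted Legendre sum with scaling", {
  nr <- 12
  r <- seq_len(nr) * 30 / nr
  mk_blr <- function(mats, l) structure(list(l = l, matrices = mats, r = r,
                                             rmax = 30, lmax = max(l)),
                                        class = "blr_set")
  # only B_0: theta-independent before the theta scaling
  M0 <- outer(seq_len(nr), seq_len(nr), function(a, b) 1 / (a + b))
  p0 <- assemble_padf(mk_blr(list(M0), 0), sintheta = FALSE,
                      radial_weight = FALSE)
  expect_lt(max(apply(p0$values, c(1, 2), sd)), 1e-12)
  expect_equal(p0$values[, , 1], M0 / 2)   # w_l = 1/2
  # exchange symmetry
  expect_equal(p0$values, aperm(p0$values, c(2, 1, 3)))
  # the sin-theta and radial scalings act as recorded
  p1 <- assemble_padf(mk_blr(list(M0), 0))
  k <- 61   # theta = 60 deg
  expect_equal(p1$values[, , k],
               M0 / 2 * outer(r^2, r^2) * sin(pi / 3), tolerance = 1e-12)
  expect_equal(p1$scaling$theta_weight, "sin")
  expect_equal(p1$scaling$unreliable_theta_deg, (360 / 0) / 2)
})

test_that("angular peaks resolve according to the l_max resolution limit", {
  # plant two angular deltas at 90 +/- s via the even addition theorem
  nr <- 4; lmax <- 32
  r <- seq_len(nr) * 10 / nr
  plant <- function(sep) {
    g1 <- (90 - sep / 2) * pi / 180; g2 <- (90 + sep / 2) * pi / 180
    l <- seq(0, lmax, 2)
    mats <- lapply(l, function(li) {
      P <- padfr:::legendre_matrix(c(cos(g1), cos(g2)), lmax)[, li + 1]
      matrix((2 * li + 1) * sum(P), nr, nr)
    })
    structure(list(l = l, matrices = mats, r = r, rmax = 10, lmax = lmax),
              class = "blr_set")
  }
  prof <- function(sep) {
    p <- assemble_padf(plant(sep), sintheta = FALSE, radial_weight = FALSE)
    p$values[1, 1, ]
  }
  npeaks <- function(v) {
    pk <- which(diff(sign(diff(v))) == -2) + 1
    sum(v[pk] > 0.5 * max(v))
  }
  res <- 360 / lmax                 # 11.25 degrees
  expect_equal(npeaks(prof(res / 2)), 1)   # closer than the limit: merged
  expect_equal(npeaks(prof(2 * res)), 2)   # twice the limit: resolved
})

test_that("truncation ripple decreases from l_max 16 to 32", {
  # truncate the extracted l <= 32 set to l <= 16 and reassemble
  blq <- hex_blq_std()
  sub16 <- blq
  keep <- blq$l <= 16
  sub16$l <- blq$l[keep]; sub16$matrices <- blq$matrices[keep]
  sub16$lmax <- 16L
  p16 <- assemble_padf(sbt_bl(resample_bl(sub16, nr = 102, rmax = 40)))
  p32 <- hex_padf_std()
  ripple <- function(p) {
    k15 <- which.min(abs(p$r - 15))
    prof <- p$values[k15, k15, ]
    prof <- prof / max(prof)
    off <- p$theta > 15 & abs(p$theta - 60) > 20 & abs(p$theta - 120) > 20 &
      p$theta < 165
    max(abs(prof[off]))
  }
  expect_lt(ripple(p32), ripple(p16))
})

test_that("the pipeline is linear in the squared intensity scale", {
  full <- hex_polar_std()
  sub <- list(polar = full$polar[1:48, , 1:40], q = full$q[1:48],
              theta = full$theta)
  scaled <- list(polar = sub$polar * 3, q = sub$q, theta = sub$theta)
  C1 <- apply_sintheta_weight(dataset_correlation(sub, "standard"))
  C2 <- apply_sintheta_weight(dataset_correlation(scaled, "standard"))
  expect_lt(max(abs(C2$values - 9 * C1$values)), 1e-9 * max(abs(C2$values)))
  p1 <- padf_from_correlation(C1, lmax = 12, wavelength = 0.1, rmax = 35)
  p2 <- padf_from_correlation(C2, lmax = 12, wavelength = 0.1, rmax = 35)
  expect_lt(max(abs(p2$values - 9 * p1$values)), 1e-9 * max(abs(p2$values)))
})
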