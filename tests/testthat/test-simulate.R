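test_that("the hexagon model has the enumerated pair-distance spectrum", {
  m <- make_hexagon(15)
  expect_equal(nrow(m$positions), 6)
  # centroid at the origin, circumradius equal to the side
  expect_equal(colMeans(m$positions), c(0, 0, 0))
  expect_equal(sqrt(rowSums(m$positions^2)), rep(15, 6))
  # ordered pair distances: 12 x 15, 12 x 15*sqrt(3), 6 x 30
  d <- as.matrix(dist(m$positions))
  dv <- sort(d[upper.tri(d)]) * 2        # ordered pairs = 2x unordered
  tab <- table(round(c(dv, dv) / 2, 6))  # count each unordered pair twice
  expect_equal(as.numeric(tab), c(12, 12, 6))
  expect_equal(as.numeric(names(tab)), c(15, round(15 * sqrt(3), 6), 30))
})

test_that("random rotations are uniform, proper and reproducible", {
  set.seed(5)
  R1 <- random_rotation()
  set.seed(5)
  expect_identical(random_rotation(), R1)
  set.seed(6)
  zs <- matrix(0, 1e4, 3)
  for (i in 1:1e4) zs[i, ] <- random_rotation()[, 3]
  # orthogonality and unit determinant for a sample
  set.seed(7)
  for (i in 1:20) {
    R <- random_rotation()
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
  # Monte-Carlo isotropy: mean rotated z-axis close to the origin
  expect_lt(sqrt(sum(colMeans(zs)^2)), 0.05)
})

test_that("kinematic patterns obey the structure-factor algebra", {
  g <- square_detector(npix = 64, q_edge = 1.28, wavelength = 0.1)
  # a single point atom at the origin scatters unit intensity everywhere
  one <- structure_model(matrix(0, 1, 3))
  expect_equal(simulate_pattern(one, g), matrix(1, 64, 64))
  # translating the whole model leaves |F|^2 unchanged
  m <- make_hexagon(15)
  set.seed(8)
  R <- random_rotation()
  I1 <- simulate_pattern(m, g, R)
  m2 <- structure_model(m$positions + rep(c(3.2, -1.1, 0.7), each = 6))
  I2 <- simulate_pattern(m2, g, R)
  expect_lt(max(abs(I1 - I2)) / max(I1), 1e-9)
  # intensities are non-negative
  expect_true(all(I1 >= 0))
})

test_that("a two-atom model fringes with period 1/d", {
  d <- 10
  g <- square_detector(npix = 256, q_edge = 1.28, wavelength = 0.1)
  m <- structure_model(rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0)))
  I <- simulate_pattern(m, g)
  row <- I[, 128]                      # central row along x
  qx <- ewald_qvector((1:256) - 0.5, 127.5, g)[, 1]
  pk <- which(diff(sign(diff(row))) == -2) + 1
  qpk <- sort(qx[pk])
  spacing <- median(diff(qpk))
  expect_equal(spacing, 1 / d, tolerance = 0.03)
})

test_that("pattern attenuation options behave physically", {
  g <- square_detector(npix = 64, q_edge = 1.28, wavelength = 0.1)
  one <- structure_model(matrix(0, 1, 3))
  # solid-angle factor: cos^3(theta), strongest attenuation at the corners
  Isa <- simulate_pattern(one, g, solid_angle = TRUE)
  ct_corner <- cos(pixel_q(sqrt(2) * 31.5 * g$pixel_size, g)$theta)
  expect_equal(Isa[1, 1], ct_corner^3, tolerance = 1e-6)
  expect_true(all(Isa <= 1))
  # Gaussian form factor attenuates high q
  soft <- structure_model(matrix(0, 1, 3), f0 = 1, b = 0.5)
  Isoft <- simulate_pattern(soft, g)
  expect_lt(Isoft[1, 1], Isoft[32, 32])
  # Poisson option is integer-valued with roughly the requested budget
  set.seed(10)
  Ip <- simulate_pattern(one, g, photons = 5000)
  expect_true(all(Ip == round(Ip)))
  expect_equal(sum(Ip), 5000, tolerance = 0.1)
  expect_error(simulate_pattern(one, g, photons = -1), "photon")
})

test_that("datasets are reproducible, isotropic on average, Friedel-symmetric", {
  # 128 px so the 30 nm fringes (period 1/30 per nm) are well sampled
  g <- square_detector(npix = 128, q_edge = 1.28, wavelength = 0.1)
  m <- make_hexagon(15)
  d1 <- simulate_dataset(m, g, n = 2, seed = 21)
  d2 <- simulate_dataset(m, g, n = 2, seed = 21)
  expect_identical(d1$patterns, d2$patterns)
  expect_identical(d1$rotations, d2$rotations)

  # ensemble-mean ring intensity becomes theta-independent as n grows
  ring_flatness <- function(n, seed) {
    ps <- simulate_polar_dataset(m, g, n = n, nq = 24, ntheta = 90,
                                 seed = seed)
    mean_ring <- apply(ps$polar, c(1, 2), mean)
    max(apply(mean_ring[5:20, ], 1, function(v) sd(v) / mean(v)))
  }
  f100 <- ring_flatness(100, 22)
  f400 <- ring_flatness(400, 22)
  expect_lt(f400, f100)
  # Monte-Carlo convergence at the 1/sqrt(n) rate (within 60%)
  expect_lt(f400, 2 * f100 / sqrt(4))

  # Friedel symmetry in the flat-Ewald regime: I(q,th) ~ I(q,th+pi). The
  # asymmetry scales as the Ewald tilt (q^2 lambda / 2) times the object
  # depth, so test a compact 5 nm object at low q and the growth with q.
  set.seed(23)
  mirr_dev <- function(p, k) {
    prof <- p$values[k, ]
    max(abs(prof - prof[c(91:180, 1:90)])) / max(prof)
  }
  duo <- structure_model(rbind(c(-2.5, 0, 0), c(2.5, 0, 0)))
  pd <- to_polar(simulate_pattern(duo, g, random_rotation()), g,
                 nq = 48, ntheta = 180)
  expect_lt(max(mirr_dev(pd, 2), mirr_dev(pd, 3)), 0.01)  # q <= 0.054
  ph <- to_polar(simulate_pattern(m, g, random_rotation()), g,
                 nq = 48, ntheta = 180)
  expect_gt(mirr_dev(ph, 24), mirr_dev(ph, 2))  # curvature bites at q=0.63
})

test_that("dataset files round trip with a manifest", {
  d <- withr::local_tempdir()
  g <- square_detector(npix = 16, q_edge = 1.28)
  ds <- simulate_dataset(make_hexagon(15), g, n = 3, seed = 2)
  paths <- write_dataset(ds, d, prefix = "patt", model = make_hexagon(15))
  expect_equal(basename(build_file_list(d, "patt_#.npy")), basename(paths))
  expect_equal(read_image(paths[2]), ds$patterns[[2]])
  expect_true(any(grepl("seed = 2", readLines(file.path(d, "manifest.txt")))))
})

test_that("the brute-force oracle reproduces the ideal hexagon geometry", {
  m <- make_hexagon(15)
  # bin edges offset so the exact distances/angles fall at bin centres
  redges <- seq(-0.5, 32.5, by = 1)
  tedges <- seq(-2.5, 182.5, by = 5)
  or <- model_padf_oracle(m, redges, tedges)
  # support on the r = r' diagonal only at the three pair distances
  diag_counts <- sapply(seq_along(or$r_mid), function(k) sum(or$counts[k, k, ]))
  hit <- which(diag_counts > 0)
  expect_setequal(or$r_mid[hit], c(15, 26, 30))
  # symmetry under pair exchange and angle reflection
  expect_equal(or$counts, aperm(or$counts, c(2, 1, 3)))
  expect_equal(or$counts, or$counts[, , rev(seq_along(or$theta_mid))])
  # ideal Table-1 ratios at the 120-degree peaks: 48 : 48 : 12
  k120 <- which(or$theta_mid == 120)
  iA <- which(or$r_mid == 15); iB <- which(or$r_mid == 26)
  iC <- which(or$r_mid == 30)
  A <- sum(or$counts[iA, iA, k120])
  B <- sum(or$counts[iB, iB, k120])
  Cc <- sum(or$counts[iC, iC, k120])
  expect_equal(c(A, B, Cc), c(48, 48, 12))
  expect_equal(B / A, 1)
  expect_equal(Cc / A, 0.25)
})

test_that("a two-atom model concentrates all angular weight at 0 and 180", {
  m <- structure_model(rbind(c(0, 0, 0), c(7, 0, 0)))
  or <- model_padf_oracle(m, seq(-0.25, 10.25, 0.5), seq(-2.5, 182.5, 5))
  nz <- which(or$counts > 0, arr.ind = TRUE)
  expect_true(all(or$theta_mid[nz[, 3]] %in% c(0, 180)))
  expect_true(all(or$r_mid[nz[, 1]] == 7))
})
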