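# Shared fixtures and independent oracles for the test suite.
# Expensive fixtures are built lazily once per session and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# O(n^2) circular cross-correlation, the oracle for the FFT path
brute_ring_corr <- function(a, b) {
  n <- length(a)
  vapply(seq_len(n) - 1, function(k)
    sum(a * b[((seq_len(n) - 1 + k) %% n) + 1]), numeric(1))
}

# random polar stacks for correlation algebra tests
rand_polar <- function(nq, nth, n, seed = 1) {
  set.seed(seed)
  array(stats::runif(nq * nth * n), c(nq, nth, n))
}

# hexagon simulation shared by several tests, at a scaled-down version of
# the reference experiment: 512 x 512 detector (so the 30 nm fringes are
# well sampled), edge q = 1.28 1/nm, 400 exposures, 256 q rings. Built once
# per session and reused.
hex_polar_std <- function() memo_fixture("hex_polar", function() {
  geom <- square_detector(npix = 512, q_edge = 1.28)
  simulate_polar_dataset(make_hexagon(15), geom, n = 400, nq = 256,
                         ntheta = 360, seed = 42)
})

hex_corr_std <- function() memo_fixture("hex_corr", function() {
  dataset_correlation(hex_polar_std(), mode = "standard")
})

# conditioned correlation and extracted B_l at l_max = 32
hex_blq_std <- function() memo_fixture("hex_blq", function() {
  extract_bl(apply_sintheta_weight(hex_corr_std()), lmax = 32,
             wavelength = 0.1)
})

hex_padf_std <- function() memo_fixture("hex_padf", function() {
  blr <- sbt_bl(resample_bl(hex_blq_std(), nr = 102, rmax = 40))
  assemble_padf(blr)
})

# synthesize a correlation volume from known even-l B_l through the
# Legendre form (the forward model the inversion must invert)
synth_correlation <- function(Bl, l, q, ntheta, wavelength) {
  nq <- length(q)
  th <- seq(0, 2 * pi, length.out = ntheta + 1)[seq_len(ntheta)]
  ct <- q * wavelength / 2
  st <- sqrt(1 - ct^2)
  vals <- array(0, c(nq, nq, ntheta))
  for (a in seq_len(nq)) for (b in seq_len(nq)) {
    cospsi <- ct[a] * ct[b] + st[a] * st[b] * cos(th)
    P <- padfr:::legendre_matrix(cospsi, max(l))[, l + 1, drop = FALSE]
    prof <- numeric(ntheta)
    for (i in seq_along(l)) prof <- prof + Bl[[i]][a, b] * P[, i]
    vals[a, b, ] <- prof
  }
  padfr:::new_correlation_volume(vals, q = q, theta = th, mode = "standard",
                                 n_patterns = 1L)
}
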