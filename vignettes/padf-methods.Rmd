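---
title: "Computing pair angle distribution functions from fluctuation scattering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing pair angle distribution functions from fluctuation scattering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Serial (fluctuation) diffraction experiments record many exposures of a
disordered sample or of particles in random orientations. Each exposure
carries angular intensity fluctuations that average away in conventional
powder analysis but retain three- and four-atom structural information. The
pair angle distribution function (PADF), `Theta(r, r', theta)`, organizes
that information in real space: it is the distribution of two atom-pair
distances `r` and `r'` together with the relative angle `theta` between the
two pair vectors. Bond angles and local packing motifs appear as peaks at
the corresponding `(r, r', theta)`.

`padfr` implements the standard chain from detector images to the PADF:

1. polar resampling of each exposure onto uniform `(q, theta)` grids,
2. the angular intensity cross-correlation `C(q, q', theta)`,
3. conditioning of the correlation volume,
4. inversion to even-order Legendre coefficient matrices `B_l(q, q')`,
5. two discrete spherical Bessel transforms to `B_l(r, r')`,
6. assembly and scaling of `Theta(r, r', theta)`.

Throughout, `q = 2 sin(theta_sc / 2) / lambda` in cycles per nm (the
electron-microscopy convention; multiply by `2*pi` for the crystallographic
one), wavelengths are in nm and detector distances in m.

## The correlation volume

For exposures `I_i(q, theta)` the package computes

    C(q, q', theta_k) = (1 / (N * n_theta)) *
        sum_i sum_j I_i(q, theta_j) I_i(q', theta_j + theta_k)

with circular indexing in `theta`, evaluated with the 1D FFT and the
convolution theorem ring pair by ring pair. The `1/n_theta` factor makes
`C` independent of the angular sampling rate; it cancels in every ratio the
package reports. Odd- and even-numbered exposures are optionally correlated
separately (the `a`/`b` volumes) as a convergence diagnostic.

Static backgrounds are estimated by correlating randomly paired distinct
exposures (`mode = "background"`, a seeded fixed-point-free pairing
`j(i)`). The estimator is accumulated symmetrically over `(i, j(i))` and
`(j(i), i)`; with that convention the single-pass difference correlation
(`mode = "difference"`, correlating `I_i - I_j(i)` with itself) satisfies

    C_DIFF = 2 * (C - C_BG)

exactly for any pairing, not only for involutive ones, and the background
volume inherits the exchange symmetry
`C(q, q', theta) = C(q', q, -theta)`.

Detector masks are handled by dividing the correlation by the correlation
of the binary mask wherever the latter is positive (relative tolerance
`1e-10`) and zeroing the rest; with an all-ones mask the mask correlation
is identically 1 under the normalization above, so the correction is the
identity.

## Conditioning

The inversion below relies on Legendre orthogonality, which is an integral
against `d cos(theta)`, while the correlation is sampled uniformly in
`theta`. `apply_sintheta_weight()` multiplies the volume by
`|sin theta|^e` (default exponent `e = 1`, the Jacobian) and records the
exponent; the inversion consumes the record, so the pipeline is consistent
for any recorded `e`. The other two conditioning steps are a hard (or
cosine-tapered) band-pass on both `q` axes and a mask that zeroes a band of
`theta` around 0 and its mirror around `2*pi`. The latter matters for noisy
data: uncorrelated detector noise adds a spike at `theta = 0`, `q = q'`
whose height is the per-ring noise variance (for Poisson data, the ring
mean), which the test suite verifies by simulation. All three operations
are elementwise and commute exactly.

## Inversion to B_l matrices

On the Ewald sphere the orientation-averaged correlation has the form

    C(q, q', theta) = sum_{even l <= l_max} B_l(q, q') P_l(cos psi),
    cos psi = cos(th_q) cos(th_q') + sin(th_q) sin(th_q') cos(theta),

where `cos(th_q) = q * lambda / 2` is the out-of-plane tilt of the
measured `q` vector (equal to the half scattering angle). Odd orders vanish
when absorption is neglected and are excluded; they also degrade the
conditioning of the fit.

`extract_bl()` solves this as a weighted least-squares problem per ring
pair. Two numerical choices matter:

* **Measure-weighted rows.** The fit minimizes the residual under the
  Legendre measure: both the design matrix and the data rows are weighted
  by `sqrt(|sin theta|)` (taking into account whatever `|sin theta|^e` the
  conditioning already applied). Rows at `theta = 0` and `pi` get weight
  zero.
* **Column equilibration before the SVD cutoff.** The Legendre columns have
  norms that fall roughly as `(2l+1)^(-1/2)`; applying a relative singular
  value cutoff to the raw matrix would silently delete the high orders.
  Columns are therefore scaled to unit norm first. After equilibration the
  singular spectrum of the design matrix is compact (ratio about 0.7 on
  the package's default grids) and the default relative cutoff of 0.5
  removes only directions the Ewald geometry makes genuinely degenerate,
  while leaving consistent synthetic systems exactly solvable — the test
  suite plants random even-order coefficients and recovers them to 1e-6.

If every singular value of a ring pair falls below the cutoff the
corresponding `B_l` row is set to zero with a warning. The design matrix
depends only on `(q, q', lambda)`, never on the data.

## Discrete spherical Bessel transforms

Each `B_l(q, q')` is carried to real space with the radial kernel
`j_l(2 pi q r)` applied along both axes. The discrete form samples order
`l` at `q_{l,n} = u_{l,n} / (2 pi R)`, where `u_{l,n}` is the n-th zero of
`j_l` and `R` is the maximum real-space distance, and evaluates

    f(r) = sum_n f~(q_{l,n}) j_l(u_{l,n} r / R) / (2 pi R^3 j_{l+1}(u_{l,n})^2).

This inverts the continuous transform exactly for functions supported on
`[0, R]` — the test suite checks the basis-reconstruction property to
1e-6. For `l = 0` the sampling points are uniform (`u_{0,n} = n pi`);
matrices for `l > 0` are interpolated from the uniform correlation grid
onto their own zero grids, with points beyond the measured `q` range set
to zero. Zeros are found by bracketed root search using the interlacing
property, starting from the analytic `l = 0` zeros, and cached.

All orders are evaluated on a common uniform output grid `r_k = k R / nr`.
With the default `nr = round(2 R q_max)` the radial step is
`1 / (2 q_max)` — 0.39 nm at the reference `q_max` of 1.28 per nm — half
the nominal `1/q_max` resolution of the data.

## Assembly and scaling

The PADF is assembled as
`Theta = sum_l w_l B_l(r, r') P_l(cos theta)` on a 1-degree grid over
`[0, 180]`. The default weight is the constant `w_l = 1/2`: the extracted
`B_l` already contain the `(2l+1)` factor of the spherical-harmonic
addition theorem, so the constant weight completes the delta-kernel
identity `sum_l ((2l+1)/2) P_l(x) P_l(x0) = delta(x - x0)` and the
assembled function is the pair-angle density in `cos theta`. A
`(2l+1)/(4 pi)` weighting is available (`lweight = "plancherel"`) for
comparison; note it sharpens but also distorts relative angular peak
heights, because it effectively squares the `(2l+1)` factor.

Two final scalings (both recorded in the volume's scaling record and both
on by default) put peak heights on the footing of the enumeration oracle:

* multiplication by `|sin theta|` converts the density in `cos theta` to a
  density in `theta`; the truncated Legendre kernel has a diagonal that
  grows like `1 / sin theta` (Christoffel–Darboux), so this also equalizes
  peak heights across angles;
* multiplication by `r^2 r'^2` undoes the radial density factors
  introduced by the spherical transforms.

After both, the height of a well-resolved peak is proportional to the
number of ordered pair–pair combinations at that `(r, r', theta)`,
weighted by the four scattering amplitudes — exactly what
`model_padf_oracle()` counts. The absolute-units option divides by
`8 pi^3 rho0^2 N_I^2` (mean density, incident quanta); it is recorded but
not validated against a physical standard and should be treated as
experimental.

Because `|sin theta|` vanishes at `theta = 0`, values within about
`(360 / l_max) / 2` degrees of zero (about 6 degrees at `l_max = 32`) are
systematically suppressed and are flagged unreliable in the scaling
record rather than repaired; no numerically reliable modification of the
factor is known to us.

## Interpolation

Both the polar resampling and the Bessel-grid resampling default to
separable cubic (Catmull–Rom) interpolation with a bilinear option. The
choice is load-bearing: `B_l(q, q')` oscillates like `j_l(2 pi q r0)` with
period `1/r0` in `q`, about 3–4 samples per period at the largest pair
distances on the default grids. Linear interpolation attenuates such
oscillations by tens of percent (squared, since both axes are
interpolated), which directly biases the recovered peak-height ratios at
large `r`; the cubic kernel keeps the attenuation at the few-percent
level. The same argument sets the detector size needed by the simulator:
on a 256-pixel grid the 30 nm fringes of the reference model are sampled
about 3 times per period, on 512 pixels about 6 times.

## The synthetic generator and what passing tests mean

The built-in simulator produces kinematic (single-scattering), elastic,
absorption-free diffraction of a rigid atom list: per exposure
`I = |sum_j f_j(q) exp(2 pi i q . (R r_j))|^2` on the Ewald sphere, with
`R` drawn uniformly from SO(3) (unit-quaternion method, reproducible under
a seed) and `f(q) = f0 exp(-b q^2)` (point scatterers by default). Options
add the flat-detector `cos^3` solid-angle factor and Poisson sampling at a
chosen photon budget; the reference configuration uses neither, matching
an idealized noise-free experiment.

The generator's default test case is six unit point scatterers on a
regular hexagon of side 15 nm, imaged at an edge `q` of 1.28 per nm — a
geometry whose ideal PADF is known exactly by enumeration: diagonal peaks
at 15, 15*sqrt(3) and 30 nm, angular peaks at 60 and 120 degrees, and
120-degree peak multiplicities 48 : 48 : 12, i.e. height ratios 1 and
0.25. The acceptance machinery simulates the experiment end to end and
compares the reconstructed ratios against the enumeration oracle; the test
suite uses 400 exposures and the acceptance script 1000, both on a
512-pixel detector (the smaller 256-pixel grid samples the 30 nm fringes
only ~3 times per period, which measurably biases the weakest peak).

What the generator does **not** emulate: dynamic (multiple) scattering of
electrons, absorption, incoherent or frame-to-frame-varying backgrounds,
polarization and solid-angle corrections of real detectors (measured data
are assumed pre-corrected), detector point-spread, and preferred
orientation. Passing tests therefore demonstrate the correctness of the
transform chain under the kinematic model, not robustness to those
effects; for electron data in particular, quantitative peak heights should
be interpreted cautiously.

## Defaults and degenerate inputs

| parameter | default | meaning |
|---|---|---|
| `ntheta` | 360 | 1-degree angular bins on `[0, 2 pi)` |
| `nq` | half the image width | uniform `q` rings from 0 to the edge `q` |
| `l_max` | 32 | angular resolution `360 / l_max` = 11.25 degrees |
| `regularization` | 0.5 | relative SVD cutoff of the Legendre fit |
| `nr` | `round(2 R q_max)` | radial step `1 / (2 q_max)` |
| `dtheta` (output) | 1 degree | PADF angular grid on `[0, 180]` |
| sin-theta exponent | 1 | recorded; the fit adapts to any value |

Degenerate cases are handled explicitly: the `q = 0` ring participates in
the fit but carries no angular information (its profile is constant);
rows with `sin theta = 0` drop out of the weighted fit; Bessel-grid points
beyond the measured range are zero; coincident source/target grids in the
resampler are returned bit-identically; the background pairing is a seeded
random derangement with the same pairing reused across `C_BG` and
`C_DIFF` so the factor-2 identity is exact.

## Known limitations

* Peak heights within ~6 degrees of `theta = 0` (at `l_max = 32`) are not
  quantitative; positions there should also be distrusted.
* The absolute-scale option is dimensional bookkeeping only.
* Finite `l_max` and `q_max` produce truncation ripple analogous to
  Fourier artifacts; it decreases with increasing `l_max` (asserted in the
  tests) but never vanishes.
* Convergence with the number of exposures is problem-dependent; the
  odd/even `a`/`b` split is the built-in diagnostic, and it is only
  meaningful when successive exposures probe statistically independent
  sample volumes.
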