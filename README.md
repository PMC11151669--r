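# padfr

Pair angle distribution functions (PADF) from fluctuation scattering data,
in R.

## What problem this solves

Serial diffraction experiments — X-ray or electron, synchrotron, XFEL or
electron microscope — record hundreds to thousands of exposures of a
disordered sample or of particles in uniformly random orientations. Each
exposure is a kinematic diffraction pattern of one local configuration.
Angular intensity fluctuations across that ensemble carry three- and
four-atom structural information that survives orientation averaging, and
the PADF technique turns it into an interpretable real-space function
`Θ(r, r′, θ)`: the distribution of two atom-pair distances and the relative
angle between the two pair vectors. Bond angles and local packing motifs of
a disordered material show up as peaks at the corresponding `(r, r′, θ)`,
without requiring crystals or resolved orientations.

`padfr` is aimed at practitioners of fluctuation scattering / X-ray
cross-correlation analysis who want the full processing chain from detector
images to the PADF, plus a forward simulator so the chain can be validated
end to end without experimental data.

## The method in brief

With `q = 2 sin(θ_sc/2)/λ` (cycles/nm; multiply by 2π for the
crystallographic convention), the pipeline is:

1. **Polar map.** Each exposure is interpolated onto uniform `(q, θ)` grids,
   `I(q, θ)`.
2. **Angular cross-correlation.**
   `C(q, q′, θ) = (1/(N nθ)) Σᵢ Σⱼ Iᵢ(q, θⱼ) Iᵢ(q′, θⱼ + θ)`,
   computed ring pair by ring pair with the FFT. Background and difference
   estimators (`C_BG`, `C_DIFF = 2(C − C_BG)`) handle static signals;
   binary detector masks are corrected by dividing by the mask's own
   correlation.
3. **Conditioning.** A `|sin θ|` weight (Legendre sampling measure), an
   optional q band-pass, and an optional mask of the noise-variance band at
   `θ ≈ 0`.
4. **Inversion.** On the Ewald sphere
   `C(q, q′, θ) = Σ_{even l} B_l(q, q′) P_l(cos ψ)` with
   `cos ψ = cos θ_q cos θ_q′ + sin θ_q sin θ_q′ cos θ`,
   `cos θ_q = qλ/2`. Each ring pair is solved by measure-weighted least
   squares with a relative SVD cutoff (default 0.5) after column
   equilibration; only even orders are used.
5. **Radial transforms.** Two discrete spherical Bessel transforms on the
   zeros of `j_l` carry `B_l(q, q′)` to `B_l(r, r′)`.
6. **Assembly.** `Θ(r, r′, θ) = Σ_l w_l B_l(r, r′) P_l(cos θ)` on a 1°
   grid, scaled by `r² r′² |sin θ|` so that peak heights are proportional
   to pair–pair multiplicities. Values within `±(360/l_max)/2` of θ = 0 are
   flagged unreliable.

The methods vignette (`vignettes/padf-methods.Rmd`) derives and motivates
every numerical choice.

## Worked example

Six point scatterers on a regular hexagon of side 15 nm, 400 exposures in
uniformly random 3D orientations on a 512×512 detector with edge
q = 1.28 nm⁻¹ (runs in about 3 minutes):

```r
library(padfr)

geom <- square_detector(npix = 512, q_edge = 1.28, wavelength = 0.1)
ps   <- simulate_polar_dataset(make_hexagon(15), geom, n = 400,
                               nq = 256, ntheta = 360, seed = 42)

C    <- dataset_correlation(ps, mode = "standard")
padf <- padf_from_correlation(apply_sintheta_weight(C), lmax = 32,
                              wavelength = 0.1, rmax = 40)

sm   <- gaussian_smooth(padf, 0.75, 1)   # radial 0.75 nm, angular 1 deg
wins <- list(A = list(r = c(12, 18),     rp = c(12, 18),     theta = c(100, 140)),
             B = list(r = c(23.5, 28),   rp = c(23.5, 28),   theta = c(100, 140)),
             C = list(r = c(28.5, 32.5), rp = c(28.5, 32.5), theta = c(100, 140)))
pt <- peak_table(sm, wins)
pt
attr(pt, "ratios")
```

Output (this run):

```
  label        r       rp theta    height
1     A 14.90196 14.90196   121 0.9295055
2     B 25.88235 25.88235   121 0.9040328
3     C 30.19608 30.19608   121 0.2150912
      A     B     C
A 1.000 1.028 4.321
B 0.973 1.000 4.203
C 0.231 0.238 1.000
```

Reading it: the three principal diagonal peaks sit at 14.9, 25.9 and
30.2 nm — within one 0.39 nm grid step of the exact pair distances 15,
15√3 ≈ 25.98 and 30 nm — at the 120° angular peak of the hexagonal
geometry. The height ratios B/A = 0.97 and C/A = 0.23 approach the exact
multiplicity ratios 1 and 0.25 that `model_padf_oracle()` computes by
direct enumeration (48 : 48 : 12 ordered pair–pair combinations at 120°).

Each stage is also exposed as a command-line tool over config files
(`inst/scripts/diffract.R`, `difftocorr.R`, `maskcorr.R`, `corrtopadf.R`,
`plotfxs3d.R`; `--help` lists each stage's flags, command-line values
override the config file).

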