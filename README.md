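# rotorscan

Quantify how much of a fluorescent dye is physisorbed at a glass/solution
interface from confocal z-scans.

## The problem

Molecular rotors — dyes such as 4-daspi whose quantum yield and lifetime
grow with local viscosity because intramolecular twisting is their main
non-radiative decay channel — are widely used to probe microviscosity near
surfaces, where microscopy is usually done right against a coverslip.  A
dye molecule adsorbed to the glass is rigidified, so it is both much
brighter and much longer-lived than the free dye.  Even sub-percent
monolayer coverage can therefore distort measurements: in a 200 µm tube at
1 µM and 1 % coverage, the adsorbed molecules already amount to ~30 % of
the bulk population (`tube_partition_ratio()`).

Measuring the adsorbed surface density σ with a confocal z-scan is
confounded by the instrument itself: optical sectioning of a bulk
(3-D) emitter is weak, and refractive-index mismatch between the dry
objective's design conditions and the sample aberrates the focus more the
deeper it goes, so the interface appears to influence the signal tens of
micrometres into the liquid.

## The model

`rotorscan` separates surface from bulk with a two-term signal model.  With
`H(z_F)` the normalised signal rise of a homogeneous (non-adsorbing)
reference scan and `I_N(z_F)` the normalised sample scan, the ratio

    U(z_F) = I_N(z_F) / H(z_F)  →  U_∞ = 1 / (1 + φ(0,0) K)

isolates the surface term.  `K = σ ε_S Φ_S / (ρ ε_B Φ_B)` (units of length)
is the surface-to-bulk brightness ratio, and `φ(0,0)` — the probability
density per µm of depth that a detected photon originates at the surface
when focused on the surface — is the single model quantity not accessible
to experiment.  The package computes it by Monte Carlo geometric-optics ray
tracing through the coverslip into the index-mismatched half-space
(`trace_depth_response()`, `phi00()`), and inverts the model for K and then
σ, using per-depth estimates with propagated uncertainties
(`fit_adsorption()`).  TCSPC utilities (`fit_biexponential()`,
`amplitude_avg_lifetime()`, `fit_forster_hoffman()`) cover the lifetime
side: distinguishing adsorbed from free dye and calibrating rotor
photophysics against viscosity.  A synthetic-data generator
(`simulate_zscan()`, `simulate_decay()`, `generate_study()`) produces
complete experiments with known ground truth.

## Worked example

Ray-trace the depth response of a 20× dry objective (NA 0.75, 56.6 µm
pinhole, 170 µm coverslip) over an aqueous sample, simulate a 70 wt%
glycerol experiment with a known adsorbed density, and recover it:

```r
library(rotorscan)

cfg <- microscope_config()     # defaults: the instrument above
dr  <- trace_depth_response(cfg, z_f_grid = c(0, 1, 2, 3, 5, 7, 10, 15, 20, 30),
                            n_rays = 2e5, seed = 1)
dr
#> Confocal depth response (Monte Carlo ray tracing)
#>   10 focus positions (0-30 um), 299 axial slices to 153 um
#>   n_rays = 2e+05 per focus, n_det = 256, seed = 1
#>   phi(0,0) = 0.2688 um^-1

p     <- study_photophysics(70)                     # bulk/surface yields & lifetimes
truth <- ground_truth(800, photophysics = p, wt_glycerol = 70,
                      noise_cv = 0.01, seed = 2)    # sigma_true = 800 um^-2
scan  <- simulate_zscan(dr, truth)                  # 1% multiplicative noise

fit <- fit_adsorption(scan, depth_response = dr, photophysics = p,
                      rho_molar = 1e-7)
fit
#> Surface adsorption fit (z-scan surface+bulk model)
#>   K       = 411.2 +/- 7.3 um (surface/bulk brightness ratio)
#>   U_inf   = 0.008967   (phi(0,0) = 0.269 um^-1, H: ray-traced)
#>   sigma   = 780.8 +/- 14 um^-2 (0.0781% of a monolayer at 1 nm^2)
```

Reading the output: the adsorbed sheet is ~400× brighter per unit length
than the bulk term (K, in µm), the scan would flatten at U_∞ ≈ 0.9 % of the
homogeneous reference at depth, and the recovered surface density
(781 ± 14 µm⁻², i.e. 0.078 % of a monolayer at 1 nm² per molecule) matches
the injected 800 µm⁻² within its uncertainty.  `summary(fit)` lists the
per-depth K estimates; `plot(fit)` shows U(z_F) against the fitted
asymptote.

Fitting a TCSPC decay histogram:

```r
h <- simulate_decay(list(c(0.8, 0.3), c(0.2, 1.7)), n_photons = 1e6, seed = 3)
fit_biexponential(h)
#> Biexponential decay fit (tail, Poisson MLE)
#>   tau1 = 0.3005 ns (A1 = 1.374e+06), tau2 = 1.699 ns (A2 = 3.453e+05)
#>   <tau> = 0.5814 ns (amplitude-averaged), background = 0.001/ns
#>   deviance/dof = 0.9 over window [0.146, 25] ns
```

A thin command-line wrapper with `raytrace`, `analyze`, `simulate` and
`fit-decay` subcommands lives in `inst/cli/rotorscan.R`; CSV/JSON formats
and the analysis configuration are documented in `?read_zscan` and
`?run_analysis`.

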