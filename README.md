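# oceanhsrl

Simulation and inversion of triple-field-of-view (FOV) high-spectral-resolution
oceanic lidar (HSRL) measurements, for ocean-optics researchers who want to
study — without an instrument or a cruise — how much information about seawater
constituents a multi-FOV molecular-channel lidar actually carries.

An oceanic HSRL separates the particulate return from the molecular
(Brillouin) return with an iodine filter. The molecular return is an
absolutely calibrated probe of the water column: multiple forward scattering
by particles widens the angular spread of the light, so receivers with nested
fields of view see different effective attenuations, between the beam
attenuation `c = a + b` (narrow FOV) and the diffuse regime near `a + b_b`
(wide FOV). From molecular signals at three FOVs (40/80/200 mrad) the package
retrieves, per depth bin, the absorption coefficient `a(z)`, the scattering
coefficient `b(z)`, and the slope `ξ(z)` of the power-law (Junge) particle
size distribution, by iteratively minimizing

    min || (B_M − B_S) / B_M ||₂ ,   B_S = F(C0, a(·), b(·), ξ(·), FOV_n)

with Gauss–Newton steps `X ← X (1 + ΔX/X)`, `ΔX/X = S⁻¹ ΔB/B`, where `S` is
the relative triple-FOV sensitivity matrix and the root-mean-square relative
difference `RMSRD = 100 √(mean((x/x̃ − 1)²))` is both the mismatch and the
accuracy metric. Particle optics close under the Fournier–Forand phase
function with `m = 1.01 + 0.1542(ξ − 3)`, including an exact closed-form
cumulative used for normalization, backscatter fraction `BF(ξ)`, sampling,
and the analytic forward model.

The package provides:

* `simulate_mc()` — a semianalytic Monte Carlo reference simulator (Rcpp):
  photon tracing with a local receiver estimator, exact aperture-cone
  integration of the singular forward peak, and first-turnaround splitting
  with importance-sampled branch directions, so molecular-channel returns are
  computed with sub-percent noise at desk-scale photon budgets;
* `forward_analytic()` — a fast quasi-single-scattering surrogate with a
  closed-form FOV-retention kernel, calibrated once against the Monte Carlo;
* `iterate_retrieval()` — the damped, weighted, regularized inversion, plus
  `initialize_state()`, `compute_sensitivity()`, `rmsrd()`;
* products: `estimate_kd()`, `estimate_bbp()`, `lidar_ratio()`,
  `single_scattering_albedo()`, `bbp_wavelength_convert()`;
* `scenario_spec()` / `make_profile()` / `make_ensemble()` — synthetic
  nearshore-to-offshore waters (presets L1–L5) and Latin-hypercube ensembles;
* CSV/JSON I/O and a command-line pipeline (`inst/cli/oceanhsrl.R`:
  `simulate`, `retrieve`, `evaluate`, `fixtures`).

## Worked example

Simulate an offshore-transition water (preset L3: a = 0.078 m⁻¹,
b = 0.40 m⁻¹, ξ = 3.35) at 10⁶ photons, retrieve, and derive products:

```r
library(oceanhsrl)
config <- lidar_config()
fx  <- make_fixture(scenario_spec("L3", depth_max = 10), config,
                    n_photons = 1e6, seed = 7)
res <- iterate_retrieval(fx$signals, config)
res
#> Triple-FOV retrieval: 4 iterations, pooled signal RMSRD 7.61% (converged)
head(as.data.frame(res$iop), 3)
#>  depth          a         b       xi
#>    0.5 0.07892700 0.3016982 3.415835
#>    1.5 0.07912739 0.3020655 3.422768
#>    2.5 0.07939396 0.3025043 3.431097
rmsrd_profiles(res$iop, fx$truth)
#> $a 3.3%   $b 24.1%   $xi 3.10%
head(derive_products(fx$signals, config, retrieved = res$iop), 3)
#>  depth     kd    bbp beta_p_180 lidar_ratio omega0
#>    0.5 0.0912 0.0018      3e-04       187.4 0.8902
#>    1.5 0.0965 0.0018      3e-04       207.7 0.8898
#>    2.5 0.1048 0.0017      2e-04       251.1 0.8893
```

Absorption comes back within a few percent. Scattering and PSD slope sit on a
weakly constrained ridge (a smaller `b` with a larger `ξ` changes the signals
by well under a percent), so their errors are larger and grow in turbid
low-`ξ` waters; the methods vignette
(`vignettes/triple-fov-hsrl-methods.Rmd`) derives the corresponding
information bounds. The diffuse attenuation (~0.09–0.12 m⁻¹) lies between
`a` and `c` as it must, and the estimated particulate backscattering matches
`BF(ξ)·b_p` of the generating water.

The same pipeline from a shell:

```sh
Rscript inst/cli/oceanhsrl.R simulate --scenario L3 --photons 1e6 --seed 7 --out l3.csv
Rscript inst/cli/oceanhsrl.R retrieve --signals l3.csv --out l3_ret.csv
Rscript inst/cli/oceanhsrl.R evaluate --retrieved l3_ret.csv --truth l3_truth.csv
```

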