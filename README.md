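# memprobe

Analysis toolkit for MD-style trajectories of fluorescent fatty-acid
probes — such as *cis*/*trans*-parinaric acid — in fluid (POPC-like) and gel
(DPPC-like) phospholipid bilayers, together with the free-energy
post-processing used to estimate their membrane partitioning.

It is written for membrane biophysicists who have (or want to emulate)
probe-in-bilayer simulations and need the standard derived quantities as a
tested, reproducible pipeline rather than a pile of one-off scripts.

## What it computes

**Structure.** Area per lipid `a = A_box / n_lipids`; bilayer thickness
`d_PP` from the mean phosphate planes; deuterium order parameters
`S_CD = ⟨3 cos²θ_CH − 1⟩ / 2`; chain tilt distributions (terminal→first
carbon axis vs the outward leaflet normal, folded to [0°, 90°]); transverse
group positions `⟨|z − z_COM|⟩` with per-molecule 95% CIs; mass density
profiles in kg/m³.

**Probe-conditioned order.** Host-lipid tilt distributions binned by the
distance R of each lipid's centre of mass to the nearest same-leaflet probe
(near R < 0.7 nm / mid / far R > 1.2 nm), and the SD-increase statistic
`100·(√(σ²_near/σ²_far) − 1)`.

**Packing.** Atom–atom radial distribution functions g(r) with standard
shell-volume × selection-density normalization, plus cumulative
coordination numbers N(r).

**Rotational dynamics.** The rank-2 orientational ACF
`C(t) = ⟨P₂(û(ξ)·û(t+ξ))⟩` (all time origins, FFT-based), fitted with the
hindered-rotation model

    C(t) = a₁ e^(−t/Φ₁) + a₂ e^(−t/Φ₂) + a₃ e^(−t/Φ₃) + a∞

by bounded, deterministically multistarted least squares; limiting
anisotropy `r∞ = r₀·a∞` (fundamental anisotropy r₀ = 2/5) and mean
correlation time `⟨Φ⟩ = Σ aᵢΦᵢ`.

**Lateral dynamics.** In-plane MSD with per-frame leaflet-COM removal and
`D_lat = ¼ d MSD/dt` in cm²/s.

**Energetics.** 1-D WHAM on umbrella windows (bin-averaged Gaussian bias
factors, water-plateau referencing), split-half convergence diagnostics,
insertion/desorption/translocation barriers on the centre→water branch,
and `K_p = exp(−ΔG(w→l)/RT)` with `ΔG(w→l) = −(ΔG_desorb − ΔG_insert)`.

**Synthetic data.** Generators with exact ground truth — a
wobbling-in-cone Brownian rotor (plateau S², S = cosθ_c(1+cosθ_c)/2), 2-D
lateral walks with common leaflet drift, a lattice bilayer with
proximity-dependent tilt disorder and probes at a stated carboxylate
depth, umbrella windows drawn exactly from analytic PMFs, and
multiexponential ACF curves — so the whole pipeline is testable without an
MD engine.

## Worked example

```r
library(memprobe)

# a gel-like synthetic bilayer: 62 lipids + 2 probes per leaflet,
# d_PP = 4 nm, probe carboxylate at 1.9 nm, near/far tilt SDs 9.2/5.8 deg
spec <- synthetic_bilayer_spec(n_lipids_per_leaflet = 62, d_PP_true = 4.0,
                               tilt_sd_near = 9.2, tilt_sd_far = 5.8,
                               n_probes_per_leaflet = 2, probe_depth = 1.9)
tr <- gen_bilayer_config(spec, n_frames = 100, seed = 1)

compute_thickness_dPP(tr)
#> d_PP: 4 +/- 0 nm (mean over 100 frames)

px <- compute_proximity_binned_tilts(tr)
px$near; px$far
#> tilt distribution [near]: n = 914, mean = 30.2 deg, var = 78.8 deg^2
#> tilt distribution [far]: n = 8701, mean = 30.2 deg, var = 33.8 deg^2
sd_increase_percent(px$far$variance, px$near$variance)
#> [1] 53        # lipids touching a probe have a 53% wider tilt SD

# hindered-rotation analysis: refit a noise-free curve synthesized from a
# published gel-phase parameter set, then read off the limiting anisotropy
fit <- fit_acf(gen_acf_curve(pna_acf_reference()$tPnA_DPPC,
                             seq(0, 1000, by = 0.1)))
fit
#> ACF fit: 3 exponential term(s) + residual
#>   a1 = 0.02002, Phi1 = 0.1594 ns
#>   a2 = 0.01, Phi2 = 22 ns
#>   a3 = 0.01, Phi3 = 850.2 ns
#>   a_inf = 0.92  (SSR 1.84e-09)
anisotropy_estimate(fit)$r_inf_reported
#> [1] 0.37      # an almost rotationally frozen fluorophore

# umbrella sampling -> WHAM -> barriers -> partition coefficient
pmf  <- analytic_pmf("amphiphile", z_range = c(-4, 4))  # min -25 kJ/mol
wins <- gen_umbrella_samples(pmf, seq(0, 4, by = 0.1), k = 3000,
                             n_samples = 5000, seed = 1)
prof <- wham(wins, reference = "plateau", water_region = c(3, 4))
bars <- extract_barriers(prof, water_region = c(3, 4))
bars
#> barriers (kJ/mol): insertion 0.301, desorption 25.9, translocation 35
#>   (minimum at z = 1.61 nm)
partition_coefficient(bars)
#> dG(w->l) = -25.6 kJ/mol, Kp = 3.02e+04 at T = 298.15 K
```

The interfacial minimum of −25 kJ/mol translates into a water→membrane
partition coefficient of a few 10⁴ — the magnitude characteristic of
long-chain fatty-acid probes partitioning into bilayers — and the residual
ACF amplitude 0.92 maps to a limiting anisotropy of 0.37, close to the
theoretical maximum 0.4, i.e. rotation that is almost fully arrested in
the gel phase.

## Command line

```sh
Rscript inst/scripts/memprobe simulate  --config cfg.json   # synthetic bilayer
Rscript inst/scripts/memprobe structure --config cfg.json   # structural battery
Rscript inst/scripts/memprobe pmf       --config cfg.json   # WHAM + barriers + Kp
Rscript inst/scripts/memprobe report    --config cfg.json   # everything configured
```

Outputs are tidy CSVs plus a JSON summary and a provenance manifest
(config hash, package version, seed); identical configs and seeds
reproduce byte-identical outputs.
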