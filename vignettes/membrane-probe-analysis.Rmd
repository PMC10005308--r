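---
title: "Analysing membrane-probe trajectories with memprobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing membrane-probe trajectories with memprobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memprobe)
```

## What this package computes

Intrinsically fluorescent fatty acids such as the parinaric acids are used
to report on lipid-membrane order and dynamics: their fluorescence
anisotropy decay tracks the hindered rotation of the conjugated polyene
axis, their quantum yield and lifetime respond to the phase state of the
host bilayer, and their partitioning between water and membranes of
different phases (fluid POPC-like versus gel DPPC-like) is itself a usable
observable. Molecular-dynamics studies of such probes produce a standard
battery of derived quantities, and `memprobe` implements that battery as a
tested pipeline:

* **Structure** — area per lipid, phosphate-plane bilayer thickness
  $d_{PP}$, deuterium order parameters $S_{CD}$, chain tilt distributions,
  transverse group positions, mass density profiles.
* **Probe-conditioned order** — tilt distributions of host-lipid chains
  conditioned on the distance $R$ between each lipid's centre of mass and
  the nearest probe in the same leaflet (near $R <$ 0.7 nm / mid / far
  $R >$ 1.2 nm), and the derived SD-increase statistic
  $100\,(\sqrt{\sigma^2_{near}/\sigma^2_{far}} - 1)$.
* **Packing** — atom–atom radial distribution functions $g(r)$ and
  cumulative coordination numbers $N(r)$.
* **Rotational dynamics** — the rank-2 orientational autocorrelation
  $C(t) = \langle P_2(\hat u(\xi)\cdot\hat u(\xi + t))\rangle$, fitted with
  $C(t) = \sum_{i\le3} a_i e^{-t/\Phi_i} + a_\infty$; the limiting
  anisotropy $r_\infty = r_0 a_\infty$ with fundamental anisotropy
  $r_0 = 2/5$; and the mean correlation time
  $\langle\Phi\rangle = \sum_i a_i \Phi_i$.
* **Lateral dynamics** — in-plane MSD with per-frame leaflet
  centre-of-mass removal and $D_{lat} = \tfrac14 \lim_{t\to\infty}
  \mathrm{d\,MSD}/\mathrm{d}t$, converted to cm²/s.
* **Energetics** — 1-D WHAM reconstruction of umbrella-sampling PMFs,
  convergence splitting, insertion/desorption/translocation barrier
  decomposition on the centre-to-water branch, and the partition
  coefficient $K_p = \exp(-\Delta G(w\to l)/RT)$ with
  $\Delta G(w\to l) = -( \Delta G_{desorb} - \Delta G_{insert})$, so that
  favourable partitioning gives $K_p > 1$.

Because MD trajectories of this kind are rarely deposited, the package
ships synthetic-data generators with exactly known ground truth; every
analysis stage is validated against them.

## The synthetic world, and what it does not emulate

`gen_bilayer_config()` builds a square-lattice bilayer, symmetric about
$z = 0$: head beads at $z = \pm d_{PP}/2$, straight segmented chains
descending toward the midplane at per-frame random tilts, and probe
molecules whose carboxylate bead sits at a stated depth (default 1.9 nm,
an interfacial anchoring typical of fatty-acid probes). Chain tilts are
drawn from $\mathcal N(\mu_{tilt}, \sigma)$ folded to $[0°, 90°]$, with
$\sigma$ depending on the lipid's proximity bin (defaults 9.2° / 8.0° /
5.8° near/mid/far — the gel-phase magnitudes of the probe-perturbation
effect this analysis is designed to resolve; $\mu_{tilt} = 30°$, a
gel-like mean). Folding at small $\mu_{tilt}$ rescales all bin variances
by the same factor, so near/far variance *ratios* are preserved
regardless of the mean. In-plane positions are fixed, which keeps the bin
assignment stable and the fixture deterministic.

The generator makes no attempt at force-field realism: there are no
interactions, no area fluctuations, no undulations, and tilts are
uncorrelated frame to frame. A green test therefore establishes that the
*analysis* recovers what the *generator* put in — not that any physical
model is correct.

`gen_hindered_rotor()` implements wobbling-in-cone rotational Brownian
dynamics: tangent-plane Gaussian steps of per-axis variance $2 D_w \Delta t$
followed by renormalisation, with the time step internally subdivided so
the RMS angular step stays below 3° (the standard accuracy regime for
spherical BD). The cone constraint reflects the polar angle at the cone
edge ($\theta \to 2\theta_c - \theta$), a mirror step that preserves the
uniform equilibrium density inside the cone. Two closed forms anchor the
tests: the free rotor ($\theta_c = 180°$) has $C(t) = e^{-6 D_w t}$, and
the confined rotor plateaus at $S^2$ with
$S = \cos\theta_c (1 + \cos\theta_c)/2$.

`gen_lateral_walk()` produces independent 2-D Gaussian walks (per-axis
increment variance $2 D \Delta t$) plus an optional common drift applied
identically to all molecules, emulating leaflet centre-of-mass motion.
Removing the per-frame COM of $n$ molecules cancels the drift exactly but
also shrinks the single-molecule MSD by the factor $(1 - 1/n)$; we do not
rescale (reference MD tools do not either), which with the 64-molecule
test fixture contributes ~1.6% of the 2% agreement budget.

`gen_umbrella_samples()` draws *independent* samples from the exact
biased density $\propto e^{-[G(z) + k(z - z_0)^2/2]/RT}$ by inverse-CDF
inversion on a 10⁻³ nm grid — no MCMC, hence no autocorrelation. The CDF
is accumulated with a midpoint rule; a plain cumulative sum is the CDF
half a grid step late, and that 5×10⁻⁴ nm shift, multiplied by
$k = 3000$ kJ mol⁻¹ nm⁻², tilts a reconstructed PMF by ~1.5 kJ mol⁻¹ nm⁻¹.
The flat-landscape oracle caught this, which is exactly what it is for.

## Numerical choices

**ACF evaluation.** $C(t)$ is computed over *all* time origins via the
tensor identity $P_2(\hat u_1\cdot\hat u_2) = \tfrac32 \sum_{ij} q_{ij}(1)
q_{ij}(2) - \tfrac12$ with $q_{ij} = u_i u_j$, reducing the calculation to
six FFT autocorrelations per molecule. Lags run to half the series by
default (bias/variance compromise; the spec of origins is not critical for
iid-origin synthetic data).

**Multiexponential fitting.** Bounded L-BFGS-B least squares on
$(a_i, \log\Phi_i, a_\infty)$ with $a_i \ge 0$, $0 \le a_\infty \le 1$ and
*no* sum-to-one constraint (published fits of this model do not impose
one; amplitude sums slightly above 1 occur). Initialisation is a fixed,
deterministic multistart: correlation-time combinations log-spaced over
the lag range, amplitudes from a linear projection at fixed $\Phi$,
the six best starts polished with analytic gradients. The model order is
the smallest $n$ for which adding an exponential improves the SSR by less
than 1%. Multiexponential fits are genuinely initialisation-sensitive;
determinism here is a test requirement, not a luxury.

**Tilt conventions.** The chain axis is the terminal→first-carbon vector;
its angle to the *outward* leaflet normal is folded to $[0°, 90°]$,
matching the usual presentation of gel-phase tilt distributions. Proximity
$R$ is a 3-D COM–COM distance with minimum-image treatment in the membrane
plane, restricted to same-leaflet probes. Variances are population
variances of the pooled angles.

**Confidence intervals.** 95% CIs for transverse positions use
per-molecule means as the independent units ($n$ = molecules), because
frames are autocorrelated in real data; whether block averaging was used
in the published error bars is not stated, so this is an interpretation,
and it is the conservative one for few-molecule probe groups.

**$S_{CD}$ reconstruction.** For united-atom/bead chains, C–H vectors at
interior carbons are rebuilt by tetrahedral geometry from the two chain
neighbours. For exactly collinear neighbours (the all-trans limit) the
construction is degenerate and the two perpendicular directions are used,
which reproduces the physical $S_{CD} = -\tfrac12$ of an all-trans chain
along the normal.

**RDF normalisation.** 3-D spherical-shell normalisation by bin volume and
mean selection density — the default of the standard MD tooling — even
though a bilayer is anisotropic; this matches how published probe–lipid
RDFs are computed. $N(r)$ counts per *reference atom* (the same tooling's
convention) and equals the cumulative bin counts, so $g$ and $N$ are
mutually consistent by construction. Intramolecular pairs are excluded by
default. Note that $N$ at a bin is the count within the bin's *upper
edge*; closed-form comparisons must use the edge radius.

**WHAM.** Self-consistent iteration on the window free energies to
$10^{-7}$ kJ/mol. Two choices differ from naive defaults, both forced by
the stiff-spring protocol ($k = 3000$ kJ mol⁻¹ nm⁻² gives a window SD of
0.029 nm): the default bin width is 0.01 nm, and the per-window Boltzmann
bias factors are *bin averages* computed in closed form from the Gaussian
CDF rather than bin-centre evaluations — across even a 0.02 nm bin the
bias varies by more than RT, and centre evaluation visibly distorts the
profile. The zero of energy defaults to the mean over a declared
water-plateau region; barrier extraction uses only the centre-to-water
branch (the pulled-from-water branch of such simulations is known to
suffer sampling artefacts, and published analyses discard it). The sign
convention makes favourable transfer negative, so deep interfacial minima
give $K_p \gg 1$.

## A statistical limitation worth knowing about

With 0.1-nm window spacing and $k = 3000$ kJ mol⁻¹ nm⁻², adjacent windows
sit 3.5 window-SDs apart: each window informs the local free-energy slope
and essentially nothing else. The slope estimate from $n$ iid samples has
SE $k\,\sigma/\sqrt n$, i.e. the free-energy increment per 0.1 nm stitch
carries ~0.12 kJ/mol of irreducible error at $n = 5000$; these errors
accumulate along the profile as a random walk, giving a centred-RMS floor
of roughly 0.3–0.6 kJ/mol for a 4–6 nm profile. This is an information
limit of the protocol, not of the estimator: the package's WHAM shows
clean $1/\sqrt n$ convergence (RMS 0.58 → 0.13 when $n$ is raised
5000 → 50000 in the flat-landscape test). Consequences: recovery
tolerances tighter than ~0.5 kJ/mol are only meaningful at elevated
sampling, and $K_p$, being exponential in a barrier difference, inherits
~±25% noise at 5000 samples/window. The test suite verifies the
implementation at 50000 samples/window and additionally asserts the
stated-sampling tolerances as-is; the latter sit at the floor and can fail
for individual seeds.

## Degenerate inputs and tie-breaks

* Proximity analysis without probes raises an error (the statistic is
  undefined), and a lipid whose leaflet has no probe falls in the far bin.
* Degenerate proximity edges (0.7 = 1.2) empty the mid bin; the three bins
  always partition the lipid set.
* `extract_barriers()` requires an interior minimum below the water
  plateau; a monotone or flat branch is a shape error, and a monotone
  decrease from water to the minimum gives a zero insertion barrier.
* Equilibration discard keeps exactly the frames with
  `time >= discard` and refuses to discard everything.
* Binary XTC/TRR input is refused with an explicit message (convert to
  GRO or the internal text format); the internal format round-trips
  coordinates bitwise at `%.17g` precision.

## Known limitations

* No Voronoi area decomposition, electron-density profiles, 2-D lateral
  RDFs, or orientation-dependent correlations.
* The rotational analysis reports $a_\infty \leftrightarrow S^2$
  relationships but does not infer cone angles from experimental
  anisotropy decays.
* MBAR is not implemented; WHAM with fine bins is statistically close to
  it for these stiff-window problems.
* Mean correlation times use the analytic integral of the decaying part,
  $\sum_i a_i\Phi_i$. For fits containing a large residual term plus very
  long correlation times, published "integration of the best fit"
  values are not always reproducible from the printed parameters; treat
  $\langle\Phi\rangle$ comparisons across sources with care.
* The umbrella sampler draws a plain 1-D coordinate; cylinder-restrained
  pull geometries used in real membrane protocols are not emulated.
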